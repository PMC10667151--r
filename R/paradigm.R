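#' Cuff-compression paradigm
#'
#' Describes the timing of a cuff-occlusion BOLD measurement: a resting
#' baseline, an arterial occlusion (thigh tourniquet inflated above systolic
#' pressure), and a post-occlusion period during which reactive hyperemia is
#' observed. Image frames are acquired continuously at interval `dt_s`, so the
#' paradigm also defines the acquisition clock.
#'
#' @param baseline_s Baseline duration in seconds before cuff inflation.
#' @param occlusion_s Occlusion (ischemic) duration in seconds; the study
#'   protocols use 300 s (5 min) or 90 s (1.5 min), but any positive value is
#'   accepted.
#' @param post_s Post-occlusion observation period in seconds.
#' @param dt_s Frame interval (temporal resolution of the T2* maps) in seconds.
#'
#' @return An object of class `cuff_paradigm` with fields `baseline_s`,
#'   `occlusion_s`, `post_s`, `dt_s`.
#' @examples
#' p <- cuff_paradigm(occlusion_s = 300)
#' n_frames(p)            # 207 frames for the 5-min protocol
#' frame_of_event(p, "inflation")
#' @export
cuff_paradigm <- function(baseline_s = 60, occlusion_s = 300, post_s = 300,
                          dt_s = 3.2) {
  for (v in c(baseline_s = baseline_s, occlusion_s = occlusion_s,
              post_s = post_s, dt_s = dt_s)) {
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("all paradigm durations and dt_s must be single positive numbers",
           call. = FALSE)
  }
  structure(list(baseline_s = baseline_s, occlusion_s = occlusion_s,
                 post_s = post_s, dt_s = dt_s),
            class = "cuff_paradigm")
}

#' @export
print.cuff_paradigm <- function(x, ...) {
  cat(sprintf(
    "<cuff_paradigm> baseline %gs | occlusion %gs | post %gs | dt %gs (%d frames)\n",
    x$baseline_s, x$occlusion_s, x$post_s, x$dt_s, n_frames(x)))
  invisible(x)
}

stopifnot_paradigm <- function(paradigm) {
  if (!inherits(paradigm, "cuff_paradigm"))
    stop("`paradigm` must be a cuff_paradigm object", call. = FALSE)
  paradigm
}

#' Multi-echo acquisition protocol
#'
#' Echo times and timing of the multi-echo gradient-echo (FLASH) readout used
#' to compute one T2* map per frame. Defaults follow the study protocol: 11
#' equidistant echoes from 2.0 to 40.0 ms, TR 44 ms.
#'
#' @param echo_times_ms Strictly increasing vector of at least two positive
#'   echo times, in milliseconds.
#' @param tr_ms Repetition time in milliseconds.
#' @param matrix In-plane matrix dimensions `c(nx, ny)`.
#' @param dt_s Frame interval in seconds (mirrors [cuff_paradigm()]).
#'
#' @return An object of class `acquisition_protocol`.
#' @export
acquisition_protocol <- function(echo_times_ms = seq(2.0, 40.0, by = 3.8),
                                 tr_ms = 44, matrix = c(64L, 64L), dt_s = 3.2) {
  if (length(echo_times_ms) < 2L || any(echo_times_ms <= 0) ||
      any(diff(echo_times_ms) <= 0))
    stop("echo_times_ms must be >= 2 strictly increasing positive values",
         call. = FALSE)
  if (tr_ms <= 0 || dt_s <= 0) stop("tr_ms and dt_s must be positive",
                                    call. = FALSE)
  matrix <- as.integer(matrix)
  if (length(matrix) != 2L || any(matrix < 1L))
    stop("matrix must be two positive integers", call. = FALSE)
  structure(list(echo_times_ms = as.numeric(echo_times_ms), tr_ms = tr_ms,
                 matrix = matrix, dt_s = dt_s),
            class = "acquisition_protocol")
}

#' Number of frames covering a paradigm
#'
#' Acquisition runs continuously over baseline + occlusion + post-occlusion,
#' so the frame count is the ceiling of total duration over the frame
#' interval: 207 frames for the 5-min and 141 for the 1.5-min occlusion at
#' dt = 3.2 s.
#'
#' @param paradigm A [cuff_paradigm()].
#' @return A positive integer frame count.
#' @export
n_frames <- function(paradigm) {
  stopifnot_paradigm(paradigm)
  total <- paradigm$baseline_s + paradigm$occlusion_s + paradigm$post_s
  as.integer(ceiling(total / paradigm$dt_s - 1e-9))
}

#' Frame index of a paradigm event
#'
#' Returns the 1-based index of the frame during which the cuff event occurs,
#' `ceiling(t_event / dt_s)`: inflation happens at the end of the baseline,
#' deflation at the end of the occlusion. For the default protocols this gives
#' inflation during frame 19 and deflation during frame 47 (short occlusion).
#'
#' @param paradigm A [cuff_paradigm()].
#' @param event `"inflation"` or `"deflation"`.
#' @return 1-based integer frame index.
#' @export
frame_of_event <- function(paradigm, event = c("inflation", "deflation")) {
  stopifnot_paradigm(paradigm)
  event <- match.arg(event)
  t_event <- event_time(paradigm, event)
  total <- paradigm$baseline_s + paradigm$occlusion_s + paradigm$post_s
  if (t_event > total)
    stop("event time lies beyond the end of the paradigm", call. = FALSE)
  # exact multiples of dt land in the frame they terminate
  as.integer(ceiling(t_event / paradigm$dt_s - 1e-9))
}

event_time <- function(paradigm, event) {
  switch(event,
         inflation = paradigm$baseline_s,
         deflation = paradigm$baseline_s + paradigm$occlusion_s,
         stop("unknown event", call. = FALSE))
}

#' Frame mid-times
#'
#' Mid-frame timestamps in seconds: frame k spans `[(k-1)*dt, k*dt]` and is
#' stamped at its centre, since each T2* map integrates signal over its
#' acquisition window.
#'
#' @param paradigm A [cuff_paradigm()].
#' @return Numeric vector of length [n_frames()].
#' @export
time_axis <- function(paradigm) {
  stopifnot_paradigm(paradigm)
  (seq_len(n_frames(paradigm)) - 0.5) * paradigm$dt_s
}
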