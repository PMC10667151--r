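#' ROI label mask
#'
#' Integer label image delineating the analysed muscles. Convention: 1 =
#' gastrocnemius, 2 = soleus, 0 = background.
#'
#' @param labels 2D integer matrix of non-negative labels.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(labels) {
  if (length(dim(labels)) != 2L) stop("labels must be a 2D matrix",
                                      call. = FALSE)
  if (any(labels < 0) || any(labels != round(labels)))
    stop("labels must be non-negative integers", call. = FALSE)
  structure(list(labels = labels), class = "roi_mask")
}

#' Names of the muscle labels
#' @param label Integer label code.
#' @return Character name ("gastrocnemius", "soleus", or "roiN").
#' @export
muscle_name <- function(label) {
  ifelse(label == 1L, "gastrocnemius",
         ifelse(label == 2L, "soleus", paste0("roi", label)))
}

#' ROI T2*-time curve
#'
#' Per-frame ROI-mean T2* values, optionally baseline normalised.
#'
#' @param times_s Frame mid-times in seconds.
#' @param t2star_ms ROI-mean T2* per frame (ms).
#' @param roi_label Integer ROI code.
#' @param normalized Optional normalised values (curve / baseline mean).
#' @param t2init_ms Baseline mean T2* used for normalisation.
#' @param baseline_frames Frame index range used for the baseline mean.
#' @param missing_frames Indices of frames with no valid voxel (interpolated).
#' @return An object of class `time_curve`.
#' @export
time_curve <- function(times_s, t2star_ms, roi_label = 1L, normalized = NULL,
                       t2init_ms = NA_real_, baseline_frames = NULL,
                       missing_frames = integer()) {
  if (length(times_s) != length(t2star_ms))
    stop("times_s and t2star_ms lengths differ", call. = FALSE)
  if (!is.null(normalized) && length(normalized) != length(times_s))
    stop("normalized length differs from times_s", call. = FALSE)
  structure(list(times_s = times_s, t2star_ms = t2star_ms,
                 normalized = normalized, t2init_ms = t2init_ms,
                 baseline_frames = baseline_frames, roi_label = roi_label,
                 missing_frames = missing_frames),
            class = "time_curve")
}

#' @export
print.time_curve <- function(x, ...) {
  cat(sprintf("<time_curve> %s, %d frames%s%s\n",
              muscle_name(x$roi_label), length(x$times_s),
              if (!is.null(x$normalized)) sprintf(", normalised (T2*init %.2f ms)",
                                                  x$t2init_ms) else "",
              if (length(x$missing_frames)) sprintf(", %d interpolated frames",
                                                    length(x$missing_frames)) else ""))
  invisible(x)
}

#' Extract a ROI-mean T2*-time curve
#'
#' For each frame, averages the valid voxel-wise T2* estimates within the
#' requested label. The mask is fixed across frames (registration-based ROI
#' propagation is out of scope). Frames in which no voxel has a valid fit are
#' linearly interpolated from their neighbours, with a warning, so downstream
#' model fitting sees a complete grid; their indices are recorded in
#' `missing_frames`.
#'
#' @param t2series A `t2star_series` from [fit_t2star_series()].
#' @param mask A [roi_mask()] with matching in-plane dimensions.
#' @param label Integer label to extract (must be present in the mask).
#' @return An unnormalised [time_curve()].
#' @export
extract_curve <- function(t2series, mask, label = 1L) {
  stopifnot(inherits(t2series, "t2star_series"), inherits(mask, "roi_mask"))
  d <- dim(t2series$t2star_ms)
  if (!all(dim(mask$labels) == d[1:2]))
    stop("mask dimensions do not match the T2* maps", call. = FALSE)
  sel <- mask$labels == label
  if (!any(sel)) stop(sprintf("label %d absent from mask", label),
                      call. = FALSE)
  nf <- d[3]
  vox <- matrix(t2series$t2star_ms, nrow = d[1] * d[2], ncol = nf)[sel, ,
                                                                   drop = FALSE]
  ok <- matrix(t2series$valid_mask, nrow = d[1] * d[2], ncol = nf)[sel, ,
                                                                   drop = FALSE]
  vox[!ok] <- NA_real_
  means <- colMeans(vox, na.rm = TRUE)
  means[colSums(ok) == 0L] <- NA_real_

  missing <- which(!is.finite(means))
  if (length(missing)) {
    if (length(missing) == nf)
      stop("no frame has a valid voxel for this label", call. = FALSE)
    warning(sprintf("%d frame(s) without valid voxels interpolated for label %d",
                    length(missing), label), call. = FALSE)
    means <- stats::approx(x = which(is.finite(means)),
                           y = means[is.finite(means)],
                           xout = seq_len(nf), rule = 2)$y
  }
  times <- (seq_len(nf) - 0.5) * t2series$dt_s
  time_curve(times_s = times, t2star_ms = means, roi_label = as.integer(label),
             missing_frames = missing)
}

#' Baseline-normalise a T2*-time curve
#'
#' Divides the curve by its mean over the pre-inflation baseline window
#' (frames 1 to `frame_of_event(paradigm, "inflation") - 1`; the inflation
#' frame itself straddles the event and is excluded). The baseline mean is
#' recorded as the initial T2* (`t2init_ms`).
#'
#' Normalisation is idempotent up to bookkeeping: renormalising an already
#' normalised curve leaves the values unchanged and sets `t2init_ms` to 1.
#'
#' @param curve A [time_curve()].
#' @param paradigm The [cuff_paradigm()] defining the baseline window.
#' @return The curve with `normalized`, `t2init_ms` and `baseline_frames`
#'   filled in.
#' @export
normalize_baseline <- function(curve, paradigm) {
  stopifnot(inherits(curve, "time_curve"))
  stopifnot_paradigm(paradigm)
  last_base <- frame_of_event(paradigm, "inflation") - 1L
  if (last_base < 1L || length(curve$t2star_ms) < last_base)
    stop("empty baseline window: paradigm baseline shorter than one frame",
         call. = FALSE)
  base <- mean(curve$t2star_ms[seq_len(last_base)])
  if (!is.finite(base) || base <= 0)
    stop("baseline mean is not positive; cannot normalise", call. = FALSE)
  curve$normalized <- curve$t2star_ms / base
  curve$t2init_ms <- base
  curve$baseline_frames <- c(1L, last_base)
  curve
}

#' Curves as a data frame
#'
#' Long-format export of one or more time curves, matching the CSV layout
#' `subject, session, measurement, roi, frame, time_s, t2star_ms, normalized`.
#'
#' @param curves A `time_curve` or list of them.
#' @param subject,session,measurement Identifier columns recycled across rows.
#' @return A `data.frame`.
#' @export
curves_to_df <- function(curves, subject = 1L, session = 1L,
                         measurement = 1L) {
  if (inherits(curves, "time_curve")) curves <- list(curves)
  do.call(rbind, lapply(curves, function(cv) {
    data.frame(subject = subject, session = session,
               measurement = measurement, roi = muscle_name(cv$roi_label),
               frame = seq_along(cv$times_s), time_s = cv$times_s,
               t2star_ms = cv$t2star_ms,
               normalized = if (is.null(cv$normalized)) NA_real_ else
                 cv$normalized)
  }))
}
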