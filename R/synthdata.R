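#' Reference BOLD parameter targets for healthy calf muscle
#'
#' Median semi-quantitative parameter values reported for healthy adults, per
#' muscle and occlusion duration, used as the default ground truth of the
#' synthetic generator: baseline T2* ~26 ms, ischemic dip to 0.94-0.96 of
#' baseline, hyperemic overshoot to 1.02-1.08 peaking ~28-32 s after cuff
#' release. Slopes are in unscaled ms/s (reports multiply them by 100).
#'
#' @param muscle `"gastrocnemius"` or `"soleus"`.
#' @param occlusion `"long"` (5 min) or `"short"` (1.5 min).
#' @return Named list of the eight target parameters.
#' @export
default_targets <- function(muscle = c("gastrocnemius", "soleus"),
                            occlusion = c("long", "short")) {
  muscle <- match.arg(muscle)
  occlusion <- match.arg(occlusion)
  tab <- list(
    gastrocnemius = list(
      long  = list(t2init_ms = 26.3, is_down_ms_per_s = 0.024, miv_au = 0.96,
                   hs_up_ms_per_s = 0.379, tthp_s = 15.8, ttp_s = 31.7,
                   hpv_au = 1.04, tthr_s = 60.4),
      short = list(t2init_ms = 26.3, is_down_ms_per_s = 0.021, miv_au = 0.96,
                   hs_up_ms_per_s = 0.250, tthp_s = 9.8, ttp_s = 27.7,
                   hpv_au = 1.02, tthr_s = 91.7)),
    soleus = list(
      long  = list(t2init_ms = 25.1, is_down_ms_per_s = 0.037, miv_au = 0.94,
                   hs_up_ms_per_s = 0.783, tthp_s = 12.9, ttp_s = 28.8,
                   hpv_au = 1.08, tthr_s = 78.8),
      short = list(t2init_ms = 25.5, is_down_ms_per_s = 0.037, miv_au = 0.94,
                   hs_up_ms_per_s = 0.423, tthp_s = 9.2, ttp_s = 29.1,
                   hpv_au = 1.06, tthr_s = 136.5)))
  tab[[muscle]][[occlusion]]
}

#' Tissue specification for the synthetic phantom
#'
#' @param label Integer ROI code (1 = gastrocnemius, 2 = soleus).
#' @param t2init_ms Baseline T2* in ms.
#' @param s0 Proton-density signal scale (arbitrary units).
#' @param truth A [descriptive_params()] ground-truth normalised trajectory.
#' @param heterogeneity_frac Voxel-wise multiplicative (log-normal) spread of
#'   the baseline T2* within the tissue.
#' @return An object of class `tissue_spec`.
#' @export
tissue_spec <- function(label, t2init_ms, s0 = 1000, truth,
                        heterogeneity_frac = 0.05) {
  stopifnot(t2init_ms > 0, s0 > 0, heterogeneity_frac >= 0)
  if (!inherits(truth, "descriptive_params"))
    stop("truth must be a descriptive_params object", call. = FALSE)
  structure(list(label = as.integer(label), t2init_ms = t2init_ms, s0 = s0,
                 truth = truth, heterogeneity_frac = heterogeneity_frac),
            class = "tissue_spec")
}

#' Default two-muscle tissue set
#'
#' Gastrocnemius (label 1) and soleus (label 2) with ground truths built from
#' [default_targets()] for the given paradigm's occlusion duration.
#'
#' @param paradigm A [cuff_paradigm()]; occlusions >= 200 s select the "long"
#'   targets, shorter ones the "short" targets.
#' @param heterogeneity_frac Passed to [tissue_spec()].
#' @return List of two `tissue_spec` objects.
#' @export
default_tissues <- function(paradigm, heterogeneity_frac = 0.05) {
  stopifnot_paradigm(paradigm)
  occ <- if (paradigm$occlusion_s >= 200) "long" else "short"
  lapply(c(gastrocnemius = 1L, soleus = 2L), function(lab) {
    tg <- default_targets(muscle_name(lab), occ)
    tissue_spec(label = lab, t2init_ms = tg$t2init_ms,
                truth = truth_from_targets(tg, paradigm),
                heterogeneity_frac = heterogeneity_frac)
  })
}

#' Phantom configuration
#'
#' Geometry, noise and seed of the synthetic 2D calf cross-section: two
#' non-overlapping ellipses (one per muscle) on a background at the noise
#' floor. Ellipses are given in fractional image coordinates.
#'
#' @param matrix In-plane dimensions `c(nx, ny)`.
#' @param ellipses List (one per tissue, in label order) of
#'   `list(center = c(fx, fy), radii = c(fx, fy))` in units of the matrix.
#' @param noise_sigma Noise scale relative to the tissue signal scale `s0`.
#' @param noise_model `"rician"` (magnitude of signal plus complex Gaussian),
#'   `"gaussian"` (real additive, clamped at zero), or `"none"`.
#' @param motion_amplitude_px Amplitude of a deterministic sinusoidal
#'   in-plane translation (integer pixels per frame); 0 disables motion.
#' @param seed RNG seed; a fixed seed makes the rendered series
#'   byte-identical across calls.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(matrix = c(64L, 64L),
                           ellipses = list(
                             list(center = c(0.30, 0.50), radii = c(0.18, 0.30)),
                             list(center = c(0.72, 0.50), radii = c(0.18, 0.26))),
                           noise_sigma = 0.02,
                           noise_model = c("rician", "gaussian", "none"),
                           motion_amplitude_px = 0, seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (noise_sigma < 0) stop("noise_sigma must be >= 0", call. = FALSE)
  matrix <- as.integer(matrix)
  stopifnot(length(matrix) == 2L, all(matrix >= 8L))
  for (e in ellipses) {
    if (any(e$center - e$radii < 0) || any(e$center + e$radii > 1))
      stop("ellipse extends outside the image matrix", call. = FALSE)
  }
  structure(list(matrix = matrix, ellipses = ellipses,
                 noise_sigma = noise_sigma, noise_model = noise_model,
                 motion_amplitude_px = motion_amplitude_px,
                 seed = as.integer(seed)),
            class = "phantom_config")
}

ellipse_mask <- function(matrix, ellipse) {
  nx <- matrix[1]; ny <- matrix[2]
  x <- (seq_len(nx) - 0.5) / nx
  y <- (seq_len(ny) - 0.5) / ny
  dx <- (x - ellipse$center[1]) / ellipse$radii[1]
  dy <- (y - ellipse$center[2]) / ellipse$radii[2]
  outer(dx^2, dy^2, `+`) <= 1
}

#' Noiseless ground-truth curve for a paradigm
#'
#' Evaluates a ground-truth parameter set on the paradigm's frame grid. The
#' result is exactly 1 throughout the baseline segment.
#'
#' @param truth A [descriptive_params()] object.
#' @param paradigm A [cuff_paradigm()].
#' @return A normalised [time_curve()] (values dimensionless).
#' @export
truth_curve <- function(truth, paradigm) {
  stopifnot_paradigm(paradigm)
  y <- model_eval(truth, time_axis(paradigm))
  time_curve(times_s = time_axis(paradigm), t2star_ms = y, normalized = y,
             t2init_ms = 1)
}

#' Render a synthetic multi-echo series
#'
#' Builds the 4D magnitude stack: every tissue voxel decays
#' mono-exponentially over the echo train, `S = s0 * exp(-TE / T2*(t))`, with
#' `T2*(t) = t2init_voxel * y_truth(t)` following the tissue's ground-truth
#' normalised trajectory. Voxel baseline T2* values are drawn log-normally
#' around the tissue value with spread `heterogeneity_frac` (multiplicative
#' heterogeneity, constant in time, cancels in the normalised ROI curve).
#' Noise is applied per `noise_model` with absolute scale
#' `noise_sigma * s0`; background voxels contain pure noise.
#'
#' @param phantom A [phantom_config()].
#' @param tissues List of [tissue_spec()] (default [default_tissues()]).
#' @param paradigm A [cuff_paradigm()].
#' @param protocol An [acquisition_protocol()].
#' @return List with `series` ([multi_echo_series()]), `mask` ([roi_mask()]),
#'   and `truth` (a ground-truth record: per-tissue model parameters, the
#'   implied BOLD parameters, the voxel-wise baseline T2* map, paradigm and
#'   seed).
#' @export
render_series <- function(phantom = phantom_config(),
                          tissues = default_tissues(paradigm),
                          paradigm = cuff_paradigm(),
                          protocol = acquisition_protocol(dt_s = paradigm$dt_s)) {
  stopifnot(inherits(phantom, "phantom_config"))
  stopifnot_paradigm(paradigm)
  if (length(tissues) > length(phantom$ellipses))
    stop("more tissues than configured ellipses", call. = FALSE)

  nx <- phantom$matrix[1]; ny <- phantom$matrix[2]
  te <- protocol$echo_times_ms
  ne <- length(te)
  nf <- n_frames(paradigm)
  t <- time_axis(paradigm)

  masks <- lapply(phantom$ellipses[seq_along(tissues)],
                  ellipse_mask, matrix = phantom$matrix)
  if (length(masks) > 1L) {
    overlap <- Reduce(`+`, lapply(masks, function(m) m * 1L))
    if (any(overlap > 1L)) stop("configured ROIs overlap", call. = FALSE)
  }
  labels <- matrix(0L, nx, ny)
  for (i in seq_along(tissues)) labels[masks[[i]]] <- tissues[[i]]$label

  set.seed(phantom$seed)
  img <- array(0, dim = c(nx, ny, ne, nf))
  t2init_map <- matrix(NA_real_, nx, ny)
  truth_tissues <- list()
  for (i in seq_along(tissues)) {
    ts <- tissues[[i]]
    vox <- which(masks[[i]])
    nv <- length(vox)
    sdlog <- sqrt(log(1 + ts$heterogeneity_frac^2))
    t2v <- ts$t2init_ms * exp(stats::rnorm(nv, 0, sdlog))
    t2init_map[vox] <- t2v
    ytruth <- model_eval(ts$truth, t)
    t2_vt <- outer(t2v, ytruth)                       # voxel x frame
    for (e in seq_len(ne)) {
      sl <- ts$s0 * exp(-te[e] / t2_vt)
      idx <- rep(vox, times = nf) +
        (nx * ny) * ((e - 1L) + ne * rep(seq_len(nf) - 1L, each = nv))
      img[idx] <- sl
    }
    # the realized ROI-mean baseline is the mean of the drawn voxel values,
    # so the stored BOLD truth scales slopes/T2*init by that, not the nominal
    truth_tissues[[muscle_name(ts$label)]] <- list(
      label = ts$label, t2init_ms = ts$t2init_ms,
      t2init_roi_ms = mean(t2v), s0 = ts$s0, params = ts$truth,
      bold = derive_parameters(ts$truth, mean(t2v), paradigm))
  }

  if (phantom$motion_amplitude_px > 0) {
    # rigid integer-pixel sinusoidal drift along x (period 20 frames),
    # nearest-neighbour resampling with zero fill at the edges
    for (k in seq_len(nf)) {
      dx <- round(phantom$motion_amplitude_px * sin(2 * pi * k / 20))
      if (dx != 0) {
        shifted <- array(0, dim = c(nx, ny, ne))
        src <- seq_len(nx) - dx
        keep <- src >= 1 & src <= nx
        shifted[keep, , ] <- img[src[keep], , , k]
        img[, , , k] <- shifted
      }
    }
  }

  s0_ref <- mean(vapply(tissues, `[[`, numeric(1), "s0"))
  sigma <- phantom$noise_sigma * s0_ref
  if (phantom$noise_model == "rician" && sigma > 0) {
    n <- length(img)
    img <- sqrt((img + stats::rnorm(n, 0, sigma))^2 +
                  stats::rnorm(n, 0, sigma)^2)
  } else if (phantom$noise_model == "gaussian" && sigma > 0) {
    img <- pmax(img + stats::rnorm(length(img), 0, sigma), 0)
  }

  list(
    series = multi_echo_series(img, te, paradigm$dt_s,
                               meta = list(seed = phantom$seed,
                                           noise_model = phantom$noise_model,
                                           noise_sigma = phantom$noise_sigma)),
    mask = roi_mask(labels),
    truth = list(tissues = truth_tissues, t2init_map = t2init_map,
                 paradigm = paradigm, seed = phantom$seed)
  )
}

#' Simulate a cohort of synthetic measurements
#'
#' Draws per-subject ground-truth BOLD parameters log-normally around the
#' [default_targets()] with the supplied coefficients of variation, then
#' renders one measurement per design row. All measurements of a subject
#' share the subject-level truth draw; a smaller per-measurement log-normal
#' jitter (`measurement_cv`) emulates within-session physiological
#' variability. Paired designs (long/short occlusion per subject, repeated
#' measurements per session) are expressed through the `design` table.
#'
#' Variability is parameterised on the physiological scale: CVs apply to
#' `t2init`, `is_down`, `miv_depth` (= 1 - MIV), `hs_up`, `tthp`, `ttp`,
#' `hpv_rise` (= HPV - 1) and `tthr`, which keeps all levels and durations on
#' their physical side of baseline.
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param design `data.frame` with columns `session`, `measurement`,
#'   `occlusion_s`; one rendered series per subject x row. Default: one 5-min
#'   and one 1.5-min session per subject.
#' @param variability Named CVs (fractions, >= 0) for the components above;
#'   unnamed components fall back to the defaults.
#' @param measurement_cv Per-measurement jitter CV applied to every component.
#' @param phantom A [phantom_config()] template (its seed is re-drawn per
#'   series from the cohort stream).
#' @param baseline_s,post_s,dt_s Paradigm timing shared by all measurements.
#' @param render If `FALSE`, skip image rendering and return only ground
#'   truth (fast cohort-level studies on curves).
#' @param seed Cohort RNG seed; fixes every draw and every rendered byte.
#' @return List of records: `subject`, `session`, `measurement`,
#'   `occlusion_s`, `paradigm`, `targets` (the drawn truth targets), `truth`,
#'   `series`, `mask` (the latter two `NULL` when `render = FALSE`).
#' @export
simulate_cohort <- function(n_subjects,
                            design = data.frame(
                              session = c(1L, 2L), measurement = c(1L, 1L),
                              occlusion_s = c(300, 90)),
                            variability = NULL, measurement_cv = 0.03,
                            phantom = phantom_config(matrix = c(32L, 32L)),
                            baseline_s = 60, post_s = 300, dt_s = 3.2,
                            render = TRUE, seed = 1L) {
  stopifnot(n_subjects >= 1)
  default_cv <- c(t2init = 0.06, is_down = 0.25, miv_depth = 0.20,
                  hs_up = 0.35, tthp = 0.18, ttp = 0.18, hpv_rise = 0.35,
                  tthr = 0.25)
  cv <- default_cv
  if (!is.null(variability)) {
    bad <- setdiff(names(variability), names(default_cv))
    if (length(bad)) stop("unknown variability component(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    if (any(unlist(variability) < 0)) stop("CVs must be >= 0", call. = FALSE)
    cv[names(variability)] <- unlist(variability)
  }
  if (measurement_cv < 0) stop("measurement_cv must be >= 0", call. = FALSE)

  set.seed(seed)
  sdlog <- function(v) sqrt(log(1 + v^2))
  draw_mult <- function(cvs) stats::setNames(
    exp(stats::rnorm(length(cvs), 0, sdlog(cvs))), names(cvs))

  perturb <- function(tg, mult) {
    out <- tg
    out$t2init_ms <- tg$t2init_ms * mult[["t2init"]]
    out$is_down_ms_per_s <- tg$is_down_ms_per_s * mult[["is_down"]]
    out$miv_au <- 1 - (1 - tg$miv_au) * mult[["miv_depth"]]
    out$hs_up_ms_per_s <- tg$hs_up_ms_per_s * mult[["hs_up"]]
    out$tthp_s <- tg$tthp_s * mult[["tthp"]]
    out$ttp_s <- tg$ttp_s * mult[["ttp"]]
    out$hpv_au <- 1 + (tg$hpv_au - 1) * mult[["hpv_rise"]]
    out$tthr_s <- tg$tthr_s * mult[["tthr"]]
    out
  }

  records <- list()
  for (s in seq_len(n_subjects)) {
    # rejection-resample the whole subject if any of its measurements yields
    # physiologically inconsistent targets (tthp >= ttp, sub-secant initial
    # slope, ...); the subject-level draw itself can be the culprit, so it is
    # redrawn together with the measurement jitters
    subj_rows <- NULL
    for (attempt in 1:40) {
      subj_mult <- draw_mult(cv)
      rows_try <- vector("list", nrow(design))
      ok <- TRUE
      for (rix in seq_len(nrow(design))) {
        row <- design[rix, ]
        paradigm <- cuff_paradigm(baseline_s = baseline_s,
                                  occlusion_s = row$occlusion_s,
                                  post_s = post_s, dt_s = dt_s)
        occ <- if (row$occlusion_s >= 200) "long" else "short"
        meas_mult <- draw_mult(stats::setNames(rep(measurement_cv,
                                                   length(cv)), names(cv)))
        tissues_try <- tryCatch({
          lapply(c(gastrocnemius = 1L, soleus = 2L), function(lab) {
            tg <- perturb(default_targets(muscle_name(lab), occ),
                          subj_mult * meas_mult)
            list(targets = tg,
                 spec = tissue_spec(label = lab, t2init_ms = tg$t2init_ms,
                                    truth = truth_from_targets(tg, paradigm)))
          })
        }, error = function(e) NULL)
        if (is.null(tissues_try)) { ok <- FALSE; break }
        rows_try[[rix]] <- list(paradigm = paradigm, row = row,
                                tissues = lapply(tissues_try, `[[`, "spec"),
                                targets = lapply(tissues_try, `[[`,
                                                 "targets"))
      }
      if (ok) { subj_rows <- rows_try; break }
    }
    if (is.null(subj_rows))
      stop("could not draw consistent truth targets; reduce the CVs",
           call. = FALSE)

    for (rix in seq_len(nrow(design))) {
      paradigm <- subj_rows[[rix]]$paradigm
      row <- subj_rows[[rix]]$row
      tissues <- subj_rows[[rix]]$tissues
      targets <- subj_rows[[rix]]$targets

      rec <- list(subject = s, session = row$session,
                  measurement = row$measurement,
                  occlusion_s = row$occlusion_s, paradigm = paradigm,
                  targets = targets, series = NULL, mask = NULL, truth = NULL)
      if (render) {
        ph <- phantom
        ph$seed <- sample.int(.Machine$integer.max - 1L, 1L)
        rendered <- render_series(ph, tissues, paradigm,
                                  acquisition_protocol(dt_s = dt_s))
        rec$series <- rendered$series
        rec$mask <- rendered$mask
        rec$truth <- rendered$truth
      } else {
        rec$truth <- list(
          tissues = lapply(tissues, function(ts) list(
            label = ts$label, t2init_ms = ts$t2init_ms, s0 = ts$s0,
            params = ts$truth,
            bold = derive_parameters(ts$truth, ts$t2init_ms, paradigm))),
          paradigm = paradigm, seed = NA_integer_)
      }
      records[[length(records) + 1L]] <- rec
    }
  }
  records
}
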