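#' Piecewise descriptive model of the cuff-occlusion T2* response
#'
#' The baseline-normalised T2*-time curve of skeletal muscle under arterial
#' occlusion and release is described by four segments joined continuously at
#' the knots `t0 < t1 <= tm <= t2`:
#'
#' * **A — baseline** (`t < t0`): constant level `b` (approximately 1 after
#'   normalisation).
#' * **B — ischemic decline** (`t0 <= t < t1`): exponential approach from `b`
#'   towards the ischemic plateau `m` with time constant `tau1`, reflecting
#'   deoxyhemoglobin accumulation after cuff inflation.
#' * **C — hyperemic rise** (`t1 <= t < t2`): after cuff release the curve
#'   rises along a logistic with midpoint `tm` and steepness `tau2`, anchored
#'   so the segment starts exactly at the value segment B reached at `t1` and
#'   approaches the asymptote `p`.
#' * **D — recovery** (`t >= t2`): exponential relaxation from the hyperemic
#'   peak value (the model value at `t2`) towards the recovery level `r` with
#'   time constant `tau3`.
#'
#' @param b Baseline level (normalised units, ~1).
#' @param m Ischemic plateau level, `0 < m <= b`.
#' @param t0_s Occlusion-onset knot (seconds; cuff inflation).
#' @param tau1_s Ischemic decay time constant (s).
#' @param t1_s Hyperemic-rise onset knot (s; cuff deflation).
#' @param tm_s Logistic midpoint of the rise (s).
#' @param tau2_s Logistic steepness constant (s).
#' @param p Logistic asymptote of the rise (normalised units).
#' @param t2_s Hyperemic peak knot (s).
#' @param r Recovery asymptote level (normalised units).
#' @param tau3_s Recovery decay time constant (s).
#'
#' @return An object of class `descriptive_params`.
#' @seealso [model_eval()], [fit_model()], [derive_parameters()]
#' @export
descriptive_params <- function(b = 1, m = 0.96, t0_s = 60, tau1_s = 45,
                               t1_s = 360, tm_s = 376, tau2_s = 1.5, p = 1.04,
                               t2_s = 392, r = 1, tau3_s = 87) {
  par <- list(b = b, m = m, t0_s = t0_s, tau1_s = tau1_s, t1_s = t1_s,
              tm_s = tm_s, tau2_s = tau2_s, p = p, t2_s = t2_s, r = r,
              tau3_s = tau3_s)
  if (any(!vapply(par, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1L))))
    stop("all model parameters must be finite scalars", call. = FALSE)
  validate_params(par)
  structure(par, class = "descriptive_params")
}

validate_params <- function(par) {
  with(par, {
    if (!(t0_s < t1_s)) stop("knot order violated: need t0 < t1", call. = FALSE)
    if (!(t1_s < tm_s)) stop("knot order violated: need t1 < tm", call. = FALSE)
    if (!(tm_s <= t2_s)) stop("knot order violated: need tm <= t2", call. = FALSE)
    if (tau1_s <= 0 || tau2_s <= 0 || tau3_s <= 0)
      stop("time constants tau1, tau2, tau3 must be positive", call. = FALSE)
    if (m <= 0 || m > b) stop("need 0 < m <= b", call. = FALSE)
  })
  invisible(par)
}

#' @export
print.descriptive_params <- function(x, ...) {
  cat("<descriptive_params>\n")
  cat(sprintf("  levels: b=%.4f m=%.4f p=%.4f r=%.4f\n", x$b, x$m, x$p, x$r))
  cat(sprintf("  knots:  t0=%.1fs t1=%.1fs tm=%.1fs t2=%.1fs\n",
              x$t0_s, x$t1_s, x$tm_s, x$t2_s))
  cat(sprintf("  taus:   tau1=%.2fs tau2=%.2fs tau3=%.2fs\n",
              x$tau1_s, x$tau2_s, x$tau3_s))
  invisible(x)
}

# Forward function without invariant checks; used inside the optimiser where
# intermediate parameter sets may sit on constraint boundaries.
model_eval_unsafe <- function(par, t_s) {
  b <- par$b; m <- par$m; t0 <- par$t0_s; tau1 <- par$tau1_s
  t1 <- par$t1_s; tm <- par$tm_s; tau2 <- par$tau2_s; p <- par$p
  t2 <- par$t2_s; r <- par$r; tau3 <- par$tau3_s

  y1 <- m + (b - m) * exp(-(t1 - t0) / tau1)     # segment-B value at deflation
  s1 <- stats::plogis((t1 - tm) / tau2)
  rise <- function(t) {
    L <- (stats::plogis((t - tm) / tau2) - s1) / (1 - s1)
    y1 + (p - y1) * L
  }
  hpv <- rise(t2)

  y <- numeric(length(t_s))
  iA <- t_s < t0
  iB <- t_s >= t0 & t_s < t1
  iC <- t_s >= t1 & t_s < t2
  iD <- t_s >= t2
  y[iA] <- b
  y[iB] <- m + (b - m) * exp(-(t_s[iB] - t0) / tau1)
  y[iC] <- rise(t_s[iC])
  y[iD] <- r + (hpv - r) * exp(-(t_s[iD] - t2) / tau3)
  y
}

#' Evaluate the descriptive model
#'
#' @param params A [descriptive_params()] object.
#' @param t_s Numeric vector of times in seconds.
#' @return Normalised model values, continuous across all knots.
#' @examples
#' par <- descriptive_params()
#' model_eval(par, c(0, 200, 370, 392, 600))
#' @export
model_eval <- function(params, t_s) {
  if (!inherits(params, "descriptive_params"))
    params <- do.call(descriptive_params, as.list(params))
  validate_params(params)
  model_eval_unsafe(params, t_s)
}

# Segment-B value at the deflation knot (start level of the rise).
model_y1 <- function(par) {
  par$m + (par$b - par$m) * exp(-(par$t1_s - par$t0_s) / par$tau1_s)
}

# Model value at the peak knot t2 (the hyperemic peak value).
model_hpv <- function(par) {
  y1 <- model_y1(par)
  s1 <- stats::plogis((par$t1_s - par$tm_s) / par$tau2_s)
  s2 <- stats::plogis((par$t2_s - par$tm_s) / par$tau2_s)
  y1 + (par$p - y1) * (s2 - s1) / (1 - s1)
}

# Maximum slope of the rise segment on [t1, t2] in normalised units per
# second. The logistic derivative sig*(1-sig)/tau2 is unimodal with its peak
# at tm, so the maximum sits at tm when tm is interior, else at the nearer
# boundary.
model_max_rise_slope <- function(par) {
  y1 <- model_y1(par)
  s1 <- stats::plogis((par$t1_s - par$tm_s) / par$tau2_s)
  amp <- (par$p - y1) / (1 - s1)
  dsig <- function(t) {
    s <- stats::plogis((t - par$tm_s) / par$tau2_s)
    s * (1 - s) / par$tau2_s
  }
  t_star <- min(max(par$tm_s, par$t1_s), par$t2_s)
  amp * dsig(t_star)
}

#' Derive the eight semi-quantitative BOLD parameters
#'
#' Converts a fitted piecewise model into the standard descriptors of the
#' cuff-occlusion BOLD response:
#'
#' * `t2init_ms` — baseline T2* (the normalisation constant, passed through);
#' * `is_down_ms_per_s` — magnitude of the initial ischemic declining slope,
#'   the model slope at occlusion onset, `(b - m)/tau1`, scaled to ms/s by
#'   `t2init_ms`;
#' * `miv_au` — minimum ischemic value, the model minimum over the occlusion
#'   interval (the segment-B value at deflation for this monotone segment);
#' * `hs_up_ms_per_s` — hyperemic upslope, the maximum model slope on the rise
#'   segment, scaled to ms/s;
#' * `tthp_s` — time from cuff release until the model first crosses the
#'   midpoint between its pre-release value and the hyperemic peak;
#' * `ttp_s` — time from cuff release to the peak knot `t2`;
#' * `hpv_au` — hyperemic peak value, the model value at `t2`;
#' * `tthr_s` — time from the peak until the recovery segment has decayed
#'   halfway towards its asymptote, `ln(2) * tau3` in closed form.
#'
#' Crossing times are located by bisection on the continuous model, not on the
#' sampled grid. If the rise amplitude is not positive the hyperemic
#' parameters are returned as `NA` and flagged.
#'
#' @param params A [descriptive_params()] object (typically from
#'   [fit_model()]).
#' @param t2init_ms Baseline T2* in ms recorded during normalisation.
#' @param paradigm The [cuff_paradigm()] supplying the cuff-release time used
#'   as the reference for TTHP and TTP.
#' @return An object of class `bold_parameters` (a named list); field
#'   `hyperemia_defined` records whether the rise amplitude was positive.
#' @export
derive_parameters <- function(params, t2init_ms, paradigm) {
  if (!inherits(params, "descriptive_params"))
    params <- do.call(descriptive_params, as.list(params))
  validate_params(params)
  stopifnot_paradigm(paradigm)
  defl <- event_time(paradigm, "deflation")

  y1 <- model_y1(params)
  hpv <- model_hpv(params)
  rise_amp <- hpv - y1

  # occlusion interval of the model is [t0, t1]; segment B decreases
  # monotonically so its minimum is the value it reaches at deflation
  miv <- y1

  is_down <- abs((params$b - params$m) / params$tau1_s) * t2init_ms
  out <- list(
    t2init_ms = t2init_ms,
    is_down_ms_per_s = is_down,
    miv_au = miv,
    hs_up_ms_per_s = NA_real_,
    tthp_s = NA_real_,
    ttp_s = NA_real_,
    hpv_au = NA_real_,
    tthr_s = NA_real_,
    hyperemia_defined = rise_amp > sqrt(.Machine$double.eps)
  )
  if (out$hyperemia_defined) {
    out$hs_up_ms_per_s <- model_max_rise_slope(params) * t2init_ms
    out$hpv_au <- hpv
    out$ttp_s <- params$t2_s - defl
    half_level <- y1 + rise_amp / 2
    t_half <- crossing_time(params, level = half_level,
                            lower = max(defl, params$t1_s), upper = params$t2_s,
                            rising = TRUE)
    out$tthp_s <- t_half - defl
    out$tthr_s <- log(2) * params$tau3_s
  }
  structure(out, class = "bold_parameters")
}

# First crossing of `level` by the continuous model on [lower, upper],
# located by bisection (uniroot).
crossing_time <- function(params, level, lower, upper, rising = TRUE) {
  f <- function(t) model_eval_unsafe(params, t) - level
  fl <- f(lower); fu <- f(upper)
  if (fl * fu > 0) {
    # level already reached at the boundary (flat or saturated segment)
    return(if (abs(fl) < abs(fu)) lower else upper)
  }
  stats::uniroot(f, lower = lower, upper = upper, tol = 1e-9)$root
}

#' @export
print.bold_parameters <- function(x, ...) {
  cat("<bold_parameters>\n")
  cat(sprintf("  T2*init %.2f ms | ISdown %.4f ms/s | MIV %.4f a.u.\n",
              x$t2init_ms, x$is_down_ms_per_s, x$miv_au))
  if (isTRUE(x$hyperemia_defined)) {
    cat(sprintf("  HSup %.4f ms/s | TTHP %.2f s | TTP %.2f s | HPV %.4f a.u. | TTHR %.2f s\n",
                x$hs_up_ms_per_s, x$tthp_s, x$ttp_s, x$hpv_au, x$tthr_s))
  } else {
    cat("  hyperemic parameters undefined (no positive rise amplitude)\n")
  }
  invisible(x)
}

#' Report BOLD parameters in publication units
#'
#' Slopes are reported multiplied by 100 (units ms/s * 1e2), times in seconds,
#' levels in arbitrary (normalised) units and T2*init in ms.
#'
#' @param params A `bold_parameters` object.
#' @return A one-row `data.frame` with columns `t2init_ms`, `is_down_e2`,
#'   `miv_au`, `hs_up_e2`, `tthp_s`, `ttp_s`, `hpv_au`, `tthr_s`.
#' @export
report_scaled <- function(params) {
  stopifnot(inherits(params, "bold_parameters"))
  data.frame(
    t2init_ms = params$t2init_ms,
    is_down_e2 = 100 * params$is_down_ms_per_s,
    miv_au = params$miv_au,
    hs_up_e2 = 100 * params$hs_up_ms_per_s,
    tthp_s = params$tthp_s,
    ttp_s = params$ttp_s,
    hpv_au = params$hpv_au,
    tthr_s = params$tthr_s
  )
}

#' Construct model parameters that realise target BOLD parameters
#'
#' Inverts [derive_parameters()]: given the eight semi-quantitative targets
#' and a paradigm, finds the descriptive-model knots, levels and time
#' constants whose derived parameters equal the targets. Used by the synthetic
#' generator so that ground-truth trajectories can be specified directly in
#' the physiologically reported quantities.
#'
#' The ischemic pair (tau1, m) is solved by 1-D root finding from `is_down`
#' and `miv`; the rise triple (tm, tau2, p) by damped Newton iteration on the
#' TTHP and HSup conditions with `p` eliminated through the peak-value
#' condition; `tau3 = tthr / ln 2` and `t2 = deflation + ttp` are closed form.
#'
#' @param targets Named list/vector with elements `t2init_ms`,
#'   `is_down_ms_per_s`, `miv_au`, `hs_up_ms_per_s`, `tthp_s`, `ttp_s`,
#'   `hpv_au`, `tthr_s` (unscaled units, i.e. slopes in ms/s).
#' @param paradigm A [cuff_paradigm()]; sets `t0` (inflation) and `t1`
#'   (deflation).
#' @param b Baseline level (default 1).
#' @param r Recovery asymptote (default 1, i.e. return to baseline).
#' @return A [descriptive_params()] object.
#' @export
truth_from_targets <- function(targets, paradigm, b = 1, r = 1) {
  stopifnot_paradigm(paradigm)
  targets <- as.list(targets)
  need <- c("t2init_ms", "is_down_ms_per_s", "miv_au", "hs_up_ms_per_s",
            "tthp_s", "ttp_s", "hpv_au", "tthr_s")
  missing <- setdiff(need, names(targets))
  if (length(missing))
    stop("missing target(s): ", paste(missing, collapse = ", "), call. = FALSE)
  t2init <- targets$t2init_ms
  miv <- targets$miv_au
  hpv <- targets$hpv_au
  if (targets$tthp_s >= targets$ttp_s)
    stop("targets require tthp < ttp", call. = FALSE)
  if (!(miv < b && hpv > miv))
    stop("targets require miv < baseline and hpv > miv", call. = FALSE)

  t0 <- event_time(paradigm, "inflation")
  t1 <- event_time(paradigm, "deflation")
  occl <- paradigm$occlusion_s

  # ischemic segment: is_down = (b - m)/tau1 * t2init with the end-of-occlusion
  # value pinned to miv; (b - m) = (b - miv)/(1 - exp(-occl/tau1)).
  secant <- (b - miv) * t2init / occl
  if (targets$is_down_ms_per_s <= secant)
    stop(sprintf(
      "is_down target %.4g ms/s is below the secant minimum %.4g ms/s for this occlusion",
      targets$is_down_ms_per_s, secant), call. = FALSE)
  g <- function(tau1) {
    q <- exp(-occl / tau1)
    (b - miv) * t2init / ((1 - q) * tau1) - targets$is_down_ms_per_s
  }
  tau1 <- stats::uniroot(g, lower = 1e-3, upper = 1e7, tol = 1e-12)$root
  q <- exp(-occl / tau1)
  m <- (miv - b * q) / (1 - q)
  if (m <= 0) stop("targets imply a non-positive ischemic plateau", call. = FALSE)

  tau3 <- targets$tthr_s / log(2)
  t2 <- t1 + targets$ttp_s
  y1 <- miv                                 # by construction of m, tau1
  t_half <- t1 + targets$tthp_s
  slope_target <- targets$hs_up_ms_per_s / t2init

  # residuals in (tm, log tau2); p eliminated via the peak-value condition
  rise_resid <- function(x) {
    tm <- x[1]; tau2 <- exp(x[2])
    s1 <- stats::plogis((t1 - tm) / tau2)
    s2 <- stats::plogis((t2 - tm) / tau2)
    sh <- stats::plogis((t_half - tm) / tau2)
    if (s2 - s1 < 1e-300) return(c(1e6, 1e6))
    val_half <- y1 + (hpv - y1) * (sh - s1) / (s2 - s1)
    t_star <- min(max(tm, t1), t2)
    ss <- stats::plogis((t_star - tm) / tau2)
    slope_max <- (hpv - y1) / (s2 - s1) * ss * (1 - ss) / tau2
    c(val_half - (y1 + hpv) / 2, slope_max - slope_target)
  }
  x <- c(t_half, log((hpv - y1) * 0.25 / slope_target))
  for (it in 1:200) {
    fx <- rise_resid(x)
    if (max(abs(fx / c(hpv - y1, slope_target))) < 1e-11) break
    J <- matrix(0, 2, 2)
    h <- 1e-6 * pmax(abs(x), 1)
    for (j in 1:2) {
      xp <- x; xp[j] <- xp[j] + h[j]
      J[, j] <- (rise_resid(xp) - fx) / h[j]
    }
    step <- tryCatch(solve(J, fx), error = function(e) fx * 0)
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      fn <- rise_resid(xn)
      if (sum(fn^2) < sum(fx^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    x <- xn
  }
  fx <- rise_resid(x)
  if (max(abs(fx / c(hpv - y1, slope_target))) > 1e-6)
    stop("could not invert rise targets (tthp/hs_up/hpv inconsistent)",
         call. = FALSE)
  tm <- x[1]; tau2 <- exp(x[2])
  s1 <- stats::plogis((t1 - tm) / tau2)
  s2 <- stats::plogis((t2 - tm) / tau2)
  p <- y1 + (hpv - y1) * (1 - s1) / (s2 - s1)

  descriptive_params(b = b, m = m, t0_s = t0, tau1_s = tau1, t1_s = t1,
                     tm_s = tm, tau2_s = tau2, p = p, t2_s = t2, r = r,
                     tau3_s = tau3)
}
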