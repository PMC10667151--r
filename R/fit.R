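#' Fit configuration for the descriptive model
#'
#' Collects solver settings and optional manual overrides of per-parameter
#' start values and box bounds. Defaults suit most curves; individual
#' measurements with atypical timing can override any subset (one
#' configuration applies to both muscles of a measurement).
#'
#' Overrides are named by the internal fit parameterisation: `b`, `m`, `t0_s`,
#' `tau1_s`, `t1_s`, `a_mid_s` (= tm - t1), `tau2_s`, `p`, `gap_s` (= t2 - tm),
#' `r`, `tau3_s`. The knot-order invariants t1 < tm <= t2 are enforced
#' structurally by fitting the non-negative offsets `a_mid_s` and `gap_s`
#' instead of tm and t2 directly.
#'
#' @param start Named list of start-value overrides.
#' @param lower,upper Named lists of bound overrides.
#' @param ftol,ptol Levenberg-Marquardt convergence tolerances.
#' @param maxiter Maximum solver iterations.
#' @param event_slack_frames Half-width, in frames, of the search window for
#'   the inflation/deflation knots around their paradigm times. The default 0
#'   pins both knots to the protocol clock (the cuff events are timed by the
#'   scanner operator, and the knots are barely identified from the flat
#'   plateau around them); positive values free them for measurements whose
#'   recorded timing is unreliable.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(start = list(), lower = list(), upper = list(),
                       ftol = 1e-10, ptol = 1e-10, maxiter = 1000,
                       event_slack_frames = 0) {
  stopifnot(is.list(start), is.list(lower), is.list(upper),
            ftol > 0, ptol > 0, maxiter >= 1)
  structure(list(start = start, lower = lower, upper = upper, ftol = ftol,
                 ptol = ptol, maxiter = maxiter,
                 event_slack_frames = event_slack_frames),
            class = "fit_config")
}

fit_par_names <- c("b", "m", "t0_s", "tau1_s", "t1_s", "a_mid_s", "tau2_s",
                   "p", "gap_s", "r", "tau3_s")

# internal (offset) parameter vector -> descriptive_params-style list
theta_to_params <- function(theta) {
  tm <- theta[["t1_s"]] + theta[["a_mid_s"]]
  list(b = theta[["b"]], m = theta[["m"]], t0_s = theta[["t0_s"]],
       tau1_s = theta[["tau1_s"]], t1_s = theta[["t1_s"]], tm_s = tm,
       tau2_s = theta[["tau2_s"]], p = theta[["p"]],
       t2_s = tm + theta[["gap_s"]], r = theta[["r"]],
       tau3_s = theta[["tau3_s"]])
}

# Deterministic, data-driven initial values and default bounds.
fit_init <- function(t, y, paradigm, cfg) {
  dt <- paradigm$dt_s
  t_inf <- event_time(paradigm, "inflation")
  t_def <- event_time(paradigm, "deflation")
  slack <- cfg$event_slack_frames * dt

  pre <- t < t_inf
  occ <- t >= t_inf & t <= t_def
  post <- t > t_def

  b0 <- if (any(pre)) mean(y[pre]) else 1
  m0 <- if (any(occ)) min(y[occ]) else 0.95 * b0
  y_def <- if (any(occ)) y[max(which(occ))] else m0
  hpv0 <- if (any(post)) max(y[post]) else b0
  t2_0 <- if (any(post)) t[post][which.max(y[post])] else t_def + 10 * dt
  half <- (y_def + hpv0) / 2
  cross <- which(post & y >= half & t <= t2_0)
  tm0 <- if (length(cross)) t[min(cross)] else (t_def + t2_0) / 2
  tm0 <- min(max(tm0, t_def + dt / 2), t2_0)
  tail_n <- max(3L, round(0.05 * length(y)))
  r0 <- mean(utils::tail(y, tail_n))

  start <- c(b = b0, m = max(m0, 0.31), t0_s = t_inf,
             tau1_s = paradigm$occlusion_s / 3, t1_s = t_def,
             a_mid_s = max(tm0 - t_def, dt / 4),
             tau2_s = max((t2_0 - tm0) / 6, dt / 8), p = hpv0,
             gap_s = max(t2_0 - tm0, dt / 4), r = r0, tau3_s = 60)
  lower <- c(b = 0.9, m = 0.3, t0_s = t_inf - slack, tau1_s = 0.5,
             t1_s = t_def - slack, a_mid_s = 0.05, tau2_s = 0.02, p = 0.8,
             gap_s = 0, r = 0.6, tau3_s = 1)
  upper <- c(b = 1.1, m = 1.05, t0_s = t_inf + slack, tau1_s = 1e4,
             t1_s = t_def + slack, a_mid_s = 200, tau2_s = 80, p = 3,
             gap_s = 300, r = 1.4, tau3_s = 1e4)

  ov <- function(vec, lst) {
    extra <- setdiff(names(lst), fit_par_names)
    if (length(extra)) stop("unknown fit parameter(s): ",
                            paste(extra, collapse = ", "), call. = FALSE)
    vec[names(lst)] <- unlist(lst)
    vec
  }
  start <- ov(start, cfg$start)
  lower <- ov(lower, cfg$lower)
  upper <- ov(upper, cfg$upper)
  start <- pmin(pmax(start, lower), upper)
  if (any(lower > upper))
    stop("fit bounds invalid: lower > upper", call. = FALSE)
  list(start = start[fit_par_names], lower = lower[fit_par_names],
       upper = upper[fit_par_names])
}

#' Fit the descriptive model to a normalised T2*-time curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt, [minpack.lm::nls.lm])
#' of the piecewise model against all frames of a baseline-normalised curve.
#' Initialisation is deterministic and data driven: the occlusion knots start
#' at the paradigm's inflation/deflation times, the ischemic plateau at the
#' occlusion minimum, the peak knot at the post-release maximum, and the
#' logistic midpoint at the observed half-rise crossing. No random restarts
#' are used, so refitting the same curve is fully reproducible.
#'
#' @param curve A [time_curve()] (must be normalised; see
#'   [normalize_baseline()]) or a list with `times_s` and `normalized`.
#' @param paradigm The [cuff_paradigm()] the curve was acquired under.
#' @param cfg A [fit_config()].
#' @return A `model_fit` object: list with `params` ([descriptive_params()]),
#'   `t2init_ms`, and `diagnostics` (`converged`, `info`, `message`, `rss`,
#'   `niter`, `degenerate` — the latter flags a rise amplitude at the noise
#'   floor, e.g. for a flat input curve).
#' @export
fit_model <- function(curve, paradigm, cfg = fit_config()) {
  stopifnot_paradigm(paradigm)
  if (!inherits(cfg, "fit_config")) stop("`cfg` must be a fit_config",
                                         call. = FALSE)
  t <- curve$times_s
  y <- curve$normalized
  if (is.null(t) || is.null(y) || length(t) != length(y) || length(t) < 12L)
    stop("curve must provide matching times_s/normalized covering the paradigm",
         call. = FALSE)
  if (anyNA(y)) stop("curve contains missing frames; interpolate first",
                     call. = FALSE)

  ini <- fit_init(t, y, paradigm, cfg)
  # parameters whose bounds coincide (e.g. the event knots by default) are
  # held fixed and excluded from the optimised vector
  free <- ini$lower < ini$upper
  theta <- ini$start
  resid_fn <- function(sub) {
    theta[free] <- sub
    model_eval_unsafe(theta_to_params(theta), t) - y
  }
  # nls.lm's status warnings duplicate the info code surfaced in the
  # diagnostics, so they are muffled here
  fit <- withCallingHandlers(
    minpack.lm::nls.lm(
      par = ini$start[free], lower = ini$lower[free],
      upper = ini$upper[free], fn = resid_fn,
      control = minpack.lm::nls.lm.control(ftol = cfg$ftol, ptol = cfg$ptol,
                                           maxiter = cfg$maxiter,
                                           maxfev = 100 * (sum(free) + 1) *
                                             ceiling(cfg$maxiter / 50))),
    warning = function(w) {
      if (grepl("lmdif|info =", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  theta[free] <- fit$par
  names(theta) <- fit_par_names
  pl <- theta_to_params(theta)
  params <- do.call(descriptive_params, pl)
  rise_amp <- model_hpv(params) - model_y1(params)

  structure(list(
    params = params,
    t2init_ms = curve$t2init_ms,
    diagnostics = list(
      converged = fit$info %in% 1:4,
      info = fit$info,
      message = fit$message,
      rss = sum(fit$fvec^2),
      niter = fit$niter,
      degenerate = rise_amp < 1e-3
    )
  ), class = "model_fit")
}

#' @export
print.model_fit <- function(x, ...) {
  d <- x$diagnostics
  cat(sprintf("<model_fit> %s (info %d, %d iter, rss %.3e)%s\n",
              if (d$converged) "converged" else "NOT converged",
              d$info, d$niter, d$rss,
              if (d$degenerate) " [degenerate: no hyperemic rise]" else ""))
  print(x$params)
  invisible(x)
}
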