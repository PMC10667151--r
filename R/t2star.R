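#' Multi-echo image series container
#'
#' A 4D magnitude image stack with dimensions (x, y, echo, frame), the echo
#' times of the multi-echo gradient-echo readout, and the frame interval.
#'
#' @param data 4D numeric array (x, y, echo, frame) of non-negative
#'   magnitudes.
#' @param echo_times_ms Echo times in ms; length must match the echo axis.
#' @param dt_s Frame interval in seconds.
#' @param meta Optional provenance list (seed, generator config, ...).
#' @return An object of class `multi_echo_series`.
#' @export
multi_echo_series <- function(data, echo_times_ms, dt_s, meta = list()) {
  if (length(dim(data)) != 4L)
    stop("data must be a 4D array (x, y, echo, frame)", call. = FALSE)
  if (dim(data)[3] != length(echo_times_ms))
    stop("echo axis length must equal length(echo_times_ms)", call. = FALSE)
  if (any(data < 0)) stop("magnitude intensities must be >= 0", call. = FALSE)
  if (any(diff(echo_times_ms) <= 0) || any(echo_times_ms <= 0))
    stop("echo_times_ms must be strictly increasing and positive",
         call. = FALSE)
  structure(list(data = data, echo_times_ms = as.numeric(echo_times_ms),
                 dt_s = dt_s, meta = meta),
            class = "multi_echo_series")
}

#' @export
print.multi_echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<multi_echo_series> %dx%d matrix, %d echoes (%.1f-%.1f ms), %d frames @ %.2fs\n",
              d[1], d[2], d[3], min(x$echo_times_ms), max(x$echo_times_ms),
              d[4], x$dt_s))
  invisible(x)
}

#' Voxel-wise T2* estimate by log-linear regression
#'
#' Ordinary least squares of `log(S)` on echo time for one voxel: with
#' mono-exponential decay `S(TE) = S0 * exp(-TE/T2*)`, the slope is `-1/T2*`
#' and the intercept `log(S0)`. Echoes with non-positive signal are excluded
#' (log undefined); the fit is flagged invalid when fewer than `min_echoes`
#' usable echoes remain or the slope is non-negative.
#'
#' @param signal Numeric vector of per-echo magnitudes.
#' @param echo_times_ms Matching echo times in ms (strictly increasing).
#' @param min_echoes Minimum usable echoes for a valid fit (default 3).
#' @return List with `t2star_ms`, `s0`, `valid`.
#' @export
fit_t2star_voxel <- function(signal, echo_times_ms, min_echoes = 3L) {
  if (length(signal) != length(echo_times_ms))
    stop("signal and echo_times_ms lengths differ", call. = FALSE)
  if (any(diff(echo_times_ms) <= 0))
    stop("echo_times_ms must be strictly increasing", call. = FALSE)
  use <- is.finite(signal) & signal > 0
  if (sum(use) < min_echoes)
    return(list(t2star_ms = NA_real_, s0 = NA_real_, valid = FALSE))
  te <- echo_times_ms[use]
  ls <- log(signal[use])
  beta <- stats::cov(te, ls) / stats::var(te)
  alpha <- mean(ls) - beta * mean(te)
  valid <- is.finite(beta) && beta < 0
  list(t2star_ms = if (valid) -1 / beta else NA_real_,
       s0 = exp(alpha), valid = valid)
}

#' Per-frame T2* maps from a multi-echo series
#'
#' Applies the voxel-wise log-linear regression independently to every voxel
#' of every frame (vectorised over voxels). Supplying a mask restricts which
#' voxels are computed but never changes their values.
#'
#' @param series A [multi_echo_series()].
#' @param mask Optional [roi_mask()]; only voxels with label > 0 are fitted.
#' @param min_echoes Minimum usable echoes per voxel (default 3).
#' @return An object of class `t2star_series`: list with `t2star_ms` (3D
#'   array x, y, frame), `s0_map`, `valid_mask` (logical), `dt_s`.
#' @export
fit_t2star_series <- function(series, mask = NULL, min_echoes = 3L) {
  stopifnot(inherits(series, "multi_echo_series"))
  d <- dim(series$data)
  nx <- d[1]; ny <- d[2]; ne <- d[3]; nf <- d[4]
  te <- series$echo_times_ms

  keep <- rep(TRUE, nx * ny)
  if (!is.null(mask)) {
    lab <- if (inherits(mask, "roi_mask")) mask$labels else mask
    if (!all(dim(lab) == c(nx, ny)))
      stop("mask dimensions do not match the image matrix", call. = FALSE)
    keep <- as.vector(lab > 0)
  }

  # echoes x (voxel*frame) design; one pass of weighted sums per echo axis
  x <- aperm(series$data, c(3L, 1L, 2L, 4L))
  dim(x) <- c(ne, nx * ny * nf)
  vox_keep <- rep(keep, times = nf)
  x <- x[, vox_keep, drop = FALSE]

  ls <- suppressWarnings(log(x))
  w <- is.finite(ls) & x > 0
  ls[!w] <- 0
  nw <- colSums(w)
  te_mat <- matrix(te, nrow = ne, ncol = ncol(x))
  sw_te <- colSums(te_mat * w)
  sw_ls <- colSums(ls)
  sw_te2 <- colSums(te_mat^2 * w)
  sw_tels <- colSums(te_mat * ls)
  denom <- sw_te2 - sw_te^2 / nw
  beta <- (sw_tels - sw_te * sw_ls / nw) / denom
  alpha <- (sw_ls - beta * sw_te) / nw

  valid <- nw >= min_echoes & is.finite(beta) & beta < 0 & denom > 0
  t2 <- ifelse(valid, -1 / beta, NA_real_)
  s0 <- ifelse(nw >= min_echoes, exp(alpha), NA_real_)

  full <- function(v, fill = NA_real_) {
    out <- rep(fill, nx * ny * nf)
    out[vox_keep] <- v
    array(out, dim = c(nx, ny, nf))
  }
  structure(list(
    t2star_ms = full(t2),
    s0_map = full(s0),
    valid_mask = array(replace(rep(FALSE, nx * ny * nf),
                               which(vox_keep)[which(valid)], TRUE),
                       dim = c(nx, ny, nf)),
    dt_s = series$dt_s
  ), class = "t2star_series")
}

#' @export
print.t2star_series <- function(x, ...) {
  d <- dim(x$t2star_ms)
  cat(sprintf("<t2star_series> %dx%d voxels, %d frames; %.1f%% valid fits\n",
              d[1], d[2], d[3], 100 * mean(x$valid_mask)))
  invisible(x)
}

#' Cap T2* values for display or export
#'
#' Analysis always uses uncapped estimates; this helper only clamps a map for
#' visualisation or file export.
#'
#' @param t2series A `t2star_series`.
#' @param ceiling_ms Cap in ms (default 200).
#' @return The series with `t2star_ms` clamped to `[0, ceiling_ms]`.
#' @export
cap_t2star <- function(t2series, ceiling_ms = 200) {
  stopifnot(inherits(t2series, "t2star_series"), ceiling_ms > 0)
  t2series$t2star_ms <- pmin(t2series$t2star_ms, ceiling_ms)
  t2series
}
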