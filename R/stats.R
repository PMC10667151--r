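#' Paired Wilcoxon signed-rank test with Hodges-Lehmann interval
#'
#' Two-sided paired signed-rank test. Zero differences are dropped, tied
#' absolute differences receive average ranks. For n <= `exact_max` non-zero
#' pairs the p-value is exact, computed from the full null distribution of the
#' signed-rank statistic over all 2^n sign assignments (evaluated by
#' generating-function convolution, which enumerates the same distribution
#' without materialising the 2^n patterns and remains exact under ties);
#' beyond that a tie-corrected normal approximation with continuity
#' correction is used. The 95% confidence interval for the location shift is
#' the Hodges-Lehmann interval built from the Walsh averages of the
#' differences.
#'
#' @param a,b Paired measurement vectors (condition A and B), equal length.
#' @param conf_level Confidence level for the Hodges-Lehmann interval.
#' @param exact_max Largest n for which the exact distribution is used.
#' @return List with `statistic` (V, sum of positive ranks), `p_value`,
#'   `estimate` (Hodges-Lehmann median difference a - b), `conf_int`,
#'   `n_used`, `exact`.
#' @export
wilcoxon_paired <- function(a, b, conf_level = 0.95, exact_max = 15L) {
  if (length(a) != length(b)) stop("paired samples differ in length",
                                   call. = FALSE)
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all paired differences are zero; test undefined",
                    call. = FALSE)
  r <- rank(abs(d))
  v <- sum(r[d > 0])

  if (n <= exact_max) {
    p <- signed_rank_exact_p(r, v)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }

  walsh <- sort(outer(d, d, `+`)[lower.tri(matrix(0, n, n), diag = TRUE)] / 2)
  est <- stats::median(walsh)
  alpha <- 1 - conf_level
  qu <- stats::qsignrank(alpha / 2, n)
  if (qu == 0) qu <- 1
  m <- length(walsh)
  ci <- c(walsh[qu], walsh[m - qu + 1])

  list(statistic = v, p_value = p, estimate = est, conf_int = ci,
       n_used = n, exact = exact)
}

# Exact two-sided p-value of the signed-rank statistic for rank vector r
# (average ranks allowed). The null distribution over all 2^n equiprobable
# sign assignments is built by convolving (1 + x^{2 r_i}) / 2 on a half-unit
# grid (doubling makes tied average ranks integral).
signed_rank_exact_p <- function(r, v) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  counts <- numeric(total + 1L)     # counts[w + 1] = #assignments with 2V = w
  counts[1L] <- 1
  for (ri in r2) {
    shifted <- c(rep(0, ri), counts[seq_len(total + 1L - ri)])
    counts <- counts + shifted
  }
  probs <- counts / sum(counts)
  w <- as.integer(round(2 * v))
  p_le <- sum(probs[seq_len(w + 1L)])
  p_ge <- sum(probs[(w + 1L):(total + 1L)])
  min(1, 2 * min(p_le, p_ge))
}

#' Within-subject coefficient of variation
#'
#' Repeatability of duplicate measurements: per subject,
#' `CV_i = sd_i / mean_i` with `sd_i = |x1 - x2| / sqrt(2)`; the aggregate is
#' the root mean square of the per-subject CVs, reported as a percentage.
#' Scale invariant and zero for perfectly repeated measurements.
#'
#' @param x1,x2 First and second measurement per subject (equal lengths).
#' @return `CV_w` in percent.
#' @export
cv_within <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("repeat vectors differ in length",
                                     call. = FALSE)
  mu <- (x1 + x2) / 2
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("CV undefined: non-positive subject mean", call. = FALSE)
  s <- abs(x1 - x2) / sqrt(2)
  100 * sqrt(mean((s / mu)^2))
}

#' ICC(2,1): two-way random effects, absolute agreement, single measurement
#'
#' Point estimate from the two-way ANOVA mean squares,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`, with the
#' lower confidence bound by the F-distribution method (Satterthwaite
#' degrees of freedom). The reliability category is assigned from the lower
#' bound: poor < 0.5, moderate 0.5-0.75, good 0.75-0.9, excellent > 0.9.
#'
#' @param ratings Numeric matrix, subjects in rows, raters in columns
#'   (complete, >= 2 of each).
#' @param conf_level Confidence level of the lower bound (default 0.95).
#' @return List with `icc`, `ci_lower`, `category`, and the mean squares
#'   `msr`, `msc`, `mse`.
#' @export
icc_2_1 <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 raters",
                             call. = FALSE)
  if (anyNA(ratings)) stop("ratings matrix must be complete", call. = FALSE)
  if (stats::var(as.vector(ratings)) == 0)
    stop("zero total variance; ICC undefined", call. = FALSE)

  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ssr <- k * sum((row_m - grand)^2)
  ssc <- n * sum((col_m - grand)^2)
  sse <- sum((ratings - outer(row_m, rep(1, k)) -
                outer(rep(1, n), col_m) + grand)^2)
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))

  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # F-method lower bound (two-way random, absolute agreement, single score)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  # perfect agreement (zero error variance): the bound degenerates to the
  # point estimate
  if (mse <= .Machine$double.eps * msr) lower <- icc
  if (!is.finite(lower)) lower <- -1

  category <- if (lower > 0.9) "excellent" else if (lower >= 0.75) "good"
              else if (lower >= 0.5) "moderate" else "poor"
  list(icc = icc, ci_lower = lower, category = category,
       msr = msr, msc = msc, mse = mse)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean paired difference) and 95% limits of agreement
#' `bias +/- 1.96 sd`, each with a t-based confidence interval: the bias CI
#' uses `sd / sqrt(n)`, the limit CIs the standard approximation
#' `sd * sqrt(3 / n)`.
#'
#' @param a,b Paired measurements (difference taken as a - b), n >= 3.
#' @return List with `bias`, `loa_lower`, `loa_upper`, and 2-vector CIs
#'   `ci_bias`, `ci_loa_lower`, `ci_loa_upper`; also `mean_ab` and `diff` for
#'   plotting.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired samples differ in length",
                                   call. = FALSE)
  n <- length(a)
  if (n < 3L) stop("Bland-Altman requires n >= 3", call. = FALSE)
  d <- a - b
  bias <- mean(d)
  s <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * s
  tq <- stats::qt(0.975, n - 1)
  list(bias = bias, loa_lower = loa[1], loa_upper = loa[2],
       ci_bias = bias + c(-1, 1) * tq * s / sqrt(n),
       ci_loa_lower = loa[1] + c(-1, 1) * tq * s * sqrt(3 / n),
       ci_loa_upper = loa[2] + c(-1, 1) * tq * s * sqrt(3 / n),
       mean_ab = (a + b) / 2, diff = d)
}

#' Percentage difference between two medians
#'
#' `100 * |m_a - m_b| / ((m_a + m_b) / 2)`: the symmetric, scale-invariant
#' percentage difference used to compare median parameter values between
#' occlusion durations.
#'
#' @param median_a,median_b The two medians; their mean must be positive.
#' @return Percentage difference (non-negative).
#' @export
pct_diff_medians <- function(median_a, median_b) {
  mid <- (median_a + median_b) / 2
  if (any(!is.finite(mid)) || any(mid <= 0))
    stop("percentage difference undefined for non-positive mean of medians",
         call. = FALSE)
  100 * abs(median_a - median_b) / mid
}

#' Cohort summary report
#'
#' Median and interquartile range per parameter x muscle x condition, the
#' percentage difference of medians between the two conditions, and the
#' paired Wilcoxon p-value over subjects present in both conditions.
#' Quartiles use the linear-interpolation convention (R's default type 7).
#'
#' @param params Long `data.frame` with columns `subject`, `condition`,
#'   `muscle`, `parameter`, `value`.
#' @param cond_a,cond_b The two condition labels to contrast (defaults: the
#'   first two in the data).
#' @return `data.frame` with one row per parameter x muscle: medians, IQRs,
#'   `delta_pct`, `p_value`, `n_pairs`.
#' @export
summarize_cohort <- function(params, cond_a = NULL, cond_b = NULL) {
  need <- c("subject", "condition", "muscle", "parameter", "value")
  if (!all(need %in% names(params)))
    stop("params must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  conds <- unique(params$condition)
  if (is.null(cond_a)) cond_a <- conds[1]
  if (is.null(cond_b)) cond_b <- if (length(conds) > 1) conds[2] else conds[1]

  out <- list()
  for (par in unique(params$parameter)) {
    for (mus in unique(params$muscle)) {
      sub <- params[params$parameter == par & params$muscle == mus, ]
      xa <- sub[sub$condition == cond_a, c("subject", "value")]
      xb <- sub[sub$condition == cond_b, c("subject", "value")]
      if (!nrow(xa) || !nrow(xb)) {
        warning(sprintf("empty group for %s/%s; omitted", par, mus),
                call. = FALSE)
        next
      }
      med_a <- stats::median(xa$value)
      med_b <- stats::median(xb$value)
      common <- intersect(xa$subject, xb$subject)
      pval <- NA_real_
      if (length(common) >= 2 && cond_a != cond_b) {
        va <- xa$value[match(common, xa$subject)]
        vb <- xb$value[match(common, xb$subject)]
        pval <- tryCatch(wilcoxon_paired(va, vb)$p_value,
                         error = function(e) NA_real_)
      }
      delta <- if (med_a + med_b > 0) pct_diff_medians(med_a, med_b)
               else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        parameter = par, muscle = mus,
        median_a = med_a, iqr_a = stats::IQR(xa$value, type = 7),
        median_b = med_b, iqr_b = stats::IQR(xb$value, type = 7),
        delta_pct = delta, p_value = pval, n_pairs = length(common))
    }
  }
  if (!length(out)) stop("no non-empty groups to summarise", call. = FALSE)
  do.call(rbind, out)
}

#' Repeatability summary for duplicate measurements
#'
#' `CV_w` per parameter x muscle for a table of paired repeats.
#'
#' @param params Long `data.frame` with columns `subject`, `muscle`,
#'   `parameter`, `value`, `repeat_id` (two levels).
#' @return `data.frame` with `parameter`, `muscle`, `cv_w_pct`, `n`.
#' @export
summarize_repeatability <- function(params) {
  need <- c("subject", "muscle", "parameter", "value", "repeat_id")
  if (!all(need %in% names(params)))
    stop("params must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  reps <- sort(unique(params$repeat_id))
  if (length(reps) != 2L) stop("repeat_id must have exactly two levels",
                               call. = FALSE)
  out <- list()
  for (par in unique(params$parameter)) {
    for (mus in unique(params$muscle)) {
      sub <- params[params$parameter == par & params$muscle == mus, ]
      x1 <- sub[sub$repeat_id == reps[1], c("subject", "value")]
      x2 <- sub[sub$repeat_id == reps[2], c("subject", "value")]
      common <- intersect(x1$subject, x2$subject)
      if (length(common) < 1L) next
      v1 <- x1$value[match(common, x1$subject)]
      v2 <- x2$value[match(common, x2$subject)]
      out[[length(out) + 1L]] <- data.frame(
        parameter = par, muscle = mus,
        cv_w_pct = cv_within(v1, v2), n = length(common))
    }
  }
  do.call(rbind, out)
}
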