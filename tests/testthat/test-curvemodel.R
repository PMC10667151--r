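default_truth <- function(paradigm = long_paradigm(),
                          muscle = "gastrocnemius",
                          occ = if (paradigm$occlusion_s >= 200) "long"
                                else "short") {
  truth_from_targets(default_targets(muscle, occ), paradigm)
}

test_that("the forward model honours its anchors and asymptote", {
  par <- default_truth()
  # baseline level before t0, continuity at every knot
  expect_equal(model_eval(par, c(0, 30, par$t0_s)), rep(par$b, 3))
  for (knot in c(par$t0_s, par$t1_s, par$t2_s)) {
    lo <- model_eval(par, knot - 1e-7)
    hi <- model_eval(par, knot + 1e-7)
    expect_equal(lo, hi, tolerance = 1e-5)
  }
  # t -> infinity approaches the recovery level r
  expect_equal(model_eval(par, 1e6), par$r, tolerance = 1e-12)
  # all-equal levels give the constant curve
  flat <- descriptive_params(b = 1, m = 1, p = 1, r = 1)
  expect_equal(model_eval(flat, seq(0, 600, by = 7)),
               rep(1, length(seq(0, 600, by = 7))))
})

test_that("invalid parameter sets are rejected", {
  expect_error(descriptive_params(t0_s = 400, t1_s = 360), "t0 < t1")
  expect_error(descriptive_params(tm_s = 500, t2_s = 400), "tm <= t2")
  expect_error(descriptive_params(tau1_s = -3), "positive")
  expect_error(descriptive_params(m = 1.2), "m <= b")
})

test_that("derived parameters follow their closed forms", {
  p <- long_paradigm()
  par <- default_truth(p)
  bp <- derive_parameters(par, 26.3, p)

  # TTHR closed form ln(2) tau3 agrees with a numerical root of the model
  expect_equal(bp$tthr_s, log(2) * par$tau3_s, tolerance = 1e-12)
  hpv <- bp$hpv_au
  half_rec <- hpv - (hpv - par$r) / 2
  root <- uniroot(function(t) model_eval(par, t) - half_rec,
                  lower = par$t2_s, upper = par$t2_s + 20 * par$tau3_s,
                  tol = 1e-10)$root
  expect_equal(root - par$t2_s, bp$tthr_s, tolerance = 1e-6)
  expect_equal(log(2) * 87.1, 60.4, tolerance = 0.05)

  # ISdown is the slope magnitude at occlusion onset, in ms/s
  eps <- 1e-6
  num_slope <- (model_eval(par, par$t0_s + eps) -
                  model_eval(par, par$t0_s + 2 * eps)) / eps
  expect_equal(bp$is_down_ms_per_s, abs(num_slope) * 26.3, tolerance = 1e-4)

  # MIV is the model minimum over the occlusion interval
  grid <- seq(par$t0_s, par$t1_s, length.out = 2000)
  expect_equal(bp$miv_au, min(model_eval(par, grid)), tolerance = 1e-9)

  # HSup matches a dense numerical slope maximum on the rise
  tt <- seq(par$t1_s, par$t2_s, length.out = 5000)
  num_max <- max(diff(model_eval(par, tt)) / diff(tt))
  expect_equal(bp$hs_up_ms_per_s, num_max * 26.3, tolerance = 1e-5)
})

test_that("a symmetric logistic rise puts TTHP at the midpoint time", {
  p <- long_paradigm()
  defl <- 360
  par <- descriptive_params(b = 1, m = 0.96, t0_s = 60, tau1_s = 20,
                            t1_s = defl, tm_s = defl + 15, tau2_s = 1.5,
                            p = 1.05, t2_s = defl + 30, r = 1, tau3_s = 80)
  bp <- derive_parameters(par, 26, p)
  expect_equal(bp$tthp_s, 15, tolerance = 0.01)
  expect_lt(bp$tthp_s, bp$ttp_s)
})

test_that("target inversion and parameter derivation are mutual inverses", {
  for (muscle in c("gastrocnemius", "soleus")) {
    for (occ in c("long", "short")) {
      p <- if (occ == "long") long_paradigm() else short_paradigm()
      tg <- default_targets(muscle, occ)
      par <- truth_from_targets(tg, p)
      bp <- derive_parameters(par, tg$t2init_ms, p)
      expect_equal(unlist(unclass(bp))[bold_names], unlist(tg)[bold_names],
                   tolerance = 1e-9)
    }
  }
  p <- long_paradigm()
  bad <- default_targets("gastrocnemius", "long")
  bad$is_down_ms_per_s <- 1e-4          # below the secant minimum
  expect_error(truth_from_targets(bad, p), "secant")
  bad2 <- default_targets("gastrocnemius", "long")
  bad2$tthp_s <- 50                     # would exceed time-to-peak
  expect_error(truth_from_targets(bad2, p), "tthp < ttp")
})

test_that("publication scaling multiplies slopes by 100", {
  p <- long_paradigm()
  bp <- derive_parameters(default_truth(p), 26.3, p)
  row <- report_scaled(bp)
  expect_equal(row$is_down_e2, 2.4, tolerance = 1e-6)
  expect_equal(row$hs_up_e2, 37.9, tolerance = 1e-6)
  zero <- bp; zero$is_down_ms_per_s <- 0
  expect_equal(report_scaled(zero)$is_down_e2, 0)
})

test_that("fitting a noiseless model curve recovers it", {
  p <- long_paradigm()
  truth <- default_truth(p)
  cv <- truth_curve(truth, p)
  cv$t2init_ms <- 26.3
  fit <- fit_model(cv, p)
  expect_true(fit$diagnostics$converged)
  expect_false(fit$diagnostics$degenerate)
  expect_lt(fit$diagnostics$rss, 1e-10)
  # the fitted curve and the derived parameters are recovered (the raw
  # logistic asymptote is only weakly identified once the rise saturates)
  expect_lt(max(abs(model_eval(fit$params, cv$times_s) - cv$normalized)),
            1e-6)
  bp <- derive_parameters(fit$params, 26.3, p)
  tg <- default_targets("gastrocnemius", "long")
  for (nm in c("miv_au", "hpv_au")) {
    expect_equal(bp[[nm]], tg[[nm]], tolerance = 1e-4)
  }
  for (nm in c("tthp_s", "ttp_s", "tthr_s")) {
    expect_lt(abs(bp[[nm]] - tg[[nm]]), 0.1)
  }
})

test_that("refitting a fit's own curve is a fixed point", {
  p <- short_paradigm()
  set.seed(3)
  cv <- noisy_curve(p, sigma = 0.004,
                    truth = default_truth(p, "soleus"))
  f1 <- fit_model(cv, p)
  own <- time_curve(cv$times_s, model_eval(f1$params, cv$times_s),
                    normalized = model_eval(f1$params, cv$times_s),
                    t2init_ms = 25.5)
  f2 <- fit_model(own, p)
  expect_lt(max(abs(model_eval(f2$params, cv$times_s) -
                      model_eval(f1$params, cv$times_s))), 1e-4)
})

test_that("a flat curve is flagged degenerate, not an error", {
  p <- long_paradigm()
  flat <- time_curve(time_axis(p), rep(1, n_frames(p)),
                     normalized = rep(1, n_frames(p)), t2init_ms = 26)
  fit <- fit_model(flat, p)
  expect_true(fit$diagnostics$degenerate)
  bp <- derive_parameters(fit$params, 26, p)
  if (!bp$hyperemia_defined) expect_true(is.na(bp$hpv_au))
})

test_that("noisy fits recover HPV within one percent of baseline", {
  p <- long_paradigm()
  tg <- default_targets("gastrocnemius", "long")
  set.seed(99)
  errs <- replicate(25, {
    cv <- noisy_curve(p, sigma = 0.005)
    f <- fit_model(cv, p)
    derive_parameters(f$params, 26.3, p)$hpv_au - tg$hpv_au
  })
  expect_lt(median(abs(errs)), 0.01)
})

test_that("TTHP precedes TTP whenever the rise has positive amplitude", {
  p <- long_paradigm()
  base <- default_targets("gastrocnemius", "long")
  set.seed(17)
  for (i in 1:30) {
    tg <- base
    tg$hpv_au <- 1 + (base$hpv_au - 1) * runif(1, 0.5, 2)
    tg$ttp_s <- base$ttp_s * runif(1, 0.7, 1.4)
    tg$tthp_s <- tg$ttp_s * runif(1, 0.3, 0.7)
    tg$hs_up_ms_per_s <- 26.3 * 1.2 *
      runif(1, 1.2, 3) * (tg$hpv_au - tg$miv_au) / tg$ttp_s
    par <- tryCatch(truth_from_targets(tg, p), error = function(e) NULL)
    if (is.null(par)) next
    bp <- derive_parameters(par, 26.3, p)
    expect_lt(bp$tthp_s, bp$ttp_s)
    expect_true(bp$miv_au <= 1 && bp$hpv_au >= 1)
  }
})
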