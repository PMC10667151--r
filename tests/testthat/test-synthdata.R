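test_that("truth curves sit at 1 during baseline and respect their levels", {
  p <- long_paradigm()
  truth <- truth_from_targets(default_targets("gastrocnemius", "long"), p)
  cv <- truth_curve(truth, p)
  base <- cv$times_s < 60
  expect_equal(cv$normalized[base], rep(1, sum(base)))
  occ <- cv$times_s >= 60 & cv$times_s <= 360
  post <- cv$times_s > 360
  expect_equal(min(cv$normalized[occ]), 0.96, tolerance = 1e-4)
  expect_equal(max(cv$normalized[post]), 1.04, tolerance = 1e-4)
  # flat truth stays constant
  flat <- descriptive_params(b = 1, m = 1, p = 1, r = 1)
  expect_equal(truth_curve(flat, p)$normalized, rep(1, 207))
})

test_that("noiseless voxel signal follows the mono-exponential closed form", {
  p <- long_paradigm()
  r <- render_series(phantom_config(matrix = c(16L, 16L),
                                    noise_model = "none"),
                     tissues = list(
                       tissue_spec(1L, t2init_ms = 26, s0 = 1000,
                                   truth = truth_from_targets(
                                     default_targets("gastrocnemius", "long"),
                                     p),
                                   heterogeneity_frac = 0)),
                     paradigm = p)
  vox <- which(r$mask$labels == 1L)[1]
  s_te2 <- r$series$data[, , 1, 1][vox]            # TE = 2 ms, baseline frame
  expect_equal(s_te2 / 1000, exp(-2 / 26), tolerance = 1e-12)
  # background voxels carry no signal without noise
  expect_equal(max(r$series$data[, , 1, 1][r$mask$labels == 0]), 0)
})

test_that("a fixed seed fixes every rendered byte", {
  p <- short_paradigm()
  ph <- phantom_config(matrix = c(12L, 12L), seed = 77L)
  r1 <- render_series(ph, paradigm = p)
  r2 <- render_series(ph, paradigm = p)
  expect_identical(r1$series$data, r2$series$data)
  expect_identical(r1$truth$t2init_map, r2$truth$t2init_map)
  r3 <- render_series(phantom_config(matrix = c(12L, 12L), seed = 78L),
                      paradigm = p)
  expect_false(identical(r1$series$data, r3$series$data))
})

test_that("overlapping ROIs and negative noise are configuration errors", {
  expect_error(phantom_config(noise_sigma = -0.1), "noise_sigma")
  ov <- phantom_config(ellipses = list(
    list(center = c(0.45, 0.5), radii = c(0.2, 0.3)),
    list(center = c(0.55, 0.5), radii = c(0.2, 0.3))))
  expect_error(render_series(ov, paradigm = short_paradigm()), "overlap")
  expect_error(phantom_config(ellipses = list(
    list(center = c(0.9, 0.5), radii = c(0.2, 0.2)))), "outside")
})

test_that("background magnitude matches the Rayleigh mean", {
  # brute-force oracle: mean magnitude of pure complex noise is sigma*sqrt(pi/2)
  set.seed(31)
  sigma <- 0.02 * 1000
  oracle <- mean(sqrt(rnorm(1e6, 0, sigma)^2 + rnorm(1e6, 0, sigma)^2))
  expect_equal(oracle, sigma * sqrt(pi / 2), tolerance = 0.01)

  p <- cuff_paradigm(occlusion_s = 90, post_s = 60)
  r <- render_series(phantom_config(matrix = c(32L, 32L), seed = 4L),
                     paradigm = p)
  bg <- r$series$data[, , 1, ][rep(r$mask$labels == 0,
                                   times = dim(r$series$data)[4])]
  expect_equal(mean(bg), sigma * sqrt(pi / 2), tolerance = 0.01)
})

test_that("zero variability reproduces the default targets for everyone", {
  zero <- as.list(setNames(rep(0, 8),
                           c("t2init", "is_down", "miv_depth", "hs_up",
                             "tthp", "ttp", "hpv_rise", "tthr")))
  coh <- simulate_cohort(3, variability = zero, measurement_cv = 0,
                         render = FALSE, seed = 10)
  expect_length(coh, 6L)                  # 3 subjects x (long, short)
  for (rec in coh) {
    occ <- if (rec$occlusion_s >= 200) "long" else "short"
    expect_equal(unlist(rec$targets$gastrocnemius),
                 unlist(default_targets("gastrocnemius", occ)),
                 tolerance = 1e-12)
  }
})

test_that("paired designs share the subject-level truth draw", {
  coh <- simulate_cohort(14, measurement_cv = 0, render = FALSE, seed = 2)
  expect_length(coh, 28L)
  subj <- vapply(coh, `[[`, numeric(1), "subject")
  occl <- vapply(coh, `[[`, numeric(1), "occlusion_s")
  for (s in unique(subj)) {
    recs <- coh[subj == s]
    # same subject multiplier: the ratio target/default is shared across
    # the long and short measurement of a subject
    ratios <- vapply(recs, function(r) {
      occ <- if (r$occlusion_s >= 200) "long" else "short"
      r$targets$gastrocnemius$t2init_ms /
        default_targets("gastrocnemius", occ)$t2init_ms
    }, numeric(1))
    expect_equal(ratios[1], ratios[2], tolerance = 1e-12)
  }
  expect_setequal(unique(occl), c(300, 90))
})

test_that("cohort variability reproduces the configured CV", {
  coh <- simulate_cohort(
    200, design = data.frame(session = 1L, measurement = 1L,
                             occlusion_s = 300),
    variability = list(hpv_rise = 0.10), measurement_cv = 0,
    render = FALSE, seed = 123)
  rises <- vapply(coh, function(r) r$targets$gastrocnemius$hpv_au - 1,
                  numeric(1))
  cv_emp <- sd(rises) / mean(rises)
  expect_gt(cv_emp, 0.08)
  expect_lt(cv_emp, 0.12)
  expect_error(simulate_cohort(2, variability = list(hpv_rise = -1)),
               ">= 0")
  expect_error(simulate_cohort(2, variability = list(banana = 0.1)),
               "unknown")
})
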