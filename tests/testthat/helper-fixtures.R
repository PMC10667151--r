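# shared fixtures: small paradigms and phantoms used across test files

long_paradigm <- function() cuff_paradigm(occlusion_s = 300)
short_paradigm <- function() cuff_paradigm(occlusion_s = 90)

# a fast-rendering phantom for pipeline-level tests
tiny_phantom <- function(noise_model = "none", seed = 1L, ...) {
  phantom_config(matrix = c(24L, 24L), noise_model = noise_model,
                 seed = seed, ...)
}

# noiseless end-to-end products for a paradigm (rendered once per size)
render_noiseless <- function(paradigm = long_paradigm(), matrix = c(24L, 24L),
                             seed = 1L) {
  render_series(phantom_config(matrix = matrix, noise_model = "none",
                               seed = seed),
                paradigm = paradigm)
}

# synthetic noisy normalised curve from the default gastrocnemius truth
noisy_curve <- function(paradigm, sigma = 0.005, truth = NULL) {
  if (is.null(truth))
    truth <- truth_from_targets(default_targets("gastrocnemius", "long"),
                                paradigm)
  y <- model_eval(truth, time_axis(paradigm)) +
    stats::rnorm(n_frames(paradigm), 0, sigma)
  time_curve(time_axis(paradigm), y, normalized = y, t2init_ms = 26.3)
}

bold_names <- c("t2init_ms", "is_down_ms_per_s", "miv_au", "hs_up_ms_per_s",
                "tthp_s", "ttp_s", "hpv_au", "tthr_s")
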