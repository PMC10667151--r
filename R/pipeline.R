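#' Analyse one multi-echo measurement
#'
#' Runs the measurement-level chain: voxel-wise T2* mapping, ROI curve
#' extraction, baseline normalisation, descriptive-model fit and parameter
#' derivation, for every requested label.
#'
#' @param series A [multi_echo_series()].
#' @param mask A [roi_mask()].
#' @param paradigm The [cuff_paradigm()].
#' @param cfg A [fit_config()].
#' @param labels Integer labels to analyse (default both muscles).
#' @return List with `params` (one row per label: scaled BOLD parameters,
#'   fit diagnostics, and the raw model parameters prefixed `model_`) and
#'   `curves` (named list of normalised [time_curve()]s).
#' @export
analyze_series <- function(series, mask, paradigm, cfg = fit_config(),
                           labels = c(1L, 2L)) {
  t2 <- fit_t2star_series(series, mask = mask)
  curves <- list()
  rows <- list()
  for (lab in labels) {
    cv <- normalize_baseline(extract_curve(t2, mask, lab), paradigm)
    fit <- fit_model(cv, paradigm, cfg)
    bp <- derive_parameters(fit$params, cv$t2init_ms, paradigm)
    row <- report_scaled(bp)
    row$muscle <- muscle_name(lab)
    row$converged <- fit$diagnostics$converged
    row$degenerate <- fit$diagnostics$degenerate
    row$rss <- fit$diagnostics$rss
    mp <- unclass(fit$params)
    names(mp) <- paste0("model_", names(mp))
    rows[[length(rows) + 1L]] <- cbind(row, as.data.frame(mp))
    curves[[muscle_name(lab)]] <- cv
  }
  list(params = do.call(rbind, rows), curves = curves)
}

#' Pipeline configuration
#'
#' One configuration object (or YAML file) drives the full reproducible run:
#' cohort simulation, T2* mapping, curve extraction, model fitting and the
#' statistical report. The seed fixes every random draw in the run.
#'
#' @param n_subjects Cohort size.
#' @param design Measurement design passed to [simulate_cohort()].
#' @param variability,measurement_cv Cohort variability settings.
#' @param matrix Phantom matrix size.
#' @param noise_sigma,noise_model Phantom noise settings.
#' @param baseline_s,post_s,dt_s Paradigm timing.
#' @param fit A [fit_config()].
#' @param out_dir Output directory.
#' @param seed Run seed.
#' @param write_images Write NIfTI intermediates (series, masks, T2* maps).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(n_subjects = 3L,
                            design = data.frame(
                              session = c(1L, 1L, 2L),
                              measurement = c(1L, 2L, 1L),
                              occlusion_s = c(300, 300, 90)),
                            variability = NULL, measurement_cv = 0.03,
                            matrix = c(32L, 32L), noise_sigma = 0.02,
                            noise_model = "rician", baseline_s = 60,
                            post_s = 300, dt_s = 3.2, fit = fit_config(),
                            out_dir = tempfile("boldpq_run_"), seed = 1L,
                            write_images = FALSE) {
  structure(list(n_subjects = n_subjects, design = design,
                 variability = variability, measurement_cv = measurement_cv,
                 matrix = as.integer(matrix), noise_sigma = noise_sigma,
                 noise_model = noise_model, baseline_s = baseline_s,
                 post_s = post_s, dt_s = dt_s, fit = fit, out_dir = out_dir,
                 seed = as.integer(seed), write_images = write_images),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `design` may
#' be given as a list of rows with `session`, `measurement`, `occlusion_s`.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$design)) y$design <- do.call(rbind, lapply(y$design,
                                                            as.data.frame))
  if (!is.null(y$fit)) y$fit <- do.call(fit_config, y$fit)
  do.call(pipeline_config, y)
}

#' Run the full synthetic-cohort pipeline
#'
#' simulate -> fit-t2star -> extract-curves -> fit-model -> stats, writing
#' every tabular artifact (curves.csv, params.csv, report_*.csv) and a run
#' manifest with file hashes. Re-running with the same configuration (same
#' seed) reproduces byte-identical CSVs.
#'
#' @param cfg A [pipeline_config()] or path to a YAML file.
#' @param quiet Suppress stage messages.
#' @return Invisibly, the manifest (also written to `manifest.json`).
#' @export
run_pipeline <- function(cfg = pipeline_config(), quiet = FALSE) {
  if (is.character(cfg)) cfg <- pipeline_config_from_yaml(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  say("[simulate] %d subjects x %d measurements (seed %d)",
      cfg$n_subjects, nrow(cfg$design), cfg$seed)
  cohort <- simulate_cohort(
    cfg$n_subjects, design = cfg$design, variability = cfg$variability,
    measurement_cv = cfg$measurement_cv,
    phantom = phantom_config(matrix = cfg$matrix,
                             noise_sigma = cfg$noise_sigma,
                             noise_model = cfg$noise_model),
    baseline_s = cfg$baseline_s, post_s = cfg$post_s, dt_s = cfg$dt_s,
    render = TRUE, seed = cfg$seed)

  curves_df <- list()
  params_df <- list()
  truth_df <- list()
  for (rec in cohort) {
    tag <- sprintf("sub%02d_S%dM%d", rec$subject, rec$session,
                   rec$measurement)
    say("[analyse] %s (occlusion %gs)", tag, rec$occlusion_s)
    if (cfg$write_images) {
      write_series(rec$series, file.path(cfg$out_dir, tag), rec$paradigm)
      write_mask(rec$mask, file.path(cfg$out_dir, paste0(tag, "_mask")))
      write_truth(rec$truth, file.path(cfg$out_dir, paste0(tag, "_truth.json")))
    }
    res <- analyze_series(rec$series, rec$mask, rec$paradigm, cfg$fit)
    meta <- data.frame(subject = rec$subject, session = rec$session,
                       measurement = rec$measurement,
                       occlusion_s = rec$occlusion_s,
                       condition = condition_label(rec$occlusion_s))
    params_df[[tag]] <- cbind(meta[rep(1, nrow(res$params)), ], res$params)
    curves_df[[tag]] <- curves_to_df(res$curves, subject = rec$subject,
                                     session = rec$session,
                                     measurement = rec$measurement)
    for (mus in names(rec$truth$tissues)) {
      tb <- report_scaled(rec$truth$tissues[[mus]]$bold)
      tb$muscle <- mus
      truth_df[[paste(tag, mus)]] <- cbind(meta, tb)
    }
  }
  curves_df <- do.call(rbind, curves_df)
  params_df <- do.call(rbind, params_df)
  truth_df <- do.call(rbind, truth_df)
  rownames(curves_df) <- rownames(params_df) <- rownames(truth_df) <- NULL

  f_curves <- file.path(cfg$out_dir, "curves.csv")
  f_params <- file.path(cfg$out_dir, "params.csv")
  f_truth <- file.path(cfg$out_dir, "truth_params.csv")
  utils::write.csv(curves_df, f_curves, row.names = FALSE)
  utils::write.csv(params_df, f_params, row.names = FALSE)
  utils::write.csv(truth_df, f_truth, row.names = FALSE)

  say("[stats] condition contrast and repeatability")
  long <- params_long(params_df)
  files <- c(f_curves, f_params, f_truth)
  conds <- unique(params_df$condition)
  if (length(conds) >= 2) {
    rep_tab <- summarize_cohort(long[long$measurement == 1, ],
                                cond_a = conds[1], cond_b = conds[2])
    f_rep <- file.path(cfg$out_dir, "report_conditions.csv")
    utils::write.csv(rep_tab, f_rep, row.names = FALSE)
    files <- c(files, f_rep)
  }
  rep2 <- repeats_long(params_df)
  if (!is.null(rep2)) {
    cvtab <- summarize_repeatability(rep2)
    f_cv <- file.path(cfg$out_dir, "report_repeatability.csv")
    utils::write.csv(cvtab, f_cv, row.names = FALSE)
    files <- c(files, f_cv)
  }

  manifest <- list(
    package = "boldpq",
    version = as.character(utils::packageVersion("boldpq")),
    seed = cfg$seed,
    n_subjects = cfg$n_subjects,
    design = cfg$design,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  say("[done] %s", cfg$out_dir)
  invisible(manifest)
}

condition_label <- function(occlusion_s) {
  sprintf("occl_%gmin", occlusion_s / 60)
}

bold_param_cols <- c("t2init_ms", "is_down_e2", "miv_au", "hs_up_e2",
                     "tthp_s", "ttp_s", "hpv_au", "tthr_s")

# wide params table -> long (subject, condition, muscle, parameter, value)
params_long <- function(params_df) {
  out <- list()
  for (p in bold_param_cols) {
    out[[p]] <- data.frame(subject = params_df$subject,
                           session = params_df$session,
                           measurement = params_df$measurement,
                           condition = params_df$condition,
                           muscle = params_df$muscle, parameter = p,
                           value = params_df[[p]])
  }
  do.call(rbind, out)
}

# long table of intra-session repeats (measurement 1 vs 2 within a session)
repeats_long <- function(params_df) {
  has_rep <- any(params_df$measurement == 2)
  if (!has_rep) return(NULL)
  long <- params_long(params_df)
  long <- long[long$measurement %in% c(1, 2), ]
  sess <- unique(long$session[long$measurement == 2])
  long <- long[long$session %in% sess, ]
  data.frame(subject = paste(long$subject, long$session, sep = "_"),
             muscle = long$muscle, parameter = long$parameter,
             value = long$value, repeat_id = long$measurement)
}

#' Figures for a completed pipeline run
#'
#' Reads `curves.csv` and `params.csv` from a run directory and writes:
#' `fig_curves.png` (subject mean +/- SD normalised curves per muscle and
#' condition, optionally with the short-occlusion curves shifted so the
#' deflation times coincide), `fig_fit_overlay.png` (data and fitted model
#' for the first measurement), and, when intra-session repeats exist,
#' `fig_bland_altman.png`.
#'
#' @param out_dir Run directory produced by [run_pipeline()].
#' @param align_deflation Shift post-inflation parts of short-occlusion
#'   curves so that deflation timings coincide across conditions.
#' @return Invisibly, the figure paths written.
#' @export
plot_outputs <- function(out_dir, align_deflation = FALSE) {
  f_curves <- file.path(out_dir, "curves.csv")
  f_params <- file.path(out_dir, "params.csv")
  if (!file.exists(f_curves) || !file.exists(f_params))
    stop("run artifacts not found in ", out_dir,
         "; run_pipeline() must complete first", call. = FALSE)
  curves <- utils::read.csv(f_curves)
  params <- utils::read.csv(f_params)
  paths <- character()

  key <- merge(curves,
               unique(params[, c("subject", "session", "measurement",
                                 "occlusion_s", "condition")]),
               by = c("subject", "session", "measurement"))
  if (align_deflation) {
    max_occl <- max(key$occlusion_s)
    shift <- ifelse(key$time_s > 60 + key$occlusion_s,
                    max_occl - key$occlusion_s, 0)
    key$time_s <- key$time_s + shift
  }
  agg <- stats::aggregate(normalized ~ roi + condition + time_s, data = key,
                          FUN = function(v) c(m = mean(v), s = stats::sd(v)))
  agg <- cbind(agg[c("roi", "condition", "time_s")],
               mean = agg$normalized[, "m"],
               sd = ifelse(is.na(agg$normalized[, "s"]), 0,
                           agg$normalized[, "s"]))
  g <- ggplot2::ggplot(agg, ggplot2::aes(x = time_s, y = mean,
                                         colour = condition,
                                         fill = condition)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = mean - sd, ymax = mean + sd),
                         alpha = 0.25, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = "time (s)", y = "normalised T2*",
                  title = "Subject mean ± SD T2*-time curves") +
    ggplot2::theme_minimal()
  f <- file.path(out_dir, "fig_curves.png")
  ggplot2::ggsave(f, g, width = 9, height = 4, dpi = 120)
  paths <- c(paths, f)

  first <- params[params$subject == min(params$subject) &
                    params$session == min(params$session) &
                    params$measurement == min(params$measurement), ]
  cd <- curves[curves$subject == first$subject[1] &
                 curves$session == first$session[1] &
                 curves$measurement == first$measurement[1], ]
  fit_lines <- do.call(rbind, lapply(seq_len(nrow(first)), function(i) {
    mp <- as.list(first[i, grep("^model_", names(first))])
    names(mp) <- sub("^model_", "", names(mp))
    tt <- sort(unique(cd$time_s))
    data.frame(roi = first$muscle[i], time_s = tt,
               fit = model_eval(do.call(descriptive_params, mp), tt))
  }))
  g2 <- ggplot2::ggplot(cd, ggplot2::aes(x = time_s, y = normalized)) +
    ggplot2::geom_point(size = 0.4, colour = "firebrick") +
    ggplot2::geom_line(data = fit_lines, ggplot2::aes(y = fit),
                       colour = "steelblue") +
    ggplot2::facet_wrap(~roi) +
    ggplot2::labs(x = "time (s)", y = "normalised T2*",
                  title = "Descriptive model fit") +
    ggplot2::theme_minimal()
  f <- file.path(out_dir, "fig_fit_overlay.png")
  ggplot2::ggsave(f, g2, width = 9, height = 4, dpi = 120)
  paths <- c(paths, f)

  rep2 <- repeats_long(params)
  if (!is.null(rep2) && nrow(rep2)) {
    sel <- rep2[rep2$parameter %in% c("t2init_ms", "hpv_au", "tthp_s",
                                      "ttp_s"), ]
    wide <- merge(sel[sel$repeat_id == 1, ], sel[sel$repeat_id == 2, ],
                  by = c("subject", "muscle", "parameter"),
                  suffixes = c("_1", "_2"))
    if (nrow(wide) >= 3) {
      wide$mean <- (wide$value_1 + wide$value_2) / 2
      wide$diff <- wide$value_1 - wide$value_2
      g3 <- ggplot2::ggplot(wide, ggplot2::aes(x = mean, y = diff,
                                               colour = muscle)) +
        ggplot2::geom_point() +
        ggplot2::geom_hline(yintercept = 0, linetype = 2) +
        ggplot2::facet_wrap(~parameter, scales = "free") +
        ggplot2::labs(x = "mean of repeats", y = "difference",
                      title = "Intra-session agreement") +
        ggplot2::theme_minimal()
      f <- file.path(out_dir, "fig_bland_altman.png")
      ggplot2::ggsave(f, g3, width = 8, height = 6, dpi = 120)
      paths <- c(paths, f)
    }
  }
  invisible(paths)
}
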