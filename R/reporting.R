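#' Compare a per-animal measure between conditions
#'
#' Group tests on per-animal values (per-animal aggregation must precede this
#' call; see [avg_within_animal()]). For two conditions, a paired design uses
#' the Wilcoxon signed-rank test when a Shapiro-Wilk screen (alpha = 0.05) on
#' the paired differences rejects normality, otherwise a paired t-test;
#' unpaired designs analogously with two-sample tests. More than two
#' conditions fall back to one-way ANOVA. P-values are Bonferroni-adjusted by
#' `family_size`.
#'
#' @param df Data.frame with columns `animal_id`, `condition`, `value` (one
#'   row per animal per condition).
#' @param design `"paired"` or `"unpaired"`.
#' @param family_size Bonferroni family size (>= 1). Default 1.
#' @param measure Label carried into the result.
#' @return List of class `comparison_result`: `measure`, `test`, `statistic`,
#'   `p_value`, `p_adjusted`, `effect` (mean condition difference,
#'   second minus first level), `n_animals`, `normal` (screen outcome).
#' @export
compare_conditions <- function(df, design = c("paired", "unpaired"),
                               family_size = 1, measure = "measure") {
  design <- match.arg(design)
  if (family_size < 1) stop("family_size must be >= 1")
  stopifnot(all(c("animal_id", "condition", "value") %in% names(df)))
  df$condition <- as.factor(df$condition)
  lev <- levels(df$condition)
  if (length(lev) < 2) stop("need at least 2 conditions")
  shapiro_ok <- function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 3 || stats::sd(v) == 0) return(TRUE)
    stats::shapiro.test(v)$p.value >= 0.05
  }
  if (length(lev) > 2) {
    fit <- stats::aov(value ~ condition, data = df)
    an <- summary(fit)[[1]]
    res <- list(test = "one-way ANOVA", statistic = an$`F value`[1],
                p_value = an$`Pr(>F)`[1], effect = NA_real_, normal = NA)
    n_an <- length(unique(df$animal_id))
  } else if (design == "paired") {
    wide <- merge(df[df$condition == lev[1], c("animal_id", "value")],
                  df[df$condition == lev[2], c("animal_id", "value")],
                  by = "animal_id", suffixes = c("_1", "_2"))
    if (nrow(wide) < 3) stop("need at least 3 animals per condition")
    d <- wide$value_2 - wide$value_1
    normal <- shapiro_ok(d)
    if (identical(d, rep(0, length(d))) || stats::sd(d) == 0) {
      res <- list(test = "paired t-test (degenerate: identical values)",
                  statistic = 0, p_value = 1, effect = mean(d), normal = normal)
    } else if (normal) {
      tt <- stats::t.test(wide$value_2, wide$value_1, paired = TRUE)
      res <- list(test = "paired t-test", statistic = unname(tt$statistic),
                  p_value = tt$p.value, effect = mean(d), normal = normal)
    } else {
      wt <- stats::wilcox.test(wide$value_2, wide$value_1, paired = TRUE,
                               exact = TRUE)
      res <- list(test = "Wilcoxon signed-rank", statistic = unname(wt$statistic),
                  p_value = wt$p.value, effect = mean(d), normal = normal)
    }
    n_an <- nrow(wide)
  } else {
    v1 <- df$value[df$condition == lev[1]]
    v2 <- df$value[df$condition == lev[2]]
    if (length(v1) < 3 || length(v2) < 3) stop("need at least 3 animals per condition")
    normal <- shapiro_ok(v1) && shapiro_ok(v2)
    if (stats::sd(c(v1, v2)) == 0) {
      res <- list(test = "two-sample t-test (degenerate: identical values)",
                  statistic = 0, p_value = 1, effect = 0, normal = normal)
    } else if (normal) {
      tt <- stats::t.test(v2, v1)
      res <- list(test = "Welch two-sample t-test",
                  statistic = unname(tt$statistic),
                  p_value = tt$p.value, effect = mean(v2) - mean(v1),
                  normal = normal)
    } else {
      wt <- stats::wilcox.test(v2, v1)
      res <- list(test = "Wilcoxon rank-sum", statistic = unname(wt$statistic),
                  p_value = wt$p.value, effect = mean(v2) - mean(v1),
                  normal = normal)
    }
    n_an <- min(length(v1), length(v2))
  }
  structure(c(list(measure = measure), res,
              list(p_adjusted = min(1, res$p_value * family_size),
                   family_size = family_size, n_animals = n_an,
                   conditions = lev)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison> %s [%s]: %s stat=%.4g p=%.4g adj=%.4g effect=%.4g\n",
              x$measure, paste(x$conditions, collapse = " vs "), x$test,
              x$statistic, x$p_value, x$p_adjusted, x$effect))
  invisible(x)
}

#' Default pipeline configuration
#'
#' @param seed Master seed for all stochastic stages.
#' @param px_per_cm Pixel scale for side/top cameras.
#' @param confidence_threshold,max_gap_s Confidence filtering parameters.
#' @param median_n,box_n Smoothing filter widths (samples).
#' @param window_s,min_amp_cm,max_overlap_s Movement segmentation parameters.
#' @param k Motif cluster count.
#' @param var_retained PCA variance retained before clustering.
#' @param K,lag,kappa,arhmm_iter,arhmm_restarts ARHMM parameters.
#' @param posterior_threshold MAP-state posterior threshold.
#' @param n_folds,n_shuffle Decoding cross-validation parameters.
#' @param eye_scale_px Eye-camera calibration scale.
#' @param max_lag_s Cross-correlation max lag (seconds).
#' @return Named list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, px_per_cm = 10,
                            confidence_threshold = 0.9, max_gap_s = 0.1,
                            median_n = 3, box_n = 5,
                            window_s = 0.5, min_amp_cm = 1.0,
                            max_overlap_s = 0.25,
                            k = 10, var_retained = 0.95,
                            K = 4, lag = 1, kappa = 100,
                            arhmm_iter = 50, arhmm_restarts = 2,
                            posterior_threshold = 0.8,
                            n_folds = 10, n_shuffle = 100,
                            eye_scale_px = 50, max_lag_s = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Load a pipeline configuration from a YAML or JSON file
#'
#' Unknown keys are rejected; missing keys take [pipeline_config()] defaults.
#'
#' @param path File path (`.yaml`, `.yml`, or `.json`).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  vals <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(pipeline_config, vals)
}

#' Run the full analysis pipeline on a session directory
#'
#' Executes, in order: pose input + confidence filtering + calibration +
#' decision-period extraction; per-trial kinematics; movement segmentation and
#' motif clustering with per-condition statistics; gaze analysis (skipped with
#' a log note when no eye-camera files are present); ARHMM state inference,
#' transition features, and condition decoding; and per-animal condition
#' comparisons. All tables are written as CSV, the decoding report as JSON,
#' plus a run log and a manifest.
#'
#' @param config A `pipeline_config` (or path readable by
#'   [read_pipeline_config()]).
#' @param data_dir Directory holding `trials.csv` and `<trial>_<camera>.csv`
#'   pose files (as written by [write_session()]).
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the main in-memory results.
#' @export
run_pipeline <- function(config, data_dir, out_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(log_lines, log_path)
      stop("[stage ", name, "] ", conditionMessage(e), call. = FALSE)
    })
  }
  note("ethokit %s pipeline run; seed=%d",
       as.character(utils::packageVersion("ethokit")), config$seed)

  ## ---- stage: pose input ---------------------------------------------------
  trials <- NULL; side_dec <- list(); top_full <- list()
  stage("pose_data", {
    trials <- read_trial_table(file.path(data_dir, "trials.csv"))
    for (i in seq_len(nrow(trials))) {
      tid <- trials$trial_id[i]
      side_path <- file.path(data_dir, paste0(tid, "_side.csv"))
      top_path <- file.path(data_dir, paste0(tid, "_top.csv"))
      if (!file.exists(side_path)) stop("missing side pose file for ", tid)
      side <- filter_confidence(read_pose_table(side_path, camera_id = "side"),
                                config$confidence_threshold, config$max_gap_s)
      cal <- calibrate(side, config$px_per_cm)
      dec <- extract_decision_period(cal, trials[i, ])
      side_dec[[tid]] <- smooth_series(dec, config$median_n, config$box_n)
      if (file.exists(top_path)) {
        top <- filter_confidence(read_pose_table(top_path, camera_id = "top"),
                                 config$confidence_threshold, config$max_gap_s)
        top_full[[tid]] <- calibrate(top, config$px_per_cm)
      }
    }
    note("pose_data: %d trials read", nrow(trials))
  })

  ## ---- stage: kinematics ---------------------------------------------------
  kin <- NULL; perf <- NULL
  stage("kinematics", {
    kin <- trial_kinematics(trials, side_dec, top_full)
    utils::write.csv(kin, file.path(out_dir, "trial_kinematics.csv"),
                     row.names = FALSE)
    perf <- performance_summary(trials, kin)
    utils::write.csv(perf$cells, file.path(out_dir, "performance_cells.csv"),
                     row.names = FALSE)
    utils::write.csv(perf$by_condition,
                     file.path(out_dir, "performance_by_condition.csv"),
                     row.names = FALSE)
    note("kinematics: %d trial rows", nrow(kin))
  })

  ## ---- stage: movement motifs ---------------------------------------------
  motif_model <- NULL; stats_out <- NULL
  stage("movement_motifs", {
    sets <- lapply(side_dec, detect_movements,
                   window_s = config$window_s, min_amp_cm = config$min_amp_cm,
                   max_overlap_s = config$max_overlap_s)
    mv <- combine_movements(sets)
    k_eff <- min(config$k, n_movements(mv))
    motif_model <- cluster_movements(
      embed_movements(mv, config$var_retained), k = k_eff, seed = config$seed)
    utils::write.csv(motif_model$movements$meta,
                     file.path(out_dir, "movements.csv"), row.names = FALSE)
    stats_out <- cluster_stats(motif_model$movements, trials)
    utils::write.csv(stats_out$frequency,
                     file.path(out_dir, "cluster_frequency.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_out$amplitude,
                     file.path(out_dir, "cluster_amplitude.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_out$timing, file.path(out_dir, "cluster_timing.csv"),
                     row.names = FALSE)
    note("movement_motifs: %d movements, k=%d", n_movements(mv), k_eff)
  })

  ## ---- stage: gaze (optional) ---------------------------------------------
  gaze_rows <- list()
  have_eyes <- all(file.exists(file.path(
    data_dir, paste0(trials$trial_id[1], c("_left_eye.csv", "_right_eye.csv")))))
  if (!have_eyes) {
    note("gaze: no eye-camera files found; stage skipped")
  } else {
    stage("gaze", {
      for (i in seq_len(nrow(trials))) {
        tid <- trials$trial_id[i]
        lp <- file.path(data_dir, paste0(tid, "_left_eye.csv"))
        rp <- file.path(data_dir, paste0(tid, "_right_eye.csv"))
        if (!file.exists(lp) || !file.exists(rp)) next
        le <- fit_pupil_series(read_pose_table(lp, camera_id = "left_eye"))
        re <- fit_pupil_series(read_pose_table(rp, camera_id = "right_eye"))
        al <- eye_angles(le, default_eye_calibration("left", config$eye_scale_px))
        ar <- eye_angles(re, default_eye_calibration("right", config$eye_scale_px))
        pitch <- head_pitch(side_dec[[tid]])
        n <- min(nrow(al), nrow(ar), length(pitch))
        verg <- vergence(al$theta_deg[seq_len(n)], ar$theta_deg[seq_len(n)])
        phi <- (al$phi_deg[seq_len(n)] + ar$phi_deg[seq_len(n)]) / 2
        epoch <- split_epochs(seq_len(n) / side_dec[[tid]]$sample_rate,
                              n / side_dec[[tid]]$sample_rate)
        xc <- xcorr(pitch[seq_len(n)], phi, config$max_lag_s,
                    side_dec[[tid]]$sample_rate)
        reg <- tryCatch(pitch_gaze_regression(pitch[seq_len(n)], verg),
                        error = function(e) list(slope = NA, r_squared = NA))
        gaze_rows[[tid]] <- data.frame(
          trial_id = tid,
          xcorr_lag0 = xc$r[xc$lag == 0],
          vergence_slope = reg$slope, vergence_r2 = reg$r_squared,
          mean_verg_early = mean(verg[epoch == "early"], na.rm = TRUE),
          mean_verg_late = mean(verg[epoch == "late"], na.rm = TRUE),
          stringsAsFactors = FALSE)
      }
      gz <- do.call(rbind, gaze_rows)
      utils::write.csv(gz, file.path(out_dir, "gaze_summary.csv"),
                       row.names = FALSE)
      note("gaze: %d trials analysed", nrow(gz))
    })
  }

  ## ---- stage: state decoding ----------------------------------------------
  decoding <- NULL
  stage("state_decoding", {
    feats <- build_features(side_dec)
    hmm <- suppressWarnings(
      fit_arhmm(unname(feats), K = config$K, lag = config$lag,
                kappa = config$kappa, n_iter = config$arhmm_iter,
                seed = config$seed, n_restarts = config$arhmm_restarts))
    seqs <- lapply(feats, function(y)
      map_states(hmm, y, config$posterior_threshold))
    tf <- lapply(seqs, transition_features)
    keep <- !vapply(tf, is.null, logical(1))
    Xf <- do.call(rbind, tf[keep])
    lab <- trials$ocular_condition[match(names(tf)[keep], trials$trial_id)]
    seq_tab <- do.call(rbind, lapply(names(seqs), function(tid) {
      cbind(trial_id = tid, as.data.frame(seqs[[tid]]))
    }))
    utils::write.csv(seq_tab, file.path(out_dir, "state_sequences.csv"),
                     row.names = FALSE)
    if (length(unique(lab)) == 2) {
      decoding <- suppressWarnings(
        decode_condition(Xf, lab, n_folds = config$n_folds,
                         n_shuffle = config$n_shuffle, seed = config$seed))
      ws <- weight_significance(decoding)
      jsonlite::write_json(
        list(accuracy = decoding$accuracy,
             fold_accuracy = decoding$fold_accuracy,
             fold_z = decoding$fold_z, mean_z = decoding$mean_z,
             p_value = decoding$p_value,
             weights = ws),
        file.path(out_dir, "decoding_report.json"),
        auto_unbox = TRUE, digits = NA, dataframe = "columns")
      note("state_decoding: accuracy %.3f, mean z %.2f",
           decoding$accuracy, decoding$mean_z)
    } else {
      note("state_decoding: fewer than two conditions; decoder skipped")
    }
  })

  ## ---- stage: comparisons --------------------------------------------------
  comparisons <- NULL
  stage("reporting", {
    rows <- list()
    for (m in c("duration_s", "path_length_cm", "mean_pitch_deg")) {
      pa <- avg_within_animal(kin, m, by = "ocular_condition")
      per <- stats::aggregate(kin[[m]],
                              by = kin[c("ocular_condition", "animal_id")],
                              FUN = mean, na.rm = TRUE)
      names(per) <- c("condition", "animal_id", "value")
      cmp <- tryCatch(
        compare_conditions(per, "paired", family_size = 3, measure = m),
        error = function(e) NULL)
      if (!is.null(cmp)) {
        rows[[m]] <- data.frame(measure = m, test = cmp$test,
                                statistic = cmp$statistic,
                                p_value = cmp$p_value,
                                p_adjusted = cmp$p_adjusted,
                                effect = cmp$effect)
      }
    }
    comparisons <- do.call(rbind, rows)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    note("reporting: %d comparisons", if (is.null(comparisons)) 0L else nrow(comparisons))
  })

  jsonlite::write_json(
    list(package = "ethokit",
         version = as.character(utils::packageVersion("ethokit")),
         seed = config$seed,
         outputs = list.files(out_dir)),
    file.path(out_dir, "manifest.json"), auto_unbox = TRUE)
  writeLines(log_lines, log_path)
  invisible(list(trials = trials, kinematics = kin, performance = perf,
                 motif_model = motif_model, cluster_stats = stats_out,
                 decoding = decoding, comparisons = comparisons))
}
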