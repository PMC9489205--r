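#' Head pitch from the eye-ear segment (side camera)
#'
#' Pitch is the angle of the eye relative to the ear in the side view:
#' `atan2(eye_y - ear_y, eye_x - ear_x)` in degrees, with +x toward the gap
#' and +y up. 0 deg = eye level with the ear; negative = eye below the ear
#' (downward head tilt). Coincident eye/ear samples give `NA`.
#'
#' @param series A calibrated side-camera `calib_series` with `eye` and `ear`
#'   landmarks.
#' @param eye,ear Landmark names.
#' @return Numeric vector of pitch in degrees, in (-180, 180].
#' @export
head_pitch <- function(series, eye = "eye", ear = "ear") {
  segment_angle(series, eye, ear)
}

#' Head yaw from the eye-ear segment (top camera)
#'
#' Same construction as [head_pitch()] in the top view; 0 deg = head aligned
#' with the take-off-to-landing axis. The signed series is returned; summary
#' statistics conventionally use its magnitude.
#'
#' @inheritParams head_pitch
#' @return Numeric vector of yaw in degrees.
#' @export
head_yaw <- function(series, eye = "eye", ear = "ear") {
  segment_angle(series, eye, ear)
}

segment_angle <- function(series, a, b) {
  stopifnot(inherits(series, "calib_series"))
  for (nm in c(a, b)) {
    if (!nm %in% names(series$landmarks)) stop("landmark '", nm, "' not present")
  }
  dx <- series$landmarks[[a]]$x - series$landmarks[[b]]$x
  dy <- series$landmarks[[a]]$y - series$landmarks[[b]]$y
  ang <- atan2(dy, dx) * 180 / pi
  ang[dx == 0 & dy == 0] <- NA_real_
  ang
}

#' Distance jumped on a success or failure trial
#'
#' Horizontal displacement (cm) of the ear landmark in the top camera at the
#' landing frame, measured from the take-off-platform edge (the calibration
#' origin). Computed on raw calibrated positions, independent of smoothing.
#'
#' @param top_series Calibrated top-camera `calib_series` covering
#'   `land_frame`.
#' @param trial Trial record (outcome must be success or failure).
#' @param ear Landmark name. Default `"ear"`.
#' @return Distance in cm.
#' @export
jump_distance <- function(top_series, trial, ear = "ear") {
  stopifnot(inherits(top_series, "calib_series"))
  if (trial$outcome == "abort") stop("no jump on an abort trial")
  i <- match(as.integer(trial$land_frame), top_series$frames)
  if (is.na(i)) stop("land_frame not covered by series")
  top_series$landmarks[[ear]]$x[i]
}

#' Decision-period duration and eye path length
#'
#' Duration is the sample count over the rate; path length is the summed
#' Euclidean step length of the (already smoothed) eye trajectory. Fewer than
#' 2 samples yield path length 0 with a warning.
#'
#' @param series Decision-period `calib_series`.
#' @param landmark Landmark to trace. Default `"eye"`.
#' @return List with `duration_s` and `path_length_cm`.
#' @export
decision_metrics <- function(series, landmark = "eye") {
  stopifnot(inherits(series, "calib_series"))
  lm <- series$landmarks[[landmark]]
  if (is.null(lm)) stop("landmark '", landmark, "' not present")
  n <- nrow(lm)
  dur <- n / series$sample_rate
  if (n < 2) {
    warning("fewer than 2 samples; path length set to 0")
    return(list(duration_s = dur, path_length_cm = 0))
  }
  steps <- sqrt(diff(lm$x)^2 + diff(lm$y)^2)
  list(duration_s = dur, path_length_cm = sum(steps, na.rm = TRUE))
}

#' Average a per-trial measure within animal, then across animals
#'
#' The standard summary rule: per-animal means are computed first (across a
#' given animal's trials), then averaged across animals. Returns mean, SD and
#' SE across animals per group.
#'
#' @param df Data.frame with an `animal_id` column.
#' @param value Name of the value column.
#' @param by Character vector of grouping columns.
#' @return Data.frame with columns `by`, `mean`, `sd`, `se`, `n_animals`.
#' @export
avg_within_animal <- function(df, value, by) {
  per_animal <- stats::aggregate(
    df[[value]], by = df[c(by, "animal_id")], FUN = mean, na.rm = TRUE)
  names(per_animal)[ncol(per_animal)] <- "value"
  agg <- function(f) {
    out <- stats::aggregate(per_animal$value, by = per_animal[by], FUN = f)
    names(out)[ncol(out)] <- "v"
    out
  }
  m <- agg(function(v) mean(v, na.rm = TRUE))
  s <- agg(function(v) stats::sd(v, na.rm = TRUE))
  n <- agg(function(v) sum(!is.na(v)))
  m$sd <- s$v; m$n_animals <- n$v
  names(m)[names(m) == "v"] <- "mean"
  m$se <- m$sd / sqrt(pmax(m$n_animals, 1))
  m
}

#' Task-performance summary per condition, gap distance, and platform width
#'
#' Outcome fractions and landing statistics per cell, with per-animal means
#' computed first and then averaged across animals. Landing statistics
#' (mean/SD of distance jumped) use success and failure trials that carry a
#' `distance_jumped_cm` value in `metrics`.
#'
#' @param trials Trial-record data.frame.
#' @param metrics Optional data.frame with `trial_id` and `distance_jumped_cm`.
#' @param by Cell definition. Default condition x gap x width.
#' @return List with `cells` (per-cell summary data.frame) and `by_condition`
#'   (collapsed across gaps/widths).
#' @export
performance_summary <- function(trials, metrics = NULL,
                                by = c("ocular_condition", "gap_distance_cm",
                                       "platform_width_cm")) {
  validate_trials(trials)
  df <- trials
  for (oc in c("success", "failure", "abort")) {
    df[[paste0("is_", oc)]] <- as.numeric(df$outcome == oc)
  }
  if (!is.null(metrics)) {
    df <- merge(df, metrics[, c("trial_id", "distance_jumped_cm")],
                by = "trial_id", all.x = TRUE, sort = FALSE)
  }
  cell_summary <- function(group_cols) {
    out <- NULL
    for (oc in c("success", "failure", "abort")) {
      a <- avg_within_animal(df, paste0("is_", oc), group_cols)
      keep <- a[, c(group_cols, "mean"), drop = FALSE]
      names(keep)[ncol(keep)] <- paste0("frac_", oc)
      out <- if (is.null(out)) keep else merge(out, keep, by = group_cols)
    }
    if (!is.null(metrics)) {
      landed <- df[!is.na(df$distance_jumped_cm), , drop = FALSE]
      if (nrow(landed)) {
        a <- avg_within_animal(landed, "distance_jumped_cm", group_cols)
        names(a)[names(a) == "mean"] <- "mean_distance_cm"
        names(a)[names(a) == "sd"] <- "sd_distance_cm"
        out <- merge(out, a[, c(group_cols, "mean_distance_cm", "sd_distance_cm")],
                     by = group_cols, all.x = TRUE)
      }
    }
    out
  }
  list(cells = cell_summary(by), by_condition = cell_summary(by[1]))
}

#' Per-trial kinematic metrics table
#'
#' Convenience wrapper producing one row per trial: decision duration, eye
#' path length, mean pitch, mean absolute yaw, and distance jumped (success /
#' failure trials only).
#'
#' @param trials Trial-record data.frame.
#' @param side_series Named list (by trial_id) of calibrated side-camera
#'   decision-period series (smoothed).
#' @param top_series_full Named list (by trial_id) of calibrated full-length
#'   top-camera series (raw, for landing positions); optional.
#' @return Data.frame with one row per trial.
#' @export
trial_kinematics <- function(trials, side_series, top_series_full = NULL) {
  rows <- lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    ss <- side_series[[tr$trial_id]]
    if (is.null(ss)) return(NULL)
    dm <- decision_metrics(ss)
    pitch <- head_pitch(ss)
    yaw <- NA_real_; dj <- NA_real_
    if (!is.null(top_series_full) && !is.null(top_series_full[[tr$trial_id]])) {
      ts_full <- top_series_full[[tr$trial_id]]
      yaw_series <- head_yaw(extract_decision_period(ts_full, tr))
      yaw <- mean(abs(yaw_series), na.rm = TRUE)
      if (tr$outcome != "abort") dj <- jump_distance(ts_full, tr)
    }
    data.frame(trial_id = tr$trial_id, animal_id = tr$animal_id,
               ocular_condition = tr$ocular_condition,
               gap_distance_cm = tr$gap_distance_cm,
               platform_width_cm = tr$platform_width_cm,
               outcome = tr$outcome,
               duration_s = dm$duration_s,
               path_length_cm = dm$path_length_cm,
               mean_pitch_deg = mean(pitch, na.rm = TRUE),
               mean_abs_yaw_deg = yaw,
               distance_jumped_cm = dj,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
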