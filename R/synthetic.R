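#' Configuration for the synthetic pose-data generator
#'
#' Defines the study conditions emulated by [generate_trial()] and
#' [generate_dataset()]: decision-period head trajectories composed of discrete
#' movement motifs placed at condition-dependent Poisson rates, condition-
#' dependent head-pitch baselines carried by a rigid 1 cm eye-ear segment,
#' compensatory eye movements anti-correlated with pitch, and (optionally) a
#' latent-state sequence drawn from a known sticky ARHMM.
#'
#' @param seed Master seed; every trial draws from a counter-based substream of
#'   it, so results are independent of generation order.
#' @param sample_rate Sampling rate in Hz for all cameras.
#' @param conditions Condition labels (ocular conditions).
#' @param motif_rate Named per-condition mean number of movement motifs per
#'   trial (Poisson).
#' @param motif_templates List of motif templates from [default_motif_templates()];
#'   each a list with `name`, `x`, `y` (cm waveforms of exactly
#'   `0.5 * sample_rate` samples).
#' @param amp_jitter Multiplicative amplitude jitter half-range; each placed
#'   motif is scaled by `U(1 - amp_jitter, 1 + amp_jitter)`.
#' @param pitch_baseline Named per-condition mean head pitch in degrees
#'   (negative = downward).
#' @param pitch_sd Stationary SD (degrees) of the AR(1) pitch fluctuation.
#' @param pitch_ar AR(1) coefficient of the pitch fluctuation per sample.
#' @param yaw_baseline,yaw_sd Head yaw mean and stationary SD in degrees.
#' @param decision_duration Named per-condition mean decision-period duration
#'   in seconds (exponential, floored at 1 s and at the shortest duration that
#'   can host the trial's motif count without overlap).
#' @param drift_speed Magnitude in cm/s of the slow vertical baseline drift of
#'   the head (a smoothed triangle wave). A nonzero drift keeps the vertical
#'   velocity away from zero between movements, as in continuously moving
#'   animals, so velocity zero crossings mark the placed motifs.
#' @param drift_period Period in seconds of the baseline drift.
#' @param compensation_gain Eye-in-head angle per unit head pitch (unitless,
#'   default -1: perfect gaze compensation).
#' @param eye_noise_sd SD in degrees of white noise added to each eye-angle
#'   series.
#' @param noise_sd_cm SD in cm of white landmark tracking noise (sub-pixel
#'   jitter typical of markerless tracking at ~10 px/cm).
#' @param px_per_cm Pixel scale used when rendering tracks to pixels.
#' @param eye_scale_px Eyeball radius in pixels used by the eye-camera model
#'   (pupil displacement = `eye_scale_px * sin(angle)`).
#' @param trials_per_condition Number of trials per condition.
#' @param n_animals Number of simulated animals; trials are dealt round-robin
#'   and each animal carries a small idiosyncratic rate and pitch offset shared
#'   across conditions (paired design).
#' @param animal_rate_sd,animal_pitch_sd SDs of the per-animal offsets.
#' @param gap_distances,platform_widths Candidate gap distances and landing
#'   platform widths in cm, sampled uniformly per trial.
#' @param outcome_probs Named probabilities of success/failure/abort outcomes.
#' @param arhmm_truth Optional [arhmm_params()] object; when supplied, a latent
#'   state sequence is simulated per trial and recorded in the ground truth.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(seed = 1,
                             sample_rate = 60,
                             conditions = c("binocular", "monocular"),
                             motif_rate = c(binocular = 2, monocular = 4),
                             motif_templates = default_motif_templates(sample_rate),
                             amp_jitter = 0.1,
                             pitch_baseline = c(binocular = -20, monocular = -27),
                             pitch_sd = 3,
                             pitch_ar = 0.95,
                             yaw_baseline = 0,
                             yaw_sd = 5,
                             decision_duration = c(binocular = 2.5, monocular = 5.5),
                             drift_speed = 1.0,
                             drift_period = 4,
                             compensation_gain = -1,
                             eye_noise_sd = 0.3,
                             noise_sd_cm = 0.02,
                             px_per_cm = 10,
                             eye_scale_px = 50,
                             trials_per_condition = 20,
                             n_animals = 8,
                             animal_rate_sd = 0.15,
                             animal_pitch_sd = 1.5,
                             gap_distances = seq(10, 22, by = 2),
                             platform_widths = c(15, 20, 25),
                             outcome_probs = c(success = 0.7, failure = 0.2,
                                               abort = 0.1),
                             arhmm_truth = NULL) {
  stopifnot(sample_rate > 0, length(conditions) >= 1,
            all(motif_rate >= 0), all(decision_duration > 0),
            pitch_sd >= 0, yaw_sd >= 0, eye_noise_sd >= 0, noise_sd_cm >= 0,
            px_per_cm > 0, trials_per_condition >= 1, n_animals >= 1,
            all(gap_distances > 0), all(platform_widths > 0))
  w <- round(0.5 * sample_rate)
  for (tp in motif_templates) {
    if (length(tp$x) != w || length(tp$y) != w) {
      stop("motif templates must be exactly 0.5 s * sample_rate samples")
    }
  }
  if (abs(sum(outcome_probs) - 1) > 1e-8) stop("outcome_probs must sum to 1")
  cfg <- as.list(environment())
  class(cfg) <- "generator_config"
  cfg
}

#' Default movement-motif templates
#'
#' Three 500 ms head-movement waveforms with vertical amplitudes between
#' 1.5 and 3 cm: an upward bob, a downward dip, and a forward lunge with a
#' vertical bob. Each has zero vertical velocity at its center sample, so the
#' segmentation stage should recover the placement time exactly in the
#' noiseless limit.
#'
#' @param sample_rate Hz.
#' @return List of templates, each `list(name, x, y)` in cm.
#' @export
default_motif_templates <- function(sample_rate = 60) {
  w <- round(0.5 * sample_rate)
  pad <- round(0.1 * w)           # flat tails keep the reversal central
  s <- seq(0, 1, length.out = w - 2 * pad)
  hann <- c(rep(0, pad), 0.5 * (1 - cos(2 * pi * s)), rep(0, pad))
  sr <- seq(0, 1, length.out = w)
  ramp <- sr^2 * (3 - 2 * sr)     # smoothstep
  list(
    list(name = "bob_up",   x = rep(0, w),    y = 2.0 * hann),
    list(name = "dip_down", x = rep(0, w),    y = -2.5 * hann),
    list(name = "lunge",    x = 1.5 * ramp,   y = 1.8 * hann)
  )
}

# Deterministic per-(condition, trial) substream seed below 2^31.
substream_seed <- function(seed, cond_i, trial_i, salt = 0) {
  as.integer((as.numeric(seed %% 65536L) * 9973 + cond_i * 1299709 +
                trial_i * 7919 + salt * 104729) %% 2147483629)
}

deg2rad <- function(d) d * pi / 180

ar1_series <- function(n, mean, sd, phi) {
  if (sd == 0) return(rep(mean, n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - phi^2))
  x <- numeric(n)
  x[1] <- stats::rnorm(1, 0, sd)
  for (i in seq_len(n)[-1]) x[i] <- phi * x[i - 1] + e[i]
  mean + x
}

# Smoothed-triangle baseline drift: vertical velocity alternates between
# +v0 and -v0 with corners rounded over `corner_n` samples. The constant
# nonzero drift between corners guarantees that velocity zero crossings occur
# only at motif extrema (and at sub-threshold corner reversals), which is what
# makes the generator's motif bookkeeping recoverable by segmentation.
drift_velocity <- function(n, rate, v0, period_s, phase, corner_n = 12L) {
  u <- ((seq_len(n) - 1) / rate / period_s + phase) %% 1
  v <- ifelse(u < 0.5, v0, -v0)
  if (corner_n > 1L) {
    pad <- corner_n %/% 2L
    vp <- c(rep(v[1], pad), v, rep(v[n], pad))
    v <- as.numeric(stats::filter(vp, rep(1 / corner_n, corner_n),
                                  sides = 2))[(pad + 1):(pad + n)]
    v[is.na(v)] <- v0
  }
  v
}

# Sign of a template's initial vertical slope (+1 rising, -1 falling).
template_sign <- function(tp) {
  q <- max(2L, length(tp$y) %/% 4L)
  s <- sign(tp$y[q] - tp$y[1])
  if (s == 0) 1 else s
}

# Place motif centers where the baseline drift has full magnitude and the
# template's sign throughout a +/- guard zone, keeping centers >= w apart.
# Returns NULL when the trial is too short to host all motifs.
place_motifs <- function(n_count, v_base, w, signs, v0, guard = 27L,
                         max_tries = 5000L) {
  if (n_count == 0L) return(list(centers = integer(0), order = integer(0)))
  n <- length(v_base)
  half <- w %/% 2
  ok_pos <- v_base >= 0.98 * v0
  ok_neg <- v_base <= -0.98 * v0
  eroded <- function(ok) {
    run <- stats::filter(as.numeric(ok), rep(1, 2 * guard + 1), sides = 2)
    which(!is.na(run) & run == 2 * guard + 1)
  }
  cand <- list(`1` = eroded(ok_pos), `-1` = eroded(ok_neg))
  in_bounds <- function(cc) cc - half >= 1L && cc - half + w - 1L <= n
  centers <- integer(0)
  for (m in seq_len(n_count)) {
    pool <- cand[[as.character(signs[m])]]
    pool <- pool[vapply(pool, in_bounds, logical(1))]
    placed <- FALSE
    for (try in seq_len(max_tries %/% max(1L, n_count))) {
      if (!length(pool)) break
      cc <- pool[sample.int(length(pool), 1L)]
      if (all(abs(cc - centers) >= w)) {
        centers <- c(centers, cc)
        placed <- TRUE
        break
      }
    }
    if (!placed) return(NULL)
  }
  ord <- order(centers)
  list(centers = centers[ord], order = ord)
}

render_px <- function(x_cm, y_cm, px_per_cm, origin_px = c(100, 400)) {
  data.frame(x = origin_px[1] + x_cm * px_per_cm,
             y = origin_px[2] - y_cm * px_per_cm,   # image y grows downward
             confidence = 0.99)
}

#' Generate one synthetic trial
#'
#' Builds side/top-camera landmark tracks (nose, eye, ear, platform edge) and
#' bilateral eye-camera pupil-point tracks for one trial, together with the
#' trial record and full ground-truth bookkeeping. Deterministic given
#' `(config$seed, condition, trial_i)`.
#'
#' The decision-period eye trajectory is baseline posture plus Poisson-placed,
#' non-overlapping motif waveforms plus white tracking noise. Eye, ear, and
#' nose sit on a rigid head segment rotated by the pitch series (eye-ear
#' distance 1 cm), so angular kinematics can be recovered from the landmarks.
#' Eye-in-head angles are `compensation_gain * pitch` plus noise, split as
#' half-gain per eye for theta (so vergence carries the full gain) and full
#' gain for phi.
#'
#' @param config A [generator_config()].
#' @param condition Condition label (must be in `config$conditions`).
#' @param trial_i Trial counter within condition (1-based).
#' @param animal_offsets Optional list with `rate` and `pitch` per-animal
#'   offsets (as produced by [generate_dataset()]); `NULL` for none.
#' @param animal_i Animal index for this trial.
#' @return List with elements `side`, `top`, `left_eye`, `right_eye`
#'   ([pose_track()]s), `trial` (one-row data.frame), `truth` (list).
#' @export
generate_trial <- function(config, condition, trial_i, animal_offsets = NULL,
                           animal_i = 1L) {
  stopifnot(inherits(config, "generator_config"))
  cond_i <- match(condition, config$conditions)
  if (is.na(cond_i)) stop("unknown condition: ", condition)
  set.seed(substream_seed(config$seed, cond_i, trial_i))
  rate_hz <- config$sample_rate
  w <- round(0.5 * rate_hz)

  rate_off <- if (is.null(animal_offsets)) 0 else animal_offsets$rate[animal_i]
  pitch_off <- if (is.null(animal_offsets)) 0 else animal_offsets$pitch[animal_i]

  ## --- motif draw, then duration long enough to host it --------------------
  lambda <- max(0, unname(config$motif_rate[condition]) + rate_off)
  n_mot <- stats::rpois(1, lambda)
  tmpl_ids <- if (n_mot) sample.int(length(config$motif_templates), n_mot,
                                    replace = TRUE) else integer(0)
  amps <- if (n_mot) stats::runif(n_mot, 1 - config$amp_jitter,
                                  1 + config$amp_jitter) else numeric(0)
  signs <- vapply(config$motif_templates, template_sign, numeric(1))[tmpl_ids]

  mean_dur <- unname(config$decision_duration[condition])
  duration <- max(1, stats::rexp(1, rate = 1 / mean_dur), 1 + 1.4 * n_mot)
  phase <- stats::runif(1)
  centers <- NULL
  for (ext in 0:20) {                     # extend if placement cannot fit
    n_dec <- round((duration + ext) * rate_hz)
    v_base <- drift_velocity(n_dec, rate_hz, config$drift_speed,
                             config$drift_period, phase)
    pl <- place_motifs(n_mot, v_base, w, signs, config$drift_speed)
    if (!is.null(pl)) { centers <- pl$centers; break }
  }
  if (is.null(centers)) stop("motif placement failed: rate too high for ",
                             "non-overlapping windows")
  tmpl_ids <- tmpl_ids[pl$order]
  amps <- amps[pl$order]
  duration <- n_dec / rate_hz

  x0 <- -1; y0 <- 3                      # eye rest position, cm from platform edge
  y_drift <- cumsum(v_base) / rate_hz
  y_drift <- y_drift - mean(y_drift)
  eye_x <- rep(x0, n_dec); eye_y <- y0 + y_drift
  half <- w %/% 2
  for (m in seq_len(n_mot)) {
    idx <- (centers[m] - half):(centers[m] - half + w - 1L)
    tp <- config$motif_templates[[tmpl_ids[m]]]
    eye_x[idx] <- eye_x[idx] + amps[m] * tp$x
    eye_y[idx] <- eye_y[idx] + amps[m] * tp$y
  }

  ## --- head angles --------------------------------------------------------
  pitch <- ar1_series(n_dec, unname(config$pitch_baseline[condition]) + pitch_off,
                      config$pitch_sd, config$pitch_ar)
  yaw <- ar1_series(n_dec, config$yaw_baseline, config$yaw_sd, config$pitch_ar)

  ## --- flight segment and outcome ----------------------------------------
  gap <- sample(config$gap_distances, 1)
  width <- sample(config$platform_widths, 1)
  outcome <- sample(names(config$outcome_probs), 1, prob = config$outcome_probs)
  n_fly <- round(0.5 * rate_hz)
  landing_x <- switch(outcome,
    success = gap + stats::rnorm(1, 1, 0.5),
    failure = gap - 1 - abs(stats::rnorm(1, 1, 0.5)),
    abort = NA_real_)
  if (outcome == "abort") {
    n_total <- n_dec
    jump_frame <- land_frame <- n_dec       # dismount moment; no flight
  } else {
    n_total <- n_dec + n_fly
    jump_frame <- n_dec
    land_frame <- n_total - 1L      # 0-based index of the landing frame
    fly_frac <- seq(0, 1, length.out = n_fly)
    eye_x <- c(eye_x, x0 + (landing_x - x0) * fly_frac)
    eye_y <- c(eye_y, y0 + 2 * sin(pi * fly_frac))     # jump arc
    pitch <- c(pitch, rep(pitch[n_dec], n_fly))
    yaw <- c(yaw, rep(yaw[n_dec], n_fly))
  }

  ## --- rigid head segment: ear behind eye, nose ahead ---------------------
  pr <- deg2rad(pitch); yr <- deg2rad(yaw)
  ear_x <- eye_x - cos(pr); ear_y <- eye_y - sin(pr)
  nose_x <- eye_x + 0.5 * cos(pr); nose_y <- eye_y + 0.5 * sin(pr)
  # top view: x along gap axis, "y" = lateral position
  eye_lat <- rep(0, n_total)
  ear_lat <- eye_lat - sin(yr)
  ear_x_top <- eye_x - cos(yr)
  nose_lat <- eye_lat + 0.5 * sin(yr)
  nose_x_top <- eye_x + 0.5 * cos(yr)
  # landing bookkeeping uses the ear in the top view
  if (outcome != "abort") ear_x_top[n_total] <- landing_x

  nz <- function(v) v + stats::rnorm(length(v), 0, config$noise_sd_cm)
  ppc <- config$px_per_cm
  side <- pose_track(list(
    nose = render_px(nz(nose_x), nz(nose_y), ppc),
    eye = render_px(nz(eye_x), nz(eye_y), ppc),
    ear = render_px(nz(ear_x), nz(ear_y), ppc),
    platform_edge = render_px(nz(rep(0, n_total)), nz(rep(0, n_total)), ppc)
  ), sample_rate = rate_hz, camera_id = "side")
  top <- pose_track(list(
    nose = render_px(nz(nose_x_top), nz(nose_lat), ppc),
    eye = render_px(nz(eye_x), nz(eye_lat), ppc),
    ear = render_px(nz(ear_x_top), nz(ear_lat), ppc),
    platform_edge = render_px(nz(rep(0, n_total)), nz(rep(0, n_total)), ppc)
  ), sample_rate = rate_hz, camera_id = "top")

  ## --- compensatory eye movements (decision period only) ------------------
  g <- config$compensation_gain
  pd <- pitch[seq_len(n_dec)]
  theta_l <- 0.5 * g * pd + stats::rnorm(n_dec, 0, config$eye_noise_sd)
  theta_r <- 0.5 * g * pd + stats::rnorm(n_dec, 0, config$eye_noise_sd)
  phi_l <- g * pd + stats::rnorm(n_dec, 0, config$eye_noise_sd)
  phi_r <- g * pd + stats::rnorm(n_dec, 0, config$eye_noise_sd)
  left_eye <- render_eye_track(theta_l, phi_l, "left_eye", config)
  right_eye <- render_eye_track(theta_r, phi_r, "right_eye", config)

  ## --- latent states (bookkeeping only) ------------------------------------
  states <- NULL
  if (!is.null(config$arhmm_truth)) {
    sim <- simulate_arhmm(config$arhmm_truth, T = n_dec,
                          seed = substream_seed(config$seed, cond_i, trial_i, 1))
    states <- sim$states
  }

  trial_id <- sprintf("%s_a%02d_t%04d", condition, animal_i, trial_i)
  trial <- data.frame(
    trial_id = trial_id, session_id = "synth",
    animal_id = sprintf("a%02d", animal_i),
    ocular_condition = condition, laser = "none",
    gap_distance_cm = gap, platform_width_cm = width, outcome = outcome,
    start_frame = 0L, jump_frame = jump_frame, land_frame = land_frame,
    stringsAsFactors = FALSE
  )
  truth <- list(
    trial_id = trial_id, condition = condition, animal_i = animal_i,
    duration_s = duration, n_decision = n_dec,
    motif_centers = centers, motif_center_times = (centers - 1) / rate_hz,
    motif_templates = tmpl_ids, motif_amplitudes = amps,
    pitch = pitch[seq_len(n_dec)], yaw = yaw[seq_len(n_dec)],
    theta_l = theta_l, theta_r = theta_r, phi_l = phi_l, phi_r = phi_r,
    landing_x = landing_x, states = states
  )
  list(side = side, top = top, left_eye = left_eye, right_eye = right_eye,
       trial = trial, truth = truth)
}

# Render eye-in-head angle series as a pupil-point pose track: eight points on
# a pupil ellipse around the displaced pupil center, in eye-camera pixels.
render_eye_track <- function(theta, phi, camera_id, config) {
  n <- length(theta)
  rest <- c(320, 240)
  sc <- config$eye_scale_px
  nasal_sign <- if (camera_id == "left_eye") 1 else -1
  cx <- rest[1] + nasal_sign * sc * sin(deg2rad(theta))
  cy <- rest[2] - sc * sin(deg2rad(phi))
  ang <- seq(0, 2 * pi, length.out = 9L)[-9L]
  a <- 30; b <- 24
  landmarks <- lapply(seq_along(ang), function(i) {
    data.frame(x = cx + a * cos(ang[i]) + stats::rnorm(n, 0, 0.3),
               y = cy + b * sin(ang[i]) + stats::rnorm(n, 0, 0.3),
               confidence = 0.99)
  })
  names(landmarks) <- sprintf("pupil%d", seq_along(ang))
  pose_track(landmarks, sample_rate = config$sample_rate, camera_id = camera_id)
}

#' Condition-specific sticky chains for the decoding benchmark
#'
#' Two experimental "conditions" that share emission parameters and differ
#' only in transition structure: both are sticky 4-state chains
#' (`p_self` on the diagonal), but condition `+1` routes its preferred
#' off-diagonal mass `pref` around the state cycle forward
#' (1 -> 2 -> 3 -> 4 -> 1) and condition `-1` backward. The remaining mass is
#' spread evenly. Emissions are well-separated AR fixed points so MAP states
#' are crisp and decoding tests isolate transition information.
#'
#' @param direction `+1` (forward cycle) or `-1` (backward).
#' @param K States. Default 4.
#' @param p_self Self-transition probability. Default 0.8.
#' @param pref Preferred off-diagonal transition probability. Default 0.14.
#' @param spread,noise_sd,rho Emission geometry, see [default_arhmm_params()].
#' @return An [arhmm_params()].
#' @export
condition_chain_params <- function(direction, K = 4, p_self = 0.8,
                                   pref = 0.14, spread = 6, noise_sd = 0.25,
                                   rho = 0.6) {
  stopifnot(direction %in% c(-1, 1), K >= 2, p_self + pref < 1)
  base <- default_arhmm_params(K = K, d = 2, p_self = p_self, spread = spread,
                               noise_sd = noise_sd, rho = rho)
  off <- (1 - p_self - pref) / max(1, K - 2)
  P <- matrix(off, K, K)
  diag(P) <- p_self
  for (i in seq_len(K)) {
    j <- if (direction > 0) i %% K + 1L else (i - 2L) %% K + 1L
    P[i, j] <- pref
  }
  arhmm_params(base$A, base$b, base$Sigma, P, lag = 1)
}

#' Generate a synthetic dataset
#'
#' `trials_per_condition` trials per condition, interleaved across conditions,
#' with animals dealt round-robin. Each animal keeps the same idiosyncratic
#' rate/pitch offset in every condition (paired design).
#'
#' @param config A [generator_config()].
#' @return List of class `synth_dataset`: `trials` (data.frame), `tracks`
#'   (named per-trial list of pose tracks), `truth` (named per-trial list),
#'   `animal_offsets`, `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (length(config$conditions) == 0) stop("empty condition list")
  set.seed(substream_seed(config$seed, 0L, 0L, 2))
  offsets <- list(rate = stats::rnorm(config$n_animals, 0, config$animal_rate_sd),
                  pitch = stats::rnorm(config$n_animals, 0, config$animal_pitch_sd))
  trials <- list(); tracks <- list(); truth <- list()
  for (i in seq_len(config$trials_per_condition)) {
    for (cond in config$conditions) {
      animal_i <- ((i - 1L) %% config$n_animals) + 1L
      tr <- generate_trial(config, cond, i, offsets, animal_i)
      trials[[tr$trial$trial_id]] <- tr$trial
      tracks[[tr$trial$trial_id]] <- tr[c("side", "top", "left_eye", "right_eye")]
      truth[[tr$trial$trial_id]] <- tr$truth
    }
  }
  trials <- do.call(rbind, trials)
  rownames(trials) <- NULL
  validate_trials(trials)
  structure(list(trials = trials, tracks = tracks, truth = truth,
                 animal_offsets = offsets, config = config),
            class = "synth_dataset")
}

#' Write a synthetic dataset to disk in the pipeline's file formats
#'
#' Writes `trials.csv`, one DLC-dialect CSV per camera per trial
#' (`<trial_id>_<camera>.csv`), a ground-truth JSON sidecar, and a manifest.
#'
#' @param dataset A `synth_dataset` from [generate_dataset()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synth_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trial_table(dataset$trials, file.path(dir, "trials.csv"))
  for (tid in names(dataset$tracks)) {
    for (cam in names(dataset$tracks[[tid]])) {
      write_pose_table(dataset$tracks[[tid]][[cam]],
                       file.path(dir, sprintf("%s_%s.csv", tid, cam)))
    }
  }
  jsonlite::write_json(dataset$truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest <- list(n_trials = nrow(dataset$trials),
                   conditions = dataset$config$conditions,
                   sample_rate = dataset$config$sample_rate,
                   px_per_cm = dataset$config$px_per_cm,
                   seed = dataset$config$seed)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
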