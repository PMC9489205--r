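#' Confidence-filter a pose track
#'
#' Samples whose tracking confidence falls below `threshold` become gaps (`NA`).
#' Gaps flanked by valid samples are then linearly interpolated when the gap is
#' no longer than `max_gap_s`; longer gaps (and gaps touching either end of the
#' series) remain missing.
#'
#' @param track A [pose_track()].
#' @param threshold Confidence threshold in `[0, 1]`. Default 0.9.
#' @param max_gap_s Longest gap (seconds) bridged by interpolation. Default 0.1.
#' @return A `pose_track` with low-confidence samples removed or interpolated.
#'   Interpolated samples keep their original (sub-threshold) confidence.
#' @export
filter_confidence <- function(track, threshold = 0.9, max_gap_s = 0.1) {
  stopifnot(inherits(track, "pose_track"))
  if (threshold < 0 || threshold > 1) stop("`threshold` must be in [0, 1]")
  max_gap_n <- floor(max_gap_s * track$sample_rate)
  nms <- names(track$landmarks)
  track$landmarks <- lapply(nms, function(nm) {
    lm <- track$landmarks[[nm]]
    bad <- is.na(lm$confidence) | lm$confidence < threshold
    if (all(bad)) {
      warning("landmark '", nm, "' entirely below confidence threshold")
      lm$x[] <- NA_real_; lm$y[] <- NA_real_
      return(lm)
    }
    lm$x[bad] <- NA_real_
    lm$y[bad] <- NA_real_
    lm$x <- bridge_gaps(lm$x, max_gap_n)
    lm$y <- bridge_gaps(lm$y, max_gap_n)
    lm
  })
  names(track$landmarks) <- nms
  track
}

# Linear interpolation of interior NA runs of length <= max_gap_n.
bridge_gaps <- function(v, max_gap_n) {
  if (!anyNA(v) || max_gap_n < 1L) return(v)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in seq_along(r$lengths)) {
    if (!r$values[i] || r$lengths[i] > max_gap_n) next
    a <- starts[i] - 1L; b <- ends[i] + 1L
    if (a < 1L || b > length(v)) next        # edge gaps stay missing
    idx <- starts[i]:ends[i]
    v[idx] <- v[a] + (v[b] - v[a]) * (idx - a) / (b - a)
  }
  v
}

#' Calibrate a pose track to centimetres
#'
#' Converts pixel coordinates to cm relative to the session-median position of
#' a static origin landmark (the take-off-platform edge), and flips the
#' vertical axis so that +y is up (image y grows downward).
#'
#' @param track A [pose_track()].
#' @param px_per_cm Pixels per centimetre (> 0).
#' @param origin_landmark Name of the origin landmark. Default
#'   `"platform_edge"`.
#' @param per_frame If `TRUE`, subtract the origin landmark frame by frame
#'   instead of its session median. Default `FALSE` (the origin is static;
#'   per-frame subtraction injects tracker jitter into every series).
#' @return A `calib_series` object: fields `t` (s), `sample_rate`, `frames`,
#'   `camera_id`, `origin`, and `landmarks` (named list of data.frames with
#'   `x`, `y` in cm).
#' @export
calibrate <- function(track, px_per_cm, origin_landmark = "platform_edge",
                      per_frame = FALSE) {
  stopifnot(inherits(track, "pose_track"))
  if (!is.numeric(px_per_cm) || px_per_cm <= 0) stop("`px_per_cm` must be > 0")
  if (!origin_landmark %in% names(track$landmarks)) {
    stop("origin landmark '", origin_landmark, "' not present in track")
  }
  o <- track$landmarks[[origin_landmark]]
  if (per_frame) {
    ox <- o$x; oy <- o$y
  } else {
    ox <- stats::median(o$x, na.rm = TRUE)
    oy <- stats::median(o$y, na.rm = TRUE)
  }
  landmarks <- lapply(track$landmarks, function(lm) {
    data.frame(x = (lm$x - ox) / px_per_cm,
               y = (oy - lm$y) / px_per_cm)   # flip: +y up
  })
  structure(
    list(t = track$frames / track$sample_rate,
         sample_rate = track$sample_rate,
         frames = track$frames,
         camera_id = track$camera_id,
         origin = origin_landmark,
         landmarks = landmarks),
    class = "calib_series"
  )
}

#' @export
print.calib_series <- function(x, ...) {
  cat(sprintf("<calib_series> camera=%s  %d samples @ %g Hz  origin=%s\n",
              x$camera_id, length(x$t), x$sample_rate, x$origin))
  invisible(x)
}

#' Median + box smoothing of calibrated series
#'
#' Applies a running-median filter (width `median_n`) followed by a moving
#' average ("box") filter (width `box_n`) to every coordinate of every
#' landmark. Length is preserved; edges are handled by reflection padding.
#'
#' @param series A `calib_series` (or single numeric vector via
#'   [smooth_vector()]).
#' @param median_n Odd median-filter width in samples. Default 3.
#' @param box_n Odd box-filter width in samples. Default 5.
#' @return The smoothed `calib_series`.
#' @export
smooth_series <- function(series, median_n = 3, box_n = 5) {
  stopifnot(inherits(series, "calib_series"))
  series$landmarks <- lapply(series$landmarks, function(lm) {
    data.frame(x = smooth_vector(lm$x, median_n, box_n),
               y = smooth_vector(lm$y, median_n, box_n))
  })
  series
}

#' Median + box smoothing of a numeric vector
#'
#' @param v Numeric vector.
#' @inheritParams smooth_series
#' @return Smoothed vector, same length.
#' @export
smooth_vector <- function(v, median_n = 3, box_n = 5) {
  if (median_n %% 2 != 1 || box_n %% 2 != 1 || median_n < 1 || box_n < 1) {
    stop("filter widths must be odd positive integers")
  }
  n <- length(v)
  if (n < max(median_n, box_n)) stop("series shorter than filter width")
  if (median_n > 1) {
    pad <- median_n %/% 2
    vp <- stats::runmed(reflect_pad(v, pad), median_n, endrule = "keep")
    v <- vp[(pad + 1):(pad + n)]
  }
  if (box_n > 1) {
    pad <- box_n %/% 2
    vp <- as.numeric(stats::filter(reflect_pad(v, pad), rep(1 / box_n, box_n),
                                   sides = 2))
    v <- vp[(pad + 1):(pad + n)]
  }
  v
}

reflect_pad <- function(v, pad) {
  if (pad == 0L) return(v)
  n <- length(v)
  if (pad >= n) stop("series shorter than filter width")
  c(v[(pad + 1):2], v, v[(n - 1):(n - pad)])
}

#' Extract the decision period of a trial
#'
#' Returns the sub-series spanning the half-open frame interval
#' `[start_frame, jump_frame)` — barrier removal up to the last frame before
#' the jump or abort.
#'
#' @param series A `calib_series`.
#' @param trial A single trial record (one-row data.frame or list with
#'   `start_frame` and `jump_frame`).
#' @return A `calib_series` restricted to the decision period.
#' @export
extract_decision_period <- function(series, trial) {
  stopifnot(inherits(series, "calib_series"))
  s <- as.integer(trial$start_frame); j <- as.integer(trial$jump_frame)
  if (j <= s) stop("jump_frame must exceed start_frame")
  keep <- series$frames >= s & series$frames < j
  if (!any(keep)) stop("decision period [", s, ", ", j, ") not covered by series")
  series$frames <- series$frames[keep]
  series$t <- series$t[keep]
  series$landmarks <- lapply(series$landmarks, function(lm) lm[keep, , drop = FALSE])
  series
}

#' Resample a pose track to a target rate by linear interpolation
#'
#' Used to bring heterogeneous camera rates onto a common 60 Hz clock before
#' analysis. Confidence is carried by nearest-neighbour lookup.
#'
#' @param track A [pose_track()].
#' @param rate Target rate in Hz. Default 60.
#' @return A `pose_track` at `rate` Hz.
#' @export
resample_track <- function(track, rate = 60) {
  stopifnot(inherits(track, "pose_track"))
  if (track$sample_rate == rate) return(track)
  t_old <- track$frames / track$sample_rate
  n_new <- floor(max(t_old) * rate) + 1L
  t_new <- (seq_len(n_new) - 1L) / rate
  track$landmarks <- lapply(track$landmarks, function(lm) {
    data.frame(
      x = stats::approx(t_old, lm$x, xout = t_new, rule = 2)$y,
      y = stats::approx(t_old, lm$y, xout = t_new, rule = 2)$y,
      confidence = stats::approx(t_old, lm$confidence, xout = t_new,
                                 method = "constant", rule = 2, f = 0)$y
    )
  })
  track$frames <- seq_len(n_new) - 1L
  track$sample_rate <- rate
  track
}
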