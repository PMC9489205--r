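#' Direct least-squares ellipse fit to pupil points
#'
#' Fits a conic constrained to an ellipse (4AC - B^2 > 0) to at least five
#' points by the numerically stable direct least-squares method (generalized
#' eigenproblem on scatter-matrix blocks). Exact on noiseless conic data.
#'
#' @param points `n x 2` matrix of x/y pixel coordinates, n >= 5.
#' @return List with `valid` (logical), `center` (x, y), `axes` (semi-major,
#'   semi-minor), `angle` (major-axis orientation, radians in `[0, pi)`).
#'   Degenerate input returns `valid = FALSE`.
#' @export
fit_pupil_ellipse <- function(points) {
  pts <- as.matrix(points)
  invalid <- list(valid = FALSE, center = c(NA_real_, NA_real_),
                  axes = c(NA_real_, NA_real_), angle = NA_real_)
  if (nrow(pts) < 5 || anyNA(pts)) return(invalid)
  mx <- mean(pts[, 1]); my <- mean(pts[, 2])
  x <- pts[, 1] - mx; y <- pts[, 2] - my
  D1 <- cbind(x^2, x * y, y^2)
  D2 <- cbind(x, y, 1)
  S1 <- crossprod(D1); S2 <- crossprod(D1, D2); S3 <- crossprod(D2)
  Tm <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(Tm)) return(invalid)
  M <- S1 + S2 %*% Tm
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)   # inv(C1) %*% M
  eg <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(eg)) return(invalid)
  V <- Re(eg$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  ok <- which(cond > 0)
  if (!length(ok)) return(invalid)
  a1 <- V[, ok[1]]
  coef <- c(a1, as.numeric(Tm %*% a1))          # A B C D E F (centered frame)
  A <- coef[1]; B <- coef[2]; C <- coef[3]
  D <- coef[4]; E <- coef[5]; Fc <- coef[6]
  den <- B^2 - 4 * A * C
  cx <- (2 * C * D - B * E) / den
  cy <- (2 * A * E - B * D) / den
  F0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + Fc
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  eq <- eigen(Q, symmetric = TRUE)
  ax2 <- -F0 / eq$values
  if (any(ax2 <= 0) || !all(is.finite(ax2))) return(invalid)
  semi <- sqrt(ax2)
  major <- which.max(semi)
  ang <- atan2(eq$vectors[2, major], eq$vectors[1, major]) %% pi
  list(valid = TRUE, center = c(cx + mx, cy + my),
       axes = c(semi[major], semi[-major]), angle = ang)
}

#' Fit pupil ellipses across an eye-camera pose track
#'
#' @param track Eye-camera [pose_track()] whose landmarks are the tracked
#'   pupil points.
#' @param pattern Regex selecting pupil landmarks. Default `"^pupil"`.
#' @return Data.frame per frame: `cx`, `cy`, `a`, `b`, `angle`, `valid`.
#' @export
fit_pupil_series <- function(track, pattern = "^pupil") {
  stopifnot(inherits(track, "pose_track"))
  parts <- grep(pattern, names(track$landmarks), value = TRUE)
  if (length(parts) < 5) stop("need at least 5 pupil landmarks")
  n <- n_frames(track)
  out <- data.frame(cx = rep(NA_real_, n), cy = NA_real_, a = NA_real_,
                    b = NA_real_, angle = NA_real_, valid = FALSE)
  xs <- sapply(parts, function(p) track$landmarks[[p]]$x)
  ys <- sapply(parts, function(p) track$landmarks[[p]]$y)
  for (i in seq_len(n)) {
    fit <- fit_pupil_ellipse(cbind(xs[i, ], ys[i, ]))
    if (fit$valid) {
      out$cx[i] <- fit$center[1]; out$cy[i] <- fit$center[2]
      out$a[i] <- fit$axes[1]; out$b[i] <- fit$axes[2]
      out$angle[i] <- fit$angle; out$valid[i] <- TRUE
    }
  }
  out
}

#' Eye-in-head angles from pupil-center displacement
#'
#' Small spherical eye model: the pupil center displaces from its rest
#' position by `scale_px * sin(angle)`, so angles are recovered by arcsine of
#' the normalized displacement. Signs: theta positive = nasal, phi positive =
#' up (image y grows downward).
#'
#' @param ellipses Data.frame from [fit_pupil_series()].
#' @param calib List with `scale_px` (eyeball radius in px), `rest` (rest
#'   pupil center, length-2), `nasal_sign` (+1 if nasal is +x in the image,
#'   -1 otherwise).
#' @return Data.frame with `theta_deg`, `phi_deg` (`NA` on invalid frames or
#'   displacement beyond the model's range).
#' @export
eye_angles <- function(ellipses, calib) {
  if (is.null(calib$scale_px) || is.null(calib$rest)) {
    stop("eye calibration must supply scale_px and rest center")
  }
  ns <- if (is.null(calib$nasal_sign)) 1 else calib$nasal_sign
  dx <- (ellipses$cx - calib$rest[1]) * ns / calib$scale_px
  dy <- (calib$rest[2] - ellipses$cy) / calib$scale_px
  safe_asin <- function(u) {
    out <- rep(NA_real_, length(u))
    ok <- is.finite(u) & abs(u) <= 1
    out[ok] <- asin(u[ok]) * 180 / pi
    out
  }
  th <- safe_asin(dx); ph <- safe_asin(dy)
  th[!ellipses$valid] <- NA_real_; ph[!ellipses$valid] <- NA_real_
  data.frame(theta_deg = th, phi_deg = ph)
}

#' Binocular vergence from per-eye horizontal angles
#'
#' Under the nasal-positive convention, vergence is the sum of the two eyes'
#' theta; positive = convergent (greater binocular overlap).
#'
#' @param theta_left,theta_right Aligned horizontal angle series (degrees).
#' @return Numeric vergence series (degrees).
#' @export
vergence <- function(theta_left, theta_right) {
  if (length(theta_left) != length(theta_right)) {
    stop("theta series lengths differ")
  }
  theta_left + theta_right
}

#' Split a decision period into early and late epochs
#'
#' The late epoch is the 2 s preceding the jump; the early epoch runs from
#' trial start to the late boundary. Decision periods of 2 s or less yield an
#' empty early epoch with a warning.
#'
#' @param t Time stamps (seconds) of the decision-period samples, relative to
#'   trial start.
#' @param jump_time Time of the jump (seconds, = decision duration).
#' @param late_s Late-epoch length in seconds. Default 2.
#' @return Character vector over samples: `"early"` or `"late"`.
#' @export
split_epochs <- function(t, jump_time, late_s = 2) {
  boundary <- jump_time - late_s
  lab <- ifelse(t < boundary, "early", "late")
  if (!any(lab == "early")) warning("decision period <= ", late_s,
                                    " s: early epoch empty")
  lab
}

#' Normalized cross-correlation between two series
#'
#' Pearson correlation of the overlapping segments at every integer-sample lag
#' in `[-max_lag, +max_lag]`; `r(lag) = cor(a[t], b[t + lag])`, so a peak at a
#' positive lag means `b` is a delayed copy of `a`. Zero-variance overlaps
#' give `NA`.
#'
#' @param a,b Equal-length numeric series.
#' @param max_lag_s Maximum lag in seconds.
#' @param rate Sampling rate in Hz.
#' @return Data.frame with `lag` (samples), `lag_s`, `r`.
#' @export
xcorr <- function(a, b, max_lag_s, rate) {
  if (length(a) != length(b)) stop("series lengths differ")
  n <- length(a)
  L <- min(floor(max_lag_s * rate), n - 2L)
  lags <- (-L):L
  r <- vapply(lags, function(k) {
    if (k >= 0) { ai <- 1:(n - k); bi <- (1 + k):n }
    else { ai <- (1 - k):n; bi <- 1:(n + k) }
    x <- a[ai]; y <- b[bi]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    stats::cor(x, y)
  }, numeric(1))
  data.frame(lag = lags, lag_s = lags / rate, r = r)
}

#' Ordinary least-squares regression of a gaze variable on head pitch
#'
#' @param pitch Head pitch samples (degrees).
#' @param gaze Gaze variable samples (degrees), same length.
#' @param min_n Minimum paired samples. Default 10.
#' @return List with `slope`, `intercept`, `r_squared`, `n`.
#' @export
pitch_gaze_regression <- function(pitch, gaze, min_n = 10) {
  ok <- is.finite(pitch) & is.finite(gaze)
  x <- pitch[ok]; y <- gaze[ok]
  if (length(x) < min_n) stop("need at least ", min_n, " paired samples")
  if (stats::sd(x) == 0) stop("constant regressor: pitch has no variance")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = summary(fit)$r.squared, n = length(x))
}

#' Default eye-camera calibration matching the synthetic generator's geometry
#'
#' @param eye `"left"` or `"right"`.
#' @param scale_px Eyeball radius in pixels.
#' @return Calibration list for [eye_angles()].
#' @export
default_eye_calibration <- function(eye = c("left", "right"), scale_px = 50) {
  eye <- match.arg(eye)
  list(scale_px = scale_px, rest = c(320, 240),
       nasal_sign = if (eye == "left") 1 else -1)
}
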