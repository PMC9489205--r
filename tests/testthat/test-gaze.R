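circle_points <- function(cx, cy, r, n = 8, a = r, b = r, rot = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x0 <- a * cos(th); y0 <- b * sin(th)
  cbind(cx + cos(rot) * x0 - sin(rot) * y0,
        cy + sin(rot) * x0 + cos(rot) * y0)
}

test_that("ellipse fit is exact on noiseless conics", {
  f <- fit_pupil_ellipse(circle_points(3, -2, 5))
  expect_true(f$valid)
  expect_equal(f$center, c(3, -2), tolerance = 1e-9)
  expect_equal(f$axes, c(5, 5), tolerance = 1e-9)
  # axis-aligned ellipse a=2, b=1
  f2 <- fit_pupil_ellipse(circle_points(0, 0, NA, a = 2, b = 1))
  expect_equal(f2$center, c(0, 0), tolerance = 1e-8)
  expect_equal(f2$axes, c(2, 1), tolerance = 1e-6)
  # rotated ellipse recovers orientation
  f3 <- fit_pupil_ellipse(circle_points(1, 1, NA, a = 3, b = 1, rot = 0.6))
  expect_equal(f3$angle, 0.6, tolerance = 1e-6)
  # degenerate inputs -> invalid frame
  expect_false(fit_pupil_ellipse(cbind(1:4, 1:4))$valid)
  expect_false(fit_pupil_ellipse(cbind(1:8, 2 * (1:8)))$valid)   # collinear
})

test_that("noisy ellipse centers are unbiased and close to a grid-search oracle", {
  set.seed(14)
  errs <- matrix(0, 200, 2)
  for (i in 1:200) {
    pts <- circle_points(10, 20, 5) + matrix(rnorm(16, sd = 0.1), 8, 2)
    f <- fit_pupil_ellipse(pts)
    errs[i, ] <- f$center - c(10, 20)
  }
  expect_lt(max(abs(colMeans(errs))), 0.02)          # bias ~ 0
  rmse <- sqrt(mean(errs^2))
  # oracle: centroid of points on a full circle is an unbiased center estimate
  # with RMSE sigma/sqrt(n); the constrained fit should be comparable
  expect_lt(rmse, 2 * 0.1 / sqrt(8))
})

test_that("eye angles invert the displacement model with the sign conventions", {
  ell <- data.frame(cx = c(320, 320 + 50 * sin(10 * pi / 180), 320),
                    cy = c(240, 240, 240 - 50 * sin(5 * pi / 180)),
                    a = 30, b = 24, angle = 0, valid = TRUE)
  cal <- default_eye_calibration("left")
  ang <- eye_angles(ell, cal)
  expect_equal(ang$theta_deg, c(0, 10, 0), tolerance = 1e-9)
  expect_equal(ang$phi_deg, c(0, 0, 5), tolerance = 1e-9)
  # right eye: nasal is -x
  angR <- eye_angles(ell, default_eye_calibration("right"))
  expect_equal(angR$theta_deg[2], -10, tolerance = 1e-9)
  expect_error(eye_angles(ell, list(rest = c(0, 0))), "calibration")
})

test_that("vergence is the nasal-positive sum and epochs partition the trial", {
  expect_equal(vergence(c(0, 2), c(0, 2)), c(0, 4))
  expect_error(vergence(1:3, 1:2), "lengths differ")
  t5 <- seq(0, 5, by = 1 / 60)
  lab <- split_epochs(t5, 5)
  expect_setequal(unique(lab), c("early", "late"))
  expect_equal(max(t5[lab == "early"]) < 3, TRUE)
  expect_equal(sum(lab == "late") / 60, 2, tolerance = 0.05)
  expect_length(lab, length(t5))                     # exact partition
  expect_warning(split_epochs(seq(0, 1.9, by = 1 / 60), 1.9), "early epoch empty")
})

test_that("cross-correlation matches a shifted-Pearson oracle and is symmetric", {
  set.seed(4)
  n <- 400
  a <- as.numeric(arima.sim(list(ar = 0.9), n))
  expect_equal(xcorr(a, a, 0.2, 60)$r[xcorr(a, a, 0.2, 60)$lag == 0], 1)
  expect_equal(xcorr(a, -a, 0.2, 60)$r[13], -1)      # lag 0 at index L+1 = 13
  b <- c(rep(NA, 5), a[1:(n - 5)]) + rnorm(n, sd = 0.1)
  xc <- xcorr(a, b, 10 / 60, 60)
  expect_equal(xc$lag[which.max(xc$r)], 5)
  # brute-force oracle at a few lags
  for (k in c(-7, 0, 3)) {
    if (k >= 0) r_or <- cor(a[1:(n - k)], b[(1 + k):n], use = "complete.obs")
    else r_or <- cor(a[(1 - k):n], b[1:(n + k)], use = "complete.obs")
    expect_equal(xc$r[xc$lag == k], r_or, tolerance = 1e-12)
  }
  # symmetry property
  xab <- xcorr(a, b, 10 / 60, 60); xba <- xcorr(b, a, 10 / 60, 60)
  expect_equal(xab$r, rev(xba$r), tolerance = 1e-12)
  # zero variance -> missing
  expect_true(is.na(xcorr(rep(1, 50), rnorm(50), 0.1, 60)$r[7]))
})

test_that("pitch regression: exact fits, nulls, and generator gain recovery", {
  x <- seq(-30, -10, length.out = 50)
  ex <- suppressWarnings(pitch_gaze_regression(x, -x + 3))  # exact fit warns
  expect_equal(ex$slope, -1); expect_equal(ex$r_squared, 1)
  set.seed(6)
  nullr <- pitch_gaze_regression(rnorm(10000), rnorm(10000))
  expect_lt(nullr$r_squared, 0.05)
  expect_error(pitch_gaze_regression(rep(1, 20), rnorm(20)), "constant")
  expect_error(pitch_gaze_regression(1:5, 1:5), "at least 10")
  # generator arithmetic: gain -1 with noise set for R^2 = 0.5
  set.seed(7)
  p <- rnorm(5000, sd = 3)
  g <- -p + rnorm(5000, sd = 3)
  r <- pitch_gaze_regression(p, g)
  expect_equal(r$r_squared, 0.5, tolerance = 0.1)
  expect_equal(r$slope, -1, tolerance = 0.1)
})

test_that("full synthetic eye loop: pupil fit, angles, vergence algebra", {
  cfg <- generator_config(seed = 19)
  g <- generate_trial(cfg, "binocular", 2)
  al <- eye_angles(fit_pupil_series(g$left_eye), default_eye_calibration("left"))
  ar <- eye_angles(fit_pupil_series(g$right_eye), default_eye_calibration("right"))
  expect_lt(sqrt(mean((al$phi_deg - g$truth$phi_l)^2)), 3 * cfg$eye_noise_sd)
  # vergence slope on true pitch is about -2 x per-eye gain (= gain)
  v <- vergence(al$theta_deg, ar$theta_deg)
  fit <- pitch_gaze_regression(g$truth$pitch, v)
  expect_equal(fit$slope, cfg$compensation_gain, tolerance = 0.15)
})
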