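make_track <- function(n = 5, parts = c("eye", "ear")) {
  lms <- lapply(seq_along(parts), function(i) {
    data.frame(x = seq_len(n) + 10 * i, y = seq_len(n) - 10 * i,
               confidence = rep(0.95, n))
  })
  names(lms) <- parts
  pose_track(lms, sample_rate = 60)
}

test_that("pose CSV round trip preserves landmarks, order, and values", {
  tk <- make_track()
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_table(tk, f)
  tk2 <- read_pose_table(f, sample_rate = 60)
  expect_equal(names(tk2$landmarks), names(tk$landmarks))
  expect_equal(n_frames(tk2), 5L)
  for (p in names(tk$landmarks)) {
    expect_equal(tk2$landmarks[[p]], tk$landmarks[[p]], tolerance = 1e-12)
  }
  # second write is byte-identical
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_pose_table(tk2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("gaps serialize as empty cells and read back as NA", {
  tk <- make_track()
  tk$landmarks$eye$x[3] <- NA
  f <- withr::local_tempfile(fileext = ".csv")
  write_pose_table(tk, f)
  row3 <- strsplit(readLines(f)[3 + 3], ",")[[1]]
  expect_identical(row3[2], "")          # eye x is the first data column
  tk2 <- read_pose_table(f)
  expect_true(is.na(tk2$landmarks$eye$x[3]))
  expect_equal(tk2$landmarks$eye$confidence[3], 0.95)
})

test_that("malformed headers and duplicated columns are rejected by name", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("scorerX,s,s,s", "bodyparts,eye,eye,eye", "coords,x,y,likelihood",
               "0,1,2,0.9"), f)
  expect_error(read_pose_table(f), "header row 1")
  writeLines(c("scorer,s,s,s,s,s,s", "bodyparts,eye,eye,eye,eye,eye,eye",
               "coords,x,y,likelihood,x,y,likelihood", "0,1,2,.9,1,2,.9"), f)
  expect_error(read_pose_table(f), "duplicated")
  tk <- make_track()
  tk$landmarks <- list()
  class(tk) <- "pose_track"
  expect_error(write_pose_table(tk, f), "no landmarks")
})

test_that("confidence filtering interpolates short gaps and keeps long ones", {
  n <- 60
  lm <- data.frame(x = as.numeric(1:n), y = as.numeric(n:1),
                   confidence = rep(1, n))
  lm$confidence[10] <- 0.2                       # single low sample
  lm$confidence[30:41] <- 0.2                    # 12 samples = 200 ms at 60 Hz
  tk <- pose_track(list(eye = lm), sample_rate = 60)
  out <- filter_confidence(tk, 0.9, max_gap_s = 0.1)
  # single gap between valid neighbours -> exact linear midpoint
  expect_equal(out$landmarks$eye$x[10], (9 + 11) / 2)
  # 200 ms gap exceeds the 100 ms bridge -> stays missing
  expect_true(all(is.na(out$landmarks$eye$x[30:41])))
  # 200 ms gap is bridged when max_gap_s covers it
  out2 <- filter_confidence(tk, 0.9, max_gap_s = 0.25)
  expect_equal(out2$landmarks$eye$x[30:41], as.numeric(30:41))
  # identity when every confidence passes
  lm$confidence <- rep(1, n)
  tk <- pose_track(list(eye = lm), sample_rate = 60)
  expect_equal(filter_confidence(tk, 1.0)$landmarks$eye, tk$landmarks$eye)
  # fully sub-threshold landmark warns and goes all-missing
  lm$confidence <- rep(0.1, n)
  tk <- pose_track(list(eye = lm), sample_rate = 60)
  expect_warning(out3 <- filter_confidence(tk, 0.9), "entirely below")
  expect_true(all(is.na(out3$landmarks$eye$x)))
})

test_that("calibration centers on the origin landmark and flips y upward", {
  n <- 4
  tk <- pose_track(list(
    eye = data.frame(x = rep(130, n), y = rep(410, n), confidence = 1),
    platform_edge = data.frame(x = rep(100, n), y = rep(400, n), confidence = 1)
  ), sample_rate = 60)
  cal <- calibrate(tk, px_per_cm = 10)
  expect_equal(cal$landmarks$eye$x, rep(3, n))      # 30 px right at 10 px/cm
  expect_equal(cal$landmarks$eye$y, rep(-1, n))     # 10 px down -> -1 cm (+y up)
  expect_equal(cal$landmarks$platform_edge$x, rep(0, n))
  expect_error(calibrate(tk, 10, origin_landmark = "nose"), "not present")
  expect_error(calibrate(tk, -1), "px_per_cm")
})

test_that("smoothing matches a brute-force reflected-window filter", {
  set.seed(42)
  v <- rnorm(200)
  ref <- function(v, pad) c(v[(pad + 1):2], v, v[(length(v) - 1):(length(v) - pad)])
  # brute force: median-3 with reflection, then box-5 with reflection
  n <- length(v)
  vp <- ref(v, 1)
  med <- vapply(seq_len(n), function(i) median(vp[i:(i + 2)]), numeric(1))
  mp <- ref(med, 2)
  box <- vapply(seq_len(n), function(i) mean(mp[i:(i + 4)]), numeric(1))
  expect_equal(smooth_vector(v, 3, 5), box, tolerance = 1e-12)
  # constant series unchanged; additive constants commute
  expect_equal(smooth_vector(rep(2.5, 30)), rep(2.5, 30))
  expect_equal(smooth_vector(v + 7), smooth_vector(v) + 7, tolerance = 1e-12)
  # a lone spike is removed by the median stage
  sp <- rep(0, 31); sp[16] <- 5
  expect_equal(smooth_vector(sp, 3, 1), rep(0, 31))
  expect_error(smooth_vector(rnorm(3), 3, 5), "shorter")
  expect_error(smooth_vector(rnorm(30), 4, 5), "odd")
})

test_that("decision period is the half-open [start, jump) window", {
  s <- make_series(seq(0, 10, length.out = 241), rep(0, 241))
  tr <- make_trial(start_frame = 0L, jump_frame = 120L, land_frame = 150L)
  dec <- extract_decision_period(s, tr)
  expect_equal(length(dec$t), 120L)
  expect_equal(length(dec$t) / dec$sample_rate, 2.0)
  tr1 <- make_trial(start_frame = 10L, jump_frame = 11L, land_frame = 12L)
  dec1 <- extract_decision_period(s, tr1)
  expect_equal(length(dec1$t), 1L)
  expect_error(extract_decision_period(
    s, make_trial(start_frame = 5L, jump_frame = 5L)), "exceed")
})

test_that("trial table round trips and invariants are enforced", {
  tr <- rbind(make_trial("t1"), make_trial("t2", outcome = "abort",
                                           jump_frame = 80L, land_frame = 80L))
  f <- withr::local_tempfile(fileext = ".csv")
  write_trial_table(tr, f)
  expect_equal(read_trial_table(f), tr)
  bad <- make_trial(start_frame = 50L, jump_frame = 40L)
  expect_error(validate_trials(bad), "ordering")
  bad2 <- make_trial(); bad2$outcome <- "meh"
  expect_error(validate_trials(bad2), "outcome")
})
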