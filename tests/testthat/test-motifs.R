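test_that("segmentation obeys the five rules on constructed signals", {
  rate <- 60
  t <- seq(0, 5, by = 1 / rate)
  # monotone series: velocity never changes sign -> no movements
  mono <- make_series(t, 2 * t, rate)
  expect_equal(n_movements(detect_movements(mono)), 0L)
  # sub-threshold oscillation: crossings exist, amplitudes 0.8 cm < 1 cm
  small <- make_series(t * 0, 0.4 * sin(2 * pi * t), rate)
  expect_equal(n_movements(detect_movements(small)), 0L)
  # 1 Hz, 2 cm sine: crossings every 0.5 s, amplitudes 4 cm, overlap 0 ms
  big <- make_series(t * 0, 2 * sin(2 * pi * t), rate)
  mv <- detect_movements(big)
  expect_gt(n_movements(mv), 0L)
  expect_true(all(mv$meta$amplitude_cm >= 1))
  expect_true(all(diff(mv$meta$center_index) >= 30))
  # empty input
  expect_equal(n_movements(detect_movements(make_series(numeric(0), numeric(0)))), 0L)
})

test_that("segmentation equals the brute-force oracle on random smoothed traces", {
  set.seed(101)
  rate <- 60
  for (rep in 1:60) {
    n <- sample(120:600, 1)
    y <- smooth_vector(cumsum(rnorm(n, sd = 0.3)), 3, 5)
    s <- make_series(rep(0, n), y, rate)
    got <- detect_movements(s)$meta$center_index
    want <- brute_force_movements(y, rate)
    expect_identical(as.integer(got), as.integer(want))
  }
})

test_that("retained movements never overlap a previous one by more than 250 ms", {
  set.seed(55)
  rate <- 60
  for (rep in 1:20) {
    n <- 500
    y <- smooth_vector(2 * sin(2 * pi * seq(0, 6, length.out = n) *
                                 runif(1, 0.5, 2)) + cumsum(rnorm(n, sd = 0.2)),
                       3, 5)
    mv <- detect_movements(make_series(rep(0, n), y, rate))
    if (n_movements(mv) > 1) {
      overlaps <- (30 - diff(mv$meta$center_index)) / rate
      expect_true(all(overlaps <= 0.25))
    }
    expect_true(all(mv$meta$amplitude_cm >= 1))
  }
})

test_that("PCA embedding retains variance and separates duplicates", {
  set.seed(3)
  w <- 30
  mk <- function(trace, n) {
    meta <- data.frame(trial_id = rep("t", n), center_index = seq_len(n) * 40,
                       center_time_s = seq_len(n) * 40 / 60,
                       amplitude_cm = 2, cluster_id = NA_integer_)
    ethokit:::movement_set(meta, matrix(rep(trace$x, n), n, byrow = TRUE),
                           matrix(rep(trace$y, n), n, byrow = TRUE), 0.5, 60)
  }
  a <- list(x = rep(0, w), y = sin(seq(0, pi, length.out = w)))
  b <- list(x = seq(0, 1, length.out = w), y = -sin(seq(0, pi, length.out = w)))
  mv <- combine_movements(list(t1 = mk(a, 5), t2 = mk(b, 5)))
  model <- embed_movements(mv)
  # two distinct movement shapes -> one component explains everything
  expect_equal(model$n_components, 1L)
  expect_equal(unname(model$scores[1, 1]), unname(-model$scores[6, 1]),
               tolerance = 1e-9)
  # duplicates get identical scores
  expect_equal(model$scores[1, ], model$scores[2, ])
  expect_error(embed_movements(mk(a, 1)), "at least 2")
})

test_that("k-means clustering is seeded and ordered by trace variance", {
  cfg <- generator_config(seed = 2, motif_rate = c(binocular = 3, monocular = 3),
                          trials_per_condition = 25, n_animals = 2)
  ds <- generate_dataset(cfg)
  sets <- list(); truth_lab <- list()
  for (tid in names(ds$tracks)) {
    tr <- ds$trials[ds$trials$trial_id == tid, ]
    sm <- smooth_series(extract_decision_period(
      calibrate(ds$tracks[[tid]]$side, cfg$px_per_cm), tr))
    mv <- detect_movements(sm)
    sets[[tid]] <- mv
    tc <- ds$truth[[tid]]$motif_centers
    ti <- ds$truth[[tid]]$motif_templates
    truth_lab[[tid]] <- vapply(mv$meta$center_index, function(d) {
      j <- which.min(abs(tc - d))
      if (length(j) && abs(tc[j] - d) <= 3) ti[j] else NA_integer_
    }, numeric(1))
  }
  mv <- combine_movements(sets)
  model <- cluster_movements(embed_movements(mv), k = 3, seed = 7)
  model2 <- cluster_movements(embed_movements(mv), k = 3, seed = 7)
  expect_identical(model$cluster, model2$cluster)       # bit-reproducible
  expect_true(all(diff(model$cluster_trace_var) <= 1e-12))  # descending order
  lab <- unlist(truth_lab)
  ok <- !is.na(lab)
  expect_gt(adjusted_rand_index(model$cluster[ok], lab[ok]), 0.9)
  expect_error(cluster_movements(embed_movements(mv), k = n_movements(mv) + 1),
               "exceeds")
})

test_that("cluster statistics count per trial and normalize timing histograms", {
  trials <- rbind(make_trial("t1", "a01"), make_trial("t2", "a01"))
  meta <- data.frame(
    trial_id = c("t1", "t1", "t1", "t2"),
    center_index = c(10L, 20L, 30L, 10L),
    center_time_s = c(10, 20, 30, 10) / 60,
    amplitude_cm = c(2, 2.5, 1.5, 3),
    cluster_id = c(2L, 2L, 2L, 1L))
  mv <- ethokit:::movement_set(meta, matrix(0, 4, 30), matrix(0, 4, 30), 0.5, 60)
  st <- cluster_stats(mv, trials)
  f <- st$frequency
  expect_equal(f$mean[f$cluster_id == 2 & f$ocular_condition == "binocular"],
               1.5)                      # (3 + 0)/2 trials
  expect_equal(f$mean[f$cluster_id == 1 & f$ocular_condition == "binocular"],
               0.5)
  for (cl in unique(st$timing$cluster_id)) {
    expect_equal(sum(st$timing$prop[st$timing$cluster_id == cl]), 1)
  }
})

test_that("pitch-frequency relation handles monotone, degenerate, coupled inputs", {
  expect_equal(pitch_frequency_relation(1:5, 5:1)$rho, -1)
  r <- pitch_frequency_relation(c(1, 2, 3), c(2, 2, 2))
  expect_true(is.na(r$rho))
  expect_error(pitch_frequency_relation(1:2, 2:1), "at least 3")
  set.seed(9)
  n <- 20
  x <- rnorm(n)
  y <- -0.8 * x + rnorm(n, sd = sqrt(1 - 0.64))
  res <- pitch_frequency_relation(x, y)
  expect_lt(res$rho, 0)
  expect_lt(res$p_value, 0.05)
  expect_lt(res$slope, 0)
})
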