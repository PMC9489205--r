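test_that("forward-backward posteriors match exhaustive path enumeration", {
  set.seed(2)
  params <- default_arhmm_params(K = 3, d = 2, p_self = 0.7, spread = 2,
                                 noise_sd = 0.5)
  sim <- simulate_arhmm(params, T = 8, seed = 5)
  gamma <- state_posteriors(params, sim$obs)
  oracle <- enumerate_posteriors(params, sim$obs)
  expect_lt(max(abs(gamma - oracle)), 1e-10)
  expect_equal(rowSums(gamma), rep(1, nrow(gamma)), tolerance = 1e-12)
})

test_that("K=1 EM reduces to closed-form least-squares AR regression", {
  set.seed(10)
  sim <- simulate_arhmm(default_arhmm_params(K = 1, d = 2), T = 2000, seed = 4)
  fit <- fit_arhmm(sim$obs, K = 1, n_iter = 5, n_restarts = 1)
  y <- sim$obs
  X <- cbind(y[-nrow(y), ], 1)
  Y <- y[-1, ]
  W <- t(solve(crossprod(X), crossprod(X, Y)))
  expect_equal(unname(cbind(fit$A[[1]], fit$b[[1]])), unname(W),
               tolerance = 1e-6)
  ms <- map_states(fit, y)
  expect_true(all(ms$posterior[-1] == 1))
  expect_false(any(ms$excluded[-1]))
})

test_that("EM objective is non-decreasing and the sticky fit recovers truth", {
  truth <- default_arhmm_params(K = 3, d = 2)
  sim <- simulate_arhmm(truth, T = 6000, seed = 8)
  # kappa = 0: the objective IS the data log-likelihood
  fit0 <- suppressWarnings(fit_arhmm(sim$obs, K = 3, kappa = 0, n_iter = 30,
                                     seed = 1, n_restarts = 1))
  expect_true(all(diff(attr(fit0, "objective")) > -1e-8))
  fit <- suppressWarnings(fit_arhmm(sim$obs, K = 3, kappa = 500, n_iter = 40,
                                    seed = 1, n_restarts = 2))
  expect_true(all(diff(attr(fit, "objective")) > -1e-8))
  ms <- map_states(fit, sim$obs, threshold = 0)
  pa <- permutation_accuracy(ms$state[-1], sim$states[-1], 3)
  expect_gt(pa$accuracy, 0.9)
})

test_that("posterior thresholding excludes exactly the sub-threshold frames", {
  params <- default_arhmm_params(K = 3, d = 2, p_self = 0.7, spread = 1.2,
                                 noise_sd = 0.6)
  sim <- simulate_arhmm(params, T = 300, seed = 3)
  ms <- map_states(params, sim$obs, threshold = 0.8)
  gam <- state_posteriors(params, sim$obs)
  pm <- apply(gam, 1, max)
  expect_equal(ms$excluded[-1], pm < 0.8)
  # boundary behavior: threshold above every posterior excludes everything
  ms_hi <- map_states(params, sim$obs, threshold = max(pm) + 1e-9)
  expect_true(all(ms_hi$excluded))
  ms_lo <- map_states(params, sim$obs, threshold = 0)
  expect_false(any(ms_lo$excluded[-1]))
})

test_that("transition features count distinct-state transitions per the rules", {
  mk_seq <- function(states, excluded = rep(FALSE, length(states))) {
    out <- data.frame(frame = seq_along(states), state = states,
                      posterior = 1, excluded = excluded)
    attr(out, "K") <- 3L
    class(out) <- c("state_sequence", "data.frame")
    out
  }
  expect_null(transition_features(mk_seq(c(1, 1, 1))))      # all dwell
  f <- transition_features(mk_seq(c(1, 2, 1, 2)))
  expect_equal(unname(f[c("1>2", "2>1")]), c(2, 1) / 3)
  expect_equal(sum(f), 1)
  # excluded frames break adjacency
  f2 <- transition_features(mk_seq(c(1, 2, 3, 2), c(FALSE, TRUE, FALSE, FALSE)))
  expect_equal(unname(f2["3>2"]), 1)
  expect_equal(sum(f2), 1)
  # oracle: brute-force pair counting on random sequences
  set.seed(20)
  for (rep in 1:25) {
    st <- sample(1:3, 60, replace = TRUE)
    ex <- runif(60) < 0.2
    f3 <- transition_features(mk_seq(st, ex), normalize = FALSE)
    cnt <- matrix(0, 3, 3)
    for (t in 1:59) {
      if (!ex[t] && !ex[t + 1] && st[t] != st[t + 1]) {
        cnt[st[t], st[t + 1]] <- cnt[st[t], st[t + 1]] + 1
      }
    }
    if (sum(cnt) == 0) { expect_null(f3); next }
    for (i in 1:3) for (j in 1:3) {
      if (i != j) expect_equal(unname(f3[paste0(i, ">", j)]), cnt[i, j])
    }
  }
})

test_that("transition features are invariant to consistent state relabeling", {
  set.seed(30)
  st <- sample(1:4, 100, replace = TRUE)
  sq <- data.frame(frame = 1:100, state = st, posterior = 1, excluded = FALSE)
  attr(sq, "K") <- 4L
  f <- transition_features(sq)
  perm <- c(3L, 1L, 4L, 2L)
  sq2 <- sq; sq2$state <- perm[st]
  f2 <- transition_features(sq2)
  for (i in 1:4) for (j in 1:4) {
    if (i != j) {
      expect_equal(unname(f[paste0(i, ">", j)]),
                   unname(f2[paste0(perm[i], ">", perm[j])]))
    }
  }
})

test_that("decoder separates constructed classes and stays calibrated on nulls", {
  set.seed(40)
  n <- 100; p <- 8
  X <- rbind(matrix(rnorm(n * p), n, p),
             sweep(matrix(rnorm(n * p), n, p), 2, rep(1.2, p), "+"))
  yl <- rep(c("A", "B"), each = n)
  res <- decode_condition(X, yl, n_folds = 10, n_shuffle = 50, seed = 2)
  expect_gt(res$accuracy, 0.95)
  expect_gt(res$mean_z, 2)
  expect_lt(res$p_value, 0.05)
  res_rep <- decode_condition(X, yl, n_folds = 10, n_shuffle = 50, seed = 2)
  expect_identical(res$fold_z, res_rep$fold_z)          # seeded
  # labels independent of features
  Xn <- matrix(rnorm(200 * p), 200, p)
  resn <- decode_condition(Xn, yl, n_folds = 10, n_shuffle = 50, seed = 3)
  expect_true(resn$accuracy >= 0.4 && resn$accuracy <= 0.6)
  expect_lt(abs(resn$mean_z), 2)
  expect_gt(resn$p_value, 0.05)
  # fold reduction warning when a class is small
  expect_warning(decode_condition(X[c(1:5, 101:105), ], yl[c(1:5, 101:105)],
                                  n_folds = 10, n_shuffle = 10, seed = 1),
                 "reduced")
})

test_that("LDA with shrinkage matches MASS::lda direction on well-posed data", {
  skip_if_not_installed("MASS")
  set.seed(41)
  n <- 150; p <- 5
  X <- rbind(matrix(rnorm(n * p), n, p),
             sweep(matrix(rnorm(n * p), n, p), 2, c(1, 0.5, 0, -0.5, 1), "+"))
  yl <- factor(rep(c("A", "B"), each = n))
  ours <- ethokit:::lda_fit(X, yl, lambda = 0)
  ref <- MASS::lda(X, yl)
  w_ref <- ref$scaling[, 1]
  cosang <- sum(ours$w * w_ref) / sqrt(sum(ours$w^2) * sum(w_ref^2))
  expect_gt(abs(cosang), 0.9999)
  # simplex-normalized features (singular pooled covariance) still fit
  Xs <- X / rowSums(abs(X))
  expect_silent(ethokit:::lda_fit(Xs, yl, lambda = 0.1))
})

test_that("weight significance flags the discriminative feature only", {
  set.seed(42)
  n <- 120; p <- 6
  X <- matrix(rnorm(2 * n * p), 2 * n, p)
  X[(n + 1):(2 * n), 3] <- X[(n + 1):(2 * n), 3] + 2    # feature 3 informative
  yl <- rep(c("A", "B"), each = n)
  res <- decode_condition(X, yl, n_folds = 10, n_shuffle = 100, seed = 5)
  ws <- weight_significance(res)
  expect_true(ws$significant[3])
  expect_equal(which.max(abs(ws$z)), 3L)
  expect_gt(abs(ws$z[3]), 2 * max(abs(ws$z[-3])))
  ws2 <- weight_significance(decode_condition(X, yl, 10, 100, seed = 5))
  expect_identical(ws$z, ws2$z)
  # all-null features: z-scores hover near zero
  Xn <- matrix(rnorm(2 * n * p), 2 * n, p)
  wsn <- weight_significance(decode_condition(Xn, yl, 10, 100, seed = 6))
  expect_lt(mean(abs(wsn$z)), 1)
})

test_that("cross-validated selection table reports held-out likelihoods per K", {
  set.seed(50)
  truth <- default_arhmm_params(K = 3, d = 2)
  obs <- lapply(1:6, function(i) simulate_arhmm(truth, T = 400, seed = 60 + i)$obs)
  tab <- suppressWarnings(cross_validated_selection(obs, K_grid = 1:4,
                                                    n_iter = 15, n_restarts = 1))
  expect_equal(nrow(tab), 8L)                     # one row per K per fold
  agg <- tapply(tab$heldout_loglik, tab$K, sum)
  # held-out log-likelihood rises sharply up to the true K = 3, then flattens
  expect_gt(agg["2"], agg["1"])
  expect_gt(agg["3"], agg["2"])
  expect_gt(agg["3"] - agg["1"], 10 * abs(agg["4"] - agg["3"]))
  expect_error(cross_validated_selection(obs[1], K_grid = 2), "at least 2")
})

test_that("feature building centers, downsamples, and skips broken trials", {
  cfg <- generator_config(seed = 25)
  g <- generate_trial(cfg, "binocular", 3)
  dec <- extract_decision_period(calibrate(g$side, cfg$px_per_cm), g$trial)
  feats <- build_features(list(t1 = dec))
  expect_equal(ncol(feats$t1), 6L)
  expect_equal(nrow(feats$t1), ceiling(length(dec$t) / 2))   # 2x downsampling
  # platform-edge-equal track -> all-zero features
  zero <- dec
  for (nm in c("nose", "eye", "ear")) {
    zero$landmarks[[nm]]$x[] <- 0; zero$landmarks[[nm]]$y[] <- 0
  }
  expect_true(all(build_features(list(z = zero))$z == 0))
  dec2 <- dec; dec2$landmarks$nose <- NULL
  expect_warning(f2 <- build_features(list(bad = dec2, ok = dec)), "skipped")
  expect_named(f2, "ok")
})
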