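# Independent brute-force oracles, deliberately written as plain loops so they
# stay structurally independent of the vectorized implementations they check.

# Movement segmentation oracle: a literal loop over the five rules
# (central-difference velocity, zero crossings with the nearest-zero tie-break
# and zero-run centers, edge-dropped windows, vertical-amplitude filter,
# chronological overlap exclusion against the last retained movement).
brute_force_movements <- function(y, rate, window_s = 0.5, min_amp_cm = 1,
                                  max_overlap_s = 0.25) {
  n <- length(y)
  w <- round(window_s * rate)
  if (n < max(w, 3)) return(integer(0))
  v <- rep(NA_real_, n)
  for (i in 2:(n - 1)) v[i] <- (y[i + 1] - y[i - 1]) / (2 / rate)
  crossings <- integer(0)
  i <- 2
  while (i <= n - 1) {
    if (v[i] == 0) {
      j <- i
      while (j + 1 <= n - 1 && v[j + 1] == 0) j <- j + 1
      crossings <- c(crossings, (i + j) %/% 2)
      i <- j + 1
    } else {
      if (i + 1 <= n - 1 && v[i + 1] != 0 && sign(v[i]) != sign(v[i + 1])) {
        at <- if (abs(v[i]) < abs(v[i + 1])) i else i + 1
        crossings <- c(crossings, at)
      }
      i <- i + 1
    }
  }
  crossings <- sort(unique(crossings))
  half <- w %/% 2
  retained <- integer(0)
  last <- -Inf
  for (cc in crossings) {
    lo <- cc - half
    hi <- cc - half + w - 1
    if (lo < 1 || hi > n) next
    amp <- max(y[lo:hi]) - min(y[lo:hi])
    if (amp < min_amp_cm) next
    if ((w - (cc - last)) / rate > max_overlap_s) next
    retained <- c(retained, cc)
    last <- cc
  }
  retained
}

# Exhaustive forward-backward oracle: smoothed state marginals by enumerating
# every state path (viable for T <= 8, K <= 3).
enumerate_posteriors <- function(params, y) {
  K <- params$K
  lag <- params$lag
  Te <- nrow(y) - lag
  logB <- matrix(0, Te, K)
  X <- cbind(y[1:Te, , drop = FALSE], 1)
  for (k in seq_len(K)) {
    W <- cbind(params$A[[k]], params$b[[k]])
    for (t in seq_len(Te)) {
      r <- y[t + lag, ] - as.numeric(W %*% X[t, ])
      S <- params$Sigma[[k]]
      logB[t, k] <- -0.5 * (length(r) * log(2 * pi) +
                              determinant(S)$modulus +
                              sum(r * solve(S, r)))
    }
  }
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), Te)))
  logp <- numeric(nrow(paths))
  for (i in seq_len(nrow(paths))) {
    z <- paths[i, ]
    lp <- log(params$pi0[z[1]]) + logB[1, z[1]]
    if (Te > 1) {
      for (t in 2:Te) lp <- lp + log(params$P[z[t - 1], z[t]]) + logB[t, z[t]]
    }
    logp[i] <- lp
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  gamma <- matrix(0, Te, K)
  for (t in seq_len(Te)) {
    for (k in seq_len(K)) gamma[t, k] <- sum(p[paths[, t] == k])
  }
  gamma
}

# Adjusted Rand index between two labelings.
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  expected <- si * sj / choose(n, 2)
  (sij - expected) / ((si + sj) / 2 - expected)
}

# Best state accuracy over all label permutations (small K).
permutation_accuracy <- function(est, truth, K) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- 0
  best_perm <- seq_len(K)
  for (p in perms(seq_len(K))) {
    acc <- mean(p[est] == truth)
    if (acc > best) { best <- acc; best_perm <- p }
  }
  list(accuracy = best, perm = best_perm)
}

# A small calibrated series directly from x/y vectors, for unit tests.
make_series <- function(x, y, rate = 60, landmark = "eye") {
  lms <- list(data.frame(x = x, y = y))
  names(lms) <- landmark
  structure(list(t = (seq_along(x) - 1) / rate, sample_rate = rate,
                 frames = seq_along(x) - 1L, camera_id = "side",
                 origin = "platform_edge", landmarks = lms),
            class = "calib_series")
}

# Minimal valid trial record.
make_trial <- function(trial_id = "t1", animal_id = "a01",
                       condition = "binocular", outcome = "success",
                       start_frame = 0L, jump_frame = 60L, land_frame = 90L,
                       gap = 16, width = 20) {
  data.frame(trial_id = trial_id, session_id = "s1", animal_id = animal_id,
             ocular_condition = condition, laser = "none",
             gap_distance_cm = gap, platform_width_cm = width,
             outcome = outcome, start_frame = start_frame,
             jump_frame = jump_frame, land_frame = land_frame,
             stringsAsFactors = FALSE)
}
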