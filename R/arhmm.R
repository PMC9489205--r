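#' Sticky autoregressive HMM parameters
#'
#' Parameters of a hidden Markov model whose per-state emissions are
#' lag-`lag` vector-autoregressive Gaussians:
#' `y_t | z_t = k  ~  N(A_k [y_{t-1}; ...; y_{t-lag}] + b_k, Sigma_k)`.
#' The "sticky" `kappa` is a self-transition pseudo-count used by the EM
#' M-step (it is stored here for bookkeeping; [simulate_arhmm()] uses only the
#' realized transition matrix `P`).
#'
#' @param A List of K `d x (d*lag)` AR coefficient matrices.
#' @param b List of K length-`d` intercepts.
#' @param Sigma List of K `d x d` positive-definite noise covariances.
#' @param P `K x K` transition matrix (rows on the simplex).
#' @param pi0 Initial state distribution (length K).
#' @param lag AR order (default 1).
#' @param kappa Sticky self-transition pseudo-count (default 0).
#' @return An object of class `arhmm_params`.
#' @export
arhmm_params <- function(A, b, Sigma, P, pi0 = NULL, lag = 1, kappa = 0) {
  K <- length(A)
  stopifnot(K >= 1, length(b) == K, length(Sigma) == K,
            nrow(P) == K, ncol(P) == K)
  d <- length(b[[1]])
  for (k in seq_len(K)) {
    stopifnot(nrow(A[[k]]) == d, ncol(A[[k]]) == d * lag,
              length(b[[k]]) == d, nrow(Sigma[[k]]) == d)
    ev <- eigen(Sigma[[k]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) stop("Sigma[[", k, "]] is not positive definite")
  }
  if (any(P < 0) || any(abs(rowSums(P) - 1) > 1e-8)) {
    stop("transition matrix rows must be non-negative and sum to 1")
  }
  if (is.null(pi0)) pi0 <- rep(1 / K, K)
  stopifnot(length(pi0) == K, all(pi0 >= 0), abs(sum(pi0) - 1) < 1e-8)
  structure(list(K = K, d = d, lag = lag, kappa = kappa,
                 A = A, b = b, Sigma = Sigma, P = P, pi0 = pi0),
            class = "arhmm_params")
}

#' @export
print.arhmm_params <- function(x, ...) {
  cat(sprintf("<arhmm_params> K=%d d=%d lag=%d kappa=%g\n",
              x$K, x$d, x$lag, x$kappa))
  invisible(x)
}

#' Default ground-truth ARHMM used by the synthetic benchmark
#'
#' K states with shared contraction dynamics toward well-separated fixed
#' points, equal isotropic noise, and a sticky transition matrix
#' (`p_self` on the diagonal, remainder spread evenly).
#'
#' @param K Number of states (default 4).
#' @param d Observation dimension (default 2).
#' @param p_self Self-transition probability (default 0.95).
#' @param rho Contraction factor of the AR dynamics (default 0.85).
#' @param noise_sd Emission noise SD (default 0.3).
#' @param spread Distance of state fixed points from the origin (default 3).
#' @return An [arhmm_params()].
#' @export
default_arhmm_params <- function(K = 4, d = 2, p_self = 0.95, rho = 0.85,
                                 noise_sd = 0.3, spread = 3) {
  ang <- 2 * pi * (seq_len(K) - 1) / K
  mu <- cbind(spread * cos(ang), spread * sin(ang))
  if (d > 2) mu <- cbind(mu, matrix(0, K, d - 2)) else mu <- mu[, seq_len(d), drop = FALSE]
  A <- replicate(K, diag(rho, d), simplify = FALSE)
  b <- lapply(seq_len(K), function(k) as.numeric((1 - rho) * mu[k, ]))
  Sigma <- replicate(K, diag(noise_sd^2, d), simplify = FALSE)
  P <- matrix((1 - p_self) / (K - 1), K, K)
  if (K == 1) P <- matrix(1, 1, 1) else diag(P) <- p_self
  arhmm_params(A, b, Sigma, P, lag = 1)
}

#' Simulate a sticky ARHMM
#'
#' States follow the Markov chain in `params$P`; observations follow the
#' state-conditional autoregressive Gaussian. The first `lag` observations are
#' drawn `N(0, I)` and carry the initial state. Deterministic given `seed`.
#'
#' @param params An [arhmm_params()].
#' @param T Number of samples (> lag).
#' @param seed Integer seed.
#' @return List with `states` (length `T`, 1-based) and `obs` (`T x d` matrix).
#' @export
simulate_arhmm <- function(params, T, seed = 1) {
  stopifnot(inherits(params, "arhmm_params"), T > params$lag)
  set.seed(seed)
  K <- params$K; d <- params$d; lag <- params$lag
  chol_S <- lapply(params$Sigma, chol)
  z <- integer(T); y <- matrix(0, T, d)
  z[seq_len(lag)] <- sample.int(K, 1, prob = params$pi0)
  y[seq_len(lag), ] <- stats::rnorm(lag * d)
  for (t in (lag + 1):T) {
    z[t] <- sample.int(K, 1, prob = params$P[z[t - 1], ])
    xlag <- as.numeric(t(y[(t - 1):(t - lag), , drop = FALSE]))
    mu <- params$A[[z[t]]] %*% xlag + params$b[[z[t]]]
    y[t, ] <- as.numeric(mu) + as.numeric(stats::rnorm(d) %*% chol_S[[z[t]]])
  }
  list(states = z, obs = y)
}

# Design matrix of lagged observations: rows t = lag+1..T, columns
# [y_{t-1}, ..., y_{t-lag}, 1].
lag_design <- function(y, lag) {
  T <- nrow(y); d <- ncol(y)
  X <- matrix(0, T - lag, d * lag + 1)
  for (l in seq_len(lag)) {
    X[, ((l - 1) * d + 1):(l * d)] <- y[(lag + 1 - l):(T - l), , drop = FALSE]
  }
  X[, d * lag + 1] <- 1
  X
}

# Per-state Gaussian AR log-densities: (T-lag) x K matrix.
arhmm_loglik_matrix <- function(params, y) {
  lag <- params$lag; d <- params$d
  X <- lag_design(y, lag)
  Y <- y[(lag + 1):nrow(y), , drop = FALSE]
  logB <- matrix(0, nrow(Y), params$K)
  for (k in seq_len(params$K)) {
    W <- cbind(params$A[[k]], params$b[[k]])
    R <- Y - X %*% t(W)
    ch <- chol(params$Sigma[[k]])
    q <- rowSums((R %*% chol2inv(ch) ) * R)
    logdet <- 2 * sum(log(diag(ch)))
    logB[, k] <- -0.5 * (d * log(2 * pi) + logdet + q)
  }
  logB
}

# Scaled forward-backward. logB: T_eff x K. Returns gamma (T_eff x K),
# xi_sum (K x K summed two-slice posteriors), loglik.
forward_backward <- function(logB, P, pi0) {
  Te <- nrow(logB); K <- ncol(logB)
  # per-row max-stabilized likelihoods
  m <- apply(logB, 1, max)
  B <- exp(logB - m)
  alpha <- matrix(0, Te, K); ct <- numeric(Te)
  a <- pi0 * B[1, ]
  ct[1] <- sum(a); alpha[1, ] <- a / ct[1]
  for (t in 2:Te) {
    a <- (alpha[t - 1, ] %*% P) * B[t, ]
    ct[t] <- sum(a)
    alpha[t, ] <- a / ct[t]
  }
  beta <- matrix(0, Te, K)
  beta[Te, ] <- 1
  xi_sum <- matrix(0, K, K)
  for (t in (Te - 1):1) {
    bb <- B[t + 1, ] * beta[t + 1, ]
    xi <- P * (alpha[t, ] %o% bb)
    xi_sum <- xi_sum + xi / sum(xi)
    beta[t, ] <- as.numeric(P %*% bb) / ct[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi_sum = xi_sum, loglik = sum(log(ct)) + sum(m))
}

as_obs_list <- function(observations) {
  if (is.matrix(observations)) list(observations)
  else if (is.list(observations)) lapply(observations, as.matrix)
  else stop("observations must be a matrix or a list of matrices")
}

# Weighted AR M-step for one state. Returns list(A, b, Sigma).
wls_ar <- function(X, Y, w, d, ridge = 1e-8) {
  sw <- sqrt(w)
  Xw <- X * sw; Yw <- Y * sw
  G <- crossprod(Xw) + diag(ridge, ncol(X))
  W <- t(solve(G, crossprod(Xw, Yw)))          # d x (d*lag + 1)
  R <- Y - X %*% t(W)
  S <- crossprod(R * sw, R) / sum(w) + diag(1e-6, d)
  list(A = W[, seq_len(ncol(X) - 1), drop = FALSE],
       b = as.numeric(W[, ncol(X)]), Sigma = (S + t(S)) / 2)
}

#' Fit a sticky ARHMM by expectation-maximization
#'
#' EM for the sticky autoregressive Gaussian HMM: forward-backward E-step;
#' weighted-least-squares AR M-step per state; transition M-step with `kappa`
#' pseudo-counts added to the self-transition counts (the sticky prior).
#' Initialization is k-means on residuals from a global AR fit; the best of
#' `n_restarts` runs by final objective is returned. The optimized objective is
#' the data log-likelihood plus the sticky-prior term
#' `kappa * sum(log(diag(P)))`, which EM increases monotonically (at
#' `kappa = 0` it is the log-likelihood itself).
#'
#' @param observations A `T x d` matrix or a list of per-trial matrices.
#' @param K Number of states.
#' @param lag AR order. Default 1.
#' @param kappa Sticky self-transition pseudo-count. Default 0.
#' @param n_iter Maximum EM iterations. Default 100.
#' @param tol Relative objective-change convergence tolerance. Default 1e-6.
#' @param seed Seed for initialization. Default 1.
#' @param n_restarts Number of EM restarts. Default 3.
#' @param verbose Print per-iteration objective.
#' @return An [arhmm_params()] with attributes `objective` (per-iteration
#'   trace of the best run), `loglik` (final data log-likelihood), and
#'   `state_weights` (total posterior mass per state).
#' @export
fit_arhmm <- function(observations, K, lag = 1, kappa = 0, n_iter = 100,
                      tol = 1e-6, seed = 1, n_restarts = 3, verbose = FALSE) {
  obs <- as_obs_list(observations)
  d <- ncol(obs[[1]])
  Xs <- lapply(obs, lag_design, lag = lag)
  Ys <- lapply(obs, function(y) y[(lag + 1):nrow(y), , drop = FALSE])
  X_all <- do.call(rbind, Xs); Y_all <- do.call(rbind, Ys)
  Te_all <- nrow(X_all)
  if (Te_all < K * (lag * d^2 + d)) stop("too few samples to fit K states")

  # global AR fit for residual-based initialization
  W0 <- t(solve(crossprod(X_all) + diag(1e-8, ncol(X_all)),
                crossprod(X_all, Y_all)))
  resid0 <- Y_all - X_all %*% t(W0)

  best <- NULL
  for (r in seq_len(n_restarts)) {
    set.seed(seed + r - 1L)
    fit <- tryCatch(
      em_arhmm_once(Xs, Ys, resid0, K, d, lag, kappa, n_iter, tol, verbose),
      error = function(e) NULL)
    if (!is.null(fit) &&
        (is.null(best) || fit$objective > best$objective)) best <- fit
  }
  if (is.null(best)) stop("ARHMM fitting failed in all restarts (non-finite likelihood)")
  params <- best$params
  attr(params, "objective") <- best$trace
  attr(params, "loglik") <- best$loglik
  attr(params, "state_weights") <- best$state_weights
  params
}

em_arhmm_once <- function(Xs, Ys, resid0, K, d, lag, kappa, n_iter, tol,
                          verbose) {
  X_all <- do.call(rbind, Xs); Y_all <- do.call(rbind, Ys)
  # init responsibilities from k-means on global-AR residuals (+ the data
  # itself, which separates states that differ in operating point)
  feats <- cbind(resid0, Y_all)
  km <- tryCatch(stats::kmeans(feats, centers = K, nstart = 5, iter.max = 50),
                 error = function(e) NULL)
  assign0 <- if (is.null(km)) sample.int(K, nrow(Y_all), replace = TRUE) else km$cluster
  gamma_all <- matrix(0.01 / max(1, K - 1), nrow(Y_all), K)
  gamma_all[cbind(seq_len(nrow(Y_all)), assign0)] <- 0.99
  if (K == 1) gamma_all[] <- 1

  # start sticky: behavioral states persist, and a uniform start lets one
  # high-persistence AR state absorb the whole sequence
  P <- matrix(if (K > 1) 0.1 / (K - 1) else 0, K, K)
  diag(P) <- if (K > 1) 0.9 else 1
  pi0 <- rep(1 / K, K)
  A <- b <- Sigma <- vector("list", K)
  mstep_emissions <- function(gamma_all) {
    for (k in seq_len(K)) {
      w <- gamma_all[, k]
      if (sum(w) < d + 1) w <- w + 1e-3   # guard nearly-empty state
      f <- wls_ar(X_all, Y_all, w, d)
      A[[k]] <<- f$A; b[[k]] <<- f$b; Sigma[[k]] <<- f$Sigma
    }
  }
  mstep_emissions(gamma_all)

  lens <- vapply(Ys, nrow, integer(1))
  offs <- cumsum(c(0L, lens))
  trace <- numeric(0)
  obj_prev <- -Inf
  reinit_used <- logical(K)
  for (it in seq_len(n_iter)) {
    params <- arhmm_params(A, b, Sigma, P, pi0, lag = lag, kappa = kappa)
    loglik <- 0
    xi_tot <- matrix(0, K, K)
    pi_acc <- numeric(K)
    for (s in seq_along(Ys)) {
      y_full <- rbind(matrix(0, lag, d), Ys[[s]])  # only X/Y used below
      logB <- local({
        W <- lapply(seq_len(K), function(k) cbind(A[[k]], b[[k]]))
        lb <- matrix(0, lens[s], K)
        for (k in seq_len(K)) {
          R <- Ys[[s]] - Xs[[s]] %*% t(W[[k]])
          ch <- chol(Sigma[[k]])
          q <- rowSums((R %*% chol2inv(ch)) * R)
          lb[, k] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
        }
        lb
      })
      fb <- forward_backward(logB, P, pi0)
      gamma_all[(offs[s] + 1):offs[s + 1], ] <- fb$gamma
      xi_tot <- xi_tot + fb$xi_sum
      pi_acc <- pi_acc + fb$gamma[1, ]
      loglik <- loglik + fb$loglik
    }
    if (!is.finite(loglik)) stop("non-finite likelihood at iteration ", it)

    # empty-state handling: reinitialize once from a random data block
    wts <- colSums(gamma_all)
    for (k in seq_len(K)) {
      if (wts[k] < 1e-3 * nrow(Y_all) / K^2 && !reinit_used[k]) {
        reinit_used[k] <- TRUE
        idx <- sample.int(nrow(Y_all), max(2 * d + 2, 20), replace = nrow(Y_all) < 20)
        gamma_all[idx, ] <- 0
        gamma_all[idx, k] <- 1
        warning("state ", k, " nearly empty; reinitialized once", call. = FALSE)
      } else if (wts[k] < 1e-3 * nrow(Y_all) / K^2 && reinit_used[k]) {
        warning("state ", k, " has extremely low prevalence", call. = FALSE)
      }
    }

    # M-step
    N <- xi_tot + diag(kappa, K)
    P <- N / rowSums(N)
    pi0 <- (pi_acc + 1e-8) / sum(pi_acc + 1e-8)
    mstep_emissions(gamma_all)

    obj <- loglik + if (kappa > 0) kappa * sum(log(diag(P))) else 0
    trace <- c(trace, obj)
    if (verbose) message(sprintf("iter %3d  obj %.4f", it, obj))
    if (it > 1 && abs(obj - obj_prev) < tol * (abs(obj_prev) + 1)) break
    obj_prev <- obj
  }
  params <- arhmm_params(A, b, Sigma, P, pi0, lag = lag, kappa = kappa)
  list(params = params, objective = trace[length(trace)], trace = trace,
       loglik = loglik, state_weights = colSums(gamma_all))
}

#' MAP state sequence with posterior thresholding
#'
#' Computes smoothed per-frame posteriors by forward-backward under fitted
#' parameters, takes the per-frame argmax (MAP) state, and flags frames whose
#' maximum posterior falls below `threshold` as excluded from analysis. The
#' first `lag` frames carry no emission and are excluded.
#'
#' @param params An [arhmm_params()].
#' @param observations `T x d` matrix for one trial.
#' @param threshold Posterior-probability threshold. Default 0.8.
#' @return Data.frame of class `state_sequence` with columns `frame`
#'   (1-based), `state`, `posterior`, `excluded`; attribute `K`.
#' @export
map_states <- function(params, observations, threshold = 0.8) {
  stopifnot(inherits(params, "arhmm_params"))
  y <- as.matrix(observations)
  logB <- arhmm_loglik_matrix(params, y)
  fb <- forward_backward(logB, params$P, params$pi0)
  pm <- apply(fb$gamma, 1, max)
  st <- apply(fb$gamma, 1, which.max)
  lag <- params$lag
  out <- data.frame(
    frame = seq_len(nrow(y)),
    state = c(rep(NA_integer_, lag), st),
    posterior = c(rep(NA_real_, lag), pm),
    excluded = c(rep(TRUE, lag), pm < threshold)
  )
  attr(out, "K") <- params$K
  class(out) <- c("state_sequence", "data.frame")
  out
}

#' Posterior state marginals (for oracle comparison)
#'
#' @param params An [arhmm_params()].
#' @param observations `T x d` matrix.
#' @return `(T - lag) x K` matrix of smoothed posteriors.
#' @export
state_posteriors <- function(params, observations) {
  y <- as.matrix(observations)
  logB <- arhmm_loglik_matrix(params, y)
  forward_backward(logB, params$P, params$pi0)$gamma
}

#' Held-out log-likelihood of fitted ARHMM parameters
#'
#' @param params An [arhmm_params()].
#' @param observations Matrix or list of matrices.
#' @return Total log-likelihood.
#' @export
arhmm_loglik <- function(params, observations) {
  obs <- as_obs_list(observations)
  sum(vapply(obs, function(y) {
    logB <- arhmm_loglik_matrix(params, y)
    forward_backward(logB, params$P, params$pi0)$loglik
  }, numeric(1)))
}

#' Twofold cross-validated model-size selection table
#'
#' Splits trials into two folds, fits each `K` on one fold and evaluates the
#' held-out log-likelihood on the other (both directions). No automatic elbow
#' choice is made; the table is reported for the user.
#'
#' @param observations List of per-trial observation matrices (>= 2 trials).
#' @param K_grid Integer vector of state counts to evaluate.
#' @param ... Passed to [fit_arhmm()].
#' @param seed Seed controlling the fold split and fits.
#' @return Data.frame with columns `K`, `fold`, `heldout_loglik`,
#'   `heldout_frames`.
#' @export
cross_validated_selection <- function(observations, K_grid, seed = 1, ...) {
  obs <- as_obs_list(observations)
  if (length(obs) < 2) stop("need at least 2 trials for twofold selection")
  set.seed(seed)
  fold <- sample(rep(1:2, length.out = length(obs)))
  rows <- list()
  for (K in K_grid) {
    for (f in 1:2) {
      train <- obs[fold != f]; test <- obs[fold == f]
      params <- fit_arhmm(train, K = K, seed = seed, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        K = K, fold = f,
        heldout_loglik = arhmm_loglik(params, test),
        heldout_frames = sum(vapply(test, nrow, integer(1)))
      )
    }
  }
  do.call(rbind, rows)
}
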