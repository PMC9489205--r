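#' Build ARHMM observation features from calibrated pose series
#'
#' Six-dimensional series per trial: x and y of the nose, eye, and ear
#' landmarks (already centered on the take-off-platform edge by calibration),
#' temporally downsampled 2x (every second sample). Trials missing a landmark
#' are skipped with a warning.
#'
#' @param series_list Named list (by trial id) of decision-period
#'   `calib_series` from the side camera.
#' @param landmarks Landmark names. Default nose, eye, ear.
#' @param downsample Temporal downsampling factor. Default 2.
#' @return Named list of `T x 6` matrices.
#' @export
build_features <- function(series_list, landmarks = c("nose", "eye", "ear"),
                           downsample = 2) {
  out <- list()
  for (tid in names(series_list)) {
    s <- series_list[[tid]]
    if (!all(landmarks %in% names(s$landmarks))) {
      warning("trial ", tid, " missing landmark(s); skipped")
      next
    }
    m <- do.call(cbind, lapply(landmarks, function(nm) {
      cbind(s$landmarks[[nm]]$x, s$landmarks[[nm]]$y)
    }))
    colnames(m) <- as.vector(rbind(paste0(landmarks, "_x"),
                                   paste0(landmarks, "_y")))
    out[[tid]] <- m[seq(1, nrow(m), by = downsample), , drop = FALSE]
  }
  out
}

#' Per-trial transition-probability features from a MAP state sequence
#'
#' Counts transitions between distinct states (`i != j`; self-transitions are
#' dwell, not transitions) across consecutive retained frames. Excluded frames
#' break adjacency: a pair is counted only when both frames are retained and
#' consecutive. The count matrix is normalized to sum to 1 over the trial.
#'
#' @param seq A `state_sequence` from [map_states()] (or a data.frame with
#'   `frame`, `state`, `excluded`).
#' @param K Number of states (taken from the attribute when present).
#' @param include_self Count self-transitions too. Default `FALSE`.
#' @param normalize Divide by the total transition count. Default `TRUE`.
#' @return Named numeric vector of length `K*(K-1)` (or `K*K` with
#'   `include_self`), names `"i>j"`; `NULL` when the trial has no transitions
#'   (fewer than 2 adjacent retained frames, or all dwell).
#' @export
transition_features <- function(seq, K = attr(seq, "K"), include_self = FALSE,
                                normalize = TRUE) {
  if (is.null(K)) stop("K not supplied and not carried by the sequence")
  ok <- !seq$excluded & !is.na(seq$state)
  cnt <- matrix(0, K, K)
  idx <- which(ok)
  if (length(idx) >= 2) {
    prev <- idx[-length(idx)]; nxt <- idx[-1]
    adj <- which(seq$frame[nxt] - seq$frame[prev] == 1L)
    for (a in adj) {
      i <- seq$state[prev[a]]; j <- seq$state[nxt[a]]
      if (include_self || i != j) cnt[i, j] <- cnt[i, j] + 1
    }
  }
  if (!include_self) diag(cnt) <- 0
  tot <- sum(cnt)
  if (tot == 0) return(NULL)
  if (normalize) cnt <- cnt / tot
  nm <- outer(seq_len(K), seq_len(K), function(i, j) paste0(i, ">", j))
  v <- as.vector(t(cnt)); names(v) <- as.vector(t(nm))
  if (!include_self) v <- v[as.vector(t(row(cnt) != col(cnt)))]
  v
}

#' Condition-level ("lexical") transition matrix
#'
#' Pooled counts of transitions between distinct states across all trials of a
#' condition, normalized by the total number of such transitions in that
#' condition.
#'
#' @param seqs List of `state_sequence`s belonging to one condition.
#' @param K Number of states.
#' @return `K x K` matrix summing to 1 (all-zero when no transitions).
#' @export
lexical_transition_matrix <- function(seqs, K) {
  tot <- matrix(0, K, K)
  for (s in seqs) {
    f <- transition_features(s, K = K, normalize = FALSE)
    if (is.null(f)) next
    tot <- tot + feature_to_matrix(f, K)
  }
  if (sum(tot) > 0) tot / sum(tot) else tot
}

# Inverse of the flattening in transition_features (no self-transitions).
feature_to_matrix <- function(v, K) {
  m <- matrix(0, K, K)
  for (nm in names(v)) {
    ij <- as.integer(strsplit(nm, ">", fixed = TRUE)[[1]])
    m[ij[1], ij[2]] <- v[[nm]]
  }
  m
}

# Pooled-covariance linear discriminant with fixed-lambda shrinkage toward
# the scaled identity. Handles the exactly singular covariance of simplex-
# normalized transition features, which is why it is written here rather than
# delegated to an unregularized fitter.
lda_fit <- function(X, y, lambda = 0.1) {
  lev <- levels(y)
  stopifnot(length(lev) == 2)
  X0 <- X[y == lev[1], , drop = FALSE]; X1 <- X[y == lev[2], , drop = FALSE]
  n0 <- nrow(X0); n1 <- nrow(X1)
  mu0 <- colMeans(X0); mu1 <- colMeans(X1)
  S <- (crossprod(sweep(X0, 2, mu0)) + crossprod(sweep(X1, 2, mu1))) /
    max(1, n0 + n1 - 2)
  tr <- mean(diag(S))
  if (tr <= 0) tr <- 1e-8
  S <- (1 - lambda) * S + lambda * tr * diag(ncol(X))
  w <- solve(S, mu1 - mu0)
  b <- -sum(w * (mu0 + mu1) / 2) + log(n1 / n0)
  list(w = w, b = b, levels = lev)
}

lda_predict <- function(fit, X) {
  sc <- as.numeric(X %*% fit$w + fit$b)
  factor(ifelse(sc > 0, fit$levels[2], fit$levels[1]), levels = fit$levels)
}

# Stratified fold assignment: within each class, indices are shuffled and
# dealt round-robin into folds.
stratified_folds <- function(y, n_folds) {
  fold <- integer(length(y))
  for (lev in levels(y)) {
    idx <- sample(which(y == lev))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Linear-discriminant decoding of condition with fold-wise shuffle nulls
#'
#' Stratified `n_folds`-fold cross-validation of a shrinkage-regularized
#' linear discriminant on per-trial features. Within each fold, training
#' labels are shuffled `n_shuffle` times (test labels untouched) to build a
#' null accuracy distribution; the fold's z-score is the true accuracy
#' standardized against that null. Fold z-scores are averaged and referred to
#' the upper standard-normal tail for the overall p-value.
#'
#' @param features `n x p` matrix (one row per trial).
#' @param labels Two-level factor (or coercible) of length `n`.
#' @param n_folds Folds. Default 10; reduced with a warning when a class has
#'   fewer trials than folds.
#' @param n_shuffle Label shuffles per fold. Default 100.
#' @param seed RNG seed. Default 1.
#' @param lambda Covariance shrinkage in `[0, 1]`. Default 0.1.
#' @return List of class `decoding_result`: `fold_accuracy`, `fold_z`,
#'   `shuffle_accuracy` (folds x shuffles), `accuracy` (overall), `mean_z`,
#'   `p_value`, `weights` (folds x p true weights), `shuffle_weights` (list of
#'   folds x p matrices per shuffle... stored as folds-list of shuffles x p),
#'   `feature_names`, `n_folds`, `n_shuffle`.
#' @export
decode_condition <- function(features, labels, n_folds = 10, n_shuffle = 100,
                             seed = 1, lambda = 0.1) {
  X <- as.matrix(features)
  y <- droplevels(as.factor(labels))
  if (nlevels(y) != 2) stop("decoding requires exactly two classes")
  n_min <- min(table(y))
  if (n_min < n_folds) {
    n_folds <- max(2L, as.integer(n_min))
    warning("class with fewer trials than folds; reduced to ", n_folds,
            " folds")
  }
  set.seed(seed)
  fold <- stratified_folds(y, n_folds)
  p <- ncol(X)
  fold_acc <- numeric(n_folds)
  fold_z <- numeric(n_folds)
  shuf_acc <- matrix(0, n_folds, n_shuffle)
  W <- matrix(0, n_folds, p)
  SW <- vector("list", n_folds)
  correct <- 0L
  for (f in seq_len(n_folds)) {
    tr <- fold != f; te <- fold == f
    fit <- lda_fit(X[tr, , drop = FALSE], y[tr], lambda)
    pred <- lda_predict(fit, X[te, , drop = FALSE])
    fold_acc[f] <- mean(pred == y[te])
    correct <- correct + sum(pred == y[te])
    W[f, ] <- fit$w
    sw <- matrix(0, n_shuffle, p)
    for (s in seq_len(n_shuffle)) {
      ys <- sample(y[tr])
      fs <- lda_fit(X[tr, , drop = FALSE], ys, lambda)
      shuf_acc[f, s] <- mean(lda_predict(fs, X[te, , drop = FALSE]) == y[te])
      sw[s, ] <- fs$w
    }
    sdev <- stats::sd(shuf_acc[f, ])
    fold_z[f] <- if (sdev < 1e-12) 0 else (fold_acc[f] - mean(shuf_acc[f, ])) / sdev
    SW[[f]] <- sw
  }
  mean_z <- mean(fold_z)
  structure(list(
    fold_accuracy = fold_acc, fold_z = fold_z, shuffle_accuracy = shuf_acc,
    accuracy = correct / length(y), mean_z = mean_z,
    p_value = stats::pnorm(mean_z, lower.tail = FALSE),
    weights = W, shuffle_weights = SW,
    feature_names = colnames(X), n_folds = n_folds, n_shuffle = n_shuffle,
    levels = levels(y)
  ), class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf(
    "<decoding_result> %s vs %s: accuracy %.3f  mean fold z %.2f  p %.3g\n",
    x$levels[1], x$levels[2], x$accuracy, x$mean_z, x$p_value))
  invisible(x)
}

#' Significance of decoder weights against the fold-wise shuffle null
#'
#' Each coefficient's true weight is standardized against its shuffle
#' distribution within each fold; fold z-scores are averaged and flagged
#' significant at `|z| >= z_crit`.
#'
#' @param result A `decoding_result` from [decode_condition()].
#' @param z_crit Critical value. Default 1.96.
#' @return Data.frame with `feature`, `z`, `significant`.
#' @export
weight_significance <- function(result, z_crit = 1.96) {
  stopifnot(inherits(result, "decoding_result"))
  p <- ncol(result$weights)
  zs <- matrix(0, result$n_folds, p)
  for (f in seq_len(result$n_folds)) {
    mu <- colMeans(result$shuffle_weights[[f]])
    sdev <- apply(result$shuffle_weights[[f]], 2, stats::sd)
    sdev[sdev < 1e-12] <- Inf
    zs[f, ] <- (result$weights[f, ] - mu) / sdev
  }
  z <- colMeans(zs)
  data.frame(
    feature = if (is.null(result$feature_names)) paste0("f", seq_len(p))
              else result$feature_names,
    z = z, significant = abs(z) >= z_crit,
    stringsAsFactors = FALSE)
}
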