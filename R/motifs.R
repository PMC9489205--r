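#' Detect discrete head movements at velocity zero crossings
#'
#' Segments a smoothed decision-period eye trajectory into discrete movements:
#'
#' 1. vertical velocity by central difference of the smoothed y series
#'    (first/last samples carry no velocity);
#' 2. zero crossings = sign changes between consecutive velocity samples,
#'    placed on whichever of the two samples has velocity nearer zero (ties
#'    on the later); exact-zero samples count as crossings at that sample, a
#'    run of zeros as one crossing at the run center (floor of the midpoint);
#' 3. a `window_s` trace is cut around each crossing; crossings whose window
#'    would leave the series are dropped;
#' 4. movements with vertical amplitude (max y - min y within the window)
#'    below `min_amp_cm` are discarded;
#' 5. scanning chronologically, a movement overlapping the last retained
#'    movement by more than `max_overlap_s` is discarded.
#'
#' @param series Smoothed decision-period `calib_series`.
#' @param landmark Landmark to segment. Default `"eye"`.
#' @param window_s Window length in seconds. Default 0.5.
#' @param min_amp_cm Minimum vertical amplitude in cm. Default 1.
#' @param max_overlap_s Maximum allowed overlap with the previous retained
#'   movement, in seconds. Default 0.25.
#' @param component Velocity component used for crossings, `"y"` (vertical,
#'   default) or `"x"`.
#' @return A `movement_set`: list with `meta` (data.frame: `trial_id`,
#'   `center_index`, `center_time_s`, `amplitude_cm`, `cluster_id`), trace
#'   matrices `x` and `y` (one row per movement, `round(window_s *
#'   sample_rate)` columns), `window_s`, `sample_rate`.
#' @export
detect_movements <- function(series, landmark = "eye", window_s = 0.5,
                             min_amp_cm = 1.0, max_overlap_s = 0.25,
                             component = c("y", "x")) {
  stopifnot(inherits(series, "calib_series"))
  component <- match.arg(component)
  lm <- series$landmarks[[landmark]]
  if (is.null(lm)) stop("landmark '", landmark, "' not present")
  rate <- series$sample_rate
  w <- round(window_s * rate)
  n <- nrow(lm)
  empty <- movement_set(data.frame(trial_id = character(0),
                                   center_index = integer(0),
                                   center_time_s = numeric(0),
                                   amplitude_cm = numeric(0),
                                   cluster_id = NA_integer_[0]),
                        matrix(0, 0, w), matrix(0, 0, w), window_s, rate)
  if (n < max(w, 3L)) return(empty)

  v_src <- if (component == "y") lm$y else lm$x
  # central-difference velocity, defined for interior samples 2..n-1
  v <- (v_src[3:n] - v_src[1:(n - 2)]) / (2 / rate)
  vi <- 2:(n - 1)                       # series index of each velocity sample

  crossings <- integer(0)
  r <- rle(v == 0)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (j in seq_along(r$lengths)) {     # zero runs -> one crossing at center
    if (r$values[j]) {
      crossings <- c(crossings, vi[(starts[j] + ends[j]) %/% 2L])
    }
  }
  # sign changes between consecutive nonzero samples; the crossing is placed
  # on whichever of the two samples is nearer zero velocity (ties -> later)
  for (j in seq_len(length(v) - 1L)) {
    if (v[j] != 0 && v[j + 1] != 0 && sign(v[j]) != sign(v[j + 1])) {
      at <- if (abs(v[j]) < abs(v[j + 1])) j else j + 1L
      crossings <- c(crossings, vi[at])
    }
  }
  crossings <- sort(unique(crossings))
  if (!length(crossings)) return(empty)

  half <- w %/% 2
  keep_meta <- list(); keep_x <- list(); keep_y <- list()
  last_center <- -Inf
  for (cc in crossings) {
    lo <- cc - half; hi <- cc - half + w - 1L
    if (lo < 1L || hi > n) next                         # rule 3: edge drop
    amp <- max(lm$y[lo:hi]) - min(lm$y[lo:hi])
    if (!is.finite(amp) || amp < min_amp_cm) next        # rule 4: amplitude
    overlap_s <- (w - (cc - last_center)) / rate
    if (overlap_s > max_overlap_s) next                  # rule 5: overlap
    last_center <- cc
    keep_meta[[length(keep_meta) + 1L]] <- data.frame(
      trial_id = NA_character_, center_index = cc,
      center_time_s = series$t[cc] - series$t[1],
      amplitude_cm = amp, cluster_id = NA_integer_,
      stringsAsFactors = FALSE)
    keep_x[[length(keep_x) + 1L]] <- lm$x[lo:hi]
    keep_y[[length(keep_y) + 1L]] <- lm$y[lo:hi]
  }
  if (!length(keep_meta)) return(empty)
  movement_set(do.call(rbind, keep_meta),
               do.call(rbind, keep_x), do.call(rbind, keep_y), window_s, rate)
}

movement_set <- function(meta, x, y, window_s, sample_rate) {
  structure(list(meta = meta, x = x, y = y, window_s = window_s,
                 sample_rate = sample_rate),
            class = "movement_set")
}

#' @export
print.movement_set <- function(x, ...) {
  cat(sprintf("<movement_set> %d movements, %.0f ms window @ %g Hz\n",
              nrow(x$meta), 1000 * x$window_s, x$sample_rate))
  invisible(x)
}

#' Number of movements in a movement set
#' @param mv A `movement_set`.
#' @return Integer count.
#' @export
n_movements <- function(mv) nrow(mv$meta)

#' Combine per-trial movement sets
#'
#' @param sets Named list of `movement_set`s (names = trial ids; used to fill
#'   `trial_id` when missing).
#' @return A single `movement_set`.
#' @export
combine_movements <- function(sets) {
  sets <- Filter(function(s) nrow(s$meta) > 0, sets)
  if (!length(sets)) stop("no movements to combine")
  for (nm in names(sets)) {
    if (all(is.na(sets[[nm]]$meta$trial_id))) sets[[nm]]$meta$trial_id <- nm
  }
  movement_set(do.call(rbind, lapply(sets, `[[`, "meta")),
               do.call(rbind, lapply(sets, `[[`, "x")),
               do.call(rbind, lapply(sets, `[[`, "y")),
               sets[[1]]$window_s, sets[[1]]$sample_rate)
}

#' PCA embedding of movement traces
#'
#' Flattens each movement to the concatenated `[x, y]` trace, mean-centers
#' across movements, and retains the smallest number of principal components
#' reaching `var_retained` cumulative variance.
#'
#' @param movements A `movement_set` with >= 2 movements.
#' @param var_retained Fraction of variance to retain. Default 0.95.
#' @return A `motif_model`: list with the `movement_set`, PCA `center` and
#'   `rotation`, `n_components`, per-movement `scores`, `var_explained`.
#' @export
embed_movements <- function(movements, var_retained = 0.95) {
  stopifnot(inherits(movements, "movement_set"))
  if (nrow(movements$meta) < 2) stop("need at least 2 movements to embed")
  flat <- cbind(movements$x, movements$y)
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  ncomp <- max(1L, which(cumsum(ve) >= var_retained - 1e-12)[1])
  structure(list(movements = movements,
                 center = pc$center,
                 rotation = pc$rotation[, seq_len(ncomp), drop = FALSE],
                 n_components = ncomp,
                 scores = pc$x[, seq_len(ncomp), drop = FALSE],
                 var_explained = ve),
            class = "motif_model")
}

#' k-means clustering of embedded movements
#'
#' k-means (multiple restarts, best inertia) on the PCA scores, then clusters
#' relabeled in descending order of total within-cluster trace variance
#' (cluster 1 has the highest total variance). Ties break by cluster size,
#' then original label. Deterministic given `seed`.
#'
#' @param model A `motif_model` from [embed_movements()].
#' @param k Number of clusters. Default 10.
#' @param seed RNG seed. Default 1.
#' @param nstart k-means restarts. Default 20.
#' @return The `motif_model` with `cluster` (per-movement 1-based label, also
#'   written into `movements$meta$cluster_id`), `centers` (k x n_components),
#'   `cluster_trace_var`, `inertia`, `k`, `seed`.
#' @export
cluster_movements <- function(model, k = 10, seed = 1, nstart = 20) {
  stopifnot(inherits(model, "motif_model"))
  n <- nrow(model$scores)
  if (k > n) stop("k exceeds the number of movements")
  set.seed(seed)
  km <- stats::kmeans(model$scores, centers = k, nstart = nstart,
                      iter.max = 100)
  flat <- cbind(model$movements$x, model$movements$y)
  tv <- vapply(seq_len(k), function(c) {
    rows <- which(km$cluster == c)
    if (length(rows) < 2) return(0)
    sum(apply(flat[rows, , drop = FALSE], 2, stats::var))
  }, numeric(1))
  sizes <- tabulate(km$cluster, k)
  ord <- order(-tv, -sizes, seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  model$cluster <- relabel[km$cluster]
  model$centers <- km$centers[ord, , drop = FALSE]
  model$cluster_trace_var <- tv[ord]
  model$inertia <- km$tot.withinss
  model$k <- k
  model$seed <- seed
  model$movements$meta$cluster_id <- model$cluster
  model
}

#' Mean trace per cluster
#'
#' @param model A clustered `motif_model`.
#' @return List of per-cluster mean traces, each a list with `x` and `y`.
#' @export
cluster_mean_traces <- function(model) {
  stopifnot(!is.null(model$cluster))
  lapply(seq_len(model$k), function(c) {
    rows <- which(model$cluster == c)
    list(x = colMeans(model$movements$x[rows, , drop = FALSE]),
         y = colMeans(model$movements$y[rows, , drop = FALSE]))
  })
}

#' Per-cluster, per-condition movement statistics
#'
#' Movements-per-trial and amplitude per cluster and condition (per-trial
#' values averaged within animal, then across animals), and the normalized
#' histogram of movement time before the jump per cluster.
#'
#' @param movements A clustered `movement_set` (meta carries `trial_id` and
#'   `cluster_id`).
#' @param trials Trial-record data.frame covering the referenced trials.
#' @param breaks_s Histogram bin edges (seconds before jump). Default
#'   `seq(0, 10, 0.5)` extended to cover the data.
#' @return List with `frequency` (cluster x condition counts per trial),
#'   `amplitude`, and `timing` (normalized histograms per cluster).
#' @export
cluster_stats <- function(movements, trials, breaks_s = NULL) {
  stopifnot(inherits(movements, "movement_set"))
  meta <- movements$meta
  if (any(is.na(meta$cluster_id))) stop("movements must be clustered first")
  tr <- trials[, c("trial_id", "animal_id", "ocular_condition", "start_frame",
                   "jump_frame")]
  meta <- merge(meta, tr, by = "trial_id", sort = FALSE)
  k <- max(meta$cluster_id)
  # per-trial counts per cluster (including zero counts)
  grid <- expand.grid(trial_id = trials$trial_id, cluster_id = seq_len(k),
                      stringsAsFactors = FALSE)
  cnt <- stats::aggregate(rep(1, nrow(meta)),
                          by = meta[c("trial_id", "cluster_id")], FUN = sum)
  names(cnt)[3] <- "count"
  grid <- merge(grid, cnt, by = c("trial_id", "cluster_id"), all.x = TRUE)
  grid$count[is.na(grid$count)] <- 0
  grid <- merge(grid, trials[, c("trial_id", "animal_id", "ocular_condition")],
                by = "trial_id")
  freq <- avg_within_animal(grid, "count",
                            by = c("cluster_id", "ocular_condition"))
  amp <- avg_within_animal(meta, "amplitude_cm",
                           by = c("cluster_id", "ocular_condition"))

  dur_s <- (meta$jump_frame - meta$start_frame) /
    movements$sample_rate
  tbj <- dur_s - meta$center_time_s               # time before jump
  if (is.null(breaks_s)) {
    breaks_s <- seq(0, max(c(tbj, 1), na.rm = TRUE) + 0.5, by = 0.5)
  }
  timing <- lapply(seq_len(k), function(c) {
    h <- hist(tbj[meta$cluster_id == c], breaks = breaks_s, plot = FALSE)
    dens <- if (sum(h$counts) > 0) h$counts / sum(h$counts) else h$counts
    data.frame(cluster_id = c, bin_lo = h$breaks[-length(h$breaks)],
               bin_hi = h$breaks[-1], prop = dens)
  })
  list(frequency = freq, amplitude = amp, timing = do.call(rbind, timing))
}

#' Relationship between condition changes in head pitch and movement frequency
#'
#' Spearman rank correlation and an ordinary least-squares line on per-animal
#' (delta pitch, delta movement frequency) pairs between two conditions.
#'
#' @param delta_pitch Per-animal change in mean pitch (degrees).
#' @param delta_freq Per-animal change in movements per trial.
#' @return List with `rho`, `p_value`, `slope`, `intercept`, `n`. `rho` is
#'   `NA` when either delta is constant.
#' @export
pitch_frequency_relation <- function(delta_pitch, delta_freq) {
  ok <- is.finite(delta_pitch) & is.finite(delta_freq)
  x <- delta_pitch[ok]; y <- delta_freq[ok]
  if (length(x) < 3) stop("need at least 3 animals with both deltas")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    rho <- NA_real_; p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    rho <- unname(ct$estimate); p <- ct$p.value
  }
  fit <- stats::lm(y ~ x)
  list(rho = rho, p_value = p,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]), n = length(x))
}
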