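# Decomposition of windowed connectivity into recurring brain states.

# Squared Euclidean distances from rows of x to rows of centers.
dist2_to_centers <- function(x, centers, xs2 = rowSums(x^2)) {
  cs2 <- rowSums(centers^2)
  d2 <- xs2 - 2 * x %*% t(centers)
  d2 <- sweep(d2, 2, cs2, "+")
  pmax(d2, 0)
}

kmeanspp_init <- function(x, k, xs2) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- dist2_to_centers(x, x[idx[1], , drop = FALSE], xs2)[, 1]
  if (k > 1) for (j in 2:k) {
    if (all(d2 <= 0)) {
      idx[j] <- sample.int(n, 1)
    } else {
      idx[j] <- sample.int(n, 1, prob = d2)
    }
    d2 <- pmin(d2, dist2_to_centers(x, x[idx[j], , drop = FALSE], xs2)[, 1])
  }
  x[idx, , drop = FALSE]
}

lloyd_once <- function(x, k, xs2, iter_max) {
  centers <- kmeanspp_init(x, k, xs2)
  labels <- integer(nrow(x))
  for (it in seq_len(iter_max)) {
    d2 <- dist2_to_centers(x, centers, xs2)
    new_labels <- max.col(-d2, ties.method = "first")
    # re-seed empty clusters from the point farthest from its centroid
    repeat {
      sizes <- tabulate(new_labels, nbins = k)
      empty <- which(sizes == 0)
      if (length(empty) == 0) break
      own <- d2[cbind(seq_len(nrow(x)), new_labels)]
      far <- which.max(own)
      centers[empty[1], ] <- x[far, ]
      d2[, empty[1]] <- dist2_to_centers(x, centers[empty[1], , drop = FALSE],
                                         xs2)[, 1]
      new_labels <- max.col(-d2, ties.method = "first")
    }
    converged <- identical(new_labels, labels)
    labels <- new_labels
    for (j in seq_len(k))
      centers[j, ] <- colMeans(x[labels == j, , drop = FALSE])
    if (converged) break
  }
  d2 <- dist2_to_centers(x, centers, xs2)
  labels <- max.col(-d2, ties.method = "first")
  wcss <- sum(d2[cbind(seq_len(nrow(x)), labels)])
  list(centers = centers, labels = labels, wcss = wcss)
}

#' K-means clustering of windowed connectivity vectors
#'
#' Lloyd's algorithm with squared-Euclidean distance, k-means++
#' initialization and `n_replicates` restarts, keeping the solution with the
#' lowest within-cluster sum of squares. Empty clusters are re-seeded from
#' the point currently farthest from its centroid. Deterministic for a given
#' seed.
#'
#' @param x N x P matrix of windowed connectivity vectors (all subjects'
#'   windows stacked).
#' @param k number of clusters (N >= k).
#' @param seed integer seed.
#' @param n_replicates number of restarts (default 10).
#' @param iter_max maximum Lloyd iterations per restart.
#' @return list with `centroids` (k x P), `labels` (length N), `wcss`.
#' @export
kmeans_states <- function(x, k, seed = 1, n_replicates = 10, iter_max = 100) {
  x <- as.matrix(x)
  if (nrow(x) < k) stop("fewer points than clusters")
  withr::with_seed(seed, {
    xs2 <- rowSums(x^2)
    best <- NULL
    for (rep in seq_len(n_replicates)) {
      fit <- lloyd_once(x, k, xs2, iter_max)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
    list(centroids = best$centers, labels = best$labels, wcss = best$wcss)
  })
}

#' Cluster validity index
#'
#' Ratio of the mean within-cluster dispersion (mean Euclidean distance of
#' points to their own centroid) to the mean between-centroid distance.
#' Lower is better. Undefined for k = 1.
#'
#' @param x data matrix.
#' @param labels cluster labels.
#' @param centroids k x P centroid matrix.
#' @return positive scalar.
#' @export
cluster_validity_index <- function(x, labels, centroids) {
  x <- as.matrix(x)
  k <- nrow(centroids)
  if (k < 2) stop("validity index undefined for k = 1")
  d2 <- dist2_to_centers(x, centroids)
  within <- mean(sqrt(d2[cbind(seq_len(nrow(x)), labels)]))
  between <- mean(stats::dist(centroids))
  within / between
}

#' Select the number of states by the elbow criterion
#'
#' Runs k-means for each k in `k_range`, computes the validity curve, and
#' returns the k with the greatest curvature (largest discrete second
#' difference of the curve), ties going to the smallest k. If the curve is
#' already at its minimum at the smallest k (it never descends, so there is
#' no bend), or no interior k has positive curvature, the smallest k is
#' returned with a warning in the latter case.
#'
#' @param x N x P data matrix.
#' @param k_range candidate cluster counts (default 2:9).
#' @param seed integer seed.
#' @param n_replicates restarts per k.
#' @param keep_models keep the fitted clustering for every k (default TRUE,
#'   so the selected model need not be refit).
#' @return list with `k` (selected), `validity_curve` (named numeric),
#'   `models` (if kept), `curvature` (named second differences).
#' @export
elbow_select_k <- function(x, k_range = 2:9, seed = 1, n_replicates = 10,
                           keep_models = TRUE) {
  x <- as.matrix(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (max(k_range) > nrow(x)) stop("k_range exceeds number of points")
  models <- vector("list", length(k_range))
  curve <- numeric(length(k_range))
  names(curve) <- k_range
  for (q in seq_along(k_range)) {
    fit <- kmeans_states(x, k_range[q], seed = seed + k_range[q],
                         n_replicates = n_replicates)
    curve[q] <- cluster_validity_index(x, fit$labels, fit$centroids)
    if (keep_models) models[[q]] <- fit
  }
  sel <- elbow_from_curve(curve)
  list(k = sel$k, validity_curve = curve, curvature = sel$curvature,
       models = if (keep_models) stats::setNames(models, k_range))
}

#' Apply the elbow rule to a validity curve
#'
#' Implements the selection rule of [elbow_select_k()] on a precomputed
#' curve: the k with the largest discrete second difference (greatest
#' curvature) wins, ties to the smallest k. If the curve never descends
#' (its minimum is at the smallest k) that k is returned directly; if no
#' interior point has positive curvature the smallest k is returned with a
#' warning.
#'
#' @param curve numeric validity values named by their k.
#' @return list with `k` and `curvature` (named second differences, NA at
#'   the range ends).
#' @export
elbow_from_curve <- function(curve) {
  k_range <- as.integer(names(curve))
  stopifnot(!anyNA(k_range), length(curve) >= 2)
  nk <- length(k_range)
  curvature <- rep(NA_real_, nk)
  names(curvature) <- k_range
  if (nk >= 3)
    curvature[2:(nk - 1)] <- curve[1:(nk - 2)] - 2 * curve[2:(nk - 1)] +
      curve[3:nk]
  if (which.min(curve) == 1L) {
    k_sel <- k_range[1]
  } else {
    interior <- curvature[!is.na(curvature)]
    if (length(interior) == 0 || all(interior <= 0)) {
      warning("validity curve has no elbow; returning smallest k")
      k_sel <- k_range[1]
    } else {
      best <- max(interior)
      k_sel <- as.integer(names(interior)[which(interior == best)][1])
    }
  }
  list(k = k_sel, curvature = curvature)
}

#' Summarize clustered windows into a state model
#'
#' Completes the clustering with occupancy rates, per-state subject counts
#' and each subject's representative (mean) connectivity vector per visited
#' state. Subjects never visiting a state are absent from that state's
#' roster.
#'
#' @param windows list of `windowed_connectivity` objects, one per subject.
#' @param labels integer vector of state labels for the stacked windows (in
#'   the same order as `do.call(rbind, lapply(windows, vectors))`).
#' @param centroids k x P centroid matrix.
#' @param validity_curve optional named validity curve for reporting.
#' @return object of class `dfnc_state_model`: list with `k`, `centroids`,
#'   `labels` (data frame subject_id/window_start/state), `occupancy`,
#'   `subject_counts`, `subject_state_means` (per subject, named list
#'   state -> P-vector), `rosters` (per state, subject ids), `pair_index`.
#' @export
summarize_states <- function(windows, labels, centroids,
                             validity_curve = NULL) {
  stopifnot(is.list(windows), length(windows) >= 1)
  k <- nrow(centroids)
  n_win <- vapply(windows, function(w) length(w$window_starts), integer(1))
  stopifnot(length(labels) == sum(n_win))
  ids <- vapply(windows, function(w) w$subject_id, character(1))
  lab_df <- data.frame(
    subject_id = rep(ids, times = n_win),
    window_start = unlist(lapply(windows, function(w) w$window_starts)),
    state = as.integer(labels))
  occupancy <- tabulate(labels, nbins = k) / length(labels)
  subject_state_means <- vector("list", length(windows))
  names(subject_state_means) <- ids
  offset <- 0L
  for (i in seq_along(windows)) {
    li <- labels[(offset + 1L):(offset + n_win[i])]
    offset <- offset + n_win[i]
    visited <- sort(unique(li))
    means <- lapply(visited, function(s)
      colMeans(windows[[i]]$vectors[li == s, , drop = FALSE]))
    names(means) <- visited
    subject_state_means[[i]] <- means
  }
  rosters <- lapply(seq_len(k), function(s)
    ids[vapply(subject_state_means,
               function(m) as.character(s) %in% names(m), logical(1))])
  structure(list(k = k, centroids = centroids, labels = lab_df,
                 occupancy = occupancy,
                 subject_counts = lengths(rosters),
                 subject_state_means = subject_state_means,
                 rosters = rosters,
                 pair_index = windows[[1]]$pair_index,
                 validity_curve = validity_curve),
            class = "dfnc_state_model")
}

#' @export
print.dfnc_state_model <- function(x, ...) {
  cat(sprintf("dfnc_state_model: k = %d, %d subjects, %d windows\n",
              x$k, length(x$subject_state_means), nrow(x$labels)))
  cat("occupancy:", paste(sprintf("%.3f", x$occupancy), collapse = " "), "\n")
  cat("subjects per state:", paste(x$subject_counts, collapse = " "), "\n")
  invisible(x)
}

#' Per-state feature matrix of subject representative vectors
#'
#' @param model a `dfnc_state_model`.
#' @param state state index.
#' @return list with `x` (n_roster x P matrix of subject state means) and
#'   `subject_id` (roster).
#' @export
state_feature_matrix <- function(model, state) {
  s <- as.character(state)
  keep <- vapply(model$subject_state_means, function(m) s %in% names(m),
                 logical(1))
  x <- do.call(rbind, lapply(model$subject_state_means[keep],
                             function(m) m[[s]]))
  list(x = x, subject_id = names(model$subject_state_means)[keep])
}

#' Match estimated state labels to reference labels
#'
#' Finds the label permutation maximizing agreement (for k up to 8 by
#' exhaustive enumeration) and returns the best accuracy and permutation.
#'
#' @param est estimated labels (1..k).
#' @param ref reference labels (1..k).
#' @param k number of states.
#' @return list with `accuracy` and `perm` (est state s corresponds to
#'   reference state perm[s]).
#' @export
match_state_labels <- function(est, ref, k = max(est, ref)) {
  stopifnot(length(est) == length(ref), k <= 8)
  conf <- table(factor(est, levels = seq_len(k)),
                factor(ref, levels = seq_len(k)))
  perms <- permutations_of(k)
  best_acc <- -1; best_perm <- seq_len(k)
  for (q in seq_len(nrow(perms))) {
    acc <- sum(conf[cbind(seq_len(k), perms[q, ])])
    if (acc > best_acc) { best_acc <- acc; best_perm <- perms[q, ] }
  }
  list(accuracy = best_acc / length(est), perm = best_perm)
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1)
  out <- matrix(0L, nrow(sub) * k, k)
  row <- 1L
  for (pos in seq_len(k)) for (q in seq_len(nrow(sub))) {
    out[row, ] <- append(sub[q, ], k, after = pos - 1L)
    row <- row + 1L
  }
  out
}
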