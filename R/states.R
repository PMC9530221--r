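#' Cluster BOLD frames into brain states by correlation-distance k-means
#'
#' Concatenates all scans in time and runs Lloyd's algorithm with distance
#' `1 - Pearson r` between each frame and each centroid (correlation taken
#' across regions). The best of `n_replicates` random initializations —
#' the one with the smallest total frame-to-centroid correlation distance —
#' is returned. Final centroids are plain arithmetic means of their member
#' frames.
#'
#' Frames with zero variance across regions (correlation undefined) are
#' assigned to the nearest centroid by Euclidean distance. A replicate
#' whose final solution contains an empty cluster is re-run with a fresh
#' derived seed (up to 3 attempts) and otherwise discarded.
#'
#' @param scans list of [parc_ts()] objects sharing a region set (a single
#'   `parc_ts` is accepted).
#' @param k number of states (>= 2).
#' @param n_replicates random restarts (default 50).
#' @param seed master seed; replicate seeds are derived by fixed offsets.
#' @param max_iter Lloyd iteration cap per replicate (default 100).
#' @return object of class `state_partition`: list with `labels` (integer
#'   per concatenated frame), `centroids` (k x regions), `k`,
#'   `variance_explained`, `tot_within` (clustering objective), `scan_id`
#'   (scan identity per frame), `tr_seconds`, `subject_id`, `condition`
#'   (per frame), and `seed`.
#' @export
cluster_states <- function(scans, k, n_replicates = 50, seed = 1,
                           max_iter = 100L) {
  if (inherits(scans, "parc_ts")) scans <- list(scans)
  stopifnot(length(scans) >= 1, k >= 2, n_replicates >= 1)
  rg <- colnames(scans[[1]]$values)
  for (s in scans)
    if (!identical(colnames(s$values), rg))
      stop("all scans must share the same region set, in the same order")
  X <- do.call(rbind, lapply(scans, function(s) s$values))
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of frames")
  best <- NULL
  for (r in seq_len(n_replicates)) {
    for (attempt in 0:2) {
      set.seed(seed + 1000L * (r - 1L) + attempt)
      fit <- kmeans_corr_once(X, k, max_iter)
      if (!fit$empty) break
    }
    if (fit$empty) next
    if (is.null(best) || fit$tot_within < best$tot_within) best <- fit
  }
  if (is.null(best)) stop("every replicate ended with an empty cluster")
  per_frame <- function(field)
    unlist(lapply(scans, function(s) rep(s[[field]], nrow(s$values))),
           use.names = FALSE)
  structure(list(labels = best$labels, centroids = best$centroids, k = k,
                 variance_explained = variance_explained_raw(X, best$labels,
                                                             best$centroids),
                 tot_within = best$tot_within,
                 frame_data = X,
                 scan_id = per_frame("scan_id"),
                 subject_id = per_frame("subject_id"),
                 condition = per_frame("condition"),
                 tr_seconds = scans[[1]]$tr_seconds, seed = seed),
            class = "state_partition")
}

#' @export
print.state_partition <- function(x, ...) {
  cat(sprintf("<state_partition> k = %d, %d frames, VE = %.3f\n",
              x$k, length(x$labels), x$variance_explained))
  invisible(x)
}

# one Lloyd run with correlation distance; centroids seeded from k frames
# by distance-weighted (k-means++ style) sampling on 1 - r
kmeans_corr_once <- function(X, k, max_iter) {
  n <- nrow(X)
  Xs <- standardize_rows(X)
  degenerate <- attr(Xs, "zero_var")
  seeds <- integer(k)
  seeds[1] <- sample.int(n, 1)
  d <- pmax(1 - drop(Xs %*% Xs[seeds[1], ]), 0)
  for (j in seq_len(k - 1)) {
    if (sum(d) <= 0) {
      # all frames coincide with a seed; fall back to uniform sampling
      seeds[j + 1] <- sample.int(n, 1)
    } else {
      seeds[j + 1] <- sample.int(n, 1, prob = d / sum(d))
    }
    d <- pmin(d, pmax(1 - drop(Xs %*% Xs[seeds[j + 1], ]), 0))
  }
  C <- X[seeds, , drop = FALSE]
  labels <- integer(n)
  for (it in seq_len(max_iter)) {
    R <- Xs %*% t(standardize_rows(C))  # frames x k Pearson r
    new_labels <- max.col(R, ties.method = "first")
    if (any(degenerate)) {
      d2 <- euclid2_to_centroids(X[degenerate, , drop = FALSE], C)
      new_labels[degenerate] <- max.col(-d2, ties.method = "first")
    }
    if (identical(new_labels, labels)) break
    labels <- new_labels
    if (length(unique(labels)) < k) break  # empty cluster: abandon replicate
    C <- rowsum(X, labels) / as.vector(table(labels))
  }
  empty <- length(unique(labels)) < k
  if (empty)
    return(list(empty = TRUE))
  C <- rowsum(X, labels) / as.vector(table(labels))
  R <- Xs %*% t(standardize_rows(C))
  tw <- sum(1 - R[cbind(seq_len(n), labels)])
  list(labels = labels, centroids = C, tot_within = tw, empty = FALSE)
}

# rows scaled to zero mean, unit norm (so tcrossprod gives Pearson r);
# zero-variance rows flagged and left as zero
standardize_rows <- function(M) {
  mu <- rowMeans(M)
  Z <- M - mu
  nrm <- sqrt(rowSums(Z^2))
  zero <- nrm < 1e-12
  nrm[zero] <- 1
  out <- Z / nrm
  attr(out, "zero_var") <- zero
  out
}

euclid2_to_centroids <- function(X, C) {
  outer(rowSums(X^2), rep(1, nrow(C))) - 2 * X %*% t(C) +
    outer(rep(1, nrow(X)), rowSums(C^2))
}

variance_explained_raw <- function(X, labels, centroids) {
  gm <- colMeans(X)
  ss_tot <- sum(sweep(X, 2L, gm)^2)
  ss_within <- sum((X - centroids[labels, , drop = FALSE])^2)
  if (ss_tot == 0) return(1)
  1 - ss_within / ss_tot
}

#' Fraction of variance explained by a partition
#'
#' `1 - SS_within / SS_total`, where `SS_within` sums squared deviations of
#' frames from their assigned centroids and `SS_total` from the grand mean.
#'
#' @param partition a `state_partition` (or integer labels).
#' @param scans the scans the partition was fit on (list of [parc_ts()]).
#' @return scalar in [0, 1].
#' @export
variance_explained <- function(partition, scans) {
  if (inherits(scans, "parc_ts")) scans <- list(scans)
  X <- do.call(rbind, lapply(scans, function(s) s$values))
  labels <- if (inherits(partition, "state_partition")) partition$labels else partition
  stopifnot(length(labels) == nrow(X))
  C <- rowsum(X, labels) / as.vector(table(labels))
  # rowsum orders by sorted unique label; index accordingly
  lev <- sort(unique(labels))
  variance_explained_raw(X, match(labels, lev), C)
}

#' Select the most representative partition by total adjusted mutual information
#'
#' Given repeated clustering runs over the same frames, returns the
#' partition with the greatest summed AMI to all other partitions
#' (ties: lowest index).
#'
#' @param partitions list of `state_partition` objects (or plain label
#'   vectors) over identical frames.
#' @return the selected element of `partitions`, with attribute
#'   `total_ami` (numeric vector of all totals).
#' @export
select_partition_by_ami <- function(partitions) {
  stopifnot(length(partitions) >= 2)
  labs <- lapply(partitions, function(p)
    if (inherits(p, "state_partition")) p$labels else p)
  n <- unique(vapply(labs, length, 1L))
  if (length(n) != 1) stop("partitions cover different numbers of frames")
  m <- length(labs)
  A <- matrix(0, m, m)
  for (i in seq_len(m - 1)) {
    for (j in (i + 1):m) {
      A[i, j] <- A[j, i] <- ami_score(labs[[i]], labs[[j]])
    }
  }
  totals <- rowSums(A)
  out <- partitions[[which.max(totals)]]
  attr(out, "total_ami") <- totals
  out
}

#' Variance-explained elbow scan over k
#'
#' Runs the clustering for each `k` in `k_range` (selecting among `n_runs`
#' independent repetitions by total AMI when `n_runs > 1`) and reports the
#' variance explained, its increment, and the smallest `k` whose gain to
#' `k + 1` falls below `threshold` (default 1%). The scan is advisory: no
#' `k` is auto-applied.
#'
#' @param scans list of [parc_ts()].
#' @param k_range contiguous integer range, min >= 2.
#' @param n_runs independent repetitions per k (default 10).
#' @param n_replicates restarts per run.
#' @param seed master seed.
#' @param threshold variance-gain threshold (fraction, default 0.01).
#' @return list with `table` (data.frame k, variance_explained, gain) and
#'   `k_elbow` (smallest k with gain below threshold, NA if none).
#' @export
elbow_scan <- function(scans, k_range = 2:14, n_runs = 10, n_replicates = 50,
                       seed = 1, threshold = 0.01) {
  stopifnot(min(k_range) >= 2, all(diff(k_range) == 1))
  ve <- vapply(k_range, function(k) {
    if (n_runs > 1) {
      runs <- lapply(seq_len(n_runs), function(r)
        cluster_states(scans, k, n_replicates, seed = seed + 7919L * r + k))
      select_partition_by_ami(runs)$variance_explained
    } else {
      cluster_states(scans, k, n_replicates,
                     seed = seed + k)$variance_explained
    }
  }, 1.0)
  gain <- c(diff(ve), NA)
  below <- which(gain < threshold)
  list(table = data.frame(k = k_range, variance_explained = ve, gain = gain),
       k_elbow = if (length(below)) k_range[below[1]] else NA_integer_)
}

#' Average centroids at group, condition, or subject-condition level
#'
#' Recomputes state centroids as means of the assigned frames restricted to
#' the requested level. Clusters with no frames at a level are flagged
#' missing (NA centroid rows), never silently zeroed.
#'
#' @param partition a `state_partition`.
#' @param level one of "group", "condition", "subject-condition".
#' @return for "group": a single `brain_state_set`; otherwise a named list
#'   of `brain_state_set` objects (per condition, or per
#'   subject x condition with names `subject.condition`).
#' @export
compute_centroids <- function(partition, level = c("group", "condition",
                                                   "subject-condition")) {
  level <- match.arg(level)
  stopifnot(inherits(partition, "state_partition"))
  groups <- switch(level,
    "group" = rep("group", length(partition$labels)),
    "condition" = partition$condition,
    "subject-condition" = paste(partition$subject_id, partition$condition,
                                sep = "."))
  out <- lapply(split(seq_along(partition$labels), groups), function(idx) {
    centroid_set(partition, idx, level)
  })
  if (level == "group") out[["group"]] else out
}

centroid_set <- function(partition, idx, level) {
  k <- partition$k
  labs <- partition$labels[idx]
  C <- matrix(NA_real_, k, ncol(partition$centroids),
              dimnames = list(paste0("state", seq_len(k)),
                              colnames(partition$centroids)))
  present <- sort(unique(labs))
  if (length(idx)) {
    M <- partition$frame_data[idx, , drop = FALSE]
    Cp <- rowsum(M, labs) / as.vector(table(labs))
    C[present, ] <- Cp
  }
  brain_state_set(C, level = level, missing_states = setdiff(seq_len(k), present))
}

#' Brain-state set container
#'
#' @param centroids k x regions matrix (NA rows = missing states).
#' @param level provenance level string.
#' @param missing_states integer indices of flagged-missing states.
#' @param meta_assignment optional integer vector mapping each sub-state to
#'   its meta-state.
#' @return object of class `brain_state_set`.
#' @export
brain_state_set <- function(centroids, level = "group",
                            missing_states = integer(),
                            meta_assignment = NULL) {
  structure(list(centroids = centroids, level = level,
                 missing_states = missing_states,
                 meta_assignment = meta_assignment),
            class = "brain_state_set")
}

#' @export
print.brain_state_set <- function(x, ...) {
  cat(sprintf("<brain_state_set> %d states x %d regions (%s level)%s\n",
              nrow(x$centroids), ncol(x$centroids), x$level,
              if (length(x$missing_states))
                paste0("; missing: ", paste(x$missing_states, collapse = ","))
              else ""))
  invisible(x)
}

#' Cosine alignment of a centroid with resting-state networks
#'
#' Splits a centroid into its supra-mean part (positive entries; regional
#' series are demeaned, so positive = above-mean amplitude) and sub-mean
#' part (absolute values of negative entries) and computes the cosine
#' similarity of each part with each binary RSN membership mask. An
#' all-zero part has similarity 0 by convention.
#'
#' @param centroid numeric region vector.
#' @param rsn_masks regions x networks binary matrix.
#' @return data.frame with columns `network`, `supra`, `sub`, values in [0, 1].
#' @export
rsn_alignment <- function(centroid, rsn_masks) {
  rsn_masks <- as.matrix(rsn_masks)
  stopifnot(length(centroid) == nrow(rsn_masks),
            all(rsn_masks %in% c(0, 1)))
  supra <- pmax(centroid, 0)
  sub <- pmax(-centroid, 0)
  cos_sim <- function(a, m) {
    na <- sqrt(sum(a^2)); nm <- sqrt(sum(m^2))
    if (na == 0 || nm == 0) return(0)
    sum(a * m) / (na * nm)
  }
  data.frame(
    network = colnames(rsn_masks) %||% paste0("RSN", seq_len(ncol(rsn_masks))),
    supra = apply(rsn_masks, 2L, cos_sim, a = supra),
    sub = apply(rsn_masks, 2L, cos_sim, a = sub),
    row.names = NULL
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pair sub-states into meta-states by anti-correlation
#'
#' Greedily pairs centroids by the most negative Pearson correlation first,
#' until all states belong to exactly one pair. A selected pair with
#' correlation >= 0 triggers a warning (the hierarchy assumption is
#' violated).
#'
#' @param centroids k x regions matrix, k even.
#' @return list with `meta_assignment` (integer meta-state index per
#'   sub-state) and `pairs` (data.frame state_a, state_b, correlation).
#' @export
pair_meta_states <- function(centroids) {
  centroids <- as.matrix(centroids)
  k <- nrow(centroids)
  if (k %% 2 != 0) stop("k must be even to pair meta-states")
  R <- stats::cor(t(centroids))
  unpaired <- seq_len(k)
  assignment <- integer(k)
  pairs <- NULL
  m <- 0L
  while (length(unpaired) > 1) {
    Rsub <- R[unpaired, unpaired, drop = FALSE]
    diag(Rsub) <- Inf
    ij <- arrayInd(which.min(Rsub), dim(Rsub))
    a <- unpaired[ij[1]]; b <- unpaired[ij[2]]
    if (R[a, b] >= 0)
      warning(sprintf("paired states %d and %d have correlation %.3f >= 0",
                      a, b, R[a, b]))
    m <- m + 1L
    assignment[c(a, b)] <- m
    pairs <- rbind(pairs, data.frame(state_a = min(a, b), state_b = max(a, b),
                                     correlation = R[a, b]))
    unpaired <- setdiff(unpaired, c(a, b))
  }
  list(meta_assignment = assignment, pairs = pairs)
}

#' Match states to a reference set by maximal total correlation
#'
#' Finds the one-to-one assignment between `centroids` rows and
#' `reference_centroids` rows maximizing the summed Pearson correlation
#' (exhaustive search over permutations; k <= 8). Ties resolve to the
#' lexicographically smallest permutation.
#'
#' @param centroids,reference_centroids k x regions matrices.
#' @return list with `order` (integer: position i holds the row of
#'   `centroids` matched to reference state i), `centroids` (reordered),
#'   and `total_correlation`.
#' @export
match_states <- function(centroids, reference_centroids) {
  centroids <- as.matrix(centroids)
  reference_centroids <- as.matrix(reference_centroids)
  k <- nrow(centroids)
  stopifnot(nrow(reference_centroids) == k,
            ncol(reference_centroids) == ncol(centroids))
  if (k > 8) stop("exhaustive assignment supported for k <= 8")
  R <- stats::cor(t(reference_centroids), t(centroids))  # ref x cand
  perms <- pracma::perms(seq_len(k))
  perms <- perms[do.call(order, as.data.frame(perms)), , drop = FALSE]
  best <- NULL; best_sum <- -Inf
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]
    s <- sum(R[cbind(seq_len(k), p)])
    if (s > best_sum + 1e-12) { best_sum <- s; best <- p }
  }
  list(order = best, centroids = centroids[best, , drop = FALSE],
       total_correlation = best_sum)
}
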