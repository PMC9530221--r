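#' Spin-permutation ensemble for a parcellated map
#'
#' Generates spatial-autocorrelation-preserving null maps by rotating the
#' parcel coordinates on the sphere. Each spin draws one uniform random
#' rotation, applies it to the left hemisphere and its sagittal mirror to
#' the right, then reassigns regions by greedy one-to-one nearest-neighbor
#' matching over ascending distance within each hemisphere. The result is
#' a true permutation of the original values (the value multiset is
#' exactly preserved), unlike plain nearest-neighbor spins which can
#' duplicate values.
#'
#' @param map named per-region numeric vector.
#' @param coords data.frame with `region_id`, `hemisphere` (left/right),
#'   `x`, `y`, `z` on the unit sphere.
#' @param n_spins number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @return list of class `spin_ensemble`: `maps` (regions x n_spins matrix
#'   of permuted values), `perm` (regions x n_spins permutation indices),
#'   `n_spins`, `seed`.
#' @export
spin_permutation <- function(map, coords, n_spins, seed = 1) {
  stopifnot(n_spins >= 1, length(map) == nrow(coords))
  hemi <- as.character(coords$hemisphere)
  for (h in unique(hemi))
    if (sum(hemi == h) < 2)
      stop("each hemisphere needs at least 2 regions to spin")
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  set.seed(seed)
  n <- length(map)
  perm <- matrix(NA_integer_, n, n_spins)
  mirror <- diag(c(-1, 1, 1))
  for (s in seq_len(n_spins)) {
    R <- random_rotation()
    for (h in unique(hemi)) {
      idx <- which(hemi == h)
      Rh <- if (h == "right") mirror %*% R %*% mirror else R
      rotated <- xyz[idx, , drop = FALSE] %*% t(Rh)
      perm[idx, s] <- idx[greedy_match(rotated, xyz[idx, , drop = FALSE])]
    }
  }
  maps <- matrix(map[perm], n, n_spins)
  rownames(maps) <- names(map)
  structure(list(maps = maps, perm = perm, n_spins = n_spins, seed = seed),
            class = "spin_ensemble")
}

# uniform random rotation: QR of a Gaussian matrix, sign-fixed, det = +1
random_rotation <- function() {
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  Q <- Q %*% diag(sign(diag(qr.R(qr_))))
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  Q
}

# one-to-one assignment: source rows (rotated positions) to target slots,
# greedily over ascending Euclidean distance.
# returns, per target slot, the index of the source region assigned to it.
greedy_match <- function(rotated, original) {
  m <- nrow(rotated)
  D <- outer(rowSums(rotated^2), rep(1, m)) - 2 * rotated %*% t(original) +
    outer(rep(1, m), rowSums(original^2))
  ord <- order(D)
  src_free <- rep(TRUE, m)
  tgt_free <- rep(TRUE, m)
  assign <- integer(m)
  left <- m
  for (o in ord) {
    i <- (o - 1L) %% m + 1L       # source (rotated region)
    j <- (o - 1L) %/% m + 1L      # target slot
    if (src_free[i] && tgt_free[j]) {
      assign[j] <- i
      src_free[i] <- FALSE
      tgt_free[j] <- FALSE
      left <- left - 1L
      if (left == 0L) break
    }
  }
  assign
}

#' Spin-test p-values for a transition-energy matrix
#'
#' For direction "lower", `p_ij` is the fraction of null maps whose energy
#' is lower than the true one, with an add-one correction:
#' `p = (#(E_null < E_true) + 1) / (n_spins + 1)`, which avoids p = 0 from
#' finite ensembles and recovers the plain fraction asymptotically.
#'
#' @param true_te k x k matrix under the true map.
#' @param null_tes k x k x n_spins array (or list of matrices) under the
#'   spun maps.
#' @param direction "lower" (null beats true by being lower) or "higher".
#' @return k x k matrix of p-values.
#' @export
spin_pvalue <- function(true_te, null_tes, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  if (is.list(null_tes))
    null_tes <- array(unlist(null_tes),
                      dim = c(dim(true_te), length(null_tes)))
  stopifnot(length(dim(null_tes)) == 3,
            all(dim(null_tes)[1:2] == dim(true_te)))
  n <- dim(null_tes)[3]
  cmp <- if (direction == "lower") `<` else `>`
  hits <- apply(cmp(null_tes, as.vector(true_te)), c(1, 2), sum)
  (hits + 1) / (n + 1)
}

#' Mean transition energy under each of several receptor profiles
#'
#' Builds a receptor-weighted control matrix from every map, computes the
#' full transition-energy matrix between the given states, and returns the
#' mean over all ordered pairs (diagonal included). A uniform-input
#' baseline is prepended when `include_uniform` is TRUE.
#'
#' @param maps named list of per-region density vectors.
#' @param A stable system matrix (or `system_matrix`).
#' @param states `brain_state_set` or centroid matrix.
#' @param T time horizon.
#' @param include_uniform prepend the uniform-B baseline.
#' @return data.frame with columns `map`, `mean_te`.
#' @export
compare_receptor_profiles <- function(maps, A, states, T = 1,
                                      include_uniform = TRUE) {
  C <- if (inherits(states, "brain_state_set")) states$centroids else
    as.matrix(states)
  n <- ncol(C)
  rows <- list()
  if (include_uniform) {
    te <- transition_energy_matrix(A, build_control_matrix(n_regions = n),
                                   C, T)
    rows[["uniform"]] <- mean(te)
  }
  for (nm in names(maps)) {
    B <- build_control_matrix(receptor_map = maps[[nm]])
    rows[[nm]] <- mean(transition_energy_matrix(A, B, C, T))
  }
  data.frame(map = names(rows), mean_te = unlist(rows), row.names = NULL)
}
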