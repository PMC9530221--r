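#' Normalize a structural connectome into a stable system matrix
#'
#' Scales the connectome by one plus its largest eigenvalue and subtracts
#' the identity:
#' `A_norm = A / (lambda_max(A) + 1) - I`,
#' the convention of the linear network-control literature. Every
#' eigenvalue of `A_norm` then has a strictly negative real part, so the
#' free dynamics `dx/dt = A_norm x` decay and finite-horizon
#' controllability Gramians are well defined.
#'
#' @param connectome symmetric nonnegative matrix with zero diagonal.
#' @param stability_margin required upper bound (-margin) on the largest
#'   real eigenvalue part; validation only.
#' @return list of class `system_matrix`: `A_norm`, `lambda_max`,
#'   `max_real_eig`.
#' @export
normalize_connectome <- function(connectome, stability_margin = 1e-9) {
  A <- as.matrix(connectome)
  if (nrow(A) != ncol(A)) stop("connectome must be square")
  if (max(abs(A - t(A))) > 1e-12) stop("connectome must be symmetric")
  if (any(A < 0)) stop("connectome must be nonnegative")
  if (any(abs(diag(A)) > 1e-12)) stop("connectome must have a zero diagonal")
  lam <- max(eigen(A, symmetric = TRUE, only.values = TRUE)$values)
  An <- A / (lam + 1) - diag(nrow(A))
  max_re <- max(eigen(An, symmetric = TRUE, only.values = TRUE)$values)
  if (max_re > -stability_margin)
    stop("normalized system is not stable to the requested margin")
  structure(list(A_norm = An, lambda_max = lam, max_real_eig = max_re),
            class = "system_matrix")
}

as_A <- function(A) if (inherits(A, "system_matrix")) A$A_norm else as.matrix(A)

# dense matrix exponential (scaling-and-squaring via Matrix, machine precision)
expm_dense <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

#' Build the control input matrix B
#'
#' Uniform mode returns the identity (every region receives equal input).
#' Receptor mode sets the diagonal to one plus the min-max-normalized
#' regional receptor density, so entries lie in [1, 2]: regions dense in
#' the receptor can absorb up to twice the input.
#'
#' @param n_regions system size (uniform mode).
#' @param receptor_map named nonnegative, non-constant density vector
#'   (receptor mode); must cover all regions.
#' @return list of class `control_matrix`: `B` (diagonal matrix), `mode`.
#' @export
build_control_matrix <- function(n_regions = NULL, receptor_map = NULL) {
  if (is.null(receptor_map)) {
    stopifnot(!is.null(n_regions))
    return(structure(list(B = diag(n_regions), mode = "uniform"),
                     class = "control_matrix"))
  }
  v <- as.numeric(receptor_map)
  if (any(v < 0)) stop("receptor densities must be nonnegative")
  rng <- range(v)
  if (diff(rng) == 0)
    stop("receptor map is constant: min-max normalization is undefined; ",
         "use uniform inputs instead")
  d <- 1 + (v - rng[1]) / diff(rng)
  structure(list(B = diag(d), mode = "receptor-weighted"),
            class = "control_matrix")
}

as_B <- function(B) {
  if (inherits(B, "control_matrix")) B$B
  else if (is.matrix(B)) B
  else if (length(B) == 1) matrix(as.numeric(B), 1, 1)
  else diag(as.numeric(B))
}

#' Finite-horizon controllability Gramian
#'
#' `W(T) = integral_0^T exp(A t) B B' exp(A' t) dt`, computed in closed
#' form with the Van Loan block matrix exponential
#' `F = expm([[-A, BB'], [0, A']] T)`, `W = F22' F12` — no quadrature.
#'
#' @param A stable system matrix (or `system_matrix`).
#' @param B control matrix (`control_matrix`, matrix, or diagonal vector).
#' @param T time horizon (> 0).
#' @return symmetric positive semidefinite N x N matrix.
#' @export
controllability_gramian <- function(A, B, T = 1) {
  A <- as_A(A); B <- as_B(B)
  stopifnot(T > 0, nrow(A) == ncol(A), nrow(B) == nrow(A))
  n <- nrow(A)
  blk <- rbind(cbind(-A, B %*% t(B)),
               cbind(matrix(0, n, n), t(A)))
  FF <- expm_dense(blk * T)
  W <- t(FF[(n + 1):(2 * n), (n + 1):(2 * n)]) %*% FF[1:n, (n + 1):(2 * n)]
  (W + t(W)) / 2
}

# Cholesky with conditioning diagnostics shared by the energy functions
gramian_factor <- function(W) {
  rc <- rcond(W)
  ch <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(ch))
    stop(sprintf(paste0("controllability Gramian is numerically singular ",
                        "(reciprocal condition number %.3e); the system is ",
                        "effectively uncontrollable over this horizon"), rc))
  attr(ch, "rcond") <- rc
  ch
}

quad_inv <- function(ch, v) {
  z <- backsolve(ch, backsolve(ch, v, transpose = TRUE))
  sum(v * z)
}

#' Minimum control energy for one state transition
#'
#' Minimum of `integral_0^T ||u(t)||^2 dt` over inputs driving
#' `dx/dt = A x + B u` from `x0` at time 0 to `xT` at time `T`:
#' `E = v' W(T)^{-1} v` with `v = xT - expm(A T) x0`.
#'
#' @param A stable system matrix (or `system_matrix`).
#' @param B control matrix.
#' @param x0,xT initial and target state vectors.
#' @param T time horizon.
#' @return nonnegative scalar energy.
#' @export
min_transition_energy <- function(A, B, x0, xT, T = 1) {
  A <- as_A(A)
  stopifnot(length(x0) == nrow(A), length(xT) == nrow(A))
  W <- controllability_gramian(A, B, T)
  v <- as.numeric(xT) - drop(expm_dense(A * T) %*% as.numeric(x0))
  quad_inv(gramian_factor(W), v)
}

#' Precompute the expensive factors for repeated energy evaluations
#'
#' Computes `expm(A T)` and the Cholesky factor of `W(T)` once, so that
#' transition-energy matrices for many centroid sets (subjects, spins)
#' under the same `A`, `B`, `T` reuse them.
#'
#' @inheritParams min_transition_energy
#' @return list of class `energy_prep` with `eAT`, `chol_W`, `rcond`, `T`.
#' @export
energy_prep <- function(A, B, T = 1) {
  A <- as_A(A)
  W <- controllability_gramian(A, B, T)
  ch <- gramian_factor(W)
  structure(list(eAT = expm_dense(A * T), chol_W = ch,
                 rcond = attr(ch, "rcond"), T = T),
            class = "energy_prep")
}

#' Transition energy matrix between all ordered pairs of brain states
#'
#' `E[i, j]` is the minimum control energy to drive the system from
#' centroid i to centroid j over horizon `T`; the diagonal is the
#' persistence energy (the cost of remaining in a state while the free
#' dynamics decay it). Centroids flagged missing yield `NA` rows/columns.
#'
#' @param A stable system matrix (or `system_matrix`).
#' @param B control matrix.
#' @param states a `brain_state_set` or a k x regions centroid matrix.
#' @param T time horizon.
#' @param prep optional [energy_prep()] to reuse across calls.
#' @return k x k matrix with attribute `T`.
#' @export
transition_energy_matrix <- function(A, B, states, T = 1, prep = NULL) {
  C <- if (inherits(states, "brain_state_set")) states$centroids else
    as.matrix(states)
  if (is.null(prep)) prep <- energy_prep(A, B, T)
  k <- nrow(C)
  E <- matrix(NA_real_, k, k, dimnames = list(rownames(C), rownames(C)))
  ok <- which(stats::complete.cases(C))
  drift <- matrix(NA_real_, k, ncol(C))
  drift[ok, ] <- C[ok, , drop = FALSE] %*% t(prep$eAT)
  for (i in ok) {
    for (j in ok) {
      v <- C[j, ] - drift[i, ]
      E[i, j] <- quad_inv(prep$chol_W, v)
    }
  }
  attr(E, "T") <- prep$T
  E
}

#' Discretized least-norm oracle for the minimum transition energy
#'
#' Independent brute-force validator: discretizes the dynamics exactly on
#' `n_steps` zero-order-hold intervals (`Ad = expm(A dt)`,
#' `Bd = A^{-1}(Ad - I) B`, computed by eigen-decomposition for symmetric
#' `A`), solves the least-norm input sequence reaching `xT`, and returns
#' `sum ||u_t||^2 dt`. Converges to the Gramian answer as `n_steps` grows.
#'
#' @inheritParams min_transition_energy
#' @param n_steps number of discretization intervals (>= 100).
#' @return nonnegative scalar energy.
#' @export
oracle_discretized_energy <- function(A, B, x0, xT, T = 1, n_steps = 2000) {
  A <- as_A(A); B <- as_B(B)
  stopifnot(n_steps >= 100)
  dt <- T / n_steps
  if (max(abs(A - t(A))) < 1e-10) {
    e <- eigen(A, symmetric = TRUE)
    Ad <- e$vectors %*% (exp(e$values * dt) * t(e$vectors))
    Bd <- e$vectors %*% (((exp(e$values * dt) - 1) / e$values) *
                           t(e$vectors)) %*% B
  } else {
    Ad <- expm_dense(A * dt)
    Bd <- solve(A, (Ad - diag(nrow(A)))) %*% B
  }
  # discrete reachability Gramian sum_{j=0}^{n-1} Ad^j Bd Bd' (Ad^j)'
  Wd <- matrix(0, nrow(A), ncol(A))
  Phi <- Bd %*% t(Bd)
  xfree <- as.numeric(x0)
  for (j in seq_len(n_steps)) {
    Wd <- Wd + Phi
    Phi <- Ad %*% Phi %*% t(Ad)
    xfree <- drop(Ad %*% xfree)
  }
  v <- as.numeric(xT) - xfree
  drop(t(v) %*% solve(Wd, v)) * dt
}

#' Sensitivity of a transition-energy matrix to the time horizon
#'
#' Recomputes the TE matrix over a grid of horizons and reports, for each
#' pair of horizons, the Spearman correlation of the vectorized energies —
#' a check that qualitative orderings are horizon-stable.
#'
#' @param A,B,states as in [transition_energy_matrix()].
#' @param horizons numeric vector of horizons.
#' @return list with `matrices` (named list of TE matrices) and
#'   `spearman` (horizon x horizon correlation of vectorized entries).
#' @export
te_sensitivity_sweep <- function(A, B, states, horizons = c(0.5, 1, 3, 5)) {
  mats <- lapply(horizons, function(Tt)
    transition_energy_matrix(A, B, states, T = Tt))
  names(mats) <- paste0("T=", horizons)
  vecs <- vapply(mats, as.vector, numeric(length(as.vector(mats[[1]]))))
  list(matrices = mats,
       spearman = stats::cor(vecs, method = "spearman",
                             use = "pairwise.complete.obs"))
}
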