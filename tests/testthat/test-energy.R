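test_that("connectome normalization produces a stable system", {
  Z <- matrix(0, 4, 4)
  expect_equal(normalize_connectome(Z)$A_norm, -diag(4))
  # hand computation on a 3x3 with known spectrum: ones(3) - I has
  # eigenvalues {2, -1, -1}, so A_norm = A/3 - I
  A <- matrix(1, 3, 3) - diag(3)
  S <- normalize_connectome(A)
  expect_equal(S$A_norm, A / 3 - diag(3))
  expect_equal(S$lambda_max, 2)
  expect_lt(S$max_real_eig, 0)
  W <- gen_connectome(20, 2, 0.4, seed = 1)
  expect_lt(max(eigen(normalize_connectome(W)$A_norm)$values), 0)
  expect_error(normalize_connectome(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
  expect_error(normalize_connectome(-A), "nonnegative")
})

test_that("control matrix bounds follow the 1 + min-max rule", {
  B <- build_control_matrix(n_regions = 5)
  expect_equal(B$B, diag(5))
  Br <- build_control_matrix(receptor_map = c(0, 5, 10))
  expect_equal(diag(Br$B), c(1, 1.5, 2))
  expect_error(build_control_matrix(receptor_map = c(-1, 2)), "nonnegative")
  expect_error(build_control_matrix(receptor_map = c(3, 3, 3)), "constant")
  set.seed(2)
  for (i in 1:20) {
    d <- diag(build_control_matrix(receptor_map = rgamma(50, 2))$B)
    expect_true(all(d >= 1) && all(d <= 2))
    expect_equal(range(d), c(1, 2))
  }
})

test_that("gramian matches scalar closed forms and the Lyapunov limit", {
  expect_equal(controllability_gramian(matrix(-1, 1, 1), 1, T = 1)[1, 1],
               (1 - exp(-2)) / 2, tolerance = 1e-12)
  expect_equal(controllability_gramian(matrix(-1, 1, 1), 0, T = 1)[1, 1], 0)
  expect_equal(controllability_gramian(matrix(-1, 1, 1), 1, T = 50)[1, 1],
               0.5, tolerance = 1e-10)
  sys <- make_random_system(6, seed = 3)
  W <- controllability_gramian(sys$A, sys$B, T = 1)
  expect_equal(W, t(W))
  expect_true(all(eigen(W, symmetric = TRUE)$values > 0))
})

test_that("minimum energy matches the closed form and quadratic scaling", {
  A1 <- matrix(-1, 1, 1)
  expect_equal(min_transition_energy(A1, 1, 0, 0, 1), 0)
  E <- min_transition_energy(A1, 1, 0, 1, 1)
  expect_equal(E, 2 / (1 - exp(-2)), tolerance = 1e-9)
  # scaling B by s divides energy by s^2
  expect_equal(min_transition_energy(A1, 2, 0, 1, 1), E / 4,
               tolerance = 1e-9)
  # doubling the displacement quadruples the energy
  expect_equal(min_transition_energy(A1, 1, 0, 2, 1), 4 * E,
               tolerance = 1e-9)
})

test_that("gramian solver agrees with the discretized least-norm oracle", {
  for (s in 1:5) {
    n <- 4 + s
    sys <- make_random_system(n, seed = s + 10)
    set.seed(s)
    x0 <- rnorm(n); xT <- rnorm(n)
    Eg <- min_transition_energy(sys$A, sys$B, x0, xT, 1)
    Eo <- oracle_discretized_energy(sys$A, sys$B, x0, xT, 1, n_steps = 2000)
    expect_lt(abs(Eo - Eg) / Eg, 0.01)
  }
  expect_equal(oracle_discretized_energy(matrix(-1, 1, 1), 1, 0, 0, 1), 0)
})

test_that("transition energy matrices respect structure and scaling", {
  sys <- make_random_system(12, seed = 20)
  C <- gen_state_centroids(12, 4, seed = 21)
  E <- transition_energy_matrix(sys$A, sys$B, C, T = 1)
  expect_true(all(E >= 0))
  expect_gt(max(abs(E - t(E))), 0)  # generally asymmetric
  expect_equal(transition_energy_matrix(sys$A, sys$B, C * 0.7, T = 1),
               E * 0.49, tolerance = 1e-9)
  expect_equal(unname(transition_energy_matrix(sys$A, sys$B, C * 0, T = 1)),
               matrix(0, 4, 4), ignore_attr = TRUE)
  # missing centroid -> NA entries
  Cm <- C; Cm[2, ] <- NA
  Em <- transition_energy_matrix(sys$A, sys$B, Cm, T = 1)
  expect_true(all(is.na(Em[2, ])) && all(is.na(Em[, 2])))
  expect_true(all(!is.na(Em[-2, -2])))
})

test_that("energies are equivariant under region relabeling", {
  sys <- make_random_system(10, seed = 30)
  C <- gen_state_centroids(10, 2, seed = 31)
  set.seed(32); perm <- sample(10)
  A2 <- sys$A$A_norm[perm, perm]
  B2 <- sys$B[perm, perm]
  E1 <- transition_energy_matrix(sys$A, sys$B, C, T = 1)
  E2 <- transition_energy_matrix(A2, B2, C[, perm], T = 1)
  expect_equal(E1, E2, tolerance = 1e-8)
})

test_that("larger control weights never increase transition energy", {
  for (s in 1:10) {
    n <- 8
    sys <- make_random_system(n, seed = s + 40)
    set.seed(s)
    inc <- runif(n, 0, 1)
    B1 <- diag(1 + numeric(n))
    B2 <- diag(1 + inc)
    C <- matrix(rnorm(2 * n), 2, n)
    E1 <- transition_energy_matrix(sys$A, B1, C, T = 1)
    E2 <- transition_energy_matrix(sys$A, B2, C, T = 1)
    expect_true(all(E2 <= E1 + 1e-12))
  }
})

test_that("energy orderings are stable across time horizons", {
  sys <- make_random_system(15, seed = 50)
  C <- gen_state_centroids(15, 4, seed = 51)
  sw <- te_sensitivity_sweep(sys$A, sys$B, C, horizons = c(0.5, 1, 3, 5))
  # adjacent horizons preserve orderings tightly; distant ones remain
  # positively related (at long T the free decay erases the source term,
  # so orderings drift toward target-dominated, never inverted)
  expect_gt(sw$spearman["T=0.5", "T=1"], 0.9)
  expect_gt(sw$spearman["T=3", "T=5"], 0.9)
  expect_true(all(sw$spearman > 0))
})
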