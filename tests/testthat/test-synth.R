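test_that("connectome generator yields symmetric, connected, modular graphs", {
  A <- gen_connectome(6, n_modules = 1, density = 1.0, seed = 1)
  expect_identical(A, t(A))
  expect_true(all(diag(A) == 0))
  expect_true(all(A[upper.tri(A)] > 0))  # complete at density 1

  A2 <- gen_connectome(50, n_modules = 5, density = 0.2, seed = 2)
  module <- sort(rep_len(1:5, 50))
  same <- outer(module, module, "==") & upper.tri(A2)
  diff <- (!outer(module, module, "==")) & upper.tri(A2)
  expect_gt(mean(A2[same][A2[same] > 0]), mean(A2[diff][A2[diff] > 0]))

  expect_identical(gen_connectome(30, 3, 0.3, seed = 7),
                   gen_connectome(30, 3, 0.3, seed = 7))
})

test_that("planted centroids form zero-mean anti-correlated pairs", {
  C <- gen_state_centroids(20, 4, seed = 3)
  expect_lte(cor(C[1, ], C[2, ]), -0.8)
  expect_lte(cor(C[3, ], C[4, ]), -0.8)
  expect_true(all(abs(rowMeans(C)) < 1e-9))

  C2 <- gen_state_centroids(20, 2, seed = 4)
  expect_lte(cor(C2[1, ], C2[2, ]), -0.8)
  expect_error(gen_state_centroids(20, 3, seed = 5), "even")
})

test_that("markov sequence generator honors the transition matrix", {
  expect_equal(gen_markov_state_sequence(diag(2), 100, seed = 1),
               rep(gen_markov_state_sequence(diag(2), 1, seed = 1), 100))
  P <- matrix(0.5, 2, 2)
  s <- gen_markov_state_sequence(P, 10000, seed = 2)
  emp <- transition_probabilities(s, 2, tr_seconds = 1)
  expect_true(max(abs(emp - 0.5)) < 0.02)
  expect_identical(gen_markov_state_sequence(P, 500, seed = 9),
                   gen_markov_state_sequence(P, 500, seed = 9))
  expect_error(gen_markov_state_sequence(matrix(1, 2, 2), 10), "sum to 1")
})

test_that("synthetic BOLD frames track their generating centroid", {
  fx <- make_planted_scans(n_regions = 30, k = 4, frames = 80, noise_sd = 0)
  X <- fx$scans[[1]]$values
  expect_true(all(abs(colMeans(X)) < 1e-9))
  # noiseless frames equal their centroid up to the per-region demeaning
  expected <- fx$centroids[fx$seqs[[1]], ]
  expected <- sweep(expected, 2L, colMeans(expected))
  r <- sapply(seq_len(nrow(X)), function(t) cor(X[t, ], expected[t, ]))
  expect_true(all(r > 1 - 1e-9))

  fy <- make_planted_scans(n_regions = 100, k = 4, frames = 1000,
                           noise_sd = 0.5, seed = 6)
  Y <- fy$scans[[1]]$values
  R <- cor(t(Y), t(fy$centroids))
  # own-centroid correlation beats all other centroids for >= 95% of frames
  expect_gte(mean(max.col(R) == fy$seqs[[1]]), 0.95)
})

test_that("receptor maps are nonnegative with tunable spatial structure", {
  co <- gen_parcel_coords(100, seed = 1)
  m <- gen_receptor_map(co, autocorr_scale = 0.7, seed = 2)
  expect_true(all(m >= 0))
  expect_gt(morans_i(m, co), 0.1)
  m0 <- gen_receptor_map(co, autocorr_scale = 0, seed = 3)
  expect_lt(abs(morans_i(m0, co)), 0.05)
  expect_identical(gen_receptor_map(co, 0.5, seed = 4),
                   gen_receptor_map(co, 0.5, seed = 4))
})

test_that("parcel coordinates sit on the unit sphere, split by hemisphere", {
  co <- gen_parcel_coords(80, seed = 5)
  xyz <- as.matrix(co[, c("x", "y", "z")])
  expect_true(all(abs(sqrt(rowSums(xyz^2)) - 1) < 1e-9))
  expect_equal(unname(table(co$hemisphere)["left"]), 40,
               ignore_attr = TRUE)
  expect_identical(co, gen_parcel_coords(80, seed = 5))
  expect_error(gen_parcel_coords(7), "even")
})

test_that("two-condition cohorts scale drug amplitude and emit covariates", {
  spec <- synth_cohort_spec(n_subjects = 15, n_regions = 40,
                            frames_per_scan = 40, seed = 8,
                            drug_amplitude_factor = 0.7)
  coh <- gen_two_condition_cohort(spec)
  expect_length(coh$scans, 30)
  expect_equal(nrow(coh$motion), 15)
  # noiseless norms scale exactly by the amplitude factor
  spec0 <- synth_cohort_spec(n_subjects = 2, n_regions = 40, noise_sd = 0,
                             frames_per_scan = 40, seed = 9,
                             drug_amplitude_factor = 0.7)
  coh0 <- gen_two_condition_cohort(spec0)
  # per-frame norms before demeaning equal centroid norms * factor; use
  # planted centroids directly
  n_pl <- sqrt(rowSums(coh0$centroids^2))
  expect_equal(sqrt(rowSums((coh0$centroids * 0.7)^2)), 0.7 * n_pl)
  # drug-condition frames have smaller amplitude in expectation
  spec2 <- synth_cohort_spec(n_subjects = 6, n_regions = 60,
                             frames_per_scan = 80, seed = 10,
                             drug_amplitude_factor = 0.7, noise_sd = 0.2)
  coh2 <- gen_two_condition_cohort(spec2)
  rms <- sapply(coh2$scans, function(s) sqrt(mean(s$values^2)))
  conds <- sapply(coh2$scans, `[[`, "condition")
  expect_lt(mean(rms[conds == "drug"]), mean(rms[conds == "placebo"]))
})
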