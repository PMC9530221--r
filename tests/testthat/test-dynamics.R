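test_that("fractional occupancy counts frames per state", {
  expect_equal(fractional_occupancy(c(1, 1, 2, 2), 2, tr_seconds = 2),
               c(0.5, 0.5))
  expect_equal(fractional_occupancy(rep(2, 10), 3, tr_seconds = 2),
               c(0, 1, 0))
  s <- gen_markov_state_sequence(matrix(0.25, 4, 4), 10000, seed = 1)
  expect_true(all(abs(fractional_occupancy(s, 4, tr_seconds = 2) - 0.25)
                  < 0.02))
  expect_equal(sum(fractional_occupancy(s, 4, tr_seconds = 2)), 1)
})

test_that("dwell times average run lengths within scans, in seconds", {
  # runs of state 1: lengths 3 and 1 -> mean 2 frames x 2 s = 4 s
  expect_equal(dwell_times(c(1, 1, 1, 2, 1), 2, tr_seconds = 2), c(4, 2))
  expect_equal(dwell_times(rep(1, 10), 2, tr_seconds = 2)[1], 20)
  expect_true(is.na(dwell_times(rep(1, 10), 2, tr_seconds = 2)[2]))
  # runs never merge across a scan boundary
  sq <- state_sequence(c(1, 1, 1, 1), tr_seconds = 2,
                       scan_id = rep(c("a", "b"), each = 2))
  expect_equal(dwell_times(sq, 1), 4)
})

test_that("appearance rate counts run starts per minute", {
  lab <- c(1, 1, 2, 1, 2, 2, 1, rep(2, 23))  # 30 frames at TR 2 = 1 min
  expect_equal(appearance_rate(lab, 2, tr_seconds = 2)[1], 3)
  expect_equal(appearance_rate(rep(1, 30), 2, tr_seconds = 2), c(1, 0))
  # switchier chains appear more often
  sticky <- gen_markov_state_sequence(sticky_tm(3, 0.9), 3000, seed = 2)
  switchy <- gen_markov_state_sequence(sticky_tm(3, 0.3), 3000, seed = 2)
  expect_true(all(appearance_rate(switchy, 3, tr_seconds = 2) >
                    appearance_rate(sticky, 3, tr_seconds = 2)))
})

test_that("transition probabilities are within-scan conditional frequencies", {
  P <- transition_probabilities(c(1, 1, 2, 1), 2, tr_seconds = 1)
  expect_equal(P[1, ], c(0.5, 0.5))
  expect_equal(P[2, ], c(1, 0))
  expect_equal(diag(transition_probabilities(rep(2, 5), 3, tr_seconds = 1))[2],
               1)
  # cross-scan pairs are not counted
  sq <- state_sequence(c(1, 1, 2, 2), tr_seconds = 1,
                       scan_id = rep(c("a", "b"), each = 2))
  P2 <- transition_probabilities(sq, 2)
  expect_equal(P2[1, ], c(1, 0))  # the 1->2 jump spans the boundary
  # generating-matrix recovery at 10,000 frames
  gen <- sticky_tm(4, 0.55)
  s <- gen_markov_state_sequence(gen, 10000, seed = 3)
  expect_lt(max(abs(transition_probabilities(s, 4, tr_seconds = 1) - gen)),
            0.02)
})

test_that("dynamics metrics are mutually consistent on a stickiness sweep", {
  stays <- c(0.3, 0.5, 0.7, 0.9)
  res <- sapply(stays, function(st) {
    s <- gen_markov_state_sequence(sticky_tm(4, st), 8000, seed = 4)
    c(dwell = mean(dwell_times(s, 4, tr_seconds = 2)),
      appear = mean(appearance_rate(s, 4, tr_seconds = 2)))
  })
  expect_true(all(diff(res["dwell", ]) > 0))    # stickier -> longer dwell
  expect_true(all(diff(res["appear", ]) < 0))   # stickier -> rarer entries
  # occupancy conservation: sum over states of runs x mean run = frames
  s <- gen_markov_state_sequence(sticky_tm(3, 0.6), 999, seed = 5)
  runs <- rle(s)
  n_runs <- tabulate(runs$values, 3)
  mean_run <- dwell_times(s, 3, tr_seconds = 1)  # TR 1: seconds == frames
  expect_equal(sum(n_runs * mean_run), 999)
})

test_that("meta-state binarization removes only within-pair switches", {
  meta <- c(1L, 1L, 2L, 2L)  # states 1,2 -> meta 0; states 3,4 -> meta 1
  expect_equal(binarize_to_meta_states(c(1, 2, 3, 4), meta), c(0, 0, 1, 1))
  expect_equal(binarize_to_meta_states(c(1, 2, 1, 2), meta), rep(0, 4))
  lab <- c(1, 2, 3, 4, 4, 3, 1, 1, 2)
  b <- binarize_to_meta_states(lab, meta)
  switches_raw <- sum(diff(lab) != 0)
  within_pair <- sum(meta[lab[-length(lab)]] == meta[lab[-1]] &
                       diff(lab) != 0)
  expect_equal(sum(diff(b) != 0), switches_raw - within_pair)
  expect_error(binarize_to_meta_states(c(1, 5), meta), "cover")
})
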