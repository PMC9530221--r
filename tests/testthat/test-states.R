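test_that("adjusted mutual information matches independent reference values", {
  # frozen from scikit-learn's adjusted_mutual_info_score (arithmetic mean)
  expect_equal(ami_score(c(1, 1, 1, 2, 2, 2), c(1, 1, 2, 2, 3, 3)),
               0.2987924581708901, tolerance = 1e-12)
  expect_equal(ami_score(rep(1:3, each = 4),
                         c(1, 1, 1, 2, 2, 2, 2, 3, 3, 3, 3, 1)),
               0.3500664905474484, tolerance = 1e-12)
  expect_equal(ami_score(1:5, 1:5), 1)
  # label-permutation invariance
  a <- rep(1:4, each = 25)
  set.seed(1); b <- sample(1:4, 100, TRUE)
  relab <- c(3L, 1L, 4L, 2L)
  expect_equal(ami_score(a, b), ami_score(relab[a], b), tolerance = 1e-12)
})

test_that("k-means with correlation distance recovers separable planted states", {
  fx <- make_planted_scans(n_regions = 30, k = 4, frames = 120,
                           noise_sd = 0, seed = 2)
  p <- cluster_states(fx$scans, k = 4, n_replicates = 10, seed = 1)
  expect_equal(ami_score(p$labels, fx$seqs[[1]]), 1)
  # determinism
  p2 <- cluster_states(fx$scans, k = 4, n_replicates = 10, seed = 1)
  expect_identical(p$labels, p2$labels)
  expect_equal(p$centroids, p2$centroids)
  # error on k > frames
  expect_error(cluster_states(fx$scans, k = 200), "frames")
  # centroids are plain means of member frames
  X <- fx$scans[[1]]$values
  for (s in 1:4)
    expect_equal(unname(p$centroids[s, ]), unname(colMeans(X[p$labels == s, ])))
})

test_that("variance explained matches a brute-force sum-of-squares oracle", {
  fx <- make_planted_scans(n_regions = 15, k = 2, frames = 150,
                           noise_sd = 0.3, seed = 3)
  p <- cluster_states(fx$scans, k = 2, n_replicates = 5, seed = 4)
  X <- fx$scans[[1]]$values
  # independent oracle: explicit loops over frames
  gm <- colMeans(X)
  ss_tot <- 0; ss_w <- 0
  cent <- rowsum(X, p$labels) / as.vector(table(p$labels))
  for (t in seq_len(nrow(X))) {
    ss_tot <- ss_tot + sum((X[t, ] - gm)^2)
    ss_w <- ss_w + sum((X[t, ] - cent[p$labels[t], ])^2)
  }
  expect_equal(p$variance_explained, 1 - ss_w / ss_tot, tolerance = 1e-10)
  expect_equal(variance_explained(p, fx$scans), 1 - ss_w / ss_tot,
               tolerance = 1e-10)
  # every frame equal to its centroid -> VE = 1
  lab <- rep(1:2, each = 10)
  C <- gen_state_centroids(15, 2, seed = 5)
  scan <- parc_ts(C[lab, ], tr_seconds = 2)
  expect_equal(variance_explained(lab, scan), 1)
  # k = 1 -> 0 (single centroid is the grand mean)
  expect_equal(variance_explained(rep(1, 20), scan), 0)
})

test_that("partition selection picks the AMI consensus member", {
  fx <- make_planted_scans(n_regions = 20, k = 4, frames = 90, seed = 6,
                           noise_sd = 0.2)
  base <- cluster_states(fx$scans, k = 3, n_replicates = 3, seed = 7)
  parts <- rep(list(base), 10)
  sel <- select_partition_by_ami(parts)
  expect_equal(attr(sel, "total_ami")[1], 9, tolerance = 1e-10)
  expect_identical(sel$labels, base$labels)
  # 9 identical + 1 random -> a consensus member wins
  rnd <- base
  set.seed(8); rnd$labels <- sample(1:3, length(base$labels), TRUE)
  parts[[4]] <- rnd
  sel2 <- select_partition_by_ami(parts)
  expect_identical(sel2$labels, base$labels)
  # permutation-invariance: relabeled copy is still consensus
  perm <- base
  perm$labels <- c(2L, 3L, 1L)[base$labels]
  expect_equal(ami_score(perm$labels, base$labels), 1)
  expect_error(select_partition_by_ami(list(base, list(labels = 1:5))),
               "different numbers of frames")
})

test_that("elbow scan flags the planted number of clusters", {
  fx <- make_planted_scans(n_regions = 30, k = 4, frames = 300,
                           noise_sd = 0.4, seed = 9)
  es <- elbow_scan(fx$scans, k_range = 2:6, n_runs = 1, n_replicates = 5,
                   seed = 10)
  ve <- es$table$variance_explained
  expect_true(all(diff(ve) > -0.02))  # nondecreasing up to sampling noise
  gains <- diff(ve)
  expect_lt(gains[3], gains[2])  # 4 -> 5 gains less than 3 -> 4
})

test_that("centroid levels average the right frames and flag missing states", {
  spec <- synth_cohort_spec(n_subjects = 4, n_regions = 30,
                            frames_per_scan = 60, seed = 11,
                            noise_sd = 0.5)
  coh <- gen_two_condition_cohort(spec)
  p <- cluster_states(coh$scans, k = 4, n_replicates = 5, seed = 12)
  grp <- compute_centroids(p, "group")
  expect_equal(unname(grp$centroids), unname(p$centroids), tolerance = 1e-12)
  cond <- compute_centroids(p, "condition")
  expect_setequal(names(cond), c("drug", "placebo"))
  # exchangeable-ish conditions: condition centroids track group centroids
  for (cc in cond)
    expect_true(all(diag(cor(t(cc$centroids), t(grp$centroids))) > 0.95))
  # force a missing state for one subject-condition
  p$labels[p$subject_id == "sub01" & p$condition == "drug"] <- 1L
  sc <- compute_centroids(p, "subject-condition")
  expect_setequal(sc$`sub01.drug`$missing_states, 2:4)
  expect_true(all(is.na(sc$`sub01.drug`$centroids[2, ])))
})

test_that("RSN alignment splits supra/sub parts and matches hand cosines", {
  masks <- cbind(RSNa = c(1, 1, 0, 0, 0, 0), RSNb = c(0, 0, 1, 1, 1, 0))
  cent <- c(2, 1, -1, -2, 0.5, 0)
  al <- rsn_alignment(cent, masks)
  supra <- c(2, 1, 0, 0, 0.5, 0); sub <- c(0, 0, 1, 2, 0, 0)
  expect_equal(al$supra[1], sum(supra * masks[, 1]) /
                 (sqrt(sum(supra^2)) * sqrt(2)))
  expect_equal(al$sub[2], sum(sub * masks[, 2]) /
                 (sqrt(sum(sub^2)) * sqrt(3)))
  # centroid equal to a mask -> supra similarity 1
  expect_equal(rsn_alignment(masks[, 1], masks)$supra[1], 1)
  # positive only outside a mask -> supra similarity 0
  expect_equal(rsn_alignment(c(0, 0, 0, 0, 0, 3), masks)$supra[1], 0)
  # all-zero part -> 0 by convention
  expect_equal(rsn_alignment(c(1, 1, 1, 1, 1, 1), masks)$sub, c(0, 0))
})

test_that("meta-state pairing groups anti-correlated centroids", {
  set.seed(13)
  c1 <- rnorm(40); d1 <- rnorm(40)
  C <- rbind(c1, -c1, d1, -d1)
  pm <- pair_meta_states(C)
  expect_equal(pm$meta_assignment[1], pm$meta_assignment[2])
  expect_equal(pm$meta_assignment[3], pm$meta_assignment[4])
  expect_equal(length(unique(pm$meta_assignment)), 2)
  # k = 2 single pair
  pm2 <- pair_meta_states(C[1:2, ])
  expect_equal(pm2$meta_assignment, c(1L, 1L))
  # planted noisy opposites recovered
  Cn <- gen_state_centroids(50, 4, seed = 14)
  pmn <- pair_meta_states(Cn)
  expect_equal(pmn$meta_assignment[1], pmn$meta_assignment[2])
  # all-positive correlations violate the hierarchy assumption -> warnings
  w <- capture_warnings(pair_meta_states(rbind(c1,
                                               c1 + rnorm(40, sd = 0.2),
                                               c1 + rnorm(40, sd = 0.2),
                                               c1 + rnorm(40, sd = 0.2))))
  expect_true(all(grepl(">= 0", w)) && length(w) == 2)
})

test_that("state matching recovers reference order", {
  C <- gen_state_centroids(40, 4, seed = 15)
  expect_equal(match_states(C, C)$order, 1:4)
  shuf <- c(3L, 1L, 4L, 2L)
  m <- match_states(C[shuf, ], C)
  expect_equal(unname(m$centroids), unname(C))
  # noisy copies still matched
  Cn <- C + matrix(rnorm(160, sd = 0.4), 4, 40)
  mn <- match_states(Cn[shuf, ], C)
  expect_equal(unname(mn$centroids), unname(Cn))
})
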