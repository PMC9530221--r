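#' Drug-vs-placebo transition-energy contrast for one cohort
#'
#' The core two-condition analysis: cluster all scans jointly into `k`
#' states (correlation-distance k-means), form individual
#' subject-by-condition centroids, compute each subject's k x k
#' transition-energy matrix under uniform control inputs on the normalized
#' connectome, and contrast the two conditions entry-wise with paired
#' t-tests (Benjamini-Hochberg within the k^2 family).
#'
#' @param cohort a `synth_cohort` (or any list with `scans` of
#'   [parc_ts()] and two conditions).
#' @param A stable `system_matrix` (or connectome passed through
#'   [normalize_connectome()] first).
#' @param k number of states.
#' @param T energy time horizon.
#' @param n_replicates k-means restarts.
#' @param seed clustering seed.
#' @param condition_a,condition_b condition labels (a contrasted minus b).
#' @return list with `partition`, `te` (named list: subject.condition ->
#'   TE matrix), `diff_mean` (k x k mean of a-minus-b paired differences),
#'   `report` (entry-wise paired test table), `all_lower` (TRUE when every
#'   ordered pair has a lower group-mean energy under `condition_a`).
#' @export
cohort_te_contrast <- function(cohort, A, k = 4, T = 1, n_replicates = 10,
                               seed = 1, condition_a = "drug",
                               condition_b = "placebo") {
  part <- cluster_states(cohort$scans, k = k, n_replicates = n_replicates,
                         seed = seed)
  prep <- energy_prep(A, build_control_matrix(n_regions = ncol(part$centroids)),
                      T)
  sets <- compute_centroids(part, level = "subject-condition")
  te <- lapply(sets, function(s)
    transition_energy_matrix(A, NULL, s, T = T, prep = prep))
  long <- te_long(te)
  rep_ <- group_report(long, condition_a, condition_b)
  diffs <- rep_$mean_a - rep_$mean_b
  list(partition = part, te = te,
       diff_mean = matrix(diffs[order(rep_$unit)], k, k, byrow = TRUE),
       report = rep_,
       all_lower = nrow(rep_) == k * k && all(diffs < 0))
}

# subject.condition TE list -> long metric table for group_report
te_long <- function(te) {
  do.call(rbind, lapply(names(te), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    E <- te[[nm]]
    k <- nrow(E)
    ij <- expand.grid(from = seq_len(k), to = seq_len(k))
    data.frame(subject_id = parts[1], condition = parts[2],
               metric = "transition_energy",
               unit = sprintf("%d->%d", ij$from, ij$to),
               value = E[cbind(ij$from, ij$to)])
  }))
}

#' Per-subject coupling of energy-landscape flattening and entropy
#'
#' For every subject, computes (i) the relative difference of the mean
#' transition energy between conditions, `(drug - placebo)/(drug +
#' placebo)` (negative = flattening), and (ii) the same relative
#' difference of the normalized Lempel-Ziv complexity of the binarized
#' meta-state sequence. Returns their correlation across subjects — plain
#' Pearson and partial, controlling for the subject's mean framewise
#' displacement — between flattening magnitude and entropy increase.
#'
#' @param cohort a `synth_cohort` (needs `motion`).
#' @param A stable `system_matrix`.
#' @param k,T,n_replicates,seed as in [cohort_te_contrast()].
#' @return list with `per_subject` (data.frame subject_id, rel_te,
#'   rel_lz, mean_fd), `pearson`, `partial` (each list r/p), and the
#'   fitted `partition`.
#' @export
te_entropy_coupling <- function(cohort, A, k = 4, T = 1, n_replicates = 10,
                                seed = 1) {
  fit <- cohort_te_contrast(cohort, A, k = k, T = T,
                            n_replicates = n_replicates, seed = seed)
  part <- fit$partition
  pairing <- pair_meta_states(part$centroids)
  seqs <- partition_sequences(part)
  subj <- unique(part$subject_id)
  per <- lapply(subj, function(s) {
    lz <- sapply(c(drug = "drug", placebo = "placebo"), function(cond) {
      sq <- seqs[[which(vapply(seqs, function(x)
        x$subject_id == s && x$condition == cond, TRUE))]]
      normalized_lz(binarize_to_meta_states(sq, pairing$meta_assignment))
    })
    mte <- sapply(c(drug = "drug", placebo = "placebo"), function(cond)
      mean(fit$te[[paste(s, cond, sep = ".")]], na.rm = TRUE))
    data.frame(subject_id = s,
               rel_te = relative_difference(mte[["drug"]], mte[["placebo"]]),
               rel_lz = relative_difference(lz[["drug"]], lz[["placebo"]]))
  })
  per <- do.call(rbind, per)
  per$mean_fd <- cohort$motion$mean_fd[match(per$subject_id,
                                             cohort$motion$subject_id)]
  # flattening magnitude (-rel_te) vs entropy increase (rel_lz)
  pr <- stats::cor.test(-per$rel_te, per$rel_lz)
  pc <- partial_correlation(-per$rel_te, per$rel_lz, per$mean_fd)
  list(per_subject = per,
       pearson = list(r = unname(pr$estimate), p = pr$p.value),
       partial = pc, partition = part)
}

#' Run the full synthetic-cohort pipeline
#'
#' Generates (or loads) a two-condition cohort, extracts brain states,
#' computes temporal dynamics, uniform- and receptor-weighted transition
#' energies with spin-permutation nulls, meta-state entropy, and the group
#' statistical report. All tables are written under `out_dir` with a JSON
#' provenance sidecar carrying seeds and parameters.
#'
#' @param config list with any of: `spec` (a [synth_cohort_spec()]),
#'   `cohort_dir` (read a written cohort instead), `k`, `n_replicates`,
#'   `T`, `n_spins`, `n_modules`, `density`, `autocorr_scale`, `seed`,
#'   `out_dir`.
#' @return invisible list of the main in-memory results.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- utils::modifyList(list(k = 4, n_replicates = 10, T = 1,
                                n_spins = 100, n_modules = 4, density = 0.3,
                                autocorr_scale = 0.5, seed = 1,
                                out_dir = tempfile("ctrlstates_run_")),
                           config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(cfg$cohort_dir)) {
    loaded <- read_cohort(cfg$cohort_dir)
    cohort <- list(scans = loaded$scans, motion = loaded$motion,
                   spec = list(seed = loaded$seed))
  } else {
    spec <- cfg$spec %||% synth_cohort_spec(seed = cfg$seed)
    cohort <- gen_two_condition_cohort(spec)
  }
  n_regions <- ncol(cohort$scans[[1]]$values)
  conn <- gen_connectome(n_regions, n_modules = cfg$n_modules,
                         density = cfg$density, seed = cfg$seed + 1L)
  A <- normalize_connectome(conn)
  coords <- gen_parcel_coords(n_regions, seed = cfg$seed + 2L)
  rmap <- gen_receptor_map(coords, autocorr_scale = cfg$autocorr_scale,
                           seed = cfg$seed + 3L)

  # states + dynamics
  fit <- cohort_te_contrast(cohort, A, k = cfg$k,
                            n_replicates = cfg$n_replicates, T = cfg$T,
                            seed = cfg$seed)
  part <- fit$partition
  pairing <- pair_meta_states(part$centroids)
  seqs <- partition_sequences(part)
  dyn <- do.call(rbind, lapply(seqs, function(sq) {
    ds <- dynamics_summary(sq, cfg$k)
    data.frame(subject_id = sq$subject_id, condition = sq$condition,
               state = seq_len(cfg$k),
               fractional_occupancy = ds$fractional_occupancy,
               dwell_time_seconds = ds$dwell_time_seconds,
               appearance_rate_per_min = ds$appearance_rate_per_min)
  }))
  lz <- do.call(rbind, lapply(seqs, function(sq) data.frame(
    subject_id = sq$subject_id, condition = sq$condition,
    normalized_lz = normalized_lz(
      binarize_to_meta_states(sq, pairing$meta_assignment)))))

  # receptor-weighted energies + spin nulls on group placebo centroids
  placebo_states <- compute_centroids(part, level = "condition")$placebo
  B_rec <- build_control_matrix(receptor_map = rmap)
  te_uniform <- transition_energy_matrix(
    A, build_control_matrix(n_regions = n_regions), placebo_states, cfg$T)
  te_receptor <- transition_energy_matrix(A, B_rec, placebo_states, cfg$T)
  ens <- spin_permutation(rmap, coords, n_spins = cfg$n_spins,
                          seed = cfg$seed + 4L)
  null_tes <- lapply(seq_len(cfg$n_spins), function(s)
    transition_energy_matrix(A,
                             build_control_matrix(receptor_map = ens$maps[, s]),
                             placebo_states, cfg$T))
  pvals <- spin_pvalue(te_receptor, null_tes, direction = "lower")

  # persisted outputs
  utils::write.csv(fit$report, file.path(cfg$out_dir, "te_report.csv"),
                   row.names = FALSE)
  utils::write.csv(dyn, file.path(cfg$out_dir, "dynamics.csv"),
                   row.names = FALSE)
  utils::write.csv(lz, file.path(cfg$out_dir, "entropy.csv"),
                   row.names = FALSE)
  write_matrix_tsv(part$centroids, file.path(cfg$out_dir, "centroids.tsv"),
                   rownames = TRUE)
  utils::write.csv(data.frame(pair = sprintf("%d->%d",
                                             row(pvals), col(pvals)),
                              te_receptor = as.vector(te_receptor),
                              te_uniform = as.vector(te_uniform),
                              spin_p = as.vector(pvals)),
                   file.path(cfg$out_dir, "receptor_spin.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(seed = cfg$seed, k = cfg$k, T = cfg$T, n_spins = cfg$n_spins,
         n_replicates = cfg$n_replicates,
         lambda_max = A$lambda_max,
         gramian_rcond_uniform =
           energy_prep(A, build_control_matrix(n_regions = n_regions),
                       cfg$T)$rcond),
    file.path(cfg$out_dir, "provenance.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(list(partition = part, te_contrast = fit, dynamics = dyn,
                 entropy = lz, te_uniform = te_uniform,
                 te_receptor = te_receptor, spin_p = pvals,
                 pairing = pairing, out_dir = cfg$out_dir))
}
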