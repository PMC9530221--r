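# Shared fixture builders; everything generated in code, no stored data.

# small scan drawn noiselessly (or noisily) from planted centroids
make_planted_scans <- function(n_regions = 20, k = 4, frames = 60,
                               noise_sd = 0, n_scans = 1, seed = 1,
                               stay = 0.6) {
  C <- gen_state_centroids(n_regions, k, seed = seed)
  P <- sticky_tm(k, stay)
  scans <- list()
  seqs <- list()
  for (i in seq_len(n_scans)) {
    s <- gen_markov_state_sequence(P, frames, seed = seed + i)
    scans[[i]] <- gen_bold_timeseries(C, s, noise_sd, seed = seed + 100 + i,
                                      scan_id = paste0("scan", i),
                                      subject_id = paste0("sub", i))
    seqs[[i]] <- s
  }
  list(scans = scans, seqs = seqs, centroids = C)
}

# small stable symmetric system + diagonal B
make_random_system <- function(n, seed) {
  A <- normalize_connectome(gen_connectome(n, 1, 1, seed = seed))
  set.seed(seed + 1000)
  B <- diag(stats::runif(n, 0.5, 2))
  list(A = A, B = B)
}
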