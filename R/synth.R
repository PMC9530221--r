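#' Parcellated time-series container
#'
#' Bundles a demeaned frames x regions BOLD matrix with its repetition time
#' and scan identity. All downstream clustering and dynamics functions
#' consume this container.
#'
#' @param values numeric matrix, frames x regions; each column is demeaned.
#' @param tr_seconds repetition time in seconds (> 0).
#' @param subject_id,condition,scan_id identifiers.
#' @return An object of class `parc_ts`.
#' @export
parc_ts <- function(values, tr_seconds, subject_id = "s1",
                    condition = "A", scan_id = "scan1") {
  values <- as.matrix(values)
  stopifnot(is.numeric(values), nrow(values) >= 2, tr_seconds > 0)
  if (anyNA(values)) stop("time series contains missing values")
  values <- sweep(values, 2L, colMeans(values))
  rownames(values) <- NULL
  structure(list(values = values, tr_seconds = tr_seconds,
                 subject_id = subject_id, condition = condition,
                 scan_id = scan_id),
            class = "parc_ts")
}

#' @export
print.parc_ts <- function(x, ...) {
  cat(sprintf("<parc_ts> %s/%s/%s: %d frames x %d regions, TR = %g s\n",
              x$subject_id, x$condition, x$scan_id,
              nrow(x$values), ncol(x$values), x$tr_seconds))
  invisible(x)
}

#' Generate a modular weighted structural connectome
#'
#' Draws a symmetric, nonnegative, zero-diagonal, connected weight matrix.
#' Edges are present independently with probability `density`; weights are
#' log-normal (heavy-tailed, like streamline counts), with a higher
#' log-mean for within-module edges so that community structure is present
#' when `n_modules > 1`. Disconnected draws are regenerated up to
#' `max_tries` times.
#'
#' @param n_regions number of regions (>= 2).
#' @param n_modules number of modules (communities); 1 disables structure.
#' @param density edge probability in (0, 1].
#' @param seed integer RNG seed.
#' @param max_tries retries for a connected draw before failing.
#' @return `n_regions` x `n_regions` numeric matrix with region names
#'   `r001`, `r002`, ...
#' @export
gen_connectome <- function(n_regions, n_modules = 1, density = 1.0,
                           seed = 1, max_tries = 100L) {
  stopifnot(n_regions >= 2, density > 0, density <= 1, n_modules >= 1)
  set.seed(seed)
  module <- sort(rep_len(seq_len(n_modules), n_regions))
  for (try in seq_len(max_tries)) {
    A <- matrix(0, n_regions, n_regions)
    idx <- which(upper.tri(A))
    present <- stats::runif(length(idx)) <= density
    same_mod <- outer(module, module, "==")[upper.tri(A)]
    mu <- ifelse(same_mod & n_modules > 1, 1.0, 0.0)
    w <- stats::rlnorm(length(idx), meanlog = mu, sdlog = 0.75)
    A[idx] <- ifelse(present, w, 0)
    A <- A + t(A)
    if (is_connected(A)) {
      dimnames(A) <- list(region_ids(n_regions), region_ids(n_regions))
      return(A)
    }
  }
  stop("failed to draw a connected connectome in ", max_tries, " tries")
}

region_ids <- function(n) sprintf("r%03d", seq_len(n))

# breadth-first reachability on the binary skeleton
is_connected <- function(A) {
  n <- nrow(A)
  seen <- logical(n)
  frontier <- 1L
  seen[1L] <- TRUE
  while (length(frontier)) {
    nb <- which(colSums(A[frontier, , drop = FALSE] > 0) > 0)
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
  }
  all(seen)
}

#' Generate planted brain-state centroids in anti-correlated pairs
#'
#' Produces `k` zero-mean activation patterns over `n_regions` regions,
#' arranged as k/2 meta-state pairs: each even-indexed centroid is a
#' sign-flipped, slightly attenuated and perturbed copy of its predecessor,
#' so within-pair Pearson correlation is <= -0.8 while cross-pair patterns
#' are approximately orthogonal.
#'
#' @param n_regions regions per centroid.
#' @param k number of states; must be even.
#' @param seed integer RNG seed.
#' @return k x n_regions matrix with rows `state1..statek`.
#' @export
gen_state_centroids <- function(n_regions, k, seed = 1) {
  if (k %% 2 != 0)
    stop("k must be even: centroids are generated as anti-correlated pairs")
  set.seed(seed)
  C <- matrix(0, k, n_regions)
  for (p in seq_len(k / 2)) {
    base <- stats::rnorm(n_regions)
    partner <- -0.9 * base + stats::rnorm(n_regions, sd = 0.1)
    C[2L * p - 1L, ] <- base - mean(base)
    C[2L * p, ] <- partner - mean(partner)
  }
  dimnames(C) <- list(paste0("state", seq_len(k)), region_ids(n_regions))
  C
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left eigenvector of `P` for eigenvalue 1, normalized to sum to one.
#' @param P row-stochastic k x k matrix.
#' @return length-k probability vector.
#' @export
stationary_distribution <- function(P) {
  check_stochastic(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

check_stochastic <- function(P) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P)) stop("transition matrix must be square")
  if (any(P < 0)) stop("transition probabilities must be nonnegative")
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1")
  invisible(P)
}

#' Generate a Markov state sequence
#'
#' Simulates `n_frames` states from a row-stochastic transition matrix.
#' The first label is drawn from the stationary distribution, removing
#' burn-in.
#'
#' @param transition_matrix k x k row-stochastic matrix.
#' @param n_frames sequence length (>= 1).
#' @param seed integer RNG seed.
#' @return integer vector of labels in `1..k`.
#' @export
gen_markov_state_sequence <- function(transition_matrix, n_frames, seed = 1) {
  P <- check_stochastic(transition_matrix)
  stopifnot(n_frames >= 1)
  k <- nrow(P)
  set.seed(seed)
  pi0 <- stationary_distribution(P)
  cumP <- t(apply(P, 1L, cumsum))
  u <- stats::runif(n_frames)
  s <- integer(n_frames)
  s[1L] <- findInterval(u[1L], cumsum(pi0), left.open = TRUE) + 1L
  if (n_frames > 1L) {
    for (t in 2:n_frames)
      s[t] <- findInterval(u[t], cumP[s[t - 1L], ], left.open = TRUE) + 1L
  }
  s
}

#' Generate noisy BOLD frames from planted centroids
#'
#' Frame t equals the centroid of its state label plus i.i.d. Gaussian
#' noise (optionally AR(1) in time per region); every regional series is
#' then demeaned, as in standard preprocessing of parcellated BOLD.
#'
#' @param centroids k x regions matrix.
#' @param sequence integer labels in `1..k`, one per frame.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed integer RNG seed.
#' @param tr_seconds repetition time for the returned scan.
#' @param ar1 AR(1) coefficient in [0, 1) for temporally correlated noise;
#'   0 (default) gives white noise.
#' @param ... identity fields passed to [parc_ts()].
#' @return a [parc_ts()] object.
#' @export
gen_bold_timeseries <- function(centroids, sequence, noise_sd, seed = 1,
                                tr_seconds = 2, ar1 = 0, ...) {
  centroids <- as.matrix(centroids)
  if (any(sequence < 1 | sequence > nrow(centroids)))
    stop("sequence labels must index centroid rows")
  stopifnot(noise_sd >= 0, ar1 >= 0, ar1 < 1)
  set.seed(seed)
  n <- length(sequence)
  p <- ncol(centroids)
  eps <- matrix(stats::rnorm(n * p, sd = noise_sd), n, p)
  if (ar1 > 0 && n > 1) {
    innov_sd <- sqrt(1 - ar1^2)  # keep marginal sd = noise_sd
    for (t in 2:n) eps[t, ] <- ar1 * eps[t - 1L, ] + innov_sd * eps[t, ]
  }
  X <- centroids[sequence, , drop = FALSE] + eps
  colnames(X) <- colnames(centroids)
  parc_ts(X, tr_seconds = tr_seconds, ...)
}

#' Generate unit-sphere parcel coordinates split across hemispheres
#'
#' Samples `n_regions / 2` points on the left (x < 0) half of the unit
#' sphere and mirrors them across the sagittal plane to form homotopic
#' right-hemisphere parcels, emulating a bilateral atlas for spin tests.
#'
#' @param n_regions even number of regions.
#' @param seed integer RNG seed.
#' @return data.frame with columns `region_id`, `hemisphere`, `x`, `y`, `z`.
#' @export
gen_parcel_coords <- function(n_regions, seed = 1) {
  if (n_regions %% 2 != 0) stop("n_regions must be even (two hemispheres)")
  set.seed(seed)
  m <- n_regions / 2
  pts <- matrix(stats::rnorm(3 * m), m, 3)
  pts <- pts / sqrt(rowSums(pts^2))
  pts[, 1] <- -abs(pts[, 1])
  right <- pts
  right[, 1] <- -right[, 1]
  out <- data.frame(
    region_id = region_ids(n_regions),
    hemisphere = rep(c("left", "right"), each = m),
    rbind(pts, right)
  )
  names(out)[3:5] <- c("x", "y", "z")
  out
}

#' Generate a spatially autocorrelated nonnegative receptor density map
#'
#' Draws a Gaussian process on the sphere with covariance
#' `exp(-d_gc / autocorr_scale)` (great-circle distance `d_gc`) and
#' exponentiates it, yielding log-normal densities whose similarity decays
#' with distance. `autocorr_scale -> 0` gives approximately i.i.d. values.
#'
#' @param coords data.frame from [gen_parcel_coords()].
#' @param autocorr_scale correlation length in radians (>= 0).
#' @param seed integer RNG seed.
#' @return named nonnegative numeric vector, one density per region.
#' @export
gen_receptor_map <- function(coords, autocorr_scale = 0.5, seed = 1) {
  stopifnot(autocorr_scale >= 0)
  set.seed(seed)
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  n <- nrow(xyz)
  if (autocorr_scale < 1e-8) {
    z <- stats::rnorm(n)
  } else {
    d <- great_circle_dist(xyz)
    K <- exp(-d / autocorr_scale) + diag(1e-8, n)
    z <- drop(t(chol(K)) %*% stats::rnorm(n))
  }
  stats::setNames(exp(z), coords$region_id)
}

great_circle_dist <- function(xyz) {
  g <- tcrossprod(xyz)
  g[g > 1] <- 1
  g[g < -1] <- -1
  acos(g)
}

#' Moran's I spatial autocorrelation on spherical parcels
#'
#' Weighted spatial autocorrelation with weights
#' `exp(-d_gc / scale)` (zero diagonal); ~0 for spatially unstructured
#' maps, positive for smooth maps.
#'
#' @param values per-region numeric vector.
#' @param coords data.frame from [gen_parcel_coords()].
#' @param scale weight decay length in radians.
#' @return scalar Moran's I.
#' @export
morans_i <- function(values, coords, scale = 0.5) {
  xyz <- as.matrix(coords[, c("x", "y", "z")])
  n <- length(values)
  stopifnot(n == nrow(xyz))
  W <- exp(-great_circle_dist(xyz) / scale)
  diag(W) <- 0
  z <- values - mean(values)
  (n / sum(W)) * sum(W * outer(z, z)) / sum(z^2)
}

#' Generate binary resting-state-network membership masks
#'
#' Partitions regions into `n_networks` contiguous blocks and returns a
#' binary membership matrix, a minimal stand-in for a priori RSN labels.
#'
#' @param n_regions number of regions.
#' @param n_networks number of networks.
#' @param seed seed used to shuffle the assignment.
#' @return regions x networks binary matrix.
#' @export
gen_rsn_masks <- function(n_regions, n_networks = 7, seed = 1) {
  stopifnot(n_networks >= 1, n_networks <= n_regions)
  set.seed(seed)
  assign <- sample(rep_len(seq_len(n_networks), n_regions))
  M <- matrix(0L, n_regions, n_networks,
              dimnames = list(region_ids(n_regions),
                              paste0("RSN", seq_len(n_networks))))
  M[cbind(seq_len(n_regions), assign)] <- 1L
  M
}

#' Specification of a synthetic two-condition cohort
#'
#' Collects the study-design parameters for [gen_two_condition_cohort()].
#' Defaults emulate a pharmacological crossover design: 15 subjects scanned
#' under placebo and under a drug whose states are amplitude-attenuated,
#' with sticky 4-state Markov switching.
#'
#' @param n_subjects,n_regions,k_states,frames_per_scan design sizes.
#' @param tr_seconds repetition time in seconds.
#' @param noise_sd within-state Gaussian noise sd (1.0 gives frame-centroid
#'   correlation near 0.7 for unit-variance centroids).
#' @param drug_amplitude_factor scalar in (0, 1], or vector of length
#'   `n_subjects`, scaling drug-condition centroids.
#' @param transition_matrix_placebo,transition_matrix_drug row-stochastic
#'   k x k matrices (defaults: stay-probability 0.7, uniform elsewhere).
#' @param drug_switch_boost per-subject weight in [0, 1] mixing the drug
#'   transition matrix toward uniform switching (0 = none).
#' @param motion_covariate_sd sd of the per-subject mean framewise
#'   displacement covariate.
#' @param seed integer master seed.
#' @return list of class `synth_cohort_spec`.
#' @export
synth_cohort_spec <- function(n_subjects = 15, n_regions = 200, k_states = 4,
                              frames_per_scan = 150, tr_seconds = 2,
                              noise_sd = 1.0, drug_amplitude_factor = 1.0,
                              transition_matrix_placebo = sticky_tm(k_states),
                              transition_matrix_drug = sticky_tm(k_states),
                              drug_switch_boost = 0,
                              motion_covariate_sd = 0.05, seed = 1) {
  if (k_states %% 2 != 0) stop("k_states must be even (meta-state pairs)")
  check_stochastic(transition_matrix_placebo)
  check_stochastic(transition_matrix_drug)
  stopifnot(all(drug_amplitude_factor > 0), all(drug_amplitude_factor <= 1),
            all(drug_switch_boost >= 0), all(drug_switch_boost <= 1),
            noise_sd >= 0, motion_covariate_sd >= 0)
  structure(list(n_subjects = n_subjects, n_regions = n_regions,
                 k_states = k_states, frames_per_scan = frames_per_scan,
                 tr_seconds = tr_seconds, noise_sd = noise_sd,
                 drug_amplitude_factor = drug_amplitude_factor,
                 transition_matrix_placebo = transition_matrix_placebo,
                 transition_matrix_drug = transition_matrix_drug,
                 drug_switch_boost = drug_switch_boost,
                 motion_covariate_sd = motion_covariate_sd, seed = seed),
            class = "synth_cohort_spec")
}

#' Sticky transition matrix with uniform off-diagonal mass
#' @param k number of states.
#' @param stay diagonal (persistence) probability.
#' @return k x k row-stochastic matrix.
#' @export
sticky_tm <- function(k, stay = 0.7) {
  P <- matrix((1 - stay) / (k - 1), k, k)
  diag(P) <- stay
  P
}

#' Generate a two-condition synthetic cohort
#'
#' Each subject contributes one placebo and one drug scan. Placebo frames
#' come from the planted centroids driven by the placebo transition matrix;
#' drug frames come from centroids scaled by the subject's amplitude factor
#' and a transition matrix optionally mixed toward uniform switching
#' (`drug_switch_boost`), emulating a flattened energy landscape with more
#' diverse dynamics. A per-subject motion covariate (mean framewise
#' displacement), independent of all signals, is emitted for
#' partial-correlation controls.
#'
#' @param spec a [synth_cohort_spec()].
#' @return list of class `synth_cohort` with elements `scans` (list of
#'   [parc_ts()]), `sequences` (planted label vectors, named as the scans),
#'   `centroids` (planted k x regions), `motion` (data.frame subject_id,
#'   mean_fd), `amplitude` (per-subject factors), and `spec`.
#' @export
gen_two_condition_cohort <- function(spec) {
  stopifnot(inherits(spec, "synth_cohort_spec"))
  k <- spec$k_states
  amp <- rep_len(spec$drug_amplitude_factor, spec$n_subjects)
  boost <- rep_len(spec$drug_switch_boost, spec$n_subjects)
  C <- gen_state_centroids(spec$n_regions, k, seed = spec$seed)
  U <- matrix(1 / k, k, k)
  scans <- list()
  seqs <- list()
  sub_seed <- spec$seed
  for (i in seq_len(spec$n_subjects)) {
    sid <- sprintf("sub%02d", i)
    for (cond in c("placebo", "drug")) {
      sub_seed <- sub_seed + 1L
      if (cond == "placebo") {
        P <- spec$transition_matrix_placebo
        Ci <- C
      } else {
        P <- (1 - boost[i]) * spec$transition_matrix_drug + boost[i] * U
        Ci <- C * amp[i]
      }
      s <- gen_markov_state_sequence(P, spec$frames_per_scan, seed = sub_seed)
      scan <- gen_bold_timeseries(Ci, s, spec$noise_sd, seed = sub_seed + 100000L,
                                  tr_seconds = spec$tr_seconds,
                                  subject_id = sid, condition = cond,
                                  scan_id = paste0(sid, "_", cond))
      scans[[scan$scan_id]] <- scan
      seqs[[scan$scan_id]] <- s
    }
  }
  set.seed(spec$seed + 999983L)
  motion <- data.frame(
    subject_id = sprintf("sub%02d", seq_len(spec$n_subjects)),
    mean_fd = abs(stats::rnorm(spec$n_subjects, mean = 0.15,
                               sd = spec$motion_covariate_sd))
  )
  structure(list(scans = scans, sequences = seqs, centroids = C,
                 motion = motion, amplitude = amp, spec = spec),
            class = "synth_cohort")
}

#' Cohort spec with coupled amplitude and switching effects
#'
#' Draws per-subject drug amplitude factors `a_i ~ U(0.5, 0.95)` and sets
#' each subject's switch boost to `1 - a_i`, so subjects with stronger
#' energy-landscape flattening also switch meta-states more, producing
#' coupled transition-energy reduction and entropy increase.
#'
#' @param seed master seed.
#' @param ... overrides passed to [synth_cohort_spec()].
#' @return a `synth_cohort_spec`.
#' @export
coupled_cohort_spec <- function(seed = 1, ...) {
  spec <- synth_cohort_spec(seed = seed, ...)
  set.seed(seed + 424243L)
  a <- stats::runif(spec$n_subjects, 0.5, 0.95)
  spec$drug_amplitude_factor <- a
  spec$drug_switch_boost <- 1 - a
  spec
}
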