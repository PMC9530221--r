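#' State-sequence container
#'
#' Integer state labels with scan boundaries; runs and transitions are
#' computed within scans only (scans are temporally disjoint).
#'
#' @param labels integer labels in `1..k`.
#' @param tr_seconds repetition time in seconds.
#' @param scan_id per-frame scan identity (single string recycled, or a
#'   vector of length `length(labels)`).
#' @param subject_id,condition identifiers.
#' @return object of class `state_sequence`.
#' @export
state_sequence <- function(labels, tr_seconds, scan_id = "scan1",
                           subject_id = "s1", condition = "A") {
  labels <- as.integer(labels)
  stopifnot(length(labels) >= 1, all(labels >= 1), tr_seconds > 0)
  scan_id <- rep_len(scan_id, length(labels))
  structure(list(labels = labels, tr_seconds = tr_seconds, scan_id = scan_id,
                 subject_id = subject_id, condition = condition),
            class = "state_sequence")
}

as_state_sequence <- function(seq, tr_seconds = 2, ...) {
  if (inherits(seq, "state_sequence")) seq else
    state_sequence(seq, tr_seconds = tr_seconds, ...)
}

# run-length encodings per scan, in scan order of first appearance
scan_runs <- function(seq) {
  lapply(split(seq$labels, factor(seq$scan_id, unique(seq$scan_id))), rle)
}

#' Fractional occupancy of each state
#'
#' Number of frames assigned to each state divided by the total number of
#' frames; sums to one, with zeros for absent states.
#'
#' @param seq a [state_sequence()] (or plain integer labels).
#' @param k number of states.
#' @param ... passed to the `state_sequence` coercion for plain labels.
#' @return length-k vector in [0, 1].
#' @export
fractional_occupancy <- function(seq, k, ...) {
  seq <- as_state_sequence(seq, ...)
  tabulate(seq$labels, nbins = k) / length(seq$labels)
}

#' Mean dwell time of each state, in seconds
#'
#' Average contiguous run length (runs never cross scan boundaries)
#' multiplied by the TR. States never visited are `NA` (missing, not 0):
#' an unobserved dwell time is not data.
#'
#' @inheritParams fractional_occupancy
#' @return length-k vector of seconds, `NA` for unvisited states.
#' @export
dwell_times <- function(seq, k, ...) {
  seq <- as_state_sequence(seq, ...)
  runs <- scan_runs(seq)
  st <- unlist(lapply(runs, `[[`, "values"))
  len <- unlist(lapply(runs, `[[`, "lengths"))
  out <- rep(NA_real_, k)
  agg <- tapply(len, factor(st, levels = seq_len(k)), mean)
  out[!is.na(agg)] <- agg[!is.na(agg)] * seq$tr_seconds
  out
}

#' Appearance rate of each state, per minute
#'
#' Number of run starts of each state divided by the total duration in
#' minutes. A run at the start of a scan counts as an appearance
#' (transitioned into at t = 0); the convention is applied uniformly to
#' all scans and conditions so paired contrasts are unbiased.
#'
#' @inheritParams fractional_occupancy
#' @return length-k vector of appearances per minute.
#' @export
appearance_rate <- function(seq, k, ...) {
  seq <- as_state_sequence(seq, ...)
  runs <- scan_runs(seq)
  st <- unlist(lapply(runs, `[[`, "values"))
  minutes <- length(seq$labels) * seq$tr_seconds / 60
  tabulate(st, nbins = k) / minutes
}

#' Empirical state transition probability matrix
#'
#' Row i gives the probability that state i is followed by state j,
#' counting consecutive frame pairs within scans only. The diagonal is the
#' persistence probability. Rows with zero outgoing observations are
#' reported as `NA` (missing).
#'
#' @inheritParams fractional_occupancy
#' @return k x k matrix; rows with observations sum to 1.
#' @export
transition_probabilities <- function(seq, k, ...) {
  seq <- as_state_sequence(seq, ...)
  counts <- matrix(0, k, k)
  for (lab in split(seq$labels, factor(seq$scan_id, unique(seq$scan_id)))) {
    if (length(lab) < 2) next
    from <- lab[-length(lab)]
    to <- lab[-1]
    for (i in seq_along(from))
      counts[from[i], to[i]] <- counts[from[i], to[i]] + 1
  }
  rs <- rowSums(counts)
  P <- counts / rs
  P[rs == 0, ] <- NA_real_
  P
}

#' Binarize a sub-state sequence to its meta-state sequence
#'
#' Maps each frame's sub-state to its meta-state and returns a 0/1 series
#' (meta-state 1 -> 0, meta-state 2 -> 1), the input to Lempel-Ziv
#' complexity. Only within-pair switches are removed by this reduction.
#'
#' @param seq a [state_sequence()] or integer labels.
#' @param meta_assignment integer vector: meta-state index (1 or 2) per
#'   sub-state, e.g. from [pair_meta_states()].
#' @return integer 0/1 vector.
#' @export
binarize_to_meta_states <- function(seq, meta_assignment) {
  labels <- if (inherits(seq, "state_sequence")) seq$labels else as.integer(seq)
  if (any(labels > length(meta_assignment)) || anyNA(meta_assignment[labels]))
    stop("meta_assignment does not cover all labels")
  if (length(unique(meta_assignment)) != 2)
    stop("binarization requires exactly two meta-states")
  as.integer(meta_assignment[labels] == max(meta_assignment))
}

#' Summarize the temporal dynamics of one state sequence
#'
#' @inheritParams fractional_occupancy
#' @return list of class `dynamics_summary` with `fractional_occupancy`,
#'   `dwell_time_seconds`, `appearance_rate_per_min`,
#'   `transition_probabilities`.
#' @export
dynamics_summary <- function(seq, k, ...) {
  seq <- as_state_sequence(seq, ...)
  structure(list(
    fractional_occupancy = fractional_occupancy(seq, k),
    dwell_time_seconds = dwell_times(seq, k),
    appearance_rate_per_min = appearance_rate(seq, k),
    transition_probabilities = transition_probabilities(seq, k),
    subject_id = seq$subject_id, condition = seq$condition, k = k,
    tr_seconds = seq$tr_seconds
  ), class = "dynamics_summary")
}

#' Split a fitted partition into per-scan state sequences
#'
#' @param partition a `state_partition` from [cluster_states()].
#' @return named list of [state_sequence()] objects, one per scan.
#' @export
partition_sequences <- function(partition) {
  stopifnot(inherits(partition, "state_partition"))
  idx <- split(seq_along(partition$labels),
               factor(partition$scan_id, unique(partition$scan_id)))
  lapply(idx, function(i)
    state_sequence(partition$labels[i], partition$tr_seconds,
                   scan_id = partition$scan_id[i][1],
                   subject_id = partition$subject_id[i][1],
                   condition = partition$condition[i][1]))
}
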