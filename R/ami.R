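#' Adjusted mutual information between two labelings
#'
#' Mutual information corrected for chance agreement under the
#' permutation (hypergeometric) model, normalized by the arithmetic mean
#' of the two label entropies:
#' `AMI = (MI - E[MI]) / (mean(H(U), H(V)) - E[MI])`.
#' Invariant to relabeling; 1 for identical partitions, ~0 for independent
#' ones. Natural logarithms are used throughout (the ratio is base-free).
#'
#' @param a,b integer or factor label vectors of equal length.
#' @return scalar AMI.
#' @export
ami_score <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  ct <- table(a, b)
  N <- sum(ct)
  ai <- rowSums(ct)
  bj <- colSums(ct)
  Ha <- entropy_nats(ai / N)
  Hb <- entropy_nats(bj / N)
  if (Ha == 0 && Hb == 0) return(1)
  nz <- ct > 0
  expected <- outer(ai, bj) / N
  mi <- sum((ct[nz] / N) * log(ct[nz] / expected[nz]))
  emi <- expected_mi(ai, bj, N)
  denom <- (Ha + Hb) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  (mi - emi) / denom
}

entropy_nats <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# E[MI] under random permutations of one labeling: sum over cells of the
# hypergeometric expectation (Vinh, Epps & Bailey 2010).
expected_mi <- function(ai, bj, N) {
  emi <- 0
  lgN <- lgamma(N + 1)
  for (a in ai) {
    for (b in bj) {
      lo <- max(1, a + b - N)
      hi <- min(a, b)
      if (hi < lo) next
      nij <- lo:hi
      lp <- lgamma(a + 1) + lgamma(b + 1) + lgamma(N - a + 1) +
        lgamma(N - b + 1) - lgN - lgamma(nij + 1) - lgamma(a - nij + 1) -
        lgamma(b - nij + 1) - lgamma(N - a - b + nij + 1)
      emi <- emi + sum((nij / N) * log(nij * N / (a * b)) * exp(lp))
    }
  }
  emi
}
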