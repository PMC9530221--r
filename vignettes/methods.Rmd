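---
title: "Brain-state dynamics and network control energy: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-state dynamics and network control energy: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctrlstates)
```

## Overview

`ctrlstates` implements a pharmacological network-neuroscience analysis
pipeline: recurrent whole-brain activation patterns ("brain states") are
extracted from parcellated BOLD time series by k-means clustering, their
temporal dynamics are summarized, and the minimum control energy needed to
move the brain between states is computed on a structural connectome under
a linear dynamical model. Control inputs can be weighted by a regional
receptor density map, and the spatial specificity of any such map is
assessed with spin-permutation null models. Finally, the entropy of the
binarized state sequence (normalized Lempel-Ziv complexity) is related to
per-subject changes of the energy landscape.

The package validates this pipeline entirely on synthetic cohorts whose
generating process is known, so every step has a recoverable ground truth.

## The dynamical model and minimum control energy

Regional activity is modeled as a linear time-invariant system on the
structural connectome,

$$\dot{x}(t) = A\,x(t) + B\,u(t),$$

where $x(t)$ is the length-$N$ vector of regional activity, $A$ is the
normalized structural connectome, $B$ is a diagonal matrix of control
input weights, and $u(t)$ is the external input. The raw connectome $W$
(symmetric, nonnegative, zero diagonal) is normalized as

$$A = \frac{W}{\lambda_{\max}(W) + 1} - I,$$

which places all eigenvalues of $A$ strictly below zero, so the free
dynamics decay and finite-horizon controllability Gramians exist. This is
the convention of the linear network-control literature; the constant 1
in the denominator sets the decay scale and is recorded in the
`system_matrix` provenance so alternatives can be compared.

The minimum-energy input that drives the system from state $x_0$ to state
$x_T$ in time $T$ has cost

$$E = v^\top W_c(T)^{-1} v, \qquad
  v = x_T - e^{AT} x_0, \qquad
  W_c(T) = \int_0^T e^{At} B B^\top e^{A^\top t}\, dt.$$

`controllability_gramian()` evaluates $W_c(T)$ in closed form with the
Van Loan block-exponential identity (no quadrature): if
$F = \exp\!\big(\begin{smallmatrix}-A & BB^\top\\ 0 & A^\top\end{smallmatrix}\big)T$,
then $W_c(T) = F_{22}^\top F_{12}$. Inversion uses a symmetric
positive-definite Cholesky factorization; the reciprocal condition number
is attached to every `energy_prep` object and a numerically singular
Gramian is an error, never a silent pseudo-inverse.

`oracle_discretized_energy()` is an independent brute-force validator: it
discretizes the dynamics exactly on `n_steps` zero-order-hold intervals
and solves the least-norm reachability problem. The Gramian solver and
the oracle agree to well below 1% relative error at `n_steps = 2000`; the
scalar system $\dot x = -x + u$ has the closed form
$E = 2/(1 - e^{-2}) \approx 2.3130$ for $x_0 = 0 \to x_T = 1$, $T = 1$,
which the solver reproduces to machine precision.

**Control weighting.** Uniform inputs use $B = I$. Receptor-weighted
inputs set $B_{ii} = 1 + \tilde r_i$ where $\tilde r$ is the min–max
normalization of the regional receptor density to $[0, 1]$, so diagonals
lie in $[1, 2]$: both endpoints are attained, and no region loses the
unit baseline input. Min–max (rather than division by the maximum) is
used because it is the simplest normalization that achieves both printed
endpoints regardless of the map's minimum. Because
$B_2 B_2^\top \succeq B_1 B_1^\top$ implies
$W_{c,2} \succeq W_{c,1}$ and therefore
$v^\top W_{c,2}^{-1} v \le v^\top W_{c,1}^{-1} v$, adding control weight
can never increase any transition energy; this monotonicity is enforced
as an exact (not statistical) test.

**Time horizon.** The default is $T = 1$ in normalized time units. The
appropriate horizon for any given application is not identifiable from
the data alone, so `te_sensitivity_sweep()` recomputes the energy
landscape across a horizon grid and reports Spearman correlations of the
vectorized energies. Adjacent horizons preserve orderings almost
perfectly; very long horizons drift toward target-dominated orderings
(the $e^{AT} x_0$ term vanishes), which is expected behavior of the
model, not a numerical artifact.

## Brain-state extraction

`cluster_states()` concatenates all scans in time and runs Lloyd's
algorithm with distance $1 - r$ (Pearson correlation between a frame and
a centroid across regions). Defaults follow the standard design of this
analysis family: 50 random restarts per run, 10 independent runs, and
selection of the run sharing the greatest *summed* adjusted mutual
information (AMI) with all other runs (`select_partition_by_ami()`). AMI
is computed exactly under the permutation model (hypergeometric expected
mutual information, arithmetic-mean normalization) and was verified to
machine precision against an independent reference implementation.

Numerical choices that the classical description leaves open, fixed here
and applied uniformly:

* **Initialization**: restarts seed centroids by distance-weighted
  (k-means++-style) sampling on the correlation distance; this makes
  empty clusters rare even on perfectly separable data.
* **Empty clusters**: a replicate whose final solution has an empty
  cluster is re-run with a fresh derived seed (up to 3 attempts) and
  otherwise discarded; the objective (summed frame-centroid correlation
  distance) is minimized over surviving replicates.
* **Degenerate frames**: a frame with zero variance across regions has
  no defined correlation and is assigned by Euclidean distance.
* **Iteration cap**: 100 Lloyd iterations (assignments converge far
  earlier on all fixtures).
* **Centroids** are arithmetic means of member frames, at every level
  (group, per condition, per subject-condition). Subject-condition
  centroids with zero assigned frames are flagged missing and propagate
  as `NA`, never as zeros.

`k = 4` is the default number of states, kept even so that sub-states
pair into meta-states; `elbow_scan()` reports variance explained over a
k-range and the first k whose gain falls below 1%, but is advisory and
never auto-applied. Meta-state pairing is greedy on the most negative
centroid correlation first — deterministic, and exact for the intended
two-pair case; a pairing forced to use a nonnegative correlation warns
that the hierarchy assumption is violated. `match_states()` aligns a
centroid set to a reference by the permutation maximizing total
correlation (exhaustive over $k \le 8$).

## Temporal dynamics

For each scan's integer state sequence: fractional occupancy (fraction
of frames per state), dwell time (mean contiguous run length × TR, in
seconds), appearance rate (run starts per minute), and the empirical
transition probability matrix (within-scan consecutive pairs; the
diagonal is the persistence probability). Conventions:

* Runs and transitions never cross scan boundaries (scans are temporally
  disjoint recordings).
* A run already in progress at the start of a scan counts as an
  appearance and contributes to dwell time. The alternative (discarding
  scan-initial runs) throws away data from short scans; either choice,
  applied uniformly to both conditions, leaves paired contrasts
  unbiased. This choice is deliberate and prominent here because it
  affects absolute (not differential) dwell/appearance values.
* States never visited are `NA` (missing), not zero: an unobserved dwell
  time is not a measurement of zero seconds.

On simulated Markov chains these estimators recover the generating
parameters (transition probabilities to < 0.02 absolute, dwell times and
appearance rates to < 5% of the closed-form expectations
$\mathrm{TR}/(1 - P_{ss})$ and $\pi_s (1 - P_{ss})$ per frame) and are
mutually consistent across a stickiness sweep.

## Spin-permutation nulls

Receptor maps live on spherical parcel coordinates, one hemisphere
mirrored onto the other. Each spin draws one uniform random rotation,
applies it to the left hemisphere and its sagittal mirror image to the
right, and then reassigns regions by greedy one-to-one nearest-neighbor
matching over ascending distance within each hemisphere. The result is a
true permutation of the original values: the value multiset is exactly
preserved (asserted in tests), while spatial autocorrelation is largely
retained — spun maps keep a Moran's I far above unconstrained shuffles.
The permutation variant (rather than plain nearest-neighbor resampling,
which can duplicate values) is required for the null to preserve the set
of weights entering $B$.

Spin p-values use the add-one estimator
$p = (\#\{E_\mathrm{null} < E_\mathrm{true}\} + 1)/(n_\mathrm{spins}+1)$,
which cannot return zero from a finite ensemble and recovers the plain
fraction asymptotically. Under a spatially structureless "true" map the
p-values are approximately uniform (calibration is part of the test
suite).

## Lempel-Ziv complexity

The 4-state sequence is binarized to its 2 meta-states (only within-pair
switches are lost) and compressed with the exhaustive-history LZ76 parse
(Kaspar–Schuster algorithm, implemented in C++ for the $O(n^2)$ worst
case). The reported statistic is the raw phrase count divided by the
sequence length, $c(n)/n$; the asymptotically scaled variant
$c(n)\log_2(n)/n$ is available behind a flag but is not the default.
Normalized LZ is invariant to a global bit flip, bounded by
$2 \le c(n) \le n$ for any sequence containing both symbols, and
increases with the entropy rate of the generating process. No
short-sequence bias correction is applied; at ~150 frames per scan the
measure needs large effects, which the tests respect by checking signs
and orderings rather than absolute values.

## Statistics

Condition contrasts are two-sided paired t-tests on subject-aligned
values, with missing pairs dropped pairwise and the retained count
logged. Benjamini-Hochberg correction is applied *within each metric
family* (e.g., across the $k^2$ transition-energy entries, or across the
$k$ states of one dynamics metric), mirroring panel-level correction
scopes; the family boundaries are a function argument, not hard-coded.
Per-subject condition changes use the symmetric relative difference
$(a - b)/(a + b)$. Brain-behavior-style couplings are partial
correlations controlling for mean framewise displacement: both variables
are residualized on the covariate (with intercept) and the residuals are
correlated, with the p-value from the t approximation on $n - 3$ degrees
of freedom (a permutation variant is intentionally out of scope; the t
approximation is standard at these sample sizes). With a constant
covariate the partial correlation equals the plain Pearson correlation
exactly, which is tested.

Type-I calibration: under exchangeable synthetic conditions the paired
t-test rejects at a rate inside $[0.03, 0.07]$ at $\alpha = 0.05$ over
1000 simulated cohorts of 15 subjects.

## The synthetic cohort generator

The generator emulates the *structure* of a two-session pharmacological
crossover fMRI study, not its physiology:

* **States**: $k$ zero-mean activation patterns in anti-correlated pairs
  (within-pair $r \le -0.8$), the planted analogue of sub-states/meta-states.
* **Dynamics**: a sticky Markov chain per scan (default stay-probability
  0.7), initial state drawn from the stationary distribution (computed
  by eigen-decomposition) so there is no burn-in.
* **Frames**: centroid of the current state plus i.i.d. Gaussian noise,
  then per-region demeaning, matching preprocessed parcellated BOLD. An
  optional AR(1) switch adds temporal autocorrelation for robustness
  checks; the default is white noise, the simplest model satisfying the
  clustering assumptions.
* **Design sizes**: 15 subjects × 2 conditions, 200 regions, 150 frames
  per scan at TR = 2 s — scan lengths and cohort size of a typical
  pharmaco-fMRI crossover study, small enough that the full pipeline
  (including 20-cohort replications) runs on one CPU in minutes.
* **Noise level**: `noise_sd = 1.0` against unit-variance centroids gives
  frame-to-centroid correlations near 0.7. Real within-state fMRI SNR is
  unknown; this value is calibrated only so that clustering recovers the
  planted states non-trivially (it is the regime where the correlation
  to the own centroid clearly exceeds correlations to other centroids,
  yet frames are far from noiseless), not to match empirical SNR.
* **Drug condition**: centroids scaled by `drug_amplitude_factor`
  (default study condition 0.7) — because energy is quadratic in the
  state vectors, this plants a uniformly flattened energy landscape —
  and, in `coupled_cohort_spec()`, per-subject amplitude factors
  $a_i \sim U(0.5, 0.95)$ with switch-boost $g_i = 1 - a_i$ mixing the
  drug transition matrix toward uniform switching. Subjects whose
  landscape flattens more therefore also produce more entropic
  meta-state sequences, planting the coupling that the entropy analysis
  must recover in sign.
* **Connectome**: Erdős–Rényi skeleton at the requested density with
  log-normal weights (heavy-tailed, like streamline counts) and a higher
  log-mean within modules; disconnected draws are regenerated.
* **Receptor maps**: exponentiated Gaussian process on the sphere with
  covariance $\exp(-d_{gc}/\ell)$ — nonnegative, log-normal-like, and
  spatially smooth; $\ell \to 0$ gives i.i.d. values for calibration
  nulls.
* **Motion covariate**: per-subject mean framewise displacement drawn
  independently of all signals — a null covariate, so partial
  correlations can be checked against plain correlations.

What the generator does **not** emulate: hemodynamic convolution,
realistic head motion and its spatial artifacts, scanner drift,
inter-subject anatomical variability, or empirical connectome topology
beyond modularity and heavy tails. Passing tests therefore demonstrate
that the pipeline's inference machinery is correct and calibrated under
its own assumptions — not that those assumptions hold in any particular
empirical dataset.

## Problem sizes used in validation

The packaged checks run the full pipeline on 20 independent cohorts at
the study conditions above (amplitude factor 0.7) and require the
drug-condition energy to be lower for all $k^2$ transitions in at least
95% of cohorts; clustering recovery uses a 10,000-frame scan at the
design SNR; solver validation uses 50 random stable systems of up to 10
regions against the discretized oracle; spin calibration uses 40-region
systems with 99 spins × 100 repeats. These sizes were chosen as the
smallest at which each property is sharply decided, so the whole suite
runs in a few minutes on one CPU.

## Known limitations

* The linear model is a local approximation; nonlinear (e.g., mean-field)
  dynamics are out of scope by design.
* Energies depend on the normalization constant and horizon; only
  qualitative orderings, differences and ratios are interpreted, and the
  sensitivity sweep is the guard.
* The greedy anti-correlation pairing is exact for two meta-state pairs
  but is not a maximum-weight matching for general $k$.
* Spin tests on parcel centroids (rather than surface vertices) coarsen
  rotations; the greedy one-to-one assignment slightly degrades the
  preserved autocorrelation relative to unconstrained nearest-neighbor
  spins — the price of exact multiset preservation.
* The LZ76 statistic on ~150-frame sequences is coarse (steps of $1/n$);
  only signed contrasts and orderings are used.
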