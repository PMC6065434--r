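---
title: "Methods: time-delay embedded HMMs for transient phase-coupling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-delay embedded HMMs for transient phase-coupling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`tdehmm` segments multichannel electrophysiological recordings into a small
number of recurring network states, each defined by a full spatio-spectral
fingerprint: frequency-resolved power in every region and frequency-resolved
phase coupling (coherence) between every pair of regions.

The observation model is a hidden Markov model over a *time-delay embedded*
representation of the data. Each sample is augmented with lagged copies of
all channels over a short window (default 15 lags, $-7\ldots+7$ samples,
i.e. 60 ms at 250 Hz). A state $k$ is a zero-mean multivariate Gaussian over
this embedded space, so its parameter is the embedded-space autocovariance
$C_k$ — the full set of within- and cross-channel lagged covariances over
the window. A lagged cross-covariance structure is exactly what linear
phase-coupling at specific frequencies looks like in the time domain, which
is why a plain Gaussian over the embedded space can capture oscillatory
coupling without any explicit spectral parameterisation. The state sequence
is first-order Markov; each subject has its own state time course while the
state parameters are shared across subjects.

With $C$ channels and $L$ lags the embedded dimension is $d = C \times L$
(630 for the canonical 42-region, 15-lag analysis), and each state
autocovariance carries $d(d-1)/2$ off-diagonal parameters (198,135). To
avoid overfitting, inference runs on a PCA reduction of the embedded space.
The default keeps twice as many components as channels: because channels
are standardized to unit variance and cross-channel lagged correlations are
small relative to within-channel autocorrelation, a component count that is
not a multiple of the channel count would spend its surplus components on an
essentially arbitrary subset of channels (requesting 100 for 42 channels
leaves 16 such components); the package warns in that case. Components are
not whitened — their variances are part of what distinguishes states.

One open choice is where PCA centering happens: the package centres the
concatenated (all-subject) embedded matrix globally, after per-subject
standardization. Per-subject means of standardized channels are already
zero, so the global centering is a no-op in practice; it is stated here
because nothing in the method forces this convention.

## Variational inference

Posterior inference is variational Bayes with conjugate priors: Dirichlet(1)
on transition-matrix rows and the initial distribution, and an
inverse-Wishart on each state covariance with degrees of freedom $d + 2$ and
scale $0.1\,\Sigma_{\text{global}}\,(d+2)$ — weakly informative but matched
to the data scale. The E-step runs scaled forward–backward recursions on
the *expected* log-densities under the covariance posteriors and expected
log transition probabilities under the Dirichlet posteriors; the M-step
applies the conjugate count/scatter updates. The variational free energy
(negative evidence lower bound) — the forward–backward data term plus the
Dirichlet and Wishart Kullback–Leibler divergences — is non-increasing over
full E/M cycles, which the test suite verifies over dozens of random
datasets, and convergence is declared at a relative change of $10^{-6}$.

Initialization seeds each state's covariance posterior with the scatter of a
random contiguous data segment (deterministic given the seed). Several such
random initializations (default 3) are each run for a few cycles and the one
with the lowest free energy is continued; this costs little and removes most
sensitivity to the starting point.

For datasets too large for full-batch cycles, stochastic inference updates
the posterior from minibatches of whole subjects, blending the full-data
prediction of each conjugate parameter with its current value at a
Robbins–Monro step size $\rho_i = (i + 2)^{-0.7}$. The schedule constants
are package defaults, declared rather than derived; the stochastic fit is
checked against the full-batch optimum (final free energies within 2% on the
reference simulation).

The Viterbi path — the most probable hard state sequence under the expected
parameters — is computed with ties broken toward the lower state index.
Because the embedding drops `max(|lag|)` samples at each recording edge,
state probabilities are padded back to the original length with uniform
$1/K$ values (and Viterbi paths with `NA`) so that state time courses align
sample-by-sample with the recordings. States are reported sorted by
descending fractional occupancy, which makes output ordering stable across
runs.

## Sign-flip disambiguation

Source reconstruction determines each region's time course only up to sign,
independently per subject, which can cancel genuine group-level coupling.
The package aligns polarity by maximising the across-subject agreement of
lagged *partial* correlations: each channel is residualized on all other
channels at lag zero (one regularized $C \times C$ inversion per subject,
with Ledoit–Wolf-style shrinkage toward the diagonal), residual series are
correlated at each lag in $-10\ldots+10$, and the objective is the sum over
channel pairs and lags of the magnitude of the across-subject mean
correlation. Residualizing both series at their own time points against the
lag-zero covariance keeps the measure exactly sign-equivariant: negating a
channel negates precisely its row and column of every lag's correlation
matrix, which is what makes the search cheap.

Exact maximisation is a hard integer programme, so the package uses a greedy
local search: random sign initialization, sweeps over (subject, channel)
cells in random order, accepting single flips only when the gain strictly
increases, with multiple restarts. Gain updates are incremental and are
tested to match full recomputation to $10^{-10}$.

Two gauge freedoms deserve note. The gain is invariant to negating all
channels of one subject, and also to negating one channel across *all*
subjects — in both cases the sign change cancels inside the objective. The
second freedom is sometimes overlooked: it means no maximiser of this
objective can pin down a per-channel global sign convention, only
*cross-subject consistency*, which is the property group-level coherence
needs. Recovery of simulated flips is therefore scored up to both freedoms.

A related practical point, visible in the simulator: if all channels follow
a single frequency within one long state visit, every channel is linearly
predictable from the others and partial correlations carry no sign
information at all. Markov switching with phase resets at state onsets — the
regime this model targets — is what keeps the partial correlations
informative.

## State-wise spectral estimation

Spectra are estimated on the original (unembedded) channels, so the PCA
step cannot bias them. Two estimators are provided.

*Soft (default):* DPSS-tapered cross-periodograms over sliding windows
(2 s, 50% overlap, time-bandwidth 4, 7 tapers; frequency grid 1–45 Hz at
0.5 Hz spacing, 89 bins) are averaged per state with weights equal to the
mean state probability over each window. Because each window's weights sum
to one across states, the occupancy-weighted sum of the state spectra
equals the static whole-recording spectrum *identically* — the package's
consistency check between the dynamic and static spectral descriptions.

*Hard:* a hard state path is cut into maximal visits; each visit is tapered
at its own length, zero-padded to the window length, and averaged into its
state's cross-spectrum weighted by visit length (visits under 10 samples
are dropped). This estimator is the one that shows coherence is measurable
from visits far shorter than an oscillation cycle: many separated sub-cycle
segments with a consistent cross-channel phase relation add coherently in
the averaged cross-spectrum. The cost is taper bandwidth — for a 100 ms
visit the smoothing is several Hz wide, so *peak positions* read from
hard-weighted spectra of very short visits are biased toward the shoulder
of the line.

For reading off a peak frequency the variance-oriented default (NW = 4) is
deliberately traded for a narrowband setting (NW = 2, 3 tapers): a
sinusoidal carrier has a line spectrum, and matching the taper bandwidth to
the expected linewidth is the standard multitaper resolution/variance
trade-off. The reference analyses in the test suite use this narrowband
readout for peak locations and the default for coherence levels.

The DPSS tapers themselves are computed from the symmetric tridiagonal
Slepian matrix (unit-energy eigenvectors, concentration-ordered), and the
"90 columns" convention of frequency grids is configurable: the default
0.5 Hz grid over 1–45 Hz has 89 bins, since the exact grid that yields 90
is not fixed by convention.

## Frequency modes by NNMF

Rather than imposing classical bands, the coherence spectra of all (state,
region-pair) combinations are stacked into a non-negative matrix A (10,332
rows for 12 states over 42 regions) and factorised as $A \approx WH$ with
multiplicative updates under the Frobenius objective (objective
non-increasing per update; best of 10 random restarts). Rows of H are the
data-driven frequency modes; four modes give the granularity of the
classical delta/theta, alpha, beta and low-gamma bands, and modes are
reported sorted by ascending peak frequency. Power is projected onto the
same H estimated from coherence, and wideband summaries are plain averages
over the grid. Note that NNMF factors are only identifiable up to
permutation and scaling, and only when the mixing matrix contains
near-anchor rows; reconstruction error, not factor identity, is the fitted
criterion.

Reported networks are thresholded by a two-component Gaussian mixture over
the population of connection values (EM via `mclust`, model selection by
BIC): connections assigned to the higher-mean component are kept, and if a
single Gaussian wins, nothing stands out and nothing is shown. Power maps
are thresholded by percentile of absolute deviation from the across-state
mean (50% wideband, 10% for frequency-specific maps by convention).

## Temporal statistics and state distances

Dwell times, interval times and fractional occupancy are computed from the
Viterbi path (visit semantics require hard assignments); soft occupancy
from the state probabilities is also available and the two agree when the
posterior is near-deterministic. Interval-time tails are summarised by the
empirical survival curve (proportion of intervals longer than a duration).
State-onset rhythmicity is probed by the multitaper spectrum of the onset
point process, with pointwise percentile bands from a moving-block
bootstrap (10 s blocks, 99% by default) — the bootstrap scheme is a package
choice. One-state-versus-rest contrasts across subjects use a permutation
test with a shared permutation set and the add-one p-value estimator, whose
size is verified (type-I error at most 0.07 at $\alpha = 0.05$) in the test
suite.

Dissimilarity between states is the affine-invariant Riemannian distance
between their embedded-space autocovariances,
$d(C_1, C_2) = \sqrt{\sum_i \log^2 \lambda_i(C_1^{-1} C_2)}$. A published
shorthand for this distance ("square root of the sum of the logs of the
eigenvalues of the product") is not a metric as written — it gives nonzero
self-distance and can be imaginary — so the package implements the standard
affine-invariant form by default and offers the literal product form only
for comparison (`literal = TRUE`). To ask whether power or coupling drives
state switching, distances are recomputed after manipulating the
channel-block structure: zeroing cross-channel blocks (power only) or
rescaling each channel block to unit average diagonal (coherence only). The
precise block recipe is a declared package reading of that analysis, and is
validated on constructions where the answer is known (states differing only
in cross-channel blocks have zero power-only distance, and vice versa).

## The simulator

`simulate_dataset()` generates Markov-switching multichannel recordings in
which every quantity the pipeline estimates is known: state paths from a
specified transition matrix (geometric dwell law, verified by
goodness-of-fit), per-state oscillations and phase-coupled channel pairs,
additive Gaussian noise, and per-subject random channel sign flips. Phase
is reset uniformly at random at each state onset and is continuous within a
visit, so separate visits are not artificially phase-locked. Coupled pairs
carry only the shared (lagged) sinusoid — coupled-oscillator semantics; an
additional independent oscillation at the same carrier would depress
coherence exactly at the carrier bin. An optional first-order-filtered
1/f-like background is available but off by default.

The bundled reference dataset (`two_state_demo()`) uses 5 subjects, 60 s at
250 Hz, 8 channels, two states with 0.995 stay-probability (mean dwell
0.8 s), 4 Hz coupling on channels 1–2 in state 1 and 10 Hz on channels 3–4
in state 2, coupling amplitude 1 against unit noise (SNR $\approx$ 1), and
carrier amplitude 0.7 on the uncoupled channels. These values are the
package's declared study conditions for all reference checks: state
recovery accuracy of at least 0.85 after label matching, coherence peaks at
the generating bins, and the soft-weighting consistency identity. The
short-visit analysis uses a separate three-state configuration with mean
dwell 100 ms (under half a 4 Hz cycle) and verifies that state-conditional
coherence at the coupling bin still exceeds the uncoupled states' several
times over.

What the simulator does *not* emulate: 1/f-dominated broadband spectra (off
by default), spatially correlated sensor noise, volume conduction/leakage
(assumed corrected upstream), non-sinusoidal waveforms, and slow
non-stationarities. Passing tests on these simulations therefore
demonstrates correctness of the algorithms under the stated generative
assumptions, not robustness to everything real recordings contain.

## Numerical choices and limitations

- Problem sizes in the tests are desk-scale by design: the reference fit
  runs on a 74,930 x 16 reduced matrix and converges in seconds. The
  canonical 55-subject analysis (4.1M x 630 embedded) is what the stochastic
  mode exists for.
- Covariance posteriors are manipulated through Cholesky factorisations
  throughout; forward–backward works in the scaled probability domain and
  never underflows for finite inputs.
- A state whose expected occupancy falls below the embedded dimension keeps
  its prior covariance (with a warning) rather than being resurrected.
- Degenerate inputs error early with informative messages: constant
  channels cannot be standardized, non-positive-definite matrices are
  rejected with their smallest eigenvalue, manifests naming missing files
  report the file.
- `K` is a user choice; the package does no model selection over the number
  of states beyond reporting free energies.
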