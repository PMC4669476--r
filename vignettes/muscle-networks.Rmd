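---
title: "Mapping frequency-specific muscle networks: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping frequency-specific muscle networks: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models behind `musclenet`, the assumptions they
rest on, the parameters that matter, and the numerical and design choices
that were genuinely open — the kind of detail a maintainer or a careful user
needs but a function reference cannot carry.

## The measurement model

Surface EMG is modelled as a broadband carrier (the interference pattern of
many motor-unit action potentials) whose *amplitude envelope* is modulated
by the net synaptic drive to the motoneuron pool. Because a motor-unit
pool's transfer of common input is approximately linear, correlated
(common) input to two pools shows up as coherence between the two muscles'
envelopes, in the frequency band of the shared drive. Everything in the
package analyses envelopes, never the raw interference signal:

1. `highpassRectify()` — 20-Hz high-pass (to remove movement artifact and
   low-frequency amplitude drifts from the carrier band), then the
   magnitude of the analytic (Hilbert) signal. This equals full-wave
   rectification in expectation but yields a smooth instantaneous
   amplitude.
2. The **coherence branch** stays at the native rate (2 kHz by default):
   `welchCoherency()` uses Hamming-tapered 1-s windows with 0.75-s overlap,
   so the frequency grid has 1-Hz resolution; per-segment means are removed
   before tapering. Complex coherency is averaged over the trials of a
   condition *before* squaring (`poolCoherence()`): phase-inconsistent
   coupling cancels, and the pooled magnitude-squared coherence can only be
   reduced relative to single trials (a convexity property the tests
   assert).
3. The **MVAR branch** (`conditionForMvar()`) band-passes the envelope to
   0.5–70 Hz, downsamples to 200 Hz and z-scores every channel, so PDC is
   not dominated by variance differences between muscles.

Assumptions worth keeping in mind: linearity of the pool transfer, spectral
stationarity within a 60-s trial, and that electrode cross-talk has been
handled at acquisition (the package performs no cross-talk removal).

## Surrogate confidence limits

`surrogateThreshold()` builds the null distribution of pooled coherence by
Fourier phase randomization: every channel of every trial receives
independent random phases while its amplitude spectrum is preserved
(conjugate symmetry maintained, so surrogates stay real), and the entire
pooling pipeline is re-run per surrogate. The per-pair, per-frequency 95th
percentile over `nSurrogates = 200` surrogates is the confidence limit; 200
is enough to stabilize a 95th percentile at acceptable cost, and the seed
makes thresholds reproducible. Whether the original analysis randomized raw
EMG or envelopes is ambiguous; the default randomizes envelopes (the signal
actually entering the coherence estimator), and `randomize = "raw"`
re-extracts envelopes from phase-randomized raw signals instead.

## MVAR models and partial directed coherence

`fitMvar()` estimates the strictly causal regression
`y_t = Σ_k A_k y_{t-k} + e_t` by ordinary least squares — deterministic,
standard, and adequate at the 12,000-sample trials the conditioning
produces. The residual covariance uses the maximum-likelihood divisor so
that `selectOrderAic()` can evaluate
`AIC(p) = ln det Σ̂_p + 2 p M² / N` consistently; the order is selected per
trial (default cap `pMax = 30`). `identifyInstantaneous()` augments the
model with a lag-zero coefficient matrix from the unit-diagonal Cholesky
factorization of the residual covariance under a stated channel ordering.
The ordering is an *identification choice*, not an estimate: it changes
`B0` but never the model-implied spectrum (asserted to 1e-8 in the tests),
which is why it is recorded in the output. Gaussian innovations cannot
reveal the true instantaneous direction, so the strictly causal model is
the default and the extended variant is opt-in.

Partial directed coherence is computed from
`Ā(f) = I − Σ_k A_k e^{−i2πfk/fs}` (or `(I − B0) − Σ_k Ã_k e^{−i2πfk/fs}`
for the extended model) with column (source) normalization that includes
the diagonal, so squared PDC sums to exactly one over targets for every
source and frequency — a built-in invariant the suite checks to 1e-10.
Like coherency, complex PDC is averaged over trials and then squared; by
convexity the pooled outflow per source stays at or below one. The
reporting grid is 0–60 Hz in 0.5-Hz steps.

A model check mirrors the pipeline's validation logic: coherence derived
from the fitted MVAR coefficients agrees with Welch coherence of the same
envelopes to a mean absolute difference well below 0.1 over 0–60 Hz on
synthetic studies (the acceptance report recomputes this as a median over
20 generator seeds).

## NMF spectral unmixing

`stackSpectra()` arranges the nonnegative spectra of all pairs, conditions
and subjects as a frequency × observation matrix on 0–60 Hz
(subject-major, then condition, then pair — a deterministic, reversible
ordering). `nmfAls()` factorizes it by projected alternating least squares:
each half-step solves the unconstrained least-squares problem and clips
negatives to zero. Plain projected ALS is not guaranteed monotone, so the
iteration *terminates when the Frobenius error stops improving* and keeps
the last improving iterate; the recorded error trace is therefore
non-increasing by construction, and convergence is declared when the
relative error change drops below `tol = 1e-6` (cap 500 iterations). Ten
uniform-random restarts are run from seeded substreams and the best final
error wins, which in practice pins the basis peak locations to within one
frequency bin across master seeds.

`K = 4` is the default component count, matching the four distinct bands
(<5, 6–10, ~16, 30–45 Hz) that postural EMG typically decomposes into;
since no principled selection rule is implied by the method, `nmfScree()`
reports reconstruction error against K instead. NMF leaves scale and
component order arbitrary, so `orderAndNormalize()` fixes the convention:
unit-norm basis columns (with the compensating scale moved into the
loadings; the product is preserved to 1e-12) and components sorted by
ascending basis peak frequency. Undirected loadings are duplicated
symmetrically into adjacency matrices; directed loadings fill ordered
(source → target) slots. Coherence and PDC stacks are factorized
separately — their spectral signatures differ and sharing bases would
entangle the two network types.

## Graph metrics

All metrics run on the *weighted* matrices; `proportionalThreshold()`
(keep the strongest `⌈fraction × candidates⌉` edges, ties broken by pair
order) exists for visualization only. Weights are normalized by the
network's maximum before the clustering coefficient, giving the Onnela
geometric-mean form for undirected networks and its directed
generalization counting all triangle orientations; the exact directed
variant is not pinned by the method's description, so the implementation is
pinned instead by brute-force triple-enumeration oracles at 1e-12.
Distances use edge lengths 1/weight with zero-weight edges absent (no
epsilon flooring — an absent connection is infinitely long, not merely
weak); global efficiency is the mean inverse shortest-path length over
ordered pairs (disconnected pairs contribute zero) and betweenness is
Brandes' fraction-weighted count, unnormalized and then averaged across
nodes. Shortest-path machinery is delegated to `igraph`; the brute-force
path-enumeration oracles in the test suite keep that delegation honest.

## Group statistics

`rmAnova()` is a two-way fully within-subject ANOVA (condition × frequency
component) by standard sum-of-squares partitioning, each effect tested
against its subject-interaction error term. Sphericity is assessed per
effect with Mauchly's test (chi-square approximation with Box's
second-order term); when Mauchly's p < 0.05 the Huynh-Feldt epsilon
(clipped to 1) rescales the degrees of freedom. Two-level effects skip the
test — sphericity holds trivially — and the test is undefined when the
error degrees of freedom do not exceed the number of contrasts, in which
case no correction is applied and the Mauchly columns are NA. The
implementation is cross-checked against `car::Anova` to 1e-6 on a seeded
fixture. Post-hoc paired t-tests are uncorrected by default, with a
`p.adjust` flag for users who want multiplicity control.

## The synthetic generator: what it emulates and what it does not

The generator reproduces the *recording geometry* of a postural study —
ten bilateral leg muscles at 2 kHz, 60-s trials, four trials in each of
four conditions — and plants connectivity ground truth two ways:

- **Common drives** (undirected truth): unit-variance Gaussian noise
  band-passed to the drive band (by exact Fourier masking — zero-phase and
  numerically stable at any bandwidth) multiplies the carrier as
  `1 + Σ gain·s(t)`, clipped below at 0.05 so the envelope scale stays
  positive. Channel pairs sharing a drive become envelope-coherent inside
  the drive band; gains above a total of 2 per channel are rejected because
  the modulator would spend a substantial fraction of its time clipped.
- **Directed coupling**: a stable VAR process simulated at 200 Hz is
  rescaled to unit stationary variance per channel (computed exactly via
  the companion-form Lyapunov equation, so the planted coefficients live on
  the same scale the pipeline's z-scoring produces), linearly interpolated
  to 2 kHz and applied as `max(1 + 0.4·z, 0.05)`. The linear modulator was
  chosen over a log-envelope formulation because it keeps the fitted-VAR
  target identical to the planted process up to additive envelope noise;
  the squared PDC of the scaled coefficients is stored in the study
  provenance as ground truth. Couplings should concentrate their power
  below ~20 Hz (pole structure, not post-hoc filtering) so the 0.5–70-Hz
  conditioning is transparent to them.

Seeding: one master seed; each trial uses substream
`(seed + 1000003·trialIndex) mod (2³¹−1)`, so any subset of a study can be
regenerated independently and full studies serialize byte-identically.

What the generator does *not* emulate: motor-unit discharge statistics,
muscle mechanics or force output, nonstationarity within trials,
condition-dependent connectivity differences (conditions are labels only),
electrode cross-talk, or movement artifact. Passing tests therefore show
that the estimators recover planted linear envelope structure — not that
real standing EMG satisfies the model.

A quantitative limitation the tests make explicit: the amplitude envelope
of a stochastic carrier carries irreducible broadband (Rayleigh)
fluctuation, which acts as measurement noise on the planted modulator and
attenuates fitted MVAR coefficients (a classical errors-in-variables
effect, strongest where planted spectra meet the noise floor, plus an edge
effect below ~2 Hz from the 0.5-Hz conditioning high-pass). Consequently
single-trial fitted squared PDC tracks the planted truth to better than
0.1 *on average* over the 0–60-Hz grid, and ranks planted edges above
absent ones with AUC above 0.9, but pointwise agreement at every bin is
not achievable at plausible modulation depths — raising the depth buys
little because clipping distortion grows in step. Pooled-coherence
magnitudes are normalized and are not affected by this attenuation.

## Problem sizes and runtime choices

The test-suite and acceptance fixtures are sized for single-core runs while
preserving the operating characteristics that matter: 60-s trials wherever
an estimator's variance depends on trial length (MVAR fits at 12,000
conditioned samples, model-vs-Welch comparisons), 30-s trials and 2–6
channels for the pooled-coherence and unmixing recoveries (the planted
effects are band-limited, so channel count only scales the pair set), 200
phase-randomization surrogates, 20 Monte-Carlo seeds for recovery medians,
and 100 random ≤6-node graphs for the brute-force metric oracles, where
exhaustive path enumeration is still exact.

## Known limitations

- PDC is reported in its original column-normalized form; generalized or
  renormalized variants, the directed transfer function, and spectral
  Granger causality are out of scope.
- Synergy alignment is by optimal *permutation* (exhaustive assignment on
  the basis-correlation matrix): nonnegativity of the basis forbids the
  general rotations of a classical orthogonal-Procrustes alignment, so
  consistency scores should be read as permutation-aligned correlations.
- The rmANOVA requires a complete balanced design; missing cells are an
  error, not an imputation target.
- No artifact rejection or cross-talk removal; inputs are assumed clean.
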