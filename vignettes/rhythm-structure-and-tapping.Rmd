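---
title: "Rhythmic structure and tapping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythmic structure and tapping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taprhythm)
```

This vignette is the package's account of its science: the objects it
models, the definitions it commits to where several were defensible, the
numerical choices behind the implementations, and what the synthetic-data
generator does and does not emulate.

## The rhythm universe

A rhythm here is a cyclic pattern of `N` isochronous pulses (234 ms apart)
with `K` of them cued. *Nondegenerate well-formed* rhythms have exactly two
interonset-interval (IOI) sizes distributed as evenly as possible, which is
equivalent to Myhill's property: every generic interval (distance of `g`
cue steps, `g = 1..K-1`) is realized in exactly two specific sizes (pulse
counts). `is_wellformed()` tests this directly from the tabulated cue-pair
sizes.

Two refinements were needed to make the enumeration well defined:

* **Primitivity.** Myhill's property alone also admits patterns whose two
  IOI sizes share a common factor — for instance IOIs (4 2) in a 6-pulse
  cycle. Such patterns are pulse-magnified copies of a smaller rhythm
  (here (2 1) in 3 pulses): all cues sit on a proper sublattice of the
  cycle, and every generator of the cue set shares a factor with `N`, so
  they are not nondegenerate well-formed in the generated-scale sense.
  `is_wellformed()` therefore additionally requires the IOI sizes to be
  coprime (toggle: `require_primitive`). Under the study constraints
  (`N` 3–13, `K` 2–11, max IOI 5, counted up to rotation) Myhill alone
  admits 96 rotation classes; primitivity removes exactly the five
  (4 2)-IOI classes, leaving the expected 91.
* **Canonical rotation.** "Small IOIs as close to the end as possible" is
  implemented as: among rotations starting on a cue, take the one with the
  lexicographically largest IOI sequence. This reproduces all three
  reference indicator vectors — (1 0 1 0 1 1 0 1), (1 0 0 1 0 0 1 1 0 0 1),
  (1 0 1 0 1 0 1 1 0 1 0 1) — deterministically from any input rotation,
  and is idempotent on the enumerated set.

Rhythms are counted up to rotation only (performances start on a random
cue, so rotation classes are the natural unit); reflections are distinct
rhythms.

## Rhythm-level predictors

* **Evenness** is the magnitude of the mean, over cues `j = 0..K-1` in
  temporal order at pulses `t_j`, of unit vectors at angle
  `2π t_j / N − 2π j / K` — the alignment of the cue set with a perfectly
  even `K`-template. It is invariant to rotation and to the labelling of
  the first cue, equals 1 exactly for equally spaced cues, and reproduces
  the worked values 0.866 for (1 1 0) and 0.707 for (1 1 0 0).
* **Balance** is `1 − |centroid|`, the complement of the distance of the
  cues' circular centre of mass from the circle centre (one minus the mean
  resultant length, i.e. the circular variance).
* **Entropies** are Shannon entropies in bits: of the `K` consecutive-cue
  IOIs (`ioi_entropy()`), and of the multiset of all `K(K−1)` directed
  inter-cue intervals modulo the period (`interval_entropy()`). The base
  and the absence of support-size normalization are free choices here:
  predictors are standardized before modelling, so both are scale
  decisions without downstream consequence.
* **Coherence quotient.** A coherence failure is an unordered pair of
  directed cue-pair intervals where the smaller generic interval spans
  strictly more pulses. The count is normalized by the worst case for a
  `K`-cue rhythm, obtained by exhaustive search over all cue patterns with
  up to 13 pulses (the largest cycle in the universe) and cached; no
  closed form is trusted. Undefined for `K < 3` (returned as `NA`).
* **Sameness quotient** sums, per generic interval, the number of distinct
  specific sizes beyond the first and normalizes by the combinatorial
  maximum `(K−1)²` (each generic interval is realized by `K` cue pairs, so
  at most `K` distinct sizes). On Myhill rhythms the quotient is exactly
  `(K−2)/(K−1)`. This normalizer — rather than a worst case restricted to
  13 pulses — is what reproduces the expected correlation of 0.80 with `K`
  across the 91 rhythms (the restricted worst case gives 0.54), so it is
  taken to be the intended definition.

Across the enumerated universe the package reproduces
`cor(balance, evenness) = 0.94` and `cor(sq, K) = 0.80` at two decimals;
both are computed, not asserted, in the test suite and the acceptance
script.

## Pulse-level predictors

All pulse-level profiles are rotation-equivariant: rotating the rhythm
rotates the profile.

* **Markov cue probability** (orders 2–4): the proportion of cyclic
  positions sharing a pulse's length-`k` context that are followed by a
  cue. Contexts wrap circularly and are estimated from the single cycle —
  identical, by periodicity, to estimating from the 30-s stream. Averaged
  over positions the profile equals `K/N` (law of total probability; a
  property test).
* **Edge detection** convolves the cue indicator, as unit impulses on the
  pulse circle, with a derivative-of-Gaussian kernel and takes magnitudes
  at pulse positions. The kernel's scale (0.36048 pulses), phase shift
  (−0.0071177 pulses) and gain (1.27829) were calibrated once against the
  worked example (0 0 1 1 0 0) → (0.00, 0.22, 0.15, 0.27, 0.20, 0.00) and
  frozen as defaults. The worked vector is mirror-asymmetric, which no
  unshifted (odd) kernel can produce; the shift is what makes the second
  cue of a two-cue cluster score higher than the first. The price is a
  small constant response to the all-ones signal (≈0.05 after gain):
  complementing a rhythm flips the sign of the convolution only up to that
  constant, so edge profiles of a rhythm and its complement agree within
  0.06 (verified over all 91 rhythms) rather than exactly, and isochronous
  rhythms give a flat profile at that constant rather than exactly zero.
  An exactly complement-invariant variant (mean-centred input) cannot
  reproduce the worked vector at two decimals, so the calibrated form is
  preferred.
* **Mean offset**: the sum of forward minus backward circular distances
  from a pulse to every cue, normalized by `K·N` into `[−1, 1]` (the
  normalizer is a free scale choice; standardization removes it). High
  near cluster ends, low near cluster starts.
* **Projected centroid**: the cue centroid projected onto the diameter
  through each pulse, `|c| cos(θ_n − arg c)` — zero everywhere for
  perfectly balanced rhythms, bounded by the centroid magnitude.
* **APM salience**: for each lag `k = 1..⌊N/2⌋`, the mean autocorrelation
  mass `x(n+ik)·x(n+(i+1)k)` along the pulse's cyclic orbit under steps of
  `k`, averaged over lags. Phase classes are defined on the cyclic orbit
  rather than as residues `n mod k`: residue classes are not preserved by
  rotation when `k` does not divide `N`, and the orbit formulation is what
  makes the profile exactly rotation-equivariant at every lag.
* **Sequential expectation**: every maximal run of `m ≥ 2` cues linked by
  a constant IOI `d` (read off the circular IOI sequence) adds
  `(1 − run_gain^(m−1)) · ioi_decay^(d−1)` to the pulse continuing it. The
  two shape constants default to 0.5 each — chosen once so contributions
  grow with run length and halve per extra pulse of IOI, the qualitative
  shape the predictor requires — and are exposed as parameters.
* **Povel accents**: isolated cues, last cues of runs of ≥2, first cues of
  runs of ≥3 (all circular).

## Dependent variables

* **Tap accuracy** is the cosine similarity of Gaussian-smoothed (10-ms SD,
  roughly the just-noticeable timing difference) indicator series of the
  taps and the cues at 1-ms resolution. It penalizes missing taps,
  spurious taps, and any timing error including a constant offset; a
  performance tapped uniformly 30 ms early scores below one tapped 15 ms
  early. The 30-s series is smoothed linearly (a performance is not
  circular); kernels are truncated at ±8 SD so the metric matches a direct
  Gaussian-summation oracle to 1e-9. Zero taps give accuracy 0 (cosine
  with the zero vector). Offset correction, when requested, maximizes over
  integer shifts within ±117 ms at the metric's resolution; the full
  performance span is used (no trimming of the initial ramp).
* **Window assignment**: each tap belongs to the pulse whose centred
  234-ms window contains it (windows tile time; the grid origin is the
  first sounded pulse, and the few taps outside all windows are dropped
  with a count). Within a window the tap with the smallest absolute
  asynchrony is kept, ties going to the earlier tap — "most accurate
  timing", with a documented arbitrary tie-break. Signed asynchronies are
  therefore confined to [−117, 117] ms, which is exactly why the
  asynchrony model is truncated.
* **Velocity** is 7-bit MIDI: taps harder than 127 are *recorded as* 127,
  so the top value is censored, not truncated.

## Observation families

All four families are fitted by maximum likelihood (BFGS from a zero
start, standard errors from the numerical observed information):

* binomial-logit for `(tap_num, n_pulses)` counts, with an optional
  Student-t(3, 0, 1) log-density penalty on non-intercept coefficients
  (off by default so recovery tests are unbiased);
* upper-censored normal for velocities (tail mass above the ceiling);
* two-sided truncated normal for asynchronies (window-renormalized
  density), with bounds recomputed from each dataset's own response SD
  since responses are scale-standardized;
* beta regression (logit mean link, common precision) for accuracies, with
  exact 0/1 nudged inward at machine-epsilon scale.

Responses `tap_vel` and `tap_delta` are divided by their SD but not
centred; all other continuous inputs are standardized to mean 0, SD 1;
binary inputs stay dummy-coded. Every pulse-level predictor interacts with
`cue`, and `sdt_decompose()` reports, per predictor, the uncued (bias)
effect, the cued effect and the discriminability effect with covariance-
propagated standard errors; `cued = uncued + discriminability` holds
exactly by construction. Likelihood implementations are validated against
numerical-quadrature oracles to 1e-8 on small tables, and the censored
family is cross-checked against an independent accelerated-failure-time
implementation.

Random-effects (multilevel) estimation is deliberately out of scope: the
package's contribution is the predictors, the likelihoods and the
decomposition identities, not posterior machinery. Fixed-effects estimates
on heterogeneous cohorts are marginal effects and are attenuated relative
to conditional generating coefficients; parameter-recovery tests therefore
simulate with the random-effect SDs at zero. Wald z-statistics stand in
for posterior summaries.

Variable selection is VIF-guarded forward addition over an externally
supplied ranking: a candidate is skipped when adding it pushes any
column's variance inflation factor above 10 (equivalently, when some
predictor becomes expressible from the rest with `R² > 0.9`); nothing is
ever removed. The projection-based ranking method used to order candidates
in the original analyses is not reimplemented.

## The synthetic cohort generator

`sim_config()` defaults encode the study conditions: 111 participants; the
91 rhythms in four disjoint sets (assigned round-robin), each assigned
rhythm performed twice with random order within each block pass; 129
pulses at 234 ms (30 s) per performance; a randomized starting cue; MIDI
velocities rounded and censored to 1–127; double taps appended 15 or 60 ms
after a kept tap with probability 0.034 (the observed discard fraction).
Tap occurrence is logistic in standardized pulse/rhythm features with
participant and rhythm intercept and cue-effect offsets; asynchronies are
truncated-normal with cued mean −9 ms and uncued mean +4.8 ms (the
reported intercepts) and an SD of 40 ms — a value chosen once as realistic
for nonmusician tapping, since no SD is reported at this grain; velocity
has mean 85, SD 25 MIDI units and a between-participant SD of 21.7 (the
reported participant-intercept SD), making the 127 ceiling visibly
occupied. Coefficient defaults (cue = 2 on the log-odds scale, feature
effects of magnitude ≤ 0.5) are illustrative of the reported regimes, not
estimates.

What the generator does *not* emulate: within-performance learning or
tempo drift, serial correlation of asynchronies beyond the lagged-tap
indicator, participant strategy shifts, and any cognitive process.
Passing tests therefore certify the pipeline's arithmetic and the
estimators' calibration under the assumed observation model — not that the
model captures human tapping.

## Problem sizes and numerical choices

The test suite runs everything at desk scale: enumeration over all 8192
patterns per cycle length; Myhill cross-validation exhaustively to 10
pulses; property tests over the full 91-rhythm universe where cheap
(edge complement bounds) and over a fixed 6–12 rhythm subsample where not
(equivariance loops); parameter recovery on 20 cohorts per family of 20
participants × 12 rhythms (two performances of each of 3 assigned rhythms
per participant), pooling Wald 95% coverage across coefficients and
requiring it in [85%, 100%]. Optimizations start from zero, use a relative
tolerance of 1e-12, and report the gradient norm; rank-deficient designs
abort with the aliased columns named; degenerate inputs (empty rhythms,
all-censored responses, out-of-window asynchronies, constant accuracy)
raise descriptive errors rather than propagating.

## Known limitations

* Complement invariance of the edge profile is exact only up to the
  kernel's constant response (< 0.06); this is forced by the calibrated
  asymmetric worked vector, as explained above.
* The coherence-quotient normalizer is search-based and therefore defined
  relative to the 13-pulse universe; rhythms with longer cycles would need
  a larger `max_n`.
* Fixed-effects fits understate uncertainty on strongly clustered cohorts
  (no random effects); interpret cohort-level standard errors accordingly.
* `markov3`/`markov4` are undefined for cycles no longer than the context
  and are returned as `NA` there.
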