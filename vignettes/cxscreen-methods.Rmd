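---
title: "Methods: optogenetic functional-connectivity screening of the central complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: optogenetic functional-connectivity screening of the central complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The screening problem

The *Drosophila* central complex — protocerebral bridge (PB), ellipsoid body
(EB), fan-shaped body (FB) and noduli (NO) — supports the fly's heading
representation. Anatomy suggests many candidate synaptic connections between
its cell types, but light-level overlap of arbors does not establish
functional coupling. An all-optical screen addresses this causally: the
candidate presynaptic type expresses the red-shifted channelrhodopsin
CsChrimson and is driven with brief light-pulse trains, while the candidate
postsynaptic type expresses the calcium indicator GCaMP6m and is imaged
under two-photon excitation. `cxscreen` implements the complete analysis of
such a screen — and, because the original recordings are large external
deposits, a synthetic-data generator that emulates the screen's structure
closely enough that every stage of the pipeline is testable end to end with
a planted ground truth.

# Trial structure and the synthetic generator

The generator reproduces the screen's design: for each cell-type pair, at
least 6 flies; for each fly one run of 4 repeats (each about 16 s) per
stimulation strength; pulse trains of 1, 5, 10, 20 or 30 pulses at 30 Hz,
2 ms per pulse. Repeats are simulated as

baseline + slow drift + (evoked response) + white noise,

with the evoked response gated per repeat by a Bernoulli reliability draw.
The response kernel is a difference of exponentials (default rise 0.15 s,
decay 1 s — GCaMP6m-like timescales) summed linearly over the pulse train.
By default the summed kernel is normalized to unit peak, so the planted
`peak_amplitude` *is* the noiseless response extremum for every protocol;
this makes analytic checks exact. A soft `tanh` ceiling (`saturation`) is
available instead when saturating pulse-number summation is wanted.

Response classes follow the taxonomy seen across such screens: strong
excitation (default peak 1.2 dF/F0), weak excitation (0.3), inhibition
visible as a dip from a tonically elevated baseline (baseline 1.0, peak
−0.8 — a dip is only representable from an excited state, so the class
constructor enforces a positive baseline), post-stimulation rebound (a
positive kernel starting one decay time after train offset), and no
response. Baselines fluctuate slowly (a random walk rescaled to sd
0.05 dF/F0, emulating spontaneous brain-state drift) on top of white noise
(sd 0.05 dF/F0). These defaults are the package's study conditions; they
were chosen once as plausible values for slow, large-ROI two-photon series
and are not tuned per analysis.

Two structural parameters the trial description leaves open are the imaging
rate and the exact repeat length in samples; the generator defaults to
10 Hz × 16 s = 160 samples, both configurable. Randomness is organized
around one master seed: each repeat's seed is derived by a stable string
hash of (pair, fly, protocol, repeat), so datasets are reproducible and
independent of generation order.

What the generator does *not* emulate: indicator nonlinearity and photo-
bleaching, correlated (shared) brain-state across repeats of a fly,
neuropil contamination, and non-rigid motion. Passing tests therefore
demonstrate correctness of the pipeline's computations under the stated
noise model, not robustness to every pathology of real recordings.

# Movie preprocessing

Optionally the generator renders traces as movie stacks (bright disc ROI
over a dim background, shot-like noise, whole-run translation drift), which
exercises the preprocessing chain:

1. **Registration.** Per run, the time-average image is computed; the
   translation between each run average and the first run's average is
   estimated by cross-correlation, refined to sub-pixel precision by
   evaluating the Fourier-domain cross-correlation on an upsampled grid
   (matrix-multiply DFT, default upsampling 10, i.e. 0.1 px resolution)
   in a ±1.5 px neighbourhood of the integer peak. Only whole-run rigid
   translation is corrected, matching the acquisition geometry. Shifts
   above a quarter of the frame trigger a warning.
2. **ROI.** One ROI per experiment, from the grand average image, by
   2-cluster k-means on pixel intensity with deterministic initialization
   (centroids at the minimum and maximum intensity) — reproducible without
   a seed, and based on intensity only, never activity, so responsive and
   non-responsive experiments are segmented identically.
3. **Background.** `B` = mean intensity of the dimmest 10% of pixels of
   the average image. (The summary over that pixel set is configurable to
   a median; the mean is the default reading.)
4. **Baseline.** `F0` = median ROI fluorescence over the dimmest 3% of
   frames pooled across *all* runs — a global baseline, because resting
   fluorescence wanders over an experiment. Frames are ranked by their
   mean ROI fluorescence (ranking within the ROI, since `F0` is an ROI
   quantity). With fewer than 34 frames the 3% set is empty and the
   dimmest single frame is used, with a warning.
5. **Normalization.** `dF/F0 = (F − F0) / (F0 − B)` per frame, an error if
   `F0 ≤ B`. The quotient form is the only reading under which the result
   is a normalized fluorescence change; it is invariant under a common
   gain applied to `F`, `F0` and `B`.

# The statistic hierarchy

**Per repeat** (with baseline window = all samples before onset):
`Fbase` (mean pre-stimulus dF/F0); the peak sample maximizes
|value − `Fbase`| after onset, keeping the sign, so inhibition yields a
negative excursion — the description "peak fluorescence value" alone does
not cover inhibitory responses, and the signed-extremum reading is what
makes negative response integrals possible; `Fpeak` (value at that
sample), `Tpeak` (its time after onset), `ItoPeak` (trapezoidal integral
of the baseline-subtracted trace from onset to the peak), `tau_half`
(first time after the peak at which the deviation from `Fbase` falls to
half the peak deviation — measured relative to `Fbase`, and recorded as
missing, not zero, when the trace never re-crosses), and the normalized
`Fpeak_norm = Fpeak / Fbase`, `ItoPeak_norm = ItoPeak / Fbase`. Because
`F0` is constructed from the dimmest frames, `Fbase` can be arbitrarily
close to 0; the divisor is floored at 0.05 dF/F0 (configurable) and a
per-repeat flag records when the floor binds.

**Per run** (4 repeats, one fly): field-wise medians (missing `tau_half`
excluded) and `R_within`, the mean of the 6 pairwise Pearson correlations
between repeat traces. Correlation type is configurable (rank correlation
available); Pearson is the default.

**Per pair** (one stimulation strength): run medians are aggregated within
fly first, then the median across flies is taken; `R_between` is the mean
pairwise correlation between per-run average transients with same-fly run
pairs excluded (it is a *between-fly* reliability); `R_state` correlates
per-fly `ItoPeak` with per-fly `Fbase` — one point per fly, matching its
role as an animal-level brain-state index.

**Scaling.** `ItoPeak` and `ItoPeak_norm` (run- and pair-level) are scaled
dataset-wide to [−1, 1]: positive values divided by the dataset maximum,
negative by the magnitude of the dataset minimum. The rule is idempotent
once the extrema are ±1 and maps a batch with both signs exactly onto both
endpoints.

# Anatomy: names, arbors, overlap

Cell types are named by their innervated regions with polarity suffixes
(`.s` spiny/postsynaptic, `.b` bouton/presynaptic), e.g.
`PBG2-9.s-FBl3.b-NO2D.b`. The parser splits on hyphens except inside
numeric ranges, expands PB glomerulus and FB layer ranges, lets bare tokens
inherit the nearest following suffix (names such as `LAL.s-IMP-FBl3.b` rely
on this), and treats wholly suffix-free names as both polarities. Irregular
historic names (ring neurons, the all-glomeruli PB interneuron, mixed-dot
names) are registered in the packaged catalog as curated overrides written
in the canonical grammar; these overrides are best-effort synthetic
annotations, since the finer subdivisions behind the original labels are
not published. The three-zone LAL subdivision is likewise not printed, so
the vocabulary accepts `LAL1`–`LAL3` for users who have a side table, with
a bare permissive `LAL` as the default (any LAL–LAL contact counts).

The overlap predicate is directional: pre-type *bouton* regions are
intersected with post-type *spine* regions, at glomerulus resolution in the
PB, layer resolution in the FB, and individual-nodulus resolution in the NO
(same nodulus number, compatible subcompartments; `NO2D` vs `NO2V` do not
overlap). EB and gall subdivisions are recorded but compared at
whole-region resolution — the published EB wedge/tile sectors interleave in
space, so token inequality there does not imply physical separation.
Non-overlapping pairs cannot be monosynaptically connected and therefore
serve as the screen's negative controls.

# Inference: robust distance to the null and its threshold

Each pair is a point x = (scaled `ItoPeak_norm`, `R_between`) in
[−1, 1]². The non-overlapping pairs form the null sample. Location μ and
scatter S of the null are estimated by the minimum covariance determinant
(MCD) estimator with support fraction 0.75 (`MASS::cov.rob`, 100 subset
candidates, fixed internal seed), so a few contaminated controls cannot
inflate the null. Every pair is scored by the squared Mahalanobis form

d(x) = (x − μ)ᵀ S⁻¹ (x − μ).

The squared form is reported as the connection *strength* throughout —
note that "Mahalanobis distance" conventionally denotes its square root.

**Significance.** The feature coordinates are far from Gaussian (the
dataset-wide scaling pins the most extreme pair at ±1; baseline-floored
normalization is heavy-tailed), so a χ²(2) cutoff is badly anti-
conservative and an empirical tail estimate is needed. The default scheme
is held-out subsampling: in each of B replicates (default 10,000),
d = max(2, ⌈0.05 n⌉) null points are held out, the MCD model is refitted on
the rest, and the held-out points' squared distances are pooled; the
significance threshold is the (1 − α) quantile of the pool (α = 0.01), and
a pair is called connected when its distance exceeds it. Holding out as few
points as possible keeps the per-replicate fit close to the full-sample
estimator, so the pooled tail estimates the null distance distribution
nearly unbiasedly; on all-null synthetic screens the flagged fraction is
statistically consistent with α (this calibration is exercised by the test
suite). The classic pair bootstrap — resample the null with replacement,
refit, pool the resampled points' distances — is kept as
`scheme = "resample"`, but is markedly conservative with a robust fit,
because duplicated points shrink the MCD scatter and inflate the pooled
tail several-fold; it is not the default for that reason. Empirical
p-values are computed against the pooled distances.

Classification defaults to the strongest stimulation protocol present
(30 pulses), configurable. Pairs with undefined `R_between` (a single
usable fly) are excluded from both null fitting and classification with a
warning. Each edge carries the squared distance (strength), the sign of
the scaled normalized integral, `R_between` (reliability), the
significance call, an empirical p-value, and a control flag; controls are
scored but never exported as network edges. No multiple-testing correction
is applied beyond the single resampling threshold.

# Numerical choices and degenerate inputs

* Trapezoidal integration on the uniform sampling grid.
* Peak ties resolve to the earliest sample.
* k-means uses Lloyd iterations from min/max centroids; a constant image
  is an error (no structure to segment).
* `fit_null` requires ≥ 5 points and rejects collinear null samples;
  singular covariances are an error in the distance computation.
* The resampling threshold requires B ≥ 1/α and fails if more than 20% of
  replicate refits degenerate.
* Pulse trains must be representable on the requested grid: each pulse at
  least one sample, adjacent pulses separated — otherwise an explicit
  undersampling error rather than a silently merged train.

# Problem sizes in the packaged checks

The packaged fixture screen is 30 pairs (10 candidates with 4 strong
excitatory, 2 inhibitory and 4 unconnected, plus 20 controls) × 6 flies ×
5 protocols × 4 repeats at 10 Hz; the calibration study in the test suite
uses 50 all-null screens of 60 control pairs each with B = 1000 replicates;
the χ² sanity check uses 10⁵ known-null points. These sizes were chosen to
give stable Monte-Carlo estimates at desk scale while keeping the default
test run fast.

# Known limitations

* Overlap labels derive from name strings plus curated overrides, not from
  registered image stacks; unpublished fine subdivisions (LAL zones, ring
  neuron sectors) are approximated permissively, so derived pair counts
  will not reproduce any specific published tally.
* The significance scheme estimates one global null tail; it does not model
  per-pair heterogeneity (e.g. differing fly counts) beyond what resampling
  captures.
* The generator's phenomenological kernels carry no biophysics (no opsin
  photocycle, no indicator Hill kinetics); dose-response curves across
  pulse numbers are only meaningful with the `saturation` ceiling enabled.
* Drug (pharmacology) comparisons are out of scope: the screen defines no
  formal pre/post-drug statistic.
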