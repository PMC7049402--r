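---
title: "Multimodal HRV features for congestive heart failure detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal HRV features for congestive heart failure detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvmodal)
```

## The problem

Congestive heart failure (CHF) depresses heart rate variability (HRV): the
beat-to-beat fluctuation of RR intervals that reflects autonomic control of
the heart. A recording is reduced to a *tachogram* — the sequence of RR
intervals in seconds — and the question is whether a battery of features
computed from that sequence separates CHF patients from subjects in normal
sinus rhythm (NSR). Because CHF alters several aspects of the signal at once
(overall variance, spectral balance, and dynamical complexity), the package
extracts four feature families and feeds them, singly or combined, to a
battery of standard classifiers evaluated under stratified 10-fold
cross-validation.

All recordings are truncated to a common length (20,000 beats by default,
`truncate_series()`) so that length-dependent features — notably the
unnormalised wavelet entropy functionals — are comparable across subjects.

## Feature families

**Time domain.** SDNN (population SD of all intervals), SDANN (SD of
5-minute-window mean RR, windows tiled on cumulative time, partial tail
dropped), SDSD (SD of successive differences), RMSSD (root mean square of
successive differences). All in seconds. Moments are population (1/N)
throughout the package; the sample convention is available via a `type`
argument but one convention had to be pinned for reproducibility.

**Frequency domain.** The tachogram is an unevenly sampled signal on its own
cumulative-time axis, so the default spectral estimator is the Lomb-Scargle
periodogram, computed on a uniform grid from 1/T to 0.4 Hz at the natural
resolution 1/T. Band powers are bin sums over the standard HRV bands — ULF
(0, 0.003], VLF (0.003, 0.04], LF (0.04, 0.15], HF (0.15, 0.40] Hz — which
partition the grid, so TP = ULF + VLF + LF + HF holds to rounding. LF/HF is
the usual sympathovagal balance proxy; when HF is exactly zero it is
reported as `Inf` and later winsorised (below). An alternative estimator
(cubic-spline resampling at 4 Hz, linear detrend, Hann-windowed Welch
averaging) is exposed as `method = "resample_welch"`; its total power
reproduces the band-limited signal variance to within a few percent.
Power units are arbitrary but consistent; only ratios and class contrasts
are interpreted.

**Statistical.** RMS, variance, skewness (`m3/m2^1.5`), kurtosis (`m4/m2^2`,
Pearson convention, Gaussian = 3 — not excess kurtosis), and a bounded
smoothness index `1 - 1/(1 + Var_ms)` evaluated on the series in
milliseconds. The millisecond scaling matters: with an SD of tens of
milliseconds the index saturates near 1 and differences live in the fifth
decimal, whereas evaluated in seconds it would sit near zero. The scaling is
explicit (`smoothness_scale`).

**Entropy.** Approximate entropy (ApEn) and sample entropy (SampEn) with
`m = 3`, `r = 0.15 * SD(x)`, Chebyshev metric — the canonical Pincus /
Richman-Moorman conventions: ApEn includes self-matches and averages
log-frequencies; SampEn excludes self-matches, counts template pairs, and
returns `-ln(A/B)`. Both are computed from KD-tree range counts: templates
are delay-embedded, a KD-tree with per-node bounding boxes is built, and a
Chebyshev ball query either absorbs or discards whole subtrees, scanning
only boundary leaves. This makes the quadratic pair count tractable at
20,000 beats. A direct O(N^2) implementation (`sampen_naive()`) is retained
and the two are held equal to 1e-12 in the tests over hundreds of random
instances — the tree must change the cost, never the count. Degenerate
tolerance (constant series, SD = 0) is guarded by an absolute floor
`r_floor = 1e-12`, under which both entropies are exactly 0 for a constant
series. When no templates match at all (e.g. a strict ramp with r below the
step), SampEn is reported as `Inf` with a warning and winsorised at table
assembly.

The five wavelet entropy functionals are additive per-sample costs:
Shannon `-sum(x^2 log x^2)` (0 log 0 = 0), log-energy `sum(log x^2)`,
threshold `#\{|x| > 0.2\}`, sure `n - #\{|x| <= 3\} + sum(min(x^2, 9))`, and
norm `sum(|x|^1.1)`. By default they are applied directly to the raw
tachogram: at RR scale this makes the threshold functional count essentially
every sample, the log-energy strongly negative, and the norm of order
`N * mean(RR)^1.1` — the magnitudes the analysis expects. Natural logarithms
are used (configurable via `log_base`); the choice of base rescales Shannon
and log-energy by a constant and affects no comparison. A
`wavelet_packet` mode decomposes the series first (hand-rolled periodised
Daubechies filter bank, since no wavelet package is available in the target
R environment); the transform is orthonormal — coefficient energy equals
signal energy to 1e-10 in the tests — but note that packet coefficients are
convention-dependent up to shifts and signs across implementations, which is
why the tests pin energy conservation and hand-computed Haar cases rather
than coefficient-by-coefficient equality with any particular library.

## The synthetic cohort

Real Holter cohorts cannot ship with a package, so `generate_cohort()`
emulates the study conditions: 72 NSR and 44 CHF subjects, 20,000 beats
each. The generator is deliberately the *smallest* model that spans all four
feature families — an amplitude-modulated oscillator plus noise, not an ECG
simulator:

RR(t) = mean_rr + slow drift (two sub-VLF sinusoids)
      + lf_amp sin(2 pi 0.10 t + phi_LF) + hf_amp sin(2 pi 0.25 t + phi_HF)
      + truncated white jitter,

with the oscillator phases re-randomised at a per-beat rate proportional to
an `irregularity` parameter. Noise is truncated at 4 SD so positivity of
every interval follows from
`mean_rr > slow_amp + lf_amp + hf_amp + 4 noise_sd`, which the constructor
enforces. Between-subject spread comes from lognormal jitter of the class
parameters (CV 0.12 on mean RR, 0.3 on modulation amplitudes, 0.25 on
noise), rescaled if a draw would break positivity.

The default class specs encode the clinically assumed contrasts, not any
particular dataset: NSR with mean RR 0.78 s, larger total variability
(SDNN ~0.08 s vs ~0.06 s), relatively stronger HF modulation (LF/HF below
1), and a high noise-to-SD ratio (hence higher SampEn ~2.1 vs ~1.7);
CHF with mean RR 0.66 s, depressed variability, LF-dominant balance
(LF/HF ~2.5), and a low noise share (reduced complexity). One calibration
subtlety: because the entropy tolerance is r = 0.15 SD, anything that
inflates a class's SD (such as a large slow drift) *loosens* its tolerance
and depresses its entropy; the slow-drift amplitudes (0.12 / 0.11 s) were
therefore chosen so the noise-to-SD contrast — and with it the SampEn
ordering — holds at the full 20,000-beat length, and they are not revisited.

What the generator does *not* emulate: ectopic beats and artefacts (so the
heavy-tailed kurtosis/skewness a real CHF cohort shows is absent), circadian
structure beyond a few slow sinusoids, respiratory frequency wander, and any
coupling between the oscillators. Passing tests on this cohort therefore
demonstrate that the pipeline recovers the *directions* it is built to
recover and that the machinery is correct end to end — they say nothing
about classification accuracy on clinical Holter data, and the package makes
no such claim.

## Classifiers and cross-validation

The battery mirrors the common "classification learner" presets
declaratively and binds them to established solvers: rpart for trees
(fine = deep, coarse = depth 2), libsvm via e1071 for the SVMs (polynomial
kernels with coef0 = 1; Gaussian kernels with the documented mapping
`gamma = 1/(2 * scale^2)` for kernel scales 0.61 / 2.4 / 9.8 on standardised
features), a small exact KNN (K = 3, Euclidean or cosine distance, ties
broken deterministically by index), randomForest with `mtry = d` for bagged
trees, and two hand-rolled ensembles with no R implementation on the target
system: a random-subspace linear discriminant (30 LDA learners on random
ceiling(d/2)-dimensional subspaces, averaged posteriors) and a RUSBoosted
tree (AdaBoost.M1 with per-iteration weighted undersampling of the majority
class, 30 depth-3 trees).

`crossvalidate()` stratifies folds by class (per-fold class counts within
one subject of proportionality), z-scores features using training-fold
statistics only — the held-out fold never touches the scaler, which the
tests assert by injecting an extreme-valued held-out subject — and produces
out-of-fold labels plus a continuous score oriented "larger = more
NSR-like". Whether features should be standardised at all is not specified
by convention everywhere; the package standardises, because fixed kernel
scales are meaningless on raw feature columns whose units differ by five
orders of magnitude. Every random choice (fold assignment, bootstrap, sub-
space, undersampling) derives from the single `seed` argument through fixed
integer arithmetic, so any result is exactly reproducible; no global RNG
state leaks (the generator saves and restores `.Random.seed`).

Infinite feature sentinels (LF/HF with zero HF, SampEn with no matches) are
winsorised to the finite column maximum at table assembly, with a message
per column, so the classifier input is always finite.

## Evaluation arithmetic

`confusion()` carries an explicit positive-class tag, because with
asymmetric cohorts the headline sensitivity/specificity depend on it:
TPR = TP/(TP+FN), TNR = TN/(TN+FP), PPV = TP/(TP+FP), NPV = TN/(TN+FN),
TA = (TP+TN)/N. Values are stored as full-precision proportions; display
rounds TA to one decimal and the rates to whole percent. The default
positive class is NSR, with a flag to flip; relabelling swaps (TPR, PPV)
with (TNR, NPV) and leaves TA unchanged, which is tested. AUC is the
tie-corrected Mann-Whitney rank statistic (equal to the trapezoidal ROC
area, invariant under monotone score transforms, and cross-checked against
pROC). The 95% CI is the textbook normal interval
`mean ± 1.95996 sd/sqrt(n)`; the package applies it to the per-fold accuracy
estimates, a choice that had to be pinned since a CI needs a replicate set
and the fold accuracies are the natural one here. Per-feature class
contrasts use Welch's unequal-variance t-test, with three significance
tiers (p < 1e-50, < 1e-25, < 0.01) rendered as stars.

## Problem sizes and numerical choices

The test-suite defaults were sized so the whole pipeline is exercised at
study scale exactly once (72 + 44 subjects at 20,000 beats for the
directional acceptance run, about 1.3 s per subject for all 22 features on
one core) while unit and property tests run on 300-4,000-beat series.
Property tests that compare entropies across signal types use 1,000-sample
series because ApEn's small-sample downward bias (sparse template matches at
m = 3) only vanishes a few hundred samples in. The Lomb grid uses the
natural resolution 1/T (oversampling configurable); the band integrals are
bin sums, so band additivity is exact by construction rather than a
numerical accident. The KD-tree recursion re-synchronises its complex phase
recurrences and bounding boxes from first principles often enough that all
oracle comparisons hold at 1e-12 absolute.

## Known limitations

- No ectopic-beat screening: the pipeline consumes NN/RR series exactly as
  given; any beat cleaning must happen upstream.
- Wavelet-packet entropies depend on filter alignment conventions and are
  not guaranteed to match other libraries coefficient-wise.
- The CI formula is a normal approximation on 10 fold estimates; it is the
  reporting convention of the analysis, not a recommendation.
- Synthetic-cohort accuracies characterise the generator, not clinical
  performance.
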