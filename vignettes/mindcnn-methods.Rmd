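---
title: "Methods: state-of-mind classification from wearable biosignals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: state-of-mind classification from wearable biosignals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mindcnn)
```

## The problem

`mindcnn` classifies a person's affective state — baseline, amusement, stress,
meditation, recovery — from simultaneous recordings of two wearable units: a
chest-worn pod sampling ECG, EMG and respiration at 700 Hz as 16-bit ADC
counts, and a wrist unit sampling blood volume pulse (BVP, 64 Hz), a triaxial
accelerometer (32 Hz) and EDA/temperature (4 Hz). A 700 Hz label stream
carries the class schedule, with a sentinel `-1` for unlabeled spans. The
reference cohort for this layout is the public WESAD wearable stress/affect
dataset (15 subjects, roughly 100 minutes each); the package ships a
synthetic generator emulating those streams so every stage runs, and is
tested, without any download.

## Signal conditioning

**Unit conversion.** Chest ADC counts map affinely to SI units:
ECG `(raw/2^16 - 0.5) * 3` mV, EMG the same form in microvolts, respiration
`(raw/2^16 - 0.5) * 100` percent displacement. Midscale (`2^15`) is exactly
zero — the only bracket reading consistent with bipolar ECG/EMG physics. The
wrist accelerometer reports units of 1/64 g and is scaled by `9.81/64`
m/s^2 per count; the scale is configurable because published descriptions of
this conversion vary (a literal `2 * 9.8128` factor circulates, which is
dimensionally inconsistent with the stated 1/64 g resolution). BVP and
temperature already arrive in physical units and pass through unchanged, as
do the chest accelerometer and EDA, which have no published conversion and
feed no model channel.

**Rate harmonization.** All streams are first brought to the 700 Hz common
grid. Sub-700 Hz streams are upsampled by linear interpolation onto the
common time grid (`t = j/700`), which handles the non-integer 32 -> 700
ratio and passes native samples through exactly; a zero-order hold is
available by configuration. Everything is then reduced to 10 Hz by
aggregating non-overlapping 70-sample blocks: signals by the mean (median
optional — the aggregation statistic is not pinned down by the source
description, and both are supported), labels by the block mode. Mode ties
break to the lowest class index for reproducibility; the sentinel is ignored
unless a block is entirely unlabeled. Trailing partial blocks are dropped,
never padded. A limitation to note: a linear interpolant localizes a peak
only to the nearest native sample, i.e. to half the native spacing
(~16 ms for 32 Hz input), which is irrelevant at the 10 Hz analysis rate.

## Feature engineering

Twenty-eight features in five channel blocks — ECG 4, EMG 3, respiration 3,
BVP 3, accelerometer 15.

**Peak-based minute features** (ECG/EMG/RESP/BVP). A sample is a peak when it
strictly exceeds its left neighbour, is at least its right neighbour, and
exceeds `mean + k * sd` of its minute (default `k = 1`); peaks closer than a
refractory distance are thinned keeping the larger amplitude (ties keep the
earlier index). The distances default to 3, 2, 10 and 3 samples at 10 Hz for
ECG, EMG, respiration and BVP — physiologically motivated (minimum RR
interval ~0.3 s; maximum ~60 breaths/min) since no values are published —
and are configurable. Per complete minute (600 samples) each signal yields
the peak count, mean peak amplitude, and the mean *absolute* successive
peak-amplitude difference (a signed mean would telescope to a degenerate
endpoint difference); ECG adds the mean peak count per 1 s window. Minutes
with no peaks report zeros rather than missing values, keeping the matrix
dense. Features broadcast to every sample of their minute.

**Subject-level accelerometer statistics.** Per axis: mean, population
standard deviation, excess kurtosis, crest factor; per axis pair: a
correlation. Two quirks of the published formula set are handled
deliberately: the correlation is a `1/(N-1)` mixed moment over *population*
standard deviations, which can exceed |1| and is clipped to `[-1, 1]`
(standard Pearson available via `method = "pearson"`); the kurtosis is
implemented with the standard sigma^4 denominator because the printed
sigma^2 form is dimensionally inconsistent (`kurtosis = "printed"` restores
it). The crest factor divides the axis maximum by the RMS of the raw,
uncentred signal with an `N - 1` normalizer, so a constant signal has crest
`sqrt((N-1)/N)`. All 15 numbers broadcast to every sample of their subject.
The wrist accelerometer, not the chest one, feeds this block.

## The multichannel network

Each channel block enters its own branch so early feature learning never
mixes modalities: two valid (unpadded, stride-1) 1-D convolutions of 128
then 64 filters with **no pooling between them** (the features' numerical
values matter more than spatial arrangement, and subsampling would discard
information), then flatten, dropout, dense 64, dropout, dense 32, all ReLU.
The five 32-unit branch outputs concatenate into a 160-wide vector feeding a
dense 32 layer and a 5-way softmax.

The convolution kernel length adapts to the branch's input width `x` as
`k = ceiling(x/2)` — the unique rounding of the published half-width rule
consistent with all five kernel shapes it reports (x = 3 -> 2, 4 -> 2,
15 -> 8). With that rule the second convolution's output length
`x - 2k + 2` is always 1 or 2, so the geometry is valid for any feature
count. `count_parameters()` and `forward_shapes()` audit the structure
without training; the test suite pins every published per-layer parameter
count (e.g. ACCL first conv `128*8 + 128 = 1152`, ECG second conv
`64*2*128 + 64 = 16448`) and output dimension.

Unpublished details resolved here: dropout rate 0.25 (configurable),
applied only where the layer listing shows it (after flatten and after the
first dense layer of each branch, not in the trunk); Glorot-uniform
initialization with a seedable RNG; valid padding and stride 1, the only
combination reproducing the published output dimensions.

The forward pass, backpropagation and the Adam/RMSprop/SGD optimizers are
implemented in the package in plain R matrix arithmetic (the branch
geometries are tiny, so im2col-style position loops suffice); gradients are
verified against central finite differences to ~1e-10 in the tests.

## Training regimes and loss

**Type I** assigns samples uniformly at random: 70% train, 20% validation
(round half up), remainder test. **Type II** is leave-one-subject-out: the
held-out subject is the entire test set and the rest splits 80:20. Both are
deterministic given a seed; the suite checks the published cohort's exact
split sizes (e.g. 880,590 -> 616,413 / 176,118 / 88,059) and zero subject
leakage per fold. The published per-channel sample table implies an 880,590
pool while the preprocessing narrative states 573,480 — the package takes
`n` from its input and supports both; the discrepancy is inherent to the
source material.

The loss is categorical cross-entropy over softmax outputs; zero predicted
probability at a true class is clipped at 1e-12 with a warning rather than
raising. The default optimizer configuration is Adam with the tuned values
learning rate 0.00125, beta_1 0.9765841, beta_2 0.8541287, decay 0.000235
(applied as `lr/(1 + decay * step)`); for RMSprop/SGD only the learning rate
and decay apply. Batch size (unpublished) defaults to 256. Features are
z-scored with training-set statistics by default, since counts per minute
and millivolt amplitudes differ by orders of magnitude. Class imbalance is
left unaddressed by default, replicating the source setup; a `class_weights`
option exists.

A dynamics note: on synthetic cohorts the minute-broadcast features make
many rows near-duplicates, so the task saturates to zero loss within a few
epochs, after which Adam's scale-invariant updates can drift weights and
eventually destabilize very long runs. The package's tests therefore use
budgets of 8–30 epochs, at which training is stable and converged; real
heterogeneous data does not saturate this way.

## Hyperparameter search

`smbo_search()` maximizes a black-box objective (here: validation accuracy)
sequentially: a Latin-hypercube initial design, then per iteration a
Gaussian-process surrogate (Matern 5/2 kernel on the unit cube, lengthscale
chosen from a small grid by marginal likelihood, outputs standardized) and
the closed-form expected improvement
`EI = (mu - f*) Phi(z) + sigma phi(z)` maximized over 1024 fresh
Latin-hypercube candidates — cheap and derivative-free. The surrogate family
is not pinned down by the source description beyond a Bayes-rule sketch; the
GP interface is internal so a density-ratio (TPE-style) surrogate could be
swapped in. Failed objective evaluations are recorded and skipped. The
search space covers learning rate (log scale, 1e-5 to 1e-2), the two betas
and the decay. Tests verify the EI closed form against Monte-Carlo, recovery
of a quadratic optimum, determinism, and that the guided search beats random
search at equal budget in at least 80% of seeded repetitions.

## Evaluation

`confusion_matrix()` and `classification_report()` produce per-class and
macro precision/recall/F1 plus accuracy. Macro averages are unweighted means
across classes; zero-denominator metrics report 0 with an explicit flag
(never NaN) and zero-support classes are excluded from the macro mean.
Prediction is softmax argmax; an optional per-class threshold vector can
exclude low-probability classes from the argmax but defaults off.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws per-subject recordings whose class effects enter
only through interpretable parameters: heart rate drives ECG/BVP pulse
trains (a von-Mises-shaped bump per cycle), respiration rate a sinusoid,
EMG burst rate/amplitude Poisson-timed activity bursts over baseline noise,
and an activity SD the wrist accelerometer. Chest streams are emitted as
ADC integers so the conversion path is on the tested route. Defaults mirror
the reference cohort: 15 subjects, 100 minutes each, class time shares
equal to the published class distribution (47.9 / 20.4 / 11.4 / 6.5 /
13.8%), resting-range rates at baseline with elevated rates under stress,
and 5% inter-subject parameter jitter. Class segments are whole minutes
(largest-remainder rounding): because all peak features are minute-based,
sub-minute segments would be unresolvable by construction, and minute
alignment keeps every analysis minute single-class.

The generator does **not** produce realistic ECG morphology (no P-QRS-T
complexes), motion artifacts, sensor drift, or within-class
non-stationarity. Passing tests therefore demonstrate that the pipeline's
mechanics — conversion, resampling, feature extraction, training,
evaluation — are correct and that the model learns class-conditional rate
structure; they say nothing about headline accuracy on real recordings,
which is why the published test metrics are not reproduction targets here.

## Problem sizes used by the test suite

Structural audits run on the full five-channel architecture (<1 s). The
end-to-end check trains on a 3-subject, 10-minutes-per-subject cohort
(18,000 samples) for 8 epochs — chosen as the smallest configuration in
which every class occupies at least one full minute per subject — under
well-separated study conditions (every pairwise heart-rate and respiration
ratio >= 20%, the separation regime in which macro recall >= 0.9 is the
documented expectation). Continuous-feature training properties use
Gaussian-blob datasets with ~3 pooled-SD class separation. The proportion
check uses 3 subjects at 50 minutes, where whole-minute rounding keeps every
class share within 2% of its target.
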