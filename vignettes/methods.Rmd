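---
title: "Simulated psychophysics of mirror versus glass: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated psychophysics of mirror versus glass: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mirrorglass)
```

## The problem this package addresses

Telling a polished mirror object from a colorless glass one is a classic
material-perception puzzle: both kinds of image are deformed pictures of
the surrounding scene, and no single pixel is diagnostic. A productive way
to study how people solve it is to build image-computable classifiers,
score every image on a 0 (glass) to 1 (mirror) continuum, and ask how well
the model's per-image scores track human judgments — not just whether both
are accurate, but whether the model reproduces the *pattern of human
errors*. That comparison needs a stimulus set in which human judgments are
consistent across observers yet decorrelated from the ground-truth label
(a "diagnostic" set), which in turn needs a multi-round psychophysical
filtering pipeline.

`mirrorglass` re-implements that entire machinery as a fully simulated,
seed-deterministic pipeline: stimulus generation, observer simulation, the
selection rounds, classifier training, representational similarity
analysis (RSA), a human-correlation hyperparameter search over network
depth, and the interpretability analyses. Everything runs from code; no
external data are downloaded.

## The synthetic stimulus world

A stimulus is a 64 × 64 RGB image with a latent appearance parameter
$a \in [0,1]$ (0 = fully glass-like, 1 = fully mirror-like). The carrier
is band-pass filtered Gaussian noise (log-Gaussian annulus centred on 8
cycles/image, amplitude `texture_amp`, default 0.15 luminance sd),
deterministic in the spec's `texture_seed`. Four cues are planted on top,
each scaled by the signed appearance $2a - 1$:

* **vertical luminance gradient** (`gradient`): an antisymmetric ramp
  (+0.5 at the top row, −0.5 at the bottom), so mirror-like images are
  brighter in the upper half and glass-like images brighter in the lower
  half;
* **contrast** (`contrast`): a multiplicative gain on the carrier;
* **saturation** (`saturation`): a red/blue channel offset;
* **mean luminance** (`luminance`): a global brightness shift, so
  mirror-like images are slightly brighter on average.

These are exactly the regularities the downstream analyses are designed to
discover (the classifiers, the class-activation maps, the inversion test);
the generator plants them, it does not imitate physically based rendering.
A `conflict` stimulus carries a label that disagrees with its appearance
(the cues always follow $a$, never the label) — the simulated analogue of
an illusory image.

Default appearance distributions: mirror $a \sim U(0.6, 1)$, glass
$a \sim U(0, 0.4)$, and the ambiguous classes (the stand-in for
generative-model images of intermediate appearance) $a \sim U(0.3, 0.7)$.

## The simulated observer

Psychophysical reports of this kind publish only behavioural aggregates,
so the observer is a latent-evidence model chosen as the simplest mechanism that
can reproduce both a bimodal rating distribution for extreme stimuli and a
10-of-10 between-observer consistency criterion:

* percept $= a + \varepsilon$, $\varepsilon \sim N(0, \sigma_{obs})$;
* 5-point rating: the percept binned into fifths of $[0,1]$ (half-open
  bins, last bin closed; ratings normalize to $(k-1)/4$);
* three-way task: "hard to recognize" with probability $p_{hard}$,
  otherwise mirror iff percept $\ge 0.5$ (the boundary goes to mirror);
* recognizability: a Bernoulli draw from a per-stimulus planted
  probability;
* with probability `lapse_rate` any response is uniform at random.

With $\sigma_{obs} = 0$ and no lapses, every observer gives the same
response to a given image — which is what makes exact selection-round
counts and the consistency criterion attainable by construction. The
defaults are calibration knobs of the simulation, not estimates of real
observers.

Crowdsourcing sessions assign 98 test images per worker in balanced
shuffled blocks (so planted worlds control the exact per-image rating
count) plus two extreme-appearance catch images; a worker passes a catch
iff the binary class of their rating matches the catch's ground truth, and
rejected workers' test ratings are excluded downstream.

## Features and classifiers

**Color-Hist** is exactly 8 numbers: mean, population variance, skewness
and excess kurtosis of the intensity plane ($\overline{RGB}$) and of the
HSV-style saturation plane ($(\max - \min)/\max$, 0 where $\max = 0$);
zero-variance planes yield skewness = kurtosis = 0 by convention.

**Texture statistics** come from a complex steerable pyramid built in the
frequency domain at full resolution (no downsampling), which makes every
spatially averaged statistic exactly invariant to circular shifts. The
families, in fixed documented order: pixel marginals (6), high-pass
variance (1), low-pass skew/kurtosis (2) and central autocorrelation
($n^2$), subband magnitude means ($SO$) and autocorrelations ($SOn^2$),
within-scale cross-orientation correlations ($S\binom{O}{2}$),
adjacent-scale magnitude correlations ($(S-1)O^2$) and adjacent-scale
phase-doubling statistics ($(S-1)O$). The vector length is a closed form
of the configuration (`texture_feature_length()`); the classic
implementation's exact dimensionality depends on a pyramid configuration
that is not part of this package's contract, so the count is configurable
rather than fixed.

Both feature sets are z-scored (population sd; constant columns map to 0)
and the texture features reduced by PCA to the smallest dimension reaching
a cumulative explained variance of 99%, fitted on the complete image set
before classifier cross-validation. Classifiers are plain binomial GLMs;
scores in $[0,1]$, 0.5-or-greater classified as mirror.

The **CNN** family is parametric in depth $d \in \{1..12\}$: $d$ blocks of
convolution → batch normalization → ReLU → max pooling, with pooling only
in the last $\min(d, 3)$ blocks, then either a flatten head
(FC(`fc_units`) → ReLU → dropout → FC(2) → softmax) or a
global-average-pooling (GAP) head (dropout → FC(2) → softmax) used for
class-activation mapping. Eleven hyperparameters control architecture and
training: `filters_base`, `filter_growth`, `kernel_size`, `pool_size`,
`fc_units`, `dropout_rate`, `init_learning_rate`, `momentum`,
`l2_penalty`, `batch_size`, `lr_decay`. Training is SGD with momentum, L2
weight decay and per-epoch exponential learning-rate decay; validation
accuracy is checked once per epoch and training stops after 3 validations
without improvement, restoring the best-validation weights.

Two numerical choices matter at desk scale. First, *precise batch-norm
calibration*: with few SGD steps per epoch, exponentially averaged BN
statistics lag the fast-moving activations and eval-mode predictions can
collapse; before every validation the running statistics are therefore
replaced by full-batch statistics computed over (up to 256 of) the
training images. Second, the engine is plain R plus two compiled
`im2col`/`col2im` kernels; convolutions are BLAS matrix products, which
keeps a desk-scale training run in seconds.

The evaluation protocol is repeated two-fold cross-validation: each repeat
draws a fresh stratified 50/50 split, every image is scored exactly once
per repeat as a test item, and final scores are per-image means across
repeats.

## The diagnostic-set pipeline

Normalized ratings are binned into fifths (half-open, top-closed — the
printed selection ranges like "0.0–0.4" are read as $[0, 0.4)$ and
"0.6–1.0" as $[0.6, 1]$). The rounds:

* **A1** excludes images whose majority three-way judgment is "hard" and
  samples an equal quota from each of the four cells of true class ×
  judged class;
* **A2** keeps images with ≥ 3 accepted crowd ratings and selects mirror
  images with mean rating in $[0, 0.4)$ and glass images in $[0.6, 1]$;
* **A3** re-rates candidates in the laboratory (3 trials × 10 observers)
  and keeps mirror with mean in $[0, 0.6)$, glass with mean in $[0.4, 1]$;
* **B1** keeps generative-class images judged recognizable by ≥ 6 of 10
  observers;
* **B2** samples an equal per-bin quota among images all 10 observers
  place in the same bin.

Assembly combines veridical members (consistent images whose bin matches
their class), illusory members (A-track survivors, balanced per class ×
bin cell) and ambiguous members (B-track), and certifies two properties:
*flatness* (equal bin counts within each rendering class — violation is an
error carrying the count table) and *decorrelation* (the Pearson
correlation between binary true class and mean rating over renderings,
reported as `decorrelation_r`). In the noiseless planted worlds the
printed quotas are reproduced exactly (10,976 / 522 / 102 / 500 / 95 /
265 / 170) and the decorrelation is exactly zero; with
$\sigma_{obs} = 0.05$ the candidate pools are planted over-full, cells are
filled by measured bin, and the decorrelation stays below 0.05.

## Hyperparameter search and the depth sweep

The search objective is the Pearson correlation between a trained model's
diagnostic-set scores and the simulated observers' mean ratings; an id
audit guarantees no diagnostic image ever enters a training fold. Each
trial trains with two-fold cross-validation on the pool; the two fold
models score the diagnostic images and their scores are averaged.

The search strategy is a deliberately simple, deterministic sequential
model-based optimizer: a random warm-up, then candidates drawn half from
the prior and half as local jitters of the incumbent, scored by a
3-nearest-neighbour inverse-distance prediction plus a small exploration
bonus; `strategy = "random"` is the uniform-sampling fallback. The
original work used a proprietary Bayesian optimizer whose internals are
unavailable, so fidelity here is to the interface (iteration budget,
objective, trace) rather than to a specific surrogate.

One honest caveat, measured during development: with desk-scale training
pools the per-trial objective is dominated by training stochasticity
(repeat evaluations of one setting vary by several tenths of a correlation
point) and the attainable optimum is reached by a handful of random draws,
so surrogate-versus-random comparisons with the CNN in the loop are
uninformative at this scale. The surrogate-beats-random property is
therefore asserted on a controlled objective with a known optimum, and the
CNN-in-the-loop path is exercised by the depth sweep instead.

The depth-sweep world plants a *mid-level, second-order* cue: contrast
(`contrast = 0.5`) with almost no gradient and no saturation or luminance
offset, and partially overlapping appearance ranges. Detecting a contrast
difference requires rectification, which a deeper stack supports better
than a single block, so the best human-correlation depth lands at 2–3
rather than 1 — the scaled-down analogue of the published depth profile.

## RSA, noise ceiling, MDS

First-stage representational dissimilarity matrices (RDMs) are absolute
differences of scalar prediction scores (or Euclidean distances between
flattened activations for network stages); the human RDM uses mean
normalized ratings. The second-stage classifier dissimilarity matrix (CDM)
is one minus the Pearson correlation between RDM upper triangles (range
$[0, 2]$), with 10 uniform-score random RDMs appended as the chance
reference. MDS is classical (metric) scaling via `stats::cmdscale`;
explained variance is the retained share of positive eigenvalues. The
noise ceiling is the mean leave-one-out correlation between each observer
and the mean of the others; for a signal+noise observer
($x_i = s + \varepsilon_i$) it has the closed form
$v_s / \sqrt{(v_s + v_n)(v_s + v_n/(m-1))}$, which the tests verify by
simulation.

## Interpretability

`compute_cam()` implements the raw per-unit class activation map (final
convolutional maps weighted by a class unit's GAP-head weights, bilinearly
upsampled). For *class-mean* analyses the raw per-unit map is unusable:
with a two-unit softmax the head is only identified up to a component
shared by both class columns, so per-unit mean maps depend on the random
initialization. `class_mean_cam_difference()` therefore uses the
gauge-invariant discriminant weights $w_{mirror} - w_{glass}$ ("net mirror
evidence"), averaged over each class's own images; identical image sets
then give an exactly zero difference, and the result is deterministic
across initializations.

Two architecture facts shape the analyses. A GAP-head network is spatially
translation invariant, so (i) it can only learn the gradient world when a
translation-invariant cue exists — the interpretability world therefore
combines the antisymmetric gradient (`gradient = 0.5`) with a small
luminance offset (`luminance = 0.1`) — and (ii) it cannot exhibit an
inversion effect; the inversion test is accordingly run on the standard
flatten-head CNN, which does rely on vertical position and loses accuracy
on upside-down images in every seed tested.

The noise-robustness curve adds per-channel Gaussian pixel noise (clipped
to $[0,1]$; the sigma grid defaults to a log sweep over $10^{-3}..10^0$),
scores the perturbed images and reports the mean and Monte-Carlo sd of the
correlation with the unperturbed reference ratings.

## What a green test establishes — and what it does not

The synthetic worlds plant exactly the regularities the analyses probe.
Green tests therefore establish that the machinery is implemented
correctly (counts, certificates, invariances, recovery of planted
parameters), not that the conclusions transfer to rendered or natural
images: the generator has no object shape, no illumination structure
beyond a vertical ramp, no rendering artifacts, and observer noise is
homogeneous across images. Published headline values that depend on the
real human data (accuracies, specific correlations and dissimilarities)
are deliberately out of scope; the acceptance suite checks the printed
pipeline quotas exactly and the qualitative phenomena as scaled-down
analogues.

## Known limitations

* The CNN engine is single-threaded R + BLAS; it is meant for desk-scale
  experiments (hundreds to a few thousand 64 × 64 images), not the
  original training scale.
* The steerable-pyramid statistics are computed at full resolution; they
  are shift-exact but not identical to the classic decimated
  implementation, and the published feature count is not reproducible
  because the original pyramid configuration is unavailable.
* The surrogate optimizer is a nearest-neighbour heuristic; it is
  reproducible and beats random search on smooth objectives, but it is
  not a calibrated Bayesian optimizer.
* Images are written as plain-text PPM (P3) rather than PNG, keeping the
  artifact chain text-only.
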