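---
title: "Wavelet scalogram deep learning for resting-state EEG screening: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wavelet scalogram deep learning for resting-state EEG screening: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parkwave)
```

## The screening problem

Resting-state EEG carries spectral signatures of Parkinson's disease (PD):
compared with healthy controls (HC), patients show elevated theta power and
reduced beta and gamma power, with partial normalization under dopaminergic
medication. `parkwave` implements a screening pipeline that turns these
diffuse spectral differences into an image-classification problem:

1. **Time–frequency transform.** Each EEG channel is mapped to a continuous
   Morlet wavelet scalogram, the magnitude $|X(s,\tau)|$ of
   $X(s,\tau) = \tfrac{1}{\sqrt{s}} \int x(t)\, \psi^*\!\big(\tfrac{t-\tau}{s}\big)\,dt$
   over a grid of scales $s$ and all sample shifts $\tau$.
2. **Tiling.** The per-channel magnitude matrix is min–max scaled to
   $[0,1]$ and cut into non-overlapping $128 \times 128$ grayscale tiles
   (the 128 lowest scales of a 138-scale grid; the final partial window is
   dropped).
3. **Classification.** A 20-layer convolutional network assigns each tile to
   HC (0), PD off medication (1), or PD on medication (2); three
   experiments are supported (HC vs OFF, OFF vs ON, three-class).
4. **Evaluation.** Subject-wise $k$-fold cross-validation (folds are sets of
   patients, never sets of tiles) with accuracy, sensitivity, specificity,
   ROC/AUC and quadratic weighted kappa, reported per fold, as cross-fold
   means, and pooled.
5. **Explanation.** Grad-CAM heat maps at the last max-pooling layer show
   which time–scale regions drove each decision.

## Morlet CWT: parameterization and numerics

The analysis wavelet is the complex Morlet
$\psi(u) = \pi^{-1/4} e^{i\omega_0 u} e^{-u^2/2}$ with center-frequency
parameter $\omega_0 = 6$ (the common default; configurable). With scales
measured in samples, the equivalent Fourier frequency is
$f = \omega_0 f_s / (2\pi s)$, so scale and frequency are reciprocal:
"low scales" are high frequencies.

Choices the transform makes, and why:

* **Scale grid** (`default_scale_grid()`): 138 geometrically spaced scales
  whose equivalent frequencies span 1–60 Hz at 512 S/s. The grid size is
  fixed by the pipeline's tiling convention (128 kept of 138); the span
  covers the delta through gamma bands that carry the PD contrast. The
  consecutive-scale ratio is constant, so "within one grid step" is a
  well-defined localization tolerance (about 3% in frequency).
* **Truncation**: each wavelet is truncated at 4 standard deviations of its
  Gaussian envelope; signals shorter than the largest wavelet's support are
  rejected rather than silently degraded.
* **Boundaries**: FFT-based linear convolution with zero padding; boundary
  columns are retained (no cone-of-influence trimming), so the magnitude
  matrix has exactly one column per input sample and tiling arithmetic is
  exact: `floor(n_samples / 128)` tiles per channel.
* **Scaling**: min–max normalization of the whole recording-channel matrix
  (not per tile), so all tiles of a recording share one intensity frame.
  A constant matrix maps to all zeros — the explicit degenerate rule. The
  map is idempotent.

The implementation is verified against an independent direct-convolution
oracle, against exact linearity/homogeneity identities (relative error
below $10^{-9}$), and against tone localization at 5/10/20/40 Hz to within
one grid step.

## The classifier

The `"deep"` preset of `cnn_spec()` is the full 20-layer network: three
blocks of four same-padding convolution + ReLU layers (11×11×32, 9×9×64,
7×7×128) each closed by a 2×2 max-pool, so spatial size runs
128 → 64 → 32 → 16, then fully connected ReLU layers 128, 64, 32, 16 and a
SoftMax output. The audit convention counts 12 convolutional + 3 pooling +
5 fully connected layers = 20 (the input is not counted);
`cnn_audit()` and `describe_cnn()` emit the accounting so it is checkable
rather than implicit.

Because no deep-learning framework is available to R in this package's
dependency footprint, the forward and backward passes are implemented in
compiled code (RcppArmadillo). Convolutions use a shift-and-add
decomposition — one BLAS multiplication per kernel offset against a shifted
copy of the image — which keeps memory flat (no im2col buffers) and is fast
for the large kernels used here. Gradients are verified against central
finite differences in the test suite.

Training follows the study regime by default: plain SGD (no momentum, no
weight decay; both exist as `train_config()` options with default 0),
mini-batches of 50 shuffled tiles, learning rate $10^{-5}$,
cross-entropy on the SoftMax outputs, 40 epochs, no augmentation, no early
stopping. The final short batch is used, not dropped. Weight
initialization is unspecified in the source description; He-uniform with
zero biases is used, seeded, so two builds from one seed are bit-identical
and training is reproducible. Decision rule: binary models label a tile
positive when $P(\text{positive}) \ge$ threshold (default 0.5 — the source
never quantifies its "appropriate threshold", so this is a package
decision); multi-class models take the arg-max with lowest-index
tie-break.

The `"small"` preset is a reduced-scale network of the same design
pattern — a 4×4 max-pooling stem followed by 5×5×12 and 3×3×16 convolution
blocks and a 32-unit head — for desk-scale experiments where the full
network's cost is not the question being asked. It is what the acceptance
experiments train; the deep preset is the default everywhere else.

## Evaluation

Fold assignment is by patient identity, stratified by the subject's class
set, so PD subjects keep their OFF and ON recordings on one side of every
split; `audit_subject_folds()` re-derives membership from the prediction
log and fails loudly on any leakage. Each fold trains a freshly
initialized model — required for valid cross-validation even though rarely
stated.

Metrics: accuracy is trace/total exactly; binary sensitivity and
specificity use PD as the positive class; zero denominators yield `NA`
rather than 0. Three-class runs report one-vs-rest sensitivity/specificity
per class plus macro averages, and macro one-vs-rest AUC. ROC curves come
from a threshold sweep over the unique scores with trapezoidal
integration, which equals the pairwise rank statistic with ties counted
one half (verified against an $O(n^2)$ oracle). The weighted kappa uses
quadratic weights $w(i,j) = (i-j)^2$; the linear form $|i-j|$ is available
behind a flag. Because published tables do not say whether they average
fold metrics or pool confusion matrices, both views are computed and
labelled.

## Grad-CAM at desk scale

`gradcam_map()` implements standard gradient-weighted class activation
mapping at the last max-pooling layer: per-feature-map weights are the
global spatial average of $\partial y_c / \partial A_k$, the weighted sum
over feature maps is ReLU-rectified, bilinearly upsampled to tile size and
min–max scaled for display. The class score $y_c$ is the pre-SoftMax logit
by default; `use_probability = TRUE` substitutes the SoftMax output, whose
gradient is proportional to the logit *difference* — the quantity a binary
SoftMax actually identifies.

Two limitations of the method itself matter when validating it on small
networks, and shaped the package's planted-feature experiment (a 32×32
block covering 1/16 of the tile, dim in one class and bright in the
other, on a black background):

* The global average pool assumes class evidence is *channel*-coded. On a
  barely-trained or perfectly saturated toy model, the head's weights
  remain near their random initialization, and the averaged gradients
  inherit that noise. The experiment therefore trains its detector to an
  interior optimum: the two classes' intensity ranges overlap slightly so
  the loss never saturates, and a small L2 penalty (`weight_decay`)
  shrinks weights that carry no evidence.
* ReLU rectification shows only excitatory evidence. A binary network is
  free to encode "bright block" as inhibition of the other class, in which
  case that class map is legitimately empty; the localization check drops
  such maps (they are rare at the experiment's settings) rather than
  reading noise.

With those conditions, the top-decile heat mass of the bright-block class
map concentrates on the planted block (roughly 65–80% of the mass on 1/16
of the area) across seeds.

## The synthetic cohort generator

The generator exists so the full pipeline is buildable and testable
without any data download. Each channel is a $1/f^\alpha$ background
(unit-variance, spectrally shaped white noise, $\alpha = 1$) plus
band-limited sinusoidal oscillators (three per band, random frequencies and
phases within the band, amplitudes scaled so band power is independent of
the oscillator count) plus white noise (SD 0.5). Class contrasts follow
the reported PD signature: relative band amplitudes for HC are
delta 1, theta 1, alpha 1.2, beta 0.8, gamma 0.4; PD-OFF doubles theta and
halves beta and gamma (`"moderate"`), or quadruples theta and quarters
beta/gamma (`"strong"`, used in reduced-scale separability experiments);
PD-ON sits at the geometric midpoint between HC and PD-OFF, reflecting
partial normalization under medication. The default cohort layout mirrors
the study conditions: 16 HC and 15 PD subjects (each PD subject yields an
OFF and an ON recording — 46 recordings), 32 channels, 512 S/s, 120 s.

What the generator does **not** emulate: artifacts (eye blinks, muscle),
nonstationarity beyond band mixing, phase–amplitude coupling, inter-channel
covariance structure, or session/washout effects (ON and OFF are drawn as
independent spectra). Passing tests on synthetic cohorts therefore
demonstrate that the pipeline's machinery is correct and that it can
recover a known band-power contrast at realistic sizes — they do not
certify the headline performance on real recordings, which would require
the public dataset and full-scale training.

## Problem sizes for the desk-scale experiments

The reduced-scale separability experiment uses 8 HC + 8 PD-OFF subjects,
60 s of one channel each (240 tiles per subject, 3,840 tiles), subject-wise
4-fold cross-validation, and the small preset trained for 5 epochs at
learning rate 0.05 — sizes chosen so the whole experiment, plus its
label-permuted control, runs comfortably on a laptop-class single core.
The permutation control re-runs the identical pipeline after permuting
class labels across subjects; because tiles are strongly correlated within
a subject, chance agreement is judged against the subject-level standard
error (the effective sample size is 16 subjects, not 3,840 tiles).

## Known limitations

* The published per-class matrix widths (96,768 and 97,792 columns) do not
  reconcile exactly with the published image totals for 16/15 subjects at
  one channel; tile counts here are always derived from the data, never
  hard-coded.
* The BrainVision reader covers the binary multiplexed/vectorized dialects
  (float-32, int-16) used by BIDS EEG exports, not the full format.
* No preprocessing (filtering, re-referencing, artifact rejection) is
  applied before the CWT, matching the source pipeline; a clean insertion
  point is to transform `rec$samples` before calling `scalogram_tiles()`.
* Training on the full 20-layer network at published scale (tens of
  thousands of tiles, 40 epochs, per channel, per fold) is supported but
  slow on a single CPU; the reduced preset exists precisely so the
  pipeline's claims stay testable at desk scale.

## A worked desk-scale run

```{r example, eval = FALSE}
library(parkwave)

cohort <- generate_cohort(
  cohort_spec(n_hc = 8, n_pd = 8, duration_s = 60, fs = 512,
              n_channels = 1, seed = 100),
  default_class_spectra("strong"))
tiles <- do.call(c, lapply(
  Filter(function(r) r$class_label %in% 0:1, cohort),
  scalogram_tiles, channels = "Fp1"))

cv <- cross_validate(tiles, "hc_vs_off", k = 4, spec = cnn_spec("small"),
                     config = train_config(batch_size = 50,
                                           learning_rate = 0.05,
                                           epochs = 5, seed = 1),
                     seed = 42)
cv
```

The same experiment, together with the bundled worked-example confusion
matrices and the Grad-CAM localization check, is what
`scripts/acceptance.R` recomputes end to end.
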