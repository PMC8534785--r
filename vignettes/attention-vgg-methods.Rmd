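---
title: "Attention-gated VGG16 for breast-ultrasound lesion classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-gated VGG16 for breast-ultrasound lesion classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attnvgg)
```

## The problem

Benign and malignant breast lesions look different on ultrasound — benign
masses (typically fibroadenomas) tend to be smooth, oval and mildly
hypoechoic, while malignant masses (typically infiltrating ductal
carcinomas) tend to be larger, markedly hypoechoic, and to carry irregular,
spiculated margins — but speckle noise, shadowing artefacts and low contrast
make the distinction hard enough that reader experience dominates accuracy.
`attnvgg` implements a convolutional classifier for this two-class problem:
a VGG16 backbone whose deep features are re-weighted by an additive
attention gate before classification, trained with a weighted ensemble of
cross-entropy and log-hyperbolic-cosine losses.

Everything — the network, its gradients, and the RMSprop optimiser — is
implemented directly on BLAS-backed matrix operations, so the package has
no deep-learning framework dependency and the whole pipeline runs on one
CPU.

## The attention gate

Let $x^l$ be the feature map at a fine scale (here the last convolution of
backbone block 4) and $g$ a gating signal from a coarser, deeper scale
(here the block-5 pooling output). For each pixel $i$ the gate computes a
pre-activation

$$A^l_i \;=\; \psi^\top\,\sigma_1\!\left(W_x^\top x^l_i + W_g^\top g_i + b_g\right) + b_\psi ,$$

with $\sigma_1$ the ReLU, and an attention coefficient
$\delta^l_i = \sigma_2(A^l_i) \in [0,1]$ with $\sigma_2$ the logistic
sigmoid. The gated features are $\hat x^l_i = \delta^l_i \, x^l_i$,
broadcast across channels. All transforms ($W_x$, $W_g$, $\psi$) are
pointwise ($1\times1$) convolutions; the gating branch is computed on
$g$'s grid and bilinearly upsampled to $x$'s grid before the additive
merge. Because the coefficients are sigmoid-bounded, gating is contractive:
it can only attenuate features, never amplify them.

The gated map is then fused with the upsampled gating context (channel
concatenation followed by a pointwise convolution and ReLU), global-average
pooled, and classified by a small dense head — ten hidden units by
default, which at this head size costs three orders of magnitude fewer
parameters than the classic 4096-unit VGG head while leaving accuracy
unchanged.

Design choices that the architecture description left open, and how this
package resolves them:

* **"Layers 13 and 18".** VGG16 has only 13 convolutional layers, so both
  indices cannot name convolutions. In sequential indexing of the conv/pool
  stack, layer 13 is the last convolution of block 4 ($16\times16$ at a
  128-px input) and layer 18 is the block-5 pool ($4\times4$): the only
  reading in which the gating signal is strictly coarser than the input
  features, as additive attention requires. Both indices are configurable.
* **Resampling side.** The gating branch is upsampled to the feature grid
  (not the features downsampled), preserving the spatial resolution of the
  gated map; upsampling is bilinear.
* **Coefficient shape.** $\psi$ projects to one channel, so coefficients
  are a single spatial map broadcast over feature channels.
* **Pointwise reading.** The gate's transforms are $1\times1$ convolutions
  over 2-D maps (the three-index notation in the attention-gate literature
  comes from its volumetric origins).
* **Head pooling.** Global average pooling precedes the dense head, which
  keeps the 10-unit head independent of input resolution.
* **Supervision point.** The ensemble loss is applied at the classifier
  head only; deep supervision of the attention output is not implemented.

## The CE–logCosh ensemble loss

For a one-hot label $y$ and predicted class probabilities $\hat y$,

$$L_{CE} = -\sum_i y_i \log \hat y_i , \qquad
  L_{LCH} = \sum_i \log\cosh(\hat y_i - y_i) ,$$

and the training objective is $\alpha L_{CE} + \beta L_{LCH}$ with
$\alpha = \beta = 0.5$ by default. Log-cosh behaves like $e^2/2$ for small
errors and like $|e| - \log 2$ for large ones, so the ensemble keeps the
probabilistic calibration pressure of cross-entropy while adding a
smooth, outlier-robust penalty on the raw prediction error. Numerical
notes:

* probabilities are clamped to $[\varepsilon, 1-\varepsilon]$ with
  $\varepsilon = 10^{-7}$ before logarithms;
* $\log\cosh$ is evaluated through the overflow-safe identity
  $\log\cosh e = |e| + \log(1 + e^{-2|e|}) - \log 2$;
* log-cosh is applied to probabilities against one-hot labels (the same
  quantities cross-entropy sees), not to logits — the formulation is
  written in terms of $y$ and $\hat y$ and this is the reading
  implemented; the logit alternative would change only the loss module;
* batch reduction is the mean for every loss.

The tests verify all closed forms, both asymptotic regimes, exact
linearity in $(\alpha, \beta)$, and agreement of every analytic gradient
with central finite differences.

## Training recipe

The faithful profile (`training_profile("paper")`) is RMSprop with initial
learning rate $2\times10^{-6}$, time-based decay
$lr_t = lr_0/(1 + 10^{-6} t)$ per update, 250 epochs, batch size 32,
dropout 0.5, full-width network at $128\times128\times3$ (grayscale inputs
are replicated to three channels at the network boundary). The decay
constant is read in the convention of time-based schedules: $t$ counts
completed parameter updates.

Training is fully seeded — initialization, shuffling and dropout draw from
one stream — so runs are bit-reproducible. The checkpoint with the best
validation accuracy is retained alongside the final weights; the best
checkpoint is what evaluation uses. The positive class is malignant
throughout, matching the clinical reading of sensitivity as the malignant
detection rate.

### Desk scale

From-scratch training of a full-width VGG16 is not a one-CPU computation,
so a second profile (`training_profile("desk")`) scales the *size* of the
run without changing any mechanism: width multiplier $1/8$ (every channel
count scaled), $64$-px inputs, learning rate $10^{-4}$, batch size 4, at
most 30 epochs, dropout off. Three of these choices deserve a note:

* **Small batches.** At 75 training images, batch 32 yields 3 updates per
  epoch — far too few for a from-scratch network. Batch 4 buys ~19 updates
  per epoch at identical per-epoch cost; at this scale update count
  dominates gradient smoothness.
* **No dropout.** A 30-epoch budget does not amortize dropout noise in a
  ten-unit head; regularization at desk scale comes from the tiny width.
  The faithful profile keeps dropout at 0.5.
* **Z-scored inputs.** The desk benchmark normalizes with train-set
  z-scoring rather than per-image min-max. With all-positive inputs and
  ReLU activations the loss surface near initialization is poorly
  conditioned, and the ten-unit head is prone to collapsing onto the
  all-dead-ReLU manifold (where the network can only output a constant);
  centred inputs remove most of that failure mode. Both normalization
  modes are first-class and the statistics persist with the model.

The learning-rate and width settings are the desk profile's definition,
chosen once; the faithful profile is untouched.

## The synthetic generator

No imaging data ships with the package; a generator produces
ultrasound-like phantoms so the full pipeline is exercisable anywhere.
Each image is a constant echo background (level 0.55) carrying one darker
elliptical lesion, with multiplicative speckle
$p \mapsto p\,(1 + \mathcal N(0, \sigma))$, clipped to $[0,1]$ —
the standard first-order surrogate for ultrasound speckle. The lesion
boundary radius is modulated by 3–8 random sinusoidal harmonics whose
total amplitude is the lesion's `margin_irregularity`; the class contrast
is:

* **margin**: benign irregularity below 0.10 (smooth), malignant at or
  above it (spiculated) — the primary discriminant, mirroring the
  fibroadenoma/IDC morphology contrast;
* **size**: lesion diameters drawn from truncated normals matching the
  study population (benign $1.4\pm1.0$ cm in $[0.3, 5]$; malignant
  $2.1\pm1.2$ cm in $[0.5, 9]$) on a 6-cm field of view;
* **echogenicity**: malignant lesions are drawn darker
  (echo contrast 0.50–0.70 versus 0.30–0.50), reflecting the marked
  hypoechogenicity of carcinomas.

Default class counts are 249 benign and 190 malignant — the combined
composition of the two-source study data. Every image derives its own
random stream from `(dataset seed, sample index)`, so datasets are
byte-identical across runs and generation order is irrelevant.

What the phantoms deliberately do **not** model: beam physics,
attenuation, posterior shadowing or enhancement, heterogeneous tissue
texture, multiple lesions, BI-RADS descriptor realism, or inter-patient
correlation. A passing benchmark on phantoms therefore demonstrates that
the architecture, losses, optimiser and metrics are implemented correctly
and can learn sonographically-styled class contrasts — not that the model
reaches any particular accuracy on clinical images.

The analytic boundary of each phantom is recoverable
(`lesion_boundary()`), and a one-number shape feature —
perimeter²/area — separates the two classes perfectly when the
irregularity gap is wide. The test suite asserts this before any network
is involved: the fixture is provably learnable.

## Splitting

`split_dataset()` stratifies by class at 75/10/15
(train/validation/test). Rounding per class: test takes the ceiling of its
fraction, validation rounds, train takes the remainder — an exact
partition for any class of at least 3. Whether the original study split at
image or patient level is not recorded; stratified image-level splitting
is the minimal reading and the implementation notes that multi-image
patients would leak across image-level splits, so grouped splitting is the
user's responsibility when patient identifiers exist.

## Evaluation

Six metrics from the confusion matrix (malignant positive): sensitivity,
specificity, precision, accuracy, F1 and the Matthews correlation
coefficient, the last computed as
$(TP\cdot TN - FP\cdot FN)/\sqrt{(TP\!+\!FP)(TP\!+\!FN)(TN\!+\!FP)(TN\!+\!FN)}$,
which equals the Pearson correlation of the binary truth/prediction
vectors (property-tested against `stats::cor`). A metric whose denominator
is zero is reported as `NA` and named in the result's `undefined`
attribute — never silently zeroed. F1 inherits undefinedness from
precision or sensitivity, since it is their harmonic mean. Display
rounding is two decimals; CSV exports keep full precision.

No unique confusion matrix is recoverable from a table of six rounded
metrics, but an exhaustive search over matrices with at most 70 test
images shows TP=24, FP=2, TN=18, FN=1 reproduces the strongest published
row (0.96/0.90/0.92/0.93/0.94/0.87) after two-decimal rounding; that
matrix serves as a synthetic rounding-consistency witness in the tests,
labelled as derived.

## Benchmark sizes

The test-suite and acceptance benchmarks use 100 phantoms (50 per class)
at 64 px for the desk training runs, three independent seeds, and a
20-phantom 32-px set for the six-cell comparison grid — sizes chosen so
the whole suite completes in minutes on one CPU while still training
end-to-end through every code path.

## Known limitations

* From-scratch training at full VGG16 width is impractical without GPU
  acceleration; the pretrained-backbone hook (`load_pretrained_backbone()`)
  accepts external conv weights but no weight file ships with the package
  and nothing requires one.
* The phantom generator's simplifications mean reported benchmark
  accuracies say nothing quantitative about clinical data.
* The comparison grid trains each cell once per seed; at desk scale the
  between-seed variance of small validation sets (10–16 images) is large,
  which is why the benchmark asserts a threshold on a majority of seeds
  rather than a mean.
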