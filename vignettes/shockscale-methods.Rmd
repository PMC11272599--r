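---
title: "Classifying shockable arrhythmias from wavelet scalograms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying shockable arrhythmias from wavelet scalograms: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

shockscale classifies short single-lead ECG fragments into four shockable
ventricular arrhythmia classes — ventricular flutter (`C1`, VFL),
ventricular fibrillation (`C2`, VF), torsade de pointes (`C3`, VTTdP) and
high-rate monomorphic ventricular tachycardia (`C4`, VTHR). Each 2-second
fragment is converted into a time–frequency image (a scalogram of
continuous-wavelet-transform magnitudes), minority classes are balanced by
SMOTE interpolation on the raw signals, and the images are classified by a
small hybrid convolutional/recurrent network trained by the package's own
engine. This vignette records the models, the tunable parameters and every
numerical or design decision that was genuinely open.

## The time–frequency front end

A fragment is a sampled voltage trace $f(t)$ at rate $f_s$ (default
250 Hz, the native rate of typical Holter recordings; the duration default
is 2 s, i.e. 500 samples). Its continuous wavelet transform over scale $a$
and shift $b$ is

$$\mathrm{CWT}(a, b) = \frac{1}{\sqrt{a}} \int f(t)\,
  \overline{\psi\!\left(\frac{t-b}{a}\right)}\, dt,$$

with the complex Morlet mother wavelet

$$\psi(t) = e^{2\pi i t}\, e^{-t^2 / 2\sigma^2}.$$

Decisions taken here:

* **Conjugation.** The analysing wavelet is conjugated, the standard CWT
  convention. For magnitude scalograms this choice does not change
  $|\mathrm{CWT}|$, but it fixes the phase convention of the coefficient
  matrix.
* **Envelope width.** $\sigma = 1$ by default. The $e^{2\pi i t}$ carrier
  fixes the wavelet's centre frequency at one cycle per unit of wavelet
  time, so scale $a$ (in seconds) responds most strongly to the
  pseudo-frequency $1/a$ Hz.
* **Scale grid.** 64 log-spaced scales spanning pseudo-frequencies
  1–50 Hz. This brackets the fundamentals (2.5–8 Hz) and low harmonics of
  all four rhythm classes while staying well below the Nyquist rate.
* **Discretisation.** The integral is evaluated as a discrete correlation
  with $\Delta t = 1/f_s$, truncating the wavelet where its Gaussian
  envelope falls below $10^{-8}$ of the peak. The correlations are done by
  FFT; a test verifies the FFT path equals the direct double-loop
  summation to better than $10^{-8}$ relative Frobenius error, and other
  tests pin linearity and the scale at which pure tones localise.

Rendering maps coefficient magnitudes through per-image min–max scaling to
$[0,1]$, a MATLAB-style "jet" colormap (the conventional rainbow rendering
for scalograms; grayscale is available), bilinear resizing to a square
image (227 px by default, matching the classifier's native input; tests
and scaled studies use 64 px), and 8-bit quantisation. Consequences worth
knowing:

* Per-image scaling makes the image exactly invariant to positive
  rescaling of the signal — amplitude information is deliberately
  discarded, frequency structure is kept. A `range` argument provides
  global normalisation when cross-fragment amplitude matters.
* Row 1 of the image is the smallest scale, so high frequencies sit at the
  top. The orientation is arbitrary but fixed; flipping it would change
  the images, not their separability.
* Raw magnitude is rendered by default; `log = TRUE` applies `log1p`
  first. Magnitude was chosen as the default because the rhythm classes
  differ in where energy sits, not across orders of magnitude.
* All pixels are divided by 255 before entering the network, so model
  inputs live in $[0, 1]$.

## Class balancing

The reference corpus composition is strongly imbalanced (97 VFL / 240 VF /
72 VTTdP / 169 VTHR = 578 fragments). SMOTE oversamples each minority
class to a per-class target (1,000 by default, giving 4,000 total with
3,422 synthetic): a synthetic fragment is $x_i + u\,(x_z - x_i)$ with
$x_i$ a real class member chosen round-robin, $x_z$ one of its $k = 5$
nearest same-class neighbours (Euclidean distance on the raw sample
vectors), and $u \sim U(0,1)$. Tests verify the interpolation geometry
(every synthetic point is collinear with and between a base/neighbour
pair, to $10^{-9}$) and that the internal k-NN equals a brute-force sort.

Two genuinely open choices are exposed as modes rather than silently
guessed:

* **Signal vs image domain.** SMOTE runs on the 1-D signals *before* the
  wavelet transform. Interpolating signals guarantees every synthetic
  sample is still a signal whose scalogram is well defined, whereas
  interpolating rendered pixels can produce images that are not the
  scalogram of anything.
* **Before vs after splitting.** `balance_mode = "pooled"` oversamples the
  whole corpus and then splits 80/10/10 — this is the mode that reproduces
  the corpus bookkeeping (4,000 → 3,200/400/400) and mirrors a protocol
  in which balancing precedes partitioning, at the cost of synthetic
  fragments interpolated from test-set members appearing in training.
  `balance_mode = "safe"` splits first and oversamples the training
  partition only, the leakage-free protocol. Both are first-class; `"off"`
  trains on the imbalanced data directly.

## The classifier

The full architecture is: input $(H, H, 3)$ → five blocks of
[3×3 same-padding convolution, ReLU, 2×2 max-pool stride 2], with dropout
after pools 3, 4 and 5 → global average pooling → the resulting
feature vector reshaped into a sequence → GRU → dense ReLU → dense
softmax. The GRU follows the gate equations

$$z_t = \sigma(W_z [h_{t-1}, x_t]), \quad
  r_t = \sigma(W_r [h_{t-1}, x_t]), \quad
  \tilde h_t = \tanh(W [r_t \odot h_{t-1}, x_t]),$$
$$h_t = (1 - z_t) \odot h_{t-1} + z_t \odot \tilde h_t.$$

Open details and how they were fixed:

* **Layer widths.** The architecture fixes only structural constraints
  (five conv/pool blocks, three dropout layers, GAP, reshape, GRU, two
  dense layers) and a total budget of roughly 208k trainable parameters,
  not individual layer widths. The defaults — conv
  filters (16, 32, 64, 64, 128), dropout (0.25, 0.25, 0.5), GRU 128 units,
  dense 128 — respect every constraint and total 201,316 parameters. All
  are configurable.
* **Reshape semantics.** GAP yields one number per feature map (a
  length-128 vector). The only reshape of a vector that gives the GRU a
  non-trivial sequence is a 128-step sequence of scalar features, so that
  is what the model does: the GRU reads the channel profile as an ordered
  sequence.
* **Biases.** The gate equations above are bias-free, and the reference
  `gru_step()` implements them exactly as written. The trained network
  uses one bias vector per gate (the usual practice); an equivalence test
  pins the engine's cell to the reference with biases zeroed, documenting
  the mapping. `count_parameters(cfg, biases = FALSE)` reports the
  bias-free convention.
* **Ablation variants.** `cnn_only` feeds the GAP vector straight into the
  dense head; `gru_only` feeds the raw image rows (one step per row,
  width×3 features) into the GRU. Both are built by the same engine and
  share the evaluation path.

### The training engine

No deep-learning framework exists in this package's dependency set, so
the forward pass, backpropagation (including backpropagation through time
in the GRU) and the optimizer are implemented in compiled code inside the
package, with im2col/GEMM convolutions on top of the BLAS. Two
consequences:

* **Precision.** The engine is templated on the floating type. Training
  defaults to single precision — the standard arithmetic for neural
  network training and roughly twice the throughput on one CPU — while the
  double-precision path backs the finite-difference gradient checks in
  the test suite (relative error $\le 10^{-4}$ on sampled coordinates) and
  any verification work.
* **Determinism.** All randomness (weight init, shuffling, dropout, data
  generation, SMOTE, splits, LIME masks) flows from named integer seeds;
  two runs with the same configuration are bit-identical.

The optimizer is Adam with learning rate $10^{-3}$ and "decay"
$10^{-6}$, batch size 16, categorical cross-entropy, 400 epochs by
default. *Decay* is interpreted as the legacy per-update learning-rate
decay $\eta_t = \eta / (1 + \mathrm{decay}\cdot t)$, the classical
meaning of an optimizer `decay` argument; weight decay is a different
mechanism and deliberately not what this knob does. Checkpoint selection keeps the best-validation-accuracy
epoch by default (`select = "best"`); the recipe trains a fixed number of
epochs without stating a selection rule, so `select = "last"` is also
available.

## Evaluation protocol

`eval_report()` computes the confusion matrix (rows = true), per-class
precision, recall, specificity and F1 (with the $P + R = 0$ case defined
as 0), their unweighted macro averages (the appropriate "Average" row for
a balanced test set), overall accuracy, and one-vs-rest ROC curves with
trapezoidal AUC. Ties in the scores are treated as a single threshold
step. Tests check the suite against brute-force one-vs-rest tallies on
random confusion matrices, hand-computed binary cases, perfect/constant
predictors, and pROC for AUC.

Splitting assigns `round(n·ratio)` members per class to validation and
test with the remainder to train, so 4,000 balanced fragments split
3,200/400/400 (800/100/100 per class) and the imbalanced 578-fragment
corpus splits 462/58/58. Stratified 5-fold cross-validation and a grid
sweep over learning rate/decay/batch size (rows sorted by accuracy, ties
toward the smaller batch) round out the protocol.

## Local explanations

`explain_prediction()` is a LIME-style surrogate: grid superpixels
(default 32-px blocks — SLIC-like segmenters would add a heavy dependency
and buy little on smooth scalograms; the `map` argument accepts any other
contiguous labelling), $n = 1000$ Bernoulli(½) on/off perturbations,
masked regions filled with the image mean colour (black behind a flag),
locality kernel $\exp(-d^2/0.25^2)$ on cosine distance to the unperturbed
pattern, and a ridge ($\lambda = 1$) regression of the target-class
probability on the binary patterns. The surrogate's settings are declared
defaults, not inferred ones. A planted-superpixel oracle (a model that
responds to exactly one region) is recovered top-1 across 20 seeds in the
acceptance suite.

## The synthetic data generator

The generator emulates the study conditions — 2-s, 250 Hz, single-lead
fragments with the four morphologies — so that the entire pipeline builds
and tests with no data download:

* `C1` (VFL): a near-sinusoid with fundamental drawn from 4–6 Hz plus a
  small second harmonic.
* `C2` (VF): a sum of 5–8 sinusoids with frequencies drawn from 3–8 Hz,
  random phases and slowly drifting amplitudes — irregular, with no stable
  period.
* `C3` (VTTdP): a 3–5 Hz train of wide Gaussian-derivative pulses whose
  amplitude is modulated by $(1-d) + d\sin(2\pi f_m t)$ with
  $f_m \in [0.2, 0.5]$ Hz and depth $d = 0.8$, so pulse polarity
  alternates about the isoelectric line — the characteristic twisting of
  torsade.
* `C4` (VTHR): a strictly periodic 2.5–4 Hz train of the same wide pulses
  at constant amplitude. The rate is drawn per fragment; within a
  fragment the train is exactly periodic, encoding the regular-vs-chaotic
  contrast with `C2`.

The Gaussian-derivative lobe stands in for a wide ventricular complex: it
is biphasic and spectrally broad like a ventricular QRS, without modelling
P or T waves — which these rhythms lack anyway. Clean waveforms are scaled
to a 1 mV peak and Gaussian noise (default sd 0.05 mV) is added. Each
fragment's stream is keyed by (seed, class, index), so generating more
fragments never changes existing ones. The class-name mapping is fixed as
`C3` = VTTdP and `C4` = VTHR throughout the package.

What the generator does *not* emulate: real conduction physiology (no
dynamical heart model), non-shockable rhythms, electrode artefacts,
baseline wander, or inter-patient variability. Passing tests on synthetic
data therefore demonstrate that the pipeline's machinery is correct and
that it separates the *morphological* signatures the four classes are
defined by; they do not certify clinical performance on real ECGs, which
requires the real corpus.

A deliberately trivial spectral rule (peak concentration, slow-envelope
power, autocorrelation regularity) classifies 400 noisy synthetic
fragments at ≥80% in the test suite — a guard that the four classes are
genuinely distinct, set well below what the network achieves so it only
fails if the generator degenerates.

## Problem sizes and reproducibility

The full-scale recipe (227-px images, 400 epochs, a 4,000-fragment
corpus) is a GPU-scale workload. The package's own studies use sizes chosen for a
single CPU: the scaled-down end-to-end study trains the default model on
800 synthetic 64×64 scalograms (100 validation, 100 test) for 30 epochs,
and the acceptance suite requires a median test accuracy of at least 90%
over three seeds — a threshold the synthetic task passes with margin.
Bookkeeping checks (SMOTE tallies, split sizes) run at the full 4,000
fragment scale, which is cheap without training. `scripts/acceptance.R`
re-runs the whole chain from scratch under a caller-supplied seed and
writes every headline quantity it computes as JSON.

## Known limitations

* Synthetic-only validation, as discussed above.
* The engine is a minimal, single-threaded trainer: no data augmentation,
  early stopping, learning-rate schedules beyond legacy decay, or
  GPU path. It is sufficient for the model sizes the package targets.
* WFDB support covers the common cases (formats 16 and 212, one- or
  multi-channel, MIT-format annotations); exotic formats are rejected
  with a clear error rather than guessed at.
* Single-precision training means two runs differing only in `precision`
  agree only to float tolerance; all within-precision runs are exactly
  reproducible.
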