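---
title: "Methods: cross-modal PPG-to-ECG translation with a pretext-pretrained Wasserstein critic"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-modal PPG-to-ECG translation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A photoplethysmogram (PPG) is cheap to record continuously from the wrist but
carries far less diagnostic information than an electrocardiogram (ECG): it
reflects peripheral blood-volume pulsation, not cardiac electrical activity.
`ppg2ecg` implements a translation framework that learns the map from PPG
windows to time-aligned single-lead ECG windows, so that heart-rate and
rhythm analyses designed for ECG (including atrial-fibrillation detection)
can be run on wearable PPG streams. Because high-quality paired recordings
are large, access-restricted, and unwieldy for continuous testing, the
package ships a synthetic cohort simulator that plays the role of those
corpora in every test and example; nothing in the package requires a
download.

## The model in brief

The generator $G$ maps a normalized PPG window $p$ to an ECG window
$\hat e = G(p)$ of the same length. It is a 1-D UNet: a convolutional
encoder downsamples by 2 per layer over $L = 4$ layers (channel schedule
16, 16, 8, 8), a bottleneck expands 8 to 16 channels and flattens the
feature map into tokens processed by a Transformer with learned positional
embeddings and causal self-attention (pre-norm blocks, GELU MLPs), and a
transposed-convolution decoder mirrors the encoder with skip concatenations
at matching depths. A Tanh head keeps outputs in $(-1, 1)$, the range of
the normalized training data.

The critic $D$ scores windows as real or generated under the Wasserstein
objective with gradient penalty:

$$
L_D = -\mathbb{E}[D(e)] + \mathbb{E}[D(G(p))] +
\lambda\,\mathbb{E}_{\hat x}\big[(\lVert \nabla_{\hat x} D(\hat x)\rVert_2 - 1)^2\big],
\qquad
L_G = -\mathbb{E}[D(G(p))],
$$

with $\hat x = \epsilon e + (1-\epsilon) G(p)$, $\epsilon \sim U(0,1)$ per
sample. The critic is a Transformer classifier: three stride-1
convolutions (kernels 65/33/17, channels 64/128/256, layer norm after the
first layer and at the encoder output) feed average-pooled token steps
projected to $d_{\text{model}} = 256$; a CLS token plus learned positions
run through 2 layers with 2 heads and feed-forward width 512. The critic
head is FC 512 → 256 → scalar with no squashing; the 512-wide penultimate
activation doubles as the embedding used for distributional analysis.

Before adversarial training the critic is pre-trained on six
self-supervised pretext tasks — recognizing noise addition, scaling,
temporal inversion, segment permutation, negation, and time warping applied
to ECG windows with automatically generated pseudo-labels. During
adversarial fine-tuning the Transformer blocks (CLS, positions, attention
and MLP tensors) are frozen and only the convolutional encoder and the FC
head continue to train, which protects the learned representation from
degradation by an immature generator.

## Differentiation engine

No automatic-differentiation framework for R is assumed; the package
contains a compact reverse-mode engine (`R/autodiff.R`) over dense
matrices. Its backward pass constructs graph nodes from the same primitive
set it differentiates, so expressions that contain a gradient — the
gradient penalty is a function of $\nabla_{\hat x} D(\hat x)$ — can be
differentiated again with respect to the critic parameters (double
backprop). Convolutions are realized as cached patch-gather (im2col)
indices followed by one BLAS matrix product per layer for the whole batch;
attention over a batch uses a single block-diagonal mask so each training
step is one graph regardless of batch size. First- and second-order
gradients are verified against central finite differences in the test
suite.

## Synthetic cohort model

Each subject is a `subject_profile`: mean heart rate (bpm), RR-interval SD
(s), P/R/T amplitudes (mV), pulse-arrival lag (s), artifact level, and a
seed. Design choices:

* **ECG morphology** is a sum of Gaussian bumps per beat (P at −200 ms,
  Q/S flanking R, T at +300 ms). This anchors the R maximum exactly at the
  stored peak time — which makes ground truth for peak-detector tests
  sample-exact — and yields a known QRS-free component for validating the
  baseline-isolation analysis. An ODE heart model would be more
  physiological but offers no such closed-form ground truth.
* **PPG pulses** use a gamma-like asymmetric kernel with its maximum at
  R-peak time plus the lag, plus a delayed attenuated bump for the dicrotic
  notch — the two landmarks that matter for systolic-peak detection.
* **RR intervals** are i.i.d. truncated-normal draws (mean $60/\text{HR}$,
  SD = `hrv_sd`, floored at 0.3 of the mean). Real HRV is autocorrelated;
  independence is the simplest model that realizes a target RR SD, which is
  the statistic the tests check.
* **Motion artifacts** combine a smoothed random-walk drift (≈0.1–1 Hz),
  Poisson transient spikes, and slow (0.15 Hz) amplitude modulation, all
  scaled by `artifact_level` in [0, 1]. Level 0 is the bit-exact identity.
  The level knob is deliberately uncalibrated against any particular
  device; what the tests rely on is monotonicity (more artifact, worse peak
  recovery), which holds by construction.
* Cohort profiles are drawn from resting-adult ranges: HR 55–95 bpm,
  RR SD 10–60 ms, lag 150–350 ms, R amplitude 0.8–1.4 mV.

What the simulator does **not** emulate: pathological morphologies beyond
the stylized AF model, respiration coupling, sensor-specific transfer
functions, or non-stationary HRV. Passing tests therefore demonstrate that
the pipeline machinery is correct and well-calibrated on signals with known
structure — not that the trained model reaches any particular accuracy on
clinical recordings.

## Preprocessing

The chain follows the order: align → resample → filter → median despike →
segment → normalize.

* **Alignment** estimates one global pulse-arrival lag per record by
  scanning shifts of the PPG peak train against the ECG R-peak train
  (0–0.6 s) and maximizing their cross-correlation at the ECG rate;
  per-beat warping is out of scope. The PPG is advanced by that lag with
  edge padding.
* **Resampling** to a common 130 Hz uses cubic-spline interpolation.
* **Filtering**: ECG through a windowed-sinc FIR band-pass 0.5–45 Hz
  (odd length ≈ 3 s of taps), applied with explicit group-delay
  compensation after demeaning; PPG through a 4th-order Butterworth
  0.5–8 Hz applied forward–backward. Both are zero-phase because R-peak
  timing feeds directly into the heart-rate MAE metric; a causal filter
  would bias it.
* **Median despiking** uses a 5-sample running median (≈38 ms at 130 Hz):
  wide enough to remove single-sample spikes, narrow enough to leave the
  80–100 ms QRS intact. Edges are replicate-padded.
* **Segmentation** produces windows from the supported set
  {4, 8, 16, 32, 64, 96, 128, 160} s with 20 % overlap by default; the hop
  is rounded to samples and trailing partial windows are dropped, giving
  exactly $\lfloor (N - w)/h \rfloor + 1$ windows.
* **Normalization** is person-specific min–max onto $(-1, 1)$, fitted per
  subject (on training data only under LOSO) and inverted after generation
  to restore mV. Values outside the fitted range are clipped with a
  counted warning rather than silently; a constant channel is an error.

## Pretext transformations

Parameter ranges: SNR $\alpha \in [2, 45]$ dB, scale $b \in [0.1, 10]$,
segment count $m \in [2, 40]$, stretch $k \in [1.05, 4]$. The noise rule
$P_N = 10^{(E_{dB} - \alpha)/10}$ is read with signal power expressed in dB
($E_{dB} = 10\log_{10}$ mean-square) and $P_N$ a linear variance — the only
dimensionally coherent reading, and the one under which the achieved SNR
equals $\alpha$; the suite verifies ±0.5 dB on average. Permutation
resamples until the shuffle is not the identity (an identity shuffle would
carry a false pseudo-label). Time warping stretches a random half of the
$m$ windows by $k$ and compresses the rest by $1/k$, then clips or
zero-pads to the original length. Each input segment yields seven labeled
examples (original plus one per task); the original carries all-negative
labels and the six tasks are independent binary heads with equal weights,
trained with logistic losses.

## Training protocol

Adam with $(\beta_1, \beta_2) = (0.5, 0.9)$ is the default: the search
grid for decay rates also lists 1 and 3, which are not admissible
exponential-decay rates and are rejected at configuration validation, so
(0.5, 0.9) is the only valid listed pair. Defaults: learning rate 0.001,
batch 128, 90 epochs with early stopping (patience 10 on a validation
reconstruction RMSE — the headline metric), 5 critic steps per generator
step, gradient-penalty $\lambda \in \{4, 6, 30, 50\}$ with 6 as default. A
divergence guard aborts when the critic loss exceeds a bound for three
consecutive epochs. Cross-validation is leave-one-subject-out with 10 % of
training segments (training subjects only) held out for validation; the
fold audit asserting zero subject overlap is part of the test suite. The
13,824-configuration hyperparameter grid is exposed as a config-matrix
expander with a `budget` cap; running it at full scale is explicitly not
part of the test battery.

At desk scale the tests train reduced models (generator: depth 2, 8/8
channels, 16-d bottleneck; critic: 8/12/16 channels, 16-d Transformer,
8 tokens) on 4-s windows resampled to 32 Hz — 128-sample windows — for
tens of epochs. Two behaviors of the full-size objective are reproduced
and asserted at this scale: the mean critic gradient norm at interpolates
is driven toward 1 when $\lambda = 30$, and removing the penalty
($\lambda = 0$) makes the epoch-wise critic-loss SD strictly larger on the
same seed.

## Evaluation

Metrics are computed after denormalization so RMSE is in mV. The curve
similarity measure is the standard discrete Fréchet distance — the minimum
over monotone couplings of the maximum pointwise distance — computed by
the two-row dynamic program in compiled code and verified against
exhaustive coupling enumeration for short curves. Heart-rate MAE uses
per-segment HR = 60 / mean RR; segments with fewer than two detected peaks
in either train are excluded and the exclusion count reported. R peaks are
detected with the Pan–Tompkins stages (5–15 Hz band-pass, derivative,
squaring, 150 ms moving-window integration, adaptive signal/noise
thresholds, 200 ms refractory period) with a final snap to the local
maximum of the squared band-passed trace, which makes detection
polarity-invariant and sample-exact on clean synthetic ECG. Systolic PPG
peaks use a clipped slope-sum function with adaptive thresholding
(250 ms minimum spacing) and the same snap-to-raw-maximum refinement.

## Distributional analysis

Real and generated windows are compared in the critic's 512-d embedding
space with two two-sample statistics: an unbiased Gaussian-kernel MMD²
(median-heuristic bandwidth; for equal sample sizes the paired cross-term
diagonal is excluded so identical multisets give exactly 0, and the
estimate may be slightly negative under the null) and the squared energy
distance. Significance uses a pooled permutation test,
$p = (1 + \#\{T_{\text{perm}} \ge T_{\text{obs}}\})/(1 + n_{\text{perm}})$,
default $n_{\text{perm}} = 1000$; the report attaches a
permutation-resampling SD to each statistic and labels it as such. The 2-D
scatter uses an exact $O(n^2)$ t-SNE (perplexity 50, learning rate 600) and
carries no exactness contract — it is for visualization only.

## AF downstream harness

Baseline fluctuation is isolated by removing ±60 ms around each detected R
peak (covering a QRS of up to 120 ms) and bridging linearly; the excised
trace retains P/T regions and wander but no QRS energy, so no heart rate is
recoverable from it — a guard asserted in the tests. Spectral power uses a
Welch periodogram (Hann windows, 50 % overlap) integrated by trapezoid over
0.05–9 Hz and the sub-bands 0.05–1 Hz (wander) and 3–9 Hz (fibrillatory
activity). The default 8-s window resolves 0.125 Hz; a ≥20 s window is
needed to genuinely resolve the 0.05 Hz band edge and both are available
through `window_s`.

Synthetic AF subjects have high-variance RR draws, zero P-wave amplitude,
and an added 4–9 Hz baseline oscillation — the three stated hallmarks —
and exist purely so the classifiers and the mixing protocol can be
exercised; they carry no clinical validity. The mixing experiment replaces
a fixed share of real training segments with generated ones at constant
total size and reports accuracy, precision, recall, F1 (recomputed from
the confusion matrix) on a subject-disjoint real test set, with a fixed
0.5 probability threshold and no calibration step. The two classifiers
follow the stated shapes — two bidirectional LSTM layers (128 hidden units
per direction) with dropout 0.5 and two 256-unit FC layers, and the hybrid
variant with two kernel-4 convolutions and 2×2 max pooling in front —
with all widths configurable downward for desk-scale runs.

## Numerical choices and degenerate inputs

Min–max round-trips are exact to 1e−9; normalization rejects constant
channels. The correlation metric errors on zero-variance input, and a
degenerate (e.g. constant) generated window is flagged in the report
rather than dropped. Softmax detaches the row maximum (shift invariance
makes all derivatives exact almost everywhere); the gradient-penalty norm
adds 1e−12 inside the square root; permutation identity shuffles are
rejected by resampling; close peak candidates are resolved by keeping the
larger. Checkpoints store a JSON header (config echo, seed, epoch)
alongside parameter values.

## Known limitations

Training at the published scale (hundreds of subjects, 90 epochs,
full-size models) is out of reach of a CPU-only R process; the package
demonstrates correctness and qualitative training behavior at reduced
scale, not clinical accuracy. The engine holds whole graphs in memory and
targets small batches. The simulator's AF model is stylized. The exact
identities of the cited PPG and ECG peak-detection implementations are not
published; family-level re-implementations with stated parameters are used
instead.
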