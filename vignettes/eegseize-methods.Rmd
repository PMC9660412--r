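---
title: "Methods: windowed wavelet subbands and a medium-weight CNN for seizure-onset EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed wavelet subbands and a medium-weight CNN for seizure-onset EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of what it computes, which
choices were genuinely open, and what the passing test suite does and does
not establish.

## The pipeline and its assumptions

The classification target is the state of a short EEG segment: baseline
(interictal), seizure (ictal), or the onset transition into a seizure. The
pipeline assumes:

* multichannel scalp EEG with one common sampling rate (the reference
  configuration is 256 Hz and 23 electrodes, the layout of the widely used
  pediatric scalp corpus);
* seizures manifest as a shift of signal energy toward higher-frequency
  rhythms, concentrated in roughly 3–29 Hz — this is the property both the
  synthetic generator and the classifier exploit;
* short windows (hundreds of milliseconds) are approximately stationary, so
  a window is a valid classification unit, and the (time × electrode) plane
  is a meaningful 2-D input for convolution.

Stages: segment → label → (optionally) decompose into subbands → train a
convolutional network per arm → evaluate by repeated stratified k-fold →
interpret via correlation maps.

## Windowing

`windowing_config()` defaults to 300 ms windows with 40% overlap, i.e. a
180 ms step. Two step conventions circulate for this design — a fixed 20 ms
increment and a 40% overlap — and they are mutually inconsistent. Both are
implemented (`step_mode`); the overlap convention is the default because it
is the one with an externally checkable consequence: 165 windows over 30 s
under the floor count `floor((T − w)/step)`. The mathematically standard
count (one more, including the last aligned window) is available as
`count_convention = "inclusive"`.

A 300 ms window at 256 Hz holds `round(0.3 · 256) = 77` samples. A window
count of 75 "step times" is sometimes quoted for this geometry; no rounding
convention reproduces it (256 × 0.3 = 76.8), so 77 is used and documented
here. Labeling uses the window **center** by default (simplest deterministic
rule; `majority` is available for sensitivity analysis), with precedence
seizure > onset > nonseizure so every window gets exactly one label.
`onset_lead_s` (default 10 s) defines the pre-seizure stretch labeled
"onset" in 3-class runs; nothing in the source material quantifies the onset
window, so this is an explicit, documented stand-in.

## The wavelet filter bank

`dwt_step()` implements one analysis step of a two-channel quadrature-mirror
bank: correlation with the reversed taps after half-sample symmetric
extension (or circular extension in `periodic` mode), downsampling by 2.
`idwt_step()` is its exact inverse (upsample, filter with the time-reversed
pair, trim `L − 2`); `decompose()` recurses five levels on the approximation
branch. Numerical contracts, all asserted in the tests:

* perfect reconstruction to < 1e−8 relative error (measured: machine
  precision) for both extensions and all supplied families;
* Parseval energy partition under periodic extension for the orthogonal
  families, to 1e−8;
* linearity of the decomposition, and probe tones at 2/6/10/20/50 Hz landing
  in delta/theta/alpha/beta/gamma respectively at 256 Hz.

The family is configurable; `db4` is the default as the common choice in
epilepsy EEG work (the source material leaves the family unstated). The
dyadic band edges at 256 Hz (0–4, 4–8, 8–16, 16–32, 32–64 Hz) are close to
but not identical to the textbook rhythm boundaries (alpha is usually quoted
to ~12–13 Hz, theta's upper edge appears as both 7 and 8 Hz); the filter-bank
branches are authoritative here and the Hz edges are metadata. Gamma is D2
alone (32–64 Hz) by default; `gamma_merge_d1 = TRUE` merges D1 so the five
bands span the full spectrum and sum exactly to the original window — the
band-sum tests use that setting. Windows too short for a level are
zero-padded on the right (recorded in the result) only when padding is
enabled; otherwise it is an error.

Because all windows in a set share one length, band reconstruction is
materialized once as an n × n linear operator (`band_transfer_matrix()`,
cached) and applied to whole window sets as a matrix product.

## The network

`build_architecture()` provides three weight classes. The medium-weight
stack is fixed: Conv1 10×1 (20 filters), Conv2 20×23 (20), stochastic pool
2×1 stride 2, Conv3 10×1 over 20 maps (40), pool, Conv4 10×1 over 40 maps
(80), softmax head. Light (4 layers) and heavy (9 layers, extra conv +
dense 64) variants sit inside the 3–5 and 8–12 layer ranges. Kernel sizes
written as `20 × 23` are read as time × electrode, so Conv2 collapses the
channel axis; on a 77-sample window the Conv4 kernel exceeds the remaining
7-step extent and is clipped to it with a warning — without clipping the
listed kernel chain cannot be all-valid on this input.

Design decisions that were open:

* **Input representation.** One model per subband, fed the
  band-reconstructed time signal as a (time × channel) plane; raw windows
  form the "without decomposition" arm. Coefficient arrays would also have
  been defensible; time signals keep both arms shape-identical.
* **Cost.** The squared-error function with the conventional ½ prefactor
  (the prefactor is corrupted in the source text; only the arg-min is
  unaffected by this choice).
* **Pooling.** Both max pooling (`p_j = max_i a_i`) and stochastic pooling
  are implemented. Stochastic pooling is the training default for the
  mw network; regions are shifted by their minimum so the sampling weights
  are non-negative with tanh units, a constant region is sampled uniformly
  (and returns its value), and inference uses the probability-weighted
  expectation, which makes prediction deterministic. Gradients route to the
  sampled (or max) unit; max-pool ties break to the first index.
* **Decision head.** A single affine + softmax layer. Published
  descriptions of deeper dense stacks for this design are internally
  inconsistent (impossible neuron/weight counts), so the minimal head is the
  default and the heavy variant adds one configurable dense layer. A
  single-logit logistic head is available for two classes.
* **Activation.** tanh by default, sigmoid selectable.
* **Optimizer.** RMSprop with lr 1e−3, decay 0.9, epsilon 1e−8 (unstated in
  the source; these are the usual defaults). Weights are initialized
  Glorot-uniform from the layer fan-in/out; inputs are globally rescaled by
  the training-set SD — per-window standardization would erase the amplitude
  differences that carry the class signal.

The engine stores feature maps as flattened matrices and runs convolutions
as BLAS products: channel-collapsing layers (Conv2–4) use a stacked
shift formulation (one large GEMM each for forward, weight gradient and
input gradient), other layers use im2col with a cached sparse scatter for
the backward pass. `conv_forward()` is the reference implementation of a
single layer and is tested element-wise against a quadruple-loop oracle;
analytic gradients are checked against central finite differences to 1e−5
relative error. Training aborts with a diagnostic on non-finite loss and
refuses single-class data.

## Evaluation

Accuracy, sensitivity and specificity are computed exactly from confusion
counts; a zero denominator yields a flagged `NA`, never a silent 0.
Three-class runs report one-vs-rest metrics per class plus macro averages
(the multiclass convention is unstated in the source; one-vs-rest is the
standard reading). Folds are stratified by class (dealt round-robin within
class, so fold sizes differ by ≤ 1 and per-fold class proportions stay
within one sample); plain "k-fold" leaves stratification open and the
stratified variant is the stabler choice at these sample sizes.
Best/mean/worst are computed over the k folds within one repeat, with the
SD over folds — the reading most consistent with the tabulated format this
mirrors — and each table row is one repeat. ROC curves sweep the cutoff
over unique scores with ties crossing simultaneously; the AUC is the
trapezoid rule, cross-checked against an independent implementation (pROC)
in the tests. Paired t-tests delegate to `stats::t.test`; zero-variance
differences return a flagged degenerate row.

## The synthetic generator

`generate_background()` draws per-channel Gaussian noise shaped in the
frequency domain to a `1/f^α` amplitude spectrum (α = 1 by default, the
classic pink-like EEG background; DC is removed, each channel rescaled to
`noise_scale` SD, default 1 µV-like unit). `inject_events()` adds, inside
each event interval, a burst of 5 sinusoids at uniform-random frequencies in
the event band (default 3–29 Hz, the span seizure rhythms concentrate in),
random phases, ±20% per-channel amplitude jitter, scaled so the added RMS is
`(gain − 1)` × the channel's background RMS. Defaults define the study
conditions used throughout: seizure gain 4, onset gain 2 with a 1 s linear
ramp-in — the onset class is defined as "same rhythm, lower amplitude,
ramping", an explicit stand-in since no quantitative onset definition
exists in the source. Events are injected coherently on all channels.

What the generator emulates: the upward shift of band energy during
seizures, an intermediate onset state, seeded bit-identical reproducibility.
What it does not: electrode-montage correlation structure, artifacts
(muscle, eye, line noise), nonstationary background, patient-to-patient
variability, realistic seizure morphology. Consequently, the passing
end-to-end tests establish that the implementation is correct and that the
pipeline recovers a planted, amplitude-coded class structure; they say
nothing about clinical accuracy on real recordings, and the headline
accuracies reported for the full scalp corpus are out of scope here.

## Problem sizes and numerical choices

The test suite and the acceptance script run at sizes chosen to exercise
every code path at full fidelity while staying desk-scale:

* end-to-end recovery: the mw network on 600 three-class windows
  (2 records/class, 18.42 s each, 256 Hz, 23 channels, gains 1/2/4), 70/30
  split, batch 100, early stop at mean loss 1e−4, epoch cap 60; the suite
  requires held-out macro accuracy ≥ 0.90;
* loss collapse: the 2-class mw run must fall below 1% of its initial loss
  within 100 epochs;
* cross-validation protocol: 300 windows, k = 5, 2 repeats, both arms;
* module oracles (wavelet, convolution, gradients, ROC, t-test) run at
  n = 10–2000 as stated in the tests.

Seeds flow top-down: every generator, fold split and training run takes an
explicit seed, and all randomness passes through R's RNG under
`withr::with_seed`, so equal arguments give bit-identical results.
Tie-breaks are deterministic (first argmax in max pooling and in label
assignment); degenerate inputs (empty records, too-short windows, truncated
containers, single-class training data) raise classed errors rather than
propagating NaN.

## Known limitations

* The EDF writer stores one data record and equal rates across channels —
  sufficient for round-tripping this pipeline's data, not a general EDF(+)
  implementation.
* Training is single-threaded CPU R; the mw network at the 600-window study
  size trains in minutes, but corpus-scale training is out of scope.
* Correlation maps use Pearson correlation of mean activations against mean
  spectral amplitudes ("correlation" is otherwise unspecified in the
  source); a wavelet-energy variant is provided (`method = "dwt"`).
* The alternative of feeding correlation maps back as network input is noted
  in the source's discussion but intentionally not implemented.
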