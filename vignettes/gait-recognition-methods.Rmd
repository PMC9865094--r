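---
title: "Recognizing gait activities from wearable sensor streams: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recognizing gait activities from wearable sensor streams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitrec)
```

## The problem

A wearable system straps an inertial measurement unit (3-axis
accelerometer + 3-axis gyroscope) and a strain-gauge muscle sensor below
each knee and samples all channels at 40 Hz (one row every 25 ms). Six
additional channels are produced on-line by complementary-filter sensor
fusion, giving 20 sensor channels plus one label channel per sample. From
such recordings the package classifies, per sample, five gait
activities — resting, walking, running, ascending stairs, descending
stairs — and, in a clinical variant, detects freezing-of-gait (FOG)
episodes in Parkinson's disease: brief (1–20 s) events in which the legs
tremble at roughly 3–8 Hz but do not move.

`gaitrec` implements the full pipeline: recording I/O, sensor fusion,
feature construction, nine classifiers behind one train/predict
contract, and the evaluation protocols, together with a synthetic
recording generator so that every stage is testable without access to
sensor hardware or patient data.

## Sensor fusion

Accelerometer-derived inclination is noisy but drift-free; integrated
gyroscope rate is precise but drifts. The complementary filter blends
them with the causal recurrence

$$\theta_t = \alpha\,(\theta_{t-1} + \omega_t\,\Delta t) + (1-\alpha)\,a_t,
  \qquad \theta_0 = a_0,$$

where $\omega_t$ is the gyroscope rate, $a_t$ the accelerometer
inclination and $\Delta t$ the sampling period. `alpha` defaults to
0.98, standard practice for this filter family: large enough that the
drift-free accelerometer path corrects the gyro integral on a ~1 s time
scale without admitting its sample-to-sample noise. `alpha = 1` is pure
integration, `alpha = 0` pure pass-through; both limits are tested
exactly. Inclination itself uses the standard tilt convention (X/Y:
elevation out of the horizontal plane; Z: tilt from vertical), computed
by `accel_inclination()`.

## Features

Two per-sample feature modes exist.

**RAW** — the 20 sensor channels, min–max normalized to $[0,5]$.
Normalization is per channel: the complementary-filter angles have much
smaller amplitude than the accelerometers, and a global scaling would
let loud channels dominate. The normalizer is always fitted on the
training rows only and applied with clipping to everything else, so no
test information leaks into the scaling; a constant channel maps to 0.

**CWT** — each channel expanded into the magnitude of its analytic
Morlet continuous wavelet transform at 27 log-spaced frequencies,
giving $20 \times 27 = 540$ per-sample features. Human gait energy
lives between roughly 0.5 and 10 Hz; the analysis band 0.2–20 Hz
brackets it with margin. The bin count follows
$\lfloor v \log_2(f_{\max}/f_{\min})\rfloor + 1 = 27$ with $v = 4$
voices per octave. The top bin sits at the Nyquist frequency of the
40 Hz stream and is attenuated but retained. The transform runs over
the whole recording in the frequency domain (the workflow is offline)
with reflection padding of half the longest wavelet support; magnitudes
are normalized so a unit sinusoid at a bin's centre frequency reads
about 1. The implementation is cross-checked in the test suite against
a brute-force time-domain inner product with Morlet atoms.

An autoencoder (`train_autoencoder()`) provides the optional feature
reduction stage: encoder, bottleneck (12 neurons on RAW-width inputs,
100 on CWT-width), decoder, trained under mean-squared reconstruction
loss.

## Classifiers

Nine kinds share one contract (`classifier_spec()`,
`train_classifier()`, `predict()`): per-sample class probabilities, a
label sequence via arg-max with ties resolved to the lowest class code,
and bit-reproducibility from the spec seed. The classical baselines
delegate to the standard R implementations (`rpart` decision tree capped
at 10 splits, `e1071` RBF support-vector machine and Gaussian naive
Bayes, `nnet` feed-forward network); their defaults, contracts and
evaluation are owned here.

The sequence models — LSTM, biLSTM over autoencoder codes, CNN+RNN and
the attention CNNA+RNN — are implemented natively in vectorized R with
exact backpropagation (finite-difference-checked in the tests) and Adam.

**CNN+RNN.** Three causal 1-D convolution layers (kernel 5, 20 filters,
ReLU) feed a single LSTM (hidden 32), then two fully connected layers
and a per-sample softmax head; on 20 raw channels this is ≈ 13.8k
learnable parameters. Convolutions never see future samples; windows
are left-padded by edge replication.

**CNNA+RNN.** Five structurally identical convolution streams process
the same input in parallel; their feature maps are merged by an
additive attention block — one learnable scalar weight per stream,
initialized to $1/5$ and learned jointly by backpropagation, merged map
$\sum_s aw_s F_s$ with the shape of a single stream's map — before the
same recurrent tail. With one stream at weight 1 and the rest at 0 the
network reduces exactly to CNN+RNN, a property the acceptance tests
assert bit-for-bit.

### Training regime

Several choices here were genuinely open; they were fixed during
development on synthetic recordings and are plain package defaults, not
per-dataset tuning knobs:

* **Windowing.** Training cuts a recording into non-overlapping
  64-sample (1.6 s) windows — about three stride cycles — and treats
  each as a sequence-labelling example (every sample in the window gets
  a prediction). Prediction runs the same fresh-state windows, stepped
  by half a window, keeping only the second-half outputs, so inference
  matches the training regime exactly and every emitted label had at
  least 0.8 s of causal context.
* **Burn-in mask.** The first 16 positions of each training window
  carry no loss: with one or two samples of context the best achievable
  prediction is the class prior, and training on those positions pulls
  the network towards majority-class collapse.
* **Input centering.** After $[0,5]$ normalization the per-feature
  training mean is subtracted (and stored in the model). All-positive
  inputs saturate LSTM gates; centering roughly quadrupled convergence
  speed in our runs.
* **Optimizer.** Adam at learning rate 0.003 for the sequence kinds,
  minibatches of 512 samples (8 windows), class-balanced per-sample
  loss weights (inverse class frequency, mean 1) so that sparse
  activities — running is ~7% of a typical recording — contribute
  equally, and a best-epoch parameter snapshot by training loss.
  Published epoch counts for comparable architectures came with higher
  learning rates (0.01–0.05) under a different optimizer and input
  scaling; under this engine those rates collapse to
  majority-class prediction, so the package treats the epoch counts as
  defaults and fixes its own stable rate.
* **Augmentation.** Training on a single 3-minute segment overfits its
  particular stride phases; two standard augmentations regularize it:
  the window grid gets a fresh random offset every epoch (so windows
  cut the signal at varying phases) and every training window receives
  a ±10% amplitude jitter. Both act on training data only.

## Evaluation protocols

`confusion()` builds the K×K matrix (rows = truth);
`per_class_metrics()` derives one-vs-rest accuracy, precision,
sensitivity, specificity and F1. Zero-denominator cases return 0 and
set a visible degeneracy flag rather than propagating NaN.
`macro_report()` averages per class *unweighted* — with the strong
class imbalance of gait recordings, weighting is a material choice, and
the unweighted mean is the literal reading of "calculated individually
for each class, and averaged". The macro F1 is the mean of per-class F1
values, not the harmonic mean of macro precision and sensitivity; the
plain fraction-correct is reported separately as `overall_accuracy`.
`std_eq7()` is the $n-1$ sample standard deviation used to aggregate
fold scores.

`segment_cv()` implements the leave-one-segment-out protocol: a
30-minute, 72,000-sample recording is split into ten 3-minute segments;
each fold trains classifier *and* normalizer on one segment alone and
tests on the remaining 27 minutes. Folds whose training segment lacks a
class are skipped with a warning. `ablate_sensors()` repeats a protocol
over the 15 non-empty sensor-group subsets (CF/ACC/GYRO/SG),
re-deriving the feature matrix — and hence the CWT width — per subset.
`fog_protocol()` is the clinical variant: a chronological (never
shuffled) 60/40 split of a binary-labelled recording, scored on the
positive (FOG) class. `detection_delay()` reports, for each true label
transition, the lag to the first subsequent predicted transition into
the same class within a 2 s horizon (the matching rule is ours; the
horizon bounds the search without affecting exact-shift fixtures);
unmatched transitions are excluded and counted.

## The synthetic generator

`generate_recording()` emulates what the classifiers exploit in real
gait data, not gait biomechanics:

* each activity is a sum of three harmonics (weights 1, 0.4, 0.15) at a
  stride frequency — walking 1.8 Hz, running 2.8 Hz at doubled
  amplitude, stair ascent 1.4 Hz with +30% left/right amplitude
  asymmetry, descent 1.6 Hz with −30%, resting amplitude 0.05 at
  frequency 0;
* legs are anti-phase; accelerometer Z carries a unit gravity baseline;
  gyroscopes get a random-walk drift (step SD 0.001); strain gauges get
  a rectified burst waveform; everything gets Gaussian noise (SD 0.05);
* the complementary-filter channels are *derived* by running the
  package's own filter over the synthetic accelerometer and gyroscope
  channels, mirroring the real pipeline;
* bout schedules realize a target activity distribution (default: the
  study's mean distribution — 9.5% resting, 58.8% walking, 6.8%
  running, 13.6% ascent, 11.3% descent) inside every 180 s block, so
  each 3-minute segment contains all five activities as the CV protocol
  requires; bout transitions cross-fade linearly over 0.5 s with the
  label switching at the midpoint, because hard steps would be
  unrealistically easy to classify;
* all randomness flows through a single seed, and the generator
  restores the caller's RNG state.

`generate_fog_recording()` builds a resting/walking background and
inserts 13 tremble episodes (3–8 Hz) totalling ≈ 8.2% of a 24-minute
recording, durations drawn in 2–18 s and rescaled to the target
fraction. Episodes aim at evenly spread positions across the session so
a chronological split has positives on both sides. Gait-initiation
episodes tremble only in the strain-gauge channels (low limb movement);
during-walking episodes tremble in the IMU channels as well. Labels
flip exactly at episode boundaries.

What passing tests on this generator do **not** show: the synthetic
waveforms carry none of the within-class variability, sensor artefacts,
posture diversity or pathology of real recordings, and the absolute
scores on synthetic data are not comparable to scores published on real
gait datasets. The generator's role is to make the pipeline's
machinery — feature construction, training, protocols, metrics —
verifiable end to end under known ground truth.

## Numerical choices and degenerate inputs

* Normalization of a constant feature maps to 0; out-of-range test
  values clip to $[0,5]$.
* `softmax()` subtracts the row maximum before exponentiation.
* Arg-max ties resolve to the lowest class code.
* The CWT refuses signals shorter than the longest wavelet's support
  (about 18 s at the default 0.2 Hz minimum frequency) with an error
  stating the minimum length.
* A recording length not divisible by the segment count is an error
  instructing the caller to truncate — never silent dropping.
* Empty recordings serialize to a header-only CSV and round-trip.
* Recording CSVs are written with 17 significant digits so the
  write/read round trip is bit-lossless for finite doubles.

## Problem sizes

The shipped test-and-acceptance runs use the study-scale defaults: a
30-minute, 72,000-sample five-class recording for the ten-fold segment
protocol (training each fold's network for its default 50 epochs takes
about half a minute on one CPU) and a 24-minute, 57,600-sample binary
recording with CWT features for FOG detection, trained for 10 epochs —
the episode signature is spectrally crisp and converges quickly. The
remaining unit tests run on recordings of a few minutes.

## Known limitations

* The native sequence-network engine is single-threaded R on BLAS; it
  is sized for the study-scale problems above, not for large-scale
  training.
* The SVM backend exposes no optimizer iteration cap, so the "max
  epoch" entry of its hyper-parameter table is informational for that
  kind.
* Detection delay depends on a matching rule (2 s horizon) that the
  underlying protocol leaves open; alternative rules change the value
  on noisy predictions (not on exact-shift fixtures).
* The attention block merges streams with scalar weights; per-channel
  attention weights are left as a configuration extension.
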