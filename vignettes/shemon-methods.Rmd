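---
title: "Methods: signal processing, networks, and contact mechanics in shemon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: signal processing, networks, and contact mechanics in shemon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shemon)
```

shemon is the computational side of a skin-wearable cardiac and motion
monitor: a single bipolar ECG lead (a surface analog of precordial V2)
sampled by a chest-worn device together with a 6-axis inertial unit. The
package covers the full path from raw samples to clinically meaningful
output — QRS detection, heart rate (HR), ECG-derived respiratory rate (RR),
per-sample ECG annotation by a convolutional sequence-to-sequence network,
activity recognition, and the adhesion mechanics that decide whether such a
device makes conformal contact with skin at all. This vignette records the
models, the tunable parameters, and the design decisions, so that a reader
can judge what the shipped defaults do and do not establish.

## Working rate and windowing

All ECG models operate at a fixed working rate of 250 Hz; recordings at
other rates (e.g. 1000 Hz or 257 Hz database material) must pass through
`resample_ecg()`, a polyphase FIR resampler with anti-aliasing on
downsampling. Analysis windows are 8 s — 2000 samples — and non-overlapping;
the trailing partial window is dropped. Windows are half-open 0-based sample
ranges `[start, start + 2000)`.

Per-sample labels are expanded from two sources with a fixed precedence:
**beat class > rhythm class > background**. An annotated ectopic beat (FB,
SVEB, VEB, paced, unknown) paints its class over ±300 ms (±75 samples)
around the R-peak — wide enough to cover one QRST complex, narrow enough not
to swallow neighbors below roughly 100 bpm. A record-level rhythm diagnosis
(MI, HF, AR) paints every sample not claimed by a beat class. Normal beats
paint nothing: they leave the rhythm class (or background) in place. The
label space has 9 classes — background/normal, MI, HF, AR, FB, SVEB, VEB,
plus two implementation-assigned classes (paced/other-ectopic and
unknown/noise) that round out the output dimension; the synthetic generator
only ever produces the first seven.

## Vital-sign extraction

**QRS detection** is a Pan-Tompkins variant: band-pass 5–15 Hz
(3rd-order Butterworth, forward-backward so zero-phase), five-point
derivative, squaring, 150 ms moving-window integration, adaptive dual
thresholds with search-back, and a 200 ms refractory period. Two details
matter for the invariants the tests assert. First, every stage is zero-phase
(including the centered moving average), so integrated-energy peaks line up
with the underlying R-peaks and the reported event is the raw-signal
extremum within ±40 ms. Second, every threshold is relative (initialized
from the first two seconds of the integrated signal), which makes detection
exactly invariant to amplitude scaling and baseline offsets.

**Heart rate** is the reciprocal RR-interval series, 60/RR assigned at
interval midpoints, cubic-spline interpolated onto a uniform 4 Hz grid and
clamped to (0, 300) beats per minute.

**Respiratory rate** uses amplitude-based ECG-derived respiration: the
R-peak peak-to-trough amplitude series (respiration modulates electrode
geometry and hence R amplitude) is interpolated to 4 Hz, band-passed to
0.066–0.7 Hz (4–42 breaths per minute), and the rate is read from the
dominant peak of a zero-padded periodogram over sliding 30 s windows. Two
numerical choices: near-ties (within 5% of peak power) resolve toward the
previous window's estimate for continuity, and a window is reported as
not-detectable (`NA`) unless its peak exceeds 50 times the in-band median
power. That factor sits between the one-order-of-magnitude fluctuations an
unmodulated amplitude series produces and the two-to-three orders of
magnitude a genuinely respiration-modulated series produces, so it
separates the two regimes with a wide margin on synthetic data. The
amplitude-based route was chosen over interval-based (sinus-arrhythmia)
respiration because amplitude modulation survives at low heart-rate
variability; the interval route is available in the generator for stress
testing.

**SNR.** Recordings are scored in 8 s windows as
`SNR_dB = 10 log10((A_signal/A_noise)^2)`, averaged over windows.
`A_signal` is the mean peak-to-trough amplitude of the detected QRS
complexes — peak-to-trough rather than peak height because it is robust to
baseline level. For `A_noise` the cardiac deflections are excised (each
complex bridged by linear interpolation, spans shrinking at high rates so
baseline always remains) and an order-99 running median — 0.396 s at
250 Hz — isolates the baseline floor; `A_noise` is the mean absolute
deviation of that floor from its median level, measured between complexes.
This reads the noise as what remains once beats are removed: wander and
drift, the dominant artifact of a moving wearer. Because each step is
homogeneous in amplitude and median-centered, the metric is scale- and
offset-invariant to machine precision.

## The synthetic generators

The generators exist so every downstream stage can be scored against exact
ground truth without any data download.

The ECG generator renders beats from a Gaussian-sum P-QRS-T template
(textbook lead-V2 morphology: P 0.15 mV, R 1.2 mV, S −0.35 mV, T 0.35 mV at
the default) placed by a renewal process with mean interval 60/HR and
configurable jitter. Respiration enters twice: R-amplitude modulation
`(1 + depth · sin(2π f_resp t))` (default depth 0.15) and beat-interval
modulation (respiratory sinus arrhythmia, default depth 0.05). Baseline
wander defaults to a 0.1 mV sinusoid at the respiratory frequency — wander
in resting recordings is mostly respiration-driven — plus 0.03 mV white
noise. Defaults describe a resting adult (72 bpm, 15 breaths per minute).
Morphology variants carry the class signal: MI-like beats add ST-segment
elevation with a tall merged T; HF-like beats are low-voltage and widened;
fusion beats are intermediate; ventricular ectopics are wide, bizarre,
P-free, premature, and followed by a compensatory pause; supraventricular
ectopics are narrow but premature and P-free. Ectopic counts are Poisson in
the configured per-minute rate, and each ectopic replaces the nearest
scheduled sinus beat so impossible overlaps cannot arise. A Gaussian-sum
template was preferred to a differential-equation heart model because the
ground truth (every beat index, class, and amplitude) is exact by
construction.

The IMU generator emulates a chest-worn device: gravity on the z
accelerometer axis at rest, cadence-locked vertical bursts with weaker
lateral coupling for gait (walk 1.8 Hz, stairs 1.5 Hz plus a slow
pitch-gyroscope oscillation, run 2.8 Hz at higher amplitude), and for falls
a single ~0.3 s transient peaking well above 3 g followed by a gravity
rotation onto the x axis (lying) and stillness.

What the generators do **not** emulate: electrode-motion artifacts with
heavy-tailed statistics, muscle noise, skin-impedance drift, contact loss,
multi-subject morphology variability, or any coupling between the ECG and
IMU channels. Passing the recovery experiments below therefore demonstrates
that the pipeline and the networks are implemented correctly and can learn
morphologically separable classes — not that they would reach the same
accuracy on clinical recordings.

## ECGSeq2Seq: per-sample annotation

The annotation network is an encoder-decoder 1-D CNN mapping an `(L, 1)`
window to an `(L, 9)` per-sample softmax field (`L = 2000` by default; any
length divisible by 8 — by 16 when the deeper pooling stage is enabled —
works, which the tests exercise at `L = 1000`).

* **Encoder**: two stride-2 stem convolutions (kernel 7) and a max-pool
  bring the sequence to L/8; a stack of Inception-style blocks follows, each
  a concatenation of parallel kernel-1/3/5 branches with batch
  normalization. With `deep_pool` (the default when divisibility allows), a
  further max-pool after the first block takes the deeper blocks to L/16,
  which roughly doubles the receptive field — necessary for context
  decisions such as "this flat baseline belongs to an ST-elevated rhythm"
  or "this narrow beat is premature".
* **Decoder**: one ×2 nearest-neighbor up-sampling plus convolution per
  encoder halving, with skip concatenations from the encoder layer of
  matching length, then a kernel-1 head and per-sample softmax.

Training is categorical cross-entropy under Adam with a starting learning
rate of 0.001, an 80/20 train/validation split inside the training set, and
a reduce-on-plateau schedule: after 2 consecutive epochs without
validation-accuracy improvement the learning rate is divided by 10
("consecutive epochs" is read as patience = 2). Optional inverse-frequency
class weights (capped at 20:1, mean-normalized) counter the background
dominance of per-sample labels. All randomness — initialization, splits,
shuffling — derives from the config seed, and training is bitwise
reproducible; the whole engine is hand-written (im2col convolutions via
RcppArmadillo, manual backpropagation) and verified against numerical
gradients in the test suite.

Inside the blocks the default activation is linear — the identity after
batch normalization, with nonlinearity entering only through max-pooling.
The desk-scale configuration (`seq2seq_scaled_config()`) switches to ReLU,
raises the learning rate to 0.003, and drops the class weighting: at 12/8/16
filter widths and a few thousand training windows those choices converge
several times faster to the same plateau, which is what a minutes-scale
cross-validation on one CPU core needs.

Beat-level annotation (`annotate()`) combines the per-sample argmax field
with the QRS detector: each beat takes the majority per-sample class within
±300 ms of its R-peak, ties resolved toward the class with the higher mean
probability over the neighborhood, confidence reported as the majority
fraction. Record flags: `abnormal_beat` when any beat is FB/SVEB/VEB, a
rhythm flag when a rhythm class covers more than half of a window.

Cross-validated evaluation uses four disjoint folds stratified by the
dataset's archetype/group labels, so no fold is starved of a class and
train/test never overlap.

## ActivityResNet: activity recognition

Six-channel IMU windows (4 s at 50 Hz — two gait cycles at walking cadence;
50% overlap in streaming) are standardized per channel with training-set
statistics and classified by a residual 1-D CNN: a stride-2 stem
convolution, a residual block with identity shortcut, a second residual
block with 1×1-projection shortcut, each followed by max-pooling, then
global average pooling and a dense softmax over
{idle, walk, stairs, run, fall}. Walking up and down stairs are merged into
one class at the default granularity. The training protocol is identical in
form to the segmentation network's. In streaming mode a fall prediction
must be corroborated by an acceleration transient above 2 g, otherwise it
is demoted to the runner-up class; since a genuine fall transient exceeds
3 g by construction, the gate can only ever suppress false alarms.

## Conformal-contact mechanics

The electrode laminate is a composite beam — elastomer substrate, polyimide,
chromium, gold — whose bending stiffness per unit width comes from the
transformed-section method: the neutral axis at the modulus-weighted
centroid and `EI = Σ E_i I_i` about it. Skin roughness is a sinusoid of
wavelength λ and peak-to-peak amplitude `h_rough`; the film conforms with
amplitude

\[ h = \frac{E_{skin}\, h_{rough}}{16\pi^3 EI/\lambda^3 + E_{skin}}, \]

the exact minimizer of bending energy `π⁴ EI h²/λ⁴` plus substrate elastic
energy `π E_skin (h_rough − h)²/(16 λ)` — the tests confirm the minimizer
numerically. Conformal contact requires the elastomer's work of adhesion to
exceed the total stored energy per unit contact area:

\[ \gamma_{elastomer} > \frac{1}{1-\alpha}\left[
   \frac{\pi^4 EI\, h^2}{\lambda^4}
   + \frac{\pi E_{skin} (h_{rough}-h)^2}{16\lambda}
     \left(1 + \frac{\pi^2 h^2}{4\lambda^2}\right)\right], \]

with α the areal fraction of the stiff PI/Au mesh and the bracketed
arc-length factor accounting for the stretched sinusoidal interface. The
inequality is strict: a candidate sitting exactly on the boundary is
classified non-conformal. The elastic term is quadratic in
`(h_rough − h)` — the form required both by dimensional consistency (J/m²)
and by the fact that the printed sag amplitude is its exact minimizer.

Shipped skin defaults (`E_skin` 130 kPa, λ 140 µm, `h_rough` 50 µm) and the
laminate layer table are representative literature values, not measurements;
every field is user-overridable, and `classify_elastomers()` expects
measured `(E, γ)` pairs for real candidates. Work of adhesion is estimated
from rolling-cylinder data as the zero-speed intercept of a least-squares
fit of peel-energy change against speed — linear by default, with the
polynomial degree configurable since the speed dependence need not be
linear. Peel energies are trapezoidal integrals of force-displacement
curves.

## Monitor loop

`run_monitor()` fuses everything at an 8 s cadence: per window it emits mean
HR, the latest RR estimate, beat annotations, the dominant activity class,
and alert flags, as a data frame and optionally as JSON lines. Alerts
(`abnormal_beat`, `fall`) are debounced to one per contiguous run of
abnormal windows. The loop is a deterministic replay over recorded or
synthetic streams: identical inputs and checkpoints give byte-identical
session logs.

## Problem sizes and runtime

The recovery experiments are sized for a single CPU core: the segmentation
experiment uses 2000 synthetic 8 s windows in four archetype-balanced
classes (background, MI, SVEB, VEB) under fourfold cross-validation with the
desk-scale network (about six minutes); the activity experiment uses 1000
windows over the five activities (about two minutes). Unit tests use
smaller sets. The QRS/HR sweep covers 60–180 bpm with four seeds per rate;
RR recovery covers 6–30 breaths per minute at modulation depths 0.1 and
0.2.

## Known limitations

* The synthetic-recovery accuracies say nothing quantitative about
  performance on real recordings; loaders for standard waveform-database
  formats (16 and 212, with beat annotations) are included so full-scale
  experiments can be run where those data are available.
* The 9-class label scheme fixes two placeholder classes; the identity of
  those classes in a deployed system is a data question, not a code one.
* Whether record-level diagnoses are best painted per-sample or per-window
  is unresolved; the package paints per-sample under beat-class precedence.
* The RR estimator reports `NA` rather than guessing when modulation is
  weak; at 30 breaths per minute and depth 0.1 a minority of windows fall
  below the detectability margin.
* The contact model treats skin as a single-wavelength sinusoid with a
  homogeneous modulus; real skin is multi-scale and anisotropic, so the
  boundary curve should be read as a design guide, not a guarantee.
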