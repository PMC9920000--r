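---
title: "Methods: smartphone IMU gait analysis for claudication detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: smartphone IMU gait analysis for claudication detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `claudigait`, and what the simulator-based tests do and do
not establish about real patient data.

## The problem

Intermittent claudication (IC) is exercise-induced lower-limb pain in
peripheral arterial disease. During a self-paced six-minute walk the onset
of pain changes gait — cadence drops, stride-to-stride variability rises,
movement amplitude shrinks. A phone riding free in a trouser pocket records
triaxial acceleration, angular rate and magnetic field; the pipeline turns
such a log into per-window binary IC labels and evaluates how well tree
ensembles detect the post-onset pattern.

## Resampling and filtering

Phone sensor events arrive irregularly (the OS batches and throttles
them), so every channel is linearly interpolated onto a shared uniform
50 Hz grid clipped to the observed time span; extrapolation beyond the
span is never performed, because it would invent data. Timestamp units
(ms vs s) are auto-detected from the median spacing, and duplicate
timestamps keep the last sample, matching how batched sensor events
overwrite.

All channels then pass a 4th-order Butterworth low-pass at 5 Hz, applied
forward and backward. Zero-phase filtering matters here: a causal filter
would delay the signal by a group-delay that varies with frequency and
shift detected gait events. The forward–backward pass squares the
magnitude response, so the effective attenuation is |H(f)|⁴ relative to a
single pass; at 2 Hz (walking band) the gain is still ≥ 0.999, at 10 Hz it
is below 0.4%. The implementation pads the signal by odd reflection before
filtering so that window edges carry no startup transient.

## Orientation estimation

The phone's pose in the pocket is arbitrary, so body-frame acceleration is
rotated into an Earth-fixed frame: X medio-lateral, Y vertical (up), Z
anterior–posterior, with yaw referenced to magnetic north along +Z
(declination is ignored — only relative orientation matters downstream).
Euler angles use the phone convention: roll about Z, pitch about X, yaw
about Y, composed as R = Ry(yaw)·Rx(pitch)·Rz(roll).

Per-sample quaternions come from Madgwick gradient-descent fusion: the
gyroscope quaternion rate is corrected along the normalized gradient of
the combined gravity and magnetic-field alignment objective, with gain
β = 0.1 rad/s — the published default range for MARG sensors, trading
convergence speed against noise amplification. Samples with a zero-norm
accelerometer or magnetometer reading fall back to gyro-only integration;
without any magnetometer the filter runs in IMU-only mode and yaw is
unreferenced.

Two implementation choices reduce transients. The filter is initialized
analytically from the first accelerometer/magnetometer sample (tilt from
gravity, heading from the horizontal field component), so there is no
large initial error to burn off. Even so, the first 5 s are flagged as a
convergence warmup and excluded from windowing by default, so the first
analysis window never contains fusion transients.

Gravity is removed by subtracting (0, 9.8, 0) m/s² after rotation
(g = 9.8 m/s² per the phone's sensor specification). Without removal,
features such as signal magnitude area and spectral energy carry a large
DC term that swamps gait information; the switch is exposed
(`fusion.remove_gravity`) for users who prefer the raw magnitude.

## Walking detection

At rest the standard deviation of the acceleration magnitude stays below
1 m/s²; that threshold is applied to the rolling standard deviation of the
filtered magnitude in a centered 1 s window, and walking runs shorter than
2 s are relabeled rest. The 1 s window spans at least one step at any
plausible cadence; the 2 s minimum suppresses boundary flicker. Both are
package choices (only the 1 m/s² threshold is fixed by the protocol) and
are exposed as `walk.window_s` and `walk.min_walk_s`.

## Gait-event detection by SSA

Singular spectrum analysis embeds a window's signal into an L-sample
lagged trajectory matrix, takes its SVD, and reconstructs one additive
component per singular triple by diagonal averaging (implemented as the
full convolution of the singular vectors divided by anti-diagonal lengths,
which makes the decomposition exact to machine precision). The embedding
length is L = 2 s of samples (100 at 50 Hz): L must exceed one stride so
the stride-periodic oscillation is separable, and must stay well below
half the 10 s window. SSA runs per window by default, matching the
windowed feature pipeline; whole-walk mode is available by calling
`detect_gait_events()` on a full recording.

The trend is the group of components whose dominant periodogram frequency
falls below 0.5 Hz — anything slower than half the slowest plausible
stride. A harmonic contributes a near-degenerate *pair* of singular
triples (its sine and cosine phases), so the "dominant oscillation" is
reconstructed from the leading eigenvalue group: components whose singular
value is within 20% of the largest. Reconstructing from a single triple of
the pair would recover the right frequency but an arbitrary phase and
about half the amplitude; the pair recovers the oscillation exactly on a
clean harmonic.

Heel contacts are minima of the dominant vertical oscillation (order-based
extrema detection with a neighborhood of a quarter step period, estimated
from the periodogram peak, to suppress micro-extrema), refined within
± 25% of the median inter-minimum spacing to the index minimizing the
product of the detrended Y and Z signals. The refinement half-width must
stay below half the spacing or neighboring contacts could swap.

Left/right assignment uses the mean of the detrended vertical signal
between the first three dominant-oscillation minima: if the first segment
mean exceeds the second, the first contact is a right heel contact; labels
then alternate. "Mean amplitude" is read as the mean of the detrended
signal (not its absolute value) — the most literal reading; the detrended
version is used because the raw mean is dominated by whatever trend
remains. The labels are *phone-side-relative*: the pocket side produces
the larger ipsilateral peak, and nothing in a pocket recording says which
anatomical side that is, so "right" means "pocket side". Exact ties
default to contact-one-is-right with a warning.

Toe-offs: for each left heel contact, the right toe-off is the first local
minimum of the detrended vertical signal strictly after it (before the
next right heel contact), and the left toe-off is the last local maximum
strictly before it. Cycles with no qualifying extremum carry no toe-off
and are excluded from stance/swing statistics. Cycles are segmented
between consecutive right heel contacts; stride time = stance + swing by
construction.

## Windowing and labels

Windows are 10 s with 50% overlap, anchored inside each maximal walking
run, so rest periods neither produce windows nor shift the grid; a
rest-free recording of duration D yields ⌊(D−10)/5⌋+1 windows (71 for a
six-minute walk). Windows with no complete gait cycle are dropped and
counted. A window is labeled IC-present iff at least half of it lies at or
after the reported pain onset — the symmetric, midpoint-equivalent
reading of "label from the onset"; a start-after-onset rule is available
via configuration. Labels are monotone within a walk since onset is a
single change-point.

## Features

Each window yields exactly 155 named features in a fixed, exported schema.
Numerical conventions worth stating:

* Standard deviation uses denominator N−1; kurtosis is the non-excess
  m₄/m₂² (3 for a Gaussian); skewness is m₃/m₂^{3/2}. Zero-variance
  windows yield flagged missing values rather than NaN arithmetic.
* Histograms use ten equal-width bins spanning the window's own min/max,
  normalized to frequencies. Per-window ranges make the feature
  amplitude-invariant and frequencies make it length-invariant; global
  ranges would be undefined without a reference dataset.
* The LCSS similarity matches two cycle-magnitude series with amplitude
  threshold ε = 0.5·sd(window magnitude) and temporal band δ = 10% of the
  shorter cycle, normalized by the shorter length and averaged over
  consecutive cycle pairs.
* The swing/stance feature returns the stance percentage of the stride
  (classically ≈ 60%); the alternative swing-minus-stance difference
  (≈ −20 points) is available via `mode = "difference"`.
* All frequency features are computed on the demeaned acceleration
  magnitude, making the excluded-DC convention exact. Welch PSD uses Hann
  windows, 128-sample segments, 50% overlap, one-sided density scaling.
  Spectral entropy is normalized to [0, 1] by log of the bin count.
  Spectral energy is the two-sided Σ|Xₖ|²/N, equal to Σx² by Parseval.
* A 10 s window at 50 Hz has exactly 0.1 Hz FFT resolution, so FFT bins
  1–40 cover 0.1–4.0 Hz (magnitudes scaled 2/N). The orthonormal DCT-II
  has 0.05 Hz per bin at N = 500, so the even bins k = 2, 4, …, 80 honor
  the same 0.1 Hz spacing; taking the first 40 bins instead (0.05–2.0 Hz)
  is available via `bins = "first40"`.

## Classification

The registry holds four tree ensembles with fixed, documented
hyperparameters — histogram gradient boosting (depth 6, η = 0.1, 200
rounds), classic shallow stagewise boosting (exact splits, depth 3,
η = 0.05, 300 rounds), random forest (500 trees) and extremely randomized
trees (500 trees) — all single-threaded and seeded for bit-identical
reports. Fixed settings replace automatic tuning deliberately:
reproducibility over opaque search.

Record-wise splits are stratified by label; patient-wise splits assign
whole patients, shuffling them and accumulating test patients while the
realized fraction approaches 20%. Cross-validation on the training side is
stratified 10-fold in record-wise mode and *patient-grouped* 10-fold in
patient-wise mode — grouping the folds too is the safer reading, since
ungrouped folds would leak patients between training and validation; a
switch (`grouped`) exposes the alternative. Leakage is asserted on every
patient-wise run. Metrics are accuracy, trapezoidal ROC-AUC from
positive-class probabilities, recall, precision and F1 at a 0.5 threshold.

## The simulator

The generator emulates the data-collection protocol: ~6-minute walks at a
self-selected pace, phone free-oriented in the pocket, a reported
pain-onset time, occasional rest blocks, 50 Hz nominal sampling with
timestamp jitter. The Earth-frame vertical acceleration is a
step-frequency oscillation with minima at heel contacts plus a second
harmonic whose push-off valley falls at the toe-off instant (the classic
double-bump vertical waveform), a sharp ~80 ms impact spike with ~100 ms
rebound at each contact, and a broad ipsilateral body-lift lobe over
pocket-side steps — the asymmetry the left/right rule exploits. The
anterior–posterior channel mixes step- and stride-frequency components;
medio-lateral is low-amplitude sway. The gyroscope reports the exact
angular rate of the orientation trajectory (fixed pocket pose plus a small
stride-synchronous wobble), the magnetometer the rotated Earth field
(horizontal 22 μT north, vertical −42 μT), and all sensors receive white
noise (0.3 m/s², 0.02 rad/s, 0.5 μT).

Claudication is a change-point at the reported onset: stride time
lengthens by 1/cadence_factor (default 0.9), stride-time CV scales by
1.5, amplitudes by 0.85. Cohorts draw per-patient latents once — baseline
stride 0.95–1.35 s, CV 0.02–0.08, stance fraction ≈ 0.60 ± 0.02,
amplitude scale 0.6–1.5, ipsilateral gain 1.15–1.45, and patient-specific
post-onset effect sizes (cadence factor 0.85–0.97, variability 1.1–1.6,
amplitude 0.8–1.0) — so trials of one patient are internally consistent
while one patient's claudication gait overlaps another's normal gait.
That latent structure is what makes patient-wise evaluation genuinely
harder than record-wise evaluation, mirroring the generalization gap seen
on clinical cohorts.

What the simulator does **not** capture: ground-reaction micro-dynamics,
turning at the ends of a shuttle path, magnetic disturbance indoors,
sensor bias drift, pathological gait beyond the three modeled effects, or
honest uncertainty in the reported onset time. Tests passing on simulated
cohorts therefore establish the pipeline's correctness and its
sensitivity to the modeled change-point, not clinical performance.

## Problem sizes used in tests

The test suite runs on scaled-down study conditions chosen to exercise
every code path: a shared 120 s walk fixture through the full sensor
pipeline, 50–60 s walks for the 20-point stride-time sweep (0.9–1.4 s),
two 60 s two-pose recordings for the orientation protocol checks, and a
12-patient × 2-trial × 120 s cohort (Earth-frame processing) for the
split-strategy experiments. Windowing arithmetic is checked at the full
360 s six-minute scale, where a rest-free walk yields exactly 71 windows
and 69 walks yield 4899.

## Known limitations

* Left toe-off detection lands on the sinusoid maximum between contacts
  rather than the true early-stance instant; only right-side stance enters
  the swing/stance feature, so the bias does not propagate there.
* The stance percentage read from the push-off valley carries a small
  negative bias (1–4 points) because the valley is a smooth minimum, not a
  point event.
* Dynamic acceleration during walking perturbs the fused attitude by a
  degree or two, leaking a few percent of the vertical signal (relative to
  the total RMS) into the near-empty medio-lateral axis; Earth-frame
  recordings are orientation-invariant at the total-signal scale, not
  exactly per axis.
* Yaw near ±180° requires circular statistics; `angle_median()` exists for
  exactly that reason, and naive averaging of headings will fail there.
* With fewer than three detected contacts a window carries no events and
  is dropped; very slow gait (> 3 s stride) would defeat the 2 s SSA
  embedding default.
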