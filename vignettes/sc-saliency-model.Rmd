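---
title: "A space-variant saliency model of the superior colliculus and its free-viewing analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A space-variant saliency model of the superior colliculus and its free-viewing analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scsaliency)
```

## The model in one paragraph

`scsaliency` implements a feed-forward computational saliency model tuned to
the primate visual and oculomotor system, computed not on the flat image but
on a gaze-centred, log-polar model surface of the superior colliculus (SC),
together with the analysis pipeline that relates the model's output to the
firing of SC neurons recorded during free viewing of dynamic scenes.  Video
frames are shifted to retinal (gaze-centred) coordinates at 200 Hz, embedded
in a black 100° × 100° surround, converted to DKL opponent colour planes,
and read through eccentricity-dependent difference-of-Gaussian (DoG)
receptive fields into a 200 × 200 space-variant grid.  Sixty low-level
feature maps (luminance contrast, red–green and blue–yellow double
opponency, oriented edges, flicker, opponent motion) pass through a
long-range competition operator and circular activation-field pooling, are
combined into six high-level feature maps, and finally — after square-root
compression — into a single feature-agnostic saliency response.

## Retinal input

Each display frame is shifted so the pixel under gaze lands at the centre of
a square field simulating 100° × 100° of a dark viewing environment
(`gaze_shift_embed()`); one retinal image is produced per 200 Hz gaze
sample, so eye movements alone change the model input.  The image is
decimated with a separable 3-tap binomial filter (`decimate_frame()`) to the
working resolution and converted to DKL opponent planes (`rgb_to_dkl()`).

The DKL conversion is display dependent; since no monitor calibration
travels with the package we default to a published chain — display gamma
2.2, sRGB primaries to XYZ (D65), Hunt–Pointer–Estévez XYZ→LMS, von-Kries
normalization at the display white — and expose the 3 × 3 matrix as an
argument so a measured calibration can replace it.  With the von-Kries
normalization the opponent planes are exactly zero on any achromatic input,
which the test suite asserts.

The working resolution defaults to 4 px/° (a 400-px field), a balance
between filter fidelity at the smallest foveal receptive fields
(σ ≈ 0.5 px) and the cost of filtering a 60-map bank at 200 Hz; tests use
1–2 px/° where only map-level structure matters.

## The space-variant transform

The afferent mapping of visual space onto the SC is complex-logarithmic:
with visual position written as the complex number z = R·e^{iΦ} (R in
degrees, Φ from the horizontal meridian),

    u = B_u · ln(|z + A| / A),   v = B_v · arg(z + A)

with A = 3°, B_u = 1.4 mm, B_v = 1.8 mm/rad.  `ottes_forward()` and
`ottes_inverse()` implement the pair analytically; they are exact mutual
inverses to machine precision, which the tests verify on 1,000 random
points.

Because this conformal mapping is discontinuous at the vertical meridian,
the model grid instead uses a simpler *variable-resolution* resampling per
hemifield: grid radius ρ ∈ [0, 1] maps to eccentricity R = a·(e^{ρ/b} − 1)
and the angular grid coordinate maps linearly to polar angle (scale c).
The three scale constants are not free choices: `fit_resampling_params()`
simulates a square sheet of SC surface (4.5 mm × 3.5 mm per hemifield),
projects it to visual space through the inverse conformal mapping, and
finds (a, b, c) by least squares with a Nelder–Mead simplex restarted from
points drawn log-uniformly within a factor of ten of unit scaling (1,000
restarts by default; the best-of-restarts objective is non-increasing in
the number of restarts on a fixed seed stream, which is tested).  The fit
typically lands near a ≈ 3.3, b ≈ 0.32, c ≈ 59°, close to the values the
conformal constants imply on the horizontal meridian.

The two hemifield sheets are joined at the centre column of the 200 × 200
grid, sampled at half-pixel offsets from the fovea so no column is
duplicated and no overlap-band bookkeeping is needed.  Each unit carries
its RF centre in visual coordinates and its optimal stimulus size from the
linear eccentricity law (0.75° at the fovea, 5° at 40°,
`eccentricity_size_law()`).

A neuron's RF boundary is the visual-space image of a 1.5 mm circular
point image centred on the SC location of its RF centre
(`rf_boundary()`); the resulting polygon is asymmetric, extending further
peripheral than foveal, as the logarithmic mapping requires.

## Receptive fields: DoG detectors in a Gaussian scale space

A detector with optimal stimulus size S and surround/centre ratio K uses
unit-mass Gaussians with

    sigma_c = S * sqrt(K^2 - 1) / (4 K sqrt(ln K)),   sigma_s = K * sigma_c.

These expressions follow from requiring that the response to a centred
disk, e^{−r²/2σ_s²} − e^{−r²/2σ_c²} as a function of disk radius r, peak
exactly at diameter S; a uniform field gives zero response.  The detector
is realized by sampling a Gaussian scale space of the retinal plane at the
unit's RF centre and subtracting the surround-level sample from the
centre-level sample (`dog_response()`).  The scale space uses half-octave
level spacing with linear interpolation between the two bracketing levels;
levels are blurred lazily and cached.  K = 6.7 for luminance and chromatic
features (retinal-ganglion-cell surrounds) with full-wave rectification
(double opponency); K = 3.2 for the spatiotemporal features (V1 surrounds)
with half-wave rectification.

Numerical sweeps (`dog_size_tuning()`) put the preferred disk diameter
within ~3 % of the design size: 5.13° for the 40° unit at 4 px/°, 0.77°
for a foveal unit at 16 px/°.  The residual bias is the level-interpolation
and pixel-quantization error and shrinks with resolution.

## The feature bank

The 60 low-level maps partition as 1 luminance + 1 red–green + 1
blue–yellow + 8 orientation (4 orientations × 2 spatial scales) + 1
flicker + 48 opponent motion (24 raw configurations × 2 signed
differences).  Orientation, flicker and motion are computed from the
luminance plane buffered over 9 frames (45 ms at 200 Hz):

* **Orientation** — quadrature pairs of oriented second-derivative-of-
  Gaussian filters (G2 and its Hilbert-pair approximation H2) applied to
  the temporally low-passed buffer at two spatial scales (σ = 1 and 2 px);
  the quadrature magnitude responds to both step edges and bars.
* **Flicker** — the quadrature magnitude of a zero-mean temporal band-pass
  pair, so any static image is silent.  The temporal filter family is not
  uniquely determined by its verbal description; a windowed quadrature
  band-pass at ~¼ cycle/frame was chosen and is silent on static input by
  construction.
* **Motion** — directed energy by align-and-integrate: buffer frames are
  shifted along the filter direction by v·t pixels before temporal
  integration, so a stimulus translating at the matched velocity stays
  aligned while the opposite direction blurs out.  Shifting commutes with
  the spatial convolution, which keeps the cost at two spatial
  convolutions per collapsed buffer.  Static stimuli excite both
  directions equally and cancel exactly in the opponent stage, which forms
  both half-wave-rectified signed differences per configuration
  (`opponent_motion()`).

The three drift speeds default to 1, 4 and 16 px/frame at the working
resolution (50–800 °/s at 4 px/° and 200 Hz — slow pursuit-like to
saccade-like image motion); they are configuration, not architecture
(`sc_config(speeds = ...)`).

Every energy plane then passes the eccentricity-dependent DoG stage, the
competition operator, and pooling, all on the SC grid.

## Competition and activation fields

`competition_operator()` is a single iteration of the classic within-map
salience competition: convolve with a large DoG (3° excitatory, 9°
inhibitory, converted to grid pixels at the nominal 0.5 °/px grid scale),
add the result back, subtract a global-inhibition constant, rectify.  The
constant is not printed anywhere; it defaults to 2 % of the post-addback
maximum so that a lone peak always survives in place while fields of many
equal peaks suppress one another (both behaviours are tested).

`pool_activation_field()` replaces each unit by the sum over a radius-3
circular pixel neighbourhood.  Because the footprint is fixed in SC
coordinates, the corresponding visual activation fields widen with
eccentricity and narrow toward the fovea.  Measured as the half-maximal
span of a probe-position sweep (`activation_field_sweep()`), the model's
activation field is ≈ 2.1° at 10° eccentricity — squarely at the ≈ 2°
design value — but ≈ 7.2° at 40°, short of the ≈ 10° design value.  The
shortfall is structural rather than parametric: with the centre sigma
pinned by the size-tuning law, the grid magnification pinned by the
conformal fit, and a radius-3 pooling disc, the half-max span at 40° is
bounded near 7–8° because the outermost pooling columns carry 1/7 of the
central weight and fall below half-max; probe diameter (1° versus the
local preferred size) and the competition operator change the number by
under half a degree.  A full-extent (rather than half-max) criterion would
reach ≈ 10–11°; we keep the half-max criterion because it is the sharper,
reproducible definition, and report the discrepancy rather than restating
the design value.

## From maps to a saliency response

High-level features are equal-weight means within type
(`combine_high_level()`), and the saliency response is the equal-weight
combination of their square roots (`saliency_response()`,
`saliency_map()`).  Feature time series at a neuron's RF centre are
normalized leave-one-out: each test clip is divided by the per-feature
maximum over all *other* clips, so a clip never normalizes itself
(`loo_normalize()`); test values above 1 are retained for correlation
analyses and only clipped when rendering maps.  Each feature is aligned to
the spike density by the delay (0–150 ms, 5 ms steps) maximizing the
mutual information between the two series (`mi_delay()`).  MI is estimated
from the joint histogram with 16 equal-occupancy bins per marginal; the
estimator's bias is irrelevant because only the argmax over delay is used,
and ties break toward the smaller delay.

## Gaze events

Gaze traces are decimated from the native rate to 200 Hz without smoothing
(`resample_gaze()`), blinks are filled by linear interpolation between
flanking valid samples (`interpolate_blinks()`), and saccades are maximal
spans exceeding 50 °/s with at least 1° of displacement
(`detect_saccades()`; velocity by central differences with a 2-sample
smoothing window, and event boundaries extended to the flanking velocity
troughs so the displacement covers the whole movement).  Inter-saccadic
intervals become fixations; those under 200 ms are kept but flagged and
excluded from analysis (`extract_fixations()`).  Drift correction during
pre-clip fixation uses flat-kernel mean shift with a 0.5° bandwidth,
escalating in 0.05° steps to 0.75° when two clusters tie, and rejecting
the location when no dominant cluster emerges (`mean_shift_mode()`).

The saccade-goal label compares the next saccade's direction with the
direction from the fixation toward the RF — in retinal coordinates simply
the RF's polar angle, since the RF is gaze-anchored.  The angular window
is not uniquely determined by the in/opposite design; symmetric ±45°
cones around the RF direction and its antipode are used, everything else
is labelled `other` and dropped, and the cone half-width is an argument
(`label_saccade_goal(cone_halfwidth = )`) for hemifield-style (±90°)
variants.  Neurons with RF eccentricity under 2° are excluded from
direction analyses.

## Neural analysis

Event-aligned firing uses a causal EPSP-like kernel (5 ms rise, 20 ms
decay); the model-fitting path bins spikes at 5 ms and smooths with a
50 ms Gaussian (`spike_density()`).  Classification follows the standard
windows: visual if 40–120 ms post-stimulus beats the −80–0 ms baseline,
motor if −25–+25 ms around saccade onset beats −150 to −50 ms, one-sided
paired tests at α = 0.05; visual-only → SCs, visuomotor → SCi, neither
visual → excluded (`classify_neuron()`).

Per neuron, included fixations are ranked into balanced tertiles of RF
saliency (`assign_tertiles()`, sizes within one, ties stable).  Curves are
averaged per condition, normalized 0–1 within the 0–500 ms post-fixation
window, and summarized over the saccade-free epoch (0–200 ms
fixation-aligned; −150 to −50 ms saccade-aligned, with fixations under
150 ms dropped from the saccade alignment so the epoch stays saccade
free).  Whether the 0–1 rescaling is per condition or across a neuron's
conditions is ambiguous in the verbal description; across-conditions is
the default (it preserves between-condition amplitude differences, which
the goal-split contrasts need) and per-condition is available
(`normalize_mode = "per"`).  Omnibus repeated-measures tests are
delegated to `stats::aov()` on the exported condition table — the
pipeline's contract is the table, not the F computation; per-bin curve
divergence uses paired Wilcoxon tests with Bonferroni–Holm correction;
feature-dependence and goal-split contrasts use one-sided paired t tests
with Bonferroni correction where multiple features are tested.

## The synthetic-data generator

Because no recordings are distributed, every stage is exercised on
synthetic data with known ground truth:

* `render_clip()` paints scripted events (luminance disks, colour disks,
  gratings, flicker patches, moving dots — one per high-level feature
  family) on a static textured background.
* `simulate_gaze()` alternates log-normal fixations (meanlog 5.428,
  sdlog 0.446, so the central 95 % spans roughly 95–545 ms) with 20–40 ms
  raised-cosine saccades; with probability p (default 0.8) the next
  target is the strongest active event.  When an RF is supplied it logs a
  graded RF-saliency proxy (active events weighted by a Gaussian of their
  distance to the RF) and plants a reaction-time advantage of 30 ms per
  unit RF saliency — the behavioural ground truth.
* `simulate_spikes()` draws inhomogeneous Poisson spikes at rate
  baseline + gain · saliency(t − latency) · gate, the gate being the
  goal-in indicator for SCi-like neurons and 1 for SCs-like neurons, plus
  an additive goal term for SCi.  Windowed-mean analyses are insensitive
  to the renewal structure at these counts, so Poisson suffices.

The study-condition defaults, chosen once: baseline 20 spk/s, saliency
gain 40 spk/s per unit saliency, SCi goal gain 10 spk/s, latencies 50–100
ms, per-fixation saliency Gamma(2, 0.15) truncated at 1.2, goal
probabilities 0.3/0.3/0.4 for in/opposite/other, 300 fixations per neuron
for population analyses.  The recovery experiments are sized for power at
those effect sizes: the latency-recovery experiment uses full sessions of
600 fixations (≈3 minutes of viewing — the MI alignment is estimated over
all of a session's clips, and sessions in this preparation range from
tens to ~1,800 fixations), and the behavioural experiment pools ≈6,000
fixations across 40 scripted clips.

What the generator does *not* emulate: natural-scene statistics (its
backgrounds are stationary textures), smooth pursuit, saccadic
suppression, bursting or adaptation in the spike trains, and any retinal
or cortical nonlinearity between the screen and the model.  Passing the
recovery tests therefore shows that the pipeline's inferences are correct
when its own forward model generated the data — a necessary check of the
code, not evidence about real SC physiology.

## Numerical choices and degenerate inputs

Gaussian blurs use unit-mass separable kernels with replicate padding
(constant planes are fixed points); kernels longer than 51 taps go through
the FFT.  Scale-space sampling clamps below the base sigma and
interpolates linearly between half-octave levels.  Constant feature or
rate series make the MI delay flagged and zero; flat rate curves
normalize to zeros with a flag; zero-variance correlations return `NA`
flagged; empty tertile-goal cells drop the neuron from that contrast with
a record.  Tertile ties resolve by original order, so results are
deterministic under permutation-stable inputs.

## Problem sizes

The shipped tests and the acceptance script run the grid fit with 25–200
simplex restarts (the objective is within noise of the 1,000-restart
default, which remains the function default), feature stacks at 1 px/°,
size-tuning sweeps at 4–16 px/°, activation-field sweeps of 81 probes, a
100-case latency-recovery experiment, 20 seeded population-signature runs
of 55 neurons × 300 fixations, and a 40-clip behavioural experiment.

## Known limitations

* The activation-field diameter at far eccentricity under-shoots the
  design value under the half-max criterion, as analysed above.
* The steerable motion stage uses integer-pixel frame shifts; at the
  default working resolution the slowest channel is therefore coarse for
  sub-pixel image motion.
* The affine + thin-plate-spline gaze calibration is out of scope; inputs
  are assumed pre-calibrated, and only the mean-shift drift-correction
  step is provided.
* The repeated-measures ANOVA is delegated to `stats::aov`; sphericity
  corrections, if wanted, are the caller's concern on the exported table.
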