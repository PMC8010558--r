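---
title: "Composite difference metrics for segment-resolved portal dosimetry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite difference metrics for segment-resolved portal dosimetry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During a VMAT (volumetric modulated arc therapy) delivery the accelerator
sweeps a single gantry arc while the multileaf collimator (MLC) reshapes
the beam at each of many control points ("segments"). Real-time portal
dosimetry watches the delivery as it happens: an electronic portal imaging
device (EPID) behind the patient records one image per segment, and each
measured image is compared against a predicted image computed at planning
time. If the delivery goes wrong — wrong monitor units, mis-positioned
leaves, unexpected anatomy such as rectal gas — the measured images drift
away from the predictions, and the sooner that drift is flagged, the less
incorrect dose is delivered.

The usual arrangement tracks several scalar difference metrics, each
against its own alarm threshold. The idea examined here is to add a single
*composite difference metric* (CDM): when an error nudges several metrics
upward *together*, each staying under its own threshold, a suitably shaped
combination can cross before any individual metric does.

`portalcdm` implements that detection machinery end to end, together with
a fully synthetic data engine — plans, phantom, deliberate errors, and an
analytic EPID forward model — so the behaviour of the metric, the
thresholding rule, and the weight optimisation can be studied and tested
without any measured data.

## Segment data and the four metrics

Images are compared on *section images*: running sums of the last 10
segment frames, which smooth per-frame fluctuation while staying local to
one part of the arc. The first 10% of segments are excluded from analysis
(the measured signal is unstable while the delivery settles), so for a
180-segment arc the evaluated sections run from index 19 to 180
(`evaluation_start_index()`).

For each section, four metrics compare measured (`M`) against predicted
(`P`) section images (`compute_metrics()`):

* **CAS** — central axis signal: `|mean(M_c) - mean(P_c)|` over the
  central 2x2 pixel block (the panel has an even number of pixels, so no
  single centre pixel exists; the 2x2 mean is this package's reading of a
  "central axis" sample).
* **MIV** — mean image value: absolute difference of means over the
  in-field mask.
* **MDM** — mean absolute difference as a percentage of the *maximum*
  predicted intensity.
* **MDL** — mean absolute difference as a percentage of the *local*
  predicted intensity.

MIV, MDM and MDL are evaluated over the mask of pixels whose predicted
intensity exceeds 10% of the image maximum; CAS is the only unmasked
metric. Because the mask excludes low-intensity pixels, the MDL
denominator is naturally bounded away from zero (an epsilon clamp guards
it anyway). CAS and MIV are taken as absolute differences so a single
one-sided threshold is meaningful in both directions of signal change.

The composite metric is a weighted power sum

```
CDM = sum_i  w_i * m_i ^ w_i ,   w_i in [0, 1],
```

with the convention that a zero weight contributes exactly zero. For
weights below one each term behaves like a root function: it rises
steeply at small metric values and then plateaus, so the CDM responds most
strongly when *all* constituent metrics are slightly elevated — precisely
the correlated sub-threshold signature the individual metrics miss. With
weights in {0, 1} the CDM degrades gracefully to a plain sum of selected
metrics. The first two metrics carry intensity units and the last two are
percentages; the working 0–100 intensity scale keeps their magnitudes
comparable, and the weights absorb the remaining difference in scale.

## Thresholds and detection scenarios

Alarm thresholds come only from error-free deliveries
(`build_thresholds()`): for each metric, take each reference patient's
maximum over their error-free trace, then set

```
threshold = median(maxima) + (max(maxima) - min(maxima)).
```

Since the median is at least the minimum, the threshold is at least the
largest observed maximum — the rule guarantees zero false positives on
the reference patients themselves, and extrapolates the upper extreme of
the error-free distribution for new patients. The CDM threshold is
derived by the same rule from the CDM traces, and because the CDM value
depends on its weights, it is recomputed for every candidate weight
vector during optimisation.

Detection (`first_detection_index()`) scans sections in order and reports
the first index at which the active metric set *strictly* exceeds its
threshold(s); ties do not trigger, which keeps the all-zero weight vector
inert. Three scenarios are compared: (1) one metric alone; (2) all four
metrics separately — the usual clinical arrangement; (3) the four metrics
plus the CDM. The active sets are nested, so detection indices obey
`index_3 <= index_2 <= index_1` delivery by delivery; undetected
deliveries are recorded at the sentinel `n_segments + 1` so that means
over mixed outcomes stay defined. A per-section traffic-light stream
(green / orange at 80% of a threshold / red) mirrors the real-time
display; the 80% near-miss level is this package's choice and is
configurable.

## Weight optimisation under leave-pair-out

Weights are found by exhaustive search on a grid (0.00 to 1.00 in steps
of 0.05; 21^4 = 194,481 vectors), minimising the mean scenario-3
first-detection index over every (patient, error case) of an optimisation
set (`optimize_weights()`). To guard against overfitting on a small
cohort, a leave-pair-out scheme is used: of six patients — three with a
varied-magnitude error menu, three with a fixed menu — each fold holds
out one varied and one fixed patient for testing and optimises on the
remaining four (two of each), giving nine folds. Ties on the objective
resolve to the first vector in grid order (CAS weight varying fastest);
the grid order is deterministic, so results are exactly reproducible.

The search is exact, not heuristic: every grid vector is evaluated. Two
structural facts make this cheap. Metric traces are computed once per
delivery and cached as matrices; and for a given weight level `w` the
transform `w * m^w` of a trace matrix depends only on `w`, so the 21
possible per-metric transforms are precomputed and each grid vector is
assembled by summing four cached matrices. Individual-metric thresholds
and the scenario-2 component of detection are fold constants. A
`cdm_objective()` reference implementation recomputes the objective
naively from the traces; the test-suite asserts the fast path equals it
vector-for-vector on coarse grids.

Fold summaries (`summarize_folds()`) report the median and range over
folds of the optimal weights, of the mean detection index per scenario,
of the per-fold benefit ratio (scenario-3 mean over scenario-2 mean,
never above one by nesting), and false-positive totals on held-out
error-free deliveries.

The objective weights every (patient, error case) equally — a varied-menu
patient contributes 20 cases and a fixed-menu patient 4 — rather than
weighting per patient; this is the package's documented choice.

## The synthetic data engine

### Plans and phantom

`generate_plan()` produces a single 358° arc of 180 segments at 2°
spacing with approximately even MU weighting (uniform ±8% about the mean,
2 MU per segment by default) and smoothly modulated apertures: an
elliptical, prostate-like target outline (50–100 mm extent) whose leaf
openings are perturbed per segment and per leaf pair by seeded
low-frequency sinusoids. This stands in for inverse-planned apertures; it
preserves the field-size and modulation scale that matter for the metrics
without a treatment planning system. The MLC has 40 leaf pairs of 5 mm
width at isocentre (the leaf geometry is not dictated by the delivery
system modelled here and is configurable). The phantom is a
water-equivalent box, 300 mm (G–T) x 300 mm (A–B) x 200 mm high, centred
on the isocentre.

### Deliberate errors

`error_menu()` defines the four error families: MU increase (2–10% in 2%
steps, fixed case 4%), retraction of all MLC leaves (2–10 mm, fixed
4 mm; each bank retreats from the aperture centre by the stated
magnitude, so each opening widens by twice the magnitude — the per-bank
convention is recorded and configurable), shift of all leaves (2–10 mm,
fixed 4 mm; area-preserving), and an air cavity in the phantom (10–50 mm
wide in 10 mm steps, fixed 20 mm; 50 mm high, 50 mm long, centred 40 mm
posterior of the isocentre as a rectal-gas analogue — the cavity length
and position are package choices, exposed in the constructor).
`inject_error()` is pure and validated: retraction cannot invert a leaf
pair, and a cavity must fit inside the phantom.

### EPID forward model

`predict_image()` composes, per segment:

1. the aperture mask rendered at the isocentre-plane pixel pitch
   (0.5 mm for the default 512 x 0.8 mm panel at SDD 1600 mm), with one
   panel pixel per isocentre sample — a single SDD/SAD magnification;
2. in-field signal `mu * gain * exp(-mu_w * (path + couch))`, with the
   water-equivalent path through the phantom (and any cavity) computed as
   an analytic chord under a parallel-beam approximation — full divergent
   ray tracing changes the images only at the field edges and is
   unnecessary for the detection behaviour under study;
3. couch attenuation as an extra 8.0 mm of water divided by cos(gantry)
   for gantry angles from 300° through 0° to 60° (16 mm at 60°);
4. a uniform out-of-field level proportional to the open aperture area
   and attenuated along the mean in-field path — the functional form
   (exponential in the mean path) is an assumption of this model;
5. two-Gaussian panel scatter (sigmas 2 mm and 20 mm, narrow-kernel
   weight 0.9), applied as separable truncated-Gaussian band-matrix
   products that preserve total signal on interior-supported images;
6. a sinusoidal longitudinal panel-sag shift, 4 mm peak-to-peak, applied
   with sub-pixel linear interpolation, identically for predicted and
   measured synthesis.

The attenuation coefficient (0.0049 per mm, 6 MV-like), scatter sigmas
and weight, out-of-field coefficient (chosen so the out-of-field level is
roughly 1–3% of the open-field signal), and the intensity gain (chosen so
section images span roughly 0–100, the working scale of rescaled portal
images) are model parameters of this package, all exposed in
`forward_params()`. The collimator rotation of 2° is ignored by default
(configurable): at these pixel sizes it is negligible for the detection
statistics. The model is linear in segment MU by construction — a pure
MU error scales every pixel exactly, which the tests exploit (`MDL = 4`
exactly under a noiseless 4% MU error).

### Measurement model

`simulate_measured_stack()` applies the forward model to the
(error-injected) plan and phantom, then perturbs it: a per-delivery
multiplicative output factor (SD 1%), additive per-pixel Gaussian noise
(SD 0.2 on the working scale), and an early-delivery instability — the
first 10% of segments are scaled by a deficit ramping linearly from 95%
back to 100%, emulating the unstable start-of-beam signal that motivates
excluding the first sections. The instability magnitude is invented (the
real effect is acquisition-specific); its role is to make the exclusion
rule consequential, not to calibrate it. All noise is seeded and
deliveries are bit-reproducible; one global seed fans out as
`plan seed = seed + 1000 * patient` and `delivery seed = plan seed +
case index`, so any single stack can be regenerated in isolation.

### What the generator does not emulate

No JPEG acquisition chain, panel calibration, dark/flood fields, gantry
-angle binning jitter, intra-segment motion, or patient anatomy. The
forward model that produces "measured" frames is the same model that
produces predictions, so the error-free residual is pure noise — real
predicted-measured residuals carry systematic model error, which raises
thresholds and delays detection. Passing tests therefore demonstrate the
correctness and internal behaviour of the detection machinery (nesting,
threshold guarantees, monotonicity in error magnitude, the correlated
sub-threshold advantage of the CDM), not clinical detection latency:
synthetic errors are cleaner than real ones, and absolute detection
indices here are earlier than would be seen on measured images.

## Numerical choices and degenerate inputs

* Detection requires a strict `>`; exact ties never trigger.
* The all-zero weight vector yields CDM = 0 with threshold 0 and can
  never fire.
* A fully closed aperture produces a valid (out-of-field-only) image; an
  all-zero predicted section is rejected (no mask exists).
* Scatter kernels are truncated at 4 sigma and renormalised; energy
  conservation on interior-supported images is asserted to 0.1%.
* Grid weights are rounded to 10 decimals so the 0.05 grid is exact in
  floating point; the grid step must divide 1 exactly.
* Ray/face tangencies in the chord computation include the boundary
  (closed box), matching the ray-marching oracle used in tests up to
  floating-point jitter.

## Problem sizes used in tests

The bundled tests and example runs use a reduced panel (64 x 64 or
32 x 32 pixels covering the same 409.6 mm physical extent) and, for unit
tests, shorter arcs (20–60 segments). The package's own end-to-end study
configuration — six patients, 180 segments, nine folds, grid step 0.1 —
runs in about a minute at 64-pixel resolution on one core; the full
512-pixel panel and the 0.05 grid are the defaults for real studies.
These sizes are the package's choices for its shipped test suite; all of
them are plain parameters.

## Known limitations

* The parallel-beam path and single-magnification aperture projection
  blur field-edge penumbra; metrics that average over the field are
  insensitive to this, but edge-localised error signatures are slightly
  smoothed.
* Thresholds derived from four synthetic patients inherit the small-
  sample volatility the median-plus-range rule is designed around; on
  held-out synthetic patients occasional false positives occur, mirroring
  the behaviour expected when transferring thresholds between patients.
* The optimisation objective treats undetected cases at the sentinel
  index; alternative policies (excluding them, or capping) would change
  the objective surface for weakly detectable cohorts.
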