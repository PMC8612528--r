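---
title: "Quantifying thermally induced behavior of Antarctic fishes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying thermally induced behavior of Antarctic fishes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rampetho)
```

## The experimental paradigm

`rampetho` analyzes video-tracked behavior of fishes in acute warming-ramp
(CTmax-style) experiments. A specimen acclimates overnight in a square tank
(93 cm x 93 cm by default), the last hour before warming serves as baseline,
and the water then warms at ~3.2 degC per hour until the animal loses
equilibrium (LOE), the humane endpoint. The raw material is a 30 Hz
tracker export: center-of-mass and snout coordinates, a temperature log,
an opercular head-width trace read off the video (quantized at 0.5 mm), and
an annotation stream of pectoral-fin and surfacing events. The target
species pair is a hemoglobin-expressing notothenioid (`HB_PLUS`,
*N. coriiceps*-like) and a hemoglobinless icefish (`HB_MINUS`,
*C. aceratus*-like), which differ in agility, ventilation rate, startle
repertoire, turning bias and fixed-action patterning.

Because each specimen reaches LOE at its own temperature, analyses that pool
specimens use the normalized thermal axis %T_LOE, the affine map sending the
ramp-start temperature to 0% and that specimen's T_LOE to 100%
(`percent_tloe()`).

## Kinematic observables

Instantaneous velocity is frame-to-frame center-of-mass displacement in body
lengths per second. Positions are smoothed with a 5-frame centered moving
average before differencing (`smooth_window`); edges use truncated windows.

Heading is the angle of the center-of-mass-to-snout vector, unwrapped.
Angular velocity Va is its centered finite difference, signed so that
positive means a rightward (clockwise) turn in the corrected (de-mirrored)
ventral view with x right and y up. The heading channel is *not* smoothed by
default (`heading_window = 1`): fast S-bends last only ~5 frames at 30 Hz
and any pre-smoothing clips their peaks. At this frame rate a half-sine
pulse of duration d recovers at best `P * cos(pi / (2 d fr))` of its true
peak P, so ~1000 deg/s S-bend peaks are systematically underestimated; the
package documents rather than corrects this.

## Maneuver detection and classification

Turn candidates are runs of |Va| above 20 deg/s (at least 3 frames), closed
by hysteresis at 10 deg/s (dips shorter than 3 frames do not end an event)
and merged when closer than 0.5 s. These thresholds are package choices —
the original measurements were manual — exposed in `default_config()` and
set so that noiseless synthetic maneuvers are recovered exactly.

Within an event, the peak |Va| is measured on a duration-adaptive smoothed
copy of Va (window ~ one sixth of the event length, capped at 7 frames, and
1 for short events). The rationale: slow maneuvers (withdrawals peak below
50 deg/s over ~1 s) tolerate smoothing that suppresses tracker jitter —
which otherwise inflates a max-over-frames peak estimate by several deg/s —
while the erosion of a genuine slow peak is under 2%; fast S-bends are left
raw. Multiple Va peaks are counted with a prominence criterion of 15 deg/s.

Classification follows the observed angular-velocity bands:

* **withdrawal-like**: peak |Va| < 50 deg/s *and* net backward
  center-of-mass displacement > 0.05 BL along the pre-turn heading;
  direction NONE;
* **S-bend**: peak |Va| > 500 deg/s;
* **multi-stage C-bend**: peak |Va| < 100 deg/s with >= 2 prominent peaks;
* **single-stage C-bend**: everything else.

The bands leave (100, 500] deg/s with multiple peaks unassigned; such events
are classified single-stage and flagged `band_ambiguous` rather than
silently resolved. S- versus C-shape of the body bend is not observable from
two tracked points; classification rests on the Va bands and displacement
features only.

## Lateralization

Free (non-near-wall) C-bend turns are tallied per 0.5 degC increment and,
for cohort profiles, per 5 %T_LOE increment. A turn is near-wall when the
center of mass at onset is strictly closer than half a body length to the
nearest wall (a distance exactly at the cutoff counts as free — walls bias
turn direction, hence the exclusion). The relative lateralization index is
`LR = 100 (R - L) / (R + L)`; a bin without tallied turns has no defined LR
and is excluded from testing rather than scored 0. Per bin, specimens' LR
values are compared against the theoretical 0 of a random choice with a
two-tailed one-sample t-test; bins with fewer than two defined values are
reported untested, and zero-variance bins are flagged degenerate (p is
reported at the machine floor when the shared LR is nonzero, 1 when it is
zero). No multiple-testing correction is applied across bins, matching the
source analysis; interpret per-bin p-values accordingly. Temperatures
exactly on a bin edge fall in the upper (lower-closed) bin; 100 %T_LOE
closes the last bin.

## Ventilation metrics

Opercular cycles are segmented at local minima of the 5-frame-smoothed head
width with prominence >= 0.5 mm, the stated accuracy of the width readout.
Per cycle: OA (opening amplitude) is the raw max-minus-min width; the
full-open time is the first frame attaining 95% of the cycle maximum (a
plateau tolerance for 30 Hz sampling of a smooth opening); OT is counted
from the last fully-closed frame (end of the quantization plateau at the
minimum) to full open, in integer frames; OV = OA/OT identically. Cycles
overlapping |Va| > 100 deg/s are dropped when kinematics are supplied,
since width cannot be measured during fast motion; the threshold is a
package choice and config-exposed. f_V is the count of cycle starts in
consecutive (not sliding) 60 s windows. Normalization divides each metric by
its baseline-window mean, so baseline maps to 1 and normalization is
idempotent. Cross-specimen correlation of ventilation series interpolates
both onto a common %T_LOE grid and reports Pearson r.

## Respiratory-locomotor coupling

For each single-stage C-bend, |Va| and head width are extracted over
(-0.5 s, +1.5 s) around onset — covering the turn and glide — normalized
per turn (|Va| by its maximum; width to [0, 1], 1 = open; per-turn rather
than per-bin normalization, following the stated convention), and averaged
in 1 degC bins. The synchrony statistic is the lag of the opercular minimum
*nearest* the |Va| peak, with minima located on the smoothed width and
plateau runs centered. Nearest-minimum lags are bounded by half a cycle, so
under no coupling the lag normalized by the local cycle period is uniform on
(-1/2, 1/2] — the property the decoupled-control test checks with a KS
test — while programmed phase-locking (opercular closure at maximal head
rotation) gives sub-frame lags.

## Other statistics

Species T_LOE comparisons use Welch's unequal-variance two-tailed t-test.
With equal group sizes and (near-)equal variances the Welch-Satterthwaite
df reduces to the pooled nA + nB - 2 — for two groups of five, df = 8 and
the critical value at alpha = 0.05 is 2.31 — and `compare_t_loe()` reports
both df conventions for transparency. p-values come from the t distribution
CDF, not tables. The dissolved-O2 saturation reference implements the
Garcia-Gordon refit of the Benson-Krause solubility coefficients with the
salinity term (11.4 mg/L at 0 degC, 35 psu), strictly decreasing in both
temperature and salinity.

## The synthetic-experiment generator

No tracking data are deposited with the source study, so the package ships a
generator (`simulate_experiment()`) whose defaults encode the study
conditions, with an exhaustive ground-truth log that serves as the oracle
for every detector. Per species (`default_species_configs()`):

* ramp 3.2 degC/h from 0.5 degC after a 60 min baseline; T_LOE drawn from
  N(15.8, 0.9) for `HB_PLUS` and N(13.8, 0.9) for `HB_MINUS` (the reported
  means, with SEM 0.4 over five fish scaled to a per-specimen SD), clipped
  to [T0+5, T0+20];
* maneuvers from per-class inhomogeneous-Poisson rate curves versus
  temperature. `HB_PLUS`: scarce S-bends near +10.5 degC, single-stage
  C-bends ramping to ~10/min total (base turns plus triplet turns) between
  +12 and +14 degC; `HB_MINUS`: sporadic multi-stage C-bends at a flat
  0.25/min and withdrawals in the +9 to +12 degC window. Amplitudes are
  uniform within class bands (620-1000, 110-245, 55-85, 25-45 deg/s) —
  the source reports only the band edges, so the within-band law is a
  package choice, config-exposed. The S-bend floor sits at 620 rather than
  just above 500 deg/s so that 30 Hz sampling of a 0.15-0.2 s pulse cannot
  pull a recovered peak below the 500 deg/s classification boundary;
* turn direction from a laterality bias of +0.8 below and -0.8 above a
  reversal at 65 %T_LOE (`HB_PLUS` only; this reproduces the
  rightward-then-leftward preference with its reversal near +11 degC);
* ventilation: piecewise-linear fold curves versus temperature with
  baseline f_V 30 (`HB_PLUS`) vs 16 (`HB_MINUS`) cycles/min, a bell peak of
  2.5x / 2.61x at +8.25 degC, then a species-specific decline-to-plateau
  (`HB_PLUS`) or sustained plateau (`HB_MINUS`); OA rises monotonically to
  2x at LOE; OT mirrors f_V biphasically. The trace is a per-cycle
  half-cosine opening/closing waveform, quantized to 0.5 mm, with 2% cycle
  period jitter and 0.15 mm width noise;
* fin behavior: fanning from +8 degC (long ~1 Hz bouts for `HB_MINUS`,
  short slower bouts for `HB_PLUS`), splays in +10 to +16 degC (`HB_PLUS`)
  or +9 to +13 degC (`HB_MINUS`) with durations growing with temperature,
  surfacing between +6 and +12 degC;
* Splay-Turn-Glide triplets (`HB_PLUS` only) as a splay ending shortly
  before a scheduled C-bend followed by a decaying-speed glide; when
  coupling is on, the opercular cycle boundary nearest each C-bend Va peak
  is snapped to it (phase-locking), disabled within the last 1 degC before
  LOE where synchrony is lost.

Maneuvers are realized as half-sine Va pulses on the heading channel
(multi-stage C-bends as 2-4 pulses with 0.25 s gaps; withdrawals as a low
pulse plus a backward center-of-mass excursion). The trajectory is a
station-and-travel path: the fish holds at an anchor during each maneuver
and travels between anchors at sub-cap labriform speeds (0.8 BL/s `HB_PLUS`,
0.4 `HB_MINUS`), reproducing the alternating locomotor phases. Tracker
artifacts are additive Gaussian positional jitter (0.05 cm) and occasional
single-frame dropouts injected at CSV-export time.

What the generator does *not* emulate: hydrodynamics, body-shape midlines,
wall-following behavior (anchors are a folded random walk, so near-wall
events arise from geometry rather than thigmotaxis), heading-locomotion
coherence outside maneuvers, and any correlation between behavioral streams
beyond the programmed ones. Passing recovery tests therefore demonstrates
that the estimators invert the assumed data model at realistic noise — not
that the model captures real fish. Two realization details depart from pure
scheduling for tractability and are visible in the log: events that would
overlap are pushed apart by a 4 s minimum gap (preserving counts), and
withdrawal/triplet anchors are kept in the tank interior so retractions and
glides stay in bounds.

## Numerical choices and degenerate inputs

* Timestamps must be uniform at 1/frame_rate within 2e-4 s (vendor exports
  round milliseconds); NaN coordinate runs up to 5 frames are interpolated
  with a warning, longer runs are fatal.
* Pixel-to-cm scale comes from the config; it is never inferred.
* Zero-variance laterality bins, empty ventilation windows, bins without
  turns, and traces shorter than one cycle all produce typed markers
  (degenerate flags, NA means, empty tables) rather than silent zeros.
* Problem sizes in the test suite: classifier studies use ~230-270
  maneuvers per run (one flat-rate run per noise level), ventilation
  recovery uses 20 seeded runs, the laterality simulation study 100
  five-specimen cohorts at the scheduling level, and coupling two full
  experiments; these sizes give stable pass/fail behavior for the stated
  thresholds. The phase-locking construction check runs with zero width
  noise (it verifies the construction); the decoupled uniformity control
  runs at default noise.

## Known limitations

Midline curvature (true S- vs C-shape) is out of reach of a two-point
tracker; escape latency is undefined without a stimulus; the near-wall
exclusion is applied to laterality tallies only, as stated for C-bends; and
fanning sub-modes (sway vs sweep) are annotation-level inputs, not computed.
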