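---
title: "Detecting ski-skating contact events from wrist and ski IMUs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting ski-skating contact events from wrist and ski IMUs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skatephase)
```

## The problem

In cross-country ski skating, each propulsion cycle interleaves pole and ski
ground contacts in a pattern that defines the sub-technique ("gear"): G2
poles once per cycle, offset from the ski plant (steep uphill); G3 poles with
every leg push (moderate terrain); G4 poles once per cycle, synchronously
with a ski plant (flat, fast terrain). Four temporal events per limb pair —
pole initial/final contact (`P_ON`, `P_OFF`) and ski initial/final contact
(`S_ON`, `S_OFF`) — induce the inner-cycle parameters coaches care about:
pole contact and swing time (`P_CT`, `P_SW`), ski contact and swing time
(`S_CT`, `S_SW`), and cycle time (`S_CY`, one left ski plant to the next).

skatephase implements an event detector for four body-worn inertial units
(left/right wrist, left/right ski; 3-axis accelerometer and gyroscope,
256 Hz), a marker-based reference detector (vertical marker position,
200 Hz), the cycle/phase assembly, a sub-technique decision tree, the
method-agreement statistics, and a synthetic trial generator that provides
ground truth for all of it.

## Detection pipelines

All filtering is zero-phase (forward-backward 2nd-order Butterworth). The
causal-versus-zero-phase choice is not neutral here: the deliverable is event
*timing*, and a causal filter would bias every detected time by its group
delay. The stated cutoff therefore applies per pass (the cascade is -6 dB at
the cutoff). Edges are odd-reflection padded by roughly three
impulse-response lengths with steady-state initial conditions, because trials
start and end mid-motion.

**Wrist (pole events).** The yaw angular velocity is integrated and
high-passed at 0.1 Hz to remove integration drift; positive maxima of the
resulting yaw angle (prominence at least 5 degrees) anchor the poling cycles.
Within each anchor-to-anchor segment, the first positive yaw-acceleration
peak with topographic prominence of at least 1 m/s^2 marks the pole impact;
`P_ON` is the last negative acceleration peak before it (searching back no
further than the anchor). `P_OFF` is the most negative peak of the 5 Hz
high-passed yaw acceleration within 0.15 s of the yaw-angle minimum.

**Ski (ski events).** The roll angular velocity, low-passed at 2 Hz,
carries the leg-cycle rhythm; positive-going zero crossings anchor the
cycles. A crossing only counts when flanked by sustained (at least 50 ms)
lobes beyond a hysteresis band of 10% of the signal's 95th-percentile
magnitude — plain zero crossings would let residual noise and filter edge
transients mint anchors. A coarse `S_ON` is the maximum of the drift-removed
integrated roll angle within the cycle; the precise `S_ON` is the tallest
raw vertical-axis acceleration peak within 0.15 s of it. `S_OFF` starts from
the roll-angle minimum in the final 40% of the cycle and takes the most
negative raw vertical acceleration peak within 0.15 s.

Two readings deserve a note. First, "positive acceleration peak" is taken to
mean a local maximum whose *value* is positive (and symmetrically for
negative peaks): with the topographic prominence convention bounded by
window ends, a sub-zero noise bump adjacent to a window boundary can acquire
prominence above the gate and pre-empt the true impact peak; requiring the
sign removes this artifact and matches the plain reading of the phrase.
Second, every "close to" window (`near_window_s`, default 0.15 s) is a
configuration key; 0.15 s is below half the shortest phase at the fastest
protocol speeds, so windows of neighbouring events cannot collide.

A cycle whose constituent peak is absent yields a miss, never an
extrapolated event; per-segment outcomes are kept so detected plus missed
always equals the number of processed cycles. Missed events can break the
strict ON/OFF alternation of the assembled series, so detector output is
built without validation; `check_event_series()` reports violations, and on
noiseless input the output validates strictly.

**Reference (marker) detector.** Ground-proximity sections are preselected
where the vertical position is below the 10% quantile plus 2 cm (both
configurable; the treadmill height is constant within a trial). For each
proximity run, contact (`*_ON`) is the maximum of the second derivative of
vertical position in a window centred on the run start; release (`*_OFF`)
likewise at the run end. Two design choices matter:

* The track is low-passed (2nd order, 6 Hz) before double differentiation —
  the customary treatment of marker data for gait analysis. At 200 Hz the
  second-difference operator amplifies 1 mm marker noise to ~100 m/s^2,
  far above the ~5-12 m/s^2 curvature signal of a landing. The cutoff was
  chosen by sweeping 4-16 Hz against generator ground truth: scatter of the
  detected times falls monotonically as the cutoff drops, while the cost is
  a *constant* per-event-type advance of the curvature maximum. Precision —
  what the validation reports — depends only on the scatter; the constant
  advance appears as bias, common to all events of a type.
* The curvature-search window defaults to ±0.15 s rather than ±0.05 s. A
  limb touching down with zero vertical velocity (C1 contact) crosses any
  height threshold while still descending, so the proximity-run boundary
  precedes the true contact by `sqrt(margin/arc height)/pi` of the flight
  duration — up to ~0.11 s at plausible arc heights. A ±0.05 s window would
  often exclude the true curvature maximum altogether.

Reference timestamps stay on the 200 Hz grid (5 ms resolution), without
sub-sample interpolation.

## Cycles, phases and the decision tree

Cycles start when the left ski hits the ground and are half-open (each event
belongs to exactly one cycle). Left and right pole events within 0.12 s of
each other are one double-poling action and merge to their mean time; the
pairing maximises the number of within-window pairs, then minimises the
total asynchrony (an optimal non-crossing assignment).

Pole plants are attributed to cycles through their *nearest ski plant*
rather than by raw interval membership: the techniques pole in fixed
relation to the leg pushes, and a plant nominally synchronous with the
cycle-opening ski plant would flicker between neighbouring cycles under
realistic timing jitter, corrupting plant counts. `delay_Pon_Son` is the
attributed plant-to-push gap (the absolute value of the shortest pole-ski
plant time difference); `delay_Soff_Poff` is the pole release minus the
nearest preceding ski release, positive when the pole leaves the ground
last.

The decision tree uses exactly the quantities the pipeline computes: two
merged plants in a cycle means poling with every push (G3); one plant is G4
when `delay_Pon_Son` is at most 0.10 s and G2 otherwise; no plant, or
missing constituent events, is the undetermined sink (`NA`, serialised as
`NaN`). The 0.10 s synchrony threshold sits between the G4 template
(plant within 0.03 s of the push) and the G2 template (offset at least
0.15 cycle durations, i.e. at least 0.17 s at the fastest cycle rate); both
are configuration keys. The exact branch structure of the original tree is
not recoverable from its description, so this tree reproduces its inputs and
outputs without claiming branch identity.

## Agreement statistics

Each detected event is attributed to the closest reference event, greedily
by increasing absolute error, bounded by half the median cycle duration
(beyond which an attribution would necessarily cross into another cycle).
Unattributed reference events are misses; unattributed detections are
spurious. The per-trial bias is the mean error and the precision the n-1
standard deviation, in ms, with the sign convention `error = reference -
IMU` (positive: detected earlier on the IMU). Across trials the median and
type-7 IQR summarise bias and precision (`b_mu`, `b_sigma`, `sigma_mu`,
`sigma_sigma`); medians because the intra-trial statistics are not normally
distributed. Phase errors are computed per phase occurrence (per poling
action for pole phases — a G3 cycle contributes two), paired between systems
through their opening events, both absolutely and relative to the reference
phase duration.

Between-technique differences are tested with a Kruskal-Wallis rank test
(tie-corrected, chi-square approximation) and, pairwise, the
Dwass-Steel-Critchlow-Fligner post-hoc test: each pair re-ranked alone,
tie-corrected Wilcoxon rank-sum, standardised and referred to the
Studentized range distribution with k groups and infinite degrees of
freedom. Fully tied pairs return statistic 0 and p = 1 by convention.

## The synthetic generator

`trial_spec()` fixes the study conditions; the defaults are the conditions
under which everything in this package is validated: cycle rates 0.9, 0.8
and 0.7 Hz for G2/G3/G4 (matching the paces at which the techniques are
used), ski contact 0.55 and pole contact 0.30 of the cycle, accelerometer
noise SD 0.5 m/s^2, gyro noise SD 2 deg/s, gyro bias 0.5 deg/s, independent
Gaussian event jitter SD 10 ms, marker noise SD 1 mm, and a 30% chance that
a ski landing splits into two wheel impacts up to 60 ms apart (the dominant
real-world ambiguity of roller-ski `S_ON`). Sub-technique templates place
the left ski plant at the cycle start, the right near mid-cycle, and the
pole actions as the gear prescribes (G2 offset drawn from 0.15-0.25 cycle
durations; left-right pole asynchrony 40 ms in the asymmetric G2, 12 ms
otherwise).

Rendering produces, per wrist: a piecewise-cosine yaw-angle oscillation
peaking 35 ms before each plant and bottoming at each release (its analytic
derivative, plus bias and noise, is the gyro channel); a smooth
swing-deceleration dip into the plant, a sharp negative-positive impact
doublet (~30 ms wide) at the plant and a 10 ms negative transient at the
release on the yaw accelerometer. Per ski: a roll oscillation peaking at the
plant and bottoming at the release (with a trailing half-cycle rise so the
rhythm does not freeze at the last rendered release), and vertical
acceleration spikes — positive at the plant, optionally split into two
wheel impacts, negative at the release. Marker tracks are near-zero contact
plateaus joined by raised-cosine flight arcs (pole arcs 0.12-0.25 m, ski
arcs 0.05-0.12 m), C1-continuous so the curvature maxima coincide with the
contact times. One pad cycle is rendered before and after the ground-truth
span so boundary events have complete detection segments; pad detections
match no ground truth and are accounted spurious.

What the generator does *not* emulate: athlete-specific movement
variability, technique asymmetries beyond the fixed side offsets,
soft-tissue and mounting artefacts, speed/incline dependence of the
waveforms, and any kinetic content. Passing tests therefore demonstrate
that the detectors recover the temporal structure the signals encode under
realistic noise — not that the pipeline is validated on real athletes.

Randomness: one root seed per trial; `simulate_trial()` derives one child
seed per stage (schedule, markers, IMU) so each stage is independently
reproducible; `batch_specs()` derives per-trial seeds from the batch seed.

## Numerical choices and degenerate inputs

* Peak prominence uses the standard topographic definition bounded by the
  signal ends; equal-height plateau samples collapse to the leftmost.
* Non-finite samples are rejected at construction; a constant marker track
  yields an all-true proximity mask with a warning.
* Cycles whose anchors violate the plausible spacing band (0.4-4 s) are
  thinned by dropping the lesser-prominence anchor.
* Jittered schedules that violate event ordering or the 50 ms refractory
  bound are re-jittered per cycle; if more than 10% of cycles cannot be
  repaired the generator refuses.
* Trials with fewer than two errors contribute no intra-trial statistics
  and are excluded from pooling; relative errors with non-positive
  durations are excluded.
* The discrete curvature maximum of a contact falling between 200 Hz
  samples can sit up to 2 samples from the true junction; noiseless
  recovery is asserted to 2 samples (10 ms).

## Problem sizes

The validation study used throughout runs 30 trials (10 per technique) of
50 cycles — about 33,000 synthetic events — and a 100-seed robustness sweep
at 3 trials of 12 cycles per seed. These sizes give stable medians and IQRs
while a full run stays comfortable on a laptop; all statistics are pooled
exactly as in the per-trial/inter-trial scheme above, so larger batches
change only the sampling error of the summaries.

## Known limitations

* The reference detector's event times carry a constant per-event-type
  advance from pre-smoothing; comparisons between two *detectors* (bias
  rows) inherit it, while precision rows do not.
* The alternation invariant is only guaranteed on series without misses.
* The decision tree covers G2/G3/G4 on straight treadmill skating; turning
  techniques and G1/G5 are out of scope.
* The free-gliding phase has no temporal event signature in these signals
  and is not detected.
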