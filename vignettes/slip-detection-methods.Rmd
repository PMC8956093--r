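---
title: "Detecting and classifying slips on icy walkways: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying slips on icy walkways: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icegait)
```

# The problem

Footwear slip-resistance testing on ice — walking participants up and down an
ice-covered walkway tipped to increasing slopes — traditionally relies on a
human observer to call each step a slip or a non-slip. Observers differ in
vigilance and skill, and small slips are easy to miss. `icegait` implements an
automated replacement: from the 3-D trajectories of a heel marker and a toe
marker sampled at 150 Hz, it segments the recording into strides, extracts 36
hand-crafted kinematic features per step, and classifies each step with two
3-class one-vs-rest linear support vector machines:

* a **toe-slip classifier** — no toe slip (NTS), backward toe slip (BTS:
  backward foot motion just before toe-off), forward toe slip (FTS: forward
  motion just before toe-off);
* a **heel-slip classifier** — no heel slip (NHS), backward heel slip (BHS:
  backward motion just after heel contact), forward heel slip (FHS: forward
  motion just after heel contact).

A step is a *slip* when either classifier assigns any slip class — the binary
decision is the inclusive-or of the four slip indicators (`slip_flag()`).

# Pipeline

## Preprocessing

Marker positions are filtered with a fourth-order (effective), zero-lag,
dual-pass Butterworth low-pass at 12 Hz and differentiated to velocities
(`butterworth_zero_lag()`, `differentiate_signal()`). "Fourth-order dual-pass"
is read the standard biomechanics way: a second-order design applied forward
and backward, giving fourth-order attenuation with zero phase lag;
`filter$order_per_pass = TRUE` switches to a full fourth-order design per pass.
Edges are handled by reflective padding (three filter orders long) and each
pass removes its leading value first, so a constant signal passes through
bit-exactly and start-up transients do not leak into short bouts. Acceleration
is obtained by differentiating the filtered velocity; there is no second
filtering stage.

All data are expressed in a participant-centric frame: the anterior–posterior
(AP) axis is flipped if necessary so forward progress has positive velocity
(`to_participant_frame()`). Inference uses the net heel AP displacement and
refuses to guess when that displacement is under 5 cm. Coordinates are assumed
walkway-aligned, so "vertical" means surface-normal when the walkway is
inclined; this is an assumption, not a measurement — gravity-aligned exports
should be rotated before import.

## Stride segmentation

Toe-off (TO) is detected from heel vertical velocity: peaks of at least
0.13 m/s, at least 90 frames (0.6 s) apart (greedy thinning by descending
height), with the event placed 5 frames (0.03 s) after the peak. A minimum
peak prominence of 0.02 m/s suppresses noise ripples; the height and
separation constants are protocol constants, the prominence floor is ours.

Heel contact (HC) has no published closed-form rule, so the package documents
its own reconstruction (all constants in `pipeline_config()$heel_contact`):
between consecutive toe-offs, candidate troughs of heel vertical velocity are
found in sliding 0.08-s windows; a candidate survives when (i) the heel height
at the trough is below 35% of the trial's heel-height range and (ii) the foot
angle sits in a band above the flat-foot offset — the heel-first landing
posture. The earliest survivor wins, and HC is placed at the first following
frame where the descent has slowed above −0.05 m/s (the heel has effectively
stopped falling). One deliberate deviation from a "foot angle decreasing, foot
angular velocity negative" formulation: at the instant of the pre-contact
velocity trough the heel is still descending, so the heel-to-toe height
difference — hence the foot angle — is momentarily *increasing*; requiring a
negative angular velocity there rejects true contacts. The posture band
(angle between offset − 2° and offset + 25°) captures the same intent —
rejecting mid-swing toe-down troughs — without that artefact.

A complete stride needs the previous HC, this TO, this HC and the next TO;
its boundaries are the midpoints between those event pairs. Strides
overlapping a direction change are discarded, where a direction change is a
*sustained* (> 0.5 s) sign reversal of heel AP velocity — slips themselves
produce brief negative excursions, so an instantaneous sign test would throw
away exactly the steps of interest.

## Features

`compute_features()` evaluates the 36-feature catalogue
(`feature_catalogue()`) per stride. Windows are: *before toe-off* (stride
start to TO − 1), *between toe-off and heel contact* (TO..HC), *after heel
contact* (HC + 1 to stride end). Two anchors support several features:
`T_heel_off`, the first frame before TO where heel AP acceleration reaches
0.5 m/s² while heel AP velocity is below 0.1 m/s; and `T_max_velocity`, the
frame of maximum heel AP velocity (earliest on ties). Curvature features use
κ(t) = v″/(1 + v′²)^{3/2} with central differences in per-frame units — the
formula names no time step, and per-frame units keep the statistic
scale-stable at the fixed 150 Hz rate.

Interpretation choices a re-implementer must make, and ours:

* "peaks separated by X ms" is a minimum inter-peak distance (7 ms at 150 Hz
  means effectively every local extremum); counted peaks must clear a
  0.02 m/s noise floor in both value and prominence, so shallow
  filter-ringing bumps beside deep troughs are not counted;
* lobe areas (features 8, 9, 13, 14, 29) are trapezoidal integrals between
  the zero crossings surrounding a peak, reported as magnitudes; peaks
  sharing a lobe are not double-counted;
* feature 9 ("a negative peak different from feature 8's") takes the largest
  remaining lobe when more than two exist;
* feature 14 integrates planar heel speed √(AP² + ML²) above a 0.05 m/s
  floor (a speed signal has no sign and a nonzero noise mean, so a floor is
  required);
* mid-stance (feature 10) is the frame of minimum total foot speed between
  HC and the stride end;
* features 33/34 use the next stride's `T_heel_off` when one exists;
* degenerate inputs (absent anchors, no qualifying peaks) yield defined
  defaults — counts/areas/velocities/curvature sums of 0, binary 0 — with a
  per-feature validity mask retained, because the classifiers need complete
  vectors.

Feature selection (`histogram_overlap_selection()`) builds class-conditional
histograms on the pooled min–max range with 50 bins, normalised per class,
and discards a feature only when *every* pairwise class overlap (the sum of
binwise minima) is ≥ 75%. The shipped classifiers use the frozen catalogue
subsets (`selected_features()`); the selection operation exists to re-derive
subsets on new data.

## Classification

For each taxonomy, the training recipe (`train_slip_model()`) is: random
under-sampling of the no-slip class down to the total slip count (slip steps
are never discarded); an 80:20 training/validation split stratified by class
and participant; z-score normalization fitted on the training split only
(zero-variance features map to 0); one binary linear SVM per class
(class-vs-rest, via `e1071`/libsvm, reduced after fitting to an explicit
weight vector and intercept); a probability-like score per class from a Platt
sigmoid fitted to the training decision values (raw margins available via
`classifier$score = "margin"`); prediction by the largest score with exact
ties resolved to the no-slip class. The SVM cost C is tuned over
{0.01, 0.1, 1, 10, 100} by validation macro-F1, smallest C on ties.

Normalization is fitted after under-sampling (on the under-sampled training
split): the alternative order is defensible too, but calibrating on the same
sample the classifier sees keeps the scores and the margins consistent.

## Evaluation

`losocv()` implements leave-one-subject-out cross-validation: each
participant is held out once; the training pool is under-sampled 10 times
(per-repeat seeds are `seed + repeat`); C is tuned once per fold, on the
first repeat's validation split, and reused across that fold's repeats —
repeats measure under-sampling variance, not hyperparameter variance, and
this keeps the cost of a full run proportionate. The final per-repeat model
is fitted on the 80% training split; the validation split is used for tuning
only. Metrics follow the exact formulas precision = tp/(tp+fp), recall =
tp/(tp+fn), F1 = harmonic mean; a metric with an empty denominator is
reported absent (`NA`), never 0. Averaging is mean over repeats within fold,
then mean over folds, and the class-average row is the arithmetic mean of
the three per-class values. Because an "average F1" can also be read as the
harmonic mean of the averaged precision and recall — and the two disagree in
the third digit — the summary reports both (`f1` and `f1_of_averages`).

`sensitivity_analysis()` perturbs TO and HC independently by −15..+15 frames,
re-extracts features with the perturbed event (strides whose perturbed event
leaves its bounds are excluded and counted), and reports each classifier's
macro-F1 change against offset 0.

`bland_altman_timing()` quantifies event-timing agreement: one-to-one nearest
matching within 15 frames (the sensitivity range), then mean difference and
mean ± 1.96 SD in milliseconds.

# The synthetic gait generator

The study's human dataset is private, so the package ships a generator
(`generate_step()`, `generate_participant()`, `simulate_cohort()`) whose
noiseless output provably carries each class's defining signature, and whose
cohorts exercise every stage including LOSOCV. It is first-class, tested
code — not a fixture.

Velocity profiles are sums of raised-cosine lobes, so every displacement is a
closed-form integral and ground truth (event frames, labels, slip distances)
is analytic. Per gait cycle (nominal toe-off T, 150 Hz): heel vertical
velocity has a rise lobe peaking at T − 5 (making the operational toe-off,
peak + 5, equal T), a mid-swing descent lobe, and a short final descent
ending at heel contact T + 58 whose trough height sits at 12.5% of the heel
height range (the mid-swing trough sits at 62.5%, so the 35% height gate
separates them); AP velocity is one swing bell per marker whose area is the
step length (default 0.9 m); toe markers sit 0.248 m ahead and 0.03 m above
the heel marker, giving the characteristic non-zero flat-foot angle offset
(≈ 6.8°).

Class perturbations (slip distance d = the displacement integral):

* **BTS / FTS** — an AP lobe on both markers (the foot slips rigidly) in the
  last quarter-second before toe-off, negative/positive respectively;
* **BHS / FHS** — a negative/positive AP lobe starting 2 frames before heel
  contact (a slip begins at touchdown, so AP velocity at contact is slightly
  nonzero);
* **FHS variant** — a lobe centred on heel contact: AP velocity is elevated
  *at* contact and decays monotonically with no post-contact local maximum.

Realism layers applied at the bout level (not in the pure single-step
archetypes, whose signatures stay analytic): most toe slips carry small extra
vertical-velocity ripples (foot-clearance disturbance) and a few ordinary
steps show the same "abnormal swing" ripples; abrupt heel slips usually leave
a 5 Hz, 0.07 m/s residual micro-motion through stance that defeats the
full-stop criterion (the smooth variant does not, which is what makes it the
hard heel-slip class); uphill backward toe and heel slips frequently co-occur
within a step; a forward toe slip always follows a forward heel slip and
often shares its step with one; and a quarter of non-toe-slip steps carry a
sub-slip AP "shuffle" of 0.2–1.0 cm that is *not* labelled a slip —
deliberately overlapping the small end of the forward-toe-slip range
(0.8–3 cm), because distinguishing small forward toe slips from abnormal
push-offs is genuinely ambiguous even for human observers. That ambiguity
is what makes FTS the weak class in the benchmark, mirroring the real
protocol's behaviour. Slip distances are drawn per class (backward heel
slips smallest, 0.5–1.5 cm) and span below 1.5 cm to above 6 cm overall.

Participant styles (cadence ~N(100, 4) steps/min, step length ~N(0.90,
0.05) m, vertical amplitude scale ~N(1, 0.06), 4% per-step jitter) are drawn
from the participant seed, so subjects genuinely differ for LOSOCV. Bouts
alternate ascending/descending over a 0–12° slope schedule; ascending bouts
are enriched in backward slips, descending bouts in forward heel (and rare
forward toe) slips; level bouts are mostly normal. Marker noise is additive
Gaussian position jitter (SD 0.5 mm) before filtering.

What the generator does **not** emulate: harness or whole-body dynamics,
force-dependent friction, marker occlusion patterns, real between-step
correlation structure beyond the co-occurrence rules above, or the exact
amplitude calibration of any real dataset. Passing the benchmark therefore
demonstrates that the pipeline's logic is correct and robust at a realistic
operating point — not that the published real-data scores are reproduced.

# Benchmark sizes and numerical choices

The acceptance benchmark uses 9 participants × ~1000 steps (~8,500 labelled
strides after segmentation), 9 LOSOCV folds × 10 under-sampling repeats, and
a 200-step (100 slip / 100 non-slip) sensitivity sample over offsets
−15..+15 — sizes chosen to mirror the study design at a scale a desktop run
completes in minutes. Tie-breaks are all deterministic (earliest frame for
anchors and trough selection, smallest C, no-slip class on score ties), every
random draw flows from a user seed, and repeated runs are bit-identical.

Known limitations: C3D input is not supported (use the documented CSV
dialect); single-foot analysis (contralateral context is modelled only
through the generator's co-occurrence rules); no online/streaming detection;
heel-contact detection assumes the walkway-aligned frame described above.
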