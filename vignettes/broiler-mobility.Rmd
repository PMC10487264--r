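---
title: "Quantifying broiler mobility from top-down detections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying broiler mobility from top-down detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neosort)
```

## The problem

Mobility is a key welfare indicator for broiler chickens: impaired
locomotion flags lameness, pain, housing problems and sometimes mortality.
Manual gait scoring is slow and episodic; a top-down camera over the pen
plus an object detector yields per-frame bounding boxes from which distance
and speed can be computed continuously. Two obstacles stand between the
boxes and usable mobility numbers:

1. **Identity.** An online tracker (Kalman prediction + Hungarian
   assignment) attaches IDs to detections, but when a bird is occluded —
   birds glide over and huddle against each other — its track dies and the
   reappearing bird receives a fresh ID. Summing displacements per raw ID
   then under-counts every occluded bird.
2. **Scale and noise.** Boxes live in pixels, and frame-to-frame body
   perturbations (shuffling, pecking) register as displacement even when
   the bird goes nowhere.

`neosort` addresses both: a kinematic multi-object tracker produces raw
tracklets; a post-hoc re-association stage repairs occlusion-induced ID
switches by positional proximity and deletes false-detection tracks; and a
mobility stage converts box centroids to cm, resamples to a fixed interval,
applies a deadband, and summarizes per-bird and flock distance and speed.

## The pipeline

### Tracker

Each track carries an 8-dimensional state
$(c_x, c_y, w, h, v_x, v_y, v_w, v_h)$ — box centroid, box size and their
per-frame velocities — filtered by a constant-velocity Kalman filter.
Detections are assigned to predicted tracks by a minimum-total-cost
one-to-one matching (Hungarian algorithm) under Euclidean centroid cost;
any matched pair costing more than `gate_distance` is dissolved.
Unmatched detections spawn tentative tracks (confirmed after `min_hits`
consecutive matches, discarded on a first miss); unmatched tracks age and
die after `max_age` consecutive misses. The cost is purely kinematic: an
appearance-descriptor hook exists but defaults to off, because the
re-association stage below is precisely the remedy for the identity
failures that a motion-only tracker suffers under occlusion.

Centroid distance is used rather than IoU because the birds are small
relative to the pen and the re-association rule is itself a distance
threshold, so the two stages share one geometry.

The gate deserves a word: `track_pen()` defaults it to *half* the median
box width, i.e. one body radius. Birds move a small fraction of their body
per frame, so a correct match is always far inside that gate, while a
track whose bird is occluded must be left unmatched rather than captured
by clutter or a neighbour — wide gates let coasting tracks wander across
birds and inflate distances badly. Surviving long gaps is the
re-association stage's job, not the gate's.

### ID re-association

After tracking, every tracklet that ends before the video does emits a
*loss* event at its final position, and every tracklet born after the
initial spawn cohort emits a *birth* event at its first position. A loss
and a birth are candidates for being the same bird when the birth follows
the loss by at most `max_gap` frames and the two positions lie within
`distance_threshold` (measured in cm through the calibration, so the
threshold is resolution-independent). Over all candidates a globally
minimum-total-distance one-to-one matching is taken, maximizing the number
of merges first — ties break toward the earlier birth. Matched pairs merge
(chains compose transitively, so one bird may pass through several IDs);
unmatched births shorter than `min_track_length` frames are deleted as
false detections; the rest stay unresolved. Merging is done offline, after
the whole recording, because the offline matcher sees every event and is
strictly better informed and reproducible than a streaming variant.

The threshold has no canonical value — it is chosen per setup by trial and
error. The default is 12 cm (about one body width);
`sweep_threshold()` plots merge counts against candidate thresholds to
support that choice. `max_gap` defaults to 10 s of frames and the deletion
length to 3 s: false-detection tracks are short because spurious boxes do
not persist, while a genuinely reappearing bird keeps its new ID for long
stretches.

### Mobility

Centroids are $(x + w/2,\; y + h/2)$; calibration is anisotropic linear
scaling (`pen_width_cm / image_width_px` per axis) under a nadir-view
assumption with no lens-distortion model. Trajectories are resampled to
one observation per `sample_interval` (default 1 s — sub-second body
perturbations are not locomotion), keeping the nearest observation within
half an interval of each grid time; the grid spans whole intervals only.
Grid cells with no observation are *absent*: displacement is summed only
within contiguous grid runs, never across gaps, because interpolating
across an occlusion would fabricate distance for a hidden bird. The
appearance percentage (observed frames / total frames) is reported
alongside so partial coverage is explicit. Steps below the deadband
(default 0.5 cm) are zeroed. Mean speed divides total distance by the
*observed* duration, not the wall-clock period, so a bird hidden half the
time is not biased toward zero speed.

## The simulator

Every claim above is tested against a pen simulator rather than video.
`simulate_motion()` implements a pause-and-travel waypoint walk: per frame
a bird rests with probability `pause_prob` (staying put, up to a
perturbation of SD `perturb_sd_cm`) or advances toward a uniformly drawn
waypoint at a bout speed drawn from $N(\mu, 0.2\mu)$. Birds are solid:
a move that would bring two centers within one body radius is blocked and
the bird re-routes; centers between one and two radii count as contact.
Expected path length is therefore
$(1-\texttt{pause\_prob}) \cdot \mu \cdot T$, which the tests verify by
Monte Carlo.

`render_detections()` corrupts the truth into a detection stream: per-bird
dropouts start by a base miss or, in contact, by an occlusion miss, and
persist geometrically (`gap_extension_prob`), producing the multi-frame
gaps that fragment tracks; boxes of fixed nominal size (two body radii)
are centered on the true centroid plus Gaussian jitter; false positives
arrive as a Poisson stream anywhere in the pen. Every detection is
labelled with its generating bird (−1 for clutter), which is the oracle
all downstream scoring uses.

Defaults were fixed once, as plausible for a 100 cm × 150 cm pen of 12 or
16 mid-grow-out birds recorded in 15-minute sessions: 5 frames/s
(the frame rate is fully configurable; the analysis needs no more than a
few Hz since displacement is read at 1 s), travel speed 3 cm/s, pause
probability 0.7, body radius 6 cm, base miss 5%, occlusion miss 50% on
contact, mean dropout length 5 frames, 0.1 false positives per frame,
0.2 cm jitter. The noise magnitudes are calibrated only qualitatively —
a 12-bird pen averages roughly 9–10 detected birds per frame, the regime a
single-class detector shows on crowded pens.

What the simulator does **not** model: photorealism and appearance (so the
appearance-descriptor hook is never exercised), behavior (feeding,
drinking), growth within a run (model growth by raising `bird_radius_cm`
between runs), camera distortion, and correlated detector failure modes
(e.g. systematic misses near feeders). Passing tests therefore demonstrate
the correctness of the tracking, re-association and mobility *algorithms*
under a realistic motion/noise geometry — not detector performance on real
video.

## Validation regimes and numerical choices

- **Noiseless identity.** With zero noise the full pipeline must reproduce
  each bird's 1-s-sampled ground-truth path length to floating-point
  accuracy, with exactly one trajectory per bird at 100% appearance. The
  deadband is 0 here: it exists to suppress jitter, and there is none.
  This is run at full study scale (12 birds, 900 s).
- **Recovery regime.** The 100%-re-association check uses controlled
  occlusion events: `inject_dropouts()` removes one bird's detections over
  isolated windows whose gap exceeds the tracker's `max_age` but stays
  well inside `max_gap`, whose net displacement is under half the
  threshold, and whose walked path is under 2 cm — i.e. rest-bout
  occlusions, which is where real occlusions live (huddled birds). Two
  reasons govern the last constraint: a hidden bird's walked path is
  unobservable in principle, so distance recovery is only meaningful for
  events where that path is small; and free-running occlusion noise
  produces spatially clustered, simultaneous loss/birth events that no
  position-threshold matcher can disambiguate — with appearance features
  out of scope, that ambiguity is a documented limitation, not a test
  failure. Under the controlled regime, across 20 seeds, every induced
  switch is re-associated, every merge is correct, and per-bird distances
  land within 5% of truth. The free-running regime is still exercised by
  the monotonicity and conservation tests, which hold unconditionally.
- **Assignment and filtering.** The Hungarian step is checked against
  exhaustive permutation enumeration on random instances up to 6×6; the
  Kalman filter against an independently coded textbook recursion, and for
  convergence (velocity and k-step prediction below 1e-6 after 20 frames)
  on exact constant-velocity input in the vanishing-measurement-noise
  regime.
- **Ties and degenerate inputs.** Resampling ties (two observations
  equidistant from a grid time) resolve to the earlier frame; matching
  ties in re-association break toward the earlier birth; empty frames age
  all tracks; an empty trajectory summarizes to zero distance and zero
  appearance rather than erroring; precision is defined as 1 when there
  are no predictions.
- **R² convention.** The coefficient of determination is implemented in
  the standard squared-residual form
  $1 - \sum_i (y_i-\hat y_i)^2 / \sum_i (y_i-\bar y)^2$. Average precision
  uses all-point interpolation (the continuous area under the
  precision–recall envelope), with IoU threshold 0.5 by default.

## Worked example

```{r example}
cfg <- run_config(frame_rate = 5, image_width_px = 500,
                  image_height_px = 750)
sim <- sim_config(n_birds = 12, duration_s = 120, seed = 7)
calib <- calibrate_pen(100, 150, 500, 750)

truth <- simulate_motion(sim)
dets <- render_detections(truth, noise_config(), calib, seed = 7,
                          bird_radius_cm = sim$bird_radius_cm)
fit <- track_pen(dets, cfg)
fit
head(fit$per_bird)
```

```{r plot, fig.width = 5, fig.height = 6}
plot(fit)
```

## Known limitations

- Re-association is positional only; birds that swap places while both are
  hidden are merged wrongly, and densely clustered simultaneous events are
  ambiguous. Appearance-based re-identification is the natural extension
  and deliberately out of scope.
- Distance accrued while a bird is hidden is never recovered (gaps are
  excluded, not interpolated); per-bird totals are lower bounds whose
  tightness is indicated by the appearance percentage.
- The calibration assumes a nadir view with the pen filling the frame;
  off-nadir mounting or lens distortion needs an external rectification
  step first.
- Hourly figures are reported per observed window; extrapolating a 15-min
  recording to a full hour is left to the user.
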