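---
title: "Counting people in ICU rooms: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting people in ICU rooms: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icucount)
```

`icucount` estimates how many people of each role — patient, clinician,
visitor — are present in an intensive-care room monitored by an ambient
camera at one frame per second, and how long each role spends at the
bedside around delirium assessments. This vignette is the package's own
account of the methods: what each stage assumes, which parameters matter,
what the synthetic-data generator does and does not emulate, and where the
design was genuinely open.

## The counting problem

The input is not video but a stream of per-frame *detections*: bounding
boxes (center form: `cx`, `cy`, `w`, `h` in pixels, origin top-left), a
class-probability vector over the three categories, a confidence score, and
a unit-norm appearance (re-identification) embedding per box. Counting by
detection is attractive in a room with at most a handful of people: it is
transparent (every count is traceable to boxes), detector-agnostic, and
cheap. Density-map and regression counting, designed for crowds, are out of
scope.

Three estimators are provided.

**Single-frame.** Every detection with confidence at or above the threshold
(default 0.3) contributes one count to the argmax category of its
class-probability vector. Ties break toward the lower category index
(patient, clinician, visitor) — a fixed, documented rule rather than a
random one, so results are reproducible.

**Multi-frame.** The single-frame counts of the $F/2$ frames before and
after frame $i$ are averaged together with frame $i$ itself, so a window of
size $F = 4$ spans 5 frames; $F$ must be even. The window is *centered*
because the averaging rationale (a person obscured in one frame is visible
in neighbours on either side) is symmetric in time; a trailing window would
also delay the estimate. At the sequence edges the window is clipped and
the divisor is the number of frames actually present — discarding edge
frames would silently shorten every analysis window downstream. $F = 0$
reduces exactly to the single-frame estimator, a property the test suite
pins down. Window means are reported as they are (fractional); rounding is
an evaluation concern, not a counting concern.

**Tracking-to-count.** A two-stage online tracker:

1. detections below the confidence threshold are discarded;
2. all active trajectories are propagated one frame forward by a Kalman
   filter;
3. *stage one*: cosine similarities between trajectory appearance summaries
   and detection embeddings form an affinity matrix; a maximum-total-
   similarity one-to-one assignment (Hungarian algorithm) is computed and
   pairs below `appearance_min_similarity` (default 0.4) are unmatched;
4. *stage two*: the leftover trajectories and detections are matched the
   same way on the IoU between each trajectory's *Kalman-predicted* box and
   the detection box, with floor `iou_min_overlap` (default 0.3);
5. matched trajectories are extended and Kalman-updated, and their
   appearance summary moves by exponential moving average (momentum 0.9)
   toward the matched feature, then is renormalised;
6. unmatched detections start new trajectories immediately (`min_hits` of 1:
   at one frame per second a visit can legitimately span very few frames);
7. trajectories unmatched for more than `max_age` (default 5) consecutive
   frames are terminated.

After the whole sequence is processed, each trajectory receives a single
category by the soft vote
$\arg\max_c \sum_j P_{k,j}$ over its members' class-probability vectors.
The vote is the mechanism that makes tracking better than frame-wise
counting at separating clinicians from visitors: a minority of mislabelled
frames cannot flip a long trajectory. Counting then asks, per frame, how
many trajectories of each category are *active* — present in that frame or
inside a bridged gap between two entries. Gaps never exceed `max_age` by
construction. Frames after a trajectory's last entry are not counted, so a
departed person does not linger in the counts.

### Kalman filter

The state is `(cx, cy, a, h)` with `a = w/h` and their velocities, under a
constant-velocity model. Noise scales follow the height-relative convention
of detection-based trackers (position noise `h/20`); the velocity process
noise is `h/80` — an order of magnitude larger than video-rate trackers
use, because at one frame per second the inter-frame acceleration of a
walking person is large. With that scale the filter's one-step prediction
error on noiseless constant-velocity motion falls below 0.1 px within 20
frames, and its covariance stays symmetric positive semi-definite over
thousands of cycles (both under test). The stage-two IoU uses the
*predicted* box as the trajectory's spatial representative: it is the
principled location estimate at the current frame, whereas the last matched
box is one frame stale.

### Choices that were genuinely open

- Whether the association threshold named alongside the counting window
  ("threshold 0.3") is a detection-confidence or an association-similarity
  floor is ambiguous; it is implemented as detection confidence, and the
  association floors are separate, documented parameters.
- The appearance summary could be the last matched feature or an aggregate;
  the exponential moving average was chosen because single noisy features
  produce identity switches, and the momentum (0.9) is exposed.
- The appearance embedding dimension is a configuration constant (default
  128). Nothing in the pipeline depends on the dimension beyond supporting
  cosine similarity; a deployed system would inherit whatever its re-ID
  backbone emits.

## The synthetic-data generator

No image data ship with the package (the motivating setting is a de-
identified clinical environment), so a seeded simulator stands in for both
the camera and the trained detector. It has two independently seeded
layers.

**Scene layer** (`sim_config()`, `simulate_ground_truth()`). A 1392 x 1044
px frame at 1 fps for 1800 frames (one 30-minute assessment window) by
default. A stationary patient box (320 x 220 px) sits at the bed region for
every frame. Visits — 8 clinician and 3 visitor per default scene — enter
at a door zone on the right wall at a uniformly random frame, walk toward a
bedside target under a mean-reverting Gaussian random walk (approach rate
0.12 per frame, step standard deviation 12 px), and leave after an
exponentially distributed dwell (means: 180 s clinician, 420 s visitor).
Those rates put a clinician at the bedside for roughly half of any window
and give visitor presence longer but rarer episodes — the qualitative
occupancy regime of an ICU room. Clinicians stand beside the bed (target
170 px lateral offset): a standing person's box overlaps the bed box only
marginally, so camera-axis occlusion of the patient is an occasional event,
not a chronic one. Every identity gets a fixed random unit appearance
embedding. `visit_schedule` adds fully deterministic visits, which is how
the tests build constant-occupancy scenes and exact dwell differences.

**Detector layer** (`noise_config()`, `simulate_detections()`). Defaults
are the pinned setting used by every benchmark in the package:

| parameter | default | meaning |
|---|---|---|
| `miss_prob` | 0.2 | per-frame miss probability for moving people |
| `patient_miss_prob` | 0.01 | miss probability for the stationary patient |
| `occlusion_iou` / `occlusion_extra_miss_prob` | 0.3 / 0.3 | additive miss surcharge when ground-truth boxes overlap above the IoU threshold |
| `fp_rate` | 0.05 | Poisson false positives per frame |
| `jitter_sd` / `jitter_log_sd` | 3 px / 0.02 | Gaussian jitter on centers and log box dimensions |
| `confusion` | 0.2 | clinician/visitor label-swap probability |
| `class_prob_softness` | 0.3 | Dirichlet softening of the one-hot class vector |
| `appearance_noise_sd` | 0.1 | tangent-space noise on the identity embedding |

Three design points deserve explanation because they shape every benchmark:

- *Per-category miss rates.* Detectors miss moving, posture-varying people
  far more often than a stationary lying patient whose appearance the model
  has seen thousands of times. The patient's failure mode is occlusion —
  someone standing between camera and bed — which the occlusion surcharge
  models. This split is what produces the characteristic pattern that
  multi-frame averaging helps the mover categories substantially while
  leaving patient accuracy nearly unchanged: mover misses are frequent and
  independent (averaging fixes them), patient misses are rare or occur in
  occlusion runs (averaging cannot fix a run longer than the window).
- *Structured confusion.* The confusion scalar builds a clinician/visitor
  swap with a clean patient row. In feature space a lying patient separates
  sharply from the two upright roles, which overlap each other (scrubs vs
  street clothes is a weak cue at 3–5 m); a flat three-way confusion matrix
  would misrepresent the problem. A full 3 x 3 row-stochastic matrix can be
  supplied when a different regime is wanted.
- *Class-probability vectors.* The observed category is sampled from the
  confusion row first, then reported as a softened one-hot vector (softness
  below 0.5 preserves the argmax). This makes the per-detection argmax
  accuracy equal the confusion diagonal by construction, giving the
  trajectory vote something real to repair. False positives are labelled
  clinician or visitor with equal probability — person-shaped false alarms
  are upright silhouettes, and an exactly uniform class vector would
  tie-break every false positive into the patient category.

With `noise_config_zero()` the detector layer is the identity: boxes,
counts and one-hot labels match ground truth exactly, which the zero-noise
recovery tests exploit.

**What the generator does not emulate.** No pixels, no photometry, no
camera geometry or perspective scaling, no correlated detector failures
beyond occlusion (real detectors fail systematically with lighting and
pose), no multi-patient rooms, no camera-to-camera handoff. A passing test
suite therefore demonstrates the pipeline's *correctness* and the relative
ordering of the three estimators under a plausible noise model — not
clinical-grade accuracy on real wards.

## Evaluation

Detection quality uses the 101-point interpolated average precision:
detections are ranked by confidence and greedily matched one-to-one to
same-frame, same-category ground truth at or above the IoU threshold
(highest IoU first), precision is interpolated as the maximum at any recall
at least $r$, and AP averages the interpolated precision over $r = 0, 0.01,
\dots, 1$. mAP averages AP over the ten IoU thresholds $0.50, 0.55, \dots,
0.95$ per category and then across categories; a category absent from both
truth and detections is excluded rather than scored 0. The IoU-threshold
comparison carries a $10^{-9}$ slack because the threshold grid itself
carries floating-point error. An independent staircase-enumeration oracle
in the test suite checks the AP implementation on random instances.

Counting quality: accuracy is the percentage of frames where the
*half-up-rounded* prediction equals the integer truth (0.5 rounds to 1 —
banker's rounding would treat equal fractional evidence asymmetrically
across frames); MAE/MSE/RMSE use the raw fractional predictions. The mean
relative error divides by the true count and is undefined on empty frames,
which are the norm for clinicians and visitors; frames with zero truth are
skipped by default (`mre_zero_policy = "skip"`, switchable to `"nan"`), and
the relative error uses the absolute deviation in its numerator.

## Occupancy around delirium assessments

Each assessment (CAM-ICU screen, CAM-ICU-7 severity 0–7) anchors a
30-minute window (15 minutes each side). Assessments whose camera-clock
offset exceeds 30 minutes are excluded — strictly: exactly 30 is retained.
The window is cut into 5-second segments (360 per full window at 1 fps) and
the mean count per category is recorded per segment. Two duration
definitions are provided because "average presence per segment" does not
determine one:

- **indicator** (default): a category is present in a segment when its mean
  count is at least 0.5 (present at least half the segment); duration =
  present segments x 5 s. Bounded by the window length.
- **person_time**: duration = sum of segment means x 5 s, i.e.
  person-minutes; can exceed 30 minutes when several people of one category
  overlap.

Neither is claimed to be canonical; analyses should state which they use.
Windows partially outside the recorded stream are scaled by the covered
fraction and flagged (`coverage` < 1); missing frames count as absence.
Group summaries (CAM-ICU positive/negative, or severity buckets 0 / 1–2 /
3–7) are descriptive means with group sizes — by design no inferential
statistics are attached, as occupancy-vs-delirium questions need a larger
sample than a single-room stream can provide.

## Problem sizes and numerical conventions

The package's benchmarks and acceptance checks use 1800-frame (30-minute)
scenes, 10 seeds for method comparisons and sweeps, 100-instance oracle
comparisons for the assignment and AP implementations, and a 6-window
occupancy recovery with a scheduled 5-minute between-group dwell
difference; these sizes give stable seed-to-seed means while keeping a full
run in the minutes range on a single core. All randomness flows through
explicit integer seeds (scene and noise streams are seeded independently so
one scene can be corrupted at several noise levels); reruns are
bit-for-bit reproducible, and the benchmark reports embed their seeds and
configurations. Degenerate inputs are defined, not accidental: an empty
frame counts as zeros, a zero-duration scene yields empty outputs and a
successful pipeline run, an empty trajectory set writes a header-only
trajectory file, and a window entirely outside the count table is an error
rather than a silent zero.

## Known limitations

- The tracker is online and single-camera; it does not re-link identities
  across long absences (a clinician leaving and returning is two
  trajectories, which is correct for counting but not for re-identification
  studies).
- Trajectory categories are fixed after finalisation; a trajectory that
  merges two people (possible under heavy occlusion) votes across both.
- The simulator's walk model is not a behavioral model of care activity;
  dwell times are exponential and visits independent, so clustered care
  events (rounds, codes) are underrepresented.
- Counting accuracy at occupancy transitions is limited for the multi-frame
  method by construction: a centered window straddling an entry or exit
  produces fractional means even with a perfect detector. The evaluation
  rounds half-up, which recovers the majority value at a clean step edge,
  but visits shorter than half the window can be averaged away entirely.
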