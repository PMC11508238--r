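# icucount

People counting and occupancy analysis for ambient monitoring of intensive
care unit (ICU) rooms.

Ambient cameras recording an ICU room at one frame per second can tell
clinicians and researchers how many people — the patient, clinicians,
visitors — are at the bedside at any time, and for how long. That signal is
clinically interesting: caregiver activity and family presence both relate
to delirium, an acute brain dysfunction affecting roughly half of ICU
patients. `icucount` implements a counting-by-detection pipeline over
per-frame person detections, together with the evaluation metrics and the
assessment-window occupancy analysis that such a study needs, and a seeded
scene/detector simulator so the whole pipeline runs end-to-end without any
video data, trained detector, or GPU.

## The methods

Given per-frame detections $B_i = \{b_{i,1}, \dots, b_{i,M_i}\}$ (boxes with
class-probability vectors over $C = 3$ categories, confidences, and
re-identification appearance features), the package counts occupancy three
ways:

1. **Single-frame** — count detections above the confidence threshold per
   category in each frame:
   $\mathrm{Out}_i = \mathrm{Count}(\mathrm{Det}(\mathrm{Image}_i)) \in \mathbb{N}^C$.
2. **Multi-frame** — average the single-frame counts over a centered window
   of $F/2$ frames on each side (a "duration 5" window is $F = 4$):
   $\mathrm{Out}_i = \frac{1}{|W|} \sum_{j = i-F/2}^{i+F/2} \mathrm{Count}(\mathrm{Det}(\mathrm{Image}_j))$,
   clipped at the sequence edges. Averaging smooths occlusion-induced misses
   and false alarms.
3. **Tracking-to-count** — a two-stage multi-object tracker links detections
   into trajectories: appearance affinity (cosine similarity of re-ID
   features) with maximum-similarity bipartite assignment, then an IoU stage
   between Kalman-predicted boxes and the leftover detections. Each
   trajectory $\mathrm{Trj}_k$ gets one category by a soft vote over its
   members:
   $\mathrm{Category}(\mathrm{Trj}_k) = \arg\max_c \sum_{j=1}^{M_k} P_{k,j}$,
   and frame $i$'s count is the number of trajectories of each category
   active at $i$ (including bridged detection gaps, so brief occlusions do
   not drop the count).

Evaluation follows the field's conventions: IoU-based detection validity,
101-point interpolated average precision, mAP over IoU thresholds
0.50–0.95, and per-category counting accuracy, MAE, MRE, MSE and RMSE. The
occupancy module cuts a 30-minute window around each delirium assessment
(CAM-ICU screen, CAM-ICU-7 severity) into 5-second segments — 360 segments
per window — and converts segment-mean presence into minutes at the bedside
per category, after excluding assessments whose clock offset from the
recording exceeds 30 minutes.

## A worked example

```r
library(icucount)
library(dplyr)

# a 30-minute scene: stationary patient, 8 clinician and 3 visitor visits
scene <- sim_config(duration_frames = 1800, seed = 42)
gt    <- simulate_ground_truth(scene)
det   <- simulate_detections(gt, noise_config(), seed = 43)

truth <- ground_truth_counts(gt)
single   <- count_sequence(det, "single", threshold = 0.3)
multi    <- count_sequence(det, "multi", window = 4, threshold = 0.3)
tracked  <- track_count(det, tracker_config())

bind_rows(
  evaluate_counts(single, truth)          %>% mutate(method = "single"),
  evaluate_counts(multi, truth)           %>% mutate(method = "multi"),
  evaluate_counts(tracked$counts, truth)  %>% mutate(method = "tracking")
) %>%
  filter(category == "clinician") %>%
  select(method, accuracy, mae, rmse)
#> # A tibble: 3 × 4
#>   method   accuracy    mae  rmse
#>   <chr>       <dbl>  <dbl> <dbl>
#> 1 single       77.8 0.254  0.564
#> 2 multi        85.9 0.217  0.405
#> 3 tracking     95.3 0.0467 0.216
```

Single-frame counting misses a fifth of the moving people (detector miss
rate 0.2 in the default noise model) and confuses clinicians with visitors;
window averaging recovers part of that; tracking bridges the missed frames
and fixes the labels by trajectory-level voting, cutting the clinician MAE
by a factor of five. Trajectories are inspectable and
exportable:

```r
glance(tracked)     # trajectory inventory
tidy(tracked)       # one row per trajectory
write_trajectories(tracked, "trajectories.txt")  # MOT-Challenge dialect
```

Benchmarks and plots:

```r
bench <- run_method_comparison(seeds = 1:10)   # Table-style method comparison
autoplot(bench, metric = "mae")
sweep <- run_window_sweep(seeds = 1:10)        # window-size sweep
autoplot(sweep, metric = "accuracy")
```

A command-line wrapper with `simulate`, `count`, `track`, `evaluate`,
`evaluate-detection`, `occupancy`, `benchmark`, `pipeline` and `fixtures`
subcommands lives at `inst/cli/icucount.R`.

## Limitations

The simulator reproduces the statistical failure modes of a person detector
(misses, occlusion, localisation jitter, class confusion, false positives,
appearance noise), not the appearance of any real ICU. Results on simulated
scenes demonstrate the pipeline's correctness and the qualitative ordering
of the three methods, not clinical performance. See the methods vignette
(`vignettes/icucount-methods.Rmd`) for the model, the noise design, and
every tunable parameter.
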