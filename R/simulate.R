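#' Simulation configuration for an ICU room scene
#'
#' Describes the ground-truth scene the synthetic generator produces: a
#' stationary patient in a bed region plus clinician and visitor visits that
#' enter through a door zone, approach the bedside with a mean-reverting
#' random walk, dwell for an exponentially distributed time, and leave. The
#' stream is regular at `fps` frames per second (default 1, matching the
#' ambient-camera setting the pipeline targets).
#'
#' Random visits draw their entry frame uniformly over the sequence and
#' their dwell from an exponential distribution with the configured mean.
#' `visit_schedule` optionally adds fully deterministic visits (a tibble with
#' columns `category`, `entry_frame`, `dwell_frames`), used for constructing
#' controlled scenes such as constant-occupancy fixtures.
#'
#' @param frame_width,frame_height Frame size in pixels (default 1392 x 1044).
#' @param fps Frames per second of the stream.
#' @param duration_frames Number of frames to simulate.
#' @param patient_present Should a stationary patient occupy the bed?
#' @param n_clinician_visits,n_visitor_visits Number of random visits.
#' @param dwell_mean_clinician,dwell_mean_visitor Mean dwell times in seconds.
#' @param motion_step_sd Per-frame Gaussian step (pixels) of the walk.
#' @param approach_rate Mean-reversion rate toward the visit target per frame.
#' @param entry_zone Rectangle `c(x1, y1, x2, y2)` where visits start
#'   (default: door region at the right wall).
#' @param visit_schedule Optional tibble of scheduled visits (see above).
#' @param appearance_dim Dimension of per-identity appearance embeddings.
#' @param seed Integer seed; the scene is deterministic given the seed.
#' @return A list of class `icu_sim_config`.
#' @export
sim_config <- function(frame_width = 1392, frame_height = 1044, fps = 1,
                       duration_frames = 1800, patient_present = TRUE,
                       n_clinician_visits = 8, n_visitor_visits = 3,
                       dwell_mean_clinician = 180, dwell_mean_visitor = 420,
                       motion_step_sd = 12, approach_rate = 0.12,
                       entry_zone = NULL, visit_schedule = NULL,
                       appearance_dim = 128, seed = 1L) {
  if (duration_frames < 0 || n_clinician_visits < 0 || n_visitor_visits < 0) {
    abort("Counts in the simulation config must be nonnegative.")
  }
  if (dwell_mean_clinician <= 0 || dwell_mean_visitor <= 0) {
    abort("Dwell-time means must be positive.")
  }
  structure(list(
    frame_width = frame_width, frame_height = frame_height, fps = fps,
    duration_frames = as.integer(duration_frames),
    patient_present = isTRUE(patient_present),
    n_clinician_visits = as.integer(n_clinician_visits),
    n_visitor_visits = as.integer(n_visitor_visits),
    dwell_mean_clinician = dwell_mean_clinician,
    dwell_mean_visitor = dwell_mean_visitor,
    motion_step_sd = motion_step_sd, approach_rate = approach_rate,
    entry_zone = entry_zone %||%
      c(frame_width - 170, frame_height * 0.35, frame_width - 20, frame_height * 0.65),
    visit_schedule = visit_schedule,
    appearance_dim = as.integer(appearance_dim),
    # scene geometry: bed region and standing-person box size
    bed_center = c(frame_width * 0.5, frame_height * 0.62),
    bed_size = c(320, 220),
    person_size = c(150, 330),
    seed = as.integer(seed)
  ), class = "icu_sim_config")
}

#' Detector noise configuration
#'
#' Models the failure modes of a trained person detector on 1 fps room
#' imagery. Defaults are the pinned benchmark setting used throughout the
#' package's experiments.
#'
#' Moving people (clinicians, visitors) are missed independently with
#' `miss_prob`; the stationary, full-visibility patient has a separate and
#' much smaller `patient_miss_prob` (stationary bed-region appearance is the
#' easy case for a detector, and the room's count tables show patient errors
#' an order of magnitude below the movers'). Any box whose IoU with another
#' ground-truth box exceeds `occlusion_iou` incurs the additive
#' `occlusion_extra_miss_prob` surcharge. Surviving boxes are jittered
#' (Gaussian on the center, Gaussian on log width/height). The observed
#' category is sampled from the `confusion` model: a scalar `confusion = c`
#' builds a clinician/visitor confusion matrix with diagonal `1 - c` and the
#' patient row left clean, reflecting that patient appearance separates
#' cleanly from the two upright roles while clinicians and visitors are the
#' pair a detector mixes up; a full row-stochastic 3 x 3 matrix may be given
#' instead. The reported class-probability vector is the one-hot vector of
#' the observed category softened by `class_prob_softness` toward a random
#' Dirichlet draw (argmax is preserved for softness < 0.5). False positives
#' arrive as a Poisson stream (`fp_rate` per frame), placed uniformly, sized
#' like a standing person, labelled clinician or visitor with equal
#' probability, and given a random appearance.
#'
#' @param miss_prob Miss probability per moving-person box.
#' @param patient_miss_prob Miss probability for the stationary patient box.
#' @param occlusion_iou IoU above which two ground-truth boxes count as
#'   occluding each other.
#' @param occlusion_extra_miss_prob Additive miss surcharge under occlusion.
#' @param fp_rate Expected false positives per frame (Poisson).
#' @param jitter_sd Gaussian localisation jitter on box centers, pixels.
#' @param jitter_log_sd Gaussian jitter on log width and log height.
#' @param confusion Scalar clinician/visitor confusion rate, or a 3 x 3
#'   row-stochastic matrix in category order patient, clinician, visitor.
#' @param class_prob_softness Mixing weight of Dirichlet noise into the
#'   one-hot class-probability vector; must stay below 0.5.
#' @param appearance_noise_sd Gaussian noise added to the identity's base
#'   embedding before renormalisation.
#' @param conf_range_true,conf_range_fp Uniform confidence ranges for true
#'   and false detections.
#' @return A list of class `icu_noise_config`.
#' @export
noise_config <- function(miss_prob = 0.2, patient_miss_prob = 0.01,
                         occlusion_iou = 0.3, occlusion_extra_miss_prob = 0.3,
                         fp_rate = 0.05, jitter_sd = 3, jitter_log_sd = 0.02,
                         confusion = 0.2, class_prob_softness = 0.3,
                         appearance_noise_sd = 0.1,
                         conf_range_true = c(0.5, 1), conf_range_fp = c(0.3, 0.6)) {
  probs <- c(miss_prob, patient_miss_prob, occlusion_extra_miss_prob, fp_rate)
  if (any(probs < 0) || any(probs[1:3] > 1)) {
    abort("Noise probabilities must lie in [0, 1] (fp_rate nonnegative).")
  }
  if (class_prob_softness < 0 || class_prob_softness >= 0.5) {
    abort("class_prob_softness must lie in [0, 0.5) to preserve the argmax.")
  }
  cm <- confusion_matrix(confusion)
  structure(list(
    miss_prob = miss_prob, patient_miss_prob = patient_miss_prob,
    occlusion_iou = occlusion_iou,
    occlusion_extra_miss_prob = occlusion_extra_miss_prob,
    fp_rate = fp_rate, jitter_sd = jitter_sd, jitter_log_sd = jitter_log_sd,
    confusion = cm, class_prob_softness = class_prob_softness,
    appearance_noise_sd = appearance_noise_sd,
    conf_range_true = conf_range_true, conf_range_fp = conf_range_fp
  ), class = "icu_noise_config")
}

#' @rdname noise_config
#' @export
noise_config_zero <- function() {
  noise_config(
    miss_prob = 0, patient_miss_prob = 0, occlusion_extra_miss_prob = 0,
    fp_rate = 0, jitter_sd = 0, jitter_log_sd = 0, confusion = 0,
    class_prob_softness = 0, appearance_noise_sd = 0,
    conf_range_true = c(1, 1)
  )
}

confusion_matrix <- function(confusion) {
  if (is.matrix(confusion)) {
    if (!all(dim(confusion) == c(3, 3)) || any(confusion < 0) ||
        any(abs(rowSums(confusion) - 1) > 1e-9)) {
      abort("A confusion matrix must be 3 x 3 and row-stochastic.")
    }
    return(confusion)
  }
  c <- confusion
  if (c < 0 || c > 1) abort("Scalar confusion rate must lie in [0, 1].")
  rbind(
    c(1, 0, 0),
    c(0, 1 - c, c),
    c(0, c, 1 - c)
  )
}

#' Simulate ground truth for an ICU room scene
#'
#' Generates the annotated scene the configuration describes: a stationary
#' patient box fixed at the bed region for every frame, and clinician or
#' visitor visits that appear in the entry zone, walk toward a bedside
#' target under a clipped mean-reverting Gaussian random walk, and disappear
#' after their dwell elapses (or at the end of the stream). Every identity
#' occupies a temporally contiguous run of frames and receives a fixed
#' random unit appearance embedding. Deterministic given `config$seed`.
#'
#' @param config An [sim_config()] object.
#' @return A ground-truth tibble (`frame`, `identity`, `category`, `cx`,
#'   `cy`, `w`, `h`) with attributes `identities` (tibble of identity,
#'   category, base appearance) and the sequence metadata.
#' @export
simulate_ground_truth <- function(config) {
  stopifnot(inherits(config, "icu_sim_config"))
  withr::with_seed(config$seed, simulate_ground_truth_impl(config))
}

simulate_ground_truth_impl <- function(config) {
  nfr <- config$duration_frames
  pw <- config$person_size[1]
  ph <- config$person_size[2]
  visits <- tibble(
    category = c(rep("clinician", config$n_clinician_visits),
                 rep("visitor", config$n_visitor_visits)),
    entry_frame = NA_integer_, dwell_frames = NA_integer_
  )
  if (nrow(visits) && nfr > 0) {
    dwell_mean <- ifelse(visits$category == "clinician",
                         config$dwell_mean_clinician, config$dwell_mean_visitor)
    visits$entry_frame <- as.integer(floor(runif(nrow(visits), 0, nfr)))
    visits$dwell_frames <- pmax(1L, as.integer(round(
      rexp(nrow(visits), rate = 1 / dwell_mean) * config$fps)))
  } else {
    visits <- visits[0, ]
  }
  if (!is.null(config$visit_schedule)) {
    sched <- as_tibble(config$visit_schedule)
    stopifnot(all(c("category", "entry_frame", "dwell_frames") %in% names(sched)))
    visits <- bind_rows(visits, sched[c("category", "entry_frame", "dwell_frames")])
  }
  # drop visits that start beyond the stream
  visits <- filter(visits, .data$entry_frame < nfr, .data$dwell_frames >= 1)

  identities <- tibble(identity = integer(0), category = character(0),
                       appearance = list())
  pieces <- list()
  next_id <- 1L

  if (config$patient_present && nfr > 0) {
    pieces[[length(pieces) + 1]] <- tibble(
      frame = 0:(nfr - 1L), identity = next_id, category = "patient",
      cx = config$bed_center[1], cy = config$bed_center[2],
      w = config$bed_size[1], h = config$bed_size[2]
    )
    identities <- bind_rows(identities, tibble(
      identity = next_id, category = "patient",
      appearance = list(random_unit(config$appearance_dim))
    ))
    next_id <- next_id + 1L
  }

  if (nrow(visits)) {
    for (v in seq_len(nrow(visits))) {
      entry <- visits$entry_frame[v]
      last <- min(nfr - 1L, entry + visits$dwell_frames[v] - 1L)
      len <- last - entry + 1L
      # start in the entry zone, walk toward a bedside target
      z <- config$entry_zone
      pos <- c(runif(1, z[1], z[3]), runif(1, z[2], z[4]))
      side <- sample(c(-1, 1), 1)
      # people stand beside the bed: a bedside box overlaps the bed box only
      # marginally, so camera-axis patient occlusion is occasional, not chronic
      target <- if (visits$category[v] == "clinician") {
        config$bed_center + c(side * 170, -10)
      } else {
        config$bed_center + c(side * 280, 40)
      }
      xs <- numeric(len)
      ys <- numeric(len)
      for (t in seq_len(len)) {
        xs[t] <- pos[1]
        ys[t] <- pos[2]
        pos <- pos + config$approach_rate * (target - pos) +
          rnorm(2, 0, config$motion_step_sd)
        pos[1] <- min(max(pos[1], pw / 2), config$frame_width - pw / 2)
        pos[2] <- min(max(pos[2], ph / 2), config$frame_height - ph / 2)
      }
      pieces[[length(pieces) + 1]] <- tibble(
        frame = entry:last, identity = next_id, category = visits$category[v],
        cx = xs, cy = ys, w = pw, h = ph
      )
      identities <- bind_rows(identities, tibble(
        identity = next_id, category = visits$category[v],
        appearance = list(random_unit(config$appearance_dim))
      ))
      next_id <- next_id + 1L
    }
  }

  gt <- if (length(pieces)) {
    arrange(bind_rows(pieces), .data$frame, .data$identity)
  } else {
    tibble(frame = integer(0), identity = integer(0), category = character(0),
           cx = numeric(0), cy = numeric(0), w = numeric(0), h = numeric(0))
  }
  gt <- set_seq_attrs(gt, list(
    n_frames = nfr, fps = config$fps,
    frame_width = config$frame_width, frame_height = config$frame_height
  ))
  attr(gt, "identities") <- identities
  attr(gt, "sim_config") <- config
  gt
}

random_unit <- function(d) {
  v <- rnorm(d)
  v / sqrt(sum(v^2))
}

#' Corrupt ground truth with detector noise
#'
#' Applies the [noise_config()] model to a ground-truth sequence: drops
#' boxes (per-category miss probability plus the occlusion surcharge when a
#' box overlaps another with IoU above the occlusion threshold), jitters
#' survivors, samples an observed category from the confusion model and
#' emits a softened one-hot class-probability vector for it, perturbs the
#' identity's base appearance embedding in tangent space and renormalises,
#' and adds Poisson false positives. With [noise_config_zero()] the output
#' reproduces the ground truth exactly: same boxes, one-hot class
#' probabilities, confidence 1. The noise stream is seeded independently of
#' the scene so the same scene can be corrupted at several noise levels.
#'
#' @param gt Ground-truth tibble from [simulate_ground_truth()].
#' @param noise An [noise_config()] object.
#' @param seed Integer seed for the noise stream.
#' @return A detections tibble (see [validate_detections()]).
#' @export
simulate_detections <- function(gt, noise = noise_config(), seed = 1L) {
  stopifnot(inherits(noise, "icu_noise_config"))
  withr::with_seed(as.integer(seed), simulate_detections_impl(gt, noise))
}

simulate_detections_impl <- function(gt, noise) {
  meta <- seq_attrs(gt)
  ids <- attr(gt, "identities")
  if (is.null(ids)) abort("Ground truth lacks the identities attribute.")
  app_dim <- if (nrow(ids)) length(ids$appearance[[1]]) else 128L
  n <- nrow(gt)

  kept <- logical(0)
  if (n) {
    # occlusion flag: max IoU against the other boxes in the same frame
    occluded <- logical(n)
    idx_by_frame <- split(seq_len(n), gt$frame)
    for (idx in idx_by_frame) {
      if (length(idx) < 2) next
      m <- box_iou_matrix(gt[idx, ], gt[idx, ])
      diag(m) <- 0
      occluded[idx] <- apply(m, 1, max) > noise$occlusion_iou
    }
    base_miss <- ifelse(gt$category == "patient",
                        noise$patient_miss_prob, noise$miss_prob)
    p_miss <- pmin(1, base_miss + occluded * noise$occlusion_extra_miss_prob)
    kept <- runif(n) >= p_miss
  }
  tp <- gt[kept, ]
  ntp <- nrow(tp)

  det_true <- empty_detections()
  if (ntp) {
    cx <- tp$cx + rnorm(ntp, 0, noise$jitter_sd)
    cy <- tp$cy + rnorm(ntp, 0, noise$jitter_sd)
    w <- tp$w * exp(rnorm(ntp, 0, noise$jitter_log_sd))
    h <- tp$h * exp(rnorm(ntp, 0, noise$jitter_log_sd))
    true_idx <- match(tp$category, ICU_CATEGORIES)
    observed <- vapply(true_idx, function(i) {
      sample.int(3L, 1L, prob = noise$confusion[i, ])
    }, integer(1))
    probs <- soften_onehot(observed, noise$class_prob_softness)
    base <- ids$appearance[match(tp$identity, ids$identity)]
    app <- lapply(seq_len(ntp), function(i) {
      v <- base[[i]]
      if (noise$appearance_noise_sd > 0) {
        v <- v + rnorm(length(v), 0, noise$appearance_noise_sd)
      }
      v / sqrt(sum(v^2))
    })
    det_true <- tibble(
      frame = tp$frame, cx = cx, cy = cy, w = w, h = h,
      p_patient = probs[, 1], p_clinician = probs[, 2], p_visitor = probs[, 3],
      confidence = runif(ntp, noise$conf_range_true[1], noise$conf_range_true[2]),
      appearance = app
    )
  }

  det_fp <- empty_detections()
  if (noise$fp_rate > 0 && meta$n_frames > 0) {
    nfp_per_frame <- rpois(meta$n_frames, noise$fp_rate)
    nfp <- sum(nfp_per_frame)
    if (nfp) {
      fp_cat <- sample(c(2L, 3L), nfp, replace = TRUE)
      probs <- soften_onehot(fp_cat, noise$class_prob_softness)
      det_fp <- tibble(
        frame = rep(0:(meta$n_frames - 1L), nfp_per_frame),
        cx = runif(nfp, 75, meta$frame_width - 75),
        cy = runif(nfp, 165, meta$frame_height - 165),
        w = runif(nfp, 100, 200),
        h = runif(nfp, 220, 380),
        p_patient = probs[, 1], p_clinician = probs[, 2], p_visitor = probs[, 3],
        confidence = runif(nfp, noise$conf_range_fp[1], noise$conf_range_fp[2]),
        appearance = replicate(nfp, random_unit(app_dim), simplify = FALSE)
      )
    }
  }

  det <- arrange(bind_rows(det_true, det_fp), .data$frame)
  det <- set_seq_attrs(det, meta)
  validate_detections(det)
  det
}

# one-hot rows softened toward a Dirichlet(1,1,1) draw; argmax preserved
soften_onehot <- function(idx, softness) {
  n <- length(idx)
  probs <- matrix(0, n, 3)
  probs[cbind(seq_len(n), idx)] <- 1
  if (softness > 0 && n) {
    g <- matrix(rgamma(3 * n, 1), n, 3)
    g <- g / rowSums(g)
    probs <- (1 - softness) * probs + softness * g
  }
  probs
}

#' Ground-truth counts per frame
#'
#' Exact integer occupancy per category per frame, including frames with no
#' objects.
#'
#' @param gt Ground-truth tibble.
#' @param n_frames Number of frames; defaults to the sequence attribute.
#' @return Count tibble: `frame`, `patient`, `clinician`, `visitor`.
#' @export
ground_truth_counts <- function(gt, n_frames = NULL) {
  meta <- seq_attrs(gt, n_frames)
  counts_from_categories(gt$frame, gt$category, meta$n_frames)
}

counts_from_categories <- function(frame, category, n_frames) {
  out <- matrix(0L, nrow = n_frames, ncol = 3,
                dimnames = list(NULL, ICU_CATEGORIES))
  if (length(frame)) {
    tab <- table(factor(frame, levels = 0:(n_frames - 1L)),
                 factor(category, levels = ICU_CATEGORIES))
    out[] <- as.integer(tab)
  }
  tibble(
    frame = if (n_frames > 0) 0:(n_frames - 1L) else integer(0),
    patient = out[, 1], clinician = out[, 2], visitor = out[, 3]
  )
}
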