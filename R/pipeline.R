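#' Pipeline configuration
#'
#' Nested configuration for the end-to-end run: scene simulation, detector
#' noise, counting parameters, tracker parameters, and the occupancy stage.
#' `load_pipeline_config()` reads the same structure from YAML (field names
#' mirror the constructor arguments of [sim_config()], [noise_config()] and
#' [tracker_config()]); unknown keys are rejected.
#'
#' @param sim,noise,tracker Component configs (or lists of constructor
#'   arguments in the YAML case).
#' @param window,threshold Counting parameters.
#' @param n_assessments Number of synthetic delirium assessments to place
#'   for the occupancy stage (0 disables the stage).
#' @param seed Global seed; stage seeds are derived from it.
#' @param path YAML file path.
#' @return A list of class `icu_pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(), noise = noise_config(),
                            tracker = tracker_config(), window = 4,
                            threshold = 0.3, n_assessments = 2, seed = 1L) {
  structure(list(sim = sim, noise = noise, tracker = tracker,
                 window = window, threshold = threshold,
                 n_assessments = as.integer(n_assessments),
                 seed = as.integer(seed)),
            class = "icu_pipeline_config")
}

#' @rdname pipeline_config
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("sim", "noise", "tracker", "window", "threshold",
             "n_assessments", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("Unknown pipeline config key(s): ", paste(unknown, collapse = ", ")))
  }
  check_args <- function(args, fn, what) {
    bad <- setdiff(names(args), names(formals(fn)))
    if (length(bad)) {
      abort(paste0("Unknown ", what, " config key(s): ", paste(bad, collapse = ", ")))
    }
    args
  }
  sim <- do.call(sim_config, check_args(raw$sim %||% list(), sim_config, "sim"))
  noise_args <- raw$noise %||% list()
  if (!is.null(noise_args$confusion) && is.list(noise_args$confusion)) {
    noise_args$confusion <- do.call(rbind, noise_args$confusion)
  }
  noise <- do.call(noise_config, check_args(noise_args, noise_config, "noise"))
  tracker <- do.call(tracker_config,
                     check_args(raw$tracker %||% list(), tracker_config, "tracker"))
  pipeline_config(sim = sim, noise = noise, tracker = tracker,
                  window = raw$window %||% 4, threshold = raw$threshold %||% 0.3,
                  n_assessments = raw$n_assessments %||% 2,
                  seed = raw$seed %||% 1L)
}

#' Run the whole pipeline and write its artifact bundle
#'
#' Linear composition of the stages: simulate ground truth, corrupt with
#' detector noise, count with all three methods, track, evaluate, and (when
#' assessments are configured) run the occupancy analysis on the
#' tracking-based counts against synthetic assessments placed evenly along
#' the stream with alternating delirium labels. Every stage's inputs and
#' outputs are written in the package's interchange formats, and a
#' line-oriented `key=value` log records each stage. Deterministic given the
#' config seed.
#'
#' @param config An [pipeline_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the computed objects and file paths.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "icu_pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  logf <- file.path(out_dir, "pipeline.log")
  logs <- character(0)
  log_line <- function(...) {
    line <- paste0("stage=", paste(..., sep = " "))
    logs <<- c(logs, line)
  }
  p <- function(name) file.path(out_dir, name)

  sim <- config$sim
  sim$seed <- config$seed
  gt <- simulate_ground_truth(sim)
  write_ground_truth(gt, p("gt.json"))
  log_line("simulate", sprintf("seed=%d frames=%d objects=%d",
                               config$seed, sim$duration_frames, nrow(gt)))

  det <- simulate_detections(gt, config$noise, seed = config$seed + 500000L)
  write_detections(det, p("detections.json"))
  log_line("detect", sprintf("detections=%d", nrow(det)))

  truth <- ground_truth_counts(gt)
  write_counts(truth, p("counts_truth.csv"))
  counts <- list(
    single = count_sequence(det, "single", threshold = config$threshold),
    multi = count_sequence(det, "multi", window = config$window,
                           threshold = config$threshold)
  )
  tracking <- track_count(det, config$tracker)
  counts$tracking <- tracking$counts
  for (m in names(counts)) write_counts(counts[[m]], p(sprintf("counts_%s.csv", m)))
  write_trajectories(tracking, p("trajectories.txt"))
  log_line("count", sprintf("methods=3 trajectories=%d",
                            length(tracking$trajectories)))

  metrics <- purrr::imap(counts, function(cc, m) {
    if (nrow(truth) == 0) return(NULL)
    ev <- evaluate_counts(cc, truth)
    rows <- split(ev[setdiff(names(ev), "category")], ev$category)
    lapply(rows, function(df) as.list(df[1, ]))
  })
  jsonlite::write_json(metrics, p("metrics.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  log_line("evaluate", sprintf("methods=%d", length(metrics)))

  occupancy <- NULL
  if (config$n_assessments > 0 && sim$duration_frames > 0) {
    centers <- round(seq(0.5, config$n_assessments - 0.5,
                         length.out = config$n_assessments) /
                       config$n_assessments * sim$duration_frames)
    assessments <- tibble(
      assessment_id = paste0("A", seq_len(config$n_assessments)),
      time = centers / sim$fps,
      offset_min = 0,
      cam_icu = rep_len(c(0L, 1L), config$n_assessments),
      cam_icu7 = rep_len(c(0L, 4L), config$n_assessments)
    )
    summaries <- segment_presence(counts$tracking, filter_aligned(assessments),
                                  fps = sim$fps)
    occupancy <- group_durations(summaries, assessments, "cam_icu_binary")
    readr::write_csv(select(summaries, -"segment_means"), p("occupancy_windows.csv"))
    readr::write_csv(occupancy, p("occupancy_groups.csv"))
    log_line("occupancy", sprintf("assessments=%d", nrow(assessments)))
  }

  cfg_echo <- list(
    sim = unclass(sim)[setdiff(names(sim), c("bed_center", "bed_size", "person_size"))],
    noise = lapply(unclass(config$noise), function(x) if (is.matrix(x)) as.data.frame(x) else x),
    tracker = unclass(config$tracker),
    window = config$window, threshold = config$threshold,
    n_assessments = config$n_assessments, seed = config$seed
  )
  cfg_echo$sim$visit_schedule <- NULL
  yaml::write_yaml(cfg_echo, p("config.yaml"))
  writeLines(logs, logf)
  invisible(list(gt = gt, detections = det, counts = counts,
                 tracking = tracking, metrics = metrics,
                 occupancy = occupancy, dir = out_dir))
}

#' Deterministic small fixtures for tests and documentation
#'
#' Builds, from a pinned seed, a named list of small detection sequences
#' (10-100 frames) covering the awkward cases the pipeline must handle:
#' `empty_frames` (a stretch of frames with zero detections), `occlusion_gap`
#' (one identity with a single-frame detection gap), `confused_track` (a
#' clinician whose per-frame argmax label disagrees with its identity in two
#' frames), and `overlapping_visitors` (two visitors whose boxes overlap
#' above the occlusion threshold).
#'
#' @param seed Integer seed.
#' @return Named list of detections tibbles; `occlusion_gap` and
#'   `confused_track` carry their source ground truth as a `gt` attribute.
#' @export
make_fixtures <- function(seed = 1L) {
  withr::with_seed(as.integer(seed), {
    zero <- noise_config_zero()

    patient_scene <- sim_config(duration_frames = 12, n_clinician_visits = 0,
                                n_visitor_visits = 0, seed = seed)
    gt1 <- simulate_ground_truth(patient_scene)
    d1 <- simulate_detections(gt1, zero, seed = seed)
    empty_frames <- d1[!d1$frame %in% 3:5, ]
    empty_frames <- set_seq_attrs(empty_frames, seq_attrs(d1))

    clin_scene <- sim_config(
      duration_frames = 10, patient_present = FALSE,
      n_clinician_visits = 0, n_visitor_visits = 0,
      visit_schedule = tibble(category = "clinician", entry_frame = 0L,
                              dwell_frames = 10L),
      seed = seed + 1L
    )
    gt2 <- simulate_ground_truth(clin_scene)
    d2 <- simulate_detections(gt2, zero, seed = seed + 1L)
    occlusion_gap <- d2[d2$frame != 5, ]
    occlusion_gap <- set_seq_attrs(occlusion_gap, seq_attrs(d2))
    attr(occlusion_gap, "gt") <- gt2

    confused_track <- simulate_detections(gt2, zero, seed = seed + 2L)
    flip <- confused_track$frame %in% c(2, 7)
    confused_track$p_clinician[flip] <- 0
    confused_track$p_visitor[flip] <- 1
    attr(confused_track, "gt") <- gt2

    app_a <- random_unit(128)
    app_b <- random_unit(128)
    overlapping_visitors <- bind_rows(lapply(0:14, function(f) {
      tibble(
        frame = f,
        cx = c(600, 660), cy = c(600, 610), w = 150, h = 330,
        p_patient = 0, p_clinician = 0, p_visitor = 1,
        confidence = 0.9,
        appearance = list(app_a, app_b)
      )
    }))
    overlapping_visitors <- set_seq_attrs(
      overlapping_visitors,
      list(n_frames = 15, fps = 1, frame_width = 1392, frame_height = 1044)
    )

    list(empty_frames = empty_frames, occlusion_gap = occlusion_gap,
         confused_track = confused_track,
         overlapping_visitors = overlapping_visitors)
  })
}
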