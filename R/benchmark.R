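#' Compare the three counting methods on simulated scenes
#'
#' For every seed: simulate a scene, corrupt it with detector noise, run
#' single-frame, multi-frame and tracking-to-count, and evaluate each
#' against the ground-truth counts. All metrics go through the evaluation
#' module; the report embeds seeds and configurations so every number is
#' recomputable.
#'
#' @param sim An [sim_config()] object (its `seed` is replaced per run).
#' @param noise An [noise_config()] object.
#' @param seeds Integer vector; one simulated scene per seed.
#' @param window Multi-frame window size `F` (default 4, a 5-frame window).
#' @param threshold Detection confidence threshold (default 0.3).
#' @param tracker An [tracker_config()] object.
#' @return A list of class `icu_benchmark`: `results` (per seed x method x
#'   category metrics), `summary` (mean and sd over seeds), plus the
#'   embedded configs and seeds.
#' @export
run_method_comparison <- function(sim = sim_config(), noise = noise_config(),
                                  seeds = 1:10, window = 4, threshold = 0.3,
                                  tracker = tracker_config()) {
  stopifnot(length(seeds) >= 1)
  results <- purrr::map_dfr(seeds, function(s) {
    run_one_scene(sim, noise, s, window, threshold, tracker)
  })
  structure(list(
    results = results,
    summary = summarise_benchmark(results),
    sim = sim, noise = noise, tracker = tracker,
    window = window, threshold = threshold, seeds = seeds
  ), class = "icu_benchmark")
}

run_one_scene <- function(sim, noise, seed, window, threshold, tracker) {
  sim$seed <- as.integer(seed)
  gt <- simulate_ground_truth(sim)
  det <- simulate_detections(gt, noise, seed = seed + 500000L)
  truth <- ground_truth_counts(gt)
  preds <- list(
    single = count_sequence(det, "single", threshold = threshold),
    multi = count_sequence(det, "multi", window = window, threshold = threshold),
    tracking = track_count(det, tracker)$counts
  )
  purrr::imap_dfr(preds, function(p, method) {
    evaluate_counts(p, truth) %>%
      mutate(method = method, seed = seed, .before = 1)
  })
}

summarise_benchmark <- function(results) {
  results %>%
    tidyr::pivot_longer(c("accuracy", "mae", "mre", "mse", "rmse"),
                        names_to = "metric") %>%
    group_by(.data$method, .data$category, .data$metric) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = stats::sd(.data$value, na.rm = TRUE), .groups = "drop")
}

#' Sweep the multi-frame window length
#'
#' Runs multi-frame counting at each window size (0 reduces exactly to
#' single-frame counting) over repeated simulated scenes and reports the
#' counting metrics per window size and category.
#'
#' @inheritParams run_method_comparison
#' @param windows Even window sizes to sweep.
#' @param seeds One repetition per seed (default 30 repetitions).
#' @return A list of class `icu_sweep` with `results`, `summary`, configs
#'   and seeds.
#' @export
run_window_sweep <- function(sim = sim_config(), noise = noise_config(),
                             windows = c(0, 2, 4, 10, 14, 20, 30),
                             seeds = 1:30, threshold = 0.3) {
  stopifnot(length(seeds) >= 1)
  for (w in windows) check_window(w)
  results <- purrr::map_dfr(seeds, function(s) {
    sim$seed <- as.integer(s)
    gt <- simulate_ground_truth(sim)
    det <- simulate_detections(gt, noise, seed = s + 500000L)
    truth <- ground_truth_counts(gt)
    purrr::map_dfr(windows, function(w) {
      p <- count_sequence(det, "multi", window = w, threshold = threshold)
      evaluate_counts(p, truth) %>%
        mutate(window = w, seed = s, .before = 1)
    })
  })
  summary <- results %>%
    tidyr::pivot_longer(c("accuracy", "mae", "mre", "mse", "rmse"),
                        names_to = "metric") %>%
    group_by(.data$window, .data$category, .data$metric) %>%
    summarise(mean = mean(.data$value, na.rm = TRUE),
              sd = stats::sd(.data$value, na.rm = TRUE), .groups = "drop")
  structure(list(results = results, summary = summary, sim = sim,
                 noise = noise, windows = windows, threshold = threshold,
                 seeds = seeds),
            class = "icu_sweep")
}

#' @export
print.icu_benchmark <- function(x, ...) {
  cat(sprintf("<icu_benchmark: %d seeds, methods single/multi/tracking>\n",
              length(x$seeds)))
  print(glance(x))
  invisible(x)
}

#' @export
print.icu_sweep <- function(x, ...) {
  cat(sprintf("<icu_sweep: windows %s, %d seeds>\n",
              paste(x$windows, collapse = "/"), length(x$seeds)))
  invisible(x)
}
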