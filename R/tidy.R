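#' Tidy and glance methods
#'
#' `tidy()` returns one row per elementary result (per trajectory, per
#' seed/method/category measurement, per category/threshold AP); `glance()`
#' returns the aggregated summary.
#'
#' @param x An `icu_tracking`, `icu_trajectories`, `icu_benchmark`,
#'   `icu_sweep` or `icu_map` object.
#' @param ... Unused.
#' @return A tibble.
#' @name icucount-tidiers
NULL

#' @rdname icucount-tidiers
#' @method tidy icu_trajectories
#' @export
tidy.icu_trajectories <- function(x, ...) {
  if (!length(x)) {
    return(tibble(id = integer(0), category = character(0),
                  start_frame = integer(0), end_frame = integer(0),
                  n_entries = integer(0), n_bridged = integer(0)))
  }
  bind_rows(lapply(x, function(tr) {
    tibble(
      id = tr$id, category = tr$category,
      start_frame = min(tr$frames), end_frame = max(tr$frames),
      n_entries = length(tr$frames),
      n_bridged = max(tr$frames) - min(tr$frames) + 1L - length(tr$frames)
    )
  }))
}

#' @rdname icucount-tidiers
#' @method tidy icu_tracking
#' @export
tidy.icu_tracking <- function(x, ...) tidy(x$trajectories)

#' @rdname icucount-tidiers
#' @method glance icu_tracking
#' @export
glance.icu_tracking <- function(x, ...) {
  tr <- tidy(x)
  tibble(
    n_frames = x$n_frames, n_trajectories = nrow(tr),
    n_patient = sum(tr$category == "patient"),
    n_clinician = sum(tr$category == "clinician"),
    n_visitor = sum(tr$category == "visitor"),
    mean_length = if (nrow(tr)) mean(tr$n_entries) else NA_real_
  )
}

#' @rdname icucount-tidiers
#' @method tidy icu_benchmark
#' @export
tidy.icu_benchmark <- function(x, ...) x$results

#' @rdname icucount-tidiers
#' @method glance icu_benchmark
#' @export
glance.icu_benchmark <- function(x, ...) x$summary

#' @rdname icucount-tidiers
#' @method tidy icu_sweep
#' @export
tidy.icu_sweep <- function(x, ...) x$results

#' @rdname icucount-tidiers
#' @method glance icu_sweep
#' @export
glance.icu_sweep <- function(x, ...) x$summary

#' @rdname icucount-tidiers
#' @method tidy icu_map
#' @export
tidy.icu_map <- function(x, ...) x$by_threshold

#' @rdname icucount-tidiers
#' @method glance icu_map
#' @export
glance.icu_map <- function(x, ...) {
  out <- tidyr::pivot_wider(x$by_category, names_from = "category",
                            values_from = "map", names_prefix = "map_")
  out$map <- x$map
  out
}
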