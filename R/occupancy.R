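#' Exclude assessments misaligned with the camera clock
#'
#' Assessments whose recording-to-assessment clock discrepancy exceeds
#' `max_offset_min` minutes are dropped; an offset exactly at the limit is
#' retained ("exceeded" is read strictly).
#'
#' @param assessments Tibble with at least `offset_min` (see
#'   [read_assessments()]).
#' @param max_offset_min Maximum tolerated discrepancy in minutes.
#' @return The retained assessments.
#' @export
filter_aligned <- function(assessments, max_offset_min = 30) {
  filter(assessments, .data$offset_min <= max_offset_min)
}

#' Segment-based presence durations around assessments
#'
#' For each assessment, the counts covering the 30-minute window centered on
#' the assessment time (configurable half-width) are cut into consecutive
#' 5-second segments — 360 segments for a full window at 1 frame per second
#' — and each segment's mean count per category is recorded. A category's
#' duration is then, under the default `"indicator"` definition, 5 seconds
#' for every segment whose mean count reaches `presence_threshold` (present
#' for at least half the segment): duration in minutes = present segments x
#' 5 / 60. The alternative `"person_time"` definition sums the segment mean
#' counts x 5 s, which measures person-minutes and can exceed the window
#' length when several people of a category overlap. Frames of the window
#' not covered by the count table are treated as absent and flagged through
#' `coverage` < 1; a window entirely outside the table is an error.
#'
#' @param counts Per-frame count tibble (typically tracking-based counts).
#' @param assessments Assessments tibble (`assessment_id`, `time` in seconds
#'   since stream start; see [read_assessments()]).
#' @param segment_seconds Segment length in seconds (default 5).
#' @param fps Frames per second of the count stream (default 1).
#' @param window_half_width_min Half-width of the window in minutes
#'   (default 15, i.e. a 30-minute window).
#' @param method `"indicator"` (default) or `"person_time"`.
#' @param presence_threshold Segment mean count at or above which the
#'   category is present in the segment (indicator method).
#' @return Tibble with one row per assessment x category: `assessment_id`,
#'   `category`, `duration_min`, `n_segments`, `n_present_segments`,
#'   `coverage`, and `segment_means` (list-column of per-segment means).
#' @export
segment_presence <- function(counts, assessments, segment_seconds = 5, fps = 1,
                             window_half_width_min = 15,
                             method = c("indicator", "person_time"),
                             presence_threshold = 0.5) {
  method <- match.arg(method)
  frames_per_segment <- max(1L, as.integer(round(segment_seconds * fps)))
  half_frames <- as.integer(round(window_half_width_min * 60 * fps))
  count_mat <- as.matrix(counts[ICU_CATEGORIES])
  frame_index <- counts$frame
  rows <- lapply(seq_len(nrow(assessments)), function(i) {
    center <- as.integer(round(assessments$time[i] * fps))
    window_frames <- (center - half_frames):(center + half_frames - 1L)
    pos <- match(window_frames, frame_index)
    if (all(is.na(pos))) {
      abort(sprintf("Assessment %s: window lies entirely outside the count table.",
                    assessments$assessment_id[i]))
    }
    wanted <- matrix(0, nrow = length(window_frames), ncol = 3,
                     dimnames = list(NULL, ICU_CATEGORIES))
    ok <- !is.na(pos)
    wanted[ok, ] <- count_mat[pos[ok], , drop = FALSE]
    n_segments <- length(window_frames) %/% frames_per_segment
    seg <- rep(seq_len(n_segments), each = frames_per_segment)
    used <- seq_len(n_segments * frames_per_segment)
    seg_means <- apply(wanted[used, , drop = FALSE], 2, function(x) {
      tapply(x, seg, mean)
    })
    seg_means <- matrix(seg_means, ncol = 3, dimnames = list(NULL, ICU_CATEGORIES))
    purrr::map_dfr(ICU_CATEGORIES, function(cc) {
      means <- seg_means[, cc]
      present <- sum(means >= presence_threshold)
      duration <- if (method == "indicator") {
        present * segment_seconds / 60
      } else {
        sum(means) * segment_seconds / 60
      }
      tibble(
        assessment_id = assessments$assessment_id[i], category = cc,
        duration_min = duration, n_segments = n_segments,
        n_present_segments = present,
        coverage = mean(ok), segment_means = list(unname(means))
      )
    })
  })
  bind_rows(rows)
}

#' Group mean presence durations by delirium status
#'
#' Joins presence durations to their (retained) assessments and averages per
#' category within delirium groups: either the binary CAM-ICU screen
#' (positive vs negative) or CAM-ICU-7 severity buckets (0 = no delirium,
#' 1-2 = subsyndromal, 3-7 = mild-to-severe). Empty groups are reported with
#' `n = 0` and a missing mean. Descriptive only — no inferential statistics
#' are attached.
#'
#' @param summaries Output of [segment_presence()].
#' @param assessments Assessments tibble with delirium labels.
#' @param grouping `"cam_icu_binary"` or `"cam_icu7_buckets"`.
#' @return Tibble `group`, `category`, `mean_duration_min`, `n`.
#' @export
group_durations <- function(summaries, assessments,
                            grouping = c("cam_icu_binary", "cam_icu7_buckets")) {
  grouping <- match.arg(grouping)
  joined <- left_join(summaries, assessments, by = "assessment_id")
  if (anyNA(joined$cam_icu)) {
    abort("Every summary must join to a retained assessment.")
  }
  joined$group <- if (grouping == "cam_icu_binary") {
    ifelse(joined$cam_icu > 0, "cam_icu_positive", "cam_icu_negative")
  } else {
    cut(joined$cam_icu7, breaks = c(-0.5, 0.5, 2.5, 7.5),
        labels = c("camicu7_0", "camicu7_1_2", "camicu7_3_7"))
  }
  levels <- if (grouping == "cam_icu_binary") {
    c("cam_icu_negative", "cam_icu_positive")
  } else {
    c("camicu7_0", "camicu7_1_2", "camicu7_3_7")
  }
  joined %>%
    group_by(group = factor(.data$group, levels = levels), .data$category) %>%
    summarise(mean_duration_min = mean(.data$duration_min), n = dplyr::n(),
              .groups = "drop") %>%
    tidyr::complete(group, category = ICU_CATEGORIES,
                    fill = list(mean_duration_min = NA_real_, n = 0L)) %>%
    mutate(group = as.character(.data$group)) %>%
    arrange(.data$group, match(.data$category, ICU_CATEGORIES))
}
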