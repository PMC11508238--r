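#' Count people in a single frame
#'
#' Counting by detection: every detection whose confidence reaches the
#' threshold contributes one count to the category given by the argmax of
#' its class-probability vector (ties break toward the lower category index:
#' patient, clinician, visitor). Output counts are integers.
#'
#' @param det Detections tibble.
#' @param frame Frame index to count; `det` may also already contain a
#'   single frame's rows, in which case `frame` can be omitted.
#' @param threshold Confidence threshold; detections below it are ignored
#'   (default 0.3, the pipeline-wide detection admission threshold).
#' @return One-row tibble with columns `patient`, `clinician`, `visitor`.
#' @export
#' @examples
#' det <- make_fixtures(1)$confused_track
#' count_single_frame(det, frame = 0)
count_single_frame <- function(det, frame = NULL, threshold = 0.3) {
  if (!is.null(frame)) det <- det[det$frame == frame, ]
  det <- det[det$confidence >= threshold, ]
  if (!nrow(det)) {
    return(tibble(patient = 0L, clinician = 0L, visitor = 0L))
  }
  cat <- prob_argmax(det[PROB_COLS])
  tibble(
    patient = sum(cat == "patient"),
    clinician = sum(cat == "clinician"),
    visitor = sum(cat == "visitor")
  )
}

#' Count people by averaging over a centered frame window
#'
#' Multi-frame counting: the single-frame counts of the `window/2` frames
#' preceding and succeeding frame `i` (plus frame `i` itself, so `window + 1`
#' frames in total; "duration 5" corresponds to `window = 4`) are averaged.
#' At the sequence edges the window is clipped and the divisor is the number
#' of frames actually in range. Counts are real-valued; rounding to integers
#' happens only in evaluation.
#'
#' @param det Detections tibble.
#' @param frame Center frame index.
#' @param window Even nonnegative window size `F`; `window = 0` reduces
#'   exactly to [count_single_frame()].
#' @param threshold Confidence threshold.
#' @param n_frames Number of frames in the sequence (defaults to the
#'   sequence attribute).
#' @return One-row tibble with real-valued `patient`, `clinician`, `visitor`.
#' @export
count_multi_frame <- function(det, frame, window = 4, threshold = 0.3,
                              n_frames = NULL) {
  check_window(window)
  meta <- seq_attrs(det, n_frames)
  if (frame < 0 || frame >= meta$n_frames) {
    abort(sprintf("Frame %d is outside the sequence (0..%d).",
                  frame, meta$n_frames - 1L))
  }
  half <- window / 2
  js <- max(0, frame - half):min(meta$n_frames - 1, frame + half)
  singles <- lapply(js, function(j) count_single_frame(det, j, threshold))
  m <- colMeans(do.call(rbind, lapply(singles, as.matrix)))
  tibble(patient = m[["patient"]], clinician = m[["clinician"]],
         visitor = m[["visitor"]])
}

#' Count people over a whole sequence
#'
#' Vectorised per-frame counting. `method = "single"` reproduces
#' [count_single_frame()] at every index; `method = "multi"` reproduces
#' [count_multi_frame()] (centered window, clipped at the edges).
#'
#' @param det Detections tibble.
#' @param method `"single"` or `"multi"`.
#' @param window Even window size for the multi-frame method.
#' @param threshold Confidence threshold.
#' @param n_frames Number of frames (defaults to the sequence attribute).
#' @return Count tibble: `frame`, `patient`, `clinician`, `visitor`; one row
#'   per frame, integer-valued for `"single"`, real-valued for `"multi"`.
#' @export
count_sequence <- function(det, method = c("single", "multi"), window = 4,
                           threshold = 0.3, n_frames = NULL) {
  method <- match.arg(method)
  meta <- seq_attrs(det, n_frames)
  if (meta$n_frames == 0) {
    return(tibble(frame = integer(0), patient = numeric(0),
                  clinician = numeric(0), visitor = numeric(0)))
  }
  singles <- single_count_matrix(det, meta$n_frames, threshold)
  out <- if (method == "single") singles else {
    check_window(window)
    half <- window / 2
    apply(singles, 2, clipped_running_mean, half = half)
  }
  if (meta$n_frames == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, ICU_CATEGORIES))
  tibble(
    frame = if (meta$n_frames > 0) 0:(meta$n_frames - 1L) else integer(0),
    patient = out[, 1], clinician = out[, 2], visitor = out[, 3]
  )
}

single_count_matrix <- function(det, n_frames, threshold) {
  det <- det[det$confidence >= threshold, ]
  m <- matrix(0, nrow = n_frames, ncol = 3, dimnames = list(NULL, ICU_CATEGORIES))
  if (nrow(det)) {
    cat <- prob_argmax(det[PROB_COLS])
    tab <- table(factor(det$frame, levels = 0:(n_frames - 1L)),
                 factor(cat, levels = ICU_CATEGORIES))
    m[] <- as.numeric(tab)
  }
  m
}

# mean over [i - half, i + half] clipped to the sequence, O(n) via cumsums
clipped_running_mean <- function(x, half) {
  n <- length(x)
  if (n == 0) return(x)
  cs <- c(0, cumsum(x))
  i <- seq_len(n)
  lo <- pmax(1, i - half)
  hi <- pmin(n, i + half)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

check_window <- function(window) {
  if (window < 0 || window %% 2 != 0) {
    abort("The window size F must be an even nonnegative integer.")
  }
}
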