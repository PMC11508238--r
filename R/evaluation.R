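#' Average precision of a detection set
#'
#' COCO-convention AP: detections are sorted by descending confidence and
#' greedily matched (within the same frame and category) to the unmatched
#' ground-truth box of highest IoU at or above `iou_threshold`; matches are
#' true positives, the rest false positives. Precision is interpolated as
#' the maximum precision at any recall at least `r`, and AP is the mean of
#' the interpolated precision over the 101-point recall grid 0, 0.01, ...,
#' 1. With ground truth present but no detections the AP is 0; with
#' detections but empty ground truth it is 0; with both empty it is `NA`
#' (the category does not participate).
#'
#' @param det Detections tibble (needs `frame`, box columns, `confidence`,
#'   and class-probability columns from which the predicted category is the
#'   argmax — or a precomputed `category` column).
#' @param truth Ground-truth tibble (`frame`, `category`, box columns).
#' @param iou_threshold Minimum IoU for a valid detection (default 0.5).
#' @param category Restrict to one category; `NULL` pools all (detections
#'   only match truth of their own category either way).
#' @return AP in \[0, 1\], or `NA_real_` when the category is absent from
#'   both detections and truth.
#' @export
average_precision <- function(det, truth, iou_threshold = 0.5, category = NULL) {
  det <- with_category(det)
  if (!is.null(category)) {
    det <- det[det$category == category, ]
    truth <- truth[truth$category == category, ]
  }
  if (nrow(truth) == 0) {
    return(if (nrow(det) == 0) NA_real_ else 0)
  }
  if (nrow(det) == 0) return(0)
  tp <- match_detections(det, truth, iou_threshold)
  ord <- order(-det$confidence)
  tp <- tp[ord]
  cum_tp <- cumsum(tp)
  precision <- cum_tp / seq_along(tp)
  recall <- cum_tp / nrow(truth)
  ap_from_pr(precision, recall)
}

# greedy confidence-ordered one-to-one matching; returns TP flags in det order
match_detections <- function(det, truth, iou_threshold) {
  tp <- logical(nrow(det))
  used <- logical(nrow(truth))
  ord <- order(-det$confidence)
  for (i in ord) {
    cand <- which(!used & truth$frame == det$frame[i] &
                    truth$category == det$category[i])
    if (!length(cand)) next
    ious <- box_iou(det[i, ], truth[cand, ])
    j <- which.max(ious)
    if (ious[j] >= iou_threshold - 1e-9) { # grid thresholds carry fp error
      tp[i] <- TRUE
      used[cand[j]] <- TRUE
    }
  }
  tp
}

# 101-point interpolated AP from a precision/recall sequence
ap_from_pr <- function(precision, recall) {
  grid <- seq(0, 1, by = 0.01)
  # max precision at recall >= r
  interp <- vapply(grid, function(r) {
    ok <- recall >= r - 1e-12
    if (any(ok)) max(precision[ok]) else 0
  }, numeric(1))
  mean(interp)
}

with_category <- function(det) {
  if (!"category" %in% names(det)) {
    det$category <- if (nrow(det)) prob_argmax(det[PROB_COLS]) else character(0)
  }
  det
}

#' Mean average precision over IoU thresholds
#'
#' AP is computed per category at each IoU threshold of the grid (default
#' 0.50 to 0.95 in steps of 0.05); a category's mAP is the mean over the ten
#' thresholds, and the headline mAP averages the per-category values.
#' Categories absent from both detections and truth are excluded from the
#' category mean.
#'
#' @inheritParams average_precision
#' @param iou_thresholds IoU threshold grid.
#' @return A list of class `icu_map`: `map` (headline number),
#'   `by_category` (tibble `category`, `map`), and `by_threshold` (tibble
#'   `category`, `iou_threshold`, `ap`).
#' @export
detection_map <- function(det, truth, iou_thresholds = seq(0.5, 0.95, by = 0.05)) {
  det <- with_category(det)
  by_threshold <- tidyr::expand_grid(
    category = ICU_CATEGORIES, iou_threshold = iou_thresholds
  ) %>%
    mutate(ap = purrr::map2_dbl(
      .data$category, .data$iou_threshold,
      ~ average_precision(det, truth, iou_threshold = .y, category = .x)
    ))
  by_category <- by_threshold %>%
    group_by(.data$category) %>%
    summarise(map = mean(.data$ap), .groups = "drop")
  structure(list(
    map = mean(by_category$map, na.rm = TRUE),
    by_category = by_category,
    by_threshold = by_threshold
  ), class = "icu_map")
}

#' @export
print.icu_map <- function(x, ...) {
  cat(sprintf("mAP@[.50:.95] = %.4f\n", x$map))
  print(x$by_category)
  invisible(x)
}

align_counts <- function(predicted, truth) {
  if (nrow(predicted) != nrow(truth) ||
      !all(predicted$frame == truth$frame)) {
    abort("Predicted and truth count tables are not aligned on frame_index.")
  }
  if (nrow(predicted) == 0) abort("Count tables are empty (n = 0).")
  invisible(NULL)
}

#' Per-category counting accuracy
#'
#' Fractional predictions (e.g. multi-frame window means) are rounded half
#' up, then the accuracy for a category is the percentage of frames whose
#' rounded prediction equals the ground-truth count exactly.
#'
#' @param predicted,truth Count tibbles aligned on `frame`.
#' @return Tibble `category`, `accuracy` (percent).
#' @export
counting_accuracy <- function(predicted, truth) {
  align_counts(predicted, truth)
  tibble(
    category = ICU_CATEGORIES,
    accuracy = vapply(ICU_CATEGORIES, function(cc) {
      100 * mean(round_half_up(predicted[[cc]]) == truth[[cc]])
    }, numeric(1), USE.NAMES = FALSE)
  )
}

#' Counting regression errors
#'
#' Mean absolute error, mean relative error, mean squared error and its
#' square root per category, computed on the raw (unrounded) predictions:
#' \deqn{MAE = \frac1n \sum_i |y_i - \hat y_i|, \quad
#'       MRE = \frac1n \sum_i \frac{|y_i - \hat y_i|}{y_i}, \quad
#'       MSE = \frac1n \sum_i (y_i - \hat y_i)^2.}
#' The relative error uses the absolute deviation in the numerator and, as
#' division by a zero count is undefined and empty-category frames are
#' common in room monitoring, frames with `y_i = 0` are skipped in the MRE
#' average by default (`mre_zero_policy = "skip"`); the alternative `"nan"`
#' propagates the undefined ratio.
#'
#' @param predicted,truth Count tibbles aligned on `frame`.
#' @param mre_zero_policy `"skip"` or `"nan"`.
#' @return Tibble `category`, `mae`, `mre`, `mse`, `rmse`; `mre` is `NA`
#'   when no frame has positive truth under the skip policy.
#' @export
count_errors <- function(predicted, truth, mre_zero_policy = c("skip", "nan")) {
  mre_zero_policy <- match.arg(mre_zero_policy)
  align_counts(predicted, truth)
  rows <- lapply(ICU_CATEGORIES, function(cc) {
    y <- truth[[cc]]
    yhat <- predicted[[cc]]
    err <- y - yhat
    mse <- mean(err^2)
    mre <- if (mre_zero_policy == "skip") {
      pos <- y > 0
      if (any(pos)) mean(abs(err[pos]) / y[pos]) else NA_real_
    } else {
      mean(abs(err) / y)
    }
    tibble(category = cc, mae = mean(abs(err)), mre = mre,
           mse = mse, rmse = sqrt(mse))
  })
  bind_rows(rows)
}

#' Full counting evaluation
#'
#' Convenience wrapper joining [counting_accuracy()] and [count_errors()].
#'
#' @inheritParams count_errors
#' @return Tibble `category`, `accuracy`, `mae`, `mre`, `mse`, `rmse`.
#' @export
evaluate_counts <- function(predicted, truth, mre_zero_policy = c("skip", "nan")) {
  left_join(counting_accuracy(predicted, truth),
            count_errors(predicted, truth, mre_zero_policy),
            by = "category")
}
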