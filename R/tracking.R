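#' Tracker configuration
#'
#' Tuning knobs of the two-stage tracking-to-count association. Defaults are
#' conventional values for appearance-plus-IoU trackers and are free
#' parameters of the pipeline, not reproductions of any reference system.
#' Tracks are confirmed immediately (at 1 frame per second a person may
#' legitimately appear in very few frames) and terminated after `max_age`
#' consecutive unmatched frames.
#'
#' @param appearance_min_similarity Minimum cosine similarity for a stage-1
#'   (re-identification) match.
#' @param iou_min_overlap Minimum IoU between a trajectory's Kalman-predicted
#'   box and a detection for a stage-2 match.
#' @param max_age Number of consecutive missed frames a trajectory survives.
#' @param ema_momentum Momentum of the exponential moving average that
#'   maintains a trajectory's appearance summary.
#' @param confidence_threshold Detections below this confidence are not
#'   admitted into tracking.
#' @return A list of class `icu_tracker_config`.
#' @export
tracker_config <- function(appearance_min_similarity = 0.4,
                           iou_min_overlap = 0.3, max_age = 5,
                           ema_momentum = 0.9, confidence_threshold = 0.3) {
  if (ema_momentum < 0 || ema_momentum > 1) abort("ema_momentum must lie in [0, 1].")
  if (confidence_threshold < 0 || confidence_threshold > 1) {
    abort("confidence_threshold must lie in [0, 1].")
  }
  structure(list(
    appearance_min_similarity = appearance_min_similarity,
    iou_min_overlap = iou_min_overlap, max_age = as.integer(max_age),
    ema_momentum = ema_momentum, confidence_threshold = confidence_threshold
  ), class = "icu_tracker_config")
}

#' Appearance affinity between trajectories and detections
#'
#' Cosine similarities between trajectory appearance summaries and detection
#' re-identification features. All vectors are expected to be unit norm, so
#' the affinity is the plain dot product, in \[-1, 1\].
#'
#' @param trajectories Matrix with one appearance summary per row, or a list
#'   of numeric vectors.
#' @param detections Matrix with one detection feature per row, or a list of
#'   numeric vectors.
#' @return Numeric matrix, trajectories by detections.
#' @export
appearance_affinity <- function(trajectories, detections) {
  a <- as_app_matrix(trajectories)
  b <- as_app_matrix(detections)
  if (nrow(a) && nrow(b) && ncol(a) != ncol(b)) {
    abort("Appearance dimensions differ between trajectories and detections.")
  }
  check_unit_rows <- function(m, what) {
    if (!nrow(m)) return()
    norms <- sqrt(rowSums(m^2))
    if (any(norms < 1e-12)) abort(paste0("Zero-norm appearance vector in ", what, "."))
  }
  check_unit_rows(a, "trajectories")
  check_unit_rows(b, "detections")
  if (!nrow(a) || !nrow(b)) return(matrix(numeric(0), nrow(a), nrow(b)))
  a %*% t(b)
}

as_app_matrix <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    if (!length(x)) return(matrix(numeric(0), 0, 0))
    return(do.call(rbind, x))
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  as.matrix(x)
}

#' Create an empty tracker state
#'
#' @param config An [tracker_config()] object.
#' @return A tracker state of class `icu_tracker`, to be advanced with
#'   [tracker_step()].
#' @export
new_tracker <- function(config = tracker_config()) {
  stopifnot(inherits(config, "icu_tracker_config"))
  structure(list(tracks = list(), next_id = 1L, last_frame = -1L,
                 config = config), class = "icu_tracker")
}

#' Advance the tracker by one frame
#'
#' One step of the two-stage association: (1) detections below the
#' confidence threshold are dropped; (2) all active trajectories are
#' Kalman-predicted forward; (3) stage one matches detections to
#' trajectories by appearance affinity with maximum-similarity bipartite
#' assignment; (4) stage two matches the leftovers by IoU between the
#' predicted boxes and the detections; (5) matched trajectories are extended
#' and Kalman-updated and their appearance summary moves by exponential
#' moving average toward the matched feature; (6) unmatched detections spawn
#' new trajectories; (7) trajectories unmatched for more than `max_age`
#' consecutive frames are terminated. Frames must be presented in strictly
#' increasing order.
#'
#' @param tracker Tracker state from [new_tracker()] or a previous step.
#' @param det Detections tibble holding one frame (or the rows of `frame`
#'   within a larger tibble).
#' @param frame Frame index; defaults to the single frame present in `det`.
#' @return The updated tracker state.
#' @export
tracker_step <- function(tracker, det, frame = NULL) {
  stopifnot(inherits(tracker, "icu_tracker"))
  if (is.null(frame)) {
    frame <- unique(det$frame)
    if (length(frame) > 1) abort("det contains several frames; pass `frame`.")
    if (length(frame) == 0) abort("Empty det and no `frame` given.")
  } else {
    det <- det[det$frame == frame, ]
  }
  boxes <- as.matrix(det[c("cx", "cy", "w", "h")])
  probs <- as.matrix(det[PROB_COLS])
  app <- if (nrow(det)) do.call(rbind, det$appearance) else matrix(numeric(0), 0, 0)
  tracker_step_impl(tracker, as.integer(frame), boxes, probs,
                    det$confidence, app)
}

tracker_step_impl <- function(tracker, frame, boxes, probs, conf, app) {
  cfg <- tracker$config
  if (frame <= tracker$last_frame) {
    abort(sprintf("Frame %d is out of order (last processed: %d).",
                  frame, tracker$last_frame))
  }
  tracker$last_frame <- frame

  admit <- which(conf >= cfg$confidence_threshold)
  boxes <- boxes[admit, , drop = FALSE]
  probs <- probs[admit, , drop = FALSE]
  conf <- conf[admit]
  app <- app[admit, , drop = FALSE]
  nd <- nrow(boxes)

  active <- which(vapply(tracker$tracks, `[[`, logical(1), "active"))
  # predict all active trajectories forward
  for (k in active) {
    tracker$tracks[[k]]$kalman <- kalman_predict(tracker$tracks[[k]]$kalman)
  }

  matched_track <- integer(0)
  matched_det <- integer(0)
  un_tracks <- active
  un_dets <- seq_len(nd)

  if (length(active) && nd) {
    # stage 1: appearance re-identification
    app_summ <- do.call(rbind, lapply(tracker$tracks[active], `[[`, "app"))
    s1 <- app_summ %*% t(app)
    m1 <- match_bipartite(s1, cfg$appearance_min_similarity)
    matched_track <- active[m1$pairs$row]
    matched_det <- m1$pairs$col
    un_tracks <- active[m1$unmatched_rows]
    un_dets <- m1$unmatched_cols

    # stage 2: IoU between Kalman-predicted boxes and leftover detections
    if (length(un_tracks) && length(un_dets)) {
      pred <- bind_rows(lapply(tracker$tracks[un_tracks],
                               function(t) kalman_box(t$kalman)))
      pred$w <- pmax(pred$w, 1e-6)
      pred$h <- pmax(pred$h, 1e-6)
      dets <- tibble(cx = boxes[un_dets, 1], cy = boxes[un_dets, 2],
                     w = boxes[un_dets, 3], h = boxes[un_dets, 4])
      s2 <- box_iou_matrix(pred, dets)
      m2 <- match_bipartite(s2, cfg$iou_min_overlap)
      matched_track <- c(matched_track, un_tracks[m2$pairs$row])
      matched_det <- c(matched_det, un_dets[m2$pairs$col])
      un_tracks <- un_tracks[m2$unmatched_rows]
      un_dets <- un_dets[m2$unmatched_cols]
    }
  }

  # extend matched trajectories
  for (i in seq_along(matched_track)) {
    k <- matched_track[i]
    j <- matched_det[i]
    tr <- tracker$tracks[[k]]
    box <- list(cx = boxes[j, 1], cy = boxes[j, 2], w = boxes[j, 3], h = boxes[j, 4])
    tr$kalman <- kalman_update(tr$kalman, as.data.frame(box))
    tr$frames <- c(tr$frames, frame)
    tr$boxes[[length(tr$boxes) + 1]] <- boxes[j, ]
    tr$probs[[length(tr$probs) + 1]] <- probs[j, ]
    tr$conf <- c(tr$conf, conf[j])
    tr$probs_sum <- tr$probs_sum + probs[j, ]
    a <- cfg$ema_momentum * tr$app + (1 - cfg$ema_momentum) * app[j, ]
    tr$app <- a / sqrt(sum(a^2))
    tr$misses <- 0L
    tracker$tracks[[k]] <- tr
  }

  # age out unmatched trajectories
  for (k in un_tracks) {
    tr <- tracker$tracks[[k]]
    tr$misses <- tr$misses + 1L
    if (tr$misses > cfg$max_age) tr$active <- FALSE
    tracker$tracks[[k]] <- tr
  }

  # unmatched detections start new trajectories
  for (j in un_dets) {
    box <- tibble(cx = boxes[j, 1], cy = boxes[j, 2], w = boxes[j, 3], h = boxes[j, 4])
    tracker$tracks[[length(tracker$tracks) + 1]] <- list(
      id = tracker$next_id, active = TRUE, misses = 0L,
      frames = frame, boxes = list(boxes[j, ]), probs = list(probs[j, ]),
      conf = conf[j], probs_sum = probs[j, ],
      app = app[j, ] / sqrt(sum(app[j, ]^2)),
      kalman = kalman_init(box)
    )
    tracker$next_id <- tracker$next_id + 1L
  }
  tracker
}

#' Category of a trajectory by accumulated class-probability vote
#'
#' The trajectory's category is the argmax, over the three categories, of
#' the entrywise sum of its members' class-probability vectors — a soft
#' majority vote over the whole trajectory, so that a minority of
#' misclassified frames cannot flip the label. Ties break toward the lower
#' category index.
#'
#' @param traj A trajectory from [track_count()]'s `trajectories`, or a
#'   numeric matrix of class-probability rows.
#' @return One of `"patient"`, `"clinician"`, `"visitor"`.
#' @export
trajectory_category <- function(traj) {
  probs <- if (is.matrix(traj)) traj else {
    if (!is.null(traj$probs_sum)) matrix(traj$probs_sum, nrow = 1) else
      do.call(rbind, traj$probs)
  }
  if (!nrow(probs)) abort("Trajectory has no entries.")
  s <- colSums(probs)
  ICU_CATEGORIES[which.max(s)] # which.max takes the first (lower index) on ties
}

#' Count people by tracking
#'
#' Runs the two-stage tracker over the full sequence, fixes each finalized
#' trajectory's category by the accumulated class-probability vote, and
#' counts, for every frame, the trajectories of each category active at that
#' frame. A trajectory is active on its entry frames and across bridged gaps
#' between entries (gaps never exceed `max_age` by construction), so brief
#' occlusions do not drop the count; frames after a trajectory's last entry
#' are not counted.
#'
#' @param det Detections tibble.
#' @param config An [tracker_config()] object.
#' @param n_frames Number of frames (defaults to the sequence attribute).
#' @return A list of class `icu_tracking`: `counts` (per-frame count
#'   tibble) and `trajectories` (class `icu_trajectories`).
#' @export
track_count <- function(det, config = tracker_config(), n_frames = NULL) {
  meta <- seq_attrs(det, n_frames)
  tracker <- new_tracker(config)
  if (meta$n_frames > 0) {
    ord <- order(det$frame)
    det <- det[ord, ]
    boxes_all <- as.matrix(det[c("cx", "cy", "w", "h")])
    probs_all <- as.matrix(det[PROB_COLS])
    app_all <- if (nrow(det)) do.call(rbind, det$appearance) else
      matrix(numeric(0), 0, 0)
    idx_by_frame <- split(seq_len(nrow(det)), factor(det$frame, levels = 0:(meta$n_frames - 1L)))
    for (f in seq_len(meta$n_frames)) {
      idx <- idx_by_frame[[f]]
      tracker <- tracker_step_impl(
        tracker, f - 1L,
        boxes_all[idx, , drop = FALSE], probs_all[idx, , drop = FALSE],
        det$confidence[idx], app_all[idx, , drop = FALSE]
      )
    }
  }
  trajectories <- finalize_tracks(tracker)
  counts <- counts_from_trajectories(trajectories, meta$n_frames)
  structure(list(counts = counts, trajectories = trajectories,
                 config = config, n_frames = meta$n_frames),
            class = "icu_tracking")
}

finalize_tracks <- function(tracker) {
  trajs <- lapply(tracker$tracks, function(tr) {
    boxes <- do.call(rbind, tr$boxes)
    colnames(boxes) <- c("cx", "cy", "w", "h")
    probs <- do.call(rbind, tr$probs)
    colnames(probs) <- PROB_COLS
    list(
      id = tr$id, frames = tr$frames, boxes = boxes, probs = probs,
      conf = tr$conf, category = trajectory_category(probs),
      app = tr$app
    )
  })
  structure(trajs, class = "icu_trajectories")
}

counts_from_trajectories <- function(trajectories, n_frames) {
  m <- matrix(0L, nrow = n_frames, ncol = 3, dimnames = list(NULL, ICU_CATEGORIES))
  for (tr in trajectories) {
    span <- (min(tr$frames)):(max(tr$frames)) # bridged gaps stay counted
    span <- span[span < n_frames]
    col <- match(tr$category, ICU_CATEGORIES)
    m[span + 1L, col] <- m[span + 1L, col] + 1L
  }
  tibble(
    frame = if (n_frames > 0) 0:(n_frames - 1L) else integer(0),
    patient = m[, 1], clinician = m[, 2], visitor = m[, 3]
  )
}

trajectory_entries <- function(trajectories) {
  if (inherits(trajectories, "icu_tracking")) {
    trajectories <- trajectories$trajectories
  }
  if (is.data.frame(trajectories)) return(trajectories)
  if (!length(trajectories)) {
    return(tibble(frame = integer(0), id = integer(0), category = character(0),
                  cx = numeric(0), cy = numeric(0), w = numeric(0),
                  h = numeric(0), confidence = numeric(0)))
  }
  bind_rows(lapply(trajectories, function(tr) {
    tibble(
      frame = tr$frames, id = tr$id, category = tr$category,
      cx = tr$boxes[, "cx"], cy = tr$boxes[, "cy"],
      w = tr$boxes[, "w"], h = tr$boxes[, "h"], confidence = tr$conf
    )
  }))
}

#' @export
print.icu_trajectories <- function(x, ...) {
  cat(sprintf("<icu_trajectories: %d trajectories, %d entries>\n",
              length(x), sum(vapply(x, function(t) length(t$frames), integer(1)))))
  invisible(x)
}

#' @export
print.icu_tracking <- function(x, ...) {
  cat(sprintf("<icu_tracking: %d frames, %d trajectories>\n",
              x$n_frames, length(x$trajectories)))
  invisible(x)
}
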