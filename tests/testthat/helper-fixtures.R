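# Shared fixture builders. Everything is generated in code from pinned seeds.

# a unit vector along axis k of dimension d
axis_vec <- function(k, d = 8) {
  v <- numeric(d)
  v[k] <- 1
  v
}

# hand-build a detections tibble from parallel vectors; one-hot class probs
# unless probs is supplied as a list of 3-vectors
make_det <- function(frame, cx, cy, w = 150, h = 330,
                     category = "clinician", confidence = 0.9,
                     appearance = NULL, probs = NULL, n_frames = NULL) {
  n <- length(frame)
  category <- rep_len(category, n)
  p <- if (is.null(probs)) {
    m <- matrix(0, n, 3)
    m[cbind(seq_len(n), match(category, icu_categories()))] <- 1
    m
  } else {
    do.call(rbind, probs)
  }
  app <- appearance %||% lapply(seq_len(n), function(i) {
    axis_vec(match(category[i], icu_categories()))
  })
  det <- tibble::tibble(
    frame = as.integer(frame),
    cx = rep_len(cx, n), cy = rep_len(cy, n),
    w = rep_len(w, n), h = rep_len(h, n),
    p_patient = p[, 1], p_clinician = p[, 2], p_visitor = p[, 3],
    confidence = rep_len(confidence, n),
    appearance = app
  )
  attr(det, "n_frames") <- as.integer(n_frames %||% (max(frame) + 1L))
  attr(det, "fps") <- 1
  attr(det, "frame_width") <- 1392
  attr(det, "frame_height") <- 1044
  det
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a scene whose occupancy never changes: patient in bed plus one clinician
# and one visitor present for every frame
constant_scene <- function(duration = 200, seed = 11) {
  sim_config(
    duration_frames = duration,
    n_clinician_visits = 0, n_visitor_visits = 0,
    visit_schedule = tibble::tibble(
      category = c("clinician", "visitor"),
      entry_frame = 0L,
      dwell_frames = as.integer(duration)
    ),
    seed = seed
  )
}

# exhaustive maximum-similarity complete assignment (oracle for bipartite
# matching); returns the optimal total similarity
brute_force_assignment <- function(s) {
  k <- nrow(s)
  m <- ncol(s)
  n <- max(k, m)
  padded <- matrix(0, n, n)
  padded[seq_len(k), seq_len(m)] <- s
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  max(vapply(perms(seq_len(n)), function(p) {
    sum(padded[cbind(seq_len(n), p)])
  }, numeric(1)))
}

# independent 101-point AP oracle: its own greedy matching and an explicit
# precision-recall staircase enumerated prefix by prefix
ap_oracle <- function(det, truth, iou_threshold) {
  if (nrow(truth) == 0) return(if (nrow(det) == 0) NA_real_ else 0)
  if (nrow(det) == 0) return(0)
  det <- det[order(-det$confidence), ]
  cat <- icu_categories()[max.col(as.matrix(
    det[c("p_patient", "p_clinician", "p_visitor")]), ties.method = "first")]
  used <- rep(FALSE, nrow(truth))
  is_tp <- rep(FALSE, nrow(det))
  for (i in seq_len(nrow(det))) {
    best <- 0
    best_j <- 0L
    for (j in seq_len(nrow(truth))) {
      if (used[j]) next
      if (truth$frame[j] != det$frame[i] || truth$category[j] != cat[i]) next
      v <- box_iou(det[i, ], truth[j, ])
      if (v > best) {
        best <- v
        best_j <- j
      }
    }
    if (best_j > 0L && best >= iou_threshold - 1e-9) {
      is_tp[i] <- TRUE
      used[best_j] <- TRUE
    }
  }
  # staircase: precision/recall after each prefix of the ranked list
  prec <- cumsum(is_tp) / seq_along(is_tp)
  rec <- cumsum(is_tp) / nrow(truth)
  mean(vapply(seq(0, 1, 0.01), function(r) {
    ok <- which(rec >= r - 1e-12)
    if (length(ok)) max(prec[ok]) else 0
  }, numeric(1)))
}

# random single-category detection/truth pair on a tiny frame grid
random_ap_instance <- function(seed) {
  set.seed(seed)
  n_truth <- sample(0:6, 1)
  n_det <- sample(0:8, 1)
  truth <- tibble::tibble(
    frame = sample(0:2, n_truth, replace = TRUE),
    identity = seq_len(n_truth),
    category = "clinician",
    cx = runif(n_truth, 0, 60), cy = runif(n_truth, 0, 60),
    w = runif(n_truth, 8, 25), h = runif(n_truth, 8, 25)
  )
  det <- make_det(
    frame = if (n_det) sample(0:2, n_det, replace = TRUE) else integer(0),
    cx = runif(n_det, 0, 60), cy = runif(n_det, 0, 60),
    w = runif(n_det, 8, 25), h = runif(n_det, 8, 25),
    category = "clinician",
    confidence = runif(n_det, 0.1, 1),
    n_frames = 3
  )
  # nudge some detections onto truth boxes so TPs exist
  if (n_det && n_truth) {
    k <- min(n_det, n_truth)
    det$cx[seq_len(k)] <- truth$cx[seq_len(k)] + runif(k, -3, 3)
    det$cy[seq_len(k)] <- truth$cy[seq_len(k)] + runif(k, -3, 3)
    det$w[seq_len(k)] <- truth$w[seq_len(k)]
    det$h[seq_len(k)] <- truth$h[seq_len(k)]
    det$frame[seq_len(k)] <- truth$frame[seq_len(k)]
  }
  list(det = det, truth = truth)
}
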