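test_that("appearance affinity is the cosine of unit feature vectors", {
  a <- axis_vec(1)
  b <- axis_vec(2)
  expect_equal(as.numeric(appearance_affinity(list(a), list(a))), 1)
  expect_equal(as.numeric(appearance_affinity(list(a), list(b))), 0)
  set.seed(10)
  trj <- lapply(1:2, function(i) { v <- rnorm(8); v / sqrt(sum(v^2)) })
  det <- lapply(1:3, function(i) { v <- rnorm(8); v / sqrt(sum(v^2)) })
  m <- appearance_affinity(trj, det)
  for (i in 1:2) for (j in 1:3) {
    expect_equal(m[i, j], sum(trj[[i]] * det[[j]]))
  }
  expect_error(appearance_affinity(list(a), list(rep(0, 8))), "Zero-norm")
})

test_that("bipartite matching maximizes total similarity and applies the floor", {
  res <- match_bipartite(matrix(c(0.9, 0.2, 0.1, 0.8), 2, 2), 0)
  expect_equal(res$pairs$row, 1:2)
  expect_equal(res$pairs$col, 1:2)
  expect_equal(sum(res$pairs$similarity), 1.7)

  low <- match_bipartite(matrix(0.1, 2, 2), min_similarity = 0.5)
  expect_equal(nrow(low$pairs), 0)
  expect_equal(low$unmatched_rows, 1:2)
  expect_equal(low$unmatched_cols, 1:2)

  one <- match_bipartite(matrix(c(0.3, 0.7), 1, 2), min_similarity = 0.5)
  expect_equal(one$pairs$col, 2)
  expect_equal(one$unmatched_cols, 1)
})

test_that("bipartite matching equals exhaustive search on random instances", {
  set.seed(2024)
  for (i in 1:120) {
    k <- sample(1:6, 1)
    m <- sample(1:6, 1)
    s <- matrix(runif(k * m, -1, 1), k, m)
    got <- sum(match_bipartite(s, min_similarity = -Inf)$pairs$similarity)
    expect_equal(got, brute_force_assignment(s), tolerance = 1e-9)
  }
})

test_that("Kalman prediction follows the constant-velocity model", {
  st <- kalman_init(tibble::tibble(cx = 100, cy = 50, w = 30, h = 60))
  pred <- kalman_predict(st)
  expect_equal(pred$mean[1:4], st$mean[1:4]) # zero velocity: mean unchanged
  expect_true(all(diag(pred$cov) >= diag(st$cov))) # process noise grows cov

  st$mean[5] <- 1 # cx velocity 1 px/frame
  expect_equal(kalman_predict(st)$mean[1], 101)
})

test_that("Kalman update is a contraction toward the measurement", {
  st <- kalman_predict(kalman_init(tibble::tibble(cx = 10, cy = 10, w = 20, h = 40)))
  same <- kalman_update(st, kalman_box(st))
  expect_equal(same$mean, st$mean, tolerance = 1e-9) # measurement = prediction
  expect_lte(sum(diag(same$cov)), sum(diag(st$cov)))

  z <- tibble::tibble(cx = 14, cy = 12, w = 20, h = 40)
  exact <- kalman_update(st, z, r_scale = 0) # zero measurement noise
  expect_equal(as.numeric(kalman_box(exact)), as.numeric(z), tolerance = 1e-9)
  expect_error(kalman_update(st, tibble::tibble(cx = 1, cy = 1, w = 2, h = -3)),
               "positive")
})

test_that("the filter converges on noiseless constant-velocity motion", {
  st <- kalman_init(tibble::tibble(cx = 0, cy = 0, w = 30, h = 60))
  err <- NA_real_
  for (t in 1:20) {
    st <- kalman_predict(st)
    err <- abs(st$mean[1] - 5 * t) # true cx moves 5 px/frame
    st <- kalman_update(st, tibble::tibble(cx = 5 * t, cy = 0, w = 30, h = 60))
  }
  expect_lt(err, 0.1)
})

test_that("covariance stays symmetric positive semi-definite over many cycles", {
  set.seed(3)
  st <- kalman_init(tibble::tibble(cx = 50, cy = 50, w = 30, h = 60))
  for (t in 1:1000) {
    st <- kalman_predict(st)
    st <- kalman_update(st, tibble::tibble(cx = 50 + rnorm(1, 0, 2),
                                           cy = 50 + rnorm(1, 0, 2),
                                           w = 30, h = 60))
    expect_identical(st$cov, t(st$cov))
  }
  expect_true(all(eigen(st$cov, symmetric = TRUE, only.values = TRUE)$values > -1e-9))
})

test_that("a cold start spawns one trajectory per admitted detection", {
  det <- make_det(frame = c(0, 0), cx = c(100, 800), cy = 300,
                  category = c("clinician", "visitor"),
                  appearance = list(axis_vec(1), axis_vec(2)))
  tr <- tracker_step(new_tracker(), det, frame = 0)
  expect_length(tr$tracks, 2)
  low_conf <- make_det(frame = 1, cx = 400, cy = 300, confidence = 0.1)
  tr <- tracker_step(tr, low_conf, frame = 1)
  expect_length(tr$tracks, 2) # below-threshold detection not admitted
  expect_error(tracker_step(tr, det, frame = 0), "out of order")
})

test_that("well-separated actors yield one clean trajectory each", {
  gt <- simulate_ground_truth(constant_scene(duration = 10, seed = 4))
  det <- simulate_detections(gt, noise_config_zero(), seed = 1)
  res <- track_count(det)
  trj <- tidy(res)
  expect_equal(nrow(trj), 3) # patient + clinician + visitor, no switches
  expect_true(all(trj$n_entries == 10))
  expect_setequal(trj$category, icu_categories())
  # partition: every admitted detection lands in exactly one trajectory
  expect_equal(sum(trj$n_entries), nrow(det))
})

test_that("a single missed frame is bridged into one trajectory", {
  fx <- make_fixtures(1)
  det <- fx$occlusion_gap
  expect_false(5 %in% det$frame) # the constructed gap
  res <- track_count(det, tracker_config(max_age = 2))
  trj <- tidy(res)
  expect_equal(nrow(trj), 1)
  expect_equal(trj$n_bridged, 1)
  expect_equal(res$counts$clinician, rep(1, 10)) # gap frame still counted
})

test_that("trajectory category is the argmax of summed class probabilities", {
  probs <- rbind(c(0.6, 0.3, 0.1), c(0.2, 0.5, 0.3), c(0.3, 0.4, 0.3))
  expect_equal(trajectory_category(probs), "clinician") # sums 1.1, 1.2, 0.7
  expect_equal(trajectory_category(matrix(c(0.5, 0.3, 0.2), 1)), "patient")
  onehot <- matrix(rep(c(0, 1, 0), 5), ncol = 3, byrow = TRUE)
  expect_equal(trajectory_category(onehot), "clinician")
  # tie breaks toward the lower category index
  expect_equal(trajectory_category(matrix(c(0.4, 0.4, 0.2), 1)), "patient")
})

test_that("the trajectory vote overrides sporadic per-frame misclassification", {
  det <- make_fixtures(1)$confused_track # visitor label in 2 of 10 frames
  per_frame <- icu_categories()[max.col(as.matrix(
    det[c("p_patient", "p_clinician", "p_visitor")]), ties.method = "first")]
  expect_equal(sum(per_frame == "visitor"), 2)
  res <- track_count(det)
  expect_equal(tidy(res)$category, "clinician") # vote 8 vs 2
  expect_equal(res$counts$clinician, rep(1, 10))
  expect_equal(res$counts$visitor, rep(0, 10))
})

test_that("an empty sequence yields an empty table and no trajectories", {
  res <- track_count(make_det(integer(0), numeric(0), numeric(0), n_frames = 0))
  expect_equal(nrow(res$counts), 0)
  expect_length(res$trajectories, 0)
})

test_that("trajectory-level voting beats per-detection labels under confusion", {
  # 120 sequential mover visits of 18 frames each; symmetric mover confusion
  # 0.3 so per-detection argmax accuracy is ~0.7, while an 18-frame majority
  # vote should exceed 0.95
  n_visits <- 120
  sched <- tibble::tibble(
    category = rep(c("clinician", "visitor"), length.out = n_visits),
    entry_frame = as.integer((seq_len(n_visits) - 1) * 25),
    dwell_frames = 18L
  )
  cfg <- sim_config(duration_frames = max(sched$entry_frame) + 25L,
                    patient_present = FALSE, n_clinician_visits = 0,
                    n_visitor_visits = 0, visit_schedule = sched, seed = 77)
  gt <- simulate_ground_truth(cfg)
  det <- simulate_detections(
    gt, noise_config(miss_prob = 0, patient_miss_prob = 0,
                     occlusion_extra_miss_prob = 0, fp_rate = 0,
                     confusion = 0.3, jitter_sd = 0), seed = 14)
  # per-detection accuracy against the identity's true category
  per_frame <- icu_categories()[max.col(as.matrix(
    det[c("p_patient", "p_clinician", "p_visitor")]), ties.method = "first")]
  det_acc <- mean(per_frame == gt$category)
  res <- track_count(det)
  trj <- tidy(res)
  # join trajectories to identities by start frame; a track that splits
  # mid-visit (appearance/IoU both missing for one frame) starts off-schedule
  # and is not attributable, so only visit-initial trajectories are scored
  truth_by_entry <- setNames(as.character(sched$category), sched$entry_frame)
  long <- trj[trj$n_entries >= 15 &
                trj$start_frame %in% sched$entry_frame, ]
  expect_gte(nrow(long), 100)
  trj_acc <- mean(long$category == truth_by_entry[as.character(long$start_frame)])
  expect_gt(det_acc, 0.6)
  expect_lt(det_acc, 0.8)
  expect_gt(trj_acc, det_acc)
})
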