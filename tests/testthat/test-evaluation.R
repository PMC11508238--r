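truth_one <- tibble::tibble(frame = 0L, identity = 1L, category = "clinician",
                            cx = 50, cy = 50, w = 20, h = 40)

test_that("average precision handles the canonical small cases", {
  det_hit <- make_det(frame = 0, cx = 50, cy = 50, w = 20, h = 40,
                      category = "clinician", confidence = 0.9, n_frames = 1)
  expect_equal(average_precision(det_hit, truth_one), 1)

  none <- make_det(integer(0), numeric(0), numeric(0), n_frames = 1)
  expect_equal(average_precision(none, truth_one), 0)
  expect_true(is.na(average_precision(none, truth_one[0, ])))
  expect_equal(average_precision(det_hit, truth_one[0, ]), 0)

  # two truths, one perfect detection: precision 1 up to recall 0.5
  truth_two <- dplyr::bind_rows(
    truth_one, dplyr::mutate(truth_one, identity = 2L, cx = 200))
  expect_equal(average_precision(det_hit, truth_two), 51 / 101)
})

test_that("the 101-point AP equals the staircase-enumeration oracle", {
  for (seed in 1:100) {
    inst <- random_ap_instance(seed)
    for (thr in c(0.5, 0.75)) {
      expect_equal(
        average_precision(inst$det, inst$truth, iou_threshold = thr),
        ap_oracle(inst$det, inst$truth, thr),
        tolerance = 1e-12,
        label = sprintf("seed %d thr %.2f", seed, thr)
      )
    }
  }
})

test_that("AP is monotone non-increasing in the IoU threshold", {
  for (seed in 101:120) {
    inst <- random_ap_instance(seed)
    aps <- vapply(seq(0.5, 0.95, 0.05), function(thr) {
      average_precision(inst$det, inst$truth, iou_threshold = thr)
    }, numeric(1))
    aps <- aps[!is.na(aps)]
    expect_true(all(diff(aps) <= 1e-12), label = sprintf("seed %d", seed))
  }
})

test_that("mAP averages per-threshold APs over the grid and categories", {
  det <- make_det(frame = 0, cx = 50, cy = 50, w = 20, h = 40,
                  category = "clinician", confidence = 0.9, n_frames = 1)
  perfect <- detection_map(det, truth_one)
  expect_equal(perfect$map, 1)

  # detection at IoU exactly 0.6: passes thresholds 0.50, 0.55, 0.60 only
  truth_shift <- dplyr::mutate(truth_one, cx = 50, w = 10, h = 10)
  det_shift <- make_det(frame = 0, cx = 52.5, cy = 50, w = 10, h = 10,
                        category = "clinician", confidence = 0.9, n_frames = 1)
  expect_equal(box_iou(det_shift, truth_shift), 0.6)
  m <- detection_map(det_shift, truth_shift)
  clin <- m$by_category$map[m$by_category$category == "clinician"]
  expect_equal(clin, 3 / 10)
  # definitional consistency: category mAP = mean of its per-threshold APs
  by_thr <- m$by_threshold[m$by_threshold$category == "clinician", ]
  expect_equal(clin, mean(by_thr$ap))
  expect_equal(glance(m)$map, m$map)
})

test_that("counting accuracy rounds half-up and compares frames exactly", {
  truth <- tibble::tibble(frame = 0:2, patient = 1L, clinician = c(1L, 2L, 0L),
                          visitor = 0L)
  exact <- counting_accuracy(truth, truth)
  expect_true(all(exact$accuracy == 100))

  pred <- dplyr::mutate(truth, clinician = c(1, 2, 1))
  acc <- counting_accuracy(pred, truth)
  expect_equal(acc$accuracy[acc$category == "clinician"], 100 * 2 / 3)

  # 0.5 rounds up to 1 (half-up, not banker's rounding)
  expect_equal(round_half_up(0.5), 1)
  expect_equal(round_half_up(1.5), 2)
  half <- dplyr::mutate(truth, clinician = c(0.5, 1.5, 0.4))
  acc2 <- counting_accuracy(half, truth)
  expect_equal(acc2$accuracy[acc2$category == "clinician"], 100)

  expect_error(counting_accuracy(pred[1:2, ], truth), "aligned")
})

test_that("regression errors match hand arithmetic under the zero policy", {
  truth <- tibble::tibble(frame = 0:2, patient = 0L, clinician = c(2L, 0L, 1L),
                          visitor = 0L)
  pred <- dplyr::mutate(truth, clinician = c(1, 0, 1))
  e <- count_errors(pred, truth)
  clin <- e[e$category == "clinician", ]
  expect_equal(clin$mae, 1 / 3)
  expect_equal(clin$mse, 1 / 3)
  expect_equal(clin$rmse, sqrt(1 / 3))
  expect_equal(clin$mre, 0.25) # zero-truth frame skipped: (1/2 + 0)/2
  expect_true(is.na(e$mre[e$category == "patient"])) # all-zero truth

  zero <- count_errors(truth, truth)
  expect_true(all(zero$mae == 0 & zero$mse == 0 & zero$rmse == 0))

  # homogeneity: doubling every error doubles MAE and quadruples MSE
  pred2 <- dplyr::mutate(truth, clinician = clinician - 2 * (clinician - c(1, 0, 1)))
  e2 <- count_errors(pred2, truth)[2, ]
  expect_equal(e2$mae, 2 * clin$mae)
  expect_equal(e2$mse, 4 * clin$mse)
})

test_that("metric identities hold on random count tables", {
  set.seed(60)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    truth <- tibble::tibble(frame = 0:(n - 1),
                            patient = sample(0:1, n, TRUE),
                            clinician = sample(0:3, n, TRUE),
                            visitor = sample(0:2, n, TRUE))
    pred <- dplyr::mutate(truth,
                          clinician = pmax(0, clinician + round(rnorm(n))),
                          visitor = visitor + runif(n, 0, 0.4))
    e <- count_errors(pred, truth)
    a <- counting_accuracy(pred, truth)
    expect_equal(e$rmse^2, e$mse, tolerance = 1e-12)
    expect_true(all(e$mae <= e$rmse + 1e-12))
    # integer-valued predictions: accuracy 100 iff MAE 0
    clin_exact <- a$accuracy[a$category == "clinician"] == 100
    expect_equal(clin_exact, e$mae[e$category == "clinician"] == 0)
  }
})
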