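make_assessments <- function(...) {
  tibble::tibble(...)
}

test_that("misaligned assessments are excluded with a strict boundary", {
  a <- make_assessments(
    assessment_id = c("A", "B", "C"),
    time = 900, offset_min = c(0, 30, 31),
    cam_icu = 0L, cam_icu7 = 0L
  )
  kept <- filter_aligned(a)
  expect_setequal(kept$assessment_id, c("A", "B")) # 30 retained, 31 excluded
})

test_that("a 30-minute window at 5-second segments yields 360 segments", {
  counts <- tibble::tibble(frame = 0:1799, patient = 1L, clinician = 0L,
                           visitor = 0L)
  a <- make_assessments(assessment_id = "A", time = 900, offset_min = 0,
                        cam_icu = 0L, cam_icu7 = 0L)
  s <- segment_presence(counts, a)
  expect_equal(unique(s$n_segments), 360)
  expect_equal(nrow(s), 3)
  expect_equal(length(s$segment_means[[1]]), 360)
})

test_that("presence durations follow the indicator rule", {
  # clinician present (count 1) for frames 0-599 of the 1800-frame window
  counts <- tibble::tibble(
    frame = 0:1799, patient = 1L,
    clinician = c(rep(1L, 600), rep(0L, 1200)), visitor = 0L
  )
  a <- make_assessments(assessment_id = "A", time = 900, offset_min = 0,
                        cam_icu = 0L, cam_icu7 = 0L)
  s <- segment_presence(counts, a)
  expect_equal(s$duration_min[s$category == "clinician"], 10) # 120 segments
  expect_equal(s$duration_min[s$category == "patient"], 30)   # full window
  expect_equal(s$duration_min[s$category == "visitor"], 0)    # absent
  expect_true(all(s$n_present_segments * 5 <= 30 * 60))
  expect_true(all(s$coverage == 1))
})

test_that("person-time durations integrate the segment means", {
  counts <- tibble::tibble(frame = 0:1799, patient = 1L, clinician = 2L,
                           visitor = 0L)
  a <- make_assessments(assessment_id = "A", time = 900, offset_min = 0,
                        cam_icu = 0L, cam_icu7 = 0L)
  s <- segment_presence(counts, a, method = "person_time")
  # two clinicians for the whole window: 60 person-minutes
  expect_equal(s$duration_min[s$category == "clinician"], 60)
})

test_that("durations are invariant to frame order within a segment", {
  base <- c(1L, 1L, 1L, 0L, 0L) # segment mean 0.6 -> present
  counts1 <- tibble::tibble(frame = 0:1799, patient = 1L,
                            clinician = rep(base, 360), visitor = 0L)
  counts2 <- counts1
  counts2$clinician <- rep(rev(base), 360) # reordered within each segment
  a <- make_assessments(assessment_id = "A", time = 900, offset_min = 0,
                        cam_icu = 0L, cam_icu7 = 0L)
  s1 <- segment_presence(counts1, a)
  s2 <- segment_presence(counts2, a)
  expect_equal(s1$duration_min, s2$duration_min)
  expect_equal(s1$duration_min[s1$category == "clinician"], 30)
})

test_that("partial coverage is flagged and out-of-range windows error", {
  counts <- tibble::tibble(frame = 0:999, patient = 1L, clinician = 1L,
                           visitor = 0L)
  a <- make_assessments(assessment_id = "A", time = 500, offset_min = 0,
                        cam_icu = 0L, cam_icu7 = 0L)
  s <- segment_presence(counts, a) # window -400..1399, frames < 0 missing
  expect_lt(s$coverage[1], 1)
  far <- make_assessments(assessment_id = "B", time = 99999, offset_min = 0,
                          cam_icu = 0L, cam_icu7 = 0L)
  expect_error(segment_presence(counts, far), "outside")
})

test_that("group means aggregate durations per delirium label", {
  counts10 <- tibble::tibble(frame = 0:1799, patient = 1L,
                             clinician = c(rep(1L, 600), rep(0L, 1200)),
                             visitor = 0L)
  counts20 <- tibble::tibble(frame = 0:1799, patient = 1L,
                             clinician = c(rep(1L, 1200), rep(0L, 600)),
                             visitor = 0L)
  a <- make_assessments(
    assessment_id = c("neg", "pos"), time = 900, offset_min = 0,
    cam_icu = c(0L, 1L), cam_icu7 = c(0L, 4L)
  )
  s <- dplyr::bind_rows(
    segment_presence(counts10, a[1, ]),
    segment_presence(counts20, a[2, ])
  )
  g <- group_durations(s, a, "cam_icu_binary")
  clin <- g[g$category == "clinician", ]
  expect_equal(clin$mean_duration_min[clin$group == "cam_icu_negative"], 10)
  expect_equal(clin$mean_duration_min[clin$group == "cam_icu_positive"], 20)

  g7 <- group_durations(s, a, "cam_icu7_buckets")
  clin7 <- g7[g7$category == "clinician", ]
  expect_equal(clin7$mean_duration_min[clin7$group == "camicu7_0"], 10)
  expect_equal(clin7$mean_duration_min[clin7$group == "camicu7_3_7"], 20)
  # empty bucket reported missing with n = 0
  expect_equal(clin7$n[clin7$group == "camicu7_1_2"], 0)
  expect_true(is.na(clin7$mean_duration_min[clin7$group == "camicu7_1_2"]))
})

test_that("group means equal a hand-computed average on a 5-window fixture", {
  durations <- c(5, 10, 15, 20, 25)
  a <- make_assessments(
    assessment_id = paste0("W", 1:5), time = 900, offset_min = 0,
    cam_icu = c(0L, 0L, 0L, 1L, 1L), cam_icu7 = c(0L, 0L, 0L, 4L, 6L)
  )
  s <- purrr::map_dfr(1:5, function(i) {
    counts <- tibble::tibble(
      frame = 0:1799, patient = 1L,
      clinician = c(rep(1L, durations[i] * 60), rep(0L, 1800 - durations[i] * 60)),
      visitor = 0L
    )
    segment_presence(counts, a[i, ])
  })
  g <- group_durations(s, a, "cam_icu_binary")
  clin <- g[g$category == "clinician", ]
  expect_equal(clin$mean_duration_min[clin$group == "cam_icu_negative"],
               mean(c(5, 10, 15)))
  expect_equal(clin$mean_duration_min[clin$group == "cam_icu_positive"],
               mean(c(20, 25)))
  expect_equal(clin$n, c(3L, 2L))
})
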