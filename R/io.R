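#' Detection and ground-truth tables
#'
#' Detections live in a tibble with one row per detected box: `frame`
#' (0-based index of the 1 frame-per-second stream), center-form box columns
#' `cx`, `cy`, `w`, `h`, the class-probability columns `p_patient`,
#' `p_clinician`, `p_visitor` (nonnegative, summing to 1), `confidence` in
#' \[0, 1\], and `appearance`, a list-column of unit-norm re-identification
#' feature vectors. Ground truth uses `frame`, `identity`, `category`, and
#' the box columns. Sequence metadata (`n_frames`, `fps`, `frame_width`,
#' `frame_height`) is carried as attributes so that frames with zero
#' detections are preserved; every consumer also accepts an explicit
#' `n_frames` argument.
#'
#' `validate_detections()` checks the invariants and names the offending row
#' in its error message.
#'
#' @param det Detections tibble.
#' @param tol Tolerance for the probability-sum and unit-norm invariants.
#' @return `det`, invisibly, if valid.
#' @export
validate_detections <- function(det, tol = 1e-9) {
  needed <- c("frame", "cx", "cy", "w", "h", PROB_COLS, "confidence", "appearance")
  missing <- setdiff(needed, names(det))
  if (length(missing)) {
    abort(paste0("Detections are missing column(s): ", paste(missing, collapse = ", ")))
  }
  bad_record <- function(i, what) {
    abort(sprintf("Invalid detection record %d (frame %d): %s", i, det$frame[i], what))
  }
  psum <- det$p_patient + det$p_clinician + det$p_visitor
  i <- which(abs(psum - 1) > tol | det$p_patient < 0 | det$p_clinician < 0 | det$p_visitor < 0)
  if (length(i)) bad_record(i[1], sprintf("class_probs sum to %.6g, not 1", psum[i[1]]))
  i <- which(det$w <= 0 | det$h <= 0)
  if (length(i)) bad_record(i[1], "nonpositive box width/height")
  i <- which(det$confidence < 0 | det$confidence > 1)
  if (length(i)) bad_record(i[1], "confidence outside [0, 1]")
  norms <- vapply(det$appearance, function(a) sqrt(sum(a^2)), numeric(1))
  i <- which(abs(norms - 1) > sqrt(tol))
  if (length(i)) bad_record(i[1], "appearance vector is not unit norm")
  invisible(det)
}

seq_attrs <- function(x, n_frames = NULL, fps = NULL) {
  list(
    n_frames = n_frames %||% attr(x, "n_frames") %||%
      (if (nrow(x)) max(x$frame) + 1L else 0L),
    fps = fps %||% attr(x, "fps") %||% 1,
    frame_width = attr(x, "frame_width") %||% 1392,
    frame_height = attr(x, "frame_height") %||% 1044
  )
}

set_seq_attrs <- function(x, meta) {
  attr(x, "n_frames") <- as.integer(meta$n_frames)
  attr(x, "fps") <- meta$fps
  attr(x, "frame_width") <- meta$frame_width
  attr(x, "frame_height") <- meta$frame_height
  x
}

#' Read and write detection sequences
#'
#' Two interchange dialects are supported. `"coco-json"` is COCO-style JSON:
#' `images[]` carry `id`, `frame_index`, `width`, `height`, `timestamp`;
#' `annotations[]` carry the COCO top-left `bbox = [x, y, w, h]` (converted to
#' center form on load) plus the extensions `class_probs`, `confidence` (as
#' `score`) and `appearance`. `"csv"` is a flat table with the tibble's
#' columns and the appearance vector packed as a `|`-separated string.
#' Frames with zero detections are preserved in both dialects. Loaded
#' sequences are validated; a violating record raises an error naming the
#' frame and record index.
#'
#' @param det Detections tibble (see [validate_detections()]).
#' @param path File path.
#' @param format `"coco-json"` or `"csv"`; guessed from the extension when
#'   omitted.
#' @param n_frames,fps Sequence metadata; defaults are taken from `det`'s
#'   attributes.
#' @return `read_detections()` returns the detections tibble, frames sorted
#'   by index, with sequence attributes set.
#' @export
write_detections <- function(det, path, format = NULL,
                             n_frames = NULL, fps = NULL) {
  format <- format %||% guess_format(path)
  meta <- seq_attrs(det, n_frames, fps)
  validate_detections(det)
  if (format == "csv") {
    flat <- det %>%
      mutate(appearance = vapply(.data$appearance, paste_nums, character(1)))
    readr::write_csv(flat, path)
    meta_path <- paste0(path, ".meta.json")
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
    return(invisible(path))
  }
  corners <- if (nrow(det)) box_to_corners(det) else
    tibble(x1 = numeric(0), y1 = numeric(0))
  images <- lapply(seq_len(meta$n_frames), function(i) {
    f <- i - 1L
    list(id = i, frame_index = f, width = meta$frame_width,
         height = meta$frame_height, timestamp = f / meta$fps)
  })
  annotations <- lapply(seq_len(nrow(det)), function(i) {
    list(
      id = i,
      image_id = det$frame[i] + 1L,
      bbox = c(corners$x1[i], corners$y1[i], det$w[i], det$h[i]),
      score = det$confidence[i],
      class_probs = c(det$p_patient[i], det$p_clinician[i], det$p_visitor[i]),
      appearance = det$appearance[[i]]
    )
  })
  out <- list(
    info = list(fps = meta$fps, n_frames = meta$n_frames),
    images = images,
    annotations = annotations,
    categories = lapply(seq_along(ICU_CATEGORIES), function(i) {
      list(id = i, name = ICU_CATEGORIES[i])
    })
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_detections
#' @export
read_detections <- function(path, format = NULL) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  format <- format %||% guess_format(path)
  if (format == "csv") {
    flat <- readr::read_csv(path, show_col_types = FALSE, col_types = readr::cols(
      frame = readr::col_integer(), appearance = readr::col_character(),
      .default = readr::col_double()
    ))
    det <- flat %>%
      mutate(appearance = lapply(strsplit(as.character(.data$appearance), "|",
                                          fixed = TRUE), as.numeric))
    meta_path <- paste0(path, ".meta.json")
    meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path) else
      seq_attrs(det)
    det <- arrange(as_tibble(det), .data$frame)
    det <- set_seq_attrs(det, meta)
    validate_detections(det)
    return(det)
  }
  raw <- jsonlite::read_json(path)
  ann <- raw$annotations
  det <- if (length(ann)) {
    bbox <- t(vapply(ann, function(a) as.numeric(unlist(a$bbox)), numeric(4)))
    probs <- t(vapply(ann, function(a) as.numeric(unlist(a$class_probs)), numeric(3)))
    tibble(
      frame = vapply(ann, function(a) as.integer(a$image_id), integer(1)) - 1L,
      cx = bbox[, 1] + bbox[, 3] / 2,
      cy = bbox[, 2] + bbox[, 4] / 2,
      w = bbox[, 3],
      h = bbox[, 4],
      p_patient = probs[, 1],
      p_clinician = probs[, 2],
      p_visitor = probs[, 3],
      confidence = vapply(ann, function(a) as.numeric(a$score), numeric(1)),
      appearance = lapply(ann, function(a) as.numeric(unlist(a$appearance)))
    )
  } else empty_detections()
  det <- arrange(det, .data$frame)
  det <- set_seq_attrs(det, list(
    n_frames = raw$info$n_frames %||% length(raw$images),
    fps = raw$info$fps %||% 1,
    frame_width = if (length(raw$images)) raw$images[[1]]$width else 1392,
    frame_height = if (length(raw$images)) raw$images[[1]]$height else 1044
  ))
  validate_detections(det)
  det
}

empty_detections <- function() {
  tibble(
    frame = integer(0), cx = numeric(0), cy = numeric(0),
    w = numeric(0), h = numeric(0),
    p_patient = numeric(0), p_clinician = numeric(0), p_visitor = numeric(0),
    confidence = numeric(0), appearance = list()
  )
}

#' Read and write ground-truth annotation sequences
#'
#' Same COCO-style dialect as [write_detections()], with per-annotation
#' `identity` and `category_id` extensions instead of scores and class
#' probabilities. The per-identity base appearance embeddings (when present,
#' i.e. for simulator output) are stored under an `identities` extension so
#' the round trip is lossless.
#'
#' @param gt Ground-truth tibble: `frame`, `identity`, `category`, `cx`,
#'   `cy`, `w`, `h`; optional `identities` attribute.
#' @inheritParams write_detections
#' @return `read_ground_truth()` returns the ground-truth tibble with
#'   sequence attributes and, when stored, the `identities` attribute.
#' @export
write_ground_truth <- function(gt, path, n_frames = NULL, fps = NULL) {
  meta <- seq_attrs(gt, n_frames, fps)
  corners <- if (nrow(gt)) box_to_corners(gt) else tibble(x1 = numeric(0))
  images <- lapply(seq_len(meta$n_frames), function(i) {
    f <- i - 1L
    list(id = i, frame_index = f, width = meta$frame_width,
         height = meta$frame_height, timestamp = f / meta$fps)
  })
  annotations <- lapply(seq_len(nrow(gt)), function(i) {
    list(
      id = i,
      image_id = gt$frame[i] + 1L,
      bbox = c(corners$x1[i], corners$y1[i], gt$w[i], gt$h[i]),
      category_id = match(gt$category[i], ICU_CATEGORIES),
      identity = gt$identity[i]
    )
  })
  ids <- attr(gt, "identities")
  out <- list(
    info = list(fps = meta$fps, n_frames = meta$n_frames),
    images = images,
    annotations = annotations,
    categories = lapply(seq_along(ICU_CATEGORIES), function(i) {
      list(id = i, name = ICU_CATEGORIES[i])
    })
  )
  if (!is.null(ids)) {
    out$identities <- lapply(seq_len(nrow(ids)), function(i) {
      list(identity = ids$identity[i], category = ids$category[i],
           appearance = ids$appearance[[i]])
    })
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  raw <- jsonlite::read_json(path)
  ann <- raw$annotations
  gt <- if (length(ann)) {
    bbox <- t(vapply(ann, function(a) as.numeric(unlist(a$bbox)), numeric(4)))
    tibble(
      frame = vapply(ann, function(a) as.integer(a$image_id), integer(1)) - 1L,
      identity = vapply(ann, function(a) as.integer(a$identity), integer(1)),
      category = ICU_CATEGORIES[
        vapply(ann, function(a) as.integer(a$category_id), integer(1))],
      cx = bbox[, 1] + bbox[, 3] / 2,
      cy = bbox[, 2] + bbox[, 4] / 2,
      w = bbox[, 3],
      h = bbox[, 4]
    )
  } else {
    tibble(frame = integer(0), identity = integer(0), category = character(0),
           cx = numeric(0), cy = numeric(0), w = numeric(0), h = numeric(0))
  }
  gt <- arrange(gt, .data$frame, .data$identity)
  if (anyDuplicated(gt[c("frame", "identity")])) {
    abort("Ground truth has more than one box for an (identity, frame) pair.")
  }
  gt <- set_seq_attrs(gt, list(
    n_frames = raw$info$n_frames %||% length(raw$images),
    fps = raw$info$fps %||% 1,
    frame_width = if (length(raw$images)) raw$images[[1]]$width else 1392,
    frame_height = if (length(raw$images)) raw$images[[1]]$height else 1044
  ))
  if (!is.null(raw$identities)) {
    attr(gt, "identities") <- tibble(
      identity = vapply(raw$identities, function(x) as.integer(x$identity), integer(1)),
      category = vapply(raw$identities, function(x) as.character(x$category), character(1)),
      appearance = lapply(raw$identities, function(x) as.numeric(unlist(x$appearance)))
    )
  }
  gt
}

#' Write trajectories in the MOT-Challenge dialect
#'
#' One line per (trajectory, frame):
#' `frame, id, bb_left, bb_top, bb_width, bb_height, conf, category_index,
#' -1, -1`, with top-left coordinates converted from the stored center form
#' and lines sorted by frame then id. Unlike classic headerless MOT files a
#' header row is written, so an empty trajectory set still produces a
#' non-empty, self-describing file.
#'
#' @param trajectories An `icu_trajectories` object from [track_count()], or
#'   the tibble returned by its `tidy()` method with per-entry rows.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  entries <- trajectory_entries(trajectories)
  out <- entries %>%
    mutate(
      bb_left = .data$cx - .data$w / 2,
      bb_top = .data$cy - .data$h / 2,
      category_index = match(.data$category, ICU_CATEGORIES) - 1L,
      x = -1L, y = -1L
    ) %>%
    select("frame", "id", "bb_left", "bb_top",
           bb_width = "w", bb_height = "h",
           conf = "confidence", "category_index", "x", "y") %>%
    arrange(.data$frame, .data$id)
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write per-frame count tables
#'
#' Counts are a tibble with columns `frame`, `patient`, `clinician`,
#' `visitor`, one row per frame.
#'
#' @param counts Count tibble.
#' @param path CSV file path.
#' @return `read_counts()` returns the count tibble sorted by frame.
#' @export
write_counts <- function(counts, path) {
  readr::write_csv(counts, path)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  arrange(readr::read_csv(path, show_col_types = FALSE), .data$frame)
}

#' Read delirium assessment tables
#'
#' Expected CSV columns: `assessment_id`, `time` (seconds since stream
#' start), `offset_min` (absolute clock discrepancy between the assessment
#' record and the camera, minutes), `cam_icu` (0/1 delirium screen) and
#' `cam_icu7` (0-7 severity score).
#'
#' @param path CSV file path.
#' @return Tibble of assessments.
#' @export
read_assessments <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  a <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("assessment_id", "time", "offset_min", "cam_icu", "cam_icu7")
  missing <- setdiff(needed, names(a))
  if (length(missing)) {
    abort(paste0("Assessments are missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(a$cam_icu7 < 0 | a$cam_icu7 > 7)) {
    abort("cam_icu7 scores must lie in [0, 7].")
  }
  a
}

guess_format <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "coco-json"
}

paste_nums <- function(x) paste(format(x, digits = 17, trim = TRUE, scientific = FALSE), collapse = "|")
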