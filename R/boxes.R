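#' Bounding-box geometry
#'
#' Boxes are stored center-based: `cx`, `cy` give the box center in pixels
#' (origin top-left, y increasing downward) and `w`, `h` its width and height.
#' `box_to_corners()` converts to corner form `(x1, y1, x2, y2)` and
#' `corners_to_box()` inverts it exactly. Both are vectorised over rows.
#'
#' @param box Data frame with columns `cx`, `cy`, `w`, `h` (or a named
#'   numeric vector with those elements).
#' @param corners Data frame with columns `x1`, `y1`, `x2`, `y2`.
#' @return A tibble of the converted coordinates, one row per box.
#' @export
#' @examples
#' box_to_corners(tibble::tibble(cx = 5, cy = 3, w = 4, h = 2))
box_to_corners <- function(box) {
  box <- as_box_df(box)
  if (any(box$w <= 0 | box$h <= 0)) {
    abort("Boxes must have positive width and height.")
  }
  tibble(
    x1 = box$cx - box$w / 2,
    y1 = box$cy - box$h / 2,
    x2 = box$cx + box$w / 2,
    y2 = box$cy + box$h / 2
  )
}

#' @rdname box_to_corners
#' @export
corners_to_box <- function(corners) {
  corners <- as.data.frame(corners)
  tibble(
    cx = (corners$x1 + corners$x2) / 2,
    cy = (corners$y1 + corners$y2) / 2,
    w = corners$x2 - corners$x1,
    h = corners$y2 - corners$y1
  )
}

as_box_df <- function(box) {
  if (is.numeric(box) && !is.null(names(box))) {
    box <- as.data.frame(as.list(box))
  }
  box <- as.data.frame(box)
  missing <- setdiff(c("cx", "cy", "w", "h"), names(box))
  if (length(missing)) {
    abort(paste0("Box is missing column(s): ", paste(missing, collapse = ", ")))
  }
  box
}

#' Intersection over union of bounding boxes
#'
#' `box_iou()` computes the IoU of paired boxes (rows of `a` against rows of
#' `b`, recycled if one has a single row). `box_iou_matrix()` computes the
#' full cross matrix, rows of `a` by rows of `b`. Disjoint boxes score 0.
#'
#' @param a,b Data frames of center-form boxes (`cx`, `cy`, `w`, `h`).
#' @return `box_iou()`: numeric vector in \[0, 1\]. `box_iou_matrix()`:
#'   an `nrow(a)` by `nrow(b)` matrix.
#' @export
#' @examples
#' a <- tibble::tibble(cx = 1, cy = 1, w = 2, h = 2)
#' b <- tibble::tibble(cx = 2, cy = 2, w = 2, h = 2)
#' box_iou(a, b) # 1/7
box_iou <- function(a, b) {
  ca <- box_to_corners(a)
  cb <- box_to_corners(b)
  n <- max(nrow(ca), nrow(cb))
  if (nrow(ca) == 1 && n > 1) ca <- ca[rep(1, n), ]
  if (nrow(cb) == 1 && n > 1) cb <- cb[rep(1, n), ]
  iw <- pmax(0, pmin(ca$x2, cb$x2) - pmax(ca$x1, cb$x1))
  ih <- pmax(0, pmin(ca$y2, cb$y2) - pmax(ca$y1, cb$y1))
  inter <- iw * ih
  area_a <- (ca$x2 - ca$x1) * (ca$y2 - ca$y1)
  area_b <- (cb$x2 - cb$x1) * (cb$y2 - cb$y1)
  inter / (area_a + area_b - inter)
}

#' @rdname box_iou
#' @export
box_iou_matrix <- function(a, b) {
  ca <- box_to_corners(a)
  cb <- box_to_corners(b)
  na <- nrow(ca)
  nb <- nrow(cb)
  if (na == 0 || nb == 0) return(matrix(numeric(0), nrow = na, ncol = nb))
  iw <- pmax(0, outer(ca$x2, cb$x2, pmin) - outer(ca$x1, cb$x1, pmax))
  ih <- pmax(0, outer(ca$y2, cb$y2, pmin) - outer(ca$y1, cb$y1, pmax))
  inter <- iw * ih
  area_a <- (ca$x2 - ca$x1) * (ca$y2 - ca$y1)
  area_b <- (cb$x2 - cb$x1) * (cb$y2 - cb$y1)
  inter / (outer(area_a, area_b, `+`) - inter)
}
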