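#' Reference dataset characterization
#'
#' Printed characteristics of the ICU room-monitoring study dataset that
#' motivates this pipeline, shipped as a small JSON file: per-category
#' annotation counts, the cleaned image count and train fraction, and the
#' delirium-assessment subgroup sizes after the clock-misalignment
#' exclusion. The package's desk-scale arithmetic checks (annotation totals,
#' split sizes, assessment totals) are computed from these inputs.
#'
#' @return A list with elements `annotations` (named counts per category),
#'   `images_cleaned`, `train_fraction`, and `assessments` (named subgroup
#'   sizes).
#' @export
#' @examples
#' s <- dataset_summary()
#' sum(unlist(s$annotations))
dataset_summary <- function() {
  path <- system.file("extdata", "dataset_summary.json", package = "icucount")
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Train/test split sizes
#'
#' Deterministic split arithmetic: the training set takes
#' `floor(n_images * train_fraction)` images and the test set the remainder.
#'
#' @param n_images Total number of images.
#' @param train_fraction Fraction allocated to training (default 0.8).
#' @return Named integer vector `c(train = ..., test = ...)`.
#' @export
#' @examples
#' split_sizes(2130)
split_sizes <- function(n_images, train_fraction = 0.8) {
  train <- as.integer(floor(n_images * train_fraction))
  c(train = train, test = as.integer(n_images) - train)
}
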