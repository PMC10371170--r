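#' Relative vector-field error
#'
#' \deqn{Error_{total} = \| E_{test} - E_{ref} \| / \| E_{ref} \|,} with the
#' 2-norm taken over all stacked vector components and the reference field
#' in the denominator.
#'
#' @param e_test,e_ref n x 3 matrices (or `field_result`s) of equal size.
#' @return non-negative scalar (dimensionless; multiply by 100 for %).
#' @export
error_total <- function(e_test, e_ref) {
  m <- metric_mats(e_test, e_ref)
  den <- sqrt(sum(m$ref^2))
  if (den == 0) stop("reference field has zero norm")
  sqrt(sum((m$test - m$ref)^2)) / den
}

#' Relative field-magnitude error
#'
#' \deqn{Error_{mag} = \| |E_{test}| - |E_{ref}| \| / \| |E_{ref}| \|,} the
#' 2-norm over per-point magnitudes. Never exceeds [error_total()] (reverse
#' triangle inequality per point).
#'
#' @inheritParams error_total
#' @return non-negative scalar.
#' @export
error_mag <- function(e_test, e_ref) {
  m <- metric_mats(e_test, e_ref)
  mt <- sqrt(rowSums(m$test^2))
  mr <- sqrt(rowSums(m$ref^2))
  den <- sqrt(sum(mr^2))
  if (den == 0) stop("reference field has zero norm")
  sqrt(sum((mt - mr)^2)) / den
}

metric_mats <- function(e_test, e_ref) {
  if (inherits(e_test, "field_result")) e_test <- e_test$e_total
  if (inherits(e_ref, "field_result")) e_ref <- e_ref$e_total
  e_test <- as.matrix(e_test)
  e_ref <- as.matrix(e_ref)
  if (!all(dim(e_test) == dim(e_ref)) || nrow(e_ref) < 1L)
    stop("fields must be non-empty and of equal size")
  list(test = e_test, ref = e_ref)
}

#' Select points inside a spherical region of interest
#'
#' Boundary-inclusive: points with \eqn{|p - center| \le diameter/2}.
#'
#' @param points n x 3 matrix.
#' @param center ROI center (3-vector, m).
#' @param diameter ROI sphere diameter (m), e.g. 0.04 for the 4 cm ROI
#'   under the coil.
#' @return integer index vector (possibly empty).
#' @export
roi_select <- function(points, center, diameter) {
  if (diameter <= 0) stop("diameter must be > 0")
  points <- rbind3(points)
  d2 <- (points[, 1] - center[1])^2 + (points[, 2] - center[2])^2 +
    (points[, 3] - center[3])^2
  which(d2 <= (diameter / 2)^2)
}

#' Error report between two fields
#'
#' @param e_test,e_ref fields (n x 3 or `field_result`).
#' @param roi optional index subset.
#' @param roi_tag description stored in the report.
#' @return list `error_total`, `error_mag`, `n_points`, `roi`.
#' @export
error_report <- function(e_test, e_ref, roi = NULL, roi_tag = "all points") {
  m <- metric_mats(e_test, e_ref)
  if (!is.null(roi)) {
    if (length(roi) == 0L)
      return(list(error_total = NA_real_, error_mag = NA_real_,
                  n_points = 0L, roi = paste(roi_tag, "(empty)")))
    m$test <- m$test[roi, , drop = FALSE]
    m$ref <- m$ref[roi, , drop = FALSE]
  }
  list(error_total = error_total(m$test, m$ref),
       error_mag = error_mag(m$test, m$ref),
       n_points = nrow(m$ref), roi = roi_tag)
}
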