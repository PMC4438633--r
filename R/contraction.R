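#' Gel silhouette area in pixels
#'
#' Thresholds a gel silhouette photograph, keeps the largest connected
#' foreground component, fills holes, and returns its pixel area. By default
#' the gel is assumed brighter than the background; `polarity = "dark"`
#' inverts the image first.
#'
#' @param image An [ecm_image()] or numeric matrix with one dominant region.
#' @param threshold `"otsu"` or a fixed intensity.
#' @param polarity `"bright"` (gel above threshold, default) or `"dark"`.
#' @return Area of the gel in pixels.
#' @export
gel_area <- function(image, threshold = "otsu", polarity = c("bright", "dark")) {
  polarity <- match.arg(polarity)
  m <- as_pixel_matrix(image)
  if (polarity == "dark") m <- max(m) - m
  th <- resolve_threshold(m, threshold)
  fg <- (m > th$value) * 1
  if (sum(fg) == 0) {
    abort("No gel found above threshold.", class = "ecmquant_no_gel_found")
  }
  lab <- EBImage::bwlabel(EBImage::Image(fg))
  counts <- table(as.vector(lab[lab > 0]))
  keep <- as.integer(names(counts)[which.max(counts)])
  mask <- (as.matrix(EBImage::imageData(lab)) == keep) * 1
  filled <- EBImage::fillHull(EBImage::Image(mask))
  sum(as.matrix(EBImage::imageData(filled)) > 0)
}

#' Percent gel contraction between baseline and follow-up
#'
#' `100 * (1 - followup_area / baseline_area)`: the percentage of gel surface
#' area lost since release. A follow-up larger than baseline (gel swelling)
#' gives a negative value with a warning rather than an error.
#'
#' @param baseline_area,followup_area Positive areas in the same units.
#' @return Percent contraction (may be negative with a warning).
#' @examples
#' percent_contraction(1000, 250)
#' @export
percent_contraction <- function(baseline_area, followup_area) {
  check_positive_scalar(baseline_area, "baseline_area")
  check_positive_scalar(followup_area, "followup_area")
  if (followup_area > baseline_area) {
    warn("Follow-up area exceeds baseline; reporting negative contraction.",
         class = "ecmquant_negative_contraction")
  }
  100 * (1 - followup_area / baseline_area)
}

#' End-to-end contraction measurement from a silhouette pair
#'
#' Measures both silhouette areas with [gel_area()] and reports percent
#' contraction plus the residual area fraction.
#'
#' @param baseline,followup Silhouette images.
#' @param ... Passed to [gel_area()].
#' @return A `contraction_result` tibble (one row): `baseline_area_px`,
#'   `followup_area_px`, `residual_fraction`, `percent_contraction`.
#' @examples
#' gs <- sim_gel_series(image_size_px = 256, initial_radius_px = 90,
#'                      area_contraction_fraction = 0.5)
#' measure_contraction(gs$baseline, gs$followup)
#' @export
measure_contraction <- function(baseline, followup, ...) {
  a0 <- gel_area(baseline, ...)
  a1 <- gel_area(followup, ...)
  out <- tibble(baseline_area_px = a0, followup_area_px = a1,
                residual_fraction = a1 / a0,
                percent_contraction = percent_contraction(a0, a1))
  class(out) <- c("contraction_result", class(out))
  out
}

#' Normalize values to the mean of a control group
#'
#' Divides every value by the mean of the control values, so the control
#' group has mean 1 and other groups are expressed as fold of control.
#'
#' @param values Numeric vector.
#' @param control_values Numeric vector with positive mean.
#' @return `values / mean(control_values)`.
#' @examples
#' normalize_to_control(c(20, 40), c(15, 25))
#' @export
normalize_to_control <- function(values, control_values) {
  if (!length(control_values) || !is.numeric(control_values) ||
      mean(control_values) <= 0) {
    abort("Control values must be numeric with a positive mean.",
          class = "ecmquant_degenerate_control")
  }
  values / mean(control_values)
}
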