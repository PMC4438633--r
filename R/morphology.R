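#' Segment the dominant cell from a single-cell image
#'
#' Thresholds the image (Otsu or fixed), keeps the largest 8-connected
#' foreground component and fills its holes. Intended for one-cell fields
#' (phalloidin-stained cells); binary masks pass through unchanged.
#'
#' @param image An [ecm_image()], numeric matrix, or logical mask.
#' @param threshold `"otsu"` or a fixed numeric value (foreground strictly
#'   above it).
#' @return A logical matrix mask.
#' @export
segment_cell <- function(image, threshold = "otsu") {
  if (is.logical(image)) {
    m <- image * 1
  } else {
    m <- as_pixel_matrix(image)
    th <- resolve_threshold(m, threshold)
    m <- (m > th$value) * 1
  }
  if (sum(m) == 0) {
    abort("No foreground found; cannot segment a cell.",
          class = "ecmquant_no_cell_found")
  }
  lab <- EBImage::bwlabel(EBImage::Image(m))
  counts <- table(as.vector(lab[lab > 0]))
  keep <- as.integer(names(counts)[which.max(counts)])
  mask <- (as.matrix(EBImage::imageData(lab)) == keep) * 1
  filled <- as.matrix(EBImage::imageData(EBImage::fillHull(EBImage::Image(mask))))
  filled > 0
}

# Chain-code boundary perimeter with Vossepoel-Smeulders correction:
# 0.980 per axial step + 1.406 per diagonal step - 0.091 per corner.
# The correction removes the systematic overestimate of raw chain length on
# discretized smooth contours (a raw chain gives ~5% excess on a circle).
mask_perimeter <- function(mask) {
  oc <- EBImage::ocontour(EBImage::Image(mask * 1))
  if (!length(oc)) return(0)
  per <- 0
  for (b in oc) {
    n <- nrow(b)
    if (n < 2) { per <- per + 4; next }
    dif <- b[c(2:n, 1), , drop = FALSE] - b
    step <- sqrt(rowSums(dif^2))
    ne <- sum(abs(step - 1) < 1e-9)
    no <- sum(step > 1.2)
    dirs <- atan2(dif[, 2], dif[, 1])
    ncorner <- sum(abs(diff(c(dirs, dirs[1]))) > 1e-9)
    per <- per + 0.980 * ne + 1.406 * no - 0.091 * ncorner
  }
  per
}

count_components <- function(mask) {
  max(EBImage::bwlabel(EBImage::Image(mask * 1)))
}

#' Roundness shape factor of a cell mask
#'
#' The isoperimetric shape factor `4 * pi * area / perimeter^2`, capped at 1:
#' 1 for a perfect disk (round, non-activated morphology), approaching 0 for
#' elongated or stellate (activated) shapes. The perimeter is the corrected
#' chain-code length of the component boundary.
#'
#' @param mask Logical matrix with a single connected component.
#' @return Roundness in `(0, 1]`.
#' @examples
#' cm <- sim_cell_mask(image_size_px = 128, body_radius_px = 30, n_arms = 0)
#' cell_roundness(cm$mask)
#' @export
cell_roundness <- function(mask) {
  check_single_component(mask)
  A <- sum(mask)
  P <- mask_perimeter(mask)
  min(1, 4 * pi * A / P^2)
}

check_single_component <- function(mask) {
  if (!is.logical(mask) || !is.matrix(mask)) {
    abort("`mask` must be a logical matrix.", class = "ecmquant_invalid_input")
  }
  if (!any(mask)) abort("Empty mask.", class = "ecmquant_invalid_input")
  if (count_components(mask) != 1) {
    abort("Mask must contain exactly one connected component.",
          class = "ecmquant_invalid_input")
  }
  invisible(mask)
}

# Zhang-Suen binary thinning to a 1-px skeleton.
skeletonize <- function(mask) {
  m <- mask * 1L
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0L, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  sh <- function(dy, dx) pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  repeat {
    changed <- FALSE
    for (phase in 1:2) {
      P <- pad[2:(nr + 1), 2:(nc + 1)]
      p2 <- sh(-1, 0); p3 <- sh(-1, 1); p4 <- sh(0, 1); p5 <- sh(1, 1)
      p6 <- sh(1, 0); p7 <- sh(1, -1); p8 <- sh(0, -1); p9 <- sh(-1, -1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      ring <- cbind(as.vector(p2), as.vector(p3), as.vector(p4), as.vector(p5),
                    as.vector(p6), as.vector(p7), as.vector(p8), as.vector(p9))
      A <- matrix(rowSums((ring == 0) & (ring[, c(2:8, 1)] == 1)), nr, nc)
      cond <- if (phase == 1) {
        P == 1 & B >= 2 & B <= 6 & A == 1 & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
      } else {
        P == 1 & B >= 2 & B <= 6 & A == 1 & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
      }
      if (any(cond)) {
        changed <- TRUE
        P[cond] <- 0L
        pad[2:(nr + 1), 2:(nc + 1)] <- P
      }
    }
    if (!changed) break
  }
  pad[2:(nr + 1), 2:(nc + 1)] == 1
}

#' Cell extension lengths from skeleton endpoints
#'
#' Skeletonizes the mask (Zhang-Suen thinning); endpoints are skeleton pixels
#' with exactly one skeleton neighbour. Endpoints inside the cell body
#' (closer to the body center than the body radius) are discarded; each
#' remaining endpoint defines one extension direction, and the extension
#' length is the straight-line distance from the cell center to the farthest
#' mask pixel within a narrow angular cone (`cone_deg`) around that
#' direction — i.e. to the tip of the extension (the skeleton endpoint itself
#' sits about half an arm-width short of the tip, so its distance alone would
#' underestimate the reach).
#'
#' The cell center defaults to the center of the largest inscribed disk
#' (argmax of the distance transform), which coincides with the body center
#' even for cells with asymmetric arms; `center = "centroid"` uses the mask
#' centroid instead. The body radius defaults to the largest inscribed disk
#' radius.
#'
#' @param mask Logical matrix with a single connected component.
#' @param body_radius_px Optional body radius override (pixels).
#' @param center `"inscribed"` (default) or `"centroid"`.
#' @param cone_deg Half-angle (degrees) of the tip-search cone around each
#'   endpoint direction; must be narrower than half the angular spacing of
#'   the extensions.
#' @return Numeric vector of extension lengths in pixels (possibly empty).
#' @examples
#' cm <- sim_cell_mask(image_size_px = 192, n_arms = 3, arm_length_px = 60)
#' extension_lengths(cm$mask)
#' @export
extension_lengths <- function(mask, body_radius_px = NULL,
                              center = c("inscribed", "centroid"),
                              cone_deg = 15) {
  check_single_component(mask)
  center <- match.arg(center)
  sk <- skeletonize(mask)
  if (!any(sk)) return(numeric(0))
  nr <- nrow(sk); nc <- ncol(sk)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- sk
  nb <- matrix(0L, nr, nc)
  for (dy in -1:1) for (dx in -1:1) if (dy != 0 || dx != 0) {
    nb <- nb + pad[(2 + dy):(nr + 1 + dy), (2 + dx):(nc + 1 + dx)]
  }
  ends <- which(sk & nb == 1, arr.ind = TRUE)
  if (!nrow(ends)) return(numeric(0))
  dm <- as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(mask * 1))))
  body_r <- if (is.null(body_radius_px)) max(dm) else body_radius_px
  cen <- if (center == "inscribed") {
    as.numeric(which(dm == max(dm), arr.ind = TRUE)[1, ])
  } else {
    colMeans(which(mask, arr.ind = TRUE))
  }
  px <- which(mask, arr.ind = TRUE)
  pang <- atan2(px[, 1] - cen[1], px[, 2] - cen[2])
  pdist <- sqrt((px[, 1] - cen[1])^2 + (px[, 2] - cen[2])^2)
  out <- numeric(0)
  for (i in seq_len(nrow(ends))) {
    d <- sqrt(sum((ends[i, ] - cen)^2))
    if (d <= body_r) next
    ea <- atan2(ends[i, 1] - cen[1], ends[i, 2] - cen[2])
    in_cone <- abs(((pang - ea + pi) %% (2 * pi)) - pi) <= cone_deg * pi / 180
    out <- c(out, max(pdist[in_cone]))
  }
  out
}

#' Full single-cell morphology measurement
#'
#' Combines segmentation (unless given a mask), roundness, and extension
#' lengths into one tidy row per cell.
#'
#' @param image Image or logical mask of one cell.
#' @param threshold Passed to [segment_cell()] for non-mask input.
#' @param ... Passed to [extension_lengths()].
#' @return A `cell_morphology` tibble (one row): centroid `y`, `x`,
#'   `area_px`, `perimeter_px`, `roundness`, `n_extensions`,
#'   `mean_extension_px`, `max_extension_px`, and a list column
#'   `extension_lengths_px`.
#' @export
cell_morphology <- function(image, threshold = "otsu", ...) {
  mask <- if (is.logical(image) && is.matrix(image)) {
    segment_cell(image)
  } else {
    segment_cell(image, threshold)
  }
  cen <- colMeans(which(mask, arr.ind = TRUE))
  ext <- extension_lengths(mask, ...)
  out <- tibble(
    y = cen[1], x = cen[2],
    area_px = sum(mask),
    perimeter_px = mask_perimeter(mask),
    roundness = cell_roundness(mask),
    n_extensions = length(ext),
    mean_extension_px = if (length(ext)) mean(ext) else 0,
    max_extension_px = if (length(ext)) max(ext) else 0,
    extension_lengths_px = list(ext))
  class(out) <- c("cell_morphology", class(out))
  out
}

#' Marker-positive cell fraction per image and per group
#'
#' Per-image percent positive (`100 * positive / total`) and their unweighted
#' mean across images, the standard way a positive fraction over several
#' random fields is reported.
#'
#' @param counts Data frame with columns `image_id`, `positive`, `total`.
#' @return A `positive_fraction` list: `per_image` tibble
#'   (`image_id`, `positive`, `total`, `percent`), `group_percent`,
#'   `n_images`. Has [tidy()] and [glance()] methods.
#' @examples
#' percent_positive(data.frame(image_id = 1:2, positive = c(10, 30), total = 100))
#' @export
percent_positive <- function(counts) {
  counts <- as_tibble(counts)
  req <- c("image_id", "positive", "total")
  if (!all(req %in% names(counts)) || nrow(counts) == 0) {
    abort("`counts` must have columns image_id, positive, total (>= 1 row).",
          class = "ecmquant_invalid_input")
  }
  if (any(counts$total <= 0)) {
    abort("`total` must be positive for every image.", class = "ecmquant_invalid_count")
  }
  if (any(counts$positive < 0) || any(counts$positive > counts$total)) {
    abort("`positive` must lie in [0, total] for every image.",
          class = "ecmquant_invalid_count")
  }
  per <- dplyr::mutate(counts, percent = 100 * .data$positive / .data$total)
  structure(list(per_image = per,
                 group_percent = mean(per$percent),
                 n_images = nrow(per)),
            class = "positive_fraction")
}

#' @export
print.positive_fraction <- function(x, ...) {
  cat(sprintf("<positive_fraction> %d images, group mean %.1f%% positive\n",
              x$n_images, x$group_percent))
  invisible(x)
}

#' @rdname percent_positive
#' @param x A `positive_fraction`.
#' @param ... Unused.
#' @export
tidy.positive_fraction <- function(x, ...) x$per_image

#' @rdname percent_positive
#' @export
glance.positive_fraction <- function(x, ...) {
  tibble(group_percent = x$group_percent, n_images = x$n_images)
}

#' Plot a cell mask with its skeleton-derived extensions
#'
#' @param object A logical cell mask.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_cell_mask <- function(object, ...) {
  df <- as.data.frame(which(object, arr.ind = TRUE))
  names(df) <- c("y", "x")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(fill = "grey30") +
    ggplot2::coord_fixed() +
    ggplot2::scale_y_reverse() +
    ggplot2::theme_minimal()
}
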