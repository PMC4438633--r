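#' Single-channel 2D image with physical pixel size
#'
#' Light wrapper around a numeric matrix that records the physical pixel size
#' in micrometres. All image-consuming functions in ecmquant accept either an
#' `ecm_image` or a plain matrix (assumed 1 um/px).
#'
#' @param pixels Numeric matrix of non-negative, finite intensities
#'   (rows = y, columns = x).
#' @param pixel_size_um Physical size of one pixel, in micrometres.
#' @return An `ecm_image`: the matrix with a `pixel_size_um` attribute.
#' @examples
#' img <- ecm_image(matrix(runif(64 * 64), 64), pixel_size_um = 0.5)
#' pixel_size(img)
#' @export
ecm_image <- function(pixels, pixel_size_um = 1) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    abort("`pixels` must be a numeric matrix.", class = "ecmquant_invalid_input")
  }
  if (anyNA(pixels) || any(!is.finite(pixels))) {
    abort("Image intensities must be finite.", class = "ecmquant_invalid_input")
  }
  if (any(pixels < 0)) {
    abort("Image intensities must be non-negative.", class = "ecmquant_invalid_input")
  }
  check_positive_scalar(pixel_size_um, "pixel_size_um")
  structure(pixels, pixel_size_um = pixel_size_um, class = c("ecm_image", class(pixels)))
}

#' 3D image stack with physical voxel size
#'
#' @param voxels Numeric Z x H x W array of non-negative, finite intensities.
#' @param voxel_size_um Length-3 numeric `(z, y, x)` voxel edge lengths in
#'   micrometres.
#' @return An `ecm_stack`: the array with a `voxel_size_um` attribute.
#' @export
ecm_stack <- function(voxels, voxel_size_um = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3) {
    abort("`voxels` must be a Z x H x W array.", class = "ecmquant_invalid_input")
  }
  if (anyNA(voxels) || any(!is.finite(voxels))) {
    abort("Stack intensities must be finite.", class = "ecmquant_invalid_input")
  }
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) != 3 || any(voxel_size_um <= 0)) {
    abort("`voxel_size_um` must be three positive values (z, y, x).",
          class = "ecmquant_invalid_parameter")
  }
  structure(voxels, voxel_size_um = voxel_size_um,
            class = c("ecm_stack", class(voxels)))
}

#' Physical pixel/voxel size of an image object
#'
#' @param x An `ecm_image` or `ecm_stack` (plain arrays default to 1 um).
#' @return Numeric scalar (images) or length-3 vector (stacks), micrometres.
#' @export
pixel_size <- function(x) {
  ps <- attr(x, "pixel_size_um")
  if (!is.null(ps)) return(ps)
  vs <- attr(x, "voxel_size_um")
  if (!is.null(vs)) return(vs)
  if (is.matrix(x)) 1 else c(1, 1, 1)
}

#' @export
print.ecm_image <- function(x, ...) {
  cat(sprintf("<ecm_image> %d x %d px, %.3g um/px, intensity range [%.3g, %.3g]\n",
              nrow(x), ncol(x), attr(x, "pixel_size_um"), min(x), max(x)))
  invisible(x)
}

#' @export
print.ecm_stack <- function(x, ...) {
  d <- dim(x)
  vs <- attr(x, "voxel_size_um")
  cat(sprintf("<ecm_stack> %d x %d x %d (Z,H,W), voxel %.3g x %.3g x %.3g um\n",
              d[1], d[2], d[3], vs[1], vs[2], vs[3]))
  invisible(x)
}

as_pixel_matrix <- function(image, min_dim = 1) {
  m <- unclass(image)
  attr(m, "pixel_size_um") <- NULL
  if (!is.matrix(m)) abort("Expected a 2D image (matrix).", class = "ecmquant_invalid_input")
  if (anyNA(m) || any(!is.finite(m))) {
    abort("Image contains non-finite pixels.", class = "ecmquant_invalid_input")
  }
  if (nrow(m) < min_dim || ncol(m) < min_dim) {
    abort(sprintf("Image must be at least %d x %d.", min_dim, min_dim),
          class = "ecmquant_invalid_input")
  }
  m
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    abort(sprintf("`%s` must be a positive finite scalar.", name),
          class = "ecmquant_invalid_parameter")
  }
  invisible(x)
}

check_nonneg_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0) {
    abort(sprintf("`%s` must be a non-negative finite scalar.", name),
          class = "ecmquant_invalid_parameter")
  }
  invisible(x)
}

# Resolve a threshold spec ("otsu" or a fixed numeric) against data values.
# Returns list(value, method). Otsu is computed by EBImage on a 256-level
# histogram of the rescaled data.
resolve_threshold <- function(x, threshold) {
  if (is.numeric(threshold)) {
    return(list(value = as.numeric(threshold)[1], method = "fixed"))
  }
  if (identical(threshold, "otsu")) {
    rng <- range(x)
    if (diff(rng) == 0) return(list(value = rng[1], method = "otsu"))
    scaled <- (x - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1), levels = 256)
    return(list(value = rng[1] + th * diff(rng), method = "otsu"))
  }
  abort("`threshold` must be \"otsu\" or a numeric value.",
        class = "ecmquant_invalid_parameter")
}

# Centered 2D FFT shift: move DC bin to (floor(nr/2)+1, floor(nc/2)+1).
fftshift2 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  m[c((floor(nr / 2) + 1):nr, seq_len(floor(nr / 2))),
    c((floor(nc / 2) + 1):nc, seq_len(floor(nc / 2)))]
}

# Separable Gaussian blur with edge replication.
gaussian_blur2 <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- ceiling(3 * sigma)
  g <- exp(-((-k):k)^2 / (2 * sigma^2))
  g <- g / sum(g)
  conv1 <- function(v) {
    p <- c(rep(v[1], k), v, rep(v[length(v)], k))
    as.numeric(stats::filter(p, g, sides = 2))[(k + 1):(k + length(v))]
  }
  t(apply(t(apply(m, 2, conv1)), 2, conv1))
}

# Circular Gaussian smoothing of a periodic sequence; sd in samples.
circular_gaussian_smooth <- function(v, sd_samples) {
  if (sd_samples <= 0) return(v)
  n <- length(v)
  k <- min(floor((n - 1) / 2), ceiling(3 * sd_samples))
  off <- (-k):k
  g <- exp(-off^2 / (2 * sd_samples^2))
  g <- g / sum(g)
  vapply(seq_len(n), function(i) sum(v[((i - 1 + off) %% n) + 1] * g), numeric(1))
}

# Bilinear interpolation of matrix values at (x = col, y = row) positions;
# positions outside the valid support contribute 0.
bilinear_at <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  v <- numeric(length(x))
  ok <- which(x0 >= 1 & x0 + 1 <= nc & y0 >= 1 & y0 + 1 <= nr)
  if (length(ok)) {
    v[ok] <- m[cbind(y0[ok], x0[ok])] * (1 - fx[ok]) * (1 - fy[ok]) +
      m[cbind(y0[ok], x0[ok] + 1)] * fx[ok] * (1 - fy[ok]) +
      m[cbind(y0[ok] + 1, x0[ok])] * (1 - fx[ok]) * fy[ok] +
      m[cbind(y0[ok] + 1, x0[ok] + 1)] * fx[ok] * fy[ok]
  }
  v
}

# Smallest absolute difference between two axial angles in degrees (mod 180).
axial_diff_deg <- function(a, b) {
  d <- (a - b) %% 180
  pmin(d, 180 - d)
}
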