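#' Read a grayscale TIFF image or stack
#'
#' Single-page TIFFs come back as an [ecm_image()]; multi-page TIFFs as an
#' [ecm_stack()] (pages = z-planes). Stored values are rescaled from the
#' TIFF's `[0, 1]` convention by `max_value`.
#'
#' @param path TIFF file path.
#' @param pixel_size_um Pixel size (scalar) or voxel size (z, y, x).
#' @param max_value Intensity that 1.0 in the file maps to.
#' @return An [ecm_image()] or [ecm_stack()].
#' @export
read_gray_tiff <- function(path, pixel_size_um = 1, max_value = 255) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  to_gray <- function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    p * max_value
  }
  pages <- lapply(pages, to_gray)
  if (length(pages) == 1) {
    ecm_image(pages[[1]], pixel_size_um = pixel_size_um[1])
  } else {
    vox <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (i in seq_along(pages)) vox[i, , ] <- pages[[i]]
    vs <- if (length(pixel_size_um) == 3) pixel_size_um else rep(pixel_size_um[1], 3)
    ecm_stack(vox, voxel_size_um = vs)
  }
}

#' Write a grayscale TIFF image or stack
#'
#' Intensities are clipped to `[0, max_value]` and stored as 16-bit
#' grayscale; an [ecm_stack()] becomes a multi-page TIFF (one page per
#' z-plane).
#'
#' @param x An [ecm_image()], matrix, [ecm_stack()] or 3D array.
#' @param path Output path.
#' @param max_value Intensity mapped to full scale.
#' @return `path`, invisibly.
#' @export
write_gray_tiff <- function(x, path, max_value = 255) {
  clip01 <- function(m) {
    m <- m / max_value
    m[m < 0] <- 0
    m[m > 1] <- 1
    m
  }
  if (is.matrix(x)) {
    tiff::writeTIFF(clip01(unclass(x)), path, bits.per.sample = 16)
  } else if (is.array(x) && length(dim(x)) == 3) {
    pages <- lapply(seq_len(dim(x)[1]), function(z) clip01(unclass(x)[z, , ]))
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else {
    abort("`x` must be a matrix or a Z x H x W array.",
          class = "ecmquant_invalid_input")
  }
  invisible(path)
}

#' Write a generator result with its ground-truth JSON sidecar
#'
#' Saves the image (or stack) as TIFF and the ground truth plus all supplied
#' generator parameters as a JSON sidecar with the same basename.
#'
#' @param sim A generator result (list with `image`/`stack`/`mask` and
#'   `ground_truth`).
#' @param path TIFF output path (`.json` sidecar is derived from it).
#' @param params Optional named list of generator parameters to echo.
#' @param max_value Passed to [write_gray_tiff()].
#' @return Invisibly, a list of the two paths written.
#' @export
write_sim_tiff <- function(sim, path, params = list(), max_value = 255) {
  img <- sim$image %||% sim$stack %||% (if (!is.null(sim$mask)) sim$mask * max_value)
  if (is.null(img)) abort("No image, stack or mask in `sim`.",
                          class = "ecmquant_invalid_input")
  write_gray_tiff(img, path, max_value = max_value)
  sidecar <- sub("\\.tiff?$", ".json", path, ignore.case = TRUE)
  if (identical(sidecar, path)) sidecar <- paste0(path, ".json")
  gt <- sim$ground_truth
  if (inherits(gt, "data.frame")) gt <- as.data.frame(gt)
  jsonlite::write_json(list(ground_truth = gt, params = params), sidecar,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(image = path, sidecar = sidecar))
}

#' Write an angular profile as a two-column CSV
#'
#' @param profile An `angular_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  check_angular_profile(profile)
  utils::write.csv(as.data.frame(profile[, c("angle_deg", "intensity")]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read an angular profile written by [write_profile_csv()]
#'
#' @param path CSV path with columns `angle_deg`, `intensity`.
#' @param normalized Whether the stored curve was control-normalized.
#' @return An `angular_profile`.
#' @export
read_profile_csv <- function(path, normalized = FALSE) {
  df <- utils::read.csv(path)
  if (!all(c("angle_deg", "intensity") %in% names(df))) {
    abort("CSV must have columns angle_deg and intensity.",
          class = "ecmquant_invalid_input")
  }
  step <- if (nrow(df) > 1) df$angle_deg[2] - df$angle_deg[1] else 1
  new_angular_profile(df$angle_deg, df$intensity, step_deg = step,
                      normalized = normalized)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
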