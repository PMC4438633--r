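#' Simulate a collagen fiber field with known orientation ground truth
#'
#' Renders anti-aliased straight fiber segments whose orientations follow an
#' axial von Mises distribution (von Mises on doubled angles, so kappa is the
#' usual circular concentration and `kappa = 0` gives orientations uniform on
#' `[0, 180)`). Segment centers are uniform over the frame; Gaussian read
#' noise is added and intensities clipped at zero. This emulates a confocal
#' reflectance image of a collagen network; there is no optical PSF and no
#' nylon grid.
#'
#' @param image_size_px Side of the square frame in pixels.
#' @param pixel_size_um Pixel size in micrometres.
#' @param n_fibers Number of fiber segments. The default (800) gives a dense
#'   overlapping mesh, as in gel reflectance images.
#' @param mean_angle_deg Mean fiber axis, degrees in `[0, 180)`;
#'   0 = x-axis, increasing counter-clockwise.
#' @param kappa Angular concentration (>= 0); 0 = uniformly random axes.
#' @param fiber_length_px,fiber_width_px Segment geometry in pixels.
#' @param fiber_intensity Peak intensity added by one fiber.
#' @param background_noise_sd SD of additive Gaussian noise.
#' @param seed Integer seed; identical parameters and seed give a
#'   bit-identical image.
#' @return A list with `image` (an [ecm_image()]) and `ground_truth`
#'   (list of `mean_angle_deg`, `kappa`, and the drawn `fiber_angles`).
#' @examples
#' ff <- sim_fiber_field(image_size_px = 64, n_fibers = 50, kappa = 8,
#'                       mean_angle_deg = 30, seed = 1)
#' range(ff$ground_truth$fiber_angles)
#' @export
sim_fiber_field <- function(image_size_px = 256, pixel_size_um = 1,
                            n_fibers = 800, mean_angle_deg = 90, kappa = 0,
                            fiber_length_px = 80, fiber_width_px = 2,
                            fiber_intensity = 100, background_noise_sd = 5,
                            seed = NULL) {
  check_positive_scalar(image_size_px, "image_size_px")
  check_positive_scalar(n_fibers, "n_fibers")
  check_positive_scalar(fiber_length_px, "fiber_length_px")
  check_positive_scalar(fiber_width_px, "fiber_width_px")
  check_positive_scalar(fiber_intensity, "fiber_intensity")
  check_nonneg_scalar(kappa, "kappa")
  check_nonneg_scalar(background_noise_sd, "background_noise_sd")
  if (mean_angle_deg < 0 || mean_angle_deg >= 180) {
    abort("`mean_angle_deg` must lie in [0, 180).", class = "ecmquant_invalid_parameter")
  }
  size <- as.integer(image_size_px)

  draw <- function() {
    angles <- raxial_deg(n_fibers, mean_angle_deg, kappa)
    cx <- runif(n_fibers, 1, size)
    cy <- runif(n_fibers, 1, size)
    img <- matrix(0, size, size)
    half <- fiber_length_px / 2
    for (i in seq_len(n_fibers)) {
      th <- angles[i] * pi / 180
      dx <- cos(th); dy <- sin(th)
      hx <- abs(dx) * half + fiber_width_px + 1
      hy <- abs(dy) * half + fiber_width_px + 1
      x0 <- max(1L, floor(cx[i] - hx)); x1 <- min(size, ceiling(cx[i] + hx))
      y0 <- max(1L, floor(cy[i] - hy)); y1 <- min(size, ceiling(cy[i] + hy))
      if (x0 > x1 || y0 > y1) next
      xs <- x0:x1; ys <- y0:y1
      X <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx[i]
      Y <- matrix(ys, length(ys), length(xs)) - cy[i]
      tpar <- pmax(-half, pmin(half, X * dx + Y * dy))
      d <- sqrt((X - tpar * dx)^2 + (Y - tpar * dy)^2)
      img[ys, xs] <- img[ys, xs] +
        fiber_intensity * pmax(0, pmin(1, fiber_width_px / 2 + 0.5 - d))
    }
    if (background_noise_sd > 0) {
      img <- img + matrix(rnorm(size * size, 0, background_noise_sd), size, size)
    }
    list(image = ecm_image(pmax(img, 0), pixel_size_um),
         ground_truth = list(mean_angle_deg = mean_angle_deg, kappa = kappa,
                             fiber_angles = angles))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a zymography z-stack of non-overlapping fluorescent spots
#'
#' Places solid constant-intensity balls (digestion "green fluorescent
#' objects") on a uniform background, with rejection sampling so that no two
#' spots overlap; the per-object ground truth (voxel membership, volume, mean
#' intensity) is therefore exact.
#'
#' @param stack_shape Integer `(Z, H, W)`.
#' @param voxel_size_um Numeric `(z, y, x)` voxel edges in micrometres.
#' @param n_spots Number of spots (0 allowed).
#' @param spot_radius_px Ball radius in voxels.
#' @param spot_intensity_range `(low, high)`; each spot's added intensity is
#'   drawn uniformly from this range.
#' @param background_level Uniform background intensity.
#' @param max_tries Rejection-sampling retry cap per spot.
#' @param seed Integer seed for reproducible placement.
#' @return A list with `stack` (an [ecm_stack()]) and `ground_truth`, a tibble
#'   with one row per spot (`id`, centroid `z, y, x`, `voxel_count`,
#'   `volume_um3`, `mean_intensity`) carrying the exact per-spot voxel linear
#'   indices in its `voxel_index` attribute.
#' @export
sim_spot_stack <- function(stack_shape = c(16, 128, 128),
                           voxel_size_um = c(1, 1, 1), n_spots = 10,
                           spot_radius_px = 4,
                           spot_intensity_range = c(100, 200),
                           background_level = 10, max_tries = 1000,
                           seed = NULL) {
  stack_shape <- as.integer(stack_shape)
  if (length(stack_shape) != 3 || any(stack_shape < 1)) {
    abort("`stack_shape` must be three positive integers (Z, H, W).",
          class = "ecmquant_invalid_parameter")
  }
  check_nonneg_scalar(n_spots, "n_spots")
  check_positive_scalar(spot_radius_px, "spot_radius_px")
  check_nonneg_scalar(background_level, "background_level")
  if (length(spot_intensity_range) != 2 || any(spot_intensity_range <= 0) ||
      spot_intensity_range[1] > spot_intensity_range[2]) {
    abort("`spot_intensity_range` must be positive (low, high).",
          class = "ecmquant_invalid_parameter")
  }
  Z <- stack_shape[1]; H <- stack_shape[2]; W <- stack_shape[3]
  r <- spot_radius_px
  if (n_spots > 0 && (H < 2 * (r + 1) || W < 2 * (r + 1))) {
    abort(sprintf("Stack footprint %d x %d too small for spots of radius %g.",
                  H, W, r), class = "ecmquant_capacity_error")
  }

  draw <- function() {
    vox <- array(background_level, dim = c(Z, H, W))
    centers <- matrix(numeric(0), 0, 3)
    truth <- vector("list", n_spots)
    vox_idx <- vector("list", n_spots)
    n_spots <- as.integer(n_spots)
    if (n_spots > 0) {
      off <- expand.grid(dz = -floor(r):floor(r), dy = -floor(r):floor(r),
                         dx = -floor(r):floor(r))
      off <- off[off$dz^2 + off$dy^2 + off$dx^2 <= r^2, ]
      for (i in seq_len(n_spots)) {
        placed <- FALSE
        for (try in seq_len(max_tries)) {
          cz <- if (Z - r >= 1 + r) runif(1, 1 + r, Z - r) else (Z + 1) / 2
          cy <- runif(1, 1 + r, H - r)
          cx <- runif(1, 1 + r, W - r)
          if (nrow(centers) == 0 ||
              all(sqrt(rowSums(sweep(centers, 2, c(cz, cy, cx))^2)) > 2 * r + 1)) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          abort(sprintf(
            "Could not place %d non-overlapping spots of radius %g in a %d x %d x %d stack.",
            n_spots, r, Z, H, W), class = "ecmquant_capacity_error")
        }
        czi <- round(cz); cyi <- round(cy); cxi <- round(cx)
        zz <- czi + off$dz; yy <- cyi + off$dy; xx <- cxi + off$dx
        keep <- zz >= 1 & zz <= Z & yy >= 1 & yy <= H & xx >= 1 & xx <= W
        zz <- zz[keep]; yy <- yy[keep]; xx <- xx[keep]
        intensity <- runif(1, spot_intensity_range[1], spot_intensity_range[2])
        lin <- zz + (yy - 1) * Z + (xx - 1) * Z * H
        vox[lin] <- vox[lin] + intensity
        centers <- rbind(centers, c(cz, cy, cx))
        vox_idx[[i]] <- sort(lin)
        truth[[i]] <- tibble(
          id = i, z = mean(zz), y = mean(yy), x = mean(xx),
          voxel_count = length(lin),
          volume_um3 = length(lin) * prod(voxel_size_um),
          mean_intensity = background_level + intensity)
      }
    }
    gt <- if (n_spots > 0) dplyr::bind_rows(truth) else
      tibble(id = integer(), z = numeric(), y = numeric(), x = numeric(),
             voxel_count = integer(), volume_um3 = numeric(),
             mean_intensity = numeric())
    attr(gt, "voxel_index") <- vox_idx
    list(stack = ecm_stack(vox, voxel_size_um), ground_truth = gt)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a single-cell binary mask (round body with radial arms)
#'
#' A disk of `body_radius_px` at the frame center plus `n_arms` rectangular
#' arms at equally spaced angles, each reaching exactly `arm_length_px` from
#' the center. `n_arms = 0` gives the round (non-activated) control; larger
#' arm counts/lengths emulate the stellate morphology of activated
#' myofibroblasts.
#'
#' @param image_size_px Side of the square frame in pixels.
#' @param body_radius_px Cell body radius.
#' @param n_arms Number of arms (0 allowed).
#' @param arm_length_px Distance from cell center to arm tip; must be at least
#'   `body_radius_px` when `n_arms > 0`.
#' @param arm_width_px Arm width.
#' @param arm_angle_offset_deg Orientation of the first arm.
#' @return A list with `mask` (logical matrix) and `ground_truth`
#'   (`arm_length_px`, `n_arms`, `centroid` = frame center `(y, x)`).
#' @export
sim_cell_mask <- function(image_size_px = 256, body_radius_px = 20,
                          n_arms = 4, arm_length_px = 80, arm_width_px = 6,
                          arm_angle_offset_deg = 0) {
  check_positive_scalar(image_size_px, "image_size_px")
  check_positive_scalar(body_radius_px, "body_radius_px")
  check_nonneg_scalar(n_arms, "n_arms")
  if (n_arms > 0) {
    check_positive_scalar(arm_length_px, "arm_length_px")
    check_positive_scalar(arm_width_px, "arm_width_px")
    if (arm_length_px < body_radius_px) {
      abort("`arm_length_px` must be >= `body_radius_px`.",
            class = "ecmquant_invalid_parameter")
    }
  }
  size <- as.integer(image_size_px)
  c0 <- (size + 1) / 2
  reach <- max(body_radius_px, if (n_arms > 0) arm_length_px else 0)
  if (c0 + reach > size) {
    abort("Cell shape exceeds the frame; increase `image_size_px`.",
          class = "ecmquant_invalid_parameter")
  }
  xs <- matrix(seq_len(size), size, size, byrow = TRUE) - c0
  ys <- matrix(seq_len(size), size, size) - c0
  mask <- xs^2 + ys^2 <= body_radius_px^2
  if (n_arms > 0) {
    for (i in seq_len(as.integer(n_arms))) {
      th <- (arm_angle_offset_deg * pi / 180) + (i - 1) * 2 * pi / n_arms
      tpar <- xs * cos(th) + ys * sin(th)
      perp <- -xs * sin(th) + ys * cos(th)
      mask <- mask | (tpar >= 0 & tpar <= arm_length_px & abs(perp) <= arm_width_px / 2)
    }
  }
  list(mask = mask,
       ground_truth = list(arm_length_px = if (n_arms > 0) arm_length_px else NA_real_,
                           n_arms = as.integer(n_arms), centroid = c(y = c0, x = c0)))
}

#' Simulate a baseline/follow-up gel silhouette pair
#'
#' The baseline silhouette is a filled disk; the follow-up disk radius is
#' shrunk so that the disk area is reduced by `area_contraction_fraction`
#' (radius scales with the square root of the remaining area fraction).
#'
#' @param image_size_px Side of the square frame in pixels.
#' @param initial_radius_px Baseline gel radius.
#' @param area_contraction_fraction Fraction of area lost in `[0, 1)`.
#' @param foreground,background Intensities of gel and surround.
#' @return List with `baseline`, `followup` (both [ecm_image()]) and
#'   `ground_truth` (`percent_contraction` = `100 * area_contraction_fraction`).
#' @export
sim_gel_series <- function(image_size_px = 512, initial_radius_px = 180,
                           area_contraction_fraction = 0.5,
                           foreground = 200, background = 20) {
  check_positive_scalar(image_size_px, "image_size_px")
  check_positive_scalar(initial_radius_px, "initial_radius_px")
  if (!is.numeric(area_contraction_fraction) ||
      area_contraction_fraction < 0 || area_contraction_fraction >= 1) {
    abort("`area_contraction_fraction` must lie in [0, 1).",
          class = "ecmquant_invalid_parameter")
  }
  size <- as.integer(image_size_px)
  c0 <- (size + 1) / 2
  if (c0 + initial_radius_px > size) {
    abort("Gel disk exceeds the frame.", class = "ecmquant_invalid_parameter")
  }
  disk <- function(r) {
    xs <- matrix(seq_len(size), size, size, byrow = TRUE) - c0
    ys <- matrix(seq_len(size), size, size) - c0
    ecm_image(ifelse(xs^2 + ys^2 <= r^2, foreground, background))
  }
  r2 <- initial_radius_px * sqrt(1 - area_contraction_fraction)
  list(baseline = disk(initial_radius_px), followup = disk(r2),
       ground_truth = list(percent_contraction = 100 * area_contraction_fraction))
}

#' Simulate per-image positive/total cell counts
#'
#' Draws the number of marker-positive cells per image from
#' `Binomial(nuclei_per_image, p_positive)`, emulating per-image alpha-SMA /
#' DAPI counts.
#'
#' @param n_images Number of images (fields).
#' @param nuclei_per_image Total nuclei per image.
#' @param p_positive True positive probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Tibble with columns `image_id`, `positive`, `total`.
#' @examples
#' sim_count_table(n_images = 4, nuclei_per_image = 50, p_positive = 0.6, seed = 1)
#' @export
sim_count_table <- function(n_images = 8, nuclei_per_image = 100,
                            p_positive = 0.5, seed = NULL) {
  check_positive_scalar(n_images, "n_images")
  check_positive_scalar(nuclei_per_image, "nuclei_per_image")
  if (!is.numeric(p_positive) || p_positive < 0 || p_positive > 1) {
    abort("`p_positive` must lie in [0, 1].", class = "ecmquant_invalid_parameter")
  }
  draw <- function() {
    tibble(image_id = seq_len(as.integer(n_images)),
           positive = rbinom(as.integer(n_images), as.integer(nuclei_per_image),
                             p_positive),
           total = as.integer(nuclei_per_image))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}
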