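# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths for the quantities they check.

# Smallest angular difference between axial angles (degrees, mod 180).
axial_err <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

# Structure-tensor dominant orientation of an image, in degrees on [0, 180).
# Central-difference gradients, box-smoothed tensor entries, dominant
# eigenvector orientation of the mean tensor; returns the orientation of the
# image texture (fiber axis), which is perpendicular to the mean gradient.
structure_tensor_axis <- function(img, blur_sigma = 2) {
  m <- unclass(img)
  if (blur_sigma > 0) {
    m <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(m), sigma = blur_sigma)))
  }
  nr <- nrow(m); nc <- ncol(m)
  gx <- (m[, c(2:nc, nc)] - m[, c(1, 1:(nc - 1))]) / 2
  gy <- (m[c(2:nr, nr), ] - m[c(1, 1:(nr - 1)), ]) / 2
  jxx <- mean(gx * gx); jyy <- mean(gy * gy); jxy <- mean(gx * gy)
  grad_dir <- 0.5 * atan2(2 * jxy, jxx - jyy) * 180 / pi
  (grad_dir + 90) %% 180
}

# Brute-force angular binning of a centered spectrum: every pixel (outside a
# small DC exclusion) is assigned to the 1-degree bin of its polar angle
# (mod 180) and intensities are summed per bin.
polar_bin_profile <- function(spec, r_min = 2, r_max = NULL) {
  m <- unclass(spec)
  nr <- nrow(m); nc <- ncol(m)
  cy <- floor(nr / 2) + 1; cx <- floor(nc / 2) + 1
  if (is.null(r_max)) r_max <- 0.45 * min(nr, nc)
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE) - cx
  ys <- matrix(seq_len(nr), nr, nc) - cy
  r <- sqrt(xs^2 + ys^2)
  keep <- r >= r_min & r <= r_max
  ang <- (atan2(ys[keep], xs[keep]) * 180 / pi) %% 180
  bins <- floor(ang) %% 180
  out <- numeric(180)
  agg <- tapply(m[keep], bins, sum)
  out[as.integer(names(agg)) + 1] <- agg
  out
}

# Brute-force circular trapezoid of a periodic curve sampled at uniform step,
# integrated over [center - w, center + w] with linear interpolation.
circular_trapezoid <- function(values, step_deg, center_deg, window_deg) {
  n <- length(values)
  val_at <- function(a) {
    pos <- (a %% 180) / step_deg
    i0 <- floor(pos) %% n
    fr <- pos - floor(pos)
    values[i0 + 1] * (1 - fr) + values[(i0 + 1) %% n + 1] * fr
  }
  grid <- seq(center_deg - window_deg, center_deg + window_deg, by = step_deg)
  if (grid[length(grid)] < center_deg + window_deg) {
    grid <- c(grid, center_deg + window_deg)
  }
  v <- vapply(grid, val_at, numeric(1))
  sum((v[-1] + v[-length(v)]) / 2 * diff(grid))
}

# Flood-fill 26-connected labelling of a logical 3D mask (queue-based BFS).
flood_fill_3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nextlab <- 0L
  idx <- which(mask)
  for (start in idx) {
    if (lab[start] > 0) next
    nextlab <- nextlab + 1L
    queue <- start
    lab[start] <- nextlab
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      z <- ((cur - 1) %% d[1]) + 1
      y <- (((cur - 1) %/% d[1]) %% d[2]) + 1
      x <- ((cur - 1) %/% (d[1] * d[2])) + 1
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        nz <- z + dz; ny <- y + dy; nx <- x + dx
        if (nz < 1 || nz > d[1] || ny < 1 || ny > d[2] || nx < 1 || nx > d[3]) next
        ni <- nz + (ny - 1) * d[1] + (nx - 1) * d[1] * d[2]
        if (mask[ni] && lab[ni] == 0L) {
          lab[ni] <- nextlab
          queue <- c(queue, ni)
        }
      }
    }
  }
  lab
}

# Brute-force total protease activity from raw voxels and a known object
# labelling: per-object means averaged, times summed object volume, divided
# by total stack volume.
brute_force_activity <- function(vox, labels, voxel_size) {
  ids <- setdiff(unique(as.vector(labels)), 0L)
  if (!length(ids)) return(0)
  means <- vapply(ids, function(i) mean(vox[labels == i]), numeric(1))
  vols <- vapply(ids, function(i) sum(labels == i) * prod(voxel_size), numeric(1))
  mean(means) * sum(vols) / (prod(dim(vox)) * prod(voxel_size))
}

# Fixture: star-shaped mask built independently of sim_cell_mask (polar test).
raster_disk <- function(size, radius, cx = (size + 1) / 2, cy = (size + 1) / 2) {
  xs <- matrix(seq_len(size), size, size, byrow = TRUE)
  ys <- matrix(seq_len(size), size, size)
  (xs - cx)^2 + (ys - cy)^2 <= radius^2
}

# Construct an angular_profile directly from values (1-degree grid default),
# bypassing the spectrum pipeline.
new_angular_profile_for_test <- function(values, step = 1, normalized = FALSE) {
  p <- tibble::tibble(
    angle_deg = seq(0, by = step, length.out = length(values)),
    intensity = values)
  class(p) <- c("angular_profile", class(p))
  attr(p, "step_deg") <- step
  attr(p, "normalized") <- normalized
  p
}

# Strip result subclasses down to a plain tibble (drops custom attributes).
as_tibble_plain <- function(x) {
  tibble::as_tibble(as.data.frame(x))
}
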