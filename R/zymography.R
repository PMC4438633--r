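#' Segment fluorescent objects in a 3D stack
#'
#' Thresholds the stack (Otsu by default, or a fixed value), groups
#' above-threshold voxels by 26-connectivity, discards components smaller
#' than `min_voxels`, and reports one row per retained object: exact voxel
#' count, physical volume, per-object mean intensity, and intensity-weighted
#' centroid. These are the "green fluorescent objects" of an in situ
#' zymography read-out.
#'
#' A fixed threshold above the stack maximum yields an empty table with a
#' warning (nothing fluoresces above it), not an error.
#'
#' @param stack An [ecm_stack()] or Z x H x W array.
#' @param threshold `"otsu"` or a fixed numeric intensity; voxels strictly
#'   above it are foreground.
#' @param min_voxels Minimum component size retained.
#' @param voxel_size_um Voxel edges `(z, y, x)` in micrometres; defaults to
#'   the stack's own.
#' @return A `fluor_objects` tibble with columns `id`, `z`, `y`, `x`
#'   (intensity-weighted centroid), `voxel_count`, `volume_um3`,
#'   `mean_intensity`; attributes `voxel_index` (list of per-object voxel
#'   linear indices), `threshold`, `voxel_size_um` and `stack_dim`.
#' @examples
#' ss <- sim_spot_stack(stack_shape = c(8, 48, 48), n_spots = 3,
#'                      background_level = 0, seed = 1)
#' segment_objects(ss$stack, threshold = 50)
#' @export
segment_objects <- function(stack, threshold = "otsu", min_voxels = 5,
                            voxel_size_um = NULL) {
  if (!is.array(stack) || length(dim(stack)) != 3) {
    abort("`stack` must be a Z x H x W array.", class = "ecmquant_invalid_input")
  }
  check_positive_scalar(min_voxels, "min_voxels")
  if (is.null(voxel_size_um)) voxel_size_um <- pixel_size(stack)
  voxel_size_um <- as.numeric(voxel_size_um)
  if (length(voxel_size_um) == 1) voxel_size_um <- rep(voxel_size_um, 3)
  vox <- unclass(stack)
  attr(vox, "voxel_size_um") <- NULL
  d <- dim(vox)
  th <- resolve_threshold(vox, threshold)
  if (th$method == "fixed" && th$value >= max(vox)) {
    warn("Fixed threshold at or above the stack maximum; no objects found.",
         class = "ecmquant_empty_segmentation")
    return(new_fluor_objects(tibble(
      id = integer(), z = numeric(), y = numeric(), x = numeric(),
      voxel_count = integer(), volume_um3 = numeric(),
      mean_intensity = numeric()), list(), th$value, voxel_size_um, d))
  }
  fg <- which(vox > th$value)
  comp <- label_components_26(fg, d)
  rows <- list()
  vox_idx <- list()
  vol <- prod(voxel_size_um)
  if (length(fg)) {
    Z <- d[1]; H <- d[2]
    zz <- ((fg - 1) %% Z) + 1
    yy <- (((fg - 1) %/% Z) %% H) + 1
    xx <- ((fg - 1) %/% (Z * H)) + 1
    ids <- 0L
    for (grp in split(seq_along(fg), comp)) {
      if (length(grp) < min_voxels) next
      ids <- ids + 1L
      idx <- fg[grp]
      w <- vox[idx]
      rows[[ids]] <- tibble(
        id = ids,
        z = sum(zz[grp] * w) / sum(w),
        y = sum(yy[grp] * w) / sum(w),
        x = sum(xx[grp] * w) / sum(w),
        voxel_count = length(idx),
        volume_um3 = length(idx) * vol,
        mean_intensity = mean(w))
      vox_idx[[ids]] <- sort(idx)
    }
  }
  tab <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(id = integer(), z = numeric(), y = numeric(), x = numeric(),
           voxel_count = integer(), volume_um3 = numeric(),
           mean_intensity = numeric())
  new_fluor_objects(tab, vox_idx, th$value, voxel_size_um, d)
}

new_fluor_objects <- function(tab, vox_idx, threshold, voxel_size_um, stack_dim) {
  class(tab) <- c("fluor_objects", class(tab))
  attr(tab, "voxel_index") <- vox_idx
  attr(tab, "threshold") <- threshold
  attr(tab, "voxel_size_um") <- voxel_size_um
  attr(tab, "stack_dim") <- stack_dim
  tab
}

# 26-connected component labels for foreground voxel linear indices `fg` in a
# Z x H x W array. Builds the neighbour graph over the (sparse) foreground and
# labels its connected components.
label_components_26 <- function(fg, d) {
  if (!length(fg)) return(integer(0))
  Z <- d[1]; H <- d[2]; W <- d[3]
  zz <- ((fg - 1) %% Z) + 1
  yy <- (((fg - 1) %/% Z) %% H) + 1
  xx <- ((fg - 1) %/% (Z * H)) + 1
  offs <- expand.grid(dz = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[offs$dz != 0 | offs$dy != 0 | offs$dx != 0, ]
  # half the offsets suffice; each undirected edge found once
  offs <- offs[offs$dz > 0 | (offs$dz == 0 & (offs$dy > 0 | (offs$dy == 0 & offs$dx > 0))), ]
  edges <- list()
  for (k in seq_len(nrow(offs))) {
    nz <- zz + offs$dz[k]; ny <- yy + offs$dy[k]; nx <- xx + offs$dx[k]
    valid <- nz >= 1 & nz <= Z & ny >= 1 & ny <= H & nx >= 1 & nx <= W
    if (!any(valid)) next
    nidx <- nz[valid] + (ny[valid] - 1) * Z + (nx[valid] - 1) * Z * H
    hit <- match(nidx, fg)
    found <- which(!is.na(hit))
    if (length(found)) {
      edges[[length(edges) + 1]] <- cbind(which(valid)[found], hit[found])
    }
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) {
    em <- do.call(rbind, edges)
    g <- igraph::add_edges(g, t(em))
  }
  igraph::components(g)$membership
}

#' Mean fluorescence intensity across segmented objects
#'
#' Unweighted mean of the per-object mean intensities: each fluorescent
#' object contributes equally regardless of its size. A voxel-weighted
#' variant (`weighted = TRUE`) weights each object by its voxel count, which
#' equals the mean intensity over all object voxels pooled; the two differ
#' whenever bright and dim objects differ in size.
#'
#' @param objects A `fluor_objects` table from [segment_objects()].
#' @param weighted Use voxel-count weighting (default FALSE).
#' @return Mean intensity; 0 for an empty object table.
#' @export
mean_fluorescence_intensity <- function(objects, weighted = FALSE) {
  if (nrow(objects) == 0) return(0)
  if (weighted) {
    sum(objects$mean_intensity * objects$voxel_count) / sum(objects$voxel_count)
  } else {
    mean(objects$mean_intensity)
  }
}

#' Total protease activity of a zymography stack
#'
#' The volume-normalized activity read-out:
#' \deqn{\mathrm{activity} = \mathrm{MFI} \times
#'       \frac{\mathrm{total\ fluorescent\ volume}}{\mathrm{image\ volume}}}
#' where MFI is the mean fluorescence intensity over segmented objects
#' ([mean_fluorescence_intensity()]), the total fluorescent volume is the sum
#' of object volumes, and the image volume is the full physical stack volume.
#'
#' @param objects A `fluor_objects` table from [segment_objects()].
#' @param stack The stack the objects were segmented from (for its dimensions
#'   and voxel size); may be omitted if `objects` carries them.
#' @param weighted_mfi Passed to [mean_fluorescence_intensity()].
#' @return A `protease_activity` list: `mean_fluorescence_intensity`,
#'   `total_volume_um3`, `image_volume_um3`, `total_activity`, `n_objects`.
#'   Has [tidy()] and [glance()] methods.
#' @examples
#' ss <- sim_spot_stack(stack_shape = c(8, 48, 48), n_spots = 3,
#'                      background_level = 0, seed = 1)
#' obj <- segment_objects(ss$stack, threshold = 50)
#' total_protease_activity(obj, ss$stack)
#' @export
total_protease_activity <- function(objects, stack = NULL, weighted_mfi = FALSE) {
  if (is.null(stack)) {
    d <- attr(objects, "stack_dim")
    vs <- attr(objects, "voxel_size_um")
    if (is.null(d) || is.null(vs)) {
      abort("Provide `stack` or a `fluor_objects` table carrying stack metadata.",
            class = "ecmquant_invalid_input")
    }
  } else {
    d <- dim(stack)
    vs <- pixel_size(stack)
  }
  mfi <- mean_fluorescence_intensity(objects, weighted = weighted_mfi)
  total_vol <- sum(objects$volume_um3)
  image_vol <- prod(d) * prod(vs)
  structure(
    list(mean_fluorescence_intensity = mfi,
         total_volume_um3 = total_vol,
         image_volume_um3 = image_vol,
         total_activity = mfi * total_vol / image_vol,
         n_objects = nrow(objects)),
    class = "protease_activity")
}

#' @export
print.protease_activity <- function(x, ...) {
  cat(sprintf("<protease_activity> %d objects, MFI %.3f, volume %.1f / %.1f um^3, total activity %.4f\n",
              x$n_objects, x$mean_fluorescence_intensity, x$total_volume_um3,
              x$image_volume_um3, x$total_activity))
  invisible(x)
}

#' @rdname total_protease_activity
#' @param x A `protease_activity`.
#' @param ... Unused.
#' @export
tidy.protease_activity <- function(x, ...) {
  tibble(mean_fluorescence_intensity = x$mean_fluorescence_intensity,
         total_volume_um3 = x$total_volume_um3,
         image_volume_um3 = x$image_volume_um3,
         total_activity = x$total_activity,
         n_objects = x$n_objects)
}

#' @rdname total_protease_activity
#' @export
glance.protease_activity <- function(x, ...) tidy.protease_activity(x)

#' Combine per-field activity results into a gel-level value
#'
#' Per-field (image) total activities are averaged arithmetically to one
#' gel-level value, mirroring the standard practice of averaging several
#' random fields per gel.
#'
#' @param results A list of `protease_activity` objects.
#' @return A tibble with one row per field plus the attribute-free summary
#'   columns `field` and `total_activity`, and the gel mean as attribute
#'   `gel_mean`; or use `summarize_gel_activity(results)$gel_mean` directly.
#' @export
summarize_gel_activity <- function(results) {
  stopifnot(length(results) > 0)
  tab <- purrr::map_dfr(results, tidy, .id = "field")
  structure(list(per_field = tab, gel_mean = mean(tab$total_activity)),
            class = "gel_activity_summary")
}

#' @export
print.gel_activity_summary <- function(x, ...) {
  cat(sprintf("<gel_activity_summary> %d fields, mean total activity %.4f\n",
              nrow(x$per_field), x$gel_mean))
  invisible(x)
}
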