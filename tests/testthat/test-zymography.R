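test_that("segmentation recovers generator ground truth exactly", {
  ss <- sim_spot_stack(stack_shape = c(12, 64, 64), n_spots = 5,
                      background_level = 0,
                      spot_intensity_range = c(100, 200), seed = 42)
  # threshold at half the minimum spot intensity over zero background
  obj <- segment_objects(ss$stack, threshold = 50)
  expect_equal(nrow(obj), 5)
  gt <- dplyr::arrange(ss$ground_truth, z, y, x)
  ob <- dplyr::arrange(as_tibble_plain(obj), z, y, x)
  expect_identical(ob$voxel_count, gt$voxel_count)
  expect_equal(ob$volume_um3, gt$volume_um3)
  expect_equal(ob$mean_intensity, gt$mean_intensity)
})

test_that("empty stacks and out-of-range thresholds give empty results", {
  ss <- sim_spot_stack(stack_shape = c(6, 48, 48), n_spots = 0,
                       background_level = 3, seed = 1)
  expect_warning(obj <- segment_objects(ss$stack, threshold = 10),
                 class = "ecmquant_empty_segmentation")
  expect_equal(nrow(obj), 0)
  expect_warning(
    obj2 <- segment_objects(
      sim_spot_stack(stack_shape = c(6, 48, 48), n_spots = 2,
                     background_level = 0, seed = 2)$stack,
      threshold = 1e6),
    class = "ecmquant_empty_segmentation")
  expect_equal(nrow(obj2), 0)
  expect_equal(total_protease_activity(obj)$total_activity, 0)
})

test_that("touching spots form one 26-connected component (flood-fill oracle)", {
  vox <- array(0, c(8, 32, 32))
  put_ball <- function(vox, c0, r, val) {
    d <- dim(vox)
    for (z in 1:d[1]) for (y in 1:d[2]) for (x in 1:d[3]) {
      if ((z - c0[1])^2 + (y - c0[2])^2 + (x - c0[3])^2 <= r^2) {
        vox[z, y, x] <- vox[z, y, x] + val
      }
    }
    vox
  }
  vox <- put_ball(vox, c(4, 12, 12), 3, 100)
  vox <- put_ball(vox, c(4, 12, 17), 3, 120)
  obj <- segment_objects(ecm_stack(vox), threshold = 50)
  lab <- flood_fill_3d(vox > 50)
  expect_equal(nrow(obj), max(lab))
  expect_equal(nrow(obj), 1)
  expect_equal(obj$voxel_count, sum(vox > 50))
})

test_that("MFI averages objects equally; weighted variant pools voxels", {
  mk <- function(mi, vc) tibble::tibble(mean_intensity = mi, voxel_count = vc)
  o <- mk(c(100, 200), c(10, 30))
  expect_equal(mean_fluorescence_intensity(o), 150)
  expect_equal(mean_fluorescence_intensity(o, weighted = TRUE),
               (100 * 10 + 200 * 30) / 40)
  expect_equal(mean_fluorescence_intensity(o[0, ]), 0)
  expect_equal(mean_fluorescence_intensity(o[1, ]), 100)
})

test_that("total activity follows the MFI x volume / image volume identity", {
  # direct substitution: MFI 100, object volume 50, image volume 1000 -> 5
  obj <- tibble::tibble(id = 1L, z = 1, y = 1, x = 1, voxel_count = 50L,
                        volume_um3 = 50, mean_intensity = 100)
  stack <- ecm_stack(array(0, c(10, 10, 10)), voxel_size_um = c(1, 1, 1))
  res <- total_protease_activity(obj, stack)
  expect_equal(res$total_activity, 5)
  expect_equal(res$total_activity,
               res$mean_fluorescence_intensity * res$total_volume_um3 /
                 res$image_volume_um3)

  # synthetic stack vs brute-force voxel oracle
  ss <- sim_spot_stack(stack_shape = c(10, 48, 48), n_spots = 4,
                       background_level = 5, voxel_size_um = c(2, 0.5, 0.5),
                       seed = 7)
  obj <- segment_objects(ss$stack, threshold = 55)
  got <- total_protease_activity(obj, ss$stack)
  lab <- flood_fill_3d(unclass(ss$stack) > 55)
  want <- brute_force_activity(unclass(ss$stack), lab, c(2, 0.5, 0.5))
  expect_equal(got$total_activity, want, tolerance = 1e-12)
})

test_that("volume conservation and scaling/dilution properties hold", {
  ss <- sim_spot_stack(stack_shape = c(10, 64, 64), n_spots = 6,
                       background_level = 0, seed = 9)
  vox <- unclass(ss$stack)
  obj <- segment_objects(ss$stack, threshold = 40, min_voxels = 5)
  expect_identical(sum(obj$voxel_count), sum(vox > 40))

  # intensity scaling: c * intensities with c * threshold scales MFI and
  # activity by c, volumes unchanged
  act1 <- total_protease_activity(obj, ss$stack)
  obj3 <- segment_objects(ecm_stack(vox * 3), threshold = 120)
  act3 <- total_protease_activity(obj3, ecm_stack(vox * 3))
  expect_equal(act3$total_volume_um3, act1$total_volume_um3)
  expect_equal(act3$mean_fluorescence_intensity,
               3 * act1$mean_fluorescence_intensity, tolerance = 1e-12)
  expect_equal(act3$total_activity, 3 * act1$total_activity, tolerance = 1e-12)

  # dilution: padding with background voxels strictly decreases activity
  big <- array(0, c(16, 64, 64))
  big[1:10, , ] <- vox
  actbig <- total_protease_activity(segment_objects(ecm_stack(big), threshold = 40),
                                    ecm_stack(big))
  expect_lt(actbig$total_activity, act1$total_activity)
  expect_equal(actbig$total_volume_um3, act1$total_volume_um3)
})

test_that("gel-level summaries average per-field activities", {
  ss <- lapply(1:3, function(s)
    sim_spot_stack(stack_shape = c(8, 48, 48), n_spots = 3,
                   background_level = 0, seed = s))
  acts <- lapply(ss, function(x)
    total_protease_activity(segment_objects(x$stack, threshold = 50), x$stack))
  g <- summarize_gel_activity(acts)
  expect_equal(g$gel_mean,
               mean(vapply(acts, function(a) a$total_activity, numeric(1))))
})
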