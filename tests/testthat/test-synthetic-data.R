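test_that("fiber fields are seed-deterministic and respect kappa limits", {
  a <- sim_fiber_field(image_size_px = 96, n_fibers = 60, kappa = 2, seed = 11)
  b <- sim_fiber_field(image_size_px = 96, n_fibers = 60, kappa = 2, seed = 11)
  expect_identical(unclass(a$image), unclass(b$image))
  expect_identical(a$ground_truth$fiber_angles, b$ground_truth$fiber_angles)

  # kappa = 0: orientations close to uniform, circular variance near 1
  u <- sim_fiber_field(image_size_px = 96, n_fibers = 300, kappa = 0, seed = 5)
  expect_gt(axial_circular_variance(u$ground_truth$fiber_angles), 0.9)

  # degenerate concentration: all angles at the mean
  d <- sim_fiber_field(image_size_px = 96, n_fibers = 80, kappa = 1e6,
                       mean_angle_deg = 30, seed = 7)
  expect_true(all(axial_err(d$ground_truth$fiber_angles, 30) < 1))
})

test_that("kappa = 0 orientations pass a chi-square uniformity check across seeds", {
  pass <- vapply(1:20, function(s) {
    ang <- sim_fiber_field(image_size_px = 64, n_fibers = 1000, kappa = 0,
                           fiber_length_px = 10, fiber_width_px = 1,
                           background_noise_sd = 0,
                           seed = s)$ground_truth$fiber_angles
    counts <- table(cut(ang, breaks = seq(0, 180, by = 10), include.lowest = TRUE))
    suppressWarnings(stats::chisq.test(as.vector(counts))$p.value) > 0.01
  }, logical(1))
  expect_gte(sum(pass), 18)
})

test_that("fiber field rejects invalid parameters", {
  expect_error(sim_fiber_field(image_size_px = -1), class = "ecmquant_invalid_parameter")
  expect_error(sim_fiber_field(n_fibers = 0), class = "ecmquant_invalid_parameter")
  expect_error(sim_fiber_field(mean_angle_deg = 180), class = "ecmquant_invalid_parameter")
  expect_error(sim_fiber_field(kappa = -1), class = "ecmquant_invalid_parameter")
})

test_that("spot stacks have exact, self-consistent ground truth", {
  # empty case: pure background
  e <- sim_spot_stack(stack_shape = c(6, 40, 40), n_spots = 0,
                      background_level = 7, seed = 1)
  expect_true(all(unclass(e$stack) == 7))
  expect_equal(nrow(e$ground_truth), 0)

  s <- sim_spot_stack(stack_shape = c(12, 64, 64), n_spots = 5,
                      background_level = 0, seed = 3)
  # non-overlap + zero background: truth voxel counts tile the nonzero voxels
  expect_identical(sum(s$ground_truth$voxel_count),
                   sum(unclass(s$stack) > 0))
  # per-spot mean intensity matches the stack at the listed coordinates exactly
  vox_idx <- attr(s$ground_truth, "voxel_index")
  for (i in seq_len(nrow(s$ground_truth))) {
    expect_identical(mean(unclass(s$stack)[vox_idx[[i]]]),
                     s$ground_truth$mean_intensity[i])
    expect_identical(s$ground_truth$volume_um3[i],
                     s$ground_truth$voxel_count[i] * 1)
  }
  # determinism
  s2 <- sim_spot_stack(stack_shape = c(12, 64, 64), n_spots = 5,
                       background_level = 0, seed = 3)
  expect_identical(s$ground_truth$z, s2$ground_truth$z)
  expect_identical(unclass(s$stack), unclass(s2$stack))
})

test_that("impossible spot placement raises a capacity error", {
  expect_error(
    sim_spot_stack(stack_shape = c(4, 20, 20), n_spots = 50,
                   spot_radius_px = 4, seed = 1),
    class = "ecmquant_capacity_error")
})

test_that("cell masks honour their geometric ground truth", {
  disk <- sim_cell_mask(image_size_px = 128, body_radius_px = 30, n_arms = 0)
  expect_true(abs(cell_roundness(disk$mask) - 1) < 0.1)

  star <- sim_cell_mask(image_size_px = 256, body_radius_px = 20,
                        n_arms = 4, arm_length_px = 80, arm_width_px = 6)
  ext <- extension_lengths(star$mask)
  expect_length(ext, 4)
  expect_true(all(abs(ext - 80) <= 2))

  one <- sim_cell_mask(image_size_px = 256, body_radius_px = 20,
                       n_arms = 1, arm_length_px = 70, arm_width_px = 6)
  expect_length(extension_lengths(one$mask), 1)

  expect_error(sim_cell_mask(body_radius_px = 40, arm_length_px = 30, n_arms = 2),
               class = "ecmquant_invalid_parameter")
  expect_error(sim_cell_mask(image_size_px = 64, arm_length_px = 60, n_arms = 2),
               class = "ecmquant_invalid_parameter")
})

test_that("gel series encode the requested area contraction", {
  g75 <- sim_gel_series(image_size_px = 256, initial_radius_px = 100,
                        area_contraction_fraction = 0.75)
  a0 <- sum(unclass(g75$baseline) > 100)
  a1 <- sum(unclass(g75$followup) > 100)
  # area quartered => radius halved
  expect_true(abs(a1 / a0 - 0.25) < 0.01)

  g0 <- sim_gel_series(image_size_px = 128, initial_radius_px = 40,
                       area_contraction_fraction = 0)
  expect_identical(unclass(g0$baseline), unclass(g0$followup))

  expect_error(sim_gel_series(area_contraction_fraction = 1),
               class = "ecmquant_invalid_parameter")
  expect_error(sim_gel_series(area_contraction_fraction = -0.1),
               class = "ecmquant_invalid_parameter")
})

test_that("count tables follow the requested binomial regime", {
  all_pos <- sim_count_table(n_images = 6, nuclei_per_image = 40,
                             p_positive = 1, seed = 2)
  expect_true(all(all_pos$positive == all_pos$total))
  none <- sim_count_table(n_images = 6, nuclei_per_image = 40,
                          p_positive = 0, seed = 2)
  expect_true(all(none$positive == 0))

  # binomial expectation: grand mean percent near 100 * p across many seeds
  grand <- vapply(1:500, function(s) {
    ct <- sim_count_table(n_images = 8, nuclei_per_image = 100,
                          p_positive = 0.6, seed = s)
    mean(100 * ct$positive / ct$total)
  }, numeric(1))
  expect_lt(abs(mean(grand) - 60), 2)
})
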