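test_that("power spectrum handles degenerate and oriented inputs", {
  # constant image: all energy in the DC bin, which windowed/mean-subtracted
  # processing removes entirely
  const <- ecm_image(matrix(5, 64, 64))
  sp <- power_spectrum(const)
  expect_lt(max(unclass(sp)), 1e-8)

  # vertical stripes (fibers at 90 deg): energy on the horizontal spectral axis
  stripes <- ecm_image(matrix(rep(c(0, 100), length.out = 64), 64, 64,
                              byrow = TRUE))
  sp <- unclass(power_spectrum(stripes, window = FALSE))
  cy <- floor(64 / 2) + 1
  horiz <- sum(sp[cy, ])
  vert <- sum(sp[, floor(64 / 2) + 1]) - sp[cy, floor(64 / 2) + 1]
  expect_gt(horiz, 10 * vert)

  expect_error(power_spectrum(matrix(c(NA, 1:1023), 32)),
               class = "ecmquant_invalid_input")
})

test_that("dominant spectral axis is orthogonal to the fiber axis", {
  ff <- sim_fiber_field(kappa = 8, mean_angle_deg = 30, seed = 21)
  prof <- angular_profile(power_spectrum(ff$image))
  spec_peak <- as.numeric(find_peak(prof))
  expect_lt(axial_err(spec_peak, 120), 5)
  # structure-tensor oracle agrees with the generator axis on the same image
  expect_lt(axial_err(structure_tensor_axis(ff$image), 30), 5)
})

test_that("angular profile is flat for isotropic inputs and matches a polar-binning oracle", {
  # seeded isotropic noise: profile close to constant when averaged over seeds
  acc <- numeric(180)
  for (s in 1:20) {
    img <- withr::with_seed(s, matrix(runif(128 * 128), 128, 128))
    acc <- acc + angular_profile(power_spectrum(ecm_image(img)))$intensity
  }
  acc <- acc / 20
  expect_lt(stats::sd(acc) / mean(acc), 0.05)

  # ray sums track per-pixel polar binning of the (equally regularized)
  # spectrum: blur via EBImage, circular smoothing via the test helper
  csm <- function(v, sd) {
    n <- length(v); k <- ceiling(3 * sd); off <- (-k):k
    g <- exp(-off^2 / (2 * sd^2)); g <- g / sum(g)
    vapply(seq_len(n), function(i) sum(v[((i - 1 + off) %% n) + 1] * g),
           numeric(1))
  }
  for (s in 1:3) {
    ff <- sim_fiber_field(image_size_px = 64, n_fibers = 120, kappa = 6,
                          mean_angle_deg = 45, seed = s)
    sp <- power_spectrum(ff$image)
    prof <- angular_profile(sp)  # defaults: spectrum blur 4 px, curve 5 deg
    spb <- as.matrix(EBImage::imageData(
      EBImage::gblur(EBImage::Image(unclass(sp)), sigma = 4)))
    oracle <- csm(polar_bin_profile(spb), 5)
    expect_gt(stats::cor(prof$intensity, oracle, method = "spearman"), 0.95)
  }
})

test_that("angular profile validates its parameters", {
  sp <- power_spectrum(ecm_image(matrix(runif(64 * 64), 64)))
  expect_error(angular_profile(sp, r_min_frac = 0.5, r_max_frac = 0.4),
               class = "ecmquant_invalid_parameter")
  expect_error(angular_profile(sp, step_deg = 7),
               class = "ecmquant_invalid_parameter")
})

test_that("normalization gives unit-mean curves with the expected invariances", {
  ff <- sim_fiber_field(image_size_px = 96, n_fibers = 150, kappa = 4, seed = 2)
  prof <- angular_profile(power_spectrum(ff$image))

  # self-normalization: exactly flat at 1
  self <- normalize_profile(prof, prof)
  expect_true(all(abs(self$intensity - 1) < 1e-12))
  expect_true(attr(self, "normalized"))

  # scale invariance: doubling the profile leaves the normalized curve unchanged
  ctrl <- angular_profile(power_spectrum(
    sim_fiber_field(image_size_px = 96, n_fibers = 150, kappa = 0, seed = 9)$image))
  n1 <- normalize_profile(prof, ctrl)
  doubled <- new_prof <- prof
  doubled$intensity <- doubled$intensity * 2
  attr(doubled, "step_deg") <- attr(prof, "step_deg")
  n2 <- normalize_profile(doubled, ctrl)
  expect_equal(n1$intensity, n2$intensity, tolerance = 1e-12)

  # mismatched grids / degenerate control
  coarse <- angular_profile(power_spectrum(ff$image), step_deg = 2)
  expect_error(normalize_profile(prof, coarse),
               class = "ecmquant_incompatible_profiles")
  zero <- ctrl
  zero$intensity[3] <- 0
  expect_error(normalize_profile(prof, zero),
               class = "ecmquant_degenerate_control")
})

test_that("whole-image intensity scaling does not move the normalized profile or index", {
  ff <- sim_fiber_field(image_size_px = 96, n_fibers = 150, kappa = 6, seed = 13)
  cc <- sim_fiber_field(image_size_px = 96, n_fibers = 150, kappa = 0, seed = 14)
  r1 <- fiber_alignment(ff$image, cc$image)
  r2 <- fiber_alignment(ecm_image(unclass(ff$image) * 3.7), cc$image)
  expect_equal(r1$alignment_index, r2$alignment_index, tolerance = 1e-9)
  expect_equal(r1$peak_angle_deg, r2$peak_angle_deg)
})

test_that("peak finding breaks ties low and flags flat profiles", {
  p <- new_angular_profile_for_test(rep(1, 180))
  expect_warning(pk <- find_peak(p), class = "ecmquant_flat_profile")
  expect_equal(as.numeric(pk), 0)
  expect_true(attr(pk, "flat"))

  v <- rep(1, 180); v[46] <- 3  # peak at 45 degrees
  p <- new_angular_profile_for_test(v)
  expect_equal(as.numeric(find_peak(p)), 45)
})

test_that("alignment index integrates the peak window circularly", {
  # flat normalized curve at 1 with the standard +/- 10 degree window: exactly 20
  flat <- new_angular_profile_for_test(rep(1, 180), normalized = TRUE)
  expect_identical(alignment_index(flat, window_deg = 10), 20)

  # peak near 0 wraps across the 0/180 seam and matches brute-force integration
  v <- 1 + exp(-axial_err(0:179, 2)^2 / 50)
  p <- new_angular_profile_for_test(v / mean(v), normalized = TRUE)
  got <- alignment_index(p, window_deg = 10)
  want <- circular_trapezoid(v / mean(v), 1, 2, 10)
  expect_equal(got, want, tolerance = 1e-12)

  # contract: raw profiles are refused, bad windows are refused
  raw <- new_angular_profile_for_test(v)
  expect_error(alignment_index(raw), class = "ecmquant_contract_violation")
  expect_error(alignment_index(flat, window_deg = 0),
               class = "ecmquant_invalid_parameter")
  expect_error(alignment_index(flat, window_deg = 95),
               class = "ecmquant_invalid_parameter")
})

test_that("self-comparison yields the flat-profile identity index", {
  ff <- sim_fiber_field(image_size_px = 96, n_fibers = 150, kappa = 3, seed = 4)
  res <- fiber_alignment(ff$image, ff$image)
  expect_true(res$flat)
  expect_lt(abs(res$alignment_index - 20), 0.5)
})

test_that("pipeline recovers the fiber axis with the 90-degree spectral correction", {
  cc <- sim_fiber_field(kappa = 0, seed = 100)
  for (mu in c(60, 150)) {
    ff <- sim_fiber_field(kappa = 8, mean_angle_deg = mu, seed = 31 + mu)
    res <- fiber_alignment(ff$image, cc$image)
    expect_lte(axial_err(res$peak_angle_deg, mu), 5)
    # structure-tensor oracle agreement on the same image
    expect_lte(axial_err(res$peak_angle_deg, structure_tensor_axis(ff$image)), 5)
  }
})

test_that("rotating the image by 90 degrees rotates the recovered axis by 90", {
  ff <- sim_fiber_field(kappa = 8, mean_angle_deg = 40, seed = 77)
  cc <- sim_fiber_field(kappa = 0, seed = 78)
  r0 <- fiber_alignment(ff$image, cc$image)
  rot <- t(unclass(ff$image))[, nrow(ff$image):1]  # 90-degree rotation
  r90 <- fiber_alignment(ecm_image(rot), cc$image)
  expect_lt(axial_err(r90$peak_angle_deg, r0$peak_angle_deg + 90), 3)
})

test_that("tidy and autoplot work on alignment results", {
  ff <- sim_fiber_field(image_size_px = 96, n_fibers = 100, kappa = 5, seed = 8)
  cc <- sim_fiber_field(image_size_px = 96, n_fibers = 100, kappa = 0, seed = 9)
  res <- fiber_alignment(ff$image, cc$image)
  td <- tidy(res)
  expect_named(td, c("peak_angle_deg", "alignment_index", "window_deg", "flat"))
  expect_s3_class(autoplot(res), "ggplot")
  expect_s3_class(autoplot(res$profile), "ggplot")
})
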