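test_that("effective_liver_suv has the stated closed form", {
  expect_equal(effective_liver_suv(2.2, 0, 0.3), 2.2)
  expect_equal(effective_liver_suv(2.2, 750, 0), 2.2)
  expect_equal(effective_liver_suv(2.2, 1000, 0.3), 2.2 / 1.3)
  expect_error(effective_liver_suv(-1, 0, 0.3),
               class = "petliver_argument_error")
  expect_error(effective_liver_suv(2.2, -5, 0.3),
               class = "petliver_argument_error")
  # strictly decreasing in tumour load whenever the sink is active
  vals <- effective_liver_suv(2.2, seq(0, 2000, by = 100), 0.3)
  expect_true(all(diff(vals) < 0))
})

test_that("phantom_spec validates its geometry and parameters", {
  expect_error(phantom_spec(liver_semiaxes_mm = c(400, 60, 50)),
               class = "petliver_geometry_error")
  expect_error(phantom_spec(count_fraction = 0),
               class = "petliver_argument_error")
  expect_error(phantom_spec(count_fraction = 1.2),
               class = "petliver_argument_error")
  expect_error(phantom_spec(cov_full = -0.1),
               class = "petliver_argument_error")
  expect_error(phantom_spec(sink_coeff = -1),
               class = "petliver_argument_error")
})

test_that("generation is deterministic and masks are consistent", {
  sp <- tiny_spec(seed = 7)
  p1 <- generate_phantom(sp)
  p2 <- generate_phantom(sp)
  expect_identical(unclass(p1$image), unclass(p2$image))
  expect_false(any(p1$liver_mask & p1$tumor_mask))
  expect_gte(sum(p1$liver_mask), 500)

  # a different seed gives a different realisation of the same anatomy
  p3 <- generate_phantom(tiny_spec(seed = 8))
  expect_false(identical(unclass(p1$image), unclass(p3$image)))
  expect_identical(p1$liver_mask, p3$liver_mask)
})

test_that("noise-free phantom equals the smoothed noiseless map", {
  sp <- tiny_spec(cov_full = 0)
  ph <- generate_phantom(sp)
  # the only residual structure is the deterministic blur of the organ
  # boundary, well under a percent inside the eroded mask
  expect_lt(sd(ph$image[ph$liver_mask]) / mean(ph$image[ph$liver_mask]), 0.005)
  expect_equal(mean(ph$image[ph$liver_mask]), sp$liver_suv, tolerance = 1e-3)
  expect_equal(ph$sigma0, 0)
  # deterministic: a second realisation is bit-identical
  expect_identical(unclass(ph$image),
                   unclass(generate_phantom(tiny_spec(cov_full = 0,
                                                      seed = 99))$image))
})

test_that("declared tumours set the analytic volume and raise the masked SUV", {
  tm <- list(center_mm = c(40, 64, 48), diameter_mm = 30, suv = 8)
  sp <- tiny_spec(tumors = list(tm), sink_coeff = 0, cov_full = 0)
  ph <- generate_phantom(sp)
  expect_equal(ph$true_mtv_ml, (4 / 3) * pi * 15^3 / 1000)
  expect_gt(max(ph$image[ph$tumor_mask]), 4)
  # sink active: effective liver uptake drops below the base value
  sp2 <- tiny_spec(tumors = list(tm), sink_coeff = 0.3, cov_full = 0)
  ph2 <- generate_phantom(sp2)
  expect_lt(ph2$true_liver_suv, sp2$liver_suv)
  expect_equal(ph2$true_liver_suv,
               effective_liver_suv(sp2$liver_suv, ph2$true_mtv_ml, 0.3))
})

test_that("calibration hits the target liver CoV at full counts", {
  sp <- compact_spec(seed = 5)
  reps <- paired_count_images(sp, rep(1, 9))
  covs <- vapply(reps, liver_cov, numeric(1))
  expect_equal(median(covs), sp$cov_full, tolerance = 0.05)
})

test_that("liver mean is an unbiased estimate of the effective uptake", {
  sp <- tiny_spec(seed = 11)
  reps <- paired_count_images(sp, rep(1, 100))
  means <- vapply(reps, function(p) mean(p$image[p$liver_mask]), numeric(1))
  expect_equal(mean(means), sp$liver_suv, tolerance = 0.02)
})

test_that("liver CoV scales as the inverse square root of retained counts", {
  sp <- compact_spec(seed = 13)
  ratios <- vapply(1:50, function(r) {
    sp$seed <- r
    pr <- paired_count_images(sp, c(1, 0.25))
    liver_cov(pr[[2]]) / liver_cov(pr[[1]])
  }, numeric(1))
  expect_gte(median(ratios), 1.8)
  expect_lte(median(ratios), 2.2)

  # three-point extension of the inverse-square-root law
  sp$seed <- 99
  tri <- paired_count_images(sp, c(1, 0.25, 0.0625))
  covs <- vapply(tri, liver_cov, numeric(1))
  expect_equal(covs[2] / covs[1], 2, tolerance = 0.1)
  expect_equal(covs[3] / covs[1], 4, tolerance = 0.15)
})

test_that("paired count images share one anatomy", {
  sp <- tiny_spec(cov_full = 0)
  pr <- paired_count_images(sp, c(1, 0.25))
  expect_identical(unclass(pr[[1]]$image), unclass(pr[[2]]$image))
  expect_error(paired_count_images(sp, numeric(0)),
               class = "petliver_argument_error")
  expect_error(paired_count_images(sp, c(1, 1.5)),
               class = "petliver_argument_error")
})

test_that("stronger smoothing never increases the liver CoV", {
  sp <- compact_spec(seed = 17)
  sigma0 <- generate_phantom(sp)$sigma0
  covs <- vapply(c(3, 5, 7, 9, 12), function(fw) {
    sp$recon <- recon_profile("EARL1", psf_fwhm_mm = fw)
    liver_cov(generate_phantom(sp, sigma0 = sigma0))
  }, numeric(1))
  expect_true(all(diff(covs) < 0))
})

test_that("the image grid follows the reconstruction profile", {
  sp <- tiny_spec(recon = recon_profile("HR2MM"))
  ph <- generate_phantom(tiny_spec())
  ph2 <- generate_phantom(sp)
  expect_equal(dim(ph2$image), dim(ph$image) * 2L)
  expect_equal(attr(ph2$image, "voxel_mm"), c(2, 2, 2))
})
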