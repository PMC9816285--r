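test_that("voi_mask follows voxel-centre inclusion", {
  img <- suv_image(array(2, c(20, 20, 20)), 4)
  # 1 mm sphere centred exactly on a voxel centre: only that centre is inside
  m <- voi_mask(img, spherical_voi(c(38, 38, 38), 1))
  expect_equal(sum(m), 1L)
  expect_true(m[10, 10, 10])

  # 30 mm sphere: exact agreement with full-grid enumeration
  for (ctr in list(c(40, 40, 40), c(38, 42, 39.5), c(33.3, 47.1, 36))) {
    m <- voi_mask(img, spherical_voi(ctr, 30))
    expect_identical(which(m), bf_sphere_members(img, ctr, 30))
  }
})

test_that("voi_mask is invariant under whole-voxel translation", {
  img <- suv_image(array(1, c(24, 24, 24)), 4)
  v1 <- voi_mask(img, spherical_voi(c(40, 40, 40), 30))
  v2 <- voi_mask(img, spherical_voi(c(44, 40, 40), 30))
  expect_equal(sum(v1), sum(v2))
  # same mask shifted by one voxel along the first axis
  expect_identical(v1[1:23, , ], v2[2:24, , ])
})

test_that("voi_mask errors when the sphere captures no voxel centre", {
  img <- suv_image(array(1, c(8, 8, 8)), 4)
  expect_error(voi_mask(img, spherical_voi(c(200, 200, 200), 10)),
               class = "petliver_empty_voi")
  # sphere nestled between voxel centres
  expect_error(voi_mask(img, spherical_voi(c(4, 4, 4), 1)),
               class = "petliver_empty_voi")
})

test_that("suv_max and suv_mean compute the obvious statistics", {
  a <- array(2, c(3, 3, 3)); a[2, 2, 2] <- 5
  img <- suv_image(a, 4)
  full <- array(TRUE, c(3, 3, 3))
  expect_equal(suv_max(img, full), 5)
  expect_equal(suv_mean(img, full), (26 * 2 + 5) / 27)
  expect_error(suv_max(img, array(FALSE, c(3, 3, 3))),
               class = "petliver_empty_voi")

  # max is monotone under mask inclusion
  inner <- array(FALSE, c(3, 3, 3)); inner[1, 1, 1] <- TRUE
  expect_lte(suv_max(img, inner), suv_max(img, full))
})

test_that("nested concentric VOIs give non-decreasing SUVmax", {
  for (s in 1:10) {
    img <- random_image(seed = s)
    ctr <- c(40, 40, 40)
    mx <- vapply(c(10, 15, 20, 30, 50), function(dm)
      suv_max(img, voi_mask(img, spherical_voi(ctr, dm))), numeric(1))
    expect_true(all(diff(mx) >= 0))
  }
})

test_that("metrics on a homogeneous image equal the constant", {
  img <- suv_image(array(2.0, c(20, 20, 20)), 4)
  m <- extract_metrics(img, spherical_voi(c(40, 40, 40), 30))
  expect_equal(m$suv_max, 2.0)
  expect_equal(m$suv_peak, 2.0)
  expect_equal(m$suv_mean, 2.0)
  expect_equal(m$voi_volume_ml, m$n_voxels * 0.064)
})

test_that("suv_peak matches the brute-force max-of-sphere-means", {
  # single hot voxel: peak averaged over ~1 mL sits strictly between
  # background and maximum
  a <- array(2, c(20, 20, 20)); a[10, 10, 10] <- 5
  img <- suv_image(a, 4)
  pk <- suv_peak(img, spherical_voi(c(38, 38, 38), 30))
  expect_gt(pk, 2); expect_lt(pk, 5)
  expect_equal(pk, bf_suv_peak(img, c(38, 38, 38), 30))

  for (s in 1:5) {
    img <- random_image(seed = 100 + s)
    expect_equal(suv_peak(img, spherical_voi(c(40, 40, 40), 30)),
                 bf_suv_peak(img, c(40, 40, 40), 30))
  }
})

test_that("suv_peak reduces to suv_max for a sub-voxel sphere", {
  img <- random_image(seed = 42)
  voi <- spherical_voi(c(40, 40, 40), 30)
  # 0.03 mL -> radius ~1.9 mm < half the 4 mm spacing: single-voxel spheres
  expect_equal(suv_peak(img, voi, peak_volume_ml = 0.03),
               suv_max(img, voi_mask(img, voi)))
})

test_that("suv_peak dominates the sphere mean at any candidate", {
  img <- random_image(seed = 9)
  voi <- spherical_voi(c(40, 40, 40), 30)
  pk <- suv_peak(img, voi)
  # the 1 mL sphere at the voxel centre (38, 38, 38) is one admissible
  # candidate, so its mean can never exceed the peak
  r_pk <- (3 * 1000 / (4 * pi))^(1 / 3)
  ctr_mean <- suv_mean(img, voi_mask(img, spherical_voi(c(38, 38, 38),
                                                        2 * r_pk)))
  expect_gte(pk, ctr_mean)
})
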