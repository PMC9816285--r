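test_that("statistical helpers implement the standard definitions", {
  # perfectly monotone pairs: Spearman rho = 1
  s <- spearman_assoc(c(1, 2, 3, 4, 5), c(2, 3, 5, 7, 11))
  expect_equal(s$rho, 1.0)
  # identical pairs: degenerate signed-rank test reported with p = 1
  w <- paired_wilcoxon(c(1, 2, 3, 4, 5), c(1, 2, 3, 4, 5))
  expect_equal(w$p_value, 1)
  # constant input: undefined correlation, p = 1
  s0 <- spearman_assoc(rep(2, 6), 1:6)
  expect_true(is.na(s0$rho)); expect_equal(s0$p_value, 1)
  expect_error(paired_wilcoxon(1:3, 1:3), class = "petliver_argument_error")
  # shifted pairs are detected
  set.seed(1)
  a <- rnorm(30); expect_lt(paired_wilcoxon(a, a + 1)$p_value, 0.001)
})

test_that("summaries are recomputable from the tidy rows", {
  res <- run_noise_experiment(tiny_spec(), n_replicates = 6, seed = 5)
  for (i in seq_len(nrow(res$summaries))) {
    s <- res$summaries[i, ]
    v <- res$rows$value[res$rows$metric == s$metric &
                        res$rows$count_fraction == s$count_fraction]
    expect_equal(s$median, median(v))
    expect_equal(s$iqr, quantile(v, 0.75, names = FALSE) -
                        quantile(v, 0.25, names = FALSE))
  }
  # odd-length sorted sample: median is the middle element
  expect_equal(median(c(1, 4, 9)), 4)
})

test_that("experiments are reproducible under a fixed master seed", {
  r1 <- run_voi_size_experiment(tiny_spec(), diameters_mm = c(10, 20, 30),
                                n_replicates = 5, seed = 42)
  r2 <- run_voi_size_experiment(tiny_spec(), diameters_mm = c(10, 20, 30),
                                n_replicates = 5, seed = 42)
  expect_identical(r1$rows, r2$rows)
  expect_identical(r1$tests, r2$tests)
})

test_that("noise-free phantoms give identical metrics across VOI sizes", {
  res <- run_voi_size_experiment(tiny_spec(cov_full = 0),
                                 diameters_mm = c(10, 20, 30),
                                 n_replicates = 5, seed = 1)
  expect_lt(max(res$rows$value) - min(res$rows$value), 2e-3)
  expect_equal(mean(res$rows$value), 2.2, tolerance = 1e-3)
})

test_that("noise-free phantoms give identical metrics at all locations", {
  res <- run_location_experiment(compact_spec(cov_full = 0),
                                 offsets_mm = compact_offsets(),
                                 n_replicates = 5, seed = 1)
  by_loc <- tapply(res$rows$value, res$rows$location, mean)
  expect_lt(max(by_loc) - min(by_loc), 1e-3)
})

test_that("a VOI deliberately placed over a tumour reads elevated SUVmax", {
  tm <- list(center_mm = c(163, 128, 96), diameter_mm = 30, suv = 8)
  sp <- compact_spec(tumors = list(tm), sink_coeff = 0, seed = 2)
  offs <- rbind(A = c(0, 0, 0), B = c(35, 0, 0))
  res <- run_location_experiment(sp, offsets_mm = offs, n_replicates = 5,
                                 seed = 3)
  mx <- tapply(res$rows$value[res$rows$metric == "suv_max"],
               res$rows$location[res$rows$metric == "suv_max"], median)
  expect_gt(mx[["B"]], 6)          # on the tumour
  expect_lt(mx[["A"]], 4)          # homogeneous liver
})

test_that("displaced VOIs leaving the liver raise a geometry error", {
  expect_error(run_location_experiment(tiny_spec(),
                                       offsets_mm = rbind(A = c(0, 0, 0),
                                                          B = c(35, 0, 0)),
                                       n_replicates = 5, seed = 1),
               class = "petliver_geometry_error")
  expect_error(run_voi_size_experiment(tiny_spec(),
                                       diameters_mm = c(10, 90),
                                       n_replicates = 5, seed = 1),
               class = "petliver_geometry_error")
})

test_that("zero noise gives zero paired differences across count fractions", {
  res <- run_noise_experiment(tiny_spec(cov_full = 0), n_replicates = 5,
                              seed = 2)
  expect_true(all(res$tests$p_value == 1))
  # both fractions yield the identical deterministic image
  expect_equal(res$cov_ratio$cov_ratio, c(1, 1))
})

test_that("identical count fractions keep the type-I error near nominal", {
  # 100 null studies: both "conditions" are fresh full-count realisations,
  # so each Wilcoxon should reject at ~5%
  rejections <- c(suv_max = 0L, suv_peak = 0L, suv_mean = 0L)
  for (s in 1:100) {
    res <- run_noise_experiment(tiny_spec(), fractions = c(1, 1),
                                n_replicates = 10, seed = 1000 + s)
    p <- res$tests$p_value
    names(p) <- sub(":.*", "", res$tests$comparison)
    rejections <- rejections + as.integer(p[names(rejections)] < 0.05)
  }
  # binomial(100, 0.05): P(X > 12) < 0.002 per metric
  expect_true(all(rejections <= 12))
})

test_that("recon profiles with equal grids and kernels are degenerate", {
  prof <- list(recon_profile("EARL1"), recon_profile("EARL2", voxel_mm = 4,
                                                     psf_fwhm_mm = 7))
  res <- run_recon_experiment(tiny_spec(), profiles = prof,
                              n_replicates = 6, seed = 4)
  expect_true(all(abs(res$spread$spread_ratio - 1) < 0.1))
})

test_that("measured MTV tracks the declared tumour load", {
  sp <- phantom_spec(shape = c(96, 96, 72), liver_semiaxes_mm = c(60, 45, 40),
                     liver_margin_mm = 10)
  res <- run_mtv_association_experiment(sp, mtv_grid_ml = c(0, 50, 200, 500),
                                        n_replicates = 5, seed = 6)
  meas <- res$summaries[res$summaries$metric == "measured_mtv_ml", ]
  meas <- meas[order(meas$mtv_ml), ]
  expect_true(all(diff(meas$median) > 0))
  expect_equal(meas$median, meas$mtv_ml, tolerance = 0.05)
})
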