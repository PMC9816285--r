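#' @name experiments
#' @title Phantom experiment drivers
#' @description
#' Each driver replays one of the liver-SUV robustness comparisons on a batch
#' of simulated phantoms and returns an `experiment_result`: a tidy `rows`
#' table (one row per replicate x condition x metric), per-condition
#' `summaries` (median and interquartile range), and the comparison `tests`.
#' Phantoms within a replicate share one anatomy so that conditions are
#' paired, mirroring patients serving as their own controls; across
#' replicates the noise realisations are independent.
NULL

.metric_names <- c("suv_max", "suv_peak", "suv_mean")

.replicate_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max, n)
}

.as_result <- function(rows, tests, extra = list()) {
  out <- c(list(rows = rows, summaries = summarize_rows(rows), tests = tests),
           extra)
  structure(out, class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cond <- setdiff(names(x$rows), c("replicate", "metric", "value"))
  cat(sprintf("<experiment_result> %d rows, conditions: %s\n",
              nrow(x$rows), paste(cond, collapse = ", ")))
  cat("summaries:\n"); print(x$summaries, row.names = FALSE)
  if (nrow(x$tests)) { cat("tests:\n"); print(x$tests, row.names = FALSE) }
  invisible(x)
}

#' Median / IQR summaries of tidy experiment rows
#'
#' Groups by every column except `replicate` and `value` and reports the
#' median, 25th and 75th percentiles (linear-interpolation quantiles) and
#' the interquartile range.
#'
#' @param rows tidy data frame with at least `replicate`, `metric`, `value`.
#' @return Data frame of per-group summaries.
#' @export
summarize_rows <- function(rows) {
  cond <- setdiff(names(rows), c("replicate", "value"))
  agg <- stats::aggregate(rows$value, by = rows[cond], FUN = function(v)
    c(median = stats::median(v),
      p25 = stats::quantile(v, 0.25, names = FALSE),
      p75 = stats::quantile(v, 0.75, names = FALSE)))
  out <- cbind(agg[cond], as.data.frame(agg$x))
  out$iqr <- out$p75 - out$p25
  out[do.call(order, out[cond]), , drop = FALSE]
}

#' Paired Wilcoxon signed-rank test
#'
#' Thin wrapper around [stats::wilcox.test()] (normal approximation) with the
#' degenerate case handled explicitly: when every paired difference is zero
#' there is no evidence of a shift and `p_value = 1` is reported.
#'
#' @param a,b paired numeric vectors of equal length >= 5.
#' @return List with `statistic`, `p_value`, `method`.
#' @export
paired_wilcoxon <- function(a, b) {
  if (length(a) != length(b) || length(a) < 5)
    .err("paired inputs must have equal length >= 5", "petliver_argument_error")
  if (all(a == b))
    return(list(statistic = NA_real_, p_value = 1,
                method = "wilcoxon_signed_rank (degenerate: all ties)"))
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            exact = FALSE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = "wilcoxon_signed_rank")
}

#' Spearman rank correlation
#'
#' @param x,y numeric vectors of equal length >= 5.
#' @return List with `rho`, `p_value`, `method`. If either input is constant
#'   the correlation is undefined and `rho = NA`, `p_value = 1`.
#' @export
spearman_assoc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 5)
    .err("inputs must have equal length >= 5", "petliver_argument_error")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(rho = NA_real_, p_value = 1,
                method = "spearman (degenerate: constant input)"))
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value, method = "spearman")
}

.metric_values <- function(rows, metric, cond_col, cond_val) {
  sel <- rows$metric == metric & rows[[cond_col]] == cond_val
  rows$value[sel][order(rows$replicate[sel])]
}

# ---- VOI size --------------------------------------------------------------

#' VOI-size comparison
#'
#' Places concentric spherical VOIs of increasing diameter at the liver
#' centre of each phantom replicate (a 1, 1.5, 2, 3 and 5 cm ladder by
#' default) and extracts SUVmax, SUVpeak and SUVmean from the same noise
#' realisation, since nested VOIs are read off one image. Consecutive
#' diameters are compared per metric with the paired Wilcoxon signed-rank
#' test.
#'
#' @param spec a [phantom_spec()].
#' @param diameters_mm VOI diameters (mm), ascending.
#' @param n_replicates number of phantom replicates.
#' @param seed master seed; replicate seeds derive from it.
#' @param peak_volume_ml SUVpeak sphere volume (mL).
#' @return An `experiment_result` with condition column `diameter_mm`.
#' @export
run_voi_size_experiment <- function(spec, diameters_mm = c(10, 15, 20, 30, 50),
                                    n_replicates = 100, seed = 1,
                                    peak_volume_ml = 1.0) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (max(diameters_mm) / 2 > min(spec$liver_semiaxes_mm))
    .err("largest VOI does not fit inside the liver at its centre",
         "petliver_geometry_error")
  rseeds <- .replicate_seeds(seed, n_replicates)
  stream <- .phantom_stream(spec)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    ph <- stream(rseeds[r])
    for (dm in diameters_mm) {
      m <- extract_metrics(ph$image, spherical_voi(spec$liver_center_mm, dm),
                           peak_volume_ml)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, diameter_mm = dm, metric = .metric_names,
        value = c(m$suv_max, m$suv_peak, m$suv_mean))
    }
  }
  rows <- do.call(rbind, rows)
  tests <- list()
  for (metric in .metric_names) {
    for (i in seq_len(length(diameters_mm) - 1L)) {
      a <- .metric_values(rows, metric, "diameter_mm", diameters_mm[i])
      b <- .metric_values(rows, metric, "diameter_mm", diameters_mm[i + 1L])
      w <- paired_wilcoxon(a, b)
      tests[[length(tests) + 1L]] <- data.frame(
        comparison = sprintf("%s: %g vs %g mm", metric, diameters_mm[i],
                             diameters_mm[i + 1L]),
        statistic = w$statistic, p_value = w$p_value, method = w$method)
    }
  }
  .as_result(rows, do.call(rbind, tests))
}

# ---- VOI location ----------------------------------------------------------

#' Default liver VOI displacement vectors
#'
#' Five locations labelled A-E: the liver centre plus displacements along
#' the liver semi-axes, chosen so that a 3 cm VOI stays well inside the
#' default liver ellipsoid.
#'
#' @return 5 x 3 matrix of displacements (mm), rownames `A`-`E`.
#' @export
default_location_offsets <- function() {
  m <- rbind(A = c(0, 0, 0), B = c(40, 0, 0), C = c(-40, 0, 0),
             D = c(0, 30, 0), E = c(0, 0, -25))
  m
}

#' VOI-location comparison
#'
#' Places a fixed-diameter spherical VOI at five locations inside the liver
#' of each replicate and compares each location against the reference
#' location A with paired Wilcoxon tests, Holm-adjusted within each metric.
#'
#' @inheritParams run_voi_size_experiment
#' @param offsets_mm matrix of displacement vectors (one row per location)
#'   relative to the liver centre; row names label the locations.
#' @param diameter_mm VOI diameter (mm).
#' @return An `experiment_result` with condition column `location`.
#' @export
run_location_experiment <- function(spec, offsets_mm = default_location_offsets(),
                                    n_replicates = 100, seed = 1,
                                    diameter_mm = 30, peak_volume_ml = 1.0) {
  stopifnot(inherits(spec, "phantom_spec"))
  offsets_mm <- as.matrix(offsets_mm)
  if (is.null(rownames(offsets_mm)))
    rownames(offsets_mm) <- LETTERS[seq_len(nrow(offsets_mm))]
  r_voi <- diameter_mm / 2
  for (i in seq_len(nrow(offsets_mm))) {
    # sufficient containment: per-axis worst case inside the ellipsoid
    if (sum(((abs(offsets_mm[i, ]) + r_voi) / spec$liver_semiaxes_mm)^2) > 1)
      .err(sprintf("displaced VOI '%s' leaves the liver",
                   rownames(offsets_mm)[i]), "petliver_geometry_error")
  }
  locs <- rownames(offsets_mm)
  rseeds <- .replicate_seeds(seed, n_replicates)
  stream <- .phantom_stream(spec)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    ph <- stream(rseeds[r])
    for (i in seq_along(locs)) {
      ctr <- spec$liver_center_mm + offsets_mm[i, ]
      m <- extract_metrics(ph$image, spherical_voi(ctr, diameter_mm),
                           peak_volume_ml)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, location = locs[i], metric = .metric_names,
        value = c(m$suv_max, m$suv_peak, m$suv_mean))
    }
  }
  rows <- do.call(rbind, rows)
  tests <- list()
  for (metric in .metric_names) {
    fam <- list()
    for (loc in locs[-1]) {
      a <- .metric_values(rows, metric, "location", locs[1])
      b <- .metric_values(rows, metric, "location", loc)
      w <- paired_wilcoxon(a, b)
      fam[[length(fam) + 1L]] <- data.frame(
        comparison = sprintf("%s: %s vs %s", metric, loc, locs[1]),
        statistic = w$statistic, p_value = w$p_value, method = w$method)
    }
    fam <- do.call(rbind, fam)
    fam$p_adjusted <- stats::p.adjust(fam$p_value, method = "holm")
    tests[[length(tests) + 1L]] <- fam
  }
  .as_result(rows, do.call(rbind, tests))
}

# ---- count fraction / noise ------------------------------------------------

#' Image-noise (count fraction) comparison
#'
#' For each replicate, generates matched images at several count fractions
#' from one shared anatomy (see [paired_count_images()]), measures the VOI
#' metrics and the liver coefficient of variation on each, and tests each
#' reduced-count fraction against the first fraction per metric with paired
#' Wilcoxon tests. The `cov_ratio` element reports the median liver CoV of
#' each fraction relative to the first — the noise amplification factor.
#'
#' @inheritParams run_location_experiment
#' @param fractions count fractions in (0, 1]; the first is the reference.
#' @return An `experiment_result` with condition column `count_fraction` and
#'   extra element `cov_ratio`.
#' @export
run_noise_experiment <- function(spec, fractions = c(1.0, 0.25),
                                 n_replicates = 30, seed = 1,
                                 diameter_mm = 30, peak_volume_ml = 1.0) {
  stopifnot(inherits(spec, "phantom_spec"))
  rseeds <- matrix(.replicate_seeds(seed, n_replicates * length(fractions)),
                   nrow = n_replicates)
  voi <- spherical_voi(spec$liver_center_mm, diameter_mm)
  stream <- .phantom_stream(spec)
  rows <- list()
  for (r in seq_len(n_replicates)) {
    for (i in seq_along(fractions)) {
      out <- stream(rseeds[r, i], fractions[i])
      m <- extract_metrics(out$image, voi, peak_volume_ml)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, count_fraction = fractions[i],
        metric = c(.metric_names, "liver_cov"),
        value = c(m$suv_max, m$suv_peak, m$suv_mean, liver_cov(out)))
    }
  }
  rows <- do.call(rbind, rows)
  tests <- list()
  for (metric in .metric_names) {
    for (f in fractions[-1]) {
      a <- .metric_values(rows, metric, "count_fraction", fractions[1])
      b <- .metric_values(rows, metric, "count_fraction", f)
      w <- paired_wilcoxon(a, b)
      tests[[length(tests) + 1L]] <- data.frame(
        comparison = sprintf("%s: f=%g vs f=%g", metric, f, fractions[1]),
        statistic = w$statistic, p_value = w$p_value, method = w$method)
    }
  }
  med_cov <- vapply(fractions, function(f)
    stats::median(rows$value[rows$metric == "liver_cov" &
                             rows$count_fraction == f]), numeric(1))
  cov_ratio <- data.frame(count_fraction = fractions,
                          cov_ratio = med_cov / med_cov[1])
  .as_result(rows, do.call(rbind, tests), list(cov_ratio = cov_ratio))
}

# ---- reconstruction profile ------------------------------------------------

#' Reconstruction-profile comparison
#'
#' Regenerates the same anatomy under several reconstruction profiles. The
#' count-level noise amplitude `sigma0` is calibrated once under the input specification's
#' own profile and held fixed across profiles, so that — as on a scanner
#' reconstructing one acquisition several ways — finer grids and weaker
#' smoothing produce visibly noisier images. Each profile is tested against
#' the first with paired Wilcoxon tests, and the `spread` element reports,
#' per metric, the ratio of the largest to the smallest across-profile
#' median.
#'
#' @inheritParams run_location_experiment
#' @param profiles list of [recon_profile()] objects.
#' @return An `experiment_result` with condition column `recon` and extra
#'   element `spread`.
#' @export
run_recon_experiment <- function(spec,
                                 profiles = list(recon_profile("EARL1"),
                                                 recon_profile("EARL2"),
                                                 recon_profile("HR2MM"),
                                                 recon_profile("HR2MMPSF")),
                                 n_replicates = 50, seed = 1,
                                 diameter_mm = 30, peak_volume_ml = 1.0) {
  stopifnot(inherits(spec, "phantom_spec"))
  true_mtv <- sum(vapply(spec$tumors, function(tm)
    (4 / 3) * pi * (tm$diameter_mm / 2)^3 / 1000, numeric(1)))
  eff <- effective_liver_suv(spec$liver_suv, true_mtv, spec$sink_coeff)
  sigma0 <- .calibrate_sigma0(spec, eff)
  prof_names <- vapply(profiles, function(p) p$name, character(1))
  rseeds <- matrix(.replicate_seeds(seed, n_replicates * length(profiles)),
                   nrow = n_replicates)
  voi <- spherical_voi(spec$liver_center_mm, diameter_mm)
  rows <- list()
  for (p in seq_along(profiles)) {
    spec_p <- spec
    spec_p$recon <- profiles[[p]]
    stream <- .phantom_stream(spec_p, sigma0 = sigma0)
    for (r in seq_len(n_replicates)) {
      ph <- stream(rseeds[r, p])
      m <- extract_metrics(ph$image, voi, peak_volume_ml)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, recon = prof_names[p], metric = .metric_names,
        value = c(m$suv_max, m$suv_peak, m$suv_mean))
    }
  }
  rows <- do.call(rbind, rows)
  tests <- list()
  for (metric in .metric_names) {
    for (pn in prof_names[-1]) {
      a <- .metric_values(rows, metric, "recon", prof_names[1])
      b <- .metric_values(rows, metric, "recon", pn)
      w <- paired_wilcoxon(a, b)
      tests[[length(tests) + 1L]] <- data.frame(
        comparison = sprintf("%s: %s vs %s", metric, pn, prof_names[1]),
        statistic = w$statistic, p_value = w$p_value, method = w$method)
    }
  }
  spread <- do.call(rbind, lapply(.metric_names, function(metric) {
    med <- vapply(prof_names, function(pn)
      stats::median(.metric_values(rows, metric, "recon", pn)), numeric(1))
    data.frame(metric = metric, spread_ratio = max(med) / min(med))
  }))
  .as_result(rows, do.call(rbind, tests), list(spread = spread))
}

# ---- tumour load / sink ----------------------------------------------------

#' Place tumour spheres realising a target total volume
#'
#' Realises a requested metabolic tumour volume as one or two spheres
#' anchored on the first axis just outside the liver ellipsoid, leaving the
#' liver VOI untouched. Loads above 500 mL are split across both sides so
#' that large volumes still fit in the field of view, mimicking disseminated
#' rather than single-mass disease.
#'
#' @param mtv_ml target total tumour volume (mL); 0 gives no tumours.
#' @param spec a [phantom_spec()] providing geometry.
#' @param suv tumour uptake (must exceed the segmentation threshold to
#'   contribute to measured MTV).
#' @param gap_mm clearance between the liver surface and each sphere.
#' @return List of tumour descriptors for [phantom_spec()].
#' @export
tumor_layout <- function(mtv_ml, spec, suv = 8, gap_mm = 8) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (mtv_ml < 0) .err("mtv_ml must be >= 0", "petliver_argument_error")
  if (mtv_ml == 0) return(list())
  vols <- if (mtv_ml <= 500) mtv_ml else rep(mtv_ml / 2, 2)
  signs <- if (length(vols) == 1) 1 else c(1, -1)
  fov <- spec$shape * spec$voxel_mm
  out <- list()
  for (i in seq_along(vols)) {
    r <- (3 * vols[i] * 1000 / (4 * pi))^(1 / 3)
    ctr <- spec$liver_center_mm
    ctr[1] <- ctr[1] + signs[i] * (spec$liver_semiaxes_mm[1] + gap_mm + r)
    if (ctr[1] - r < 0 || ctr[1] + r > fov[1] ||
        any(ctr[2:3] - r < 0) || any(ctr[2:3] + r > fov[2:3]))
      .err(sprintf("tumour sphere of %.0f mL does not fit in the field of view",
                   vols[i]), "petliver_geometry_error")
    out[[i]] <- list(center_mm = ctr, diameter_mm = 2 * r, suv = suv)
  }
  out
}

#' Tumour-load association
#'
#' Simulates phantoms over a grid of total tumour volumes with the sink
#' model coupling tumour load to liver uptake, segments the metabolic tumour
#' volume with the fixed SUV 4.0 threshold, and correlates each liver VOI
#' metric against the measured total MTV with Spearman's rank correlation.
#' With `sink_coeff = 0` the coupling is switched off and the correlations
#' should be null.
#'
#' @inheritParams run_location_experiment
#' @param mtv_grid_ml tumour-load levels (mL).
#' @param sink_coeff sink coefficient; defaults to the value in `spec`.
#' @param tumor_suv uptake of the simulated tumours.
#' @param mtv_threshold segmentation threshold passed to [segment_mtv()].
#' @return An `experiment_result` with condition column `mtv_ml`; rows
#'   include the measured total volume as metric `measured_mtv_ml`.
#' @export
run_mtv_association_experiment <- function(spec,
                                           mtv_grid_ml = c(0, 50, 200, 500, 1000),
                                           sink_coeff = NULL,
                                           n_replicates = 30, seed = 1,
                                           diameter_mm = 30,
                                           peak_volume_ml = 1.0,
                                           tumor_suv = 8,
                                           mtv_threshold = 4.0) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (is.null(sink_coeff)) sink_coeff <- spec$sink_coeff
  layouts <- lapply(mtv_grid_ml, tumor_layout, spec = spec, suv = tumor_suv)
  rseeds <- matrix(.replicate_seeds(seed, n_replicates * length(mtv_grid_ml)),
                   nrow = n_replicates)
  voi <- spherical_voi(spec$liver_center_mm, diameter_mm)
  rows <- list()
  for (l in seq_along(mtv_grid_ml)) {
    spec_l <- spec
    spec_l$tumors <- layouts[[l]]
    spec_l$sink_coeff <- sink_coeff
    stream <- .phantom_stream(spec_l)
    for (r in seq_len(n_replicates)) {
      ph <- stream(rseeds[r, l])
      seg <- segment_mtv(ph$image, threshold = mtv_threshold)
      m <- extract_metrics(ph$image, voi, peak_volume_ml)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate = r, mtv_ml = mtv_grid_ml[l],
        metric = c(.metric_names, "measured_mtv_ml"),
        value = c(m$suv_max, m$suv_peak, m$suv_mean, seg$total_ml))
    }
  }
  rows <- do.call(rbind, rows)
  # align measured MTV and metric values by replicate x level
  key <- function(metric) {
    sel <- rows$metric == metric
    ord <- order(rows$replicate[sel], rows$mtv_ml[sel])
    rows$value[sel][ord]
  }
  measured <- key("measured_mtv_ml")
  tests <- do.call(rbind, lapply(.metric_names, function(metric) {
    s <- spearman_assoc(measured, key(metric))
    data.frame(comparison = sprintf("%s vs measured MTV", metric),
               statistic = s$rho, p_value = s$p_value, method = s$method)
  }))
  .as_result(rows, tests)
}
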