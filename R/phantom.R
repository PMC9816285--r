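#' Reconstruction profile
#'
#' PET reconstruction protocols are emulated by two knobs: the reconstruction
#' grid spacing and an isotropic Gaussian smoothing kernel whose full width at
#' half maximum stands in for the reconstructed spatial resolution. Four named
#' presets mirror the protocols commonly compared in harmonisation studies:
#' two EARL-compliant protocols on a 4 mm grid and two high-resolution 2 mm
#' protocols, with and without point-spread-function (PSF) style resolution
#' recovery. The presets are ordered so that smaller voxels and less smoothing
#' yield noisier images.
#'
#' @param name one of `"EARL1"`, `"EARL2"`, `"HR2MM"`, `"HR2MMPSF"`.
#' @param voxel_mm reconstruction grid spacing (mm); default per preset.
#' @param psf_fwhm_mm Gaussian smoothing FWHM (mm); default per preset.
#' @return A `recon_profile` list with `name`, `voxel_mm`, `psf_fwhm_mm`.
#' @examples
#' recon_profile("EARL1")
#' recon_profile("HR2MMPSF")
#' @export
recon_profile <- function(name = c("EARL1", "EARL2", "HR2MM", "HR2MMPSF"),
                          voxel_mm = NULL, psf_fwhm_mm = NULL) {
  name <- match.arg(name)
  defaults <- list(
    EARL1    = list(voxel_mm = 4, psf_fwhm_mm = 7),
    EARL2    = list(voxel_mm = 4, psf_fwhm_mm = 5),
    HR2MM    = list(voxel_mm = 2, psf_fwhm_mm = 4),
    HR2MMPSF = list(voxel_mm = 2, psf_fwhm_mm = 3)
  )[[name]]
  if (is.null(voxel_mm)) voxel_mm <- defaults$voxel_mm
  if (is.null(psf_fwhm_mm)) psf_fwhm_mm <- defaults$psf_fwhm_mm
  if (any(voxel_mm <= 0) || psf_fwhm_mm <= 0)
    .err("voxel_mm and psf_fwhm_mm must be > 0", "petliver_argument_error")
  structure(list(name = name, voxel_mm = .as_len3(voxel_mm, "voxel_mm"),
                 psf_fwhm_mm = as.numeric(psf_fwhm_mm)),
            class = "recon_profile")
}

#' Phantom specification
#'
#' Describes a digital liver phantom: an ellipsoidal liver of roughly
#' homogeneous uptake embedded in soft-tissue background, optional spherical
#' high-uptake tumours, and a noise model in which zero-mean Gaussian noise is
#' injected before reconstruction smoothing with per-voxel standard deviation
#' proportional to `1 / sqrt(count_fraction * voxel_volume)`. The noise
#' amplitude is calibrated so that the liver coefficient of variation of the
#' smoothed image at full counts equals `cov_full`; halving counts twice
#' therefore doubles the percentage noise. A tumour-load "sink" term lowers
#' the effective liver uptake via [effective_liver_suv()].
#'
#' `shape` and `voxel_mm` define the physical field of view; the image itself
#' is generated on the grid of `recon`, resampled to cover the same field of
#' view. `liver_margin_mm` erodes the liver ellipsoid for the reported
#' homogeneous-liver mask so that noise statistics are measured away from the
#' blurred organ boundary, as a reader placing a VOI in uniform liver would.
#'
#' @param shape voxel counts per axis of the nominal grid.
#' @param voxel_mm spacing of the nominal grid (mm).
#' @param liver_center_mm liver centre (mm); default: centre of the volume.
#' @param liver_semiaxes_mm liver ellipsoid semi-axes (mm).
#' @param liver_suv true liver uptake before any sink adjustment.
#' @param background_suv surrounding soft-tissue uptake.
#' @param tumors list of tumours, each `list(center_mm=, diameter_mm=, suv=)`.
#' @param cov_full target liver coefficient of variation at full counts.
#' @param count_fraction retained count fraction, in (0, 1].
#' @param recon a [recon_profile()].
#' @param sink_coeff dimensionless tumour-sink coefficient (>= 0).
#' @param liver_margin_mm erosion margin for the homogeneous-liver mask (mm).
#' @param seed integer RNG seed; same spec + same seed gives identical output.
#' @return A `phantom_spec` list.
#' @seealso [generate_phantom()], [paired_count_images()]
#' @export
phantom_spec <- function(shape = c(128, 128, 96),
                         voxel_mm = c(4, 4, 4),
                         liver_center_mm = NULL,
                         liver_semiaxes_mm = c(80, 60, 50),
                         liver_suv = 2.2,
                         background_suv = 0.8,
                         tumors = list(),
                         cov_full = 0.12,
                         count_fraction = 1,
                         recon = recon_profile("EARL1"),
                         sink_coeff = 0.3,
                         liver_margin_mm = 12,
                         seed = 1L) {
  shape <- as.integer(.as_len3(shape, "shape"))
  voxel_mm <- .as_len3(voxel_mm, "voxel_mm")
  if (any(shape < 1L)) .err("shape must be >= 1", "petliver_argument_error")
  if (any(voxel_mm <= 0)) .err("spacings must be > 0", "petliver_argument_error")
  fov <- shape * voxel_mm
  if (is.null(liver_center_mm)) liver_center_mm <- fov / 2
  liver_center_mm <- .as_len3(liver_center_mm, "liver_center_mm")
  liver_semiaxes_mm <- .as_len3(liver_semiaxes_mm, "liver_semiaxes_mm")
  if (any(liver_semiaxes_mm <= 0))
    .err("liver semi-axes must be > 0", "petliver_argument_error")
  if (any(liver_center_mm - liver_semiaxes_mm < 0) ||
      any(liver_center_mm + liver_semiaxes_mm > fov))
    .err("liver ellipsoid extends outside the image bounds",
         "petliver_geometry_error")
  if (liver_suv <= 0 || background_suv < 0)
    .err("uptake values must be positive", "petliver_argument_error")
  if (!(count_fraction > 0 && count_fraction <= 1))
    .err("count_fraction must be in (0, 1]", "petliver_argument_error")
  if (cov_full < 0) .err("cov_full must be >= 0", "petliver_argument_error")
  if (sink_coeff < 0) .err("sink_coeff must be >= 0", "petliver_argument_error")
  if (!inherits(recon, "recon_profile"))
    .err("`recon` must be a recon_profile", "petliver_argument_error")
  if (liver_margin_mm < 0 || liver_margin_mm >= min(liver_semiaxes_mm))
    .err("liver_margin_mm must be in [0, min semi-axis)",
         "petliver_argument_error")
  for (tm in tumors) {
    if (!all(c("center_mm", "diameter_mm", "suv") %in% names(tm)))
      .err("each tumour needs center_mm, diameter_mm and suv",
           "petliver_argument_error")
    if (tm$diameter_mm <= 0 || tm$suv <= 0)
      .err("tumour diameter and suv must be > 0", "petliver_argument_error")
  }
  structure(list(shape = shape, voxel_mm = voxel_mm,
                 liver_center_mm = liver_center_mm,
                 liver_semiaxes_mm = liver_semiaxes_mm,
                 liver_suv = liver_suv, background_suv = background_suv,
                 tumors = tumors, cov_full = cov_full,
                 count_fraction = count_fraction, recon = recon,
                 sink_coeff = sink_coeff, liver_margin_mm = liver_margin_mm,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Effective liver uptake under tumour load
#'
#' Models the hypothesis that a large total metabolic tumour volume acts as a
#' sink for the tracer, depressing liver availability:
#' `base_suv / (1 + sink_coeff * mtv_ml / 1000)`. The form is a deliberately
#' simple stand-in, strictly decreasing in tumour load when `sink_coeff > 0`
#' and inert when the coefficient or the load is zero.
#'
#' @param base_suv liver uptake without tumour load (> 0).
#' @param mtv_ml total metabolic tumour volume in mL (>= 0).
#' @param sink_coeff dimensionless coefficient (>= 0).
#' @return Effective liver SUV.
#' @examples
#' effective_liver_suv(2.2, 0, 0.3)     # no tumour load: unchanged
#' effective_liver_suv(2.2, 1000, 0.3)  # 1 L of tumour: ~23% lower
#' @export
effective_liver_suv <- function(base_suv, mtv_ml, sink_coeff) {
  if (any(base_suv <= 0)) .err("base_suv must be > 0", "petliver_argument_error")
  if (any(mtv_ml < 0)) .err("mtv_ml must be >= 0", "petliver_argument_error")
  if (any(sink_coeff < 0)) .err("sink_coeff must be >= 0", "petliver_argument_error")
  base_suv / (1 + sink_coeff * mtv_ml / 1000)
}

# ---- internal scene construction -------------------------------------------

# grid actually used for image generation: same field of view, recon spacing
.phantom_grid <- function(spec) {
  fov <- spec$shape * spec$voxel_mm
  vox <- spec$recon$voxel_mm
  list(n = pmax(1L, as.integer(round(fov / vox))), voxel_mm = vox)
}

# noiseless SUV map, masks and analytic tumour volume for a spec
.phantom_scene <- function(spec) {
  g <- .phantom_grid(spec)
  n <- g$n; vox <- g$voxel_mm
  cx <- (seq_len(n[1]) - 0.5) * vox[1]
  cy <- (seq_len(n[2]) - 0.5) * vox[2]
  cz <- (seq_len(n[3]) - 0.5) * vox[3]

  true_mtv_ml <- sum(vapply(spec$tumors, function(tm)
    (4 / 3) * pi * (tm$diameter_mm / 2)^3 / 1000, numeric(1)))
  eff <- effective_liver_suv(spec$liver_suv, true_mtv_ml, spec$sink_coeff)

  ell <- function(semi) {
    ex <- ((cx - spec$liver_center_mm[1]) / semi[1])^2
    ey <- ((cy - spec$liver_center_mm[2]) / semi[2])^2
    ez <- ((cz - spec$liver_center_mm[3]) / semi[3])^2
    outer(outer(ex, ey, "+"), ez, "+") <= 1
  }
  liver_full <- ell(spec$liver_semiaxes_mm)
  liver_core <- ell(spec$liver_semiaxes_mm - spec$liver_margin_mm)

  map <- array(spec$background_suv, n)
  map[liver_full] <- eff

  tumor_mask <- array(FALSE, n)
  for (tm in spec$tumors) {
    dx2 <- (cx - tm$center_mm[1])^2
    dy2 <- (cy - tm$center_mm[2])^2
    dz2 <- (cz - tm$center_mm[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= (tm$diameter_mm / 2)^2
    map[inside] <- tm$suv
    tumor_mask <- tumor_mask | inside
  }
  liver_core <- liver_core & !tumor_mask

  list(grid = g, map = map, smoothed_map = NULL,
       liver_mask = liver_core, tumor_mask = tumor_mask,
       true_liver_suv = eff, true_mtv_ml = true_mtv_ml)
}

# analytic noise amplitude: after smoothing with a normalised separable
# kernel k, white noise of per-voxel sd s has sd s * ||k||_2 at interior
# voxels, so sigma0 has a closed form -- no iterative calibration needed
.calibrate_sigma0 <- function(spec, eff_suv) {
  g <- .phantom_grid(spec)
  if (spec$cov_full == 0) return(0)
  l2 <- .kernel_l2(g$voxel_mm, spec$recon$psf_fwhm_mm)
  spec$cov_full * eff_suv * sqrt(prod(g$voxel_mm)) / l2
}

# closure over a pre-smoothed scene: realising many replicates of one
# anatomy only pays the smoothing of the noise, not of the map
.phantom_stream <- function(spec, sigma0 = NULL) {
  scene <- .phantom_scene(spec)
  scene$smoothed_map <- .smooth3d(scene$map, scene$grid$voxel_mm,
                                  spec$recon$psf_fwhm_mm)
  if (is.null(sigma0)) sigma0 <- .calibrate_sigma0(spec, scene$true_liver_suv)
  function(seed, count_fraction = spec$count_fraction)
    .phantom_realize(scene, spec, count_fraction, seed, sigma0)
}

# one noisy realisation on top of a pre-smoothed scene
.phantom_realize <- function(scene, spec, count_fraction, seed, sigma0) {
  g <- scene$grid
  vals <- scene$smoothed_map
  if (sigma0 > 0) {
    set.seed(seed)
    sd_vox <- sigma0 / sqrt(count_fraction * prod(g$voxel_mm))
    noise <- array(stats::rnorm(prod(g$n), sd = sd_vox), g$n)
    vals <- vals + .smooth3d(noise, g$voxel_mm, spec$recon$psf_fwhm_mm)
  }
  vals[vals < 0] <- 0
  structure(list(
    image = suv_image(vals, g$voxel_mm),
    liver_mask = scene$liver_mask, tumor_mask = scene$tumor_mask,
    true_liver_suv = scene$true_liver_suv, true_mtv_ml = scene$true_mtv_ml,
    sigma0 = sigma0, count_fraction = count_fraction),
    class = "phantom_output")
}

#' Generate a synthetic liver phantom
#'
#' Realises a [phantom_spec()]: paints the noiseless SUV map (background,
#' liver at its sink-adjusted effective uptake, tumour spheres by voxel-centre
#' inclusion), adds white Gaussian noise with per-voxel standard deviation
#' `sigma0 / sqrt(count_fraction * voxel_volume)`, convolves with the
#' reconstruction profile's isotropic Gaussian, and clips negative voxels to
#' zero. `sigma0` is calibrated in closed form so that the post-smoothing
#' liver coefficient of variation at full counts equals `spec$cov_full`; it
#' can be overridden to hold the count-level noise fixed while the
#' reconstruction profile varies.
#'
#' The output is deterministic: the same spec (including its seed) always
#' produces a bit-identical image.
#'
#' @param spec a [phantom_spec()].
#' @param sigma0 optional noise amplitude override (SUV * mm^(3/2)).
#' @return A `phantom_output` list: `image` ([suv_image]), `liver_mask`
#'   (eroded homogeneous-liver voxels), `tumor_mask`, `true_liver_suv`
#'   (effective liver uptake after sink adjustment), `true_mtv_ml` (analytic
#'   tumour volume), `sigma0`, `count_fraction`.
#' @examples
#' ph <- generate_phantom(phantom_spec(shape = c(48, 48, 36),
#'                                     liver_semiaxes_mm = c(50, 40, 35),
#'                                     seed = 7))
#' liver_cov(ph)
#' @export
generate_phantom <- function(spec, sigma0 = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  .phantom_stream(spec, sigma0)(spec$seed)
}

#' Matched phantoms at several count fractions
#'
#' Emulates reconstructing one acquisition from subsets of its counts (for
#' example the full 120 s listmode data and only the first 30 s, i.e. 25% of
#' the counts): all outputs share a single noiseless anatomy and effective
#' liver uptake, and differ only in independent noise realisations whose
#' amplitude scales as `1 / sqrt(fraction)`.
#'
#' @param spec a [phantom_spec()]; its own `count_fraction` is ignored.
#' @param fractions numeric vector of count fractions in (0, 1].
#' @return List of `phantom_output`, one per fraction, in order.
#' @examples
#' sp <- phantom_spec(shape = c(48, 48, 36), liver_semiaxes_mm = c(50, 40, 35))
#' pr <- paired_count_images(sp, c(1, 0.25))
#' liver_cov(pr[[2]]) / liver_cov(pr[[1]])  # ~2
#' @export
paired_count_images <- function(spec, fractions) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (length(fractions) == 0)
    .err("`fractions` must not be empty", "petliver_argument_error")
  if (any(fractions <= 0 | fractions > 1))
    .err("all fractions must be in (0, 1]", "petliver_argument_error")
  stream <- .phantom_stream(spec)
  set.seed(spec$seed)
  seeds <- sample.int(.Machine$integer.max, length(fractions))
  lapply(seq_along(fractions), function(i) stream(seeds[i], fractions[i]))
}

#' Build a phantom specification from a JSON config file
#'
#' Reads a JSON object whose fields mirror the arguments of
#' [phantom_spec()]; `recon` may be given as a profile name or as an object
#' with `name`, `voxel_mm`, `psf_fwhm_mm`. Unknown fields are rejected so
#' typos in configs fail loudly.
#'
#' @param path JSON file path.
#' @return A `phantom_spec`.
#' @export
phantom_spec_from_json <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(phantom_spec))
  bad <- setdiff(names(cfg), known)
  if (length(bad))
    .err(sprintf("unknown phantom config fields: %s",
                 paste(bad, collapse = ", ")), "petliver_argument_error")
  if (!is.null(cfg$recon)) {
    cfg$recon <- if (is.character(cfg$recon)) recon_profile(cfg$recon)
                 else do.call(recon_profile, as.list(cfg$recon))
  }
  if (!is.null(cfg$tumors)) {
    if (is.data.frame(cfg$tumors))
      cfg$tumors <- lapply(seq_len(nrow(cfg$tumors)), function(i)
        list(center_mm = unlist(cfg$tumors$center_mm[i]),
             diameter_mm = cfg$tumors$diameter_mm[i],
             suv = cfg$tumors$suv[i]))
  }
  do.call(phantom_spec, cfg)
}

#' Liver coefficient of variation of a phantom
#'
#' Standard deviation over mean of the homogeneous-liver voxels — the
#' "percentage noise" of the liver region.
#'
#' @param output a `phantom_output` from [generate_phantom()].
#' @return CoV as a fraction.
#' @export
liver_cov <- function(output) {
  v <- output$image[output$liver_mask]
  stats::sd(v) / mean(v)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> FOV %s mm, recon %s (%g mm vox, FWHM %g mm)\n",
              paste(x$shape * x$voxel_mm, collapse = " x "),
              x$recon$name, x$recon$voxel_mm[1], x$recon$psf_fwhm_mm))
  cat(sprintf("  liver SUV %.2f (semi-axes %s mm), background %.2f, CoV %.2f @ f=%.2g\n",
              x$liver_suv, paste(x$liver_semiaxes_mm, collapse = "/"),
              x$background_suv, x$cov_full, x$count_fraction))
  cat(sprintf("  %d tumour(s), sink %.2f, seed %d\n",
              length(x$tumors), x$sink_coeff, x$seed))
  invisible(x)
}

#' @export
print.phantom_output <- function(x, ...) {
  cat(sprintf("<phantom_output> liver SUV %.3f (effective), MTV %.1f mL, f=%.2g\n",
              x$true_liver_suv, x$true_mtv_ml, x$count_fraction))
  print(x$image)
  invisible(x)
}

# ---- separable Gaussian smoothing ------------------------------------------

.gauss_kernel1d <- function(spacing, fwhm) {
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  h <- max(1L, as.integer(ceiling(4 * sigma / spacing)))
  x <- (-h:h) * spacing
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# L2 norm of the full separable 3-D kernel (interior voxels)
.kernel_l2 <- function(voxel_mm, fwhm) {
  sqrt(prod(vapply(1:3, function(a)
    sum(.gauss_kernel1d(voxel_mm[a], fwhm)^2), numeric(1))))
}

# dense banded convolution matrix with edge renormalisation
.smooth_matrix <- function(n, spacing, fwhm) {
  k <- .gauss_kernel1d(spacing, fwhm)
  h <- (length(k) - 1L) / 2L
  K <- matrix(0, n, n)
  for (d in -h:h) {
    i <- seq_len(n)
    j <- i + d
    ok <- j >= 1L & j <= n
    K[cbind(i[ok], j[ok])] <- k[d + h + 1L]
  }
  K / rowSums(K)
}

.smooth3d <- function(arr, voxel_mm, fwhm_mm) {
  d <- dim(arr)
  # axis 1
  K <- .smooth_matrix(d[1], voxel_mm[1], fwhm_mm)
  arr <- array(K %*% matrix(arr, d[1]), d)
  # axis 2
  arr <- aperm(arr, c(2, 1, 3))
  K <- .smooth_matrix(d[2], voxel_mm[2], fwhm_mm)
  arr <- array(K %*% matrix(arr, d[2]), dim(arr))
  arr <- aperm(arr, c(2, 1, 3))
  # axis 3
  arr <- aperm(arr, c(3, 2, 1))
  K <- .smooth_matrix(d[3], voxel_mm[3], fwhm_mm)
  arr <- array(K %*% matrix(arr, d[3]), dim(arr))
  aperm(arr, c(3, 2, 1))
}
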