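#' Spherical volume of interest
#'
#' A sphere defined in the physical (mm) frame, independent of any image
#' grid. Rasterisation onto a grid uses voxel-centre inclusion: a voxel
#' belongs to the sphere iff its centre lies within the radius.
#'
#' @param center_mm sphere centre (mm), length 3.
#' @param diameter_mm sphere diameter (mm), > 0.
#' @return A `spherical_voi` list.
#' @examples
#' spherical_voi(c(100, 100, 100), 30)
#' @export
spherical_voi <- function(center_mm, diameter_mm) {
  center_mm <- .as_len3(center_mm, "center_mm")
  if (!is.numeric(diameter_mm) || length(diameter_mm) != 1L || diameter_mm <= 0)
    .err("diameter_mm must be a single value > 0", "petliver_argument_error")
  structure(list(center_mm = center_mm, diameter_mm = as.numeric(diameter_mm)),
            class = "spherical_voi")
}

#' @export
print.spherical_voi <- function(x, ...) {
  cat(sprintf("<spherical_voi> d = %g mm at (%s) mm\n", x$diameter_mm,
              paste(format(x$center_mm), collapse = ", ")))
  invisible(x)
}

#' Rasterise a spherical VOI onto an image grid
#'
#' @param image an [suv_image].
#' @param voi a [spherical_voi].
#' @return Logical array of the image's dimensions; `TRUE` where the voxel
#'   centre lies within the sphere. Errors if no voxel centre falls inside.
#' @examples
#' img <- suv_image(array(2, c(16, 16, 16)), 4)
#' sum(voi_mask(img, spherical_voi(c(32, 32, 32), 30)))
#' @export
voi_mask <- function(image, voi) {
  stopifnot(inherits(voi, "spherical_voi"))
  r <- voi$diameter_mm / 2
  d <- dim(image)
  mask <- array(FALSE, d)
  idx <- lapply(1:3, function(a) {
    cc <- .axis_centers(image, a)
    which(abs(cc - voi$center_mm[a]) <= r)
  })
  if (any(lengths(idx) == 0L))
    .err("spherical VOI contains no voxel centre", "petliver_empty_voi")
  sq <- lapply(1:3, function(a)
    (.axis_centers(image, a)[idx[[a]]] - voi$center_mm[a])^2)
  inside <- outer(outer(sq[[1]], sq[[2]], "+"), sq[[3]], "+") <= r^2
  if (!any(inside))
    .err("spherical VOI contains no voxel centre", "petliver_empty_voi")
  mask[idx[[1]], idx[[2]], idx[[3]]] <- inside
  mask
}

#' Maximum SUV within a mask
#' @param image an [suv_image].
#' @param mask logical array of matching dimensions.
#' @return SUVmax over the masked voxels.
#' @export
suv_max <- function(image, mask) {
  .check_mask(image, mask)
  max(image[mask])
}

#' Mean SUV within a mask
#' @inheritParams suv_max
#' @return SUVmean over the masked voxels.
#' @export
suv_mean <- function(image, mask) {
  .check_mask(image, mask)
  mean(image[mask])
}

.check_mask <- function(image, mask) {
  if (!is.logical(mask) || !identical(dim(mask), dim(image)))
    .err("mask must be a logical array matching the image",
         "petliver_argument_error")
  if (!any(mask)) .err("mask selects no voxels", "petliver_empty_voi")
}

#' Peak SUV: maximum 1-mL sphere mean
#'
#' SUVpeak following the EANM convention: over candidate placements of a
#' sphere of fixed volume (1 mL by default, radius about 6.2 mm), the maximum
#' of the mean SUV within the sphere. Candidate centres are the voxel centres
#' inside the search region; for each, the peak sphere is rasterised by
#' voxel-centre inclusion. The sphere may extend beyond the search region but
#' must stay inside the image; candidates whose sphere would leave the image
#' are skipped. Ties resolve to the first candidate in linear index order, so
#' the result is deterministic.
#'
#' @param image an [suv_image].
#' @param search a [spherical_voi] delimiting candidate centres.
#' @param peak_volume_ml volume of the averaging sphere in mL.
#' @return SUVpeak value.
#' @examples
#' img <- suv_image(array(2, c(20, 20, 20)), 4)
#' suv_peak(img, spherical_voi(c(40, 40, 40), 30))  # homogeneous: 2
#' @export
suv_peak <- function(image, search, peak_volume_ml = 1.0) {
  stopifnot(inherits(search, "spherical_voi"))
  if (peak_volume_ml <= 0)
    .err("peak_volume_ml must be > 0", "petliver_argument_error")
  r_pk <- (3 * peak_volume_ml * 1000 / (4 * pi))^(1 / 3)
  vox <- attr(image, "voxel_mm")
  d <- dim(image)

  cand <- which(voi_mask(image, search))           # linear, ascending
  cij <- arrayInd(cand, d)

  # integer offsets of the peak-sphere rasterisation, shared by all
  # candidates because candidate centres sit on the voxel lattice
  hw <- floor(r_pk / vox)
  off <- as.matrix(expand.grid(-hw[1]:hw[1], -hw[2]:hw[2], -hw[3]:hw[3]))
  off <- off[colSums((t(off) * vox)^2) <= r_pk^2, , drop = FALSE]

  lo <- apply(off, 2, min); hi <- apply(off, 2, max)
  ok <- cij[, 1] + lo[1] >= 1L & cij[, 1] + hi[1] <= d[1] &
        cij[, 2] + lo[2] >= 1L & cij[, 2] + hi[2] <= d[2] &
        cij[, 3] + lo[3] >= 1L & cij[, 3] + hi[3] <= d[3]
  if (!any(ok))
    .err("no admissible SUVpeak candidate: peak sphere never fits inside the image",
         "petliver_empty_voi")
  cand <- cand[ok]

  doff <- off[, 1] + off[, 2] * d[1] + off[, 3] * d[1] * d[2]
  means <- rowMeans(matrix(image[rep(cand, times = length(doff)) +
                                 rep(doff, each = length(cand))],
                           nrow = length(cand)))
  means[which.max(means)]
}

#' Extract all liver uptake metrics for one VOI
#'
#' Bundles SUVmax, SUVpeak (searched within the VOI) and SUVmean with the
#' rasterised voxel count and volume.
#'
#' @inheritParams suv_peak
#' @param voi a [spherical_voi].
#' @return An `uptake_metrics` list: `suv_max`, `suv_peak`, `suv_mean`,
#'   `n_voxels`, `voi_volume_ml`.
#' @examples
#' img <- suv_image(array(2.2, c(24, 24, 24)), 4)
#' extract_metrics(img, spherical_voi(c(48, 48, 48), 30))
#' @export
extract_metrics <- function(image, voi, peak_volume_ml = 1.0) {
  mask <- voi_mask(image, voi)
  structure(list(
    suv_max = suv_max(image, mask),
    suv_peak = suv_peak(image, voi, peak_volume_ml),
    suv_mean = suv_mean(image, mask),
    n_voxels = sum(mask),
    voi_volume_ml = sum(mask) * voxel_volume_ml(image)),
    class = "uptake_metrics")
}

#' @export
print.uptake_metrics <- function(x, ...) {
  cat(sprintf("<uptake_metrics> SUVmax %.3f | SUVpeak %.3f | SUVmean %.3f (%d voxels, %.2f mL)\n",
              x$suv_max, x$suv_peak, x$suv_mean, x$n_voxels, x$voi_volume_ml))
  invisible(x)
}
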