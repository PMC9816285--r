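#' 3-D SUV image
#'
#' Container for a 3-D grid of standardised uptake values (or, before
#' conversion, activity concentration in Bq/mL) together with its voxel
#' spacing and physical origin. All geometry in the package is expressed in
#' millimetres; the centre of voxel `(i, j, k)` (1-based indices) sits at
#' `origin_mm + (c(i, j, k) - 0.5) * voxel_mm`.
#'
#' @param values numeric 3-D array; finite, non-negative.
#' @param voxel_mm voxel spacing per axis in mm (length 1 or 3, all > 0).
#' @param origin_mm physical position (mm) of the outer corner of the first
#'   voxel; defaults to `c(0, 0, 0)`.
#' @return An object of class `suv_image`: the array with `voxel_mm` and
#'   `origin_mm` attributes.
#' @examples
#' img <- suv_image(array(2, c(8, 8, 8)), voxel_mm = 4)
#' voxel_volume_ml(img)
#' @export
suv_image <- function(values, voxel_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    .err("`values` must be a 3-D array", "petliver_argument_error")
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    .err("image values must be finite numbers", "petliver_argument_error")
  if (any(values < 0))
    .err("image values must be non-negative", "petliver_argument_error")
  voxel_mm <- .as_len3(voxel_mm, "voxel_mm")
  origin_mm <- .as_len3(origin_mm, "origin_mm")
  if (any(voxel_mm <= 0))
    .err("voxel spacings must be > 0", "petliver_argument_error")
  structure(values, voxel_mm = voxel_mm, origin_mm = origin_mm,
            class = c("suv_image", "array"))
}

#' @export
print.suv_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<suv_image> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3],
              paste(format(attr(x, "voxel_mm")), collapse = " x ")))
  cat(sprintf("  value range [%.3g, %.3g], origin (%s) mm\n",
              min(x), max(x),
              paste(format(attr(x, "origin_mm")), collapse = ", ")))
  invisible(x)
}

#' Voxel volume of an image in millilitres
#'
#' @param image an [suv_image].
#' @return Volume of one voxel in mL.
#' @export
voxel_volume_ml <- function(image) {
  prod(attr(image, "voxel_mm")) / 1000
}

# physical coordinates (mm) of voxel centres along one axis
.axis_centers <- function(image, axis) {
  n <- dim(image)[axis]
  attr(image, "origin_mm")[axis] +
    (seq_len(n) - 0.5) * attr(image, "voxel_mm")[axis]
}

.as_len3 <- function(x, name) {
  if (!is.numeric(x) || !(length(x) %in% c(1L, 3L)) || anyNA(x))
    .err(sprintf("`%s` must be numeric of length 1 or 3", name),
         "petliver_argument_error")
  if (length(x) == 1L) rep(as.numeric(x), 3L) else as.numeric(x)
}

# classed conditions so callers can distinguish geometry/argument/VOI errors
.err <- function(msg, class) {
  stop(structure(class = c(class, "petliver_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
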