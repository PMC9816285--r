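#' Acquisition metadata for SUV conversion
#'
#' The quantities needed to convert an activity-concentration image (Bq/mL)
#' into body-weight standardised uptake values: patient weight, injected
#' activity at injection time, the uptake interval between injection and
#' scan start, and the tracer half-life (fluorine-18 by default). Errors in
#' weight or injected activity propagate directly into every SUV, which is
#' why liver SUV is used as a per-scan quality check.
#'
#' @param body_weight_kg patient weight (kg).
#' @param injected_activity_MBq injected activity at injection time (MBq).
#' @param injection_to_scan_min uptake interval (minutes).
#' @param half_life_min isotope half-life (minutes); 109.77 for 18F.
#' @return An `acquisition_meta` list.
#' @export
acquisition_meta <- function(body_weight_kg, injected_activity_MBq,
                             injection_to_scan_min, half_life_min = 109.77) {
  vals <- c(body_weight_kg, injected_activity_MBq, injection_to_scan_min,
            half_life_min)
  if (!is.numeric(vals) || length(vals) != 4L || anyNA(vals) || any(vals <= 0))
    .err("all acquisition metadata fields must be strictly positive",
         "petliver_argument_error")
  structure(list(body_weight_kg = body_weight_kg,
                 injected_activity_MBq = injected_activity_MBq,
                 injection_to_scan_min = injection_to_scan_min,
                 half_life_min = half_life_min),
            class = "acquisition_meta")
}

#' Radioactive decay factor
#'
#' Fraction of activity remaining after `delta_min` minutes:
#' `2^(-delta_min / half_life_min)`.
#'
#' @param delta_min elapsed time (minutes), >= 0.
#' @param half_life_min half-life (minutes), > 0.
#' @return Dimensionless decay factor in (0, 1].
#' @examples
#' decay_factor(109.77, 109.77)  # one half-life: 0.5
#' @export
decay_factor <- function(delta_min, half_life_min = 109.77) {
  if (half_life_min <= 0) .err("half_life_min must be > 0",
                               "petliver_argument_error")
  if (any(delta_min < 0)) .err("delta_min must be >= 0",
                               "petliver_argument_error")
  2^(-delta_min / half_life_min)
}

#' Convert activity concentration to body-weight SUV
#'
#' `SUV = C / (decayed dose per gram)` where the decayed dose is the injected
#' activity corrected to scan start and tissue density is taken as 1 g/mL so
#' grams and millilitres coincide:
#' `SUV(v) = C(v) * body_weight_kg * 1000 / (injected_MBq * 1e6 * decay)`.
#'
#' @param activity_image an [suv_image] holding activity concentration
#'   (Bq/mL).
#' @param meta an [acquisition_meta()].
#' @return An [suv_image] of dimensionless SUV.
#' @seealso [suv_to_activity()] for the inverse.
#' @export
activity_to_suv <- function(activity_image, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  dose_per_g <- .dose_per_gram(meta)
  suv_image(unclass(activity_image) / dose_per_g,
            attr(activity_image, "voxel_mm"),
            attr(activity_image, "origin_mm"))
}

#' Convert SUV back to activity concentration
#' @param suv an [suv_image] of SUV values.
#' @inheritParams activity_to_suv
#' @return An [suv_image] holding Bq/mL.
#' @export
suv_to_activity <- function(suv, meta) {
  stopifnot(inherits(meta, "acquisition_meta"))
  suv_image(unclass(suv) * .dose_per_gram(meta),
            attr(suv, "voxel_mm"), attr(suv, "origin_mm"))
}

.dose_per_gram <- function(meta) {
  meta$injected_activity_MBq * 1e6 *
    decay_factor(meta$injection_to_scan_min, meta$half_life_min) /
    (meta$body_weight_kg * 1000)
}

#' Write an SUV image as NIfTI with a JSON sidecar
#'
#' Values, spacing and origin are stored losslessly in a NIfTI-1 file
#' (float64). A JSON sidecar `<name>.json` records acquisition metadata and
#' any provenance the caller supplies (for phantoms: generation parameters
#' and seed).
#'
#' @param image an [suv_image].
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @param meta optional [acquisition_meta()].
#' @param provenance optional list serialised verbatim into the sidecar.
#' @return `path`, invisibly.
#' @export
write_suv_image <- function(image, path, meta = NULL, provenance = NULL) {
  vox <- attr(image, "voxel_mm")
  origin <- attr(image, "origin_mm")
  nii <- RNifti::asNifti(unclass(image))
  RNifti::pixdim(nii) <- vox
  aff <- diag(c(vox, 1))
  aff[1:3, 4] <- origin + 0.5 * vox   # NIfTI maps 0-based index to centre
  attr(aff, "code") <- 2L
  nii <- RNifti::`qform<-`(nii, value = aff)
  nii <- RNifti::`sform<-`(nii, value = aff)
  RNifti::writeNifti(nii, path)
  side <- .sidecar_path(path)
  payload <- list(units = "SUV")
  if (!is.null(meta)) payload$acquisition <- unclass(meta)
  if (!is.null(provenance)) payload$provenance <- provenance
  jsonlite::write_json(payload, side, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an SUV (or activity) image from NIfTI
#'
#' Restores values, spacing and origin; only axis-aligned orientations with
#' positive spacings are accepted. If the JSON sidecar is present its
#' acquisition metadata is attached as the `"meta"` attribute; without a
#' sidecar the image is accepted as already being in SUV units and flagged
#' with attribute `"units_assumed" = TRUE`. With `convert = TRUE` the voxel
#' values are treated as Bq/mL and converted through the sidecar metadata,
#' which must then be present.
#'
#' @param path NIfTI file path.
#' @param convert convert activity concentration to SUV using the sidecar.
#' @return An [suv_image].
#' @export
read_suv_image <- function(path, convert = FALSE) {
  if (!file.exists(path))
    .err(sprintf("file not found: %s", path), "petliver_io_error")
  nii <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    .err(sprintf("malformed NIfTI: %s (%s)", path,
                                 conditionMessage(e)), "petliver_io_error"))
  vox <- RNifti::pixdim(nii)
  if (length(vox) != 3L || any(!is.finite(vox)) || any(vox <= 0))
    .err(sprintf("invalid voxel spacing in %s", path), "petliver_io_error")
  x <- RNifti::xform(nii)
  if (max(abs(x[1:3, 1:3] - diag(vox))) > 1e-4)
    .err(sprintf("unsupported (non axis-aligned) orientation in %s", path),
         "petliver_io_error")
  origin <- x[1:3, 4] - 0.5 * vox
  img <- suv_image(array(as.numeric(nii), dim(nii)), vox, origin)

  side <- .sidecar_path(path)
  meta <- NULL
  if (file.exists(side)) {
    payload <- jsonlite::read_json(side, simplifyVector = TRUE)
    if (!is.null(payload$acquisition))
      meta <- do.call(acquisition_meta, payload$acquisition)
    attr(img, "meta") <- meta
  } else {
    attr(img, "units_assumed") <- TRUE
  }
  if (convert) {
    if (is.null(meta))
      .err(sprintf("conversion requested but no acquisition sidecar for %s",
                   path), "petliver_io_error")
    img <- activity_to_suv(img, meta)
    attr(img, "meta") <- meta
  }
  img
}

.sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}
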