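#' Liver SUV quality-control check
#'
#' EANM-style per-scan sanity check: the mean SUV of a 3-cm spherical VOI
#' placed in homogeneous liver is expected to fall between SUV 1.3 and 3.0.
#' Values outside that range may indicate errors in the recorded patient
#' weight or injected activity, or a scanner calibration or reconstruction
#' deviation. Bounds are inclusive: a value exactly on a limit passes.
#'
#' @param image an [suv_image] in SUV units.
#' @param center_mm VOI centre (mm) inside homogeneous liver.
#' @param diameter_mm VOI diameter (mm); 30 per the guideline.
#' @param low,high acceptance bounds (SUV).
#' @return A `qc_report` list: `suv_mean`, `low`, `high`, `status`
#'   (`"pass"` or `"flag"`), `message`.
#' @examples
#' img <- suv_image(array(2.2, c(24, 24, 24)), 4)
#' qc_liver(img, center_mm = c(48, 48, 48))
#' @export
qc_liver <- function(image, center_mm, diameter_mm = 30,
                     low = 1.3, high = 3.0) {
  voi <- spherical_voi(center_mm, diameter_mm)
  sm <- suv_mean(image, voi_mask(image, voi))
  qc_decision(sm, low, high)
}

#' QC decision from a measured liver SUVmean
#'
#' Pure decision rule behind [qc_liver()]: pass iff `low <= suv_mean <= high`.
#'
#' @param suv_mean measured liver mean SUV.
#' @param low,high inclusive acceptance bounds.
#' @return A `qc_report` list.
#' @export
qc_decision <- function(suv_mean, low = 1.3, high = 3.0) {
  if (low > high) .err("low must be <= high", "petliver_argument_error")
  pass <- suv_mean >= low && suv_mean <= high
  msg <- if (pass) {
    sprintf("liver SUVmean %.2f within [%.2f, %.2f]", suv_mean, low, high)
  } else {
    sprintf(paste("liver SUVmean %.2f outside [%.2f, %.2f]: check patient",
                  "weight, injected activity and scanner calibration/",
                  "reconstruction settings"), suv_mean, low, high)
  }
  structure(list(suv_mean = suv_mean, low = low, high = high,
                 status = if (pass) "pass" else "flag", message = msg),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: %s\n", toupper(x$status), x$message))
  invisible(x)
}
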