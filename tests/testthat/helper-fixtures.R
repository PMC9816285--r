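# Compact phantoms keep simulation-heavy tests fast while preserving the
# statistical structure (homogeneous liver interior >= 500 mask voxels,
# reconstruction-correlated noise).

compact_spec <- function(...) {
  args <- list(shape = c(64, 64, 48), liver_semiaxes_mm = c(60, 45, 40),
               liver_margin_mm = 10, seed = 1L)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

tiny_spec <- function(...) {
  args <- list(shape = c(32, 32, 24), liver_semiaxes_mm = c(40, 30, 25),
               liver_margin_mm = 8, seed = 1L)
  do.call(phantom_spec, utils::modifyList(args, list(...)))
}

# offsets scaled so a 3 cm VOI stays inside the compact liver
compact_offsets <- function() {
  rbind(A = c(0, 0, 0), B = c(25, 0, 0), C = c(-25, 0, 0),
        D = c(0, 18, 0), E = c(0, 0, -15))
}

random_image <- function(n = 20, voxel_mm = 4, seed = 1, lo = 1, hi = 5) {
  set.seed(seed)
  suv_image(array(stats::runif(n^3, lo, hi), c(n, n, n)), voxel_mm)
}

# ---- independent brute-force oracles ---------------------------------------
# These deliberately recompute everything per voxel on the full grid, with
# none of the bounding-box / shared-offset machinery of the implementation.

.grid_coords <- function(image) {
  d <- dim(image)
  vox <- attr(image, "voxel_mm"); org <- attr(image, "origin_mm")
  idx <- arrayInd(seq_len(prod(d)), d)
  cbind(org[1] + (idx[, 1] - 0.5) * vox[1],
        org[2] + (idx[, 2] - 0.5) * vox[2],
        org[3] + (idx[, 3] - 0.5) * vox[3])
}

bf_sphere_members <- function(image, center_mm, diameter_mm) {
  xyz <- .grid_coords(image)
  d2 <- (xyz[, 1] - center_mm[1])^2 + (xyz[, 2] - center_mm[2])^2 +
        (xyz[, 3] - center_mm[3])^2
  which(d2 <= (diameter_mm / 2)^2)
}

bf_suv_peak <- function(image, search_center, search_diameter,
                        peak_volume_ml = 1.0) {
  d <- dim(image)
  xyz <- .grid_coords(image)
  idx <- arrayInd(seq_len(prod(d)), d)
  r_pk <- (3 * peak_volume_ml * 1000 / (4 * pi))^(1 / 3)
  vox <- attr(image, "voxel_mm")
  # the widest single-axis reach of a voxel-centre sphere of radius r_pk
  hw <- floor(r_pk / vox)
  cand <- bf_sphere_members(image, search_center, search_diameter)
  vals <- as.vector(unclass(image))
  best <- -Inf
  for (ci in cand) {
    if (any(idx[ci, ] - hw < 1) || any(idx[ci, ] + hw > d)) next
    ctr <- xyz[ci, ]
    mem <- (xyz[, 1] - ctr[1])^2 + (xyz[, 2] - ctr[2])^2 +
           (xyz[, 3] - ctr[3])^2 <= r_pk^2
    best <- max(best, mean(vals[mem]))
  }
  best
}
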