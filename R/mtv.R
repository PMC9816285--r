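#' Fixed-threshold metabolic tumour volume segmentation
#'
#' Segments metabolic tumour volume with the fixed SUV 4.0 threshold: voxels
#' with SUV greater than or equal to the threshold are selected (the boundary
#' value is included), grouped into connected components at the requested
#' 3-D connectivity, and optionally filtered by a minimum component volume.
#' Volumes are voxel counts times voxel volume.
#'
#' @param image an [suv_image].
#' @param threshold SUV threshold; voxels `>= threshold` are selected.
#' @param connectivity 6 (faces), 18 (faces + edges) or 26 (full
#'   neighbourhood); default 26.
#' @param min_component_ml drop components smaller than this volume (mL).
#' @return An `mtv_result` list: `mask` (logical array after filtering),
#'   `total_ml`, and `components`, a data frame with `label`, `volume_ml`
#'   and `suv_max` per component. Labels follow first-encounter order in
#'   linear index scan, so results are deterministic. An empty segmentation
#'   (`total_ml = 0`) is a valid result.
#' @examples
#' a <- array(2, c(10, 10, 10)); a[4:6, 4:6, 4:6] <- 8
#' segment_mtv(suv_image(a, 4))$total_ml  # 27 voxels * 0.064 mL
#' @export
segment_mtv <- function(image, threshold = 4.0, connectivity = 26,
                        min_component_ml = 0) {
  if (threshold <= 0) .err("threshold must be > 0", "petliver_argument_error")
  if (!connectivity %in% c(6, 18, 26))
    .err("connectivity must be 6, 18 or 26", "petliver_argument_error")
  d <- dim(image)
  sel <- image >= threshold
  vv <- voxel_volume_ml(image)

  labels <- .label_components(sel, connectivity)
  n_comp <- max(labels, 0L)
  if (n_comp == 0L) {
    return(structure(list(mask = array(FALSE, d), total_ml = 0,
                          components = data.frame(label = integer(),
                                                  volume_ml = numeric(),
                                                  suv_max = numeric())),
                     class = "mtv_result"))
  }
  counts <- tabulate(labels, n_comp)
  keep <- which(counts * vv >= min_component_ml)

  mask <- array(FALSE, d)
  comps <- data.frame(label = integer(), volume_ml = numeric(),
                      suv_max = numeric())
  new_lab <- 0L
  for (lab in keep) {
    vox <- labels == lab
    new_lab <- new_lab + 1L
    mask[vox] <- TRUE
    comps <- rbind(comps, data.frame(label = new_lab,
                                     volume_ml = counts[lab] * vv,
                                     suv_max = max(image[vox])))
  }
  structure(list(mask = mask, total_ml = sum(mask) * vv, components = comps),
            class = "mtv_result")
}

#' @export
print.mtv_result <- function(x, ...) {
  cat(sprintf("<mtv_result> total MTV %.2f mL in %d component(s)\n",
              x$total_ml, nrow(x$components)))
  if (nrow(x$components)) print(x$components)
  invisible(x)
}

# neighbourhood offsets for a 3-D connectivity level
.conn_offsets <- function(connectivity) {
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nn <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6" = nn == 1, "18" = nn >= 1 & nn <= 2, "26" = nn >= 1)
  off[keep, , drop = FALSE]
}

# breadth-first connected-component labelling on a logical 3-D array;
# frontier expansion is vectorised over the whole frontier at once
.label_components <- function(sel, connectivity) {
  d <- dim(sel)
  labels <- array(0L, d)
  todo <- which(sel)
  if (length(todo) == 0L) return(labels)
  off <- .conn_offsets(connectivity)
  lab <- 0L
  for (seed in todo) {
    if (labels[seed] != 0L) next
    lab <- lab + 1L
    labels[seed] <- lab
    frontier <- matrix(arrayInd(seed, d), ncol = 3)
    while (nrow(frontier) > 0L) {
      nb <- frontier[rep(seq_len(nrow(frontier)), each = nrow(off)), ,
                     drop = FALSE] +
            off[rep(seq_len(nrow(off)), times = nrow(frontier)), ,
                drop = FALSE]
      ok <- nb[, 1] >= 1L & nb[, 1] <= d[1] &
            nb[, 2] >= 1L & nb[, 2] <= d[2] &
            nb[, 3] >= 1L & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- unique(nb[, 1] + (nb[, 2] - 1L) * d[1] +
                    (nb[, 3] - 1L) * d[1] * d[2])
      lin <- lin[sel[lin] & labels[lin] == 0L]
      labels[lin] <- lab
      frontier <- arrayInd(lin, d)
    }
  }
  labels
}
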