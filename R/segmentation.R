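#' Subtract a scalar background from an intensity image
#'
#' Quantitative paths use the image median as the background estimate; the
#' mean over a user-supplied empty region is available as an alternative.
#' No smoothing is applied: median filtering is a display aid only and is
#' excluded from all quantitative measurements.
#'
#' @param image Numeric matrix, finite.
#' @param method `"median"` (default) or `"mean-of-region"`.
#' @param empty_region For `"mean-of-region"`: integer vector
#'   `c(row_min, row_max, col_min, col_max)` of a background rectangle.
#' @return Matrix `pmax(image - b, 0)`; the scalar `b` is attached as
#'   attribute `"background"`.
#' @export
subtract_background <- function(image, method = c("median", "mean-of-region"),
                                empty_region = NULL) {
  method <- match.arg(method)
  stopifnot(is.matrix(image), all(is.finite(image)))
  if (method == "median") {
    b <- median(image)
  } else {
    if (is.null(empty_region) || length(empty_region) != 4) {
      abort("mean-of-region needs empty_region = c(row_min, row_max, col_min, col_max)")
    }
    r <- empty_region
    if (r[1] < 1 || r[3] < 1 || r[2] > nrow(image) || r[4] > ncol(image) ||
      r[1] > r[2] || r[3] > r[4]) {
      abort("empty_region lies outside the image")
    }
    b <- mean(image[r[1]:r[2], r[3]:r[4]])
  }
  out <- pmax(image - b, 0)
  attr(out, "background") <- b
  out
}

#' Segment cells on the receptor channel
#'
#' Otsu threshold (or a fixed threshold) on the background-subtracted
#' receptor image, hole filling (cells must be solid for the erosion
#' partition), connected-component labeling and an area filter.
#' Border-touching components are flagged and, by default, excluded.
#'
#' @param receptor Background-subtracted receptor matrix.
#' @param min_area_px Minimum component area in pixels.
#' @param threshold_method `"otsu"` or `"fixed"`.
#' @param threshold Intensity threshold when `threshold_method = "fixed"`.
#' @param exclude_border Drop border-touching cells (default `TRUE`).
#' @return List: `labels` (integer matrix, 0 = background; retained cells
#'   only) and `cells`, a tibble with `cell_id`, `area_px`,
#'   `border_touching`, `retained`.
#' @export
segment_cells <- function(receptor, min_area_px = 200,
                          threshold_method = c("otsu", "fixed"),
                          threshold = NULL, exclude_border = TRUE) {
  threshold_method <- match.arg(threshold_method)
  stopifnot(is.matrix(receptor), all(is.finite(receptor)))
  empty <- list(
    labels = matrix(0L, nrow(receptor), ncol(receptor)),
    cells = tibble(
      cell_id = integer(), area_px = integer(),
      border_touching = logical(), retained = logical()
    )
  )
  rng <- range(receptor)
  if (rng[1] == rng[2]) {
    if (rng[1] > 0) warn("constant image: threshold undefined, returning zero cells")
    return(empty)
  }
  if (threshold_method == "otsu") {
    scaled <- receptor / rng[2]
    thr <- EBImage::otsu(EBImage::Image(scaled), range = c(0, 1)) * rng[2]
  } else {
    if (is.null(threshold)) abort("fixed thresholding needs `threshold`")
    thr <- threshold
  }
  bw <- receptor > thr
  if (!any(bw)) {
    return(empty)
  }
  filled <- EBImage::fillHull(EBImage::Image(bw * 1)) > 0.5
  labels_all <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(filled * 1)))
  labels_all <- matrix(as.integer(round(labels_all)), nrow(receptor), ncol(receptor))
  n <- max(labels_all)
  if (n == 0) {
    return(empty)
  }
  area <- tabulate(labels_all[labels_all > 0], nbins = n)
  on_border <- rep(FALSE, n)
  edge <- unique(c(
    labels_all[1, ], labels_all[nrow(labels_all), ],
    labels_all[, 1], labels_all[, ncol(labels_all)]
  ))
  on_border[edge[edge > 0]] <- TRUE
  keep <- area >= min_area_px & (!exclude_border | !on_border)
  # relabel retained components 1..k in original order
  new_id <- integer(n)
  new_id[keep] <- seq_len(sum(keep))
  labels <- matrix(0L, nrow(receptor), ncol(receptor))
  pos <- labels_all > 0
  labels[pos] <- new_id[labels_all[pos]]
  cells <- tibble(
    cell_id = ifelse(keep, new_id, NA_integer_),
    area_px = as.integer(area),
    border_touching = on_border,
    retained = keep
  )
  list(labels = labels, cells = cells)
}

# structuring-element neighbourhood offsets
se_offsets <- function(connectivity) {
  if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0, 0), c(0, 0, -1, 1, 0))
  } else {
    as.matrix(expand.grid(dr = -1:1, dc = -1:1))
  }
}

# one erosion step with the given connectivity; pixels outside the image are
# treated as background (so the mask is peeled at the field edge too)
erode_once <- function(mask, connectivity) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  out <- mask
  for (k in seq_len(nrow(se_offsets(connectivity)))) {
    off <- se_offsets(connectivity)[k, ]
    shifted <- matrix(FALSE, nr, nc)
    r_src <- max(1, 1 + off[1]):min(nr, nr + off[1])
    c_src <- max(1, 1 + off[2]):min(nc, nc + off[2])
    shifted[r_src - off[1], c_src - off[2]] <- mask[r_src, c_src]
    out <- out & shifted
  }
  out
}

#' Binary erosion with alternating connectivity
#'
#' Erodes a mask `iterations` times, alternating the structuring element
#' between the 4-connected cross (odd iterations) and the 8-connected 3x3
#' square (even iterations). Alternating the two elements approximates a
#' disk better than either alone, which is why the membrane band peeled off
#' by the partition has near-uniform width. Pixels beyond the image edge
#' count as background.
#'
#' @param mask Logical matrix.
#' @param iterations Integer `>= 1`.
#' @param connectivity `"alternating"` (default), `"four"` or `"eight"`.
#' @return Logical matrix, a subset of `mask`.
#' @export
erode_alternating <- function(mask, iterations,
                              connectivity = c("alternating", "four", "eight")) {
  connectivity <- match.arg(connectivity)
  stopifnot(is.matrix(mask), is.logical(mask))
  if (iterations < 1) abort("iterations must be >= 1")
  out <- mask
  for (k in seq_len(iterations)) {
    conn <- switch(connectivity,
      alternating = if (k %% 2 == 1) 4 else 8,
      four = 4,
      eight = 8
    )
    out <- erode_once(out, conn)
    if (!any(out)) break
  }
  out
}

#' Mask QD-positive pixels
#'
#' Marks pixels whose background-subtracted QD intensity exceeds the image
#' median by more than `k_sigma` times a robust noise scale. The scale is
#' the larger of the normal-consistent MAD and the upper-quartile spread
#' `(q75 - median)/0.6745`; the latter still estimates the noise sigma when
#' background subtraction has clamped half the pixels to zero (where the
#' MAD collapses to 0), while for a noiseless sparse image both terms
#' vanish and any strictly positive signal is marked.
#'
#' @param qd Background-subtracted QD matrix.
#' @param k_sigma Positive multiplier (default 3).
#' @return Logical matrix; the threshold is attached as attribute
#'   `"threshold"`. A constant image yields an empty mask.
#' @export
compute_qd_mask <- function(qd, k_sigma = 3) {
  stopifnot(is.matrix(qd), all(is.finite(qd)), k_sigma > 0)
  if (diff(range(qd)) == 0) {
    out <- matrix(FALSE, nrow(qd), ncol(qd))
    attr(out, "threshold") <- Inf
    return(out)
  }
  med <- median(qd)
  scale <- max(mad(qd), (quantile(qd, 0.75, names = FALSE) - med) / 0.6745)
  thr <- med + k_sigma * scale
  out <- qd > thr
  attr(out, "threshold") <- thr
  out
}

#' Partition a cell mask into membrane and interior compartments
#'
#' The pre-interior is the alternating-connectivity erosion of the cell
#' mask; the pre-membrane is the cell minus the pre-interior; the membrane
#' and interior are their intersections with the QD mask. A cell whose
#' pre-interior erodes away completely is flagged degenerate and excluded
#' from measurement downstream.
#'
#' @param cell Logical cell mask (non-empty).
#' @param erosion_iterations Integer `>= 1` (default 8; the useful range for
#'   cell-sized masks is about 5-20).
#' @param qd_mask Logical matrix, same shape.
#' @param connectivity Passed to [erode_alternating()].
#' @return A `compartment_masks` list: `cell`, `pre_membrane`,
#'   `pre_interior`, `membrane`, `interior`, `qd_mask`,
#'   `erosion_iterations`, `degenerate`.
#' @export
partition_cell <- function(cell, erosion_iterations = 8, qd_mask,
                           connectivity = "alternating") {
  stopifnot(is.matrix(cell), is.logical(cell), is.matrix(qd_mask))
  if (!any(cell)) abort("cell mask is empty")
  if (!all(dim(cell) == dim(qd_mask))) abort("qd_mask shape differs from cell")
  pre_interior <- erode_alternating(cell, erosion_iterations, connectivity)
  pre_membrane <- cell & !pre_interior
  structure(
    list(
      cell = cell,
      pre_membrane = pre_membrane,
      pre_interior = pre_interior,
      membrane = qd_mask & pre_membrane,
      interior = qd_mask & pre_interior,
      qd_mask = qd_mask,
      erosion_iterations = as.integer(erosion_iterations),
      degenerate = !any(pre_interior)
    ),
    class = "compartment_masks"
  )
}

#' Measure one cell's per-compartment intensities
#'
#' Sums the QD channel over the membrane and interior compartments, records
#' compartment sizes and estimates receptor expression as the mean SYFP
#' signal over the cell (sum / cell area).
#'
#' @param masks A `compartment_masks` from [partition_cell()].
#' @param qd,receptor Background-subtracted channel matrices.
#' @param field_id,cell_id,ligand,time_min Metadata for the output row.
#' @return One-row tibble: identifiers, `qd_membrane_sum`,
#'   `qd_interior_sum`, `membrane_px`, `interior_px`, `cell_px`,
#'   `syfp_mean`, `excluded`, `exclude_reason`.
#' @export
measure_cell <- function(masks, qd, receptor, field_id = "F1", cell_id = 1L,
                         ligand = NA_character_, time_min = NA_real_) {
  stopifnot(inherits(masks, "compartment_masks"))
  cell_px <- sum(masks$cell)
  excluded <- FALSE
  reason <- NA_character_
  if (masks$degenerate) {
    excluded <- TRUE
    reason <- "degenerate interior (erosion exhausted the cell)"
  } else if (!any(masks$membrane) && !any(masks$interior)) {
    excluded <- TRUE
    reason <- "no QD signal"
  }
  tibble(
    field_id = field_id, cell_id = cell_id, ligand = ligand,
    time_min = time_min,
    qd_membrane_sum = sum(qd[masks$membrane]),
    qd_interior_sum = sum(qd[masks$interior]),
    membrane_px = sum(masks$membrane),
    interior_px = sum(masks$interior),
    cell_px = cell_px,
    syfp_mean = sum(receptor[masks$cell]) / cell_px,
    excluded = excluded,
    exclude_reason = reason
  )
}

#' Measure every cell in a field
#'
#' Convenience wrapper running the full per-field chain: background
#' subtraction on both channels, cell segmentation on the receptor channel,
#' QD masking, erosion partition and per-cell measurement.
#'
#' @param field A [field_of_view()].
#' @param erosion_iterations,connectivity Passed to [partition_cell()].
#' @param k_sigma Passed to [compute_qd_mask()].
#' @param min_area_px,exclude_border Passed to [segment_cells()].
#' @param background_method Passed to [subtract_background()].
#' @return Per-cell measurement tibble (one row per retained cell).
#' @export
measure_field <- function(field, erosion_iterations = 8, k_sigma = 3,
                          min_area_px = 200, exclude_border = TRUE,
                          background_method = "median",
                          connectivity = "alternating") {
  stopifnot(inherits(field, "field_of_view"))
  rec <- subtract_background(field$receptor, method = background_method)
  qd <- subtract_background(field$qd, method = background_method)
  seg <- segment_cells(rec,
    min_area_px = min_area_px,
    exclude_border = exclude_border
  )
  qd_mask <- compute_qd_mask(qd, k_sigma = k_sigma)
  ids <- setdiff(sort(unique(as.vector(seg$labels))), 0L)
  purrr::map_dfr(ids, function(i) {
    masks <- partition_cell(seg$labels == i, erosion_iterations, qd_mask,
      connectivity = connectivity
    )
    measure_cell(masks, qd, rec,
      field_id = field$metadata$field_id, cell_id = i,
      ligand = field$metadata$ligand, time_min = field$metadata$time_min
    )
  })
}
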