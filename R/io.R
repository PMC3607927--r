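#' Two-channel field of view
#'
#' A light container for one imaging field: the receptor (SYFP/VFP) channel
#' used for cell segmentation and expression estimation, and the QD ligand
#' channel used for internalization measurement, plus acquisition metadata.
#'
#' @param receptor,qd Numeric matrices of identical shape, finite and
#'   non-negative (intensity counts).
#' @param field_id Field identifier.
#' @param ligand Ligand label (e.g. `"IGF-II"`, `"insulin"`).
#' @param time_min Minutes at 37 degrees C; `>= 0`.
#' @param pixel_size Optional pixel size in micrometers.
#' @return A `field_of_view` object.
#' @export
field_of_view <- function(receptor, qd, field_id = "F1",
                          ligand = NA_character_, time_min = NA_real_,
                          pixel_size = NA_real_) {
  stopifnot(is.matrix(receptor), is.matrix(qd))
  if (!all(dim(receptor) == dim(qd))) abort("channel shapes differ")
  if (!all(is.finite(receptor)) || !all(is.finite(qd))) {
    abort("channels must be finite")
  }
  if (any(receptor < 0) || any(qd < 0)) abort("channels must be non-negative")
  if (!is.na(time_min) && time_min < 0) abort("time_min must be >= 0")
  structure(
    list(
      receptor = receptor, qd = qd,
      metadata = tibble(
        field_id = field_id, ligand = ligand,
        time_min = time_min, pixel_size = pixel_size
      )
    ),
    class = "field_of_view"
  )
}

#' @export
print.field_of_view <- function(x, ...) {
  cat(sprintf(
    "<field_of_view> %s: %d x %d px, ligand %s, t = %s min\n",
    x$metadata$field_id, nrow(x$receptor), ncol(x$receptor),
    x$metadata$ligand, format(x$metadata$time_min)
  ))
  invisible(x)
}

#' Write a field of view to a multi-page 16-bit TIFF
#'
#' Page 1 is the receptor channel, page 2 the QD channel. Intensities are
#' stored as 16-bit unsigned integers; values are rounded and clipped to
#' `[0, 65535]`, so integer-valued count images round-trip exactly.
#'
#' @param field A [field_of_view()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(field, path) {
  stopifnot(inherits(field, "field_of_view"))
  enc <- function(m) pmin(pmax(round(m), 0), 65535) / 65535
  tiff::writeTIFF(list(enc(field$receptor), enc(field$qd)), path,
    bits.per.sample = 16L
  )
  invisible(path)
}

#' Read a field of view from a multi-page TIFF
#'
#' @param path TIFF file with at least two pages/channels.
#' @param channel_map Named integer vector mapping `receptor` and `qd` to
#'   page indices.
#' @param field_id,ligand,time_min Metadata (e.g. from a manifest row).
#' @return A [field_of_view()] with intensities on the original count scale.
#' @export
read_field <- function(path, channel_map = c(receptor = 1L, qd = 2L),
                       field_id = basename(path), ligand = NA_character_,
                       time_min = NA_real_) {
  if (!all(c("receptor", "qd") %in% names(channel_map))) {
    abort("channel_map must name 'receptor' and 'qd' pages")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  need <- max(channel_map)
  if (length(pages) < need) {
    abort(sprintf(
      "%s: needs %d channel pages, found %d (missing %s)",
      path, need, length(pages),
      paste(names(channel_map)[channel_map > length(pages)], collapse = ", ")
    ))
  }
  grab <- function(i) {
    m <- pages[[i]]
    if (length(dim(m)) == 3) m <- m[, , 1]
    round(m * 65535)
  }
  rec <- grab(channel_map[["receptor"]])
  qd <- grab(channel_map[["qd"]])
  if (!all(dim(rec) == dim(qd))) abort(sprintf("%s: channel shape mismatch", path))
  field_of_view(rec, qd, field_id = field_id, ligand = ligand, time_min = time_min)
}

#' Write an imaging dataset to disk
#'
#' Writes one multi-page TIFF per field plus a `manifest.csv` holding the
#' per-cell ground truth.
#'
#' @param dataset An `image_dataset` from [generate_image_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_image_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "image_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (fid in names(dataset$fields)) {
    write_field(dataset$fields[[fid]], file.path(dir, paste0(fid, ".tif")))
  }
  write.csv(dataset$truth, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
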