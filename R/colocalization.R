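#' Manders colocalization coefficients
#'
#' `m_r` is the fraction of the R channel's integrated intensity located at
#' pixels where the G channel exceeds its threshold (and vice versa for
#' `m_g`), computed within an analysis mask. With background-subtracted
#' inputs the default thresholds of 0 reproduce the common
#' intensity-correlation-analysis convention. Both coefficients lie in
#' `[0, 1]` by construction.
#'
#' @param r,g Same-shape, background-subtracted intensity matrices.
#' @param thr_r,thr_g Non-negative intensity thresholds (default 0).
#' @param mask Optional logical analysis mask (default: the whole image;
#'   in pipelines, pass the segmented cell so background pixels do not
#'   dominate).
#' @return A `coloc_result` list: `m_r`, `m_g` (each `NA` when the
#'   corresponding channel has zero integrated intensity in the mask),
#'   thresholds and mask. Supports [tidy()].
#' @export
manders_coefficients <- function(r, g, thr_r = 0, thr_g = 0, mask = NULL) {
  stopifnot(is.matrix(r), is.matrix(g), all(dim(r) == dim(g)),
    thr_r >= 0, thr_g >= 0)
  mask <- mask %||% matrix(TRUE, nrow(r), ncol(r))
  stopifnot(all(dim(mask) == dim(r)))
  rv <- r[mask]
  gv <- g[mask]
  sum_r <- sum(rv)
  sum_g <- sum(gv)
  m_r <- if (sum_r > 0) sum(rv[gv > thr_g]) / sum_r else NA_real_
  m_g <- if (sum_g > 0) sum(gv[rv > thr_r]) / sum_g else NA_real_
  structure(
    list(m_r = m_r, m_g = m_g, thr_r = thr_r, thr_g = thr_g, mask = mask),
    class = "coloc_result"
  )
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("<coloc_result> m_r = %.4g, m_g = %.4g\n", x$m_r, x$m_g))
  invisible(x)
}

#' @export
tidy.coloc_result <- function(x, ...) {
  tibble(m_r = x$m_r, m_g = x$m_g, thr_r = x$thr_r, thr_g = x$thr_g)
}

#' Product of the differences from the mean (PDM)
#'
#' For every pixel inside the mask,
#' `pdm = (r - mean_mask(r)) * (g - mean_mask(g))`: positive where the two
#' channels co-vary, negative where they anti-vary. The PDM map shows each
#' pixel's contribution to the colocalization; its mean over the mask
#' equals the population covariance of the two channels within the mask.
#'
#' @param r,g Same-shape intensity matrices.
#' @param mask Optional logical analysis mask (default: whole image). Must
#'   select at least one pixel.
#' @return List: `pdm` (matrix, `NA` outside the mask) and `pdm_mean`.
#' @export
pdm_image <- function(r, g, mask = NULL) {
  stopifnot(is.matrix(r), is.matrix(g), all(dim(r) == dim(g)))
  mask <- mask %||% matrix(TRUE, nrow(r), ncol(r))
  stopifnot(all(dim(mask) == dim(r)))
  if (!any(mask)) abort("empty analysis mask")
  mr <- mean(r[mask])
  mg <- mean(g[mask])
  pdm <- matrix(NA_real_, nrow(r), ncol(r))
  pdm[mask] <- (r[mask] - mr) * (g[mask] - mg)
  list(pdm = pdm, pdm_mean = mean(pdm[mask]))
}
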