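#' @export
autoplot.logistic_fit <- function(object, n = 200, ...) {
  tmax <- max(object$data$time_min)
  grid <- tibble(
    time_min = seq(0, 1.05 * tmax, length.out = n)
  )
  grid$value <- logistic_value(object, grid$time_min)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_min, y = .data$value)) +
    ggplot2::geom_line(data = grid, color = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_vline(
      xintercept = object$t_at_kmax,
      linetype = "dashed", color = "grey50"
    ) +
    ggplot2::labs(
      x = "time at 37 °C (min)", y = "internalized fraction",
      subtitle = sprintf(
        "k_max = %.3g min⁻¹, t½ = %.3g min",
        object$k_max, object$t_half
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot internalization time courses with fitted curves
#'
#' @param summaries Summary tibble (`ligand`, `time_min`, `mean`, `sem`).
#' @param fits Optional named list of `logistic_fit` objects per ligand.
#' @param n Curve resolution.
#' @return A ggplot.
#' @export
plot_timecourse <- function(summaries, fits = NULL, n = 200) {
  p <- ggplot2::ggplot(summaries, ggplot2::aes(
    x = .data$time_min, y = .data$mean, color = .data$ligand
  )) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean - .data$sem,
        ymax = .data$mean + .data$sem
      ),
      width = 2
    ) +
    ggplot2::labs(
      x = "time at 37 °C (min)",
      y = "internalized fraction QD_interior / QD_total", color = NULL
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fits)) {
    tmax <- max(summaries$time_min)
    curves <- purrr::imap_dfr(fits, function(f, lg) {
      tt <- seq(0, 1.05 * tmax, length.out = n)
      tibble(ligand = lg, time_min = tt, mean = logistic_value(f, tt))
    })
    p <- p + ggplot2::geom_line(data = curves)
  }
  p
}

#' @export
autoplot.field_of_view <- function(object, ...) {
  to_df <- function(m, ch) {
    tibble(
      row = rep(seq_len(nrow(m)), ncol(m)),
      col = rep(seq_len(ncol(m)), each = nrow(m)),
      intensity = as.vector(m), channel = ch
    )
  }
  df <- dplyr::bind_rows(
    to_df(object$receptor, "receptor (SYFP)"),
    to_df(object$qd, "ligand (QD)")
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "counts") +
    ggplot2::theme_minimal()
}

#' Plot a normalized marker (M1) time series
#'
#' @param marker Output of [marker_series()].
#' @return A ggplot.
#' @export
plot_marker_series <- function(marker) {
  ggplot2::ggplot(marker, ggplot2::aes(x = .data$time_min, y = .data$normalized)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "time at 37 °C (min)", y = "Marker / 0 min") +
    ggplot2::theme_minimal()
}
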