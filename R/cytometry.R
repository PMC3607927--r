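#' Read a cytometry event table from CSV
#'
#' Expects (at least) per-event intensity columns named by `channel_map`,
#' plus optional `time_min`, `ligand` and `acid_treated` metadata columns.
#' Intensities are floored at `floor_value` so downstream log/geometric
#' operations are defined (list-mode exports can contain zeros).
#'
#' @param path CSV file.
#' @param channel_map Named character vector mapping the canonical channel
#'   names `syfp` and `qd` to column names in the file.
#' @param floor_value Small positive floor applied to both channels.
#' @return Tibble with `event_id`, `syfp`, `qd` and any metadata columns
#'   present.
#' @export
read_event_table <- function(path, channel_map = c(syfp = "syfp", qd = "qd"),
                             floor_value = 1e-3) {
  df <- as_tibble(utils::read.csv(path))
  for (ch in c("syfp", "qd")) {
    src <- channel_map[[ch]]
    if (!src %in% names(df)) abort(sprintf("%s: missing channel column '%s'", path, src))
    df[[ch]] <- pmax(df[[src]], floor_value)
  }
  if (!"event_id" %in% names(df)) df$event_id <- seq_len(nrow(df))
  df
}

#' Gate events positive in one channel against a control sample
#'
#' The threshold is a high quantile of the control (autofluorescence)
#' distribution in the requested channel -- the standard way of selecting
#' transfected (SYFP-positive) events against non-transfected control
#' cells. Quantiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7), so the gate is deterministic.
#'
#' @param sample,control Event tibbles with the gating channel column.
#' @param channel `"syfp"` (default) or `"qd"`.
#' @param quantile Control quantile defining the threshold (default 0.995).
#' @return List: `gate` (list with `channel`, `threshold`, `quantile`,
#'   `control_n`) and `events` (the sample rows above the threshold).
#' @export
gate_positive <- function(sample, control, channel = c("syfp", "qd"),
                          quantile = 0.995) {
  channel <- match.arg(channel)
  stopifnot(is.data.frame(sample), is.data.frame(control))
  if (nrow(control) == 0) abort("empty control sample")
  if (nrow(control) < 100) {
    warn("control has fewer than 100 events; gate threshold will be noisy")
  }
  thr <- unname(stats::quantile(control[[channel]], quantile, type = 7))
  list(
    gate = list(
      channel = channel, threshold = thr, quantile = quantile,
      control_n = nrow(control)
    ),
    events = sample[sample[[channel]] > thr, , drop = FALSE]
  )
}

#' Quadrant statistics for a two-channel event table
#'
#' Quadrant convention: I = QD-high / SYFP-low, II = both high,
#' III = both low, IV = SYFP-high / QD-low. The labeled fraction is
#' II / (II + IV): among receptor-expressing (SYFP-high) events, the
#' fraction that also carry high QD signal.
#'
#' @param events Event tibble with `syfp` and `qd`.
#' @param syfp_threshold,qd_threshold Gate thresholds (e.g. from
#'   [gate_positive()] gates on a control sample).
#' @return One-row tibble: counts `I`-`IV`, `total` and
#'   `labeled_fraction` (`NA` when II + IV = 0).
#' @export
quadrant_statistics <- function(events, syfp_threshold, qd_threshold) {
  stopifnot(all(c("syfp", "qd") %in% names(events)))
  s_hi <- events$syfp > syfp_threshold
  q_hi <- events$qd > qd_threshold
  q1 <- sum(q_hi & !s_hi)
  q2 <- sum(q_hi & s_hi)
  q3 <- sum(!q_hi & !s_hi)
  q4 <- sum(!q_hi & s_hi)
  tibble(
    I = q1, II = q2, III = q3, IV = q4, total = nrow(events),
    labeled_fraction = if (q2 + q4 > 0) q2 / (q2 + q4) else NA_real_
  )
}

#' Geometric mean of positive intensities
#'
#' `exp(mean(log(x)))`, the standard per-histogram statistic for
#' log-normally distributed cytometry intensities. Non-positive values are
#' either excluded or floored at `floor_value` first.
#'
#' @param values Numeric vector.
#' @param zero_policy `"exclude"` (default) or `"floor"`.
#' @param floor_value Floor used by `zero_policy = "floor"`.
#' @return The geometric mean (always `<=` the arithmetic mean of the same
#'   retained values).
#' @export
geometric_mean <- function(values, zero_policy = c("exclude", "floor"),
                           floor_value = 1e-3) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(is.numeric(values))
  x <- if (zero_policy == "exclude") values[values > 0] else pmax(values, floor_value)
  if (length(x) == 0) abort("no positive values remain after zero policy")
  exp(mean(log(x)))
}

#' Normalize per-time geometric means to the time-zero histogram
#'
#' @param events Gated event tibble with `qd` and `time_min`.
#' @param t0 Reference time (default 0; must be present).
#' @param ... Passed to [geometric_mean()].
#' @return Tibble: `time_min`, `n`, `geo_mean`, `normalized`
#'   (geo_mean / geo_mean at `t0`, equal to 1 at `t0` by construction).
#' @export
geometric_mean_series <- function(events, t0 = 0, ...) {
  stopifnot(all(c("qd", "time_min") %in% names(events)))
  if (!t0 %in% events$time_min) abort("reference time t0 not present in events")
  out <- events |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(
      n = dplyr::n(),
      geo_mean = geometric_mean(.data$qd, ...),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$time_min)
  out$normalized <- out$geo_mean / out$geo_mean[out$time_min == t0]
  out
}

#' Place the M1 marker on a reference histogram
#'
#' The marker threshold is set so that approximately `tail_fraction` of the
#' reference (time-zero, gated) events exceed it: the
#' `1 - tail_fraction` quantile of the reference QD intensities, with
#' linear interpolation between order statistics (type 7). With heavy ties
#' at the threshold the realized tail fraction can deviate; inspect
#' `attr(, "realized_tail")`.
#'
#' @param reference Event tibble (gated, reference time) with a `qd`
#'   column, or a numeric vector of QD intensities.
#' @param tail_fraction Target tail fraction in (0, 0.5); default 0.04.
#' @return The marker threshold, with attribute `"realized_tail"`.
#' @export
place_marker <- function(reference, tail_fraction = 0.04) {
  if (is.data.frame(reference)) reference <- reference$qd
  stopifnot(is.numeric(reference))
  if (tail_fraction <= 0 || tail_fraction >= 0.5) {
    abort("tail_fraction must be in (0, 0.5)")
  }
  if (length(reference) < 50) {
    warn("fewer than 50 reference events; marker placement will be noisy")
  }
  thr <- unname(stats::quantile(reference, 1 - tail_fraction, type = 7))
  attr(thr, "realized_tail") <- mean(reference > thr)
  thr
}

#' Marker (M1) time series normalized to time zero
#'
#' For each time, the percentage of gated events above the M1 threshold,
#' normalized to the time-zero percentage ("Marker/0 min"). The normalized
#' series equals 1 at time zero by construction and, under an upward
#' location shift of the QD distribution (more internalized label
#' retained), is non-decreasing in the shift.
#'
#' @param events Gated event tibble with `qd` and `time_min` (t = 0
#'   present).
#' @param m1_threshold Threshold from [place_marker()].
#' @param t0 Reference time (default 0).
#' @return Tibble: `time_min`, `n`, `pct_above`, `normalized`.
#' @export
marker_series <- function(events, m1_threshold, t0 = 0) {
  stopifnot(all(c("qd", "time_min") %in% names(events)))
  if (!t0 %in% events$time_min) abort("reference time t0 not present in events")
  out <- events |>
    dplyr::group_by(.data$time_min) |>
    dplyr::summarise(
      n = dplyr::n(),
      pct_above = 100 * mean(.data$qd > m1_threshold),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$time_min)
  p0 <- out$pct_above[out$time_min == t0]
  if (p0 == 0) abort("0% of reference events above the marker: normalization undefined")
  out$normalized <- out$pct_above / p0
  out
}

#' Fold change of a labeled fraction versus a control sample
#'
#' @param sample_fraction Labeled fraction in the sample.
#' @param control_fraction Labeled fraction in the control; must be > 0.
#' @return `sample_fraction / control_fraction`.
#' @export
fold_vs_control <- function(sample_fraction, control_fraction) {
  stopifnot(is.numeric(sample_fraction), is.numeric(control_fraction))
  if (any(control_fraction <= 0)) abort("control_fraction must be > 0")
  sample_fraction / control_fraction
}
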