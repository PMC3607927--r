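#' Configuration for the imaging pipeline
#'
#' Bundles every tunable of the imaging analysis chain with its default.
#' Either `simulation` (an [image_dataset_config()]) or `input_dir` (a
#' directory of multi-page TIFFs plus `manifest.csv`, as written by
#' [write_image_dataset()]) must supply the fields.
#'
#' @param simulation An [image_dataset_config()], or `NULL` when reading
#'   from disk.
#' @param input_dir Directory with fields and a manifest, or `NULL`.
#' @param erosion_iterations Erosion iterations for the membrane/interior
#'   partition (default 8; useful range about 5-20).
#' @param connectivity Structuring-element sequence for the erosion.
#' @param k_sigma QD-mask threshold multiplier.
#' @param min_area_px Minimum cell area.
#' @param exclude_border Drop border-touching cells.
#' @param background_method `"median"` or `"mean-of-region"`.
#' @param fold_window Expression-similarity window around the median.
#' @param fit_model `"power"` (matches the simulated truth) or `"exp"`.
#' @param fit_weights `NULL`, `"n"` or `"1/sem^2"`.
#' @param outdir Optional output directory for CSVs and the JSON report.
#' @return An `imaging_config` list.
#' @export
imaging_config <- function(simulation = image_dataset_config(),
                           input_dir = NULL,
                           erosion_iterations = 8,
                           connectivity = "alternating",
                           k_sigma = 3,
                           min_area_px = 200,
                           exclude_border = TRUE,
                           background_method = "median",
                           fold_window = 2,
                           fit_model = "power",
                           fit_weights = NULL,
                           outdir = NULL) {
  if (is.null(simulation) && is.null(input_dir)) {
    abort("either a simulation config or an input directory is required")
  }
  stopifnot(erosion_iterations >= 1, k_sigma > 0, fold_window >= 1)
  structure(
    list(
      simulation = simulation, input_dir = input_dir,
      erosion_iterations = erosion_iterations, connectivity = connectivity,
      k_sigma = k_sigma, min_area_px = min_area_px,
      exclude_border = exclude_border, background_method = background_method,
      fold_window = fold_window, fit_model = fit_model,
      fit_weights = fit_weights, outdir = outdir
    ),
    class = "imaging_config"
  )
}

#' Read an imaging dataset written by [write_image_dataset()]
#'
#' @param dir Directory holding per-field TIFFs and `manifest.csv`.
#' @return An `image_dataset` list (`fields`, `truth`).
#' @export
read_image_dataset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.csv")
  if (!file.exists(manifest_path)) abort(sprintf("no manifest.csv in %s", dir))
  truth <- as_tibble(utils::read.csv(manifest_path))
  meta <- dplyr::distinct(truth, .data$field_id, .data$ligand, .data$time_min)
  fields <- lapply(seq_len(nrow(meta)), function(i) {
    read_field(file.path(dir, paste0(meta$field_id[i], ".tif")),
      field_id = meta$field_id[i], ligand = meta$ligand[i],
      time_min = meta$time_min[i]
    )
  })
  names(fields) <- meta$field_id
  structure(list(fields = fields, truth = truth), class = "image_dataset")
}

#' Run the imaging internalization pipeline end to end
#'
#' Executes, in order: simulate (or load) fields; per field: background
#' subtraction, cell segmentation on the receptor channel, QD masking,
#' alternating-connectivity erosion partition, per-cell measurement; then
#' internalization ratios, the expression-similarity filter, per-condition
#' summaries, ligand comparisons (two-tailed t-tests from summaries) and
#' per-ligand logistic fits with k_max and half-time. Deterministic for a
#' fixed configuration.
#'
#' @param config An [imaging_config()].
#' @return An `imaging_run` list: `measurements` (per cell, with exclusion
#'   flags), `summaries`, `comparisons`, `fits` (list of `logistic_fit`),
#'   `fit_table`, `truth`, and `report` (stage counts, config echo).
#' @export
run_imaging_pipeline <- function(config = imaging_config()) {
  stopifnot(inherits(config, "imaging_config"))
  dataset <- if (!is.null(config$input_dir)) {
    read_image_dataset(config$input_dir)
  } else {
    generate_image_dataset(config$simulation)
  }
  measurements <- purrr::map_dfr(dataset$fields, measure_field,
    erosion_iterations = config$erosion_iterations,
    k_sigma = config$k_sigma, min_area_px = config$min_area_px,
    exclude_border = config$exclude_border,
    background_method = config$background_method,
    connectivity = config$connectivity
  )
  measurements <- internalization_ratio(measurements)
  usable <- dplyr::filter(measurements, !.data$excluded)
  filtered <- filter_by_expression(usable, fold_window = config$fold_window)
  expr_excl <- attr(filtered, "exclusions")
  summaries <- summarize_timepoint(filtered)
  ligs <- unique(summaries$ligand)
  comparisons <- if (length(ligs) >= 2) compare_ligands(summaries) else tibble()
  fits <- fit_ligand_kinetics(summaries,
    model = config$fit_model,
    weights = config$fit_weights
  )
  fit_table <- kinetics_table(fits)
  report <- list(
    package_version = as.character(utils::packageVersion("endoquant")),
    n_fields = length(dataset$fields),
    n_cells_measured = nrow(measurements),
    n_excluded_measurement = sum(measurements$excluded),
    n_excluded_expression = if (is.null(expr_excl)) 0L else nrow(expr_excl),
    n_retained = nrow(filtered),
    config = config[setdiff(names(config), "simulation")],
    simulation_seed = if (!is.null(config$simulation)) config$simulation$seed else NA
  )
  run <- structure(
    list(
      measurements = measurements, filtered = filtered,
      summaries = summaries, comparisons = comparisons,
      fits = fits, fit_table = fit_table,
      truth = dataset$truth, report = report
    ),
    class = "imaging_run"
  )
  if (!is.null(config$outdir)) write_imaging_run(run, config$outdir)
  run
}

write_imaging_run <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write.csv(run$measurements, file.path(outdir, "measurements.csv"), row.names = FALSE)
  write.csv(run$summaries, file.path(outdir, "summary.csv"), row.names = FALSE)
  if (nrow(run$comparisons) > 0) {
    write.csv(run$comparisons, file.path(outdir, "comparisons.csv"), row.names = FALSE)
  }
  write.csv(run$fit_table, file.path(outdir, "fits.csv"), row.names = FALSE)
  jsonlite::write_json(run$report, file.path(outdir, "report.json"),
    auto_unbox = TRUE, pretty = TRUE, force = TRUE
  )
  invisible(outdir)
}

#' @export
print.imaging_run <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "<imaging_run> %d fields, %d cells (%d excluded at measurement, %d by expression filter, %d retained)\n",
    r$n_fields, r$n_cells_measured, r$n_excluded_measurement,
    r$n_excluded_expression, r$n_retained
  ))
  print(x$fit_table)
  invisible(x)
}

#' Configuration for the cytometry pipeline
#'
#' @param simulation An [event_dataset_config()], or `NULL` when supplying
#'   `event_tables`.
#' @param event_tables Optional named list with `events` (tibble across
#'   times, including time 0) and `control` (untransfected sample).
#' @param gate_quantile Control quantile for the SYFP-positive gate (also
#'   used for the QD quadrant threshold).
#' @param tail_fraction M1 marker tail at time zero.
#' @param zero_policy Passed to [geometric_mean()].
#' @param outdir Optional output directory.
#' @return A `cytometry_config` list.
#' @export
cytometry_config <- function(simulation = event_dataset_config(),
                             event_tables = NULL,
                             gate_quantile = 0.995,
                             tail_fraction = 0.04,
                             zero_policy = "exclude",
                             outdir = NULL) {
  if (is.null(simulation) && is.null(event_tables)) {
    abort("either a simulation config or event tables are required")
  }
  structure(
    list(
      simulation = simulation, event_tables = event_tables,
      gate_quantile = gate_quantile, tail_fraction = tail_fraction,
      zero_policy = zero_policy, outdir = outdir
    ),
    class = "cytometry_config"
  )
}

#' Run the cytometry internalization pipeline end to end
#'
#' Gates SYFP-positive (transfected) events against the control sample,
#' computes per-time QD geometric means normalized to time zero, places the
#' M1 marker on the time-zero histogram and tracks the normalized marker
#' series, and tabulates quadrant statistics per time.
#'
#' @param config A [cytometry_config()].
#' @return A `cytometry_run` list: `gate`, `qd_threshold`, `gated`,
#'   `geo_series`, `m1_threshold`, `marker`, `quadrants`, `truth`,
#'   `report`.
#' @export
run_cytometry_pipeline <- function(config = cytometry_config()) {
  stopifnot(inherits(config, "cytometry_config"))
  if (!is.null(config$event_tables)) {
    events <- config$event_tables$events
    control <- config$event_tables$control
    truth <- NULL
    if (is.null(control)) abort("missing control sample")
  } else {
    ds <- generate_event_dataset(config$simulation)
    events <- ds$events
    control <- ds$control
    truth <- ds$truth
  }
  if (!0 %in% events$time_min) abort("missing time-zero sample")
  g <- gate_positive(events, control, channel = "syfp", quantile = config$gate_quantile)
  gated <- g$events
  qd_thr <- unname(stats::quantile(control$qd, config$gate_quantile, type = 7))
  geo <- geometric_mean_series(gated, zero_policy = config$zero_policy)
  m1 <- place_marker(gated[gated$time_min == 0, ],
    tail_fraction = config$tail_fraction
  )
  marker <- marker_series(gated, m1)
  quadrants <- events |>
    dplyr::group_by(.data$time_min) |>
    dplyr::group_modify(~ quadrant_statistics(.x, g$gate$threshold, qd_thr)) |>
    dplyr::ungroup()
  report <- list(
    package_version = as.character(utils::packageVersion("endoquant")),
    n_events = nrow(events), n_gated = nrow(gated),
    gated_fraction = nrow(gated) / nrow(events),
    syfp_threshold = g$gate$threshold, qd_threshold = qd_thr,
    m1_threshold = as.numeric(m1),
    m1_realized_tail = attr(m1, "realized_tail"),
    config = config[setdiff(names(config), c("simulation", "event_tables"))]
  )
  run <- structure(
    list(
      gate = g$gate, qd_threshold = qd_thr, gated = gated,
      geo_series = geo, m1_threshold = m1, marker = marker,
      quadrants = quadrants, truth = truth, report = report
    ),
    class = "cytometry_run"
  )
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write.csv(run$geo_series, file.path(config$outdir, "geometric_means.csv"),
      row.names = FALSE
    )
    write.csv(run$marker, file.path(config$outdir, "marker_series.csv"),
      row.names = FALSE
    )
    write.csv(run$quadrants, file.path(config$outdir, "quadrants.csv"),
      row.names = FALSE
    )
    jsonlite::write_json(run$report, file.path(config$outdir, "report.json"),
      auto_unbox = TRUE, pretty = TRUE, force = TRUE
    )
  }
  run
}

#' @export
print.cytometry_run <- function(x, ...) {
  cat(sprintf(
    "<cytometry_run> %d events, %d gated (%.1f%%); M1 at %.4g (tail %.2f%%)\n",
    x$report$n_events, x$report$n_gated, 100 * x$report$gated_fraction,
    x$report$m1_threshold, 100 * x$report$m1_realized_tail
  ))
  print(x$marker)
  invisible(x)
}
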