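#' Per-cell internalization ratio
#'
#' Adds `qd_total` and the internalization ratio
#' `QD_interior / (QD_interior + QD_membrane)` to a per-cell measurement
#' table. Because both compartment sums share the detector and amplifier
#' settings, the ratio is invariant to any joint positive rescaling of the
#' two sums (an internal calibration that removes gain effects). Cells with
#' `qd_total = 0` are excluded with reason `"no QD signal"`, never given a
#' numeric ratio.
#'
#' @param measurements Tibble with `qd_membrane_sum` and `qd_interior_sum`
#'   (e.g. from [measure_field()]).
#' @return The input with `qd_total` and `ratio` columns added and the
#'   `excluded`/`exclude_reason` columns updated.
#' @export
internalization_ratio <- function(measurements) {
  stopifnot(all(c("qd_membrane_sum", "qd_interior_sum") %in% names(measurements)))
  if (!"excluded" %in% names(measurements)) {
    measurements$excluded <- FALSE
    measurements$exclude_reason <- NA_character_
  }
  measurements |>
    dplyr::mutate(
      qd_total = .data$qd_interior_sum + .data$qd_membrane_sum,
      ratio = dplyr::if_else(.data$qd_total > 0,
        .data$qd_interior_sum / .data$qd_total, NA_real_
      ),
      exclude_reason = dplyr::if_else(!.data$excluded & .data$qd_total <= 0,
        "no QD signal", .data$exclude_reason
      ),
      excluded = .data$excluded | .data$qd_total <= 0
    )
}

#' Filter cells by receptor-expression similarity
#'
#' Retains only cells whose mean SYFP signal lies within a fold window of
#' the experiment-wide median, emulating the practice of comparing only
#' cells with similar receptor expression (expression level itself alters
#' internalization rates). Deterministic; exclusions are logged.
#'
#' @param measurements Tibble with a `syfp_mean` column.
#' @param fold_window Numeric `>= 1`; retain
#'   `syfp_mean` in `[median / fold_window, median * fold_window]`.
#' @return The retained subset; the excluded rows (with the window bounds in
#'   columns `window_lo`/`window_hi`) are attached as attribute
#'   `"exclusions"`.
#' @export
filter_by_expression <- function(measurements, fold_window = 2) {
  stopifnot("syfp_mean" %in% names(measurements), fold_window >= 1)
  if (nrow(measurements) == 0) {
    attr(measurements, "exclusions") <- measurements
    return(measurements)
  }
  med <- median(measurements$syfp_mean)
  lo <- med / fold_window
  hi <- med * fold_window
  keep <- measurements$syfp_mean >= lo & measurements$syfp_mean <= hi
  out <- measurements[keep, , drop = FALSE]
  excl <- measurements[!keep, , drop = FALSE]
  if (nrow(excl) > 0) {
    excl$window_lo <- lo
    excl$window_hi <- hi
  }
  attr(out, "exclusions") <- excl
  attr(out, "expression_window") <- c(lo = lo, hi = hi)
  out
}

#' Summarize internalization ratios per ligand and time
#'
#' @param measurements Tibble with `ligand`, `time_min` and `ratio`
#'   (excluded cells are dropped first when an `excluded` column is
#'   present).
#' @return Tibble with `ligand`, `time_min`, `mean`, `sem`
#'   (sample SD / sqrt(n); `NA` when n = 1) and `n`.
#' @export
summarize_timepoint <- function(measurements) {
  stopifnot(all(c("ligand", "time_min", "ratio") %in% names(measurements)))
  if ("excluded" %in% names(measurements)) {
    measurements <- dplyr::filter(measurements, !.data$excluded)
  }
  measurements |>
    dplyr::filter(!is.na(.data$ratio)) |>
    dplyr::group_by(.data$ligand, .data$time_min) |>
    dplyr::summarise(
      mean = mean(.data$ratio),
      sem = if (dplyr::n() > 1) sd(.data$ratio) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$ligand, .data$time_min)
}

#' Two-sample two-tailed t-test from raw values or summaries
#'
#' From raw values: a pooled-variance Student t-test (default) or Welch
#' test via [stats::t.test()]. From `(mean, sem, n)` summaries (all that a
#' published table provides): the statistic is
#' \eqn{t = (m_1 - m_2)/\sqrt{sem_1^2 + sem_2^2}} with Welch-Satterthwaite
#' degrees of freedom computed from the sems and group sizes.
#'
#' @param a,b Either numeric vectors of raw values, or named numeric vectors
#'   `c(mean = , sem = , n = )`.
#' @param method `"student_pooled"` (default) or `"welch"`; ignored for
#'   summaries (reported as `"from_summary"`).
#' @return One-row tibble: `statistic`, `df`, `p_two_tailed`, `method`,
#'   `zero_variance` flag.
#' @export
t_test_two_sample <- function(a, b, method = c("student_pooled", "welch")) {
  method <- match.arg(method)
  is_summary <- function(x) {
    !is.null(names(x)) && all(c("mean", "sem", "n") %in% names(x))
  }
  if (is_summary(a) || is_summary(b)) {
    if (!(is_summary(a) && is_summary(b))) {
      abort("both groups must be summaries (mean, sem, n) or both raw vectors")
    }
    if (a[["n"]] < 2 || b[["n"]] < 2) abort("need n >= 2 per group")
    se2 <- a[["sem"]]^2 + b[["sem"]]^2
    if (se2 == 0) {
      return(tibble(
        statistic = 0, df = a[["n"]] + b[["n"]] - 2, p_two_tailed = 1,
        method = "from_summary", zero_variance = TRUE
      ))
    }
    stat <- (a[["mean"]] - b[["mean"]]) / sqrt(se2)
    df <- se2^2 / (a[["sem"]]^4 / (a[["n"]] - 1) + b[["sem"]]^4 / (b[["n"]] - 1))
    return(tibble(
      statistic = stat, df = df,
      p_two_tailed = 2 * pt(-abs(stat), df),
      method = "from_summary", zero_variance = FALSE
    ))
  }
  if (length(a) < 2 || length(b) < 2) abort("need n >= 2 per group")
  if (sd(a) == 0 && sd(b) == 0) {
    equal <- isTRUE(all.equal(mean(a), mean(b)))
    return(tibble(
      statistic = if (equal) 0 else Inf,
      df = length(a) + length(b) - 2,
      p_two_tailed = if (equal) 1 else 0,
      method = method, zero_variance = TRUE
    ))
  }
  ht <- stats::t.test(a, b, var.equal = (method == "student_pooled"))
  tibble(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_two_tailed = ht$p.value, method = method, zero_variance = FALSE
  )
}

#' Compare two ligands at every shared timepoint
#'
#' Runs [t_test_two_sample()] on the summary rows of each timepoint shared
#' by the two ligands (the layout published alongside internalization
#' summaries: one p-value per time column).
#'
#' @param summaries Output of [summarize_timepoint()] (or any tibble with
#'   `ligand`, `time_min`, `mean`, `sem`, `n`).
#' @param ligand_a,ligand_b Ligand labels to compare; default the first two.
#' @return Tibble: `time_min`, `statistic`, `df`, `p_two_tailed`, `method`.
#' @export
compare_ligands <- function(summaries, ligand_a = NULL, ligand_b = NULL) {
  ligs <- unique(summaries$ligand)
  ligand_a <- ligand_a %||% ligs[1]
  ligand_b <- ligand_b %||% ligs[2]
  times <- intersect(
    summaries$time_min[summaries$ligand == ligand_a],
    summaries$time_min[summaries$ligand == ligand_b]
  )
  purrr::map_dfr(sort(times), function(tm) {
    ra <- summaries[summaries$ligand == ligand_a & summaries$time_min == tm, ]
    rb <- summaries[summaries$ligand == ligand_b & summaries$time_min == tm, ]
    res <- t_test_two_sample(
      c(mean = ra$mean, sem = ra$sem, n = ra$n),
      c(mean = rb$mean, sem = rb$sem, n = rb$n)
    )
    dplyr::bind_cols(tibble(time_min = tm), res)
  })
}
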