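#' Configuration for a synthetic cytometry event dataset
#'
#' Emulates the flow-cytometry arm of the internalization experiment:
#' a mixed population of transfected (receptor-SYFP expressing) and
#' untransfected HeLa-like cells, a subset of transfected cells carrying
#' QD-labeled ligand, and an acid-strip step that removes surface-bound
#' label so that only internalized label retains high QD signal. Channel
#' intensities are bivariate log-normal per subpopulation; the internalized
#' fraction follows the ligand's logistic time course.
#'
#' @param n_events Events per time point.
#' @param transfected_fraction Fraction of events with elevated SYFP.
#' @param labeled_fraction Fraction of transfected events that bound
#'   QD-ligand during labeling.
#' @param times Minutes at 37 degrees C before the acid strip.
#' @param kinetics [kinetics_spec()] giving the internalized fraction f(t)
#'   among labeled events.
#' @param ligand Ligand label.
#' @param acid_treated If `TRUE` (default), surface-retained label is
#'   stripped: such events draw their QD intensity from the unlabeled
#'   distribution. If `FALSE` all labeled events keep labeled-level QD
#'   signal, so the marker and geometric-mean series stay flat.
#' @param syfp_untransfected,syfp_transfected,qd_unlabeled,qd_labeled
#'   Length-2 numeric `c(meanlog, sdlog)` log-normal parameters.
#' @param seed Master seed.
#' @return An `event_dataset_config` list.
#' @export
event_dataset_config <- function(n_events = 10000,
                                 transfected_fraction = 0.4,
                                 labeled_fraction = 0.9,
                                 times = c(0, 20, 40, 90),
                                 kinetics = kinetics_spec(0.05, 0.95, 15, 1.5),
                                 ligand = "IGF-II",
                                 acid_treated = TRUE,
                                 syfp_untransfected = c(log(100), 0.5),
                                 syfp_transfected = c(log(2500), 0.7),
                                 qd_unlabeled = c(log(80), 0.5),
                                 qd_labeled = c(log(1500), 0.6),
                                 seed = 1L) {
  if (transfected_fraction < 0 || transfected_fraction > 1 ||
    labeled_fraction < 0 || labeled_fraction > 1) {
    abort("fractions must be in [0, 1]")
  }
  if (length(times) == 0) abort("times must be non-empty")
  stopifnot(inherits(kinetics, "kinetics_spec"), n_events >= 1)
  structure(
    list(
      n_events = as.integer(n_events),
      transfected_fraction = transfected_fraction,
      labeled_fraction = labeled_fraction,
      times = times, kinetics = kinetics, ligand = ligand,
      acid_treated = isTRUE(acid_treated),
      syfp_untransfected = syfp_untransfected,
      syfp_transfected = syfp_transfected,
      qd_unlabeled = qd_unlabeled, qd_labeled = qd_labeled,
      seed = as.integer(seed)
    ),
    class = "event_dataset_config"
  )
}

#' Generate a synthetic cytometry event dataset
#'
#' One event table per time point plus an untransfected control table (for
#' gating). Per event: transfected ~ Bernoulli(transfected fraction);
#' labeled ~ Bernoulli(labeled fraction) among transfected; internalized ~
#' Bernoulli(f(t)) among labeled. Acid treatment resets the QD intensity of
#' labeled-but-not-internalized events to the unlabeled distribution.
#' Intensities are strictly positive (log-normal). Deterministic for a
#' fixed config and seed.
#'
#' @param config An [event_dataset_config()].
#' @param seed Optional override of `config$seed`.
#' @return An `event_dataset` list: `events` (tibble over all times with
#'   truth columns `transfected`, `labeled`, `internalized`), `control`
#'   (untransfected-only table at t = 0) and `truth` (per-time tibble with
#'   the nominal internalized fraction).
#' @export
generate_event_dataset <- function(config = event_dataset_config(), seed = NULL) {
  stopifnot(inherits(config, "event_dataset_config"))
  seed <- seed %||% config$seed
  fr <- interior_fraction_timecourse(config$kinetics, config$times)
  withr::with_seed(seed, {
    tables <- purrr::map2(config$times, fr, function(tm, f) {
      n <- config$n_events
      transfected <- runif(n) < config$transfected_fraction
      labeled <- transfected & (runif(n) < config$labeled_fraction)
      internalized <- labeled & (runif(n) < f)
      syfp <- ifelse(transfected,
        rlnorm(n, config$syfp_transfected[1], config$syfp_transfected[2]),
        rlnorm(n, config$syfp_untransfected[1], config$syfp_untransfected[2])
      )
      keeps_label <- if (config$acid_treated) internalized else labeled
      qd <- ifelse(keeps_label,
        rlnorm(n, config$qd_labeled[1], config$qd_labeled[2]),
        rlnorm(n, config$qd_unlabeled[1], config$qd_unlabeled[2])
      )
      tibble(
        event_id = seq_len(n), syfp = syfp, qd = qd,
        time_min = tm, ligand = config$ligand,
        acid_treated = config$acid_treated,
        transfected = transfected, labeled = labeled,
        internalized = internalized
      )
    })
    nctrl <- config$n_events
    control <- tibble(
      event_id = seq_len(nctrl),
      syfp = rlnorm(nctrl, config$syfp_untransfected[1], config$syfp_untransfected[2]),
      qd = rlnorm(nctrl, config$qd_unlabeled[1], config$qd_unlabeled[2]),
      time_min = 0, ligand = "control", acid_treated = config$acid_treated,
      transfected = FALSE, labeled = FALSE, internalized = FALSE
    )
  })
  structure(
    list(
      events = dplyr::bind_rows(tables),
      control = control,
      truth = tibble(
        time_min = config$times,
        true_internalized_fraction = fr,
        ligand = config$ligand
      ),
      config = config
    ),
    class = "event_dataset"
  )
}

#' @export
print.event_dataset <- function(x, ...) {
  cat(sprintf(
    "<event_dataset> %s: %d events x %d times (%s min), acid_treated = %s\n",
    x$config$ligand, x$config$n_events, length(x$config$times),
    paste(x$config$times, collapse = ", "), x$config$acid_treated
  ))
  invisible(x)
}
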