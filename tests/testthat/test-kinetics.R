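test_that("noiseless power-logistic curves are recovered to high precision", {
  truth <- c(a1 = 0.1, a2 = 0.9, x0 = 20, p = 2)
  tt <- seq(0, 150, length.out = 20)
  y <- truth["a2"] + (truth["a1"] - truth["a2"]) / (1 + (tt / truth["x0"])^truth["p"])
  fit <- fit_logistic(tt, y, model = "power")
  expect_true(fit$converged)
  for (nm in names(truth)) {
    expect_lt(abs(fit$coef[[nm]] - truth[[nm]]) / truth[[nm]], 1e-4)
  }
  # numeric k_max agrees with the closed-form derivative maximum
  an <- power_kmax_analytic(0.1, 0.9, 20, 2)
  km <- k_max(fit)
  expect_lt(abs(km[["k_max"]] - an[["k_max"]]), 1e-6)
  expect_lt(abs(km[["t_at_kmax"]] - an[["t_at_kmax"]]) / an[["t_at_kmax"]], 1e-3)
})

test_that("exponential-model k_max matches the analytic a*k/4 at t0", {
  tt <- seq(0, 120, length.out = 25)
  a <- 0.95
  k <- 0.11
  t0 <- 18
  y <- a / (1 + exp(-k * (tt - t0)))
  fit <- fit_logistic(tt, y, model = "exp")
  expect_lt(abs(fit$coef[["k"]] - k) / k, 1e-5)
  expect_lt(abs(fit$k_max - a * k / 4), 1e-6)
  expect_lt(abs(fit$t_at_kmax - t0), 1e-3)
  expect_equal(fit$t_half, log(2) / fit$k_max)
})

test_that("degenerate and invalid inputs are flagged, not fitted", {
  flat <- fit_logistic(c(0, 10, 20, 150), rep(0.5, 4))
  expect_true(flat$degenerate)
  expect_equal(flat$k_max, 0)
  expect_true(is.na(flat$t_half))
  expect_error(fit_logistic(c(0, 10, 20), c(0.1, 0.5, 0.9)), "at least 4")
  expect_error(fit_logistic(c(-5, 10, 20, 30), c(0.1, 0.2, 0.5, 0.9)), ">= 0")
})

test_that("logistic value and derivative follow the closed forms", {
  tt <- seq(0, 150, length.out = 20)
  sp <- kinetics_spec(0.2, 0.8, 25, 2)
  fit <- fit_logistic(tt, interior_fraction_timecourse(sp, tt), model = "power")
  # value at the center is the midpoint of baseline and plateau
  expect_equal(logistic_value(fit, 25), 0.5, tolerance = 1e-6)
  # derivative at t = x0 for p = 2: (a2 - a1) / (2 x0)
  expect_equal(logistic_derivative(fit, 25), (0.8 - 0.2) / (2 * 25),
    tolerance = 1e-5
  )
  # analytic limit at the origin: 0 for p > 1
  expect_equal(logistic_derivative(fit, 0), 0)
  expect_error(logistic_derivative(fit, -1), ">= 0")
  # finite differences agree in the interior
  h <- 1e-5
  for (t in c(5, 25, 60)) {
    fd <- (logistic_value(fit, t + h) - logistic_value(fit, t - h)) / (2 * h)
    expect_equal(logistic_derivative(fit, t), fd, tolerance = 1e-6)
  }
})

test_that("fits are invariant to time-unit rescaling", {
  tt <- c(0, 5, 10, 20, 40, 90, 150)
  y <- 0.9 / (1 + exp(-0.12 * (tt - 15)))
  f_min <- fit_logistic(tt, y, model = "exp")
  f_sec <- fit_logistic(tt * 60, y, model = "exp")
  expect_equal(f_sec$k_max * 60, f_min$k_max, tolerance = 1e-4)
  expect_equal(f_sec$t_half / 60, f_min$t_half, tolerance = 1e-4)
})

test_that("reference time courses give the published rate ordering", {
  fits <- fit_ligand_kinetics(reference_timecourse(), model = "exp")
  expect_true(all(vapply(fits, function(f) f$converged, logical(1))))
  # monotone increasing fits describing the data well
  for (f in fits) {
    expect_gt(f$r_squared, 0.9)
    curve <- logistic_value(f, seq(0, 150, by = 1))
    expect_true(all(diff(curve) >= -1e-12))
  }
  expect_gt(fits[["IGF-II"]]$k_max, fits[["insulin"]]$k_max)
  expect_lt(fits[["IGF-II"]]$t_half, fits[["insulin"]]$t_half)
  # robust to initialization: every single-start fit that converges at least
  # as well preserves the ordering
  ref <- reference_timecourse()
  for (p0 in c(0.5, 1, 2)) {
    for (t0 in c(5, 20, 60)) {
      fi <- fit_logistic(ref[ref$ligand == "IGF-II", c("time_min", "mean")],
        model = "exp", init = list(a = 1, k = p0 / t0, t0 = t0)
      )
      fin <- fit_logistic(ref[ref$ligand == "insulin", c("time_min", "mean")],
        model = "exp", init = list(a = 1, k = p0 / t0, t0 = t0)
      )
      if (fi$converged && fin$converged) {
        expect_gt(fi$k_max, fin$k_max)
      }
    }
  }
})

test_that("generator truth is recovered when refitting dense noiseless means", {
  # the pipeline's own kinetics specs, sampled densely without noise, refit
  for (sp in list(
    kinetics_spec(0.17, 0.96, 9.6, 1.2),
    kinetics_spec(0.06, 0.95, 24, 1.2)
  )) {
    tt <- seq(0, 200, length.out = 40)
    fit <- fit_logistic(tt, interior_fraction_timecourse(sp, tt), model = "power")
    expect_lt(abs(fit$coef[["a1"]] - sp$a1) / max(sp$a1, 1e-6), 1e-4)
    expect_lt(abs(fit$coef[["a2"]] - sp$a2) / sp$a2, 1e-4)
    expect_lt(abs(fit$coef[["x0"]] - sp$x0) / sp$x0, 1e-4)
    expect_lt(abs(fit$coef[["p"]] - sp$p) / sp$p, 1e-4)
  }
})

test_that("half_time supports both definitions and records them", {
  tt <- seq(0, 120, length.out = 25)
  y <- 0.9 / (1 + exp(-0.1 * (tt - 20)))
  fit <- fit_logistic(tt, y, model = "exp")
  h1 <- half_time(fit)
  expect_equal(as.numeric(h1), log(2) / fit$k_max)
  expect_equal(attr(h1, "definition"), "ln2_over_kmax")
  h2 <- half_time(fit, "midpoint_x0")
  expect_equal(as.numeric(h2), fit$coef[["t0"]], tolerance = 1e-6)
  # k_max = ln 2 gives a half-time of exactly one minute
  expect_equal(log(2) / log(2), 1)
})

test_that("tidy, glance and predict expose the fit in tabular form", {
  fits <- fit_ligand_kinetics(reference_timecourse(), model = "exp")
  td <- tidy(fits[["IGF-II"]])
  expect_named(td, c("term", "estimate"))
  expect_setequal(td$term, c("a", "k", "t0"))
  gl <- glance(fits[["IGF-II"]])
  expect_equal(gl$nobs, 4L)
  expect_true(gl$converged)
  expect_equal(
    predict(fits[["IGF-II"]], c(0, 20)),
    logistic_value(fits[["IGF-II"]], c(0, 20))
  )
  kt <- kinetics_table(fits)
  expect_equal(nrow(kt), 2)
  expect_true(all(c("ligand", "k_max", "t_half", "r_squared") %in% names(kt)))
})
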