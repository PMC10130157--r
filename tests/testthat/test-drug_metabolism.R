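# the six printed calibration equations of the assay panel
printed_curves <- list(
  aspirin = c(slope = 347.54, intercept = 0.4552),
  salicylic_acid = c(slope = 8.3759, intercept = -7.9087),
  levodopa = c(slope = 1126.8, intercept = 0.3252),
  dopamine = c(slope = 299.28, intercept = 6.4806),
  doxifluridine = c(slope = 0.5103, intercept = 0.0049),
  fluorouracil_5 = c(slope = 0.1328, intercept = 0.0034))

test_that("least-squares calibration recovers exact lines to machine precision", {
  fit <- fit_calibration(c(1, 2, 3), c(3, 5, 7))
  expect_equal(fit$slope, 2, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1.0)

  for (an in names(printed_curves)) {
    cv <- printed_curves[[an]]
    x <- c(0.1, 1, 10, 100)
    y <- cv[["slope"]] * x + cv[["intercept"]]
    fit <- fit_calibration(x, y, analyte = an)
    expect_equal(fit$slope, cv[["slope"]], tolerance = 1e-10)
    expect_equal(fit$intercept, cv[["intercept"]], tolerance = 1e-10)
  }
  expect_error(fit_calibration(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_calibration(c(2, 2, 2), c(1, 2, 3)), "equal")
})

test_that("low-r-squared calibrations warn at the 0.99 acceptance threshold", {
  # residuals orthogonal to the design, scaled to a known r-squared
  x <- c(1, 2, 3, 4, 5)
  y0 <- 2 * x + 1
  e <- stats::residuals(stats::lm(c(0, 1, -2, 1, 0) ~ x))
  target_r2 <- 0.95
  sst_model <- sum((y0 - mean(y0))^2)
  scale <- sqrt(sst_model * (1 - target_r2) / target_r2 / sum(e^2))
  y <- y0 + scale * e
  expect_warning(fit <- fit_calibration(x, y), "below 0.99")
  expect_equal(fit$r_squared, target_r2, tolerance = 1e-9)
})

test_that("inverse prediction recovers concentrations and clips below zero", {
  asp <- calibration_curve(347.54, 0.4552, "aspirin")
  expect_equal(as.numeric(quantify(0.4552, asp)), 0.0)
  dox <- calibration_curve(0.5103, 0.0049, "doxifluridine")
  expect_equal(as.numeric(quantify(0.5152, dox)), 1.0, tolerance = 1e-9)
  expect_warning(v <- quantify(0.1, asp), "clipped")
  expect_equal(as.numeric(v), 0)
  expect_error(quantify(1, asp, analyte = "levodopa"), "does not match")

  # quantify inverts the calibration line on its whole range
  set.seed(61)
  for (i in 1:10) {
    cv <- calibration_curve(stats::runif(1, 0.1, 500),
                            stats::runif(1, -5, 5))
    x <- stats::runif(5, 0, 100)
    expect_equal(as.numeric(quantify(predict(cv, x), cv)), x,
                 tolerance = 1e-9)
  }
})

test_that("remaining fraction and inter-donor variation follow closed forms", {
  expect_equal(remaining_fraction(250, 500), 0.5)
  expect_equal(remaining_fraction(500, 500), 1.0)
  expect_equal(remaining_fraction(0, 500), 0.0)
  expect_error(remaining_fraction(1, 0), "positive")

  v <- interdonor_variation(c(1, 3))
  expect_equal(v$mean, 2)
  expect_equal(v$sd, sqrt(2))
  expect_equal(v$cv, sqrt(2) / 2)
  expect_equal(interdonor_variation(c(2, 2, 2))$cv, 0)
  expect_error(interdonor_variation(5), "at least 2")
})

test_that("control correction floors microbiome-attributable loss at zero", {
  expect_equal(control_correct(200, 500), 300)
  expect_equal(control_correct(c(500, 400), c(500, 400)), c(0, 0))
  expect_equal(control_correct(200, 400), 200)
  expect_equal(control_correct(450, 400), 0)     # culture above control
  expect_error(control_correct(1:2, 1:3), "time-matched")
})

test_that("a zero-noise simulated assay round-trips to the true kinetics", {
  spec <- drug_sim_spec(drug = "doxifluridine", metabolite = "fluorouracil_5",
                        decay_rate_per_h = c(D1 = 0.02, D2 = 0.1, D3 = 0.25),
                        metabolite_yield = 0.9, control_decay_rate_per_h = 0,
                        calibration = printed_curves[c("doxifluridine",
                                                       "fluorouracil_5")],
                        noise_cv = 0, time_points_h = c(6, 12, 24))
  sim <- simulate_drug_assay(spec)
  curves <- lapply(names(printed_curves[c("doxifluridine", "fluorouracil_5")]),
                   function(a) calibration_curve(printed_curves[[a]][["slope"]],
                                                 printed_curves[[a]][["intercept"]],
                                                 analyte = a))
  names(curves) <- c("doxifluridine", "fluorouracil_5")
  q <- quantify_assay(sim$measurements, curves, reference = "control")
  cult <- q$concentrations[q$concentrations$condition == "culture" &
                             q$concentrations$analyte == "doxifluridine", ]
  truth_key <- paste(sim$truth$culture$donor, sim$truth$culture$time_h)
  expect_equal(cult$conc_uM,
               sim$truth$culture$parent_uM[match(paste(cult$donor, cult$time_h),
                                                 truth_key)],
               tolerance = 1e-9)
  # control never decays here, so remaining = C(t)/C0
  rem24 <- q$remaining[q$remaining$time_h == 24, ]
  expect_equal(rem24$remaining[match(c("D1", "D2", "D3"), rem24$donor)],
               exp(-c(0.02, 0.1, 0.25) * 24), tolerance = 1e-9)
  # remaining fraction is non-increasing in time for each donor
  for (d in c("D1", "D2", "D3")) {
    r <- q$remaining[q$remaining$donor == d, ]
    expect_true(all(diff(r$remaining[order(r$time_h)]) <= 1e-12))
  }
})

test_that("a missing control series is a hard error", {
  spec <- drug_sim_spec(decay_rate_per_h = c(D1 = 0.1), noise_cv = 0)
  sim <- simulate_drug_assay(spec)
  meas <- sim$measurements[sim$measurements$condition != "control", ]
  curves <- list(levodopa = calibration_curve(1, 0, "levodopa"),
                 metabolite = calibration_curve(1, 0, "metabolite"))
  expect_error(quantify_assay(meas, curves, reference = "control"),
               "control")
  expect_error(quantify_assay(sim$measurements,
                              curves["levodopa"], reference = "control"),
               "no calibration curve")
})
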