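test_that("the fitter is exact on continuum-generated curves", {
  rc <- default_construct()
  times <- seq(-120, 720, by = 30)
  for (k_true in c(2, 3.5, 5)) {
    traces <- tibble::tibble(mrna_id = "m1", time_s = times,
                             green = runoff_model_curve(times, k_true, rc, t0 = 60))
    fit <- fit_runoff_elongation(traces, rc, entry_delay_s = 60, n_boot = 0)
    expect_equal(fit$rate_codons_per_s, k_true, tolerance = 1e-3)
  }
})

test_that("the linear-stage slope of the model equals -k/(L*cbar)", {
  rc <- default_construct()
  # stage boundaries: front inside the plain ORF, before reaching the end
  t1 <- 60 + 700 / 3.5; t2 <- 60 + 1200 / 3.5
  slope <- (runoff_model_curve(t2, 3.5, rc) - runoff_model_curve(t1, 3.5, rc)) /
    (t2 - t1)
  cbar_c <- mean_positional_correction(rc, mode = "continuum")
  expect_equal(slope, -3.5 / (1467 * cbar_c), tolerance = 1e-3)
  expect_equal(-3.5 / (1467 * 0.752), -3.17e-3, tolerance = 1e-2)
})

test_that("the fitter recovers the rate from a stochastic ensemble", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.0358, k_elong = 3.5)
  traces <- simulate_runoff_ensemble(rc, kin, 200, drug_event("harringtonine"),
                                     post_drug_s = 720, noise = c(0.2, 0.1),
                                     seed = 31)
  fit <- fit_runoff_elongation(traces, rc, entry_delay_s = 60, n_boot = 50,
                               seed = 32)
  expect_true(fit$success)
  expect_equal(fit$rate_codons_per_s, 3.5, tolerance = 0.3 / 3.5)
  expect_gt(fit$sd, 0)
  expect_equal(length(fit$stage_boundaries_s), 2)
})

test_that("a non-decaying ensemble is flagged, not an error", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.04)
  traces <- simulate_runoff_ensemble(rc, kin, 5, drug_event("cycloheximide"),
                                     post_drug_s = 600, seed = 33)
  fit <- fit_runoff_elongation(traces, rc, n_boot = 0)
  expect_false(fit$success)
})

test_that("total-runoff-time estimator matches its closed form", {
  rc <- default_construct()
  fit <- elongation_from_runoff_time(c(480, 520, 560), rc, entry_delay_s = 60)
  expect_equal(fit$rate_codons_per_s, 1467 / 460, tolerance = 1e-9)
  # inverse identity: a single time L/k + delay returns exactly k
  for (k_star in c(2.2, 3.1, 4.9)) {
    fit1 <- elongation_from_runoff_time(1467 / k_star + 60, rc)
    expect_equal(fit1$rate_codons_per_s, k_star)
  }
  expect_error(elongation_from_runoff_time(numeric(0), rc))
  expect_error(elongation_from_runoff_time(c(500, 50), rc), "entry delay")
})

test_that("runoff-time estimator recovers the rate from simulation", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.03, k_elong = 3.1)
  traces <- simulate_runoff_ensemble(rc, kin, 200, drug_event("harringtonine"),
                                     post_drug_s = 840, noise = c(0, 0),
                                     seed = 34)
  times <- runoff_disappearance_times(traces)
  expect_gt(nrow(times), 190)
  fit <- elongation_from_runoff_time(times$disappearance_s, rc)
  expect_gt(fit$rate_codons_per_s, 2.9)
  expect_lt(fit$rate_codons_per_s, 3.3)
})

test_that("both elongation estimators agree on the same ensemble", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.0358, k_elong = 3.3)
  traces <- simulate_runoff_ensemble(rc, kin, 150, drug_event("harringtonine"),
                                     post_drug_s = 840, noise = c(0, 0),
                                     seed = 35)
  f1 <- fit_runoff_elongation(traces, rc, n_boot = 50, seed = 36)
  f2 <- elongation_from_runoff_time(
    runoff_disappearance_times(traces)$disappearance_s, rc)
  joint_sd <- sqrt(f1$sd^2 + f2$sd^2) + 0.15
  expect_lt(abs(f1$rate_codons_per_s - f2$rate_codons_per_s), 3 * joint_sd)
})

test_that("initiation-rate flux balance reproduces the printed range", {
  rc <- default_construct()
  expect_equal(estimate_initiation_rate(10, 3.5, rc), 1.43, tolerance = 5e-3)
  expect_equal(estimate_initiation_rate(25, 3.5, rc), 3.58, tolerance = 5e-3)
  expect_equal(estimate_initiation_rate(0, 3.5, rc), 0)
  expect_error(estimate_initiation_rate(Inf, 3.5, rc))
})

test_that("tidy and glance methods expose the fit", {
  rc <- default_construct()
  fit <- elongation_from_runoff_time(c(480, 520), rc)
  expect_equal(tidy(fit)$estimate, fit$rate_codons_per_s)
  expect_equal(glance(fit)$method, "total_runoff_time")
})
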