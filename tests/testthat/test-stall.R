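test_that("normal runoff is not stalled and classified normal", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.0358, k_elong = 3.5)
  traces <- simulate_runoff_ensemble(rc, kin, 5, drug_event("harringtonine"),
                                     post_drug_s = 1200, seed = 51)
  calls <- classify_stall_ensemble(traces)
  expect_true(all(!calls$is_stalled))
  expect_true(all(calls$retained_fraction_at_check == 0))
  expect_true(all(calls$decay_class == "normal"))
})

test_that("a roadblock gives a burst decay signature", {
  set.seed(52)
  rc <- default_construct()
  calls <- replicate(25, {
    tr <- make_roadblock_trace(rc, p = sample(300:1200, 1),
                               release_s = 900 + runif(1, 0, 600))
    classify_stall(tr)$decay_class
  })
  expect_gt(mean(calls == "burst"), 0.9)
})

test_that("a damage site gives a slow linear decay signature", {
  rc <- default_construct()
  ds <- generate_dataset(scenario_config("damage_stall_runoff", n_mrna = 25,
                                         seed = 53))
  calls <- classify_stall_ensemble(ds$traces)
  expect_gt(mean(calls$decay_class == "slow_linear"), 0.9)
})

test_that("roadblock and damage ensembles separate with >= 95% accuracy", {
  set.seed(54)
  rc <- default_construct()
  n_each <- 100
  rb <- vapply(seq_len(n_each), function(i) {
    tr <- make_roadblock_trace(rc, p = sample(300:1200, 1),
                               release_s = 900 + runif(1, 0, 600))
    classify_stall(tr)$decay_class
  }, character(1))
  ds <- generate_dataset(scenario_config("damage_stall_runoff",
                                         n_mrna = n_each, seed = 55))
  dm <- classify_stall_ensemble(ds$traces)$decay_class
  accuracy <- (sum(rb == "burst") + sum(dm == "slow_linear")) / (2 * n_each)
  expect_gte(accuracy, 0.95)
})

test_that("stalled calls use the retention threshold", {
  rc <- default_construct()
  times <- seq(-120, 1500, 30)
  flat <- tibble::tibble(time_s = times, green = 10)
  s <- classify_stall(flat)
  expect_true(s$is_stalled)
  expect_gt(s$retained_fraction_at_check, 0.9)
  expect_error(classify_stall(flat[flat$time_s < 600, ]), "check_time")
})
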