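test_that("unknown scenarios are rejected", {
  expect_error(scenario_config("nonsense"), "unknown scenario")
  expect_error(scenario_config("steady_state", n_mrna = 0), "n_mrna")
})

test_that("datasets are deterministic given the seed", {
  cfg <- scenario_config("steady_state", n_mrna = 5, duration_s = 600, seed = 5)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$traces, b$traces)
  expect_identical(a$truth, b$truth)
  c2 <- generate_dataset(scenario_config("steady_state", n_mrna = 5,
                                         duration_s = 600, seed = 6))
  expect_false(identical(a$traces, c2$traces))
})

test_that("every mRNA has exactly one truth record and valid traces", {
  for (sc in c("steady_state", "single_ribosome", "harringtonine_runoff")) {
    cfg <- scenario_config(sc, n_mrna = 4, duration_s = 600, seed = 2)
    ds <- generate_dataset(cfg)
    expect_equal(nrow(ds$truth), 4)
    expect_setequal(unique(ds$traces$mrna_id), ds$truth$mrna_id)
    expect_true(all(is.finite(ds$traces$green)))
    # uniform frame grid per mRNA
    grids <- ds$traces |>
      dplyr::group_by(.data$mrna_id) |>
      dplyr::summarise(ok = length(unique(round(diff(.data$time_s), 9))) == 1)
    expect_true(all(grids$ok))
  }
})

test_that("steady state puts most translating mRNAs in the 10-25 ribosome band", {
  ds <- generate_dataset(scenario_config("steady_state", n_mrna = 60, seed = 9))
  rc <- ds$construct
  per <- ds$traces |>
    dplyr::group_by(.data$mrna_id) |>
    dplyr::summarise(I = mean(.data$green))
  counts <- estimate_ribosome_count(pmax(per$I, 0), rc)$ribosomes
  expect_gt(mean(counts >= 10 & counts <= 25), 0.6)
})

test_that("diffusion scenarios emit tracks with the preset coefficients", {
  ds <- generate_dataset(scenario_config("diffusion_tethered", n_mrna = 3, seed = 3))
  expect_equal(unique(ds$truth$D_um2_per_s), 1.06e-3)
  expect_equal(nrow(ds$tracks), 3 * 120)
  dsf <- generate_dataset(scenario_config("diffusion_free", n_mrna = 2, seed = 3))
  expect_equal(diff(dsf$tracks$time_s[1:2]), 1)
})

test_that("calibrated defaults are internally consistent", {
  p <- paper_default_parameters()
  get <- function(n) p$value[p$parameter == n]
  # off dwell derived so that cycle rate x dwell = off fraction
  expect_equal(get("shutdown_per_hr") * get("off_dwell_mean_s") / 3600,
               get("off_fraction"), tolerance = 0.01)
  expect_equal(get("stall_fraction"), 0.075)
  # initiation range endpoints follow from flux balance at 10 and 25 ribosomes
  rc <- default_construct()
  expect_equal(estimate_initiation_rate(10, get("k_elong_model_fit"), rc),
               get("k_init_min"), tolerance = 0.03)
  expect_equal(estimate_initiation_rate(25, get("k_elong_model_fit"), rc),
               get("k_init_max"), tolerance = 0.01)
})

test_that("xbp1 pause scenario delays runoff relative to the plain reporter", {
  ds_p <- generate_dataset(scenario_config("xbp1_pause_runoff", n_mrna = 25,
                                           duration_s = 1500, seed = 13))
  retained <- ds_p$traces |>
    dplyr::filter(.data$time_s == 900) |>
    dplyr::summarise(m = mean(.data$green))
  pre <- mean(ds_p$traces$green[ds_p$traces$time_s < 0])
  # with a 10% long-stall component some signal persists at 15 min
  expect_gt(retained$m / pre, 0.05)
})
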