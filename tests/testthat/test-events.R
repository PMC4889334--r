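test_that("flat traces yield no events", {
  rc <- default_construct()
  trace <- tibble::tibble(time_s = seq(0, 3600, 30), green = 0)
  expect_equal(nrow(detect_single_ribosome_events(trace, rc)), 0)
  noisy <- dplyr::mutate(trace, green = rnorm(dplyr::n(), 0, 0.15))
  expect_equal(nrow(detect_single_ribosome_events(noisy, rc)), 0)
})

test_that("a deterministic noiseless event gives the exact duration and rate", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0, k_elong = 3)
  tr <- simulate_translation(rc, kin, 1200, deterministic = TRUE,
                             inject_times = 120, frame_interval_s = 5)
  trace <- render_intensity_trace(tr, noise = c(0, 0))
  ev <- detect_single_ribosome_events(trace, rc, median_filter = 1)
  expect_equal(nrow(ev), 1)
  expect_false(ev$overlapping)
  # (L - (e1 + delta)) / k = 1406 / 3 = 468.7 s, inside the 6-8 min window
  dur <- ev$t_loss_s - ev$t_appear_s
  expect_equal(dur, 468.7, tolerance = 0.02)
  expect_gt(dur, 6 * 60); expect_lt(dur, 8 * 60)
  expect_equal(ev$inferred_rate_codons_per_s, 3.0, tolerance = 0.02)
  expect_equal(ev$plateau_intensity, 1)
  expect_true(ev$t_appear_s < ev$t_plateau_start_s &
                ev$t_plateau_start_s < ev$t_loss_s)
})

test_that("stochastic single-ribosome events recover ~3 codons/s", {
  set.seed(41)
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0, k_elong = 3)
  events <- purrr::map_dfr(1:110, function(i) {
    tr <- simulate_translation(rc, kin, 1500, inject_times = 120,
                               mrna_id = paste0("m", i))
    trace <- render_intensity_trace(tr, noise = c(0.2, 0.1))
    detect_single_ribosome_events(trace, rc)
  })
  ok <- events[!events$overlapping, ]
  expect_gt(nrow(ok), 100)
  m <- mean(ok$inferred_rate_codons_per_s)
  expect_gt(m, 2.8); expect_lt(m, 3.2)
})

test_that("two well-separated events on one trace are both found", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0, k_elong = 3)
  tr <- simulate_translation(rc, kin, 3000, deterministic = TRUE,
                             inject_times = c(120, 1800), frame_interval_s = 30)
  trace <- render_intensity_trace(tr, noise = c(0, 0))
  ev <- detect_single_ribosome_events(trace, rc, median_filter = 1)
  expect_equal(nrow(ev), 2)
  expect_true(all(!ev$overlapping))
})

test_that("overlapping events are flagged rather than split", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0, k_elong = 3)
  tr <- simulate_translation(rc, kin, 1500, deterministic = TRUE,
                             inject_times = c(120, 200), frame_interval_s = 30)
  trace <- render_intensity_trace(tr, noise = c(0, 0))
  ev <- detect_single_ribosome_events(trace, rc, median_filter = 1)
  expect_true(any(ev$overlapping))
})
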