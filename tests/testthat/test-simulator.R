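test_that("no initiation means no ribosomes and zero intensity", {
  rc <- default_construct()
  tr <- simulate_translation(rc, kinetic_parameters(k_init = 0), 600, seed = 1)
  expect_equal(nrow(tr$ribosomes), 0)
  trace <- render_intensity_trace(tr, noise = c(0, 0))
  expect_true(all(trace$green == 0))
})

test_that("deterministic single ribosome terminates after L steps at 1/k each", {
  rc <- default_construct()
  tr <- simulate_translation(rc, kinetic_parameters(k_init = 0, k_elong = 3),
                             600, deterministic = TRUE, inject_times = 0)
  expect_equal(tr$ribosomes$term_time_s, 1467 / 3, tolerance = 1e-6)
  # noiseless rendering is rise-plateau-drop with plateau at one unit
  trace <- render_intensity_trace(tr, noise = c(0, 0))
  expect_equal(max(trace$green), 1)
  on <- trace$green[trace$time_s > 250 & trace$time_s < 480]
  expect_true(all(on == 1))
  expect_true(all(diff(trace$green[trace$time_s <= 480]) >= 0))
})

test_that("steric exclusion is never violated at any sampled frame", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.08, k_elong = 3.5, footprint_codons = 10)
  tr <- simulate_translation(rc, kin, 2400, seed = 5)
  gaps <- tr$positions |>
    dplyr::arrange(.data$frame, .data$position) |>
    dplyr::group_by(.data$frame) |>
    dplyr::summarise(min_gap = if (dplyr::n() > 1) min(diff(.data$position)) else Inf)
  expect_true(all(gaps$min_gap >= 10))
  expect_true(all(tr$positions$position >= 1 &
                    tr$positions$position <= rc$orf_length_codons))
})

test_that("per-ribosome positions are nondecreasing in time", {
  rc <- default_construct()
  tr <- simulate_translation(rc, kinetic_parameters(k_init = 0.03), 1800, seed = 8)
  mono <- tr$positions |>
    dplyr::arrange(.data$ribosome, .data$frame) |>
    dplyr::group_by(.data$ribosome) |>
    dplyr::summarise(ok = all(diff(.data$position) >= 0))
  expect_true(all(mono$ok))
})

test_that("long-run occupancy follows Little's law", {
  # k_init * L / k_elong = 10.0 ribosomes; >= 200 mRNA-hours
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.0239, k_elong = 3.5)
  set.seed(42)
  burn <- 900
  counts <- replicate(50, {
    tr <- simulate_translation(rc, kin, duration_s = burn + 4 * 3600,
                               frame_interval_s = 60)
    keep <- tr$positions$time_s >= burn
    sum(keep) / length(unique(tr$positions$time_s[keep]))
  })
  expect_equal(mean(counts), 0.0239 * 1467 / 3.5, tolerance = 0.05)
})

test_that("puromycin empties the mRNA and zeroes the signal", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.04)
  traces <- simulate_runoff_ensemble(rc, kin, 3,
                                     drug_event("puromycin", entry_delay_s = 30),
                                     post_drug_s = 300, seed = 2)
  expect_true(all(traces$green[traces$time_s > 30] == 0))
  expect_gt(mean(traces$green[traces$time_s < 0]), 5)
})

test_that("cycloheximide freezes the signal exactly in noiseless mode", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.04)
  traces <- simulate_runoff_ensemble(rc, kin, 3, drug_event("cycloheximide"),
                                     post_drug_s = 600, seed = 3)
  per <- traces |>
    dplyr::filter(.data$time_s > 60) |>
    dplyr::group_by(.data$mrna_id) |>
    dplyr::summarise(v = stats::var(.data$green))
  expect_true(all(per$v == 0))
})

test_that("harringtonine runoff completes by one traversal time", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.0358, k_elong = 3.5)
  traces <- simulate_runoff_ensemble(rc, kin, 20, drug_event("harringtonine"),
                                     post_drug_s = 720, seed = 4)
  # the ensemble-mean noiseless trace is nonincreasing after the entry
  # delay (single traces can tick up while a ribosome crosses the epitope
  # array between terminations, but never by more than the array gain)
  mt <- traces |>
    dplyr::filter(.data$time_s >= 60) |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(g = mean(.data$green))
  expect_true(all(diff(mt$g) <= 0.05))
  # each trace ends at zero and never climbs back near its starting level
  per <- traces |>
    dplyr::filter(.data$time_s >= 60) |>
    dplyr::group_by(.data$mrna_id) |>
    dplyr::summarise(net = .data$green[dplyr::n()] - .data$green[1],
                     peak_after = max(.data$green) - .data$green[1])
  expect_true(all(per$net < 0))
  # any transient gain is bounded by the ribosomes still inside the epitope
  # array at drug-effect time (each can add at most one unit)
  expect_true(all(per$peak_after <= 8))
  # ... and reach zero by L/k plus delay and queueing slack
  final <- traces |> dplyr::filter(.data$time_s >= 60 + 1467 / 3.5 + 90)
  expect_true(all(final$green == 0))
})

test_that("ensemble-mean runoff matches the deterministic continuum curve", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.0358, k_elong = 3.5)
  traces <- simulate_runoff_ensemble(rc, kin, 300, drug_event("harringtonine"),
                                     post_drug_s = 720, seed = 8)
  mt <- traces |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(g = mean(.data$green))
  pre <- mean(mt$g[mt$time_s <= 0 & mt$time_s >= -120])
  post <- mt[mt$time_s >= 0, ]
  model <- runoff_model_curve(post$time_s, 3.5, rc, t0 = 60)
  dev <- abs(post$g / pre - model)
  expect_lt(max(dev), 0.04)   # Monte-Carlo + front-smearing error
  expect_lt(mean(dev), 0.02)
})

test_that("a damage site retains intensity at 15 minutes", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.0358, k_elong = 3.5,
                            damage_sites = list(damage_site(700, 300)))
  traces <- simulate_runoff_ensemble(rc, kin, 30, drug_event("harringtonine"),
                                     post_drug_s = 1200, seed = 6)
  at900 <- traces |>
    dplyr::filter(.data$time_s == 900) |>
    dplyr::summarise(m = mean(.data$green))
  pre <- mean(traces$green[traces$time_s < 0])
  expect_gt(at900$m / pre, 0.3)
})

test_that("identical seeds give byte-identical runs", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.04, k_shutdown_per_hr = 1,
                            k_reinit_per_s = 0.003)
  a <- simulate_translation(rc, kin, 1200, seed = 99, log_events = TRUE)
  b <- simulate_translation(rc, kin, 1200, seed = 99, log_events = TRUE)
  expect_identical(a$events, b$events)
  expect_identical(a$positions, b$positions)
  expect_identical(a$state_log, b$state_log)
})

test_that("noise model matches its stated variance", {
  rc <- default_construct()
  tr <- simulate_translation(rc, kinetic_parameters(k_init = 0), 1e4,
                             frame_interval_s = 1, seed = 1)
  trace <- render_intensity_trace(tr, noise = c(0.3, 0), seed = 12)
  expect_equal(sd(trace$green), 0.3, tolerance = 0.03)
  expect_error(render_intensity_trace(tr, noise = c(-0.1, 0)), "noise")
})

test_that("drug entry delay is honored", {
  rc <- default_construct()
  kin <- kinetic_parameters(k_init = 0.04)
  traces <- simulate_runoff_ensemble(rc, kin, 3,
                                     drug_event("puromycin", entry_delay_s = 120),
                                     post_drug_s = 400, seed = 9)
  expect_gt(mean(traces$green[traces$time_s == 90]), 1)
  expect_true(all(traces$green[traces$time_s > 120] == 0))
})

test_that("2D diffusion increments have the closed-form variance", {
  set.seed(13)
  tr <- simulate_diffusion_track(D = 0.05, duration_s = 1e4, frame_interval_s = 1)
  expect_equal(var(diff(tr$x_um)), 2 * 0.05 * 1, tolerance = 0.05)
  # ensemble MSD at one lag of 30 s near 4 D dt
  tracks <- simulate_diffusion_track(0.047, 3000, 30, n_tracks = 50, seed = 14)
  msd1 <- tracks |>
    dplyr::group_by(.data$mrna_id) |>
    dplyr::summarise(m = mean(diff(.data$x_um)^2 + diff(.data$y_um)^2))
  expect_equal(mean(msd1$m), 4 * 0.047 * 30, tolerance = 0.1)
  still <- simulate_diffusion_track(0, 100, 10)
  expect_true(all(still$x_um == 0 & still$y_um == 0))
  expect_error(simulate_diffusion_track(-1, 100, 10), "nonnegative")
})
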