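test_that("exposed epitope fraction matches the enumeration oracle", {
  rc <- default_construct()
  expect_equal(exposed_epitope_fraction(0, rc), 0)
  expect_equal(exposed_epitope_fraction(rc$orf_length_codons, rc), 1)
  # 12 of 24 epitopes are visible from codon 374 on the default reporter
  expect_equal(exposed_epitope_fraction(374, rc), 0.5)
  expect_equal(exposed_epitope_fraction(374, rc),
               oracle_fraction(374, rc$epitope_positions, rc$exit_tunnel_codons))
  expect_error(exposed_epitope_fraction(-1, rc), "position")
  expect_error(exposed_epitope_fraction(rc$orf_length_codons + 1, rc), "position")
})

test_that("fraction is monotone and bounded for random constructs", {
  set.seed(11)
  for (i in 1:20) {
    rc <- random_construct()
    xs <- sort(sample(0:rc$orf_length_codons, 40))
    f <- exposed_epitope_fraction(xs, rc)
    expect_true(all(diff(f) >= 0))
    expect_true(all(f >= 0 & f <= 1))
    fc <- exposed_epitope_fraction(xs, rc, mode = "continuum")
    expect_true(all(diff(fc) >= 0))
    expect_true(all(fc >= 0 & fc <= 1))
  }
})

test_that("site intensity is additive and handles edge cases", {
  rc <- default_construct()
  expect_equal(site_intensity(integer(0), rc), 0)
  expect_equal(site_intensity(rc$orf_length_codons, rc), 1)
  expect_equal(site_intensity(c(374, 1467), rc), 1.5)
  set.seed(3)
  a <- sample(1:1467, 7); b <- sample(1:1467, 5)
  expect_equal(site_intensity(c(a, b), rc),
               site_intensity(a, rc) + site_intensity(b, rc))
  expect_error(site_intensity(0, rc))
})

test_that("mean positional correction equals exact enumeration", {
  rc <- default_construct()
  cbar <- mean_positional_correction(rc)
  expect_equal(cbar, oracle_mean_correction(rc))
  expect_equal(cbar, 0.752, tolerance = 1e-3)
  # continuum ramp agrees with the discrete step form within half a step
  cbar_c <- mean_positional_correction(rc, mode = "continuum")
  expect_lt(abs(cbar - cbar_c), 1 / (2 * length(rc$epitope_positions)))
  # all epitopes visible immediately -> correction 1
  rc0 <- reporter_construct("instant", 100, c(1, 2, 3), exit_tunnel_codons = 0)
  expect_lt(1 - mean_positional_correction(rc0), 0.03)
  # single epitope visible only at the stop codon -> 1/L
  rc1 <- reporter_construct("terminal", 100, 100, exit_tunnel_codons = 0)
  expect_equal(mean_positional_correction(rc1), 1 / 100)
})

test_that("ribosome count inverts the intensity model", {
  rc <- default_construct()
  cbar <- mean_positional_correction(rc)
  expect_equal(estimate_ribosome_count(0, rc)$ribosomes, 0)
  expect_equal(estimate_ribosome_count(10 * cbar, rc)$ribosomes, 10)
  expect_error(estimate_ribosome_count(NaN, rc))
  # unbiased under uniform ribosome placement (Monte-Carlo oracle)
  set.seed(7)
  est <- replicate(1000, {
    pos <- sample(1:1467, 15)
    estimate_ribosome_count(site_intensity(pos, rc), rc)$ribosomes
  })
  expect_lt(abs(mean(est) / 15 - 1), 0.02)
})

test_that("label stoichiometry gives the expected brightness ratios", {
  expect_equal(expected_label_ratio(label_stoichiometry(24, 2, 2, 1, 24)), 4)
  expect_equal(expected_label_ratio(label_stoichiometry(24, 2, 2, 0.5, 24)), 2)
  expect_equal(expected_label_ratio(label_stoichiometry(occupancy = 0)), 0)
  expect_error(expected_label_ratio(label_stoichiometry(reference_fluorophores = 0)))
  expect_error(label_stoichiometry(occupancy = 1.2))
})

test_that("construct round-trips through YAML and JSON", {
  rc <- reporter_preset("xbp1_pause")
  for (ext in c("yaml", "json")) {
    path <- file.path(withr::local_tempdir(), paste0("c.", ext))
    write_construct(rc, path)
    rc2 <- read_construct(path)
    expect_equal(rc2$orf_length_codons, rc$orf_length_codons)
    expect_equal(rc2$epitope_positions, rc$epitope_positions)
  }
  expect_error(reporter_construct("bad", 100, c(5, 5)), "increasing")
  expect_error(reporter_construct("bad", 100, 200), "\\[1, L\\]")
})
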