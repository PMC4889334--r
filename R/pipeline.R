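#' Run a simulation scenario from a YAML config file
#'
#' Reads a scenario config (keys as in [scenario_config()]), generates the
#' dataset, and writes `traces.csv`/`tracks.csv`, `truth.json` and
#' `manifest.json` to `out_dir`.  Files are written to a temporary name and
#' renamed, so a failed run leaves no partial output.
#'
#' @param config_path Path to a YAML config.
#' @param out_dir Output directory (created if missing).
#' @param seed Optional seed override.
#' @return The generated dataset, invisibly.
#' @export
run_simulate <- function(config_path, out_dir, seed = NULL) {
  if (!file.exists(config_path)) abort(sprintf("config not found: %s", config_path))
  raw <- yaml::read_yaml(config_path)
  cfg <- scenario_config(
    scenario = raw$scenario %||% abort("config must name a scenario"),
    construct = raw$construct, n_mrna = raw$n_mrna,
    duration_s = raw$duration_s,
    frame_interval_s = raw$frame_interval_s %||% 30,
    noise = unlist(raw$noise %||% c(0.2, 0.1)),
    seed = seed %||% raw$seed %||% 1,
    kinetics_overrides = raw$kinetics %||% list())
  invisible(generate_dataset(cfg, out_dir = out_dir))
}

#' Run an estimator on a trace file
#'
#' Dispatches to the matching estimator and writes `results.json` (and a
#' `summary.tsv` for tabular results) plus a manifest to `out_dir`.
#'
#' @param what One of `"runoff"`, `"states"`, `"single-ribosome"`,
#'   `"stalls"`, `"buildup"`, `"distribution"`, `"diffusion"`, `"count"`.
#' @param traces_path CSV of traces (or tracks for `"diffusion"`).
#' @param construct Construct preset name or [reporter_construct()].
#' @param out_dir Optional output directory; when `NULL` nothing is
#'   written.
#' @param ... Passed on to the estimator.
#' @return The estimator result, invisibly when writing, visibly
#'   otherwise.
#' @export
run_analyze <- function(what = c("runoff", "states", "single-ribosome",
                                 "stalls", "buildup", "distribution",
                                 "diffusion", "count"),
                        traces_path, construct = "kif18b_suntag24",
                        out_dir = NULL, ...) {
  what <- match.arg(what)
  construct <- .resolve_construct(construct)
  traces <- read_traces(traces_path,
                        require = if (what == "diffusion") "tracks" else "traces")
  res <- switch(what,
    runoff = fit_runoff_elongation(traces, construct, ...),
    states = summarize_state_switching(traces, ...),
    `single-ribosome` = purrr::map_dfr(
      split(traces, traces$mrna_id),
      detect_single_ribosome_events, construct = construct, ...),
    stalls = classify_stall_ensemble(traces, ...),
    buildup = buildup_analysis(traces, construct, ...),
    distribution = {
      per_site <- traces |>
        dplyr::group_by(.data$mrna_id) |>
        dplyr::summarise(intensity = mean(.data$green), .groups = "drop")
      intensity_distribution(per_site$intensity,
                             bin_edges = seq(0, ceiling(max(per_site$intensity) + 1),
                                             length.out = 13), ...)
    },
    diffusion = estimate_diffusion_ensemble(traces, ...),
    count = {
      per_site <- traces |>
        dplyr::group_by(.data$mrna_id) |>
        dplyr::summarise(intensity = mean(.data$green), .groups = "drop")
      dplyr::bind_cols(per_site["mrna_id"],
                       estimate_ribosome_count(pmax(per_site$intensity, 0), construct))
    })
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    js <- if (is.data.frame(res)) res
          else if (inherits(res, c("elongation_fit", "buildup_fit")))
            as.list(glance(res))
          else res[!vapply(res, is.data.frame, logical(1))]
    jsonlite::write_json(js, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    if (is.data.frame(res))
      write.table(res, file.path(out_dir, "summary.tsv"), sep = "\t",
                  row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(command = "analyze", what = what,
                              traces = traces_path, construct = construct$name,
                              package_version = as.character(utils::packageVersion("ribotrace"))),
                         file.path(out_dir, "manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    return(invisible(res))
  }
  res
}

#' End-to-end reproduction of the headline quantities
#'
#' Regenerates, from scratch, the quantities the package is calibrated to:
#' the expected mRNA-label brightness ratio at half hairpin occupancy, the
#' runoff-model and total-runoff-time elongation rates, the mean
#' single-ribosome elongation rate, and the free and tethered diffusion
#' coefficients — each by simulating the matching scenario at its
#' ground-truth parameters and running the corresponding estimator.
#'
#' @param seed Integer seed driving every simulation.
#' @param targets Optional character vector restricting the quantities
#'   (`"none"` gives an empty report).
#' @param out_dir Optional directory for `report.json` and
#'   `manifest.json`.
#' @return A tibble (`quantity`, `value`, `expected`, `tol_rel`, `n`,
#'   `pass`).
#' @export
run_reproduce <- function(seed = 1, targets = NULL, out_dir = NULL) {
  all_q <- c("label_ratio_half_occupancy", "runoff_fit_elongation",
             "runoff_time_elongation", "single_ribosome_elongation",
             "diffusion_free", "diffusion_tethered")
  targets <- if (is.null(targets)) all_q
             else if (identical(targets, "none")) character(0)
             else match.arg(targets, all_q, several.ok = TRUE)
  rows <- list()
  add <- function(q, value, expected, tol_rel, n) {
    rows[[q]] <<- tibble::tibble(quantity = q, value = value,
                                 expected = expected, tol_rel = tol_rel,
                                 n = n,
                                 pass = abs(value - expected) <= tol_rel * expected)
  }
  if ("label_ratio_half_occupancy" %in% targets) {
    add("label_ratio_half_occupancy",
        expected_label_ratio(label_stoichiometry(occupancy = 0.5)), 2, 1e-9, 1L)
  }
  if ("runoff_fit_elongation" %in% targets) {
    r <- reproduce_runoff_fit(seed = seed)
    add("runoff_fit_elongation", r$value, 3.5, 0.1, r$n)
  }
  if ("runoff_time_elongation" %in% targets) {
    r <- reproduce_runoff_time(seed = seed + 1)
    add("runoff_time_elongation", r$value, 3.1, 0.1, r$n)
  }
  if ("single_ribosome_elongation" %in% targets) {
    r <- reproduce_single_ribosome(seed = seed + 2)
    add("single_ribosome_elongation", r$value, 3.0, 0.1, r$n)
  }
  if ("diffusion_free" %in% targets) {
    r <- reproduce_diffusion("diffusion_free", seed = seed + 3)
    add("diffusion_free", r$value, 0.047, 0.1, r$n)
  }
  if ("diffusion_tethered" %in% targets) {
    r <- reproduce_diffusion("diffusion_tethered", seed = seed + 4)
    add("diffusion_tethered", r$value, 1.06e-3, 0.1, r$n)
  }
  report <- if (length(rows)) dplyr::bind_rows(rows)
            else tibble::tibble(quantity = character(0), value = numeric(0),
                                expected = numeric(0), tol_rel = numeric(0),
                                n = integer(0), pass = logical(0))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    jsonlite::write_json(list(command = "reproduce", seed = seed,
                              package_version = as.character(utils::packageVersion("ribotrace"))),
                         file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  report
}

#' Recompute one headline quantity by simulation + estimation
#'
#' These helpers run the full pipeline for a single quantity and are the
#' building blocks of [run_reproduce()] and of the repository's
#' reproduction script.  Each returns `list(value, n)`.
#'
#' @param n_mrna Ensemble size.
#' @param k_elong Ground-truth elongation rate (codons/s).
#' @param seed Integer seed.
#' @name reproduce_quantities
NULL

#' @rdname reproduce_quantities
#' @export
reproduce_runoff_fit <- function(n_mrna = 300, k_elong = 3.5, seed = 1) {
  construct <- reporter_preset("kif18b_suntag24")
  kin <- kinetic_parameters(k_init = 15 * k_elong / construct$orf_length_codons,
                            k_elong = k_elong)
  traces <- simulate_runoff_ensemble(construct, kin, n_mrna = n_mrna,
                                     drug = drug_event("harringtonine"),
                                     post_drug_s = 720, noise = c(0.2, 0.1),
                                     seed = seed)
  fit <- fit_runoff_elongation(traces, construct, entry_delay_s = 60,
                               n_boot = 0)
  list(value = fit$rate_codons_per_s, n = n_mrna)
}

#' @rdname reproduce_quantities
#' @export
reproduce_runoff_time <- function(n_mrna = 300, k_elong = 3.1, seed = 1) {
  construct <- reporter_preset("kif18b_suntag24")
  kin <- kinetic_parameters(k_init = 0.03, k_elong = k_elong)
  traces <- simulate_runoff_ensemble(construct, kin, n_mrna = n_mrna,
                                     drug = drug_event("harringtonine"),
                                     post_drug_s = 840, noise = c(0, 0),
                                     seed = seed)
  times <- runoff_disappearance_times(traces)
  fit <- elongation_from_runoff_time(times$disappearance_s, construct,
                                     entry_delay_s = 60)
  list(value = fit$rate_codons_per_s, n = nrow(times))
}

#' @rdname reproduce_quantities
#' @export
reproduce_single_ribosome <- function(n_mrna = 150, k_elong = 3.0, seed = 1) {
  cfg <- scenario_config("single_ribosome", n_mrna = n_mrna, seed = seed,
                         kinetics_overrides = list(k_elong = k_elong))
  ds <- generate_dataset(cfg)
  construct <- ds$construct
  events <- purrr::map_dfr(split(ds$traces, ds$traces$mrna_id),
                           detect_single_ribosome_events,
                           construct = construct)
  ok <- events[!events$overlapping, ]
  list(value = mean(ok$inferred_rate_codons_per_s), n = nrow(ok))
}

#' @rdname reproduce_quantities
#' @param scenario `"diffusion_free"` or `"diffusion_tethered"`.
#' @export
reproduce_diffusion <- function(scenario = "diffusion_free", n_mrna = 300,
                                seed = 1) {
  ds <- generate_dataset(scenario_config(scenario, n_mrna = n_mrna, seed = seed))
  fits <- estimate_diffusion_ensemble(ds$tracks, max_lag_frames = 5)
  list(value = mean(fits$D_um2_per_s), n = nrow(fits))
}
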