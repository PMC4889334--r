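#' Calibrated default parameters for the simulation scenarios
#'
#' The numbers the scenario generator is calibrated to: steady-state
#' polysomes of 10–25 ribosomes, harringtonine-runoff elongation near
#' 3.5 codons/s (3.1 by the total-runoff-time route, 3.0 for single
#' ribosomes, 4.9 for the codon-optimized reporter), initiation between
#' 1.4 and 3.6 per minute, complete translational shutdown/re-initiation
#' cycles at 0.29 per mRNA per hour with about 2.5% of the lifetime spent
#' off (hence a mean off dwell of ~5.2 min), a 5–10% stalled-mRNA
#' fraction after runoff, and diffusion coefficients of 0.047 um^2/s
#' (free mRNA) and 1.06e-3 um^2/s (membrane-tethered).
#'
#' @return A tibble (`parameter`, `value`, `unit`, `description`).
#' @export
paper_default_parameters <- function() {
  tibble::tribble(
    ~parameter, ~value, ~unit, ~description,
    "k_elong_model_fit", 3.5, "codons/s", "elongation rate from runoff model fitting on the main reporter",
    "k_elong_runoff_time", 3.1, "codons/s", "elongation rate from total runoff times",
    "k_elong_single_ribosome", 3.0, "codons/s", "mean single-ribosome elongation rate",
    "k_elong_codon_optimized", 4.9, "codons/s", "elongation rate on the codon-optimized reporter",
    "k_init_steady", 0.04, "1/s", "steady-state initiation rate giving ~17 ribosomes on the main reporter",
    "k_init_min", 1.4, "1/min", "low end of the initiation-rate range (10 ribosomes)",
    "k_init_max", 3.6, "1/min", "high end of the initiation-rate range (25 ribosomes)",
    "footprint_codons", 10, "codons", "steric exclusion length (~30 nt)",
    "shutdown_per_hr", 0.29, "1/hr", "complete translational shutdown/re-initiation cycles per mRNA-hour",
    "off_fraction", 0.025, "fraction", "fraction of mRNA lifetime spent in the non-translating state",
    "off_dwell_mean_s", 312, "s", "mean non-translating dwell (0.025 / 0.29 per hr = 5.2 min)",
    "stall_fraction", 0.075, "fraction", "fraction of mRNAs with a stalled ribosome (midpoint of 5-10%)",
    "damage_dwell_mean_s", 300, "s", "per-ribosome dwell at a damaged nucleotide",
    "pause_short_dwell_s", 10, "s", "short component of the pause-site dwell mixture",
    "pause_long_dwell_s", 800, "s", "long (>10 min) component of the pause-site dwell mixture",
    "pause_long_fraction", 0.1, "fraction", "probability of the long pause component",
    "emi1_silent_fraction", 0.80, "fraction", "mixture weight of non-translating transcripts (long 5' UTR)",
    "emi1_low_k_init", 0.004, "1/s", "initiation rate of the weakly translating mixture component",
    "emi1_high_fraction", 0.02, "fraction", "mixture weight of the highly translating component",
    "D_free", 0.047, "um^2/s", "diffusion coefficient of free cytosolic mRNA spots",
    "D_tethered", 1.06e-3, "um^2/s", "diffusion coefficient of membrane-tethered mRNA spots",
    "frame_interval_s", 30, "s", "imaging frame interval",
    "noise_sigma0", 0.2, "units", "additive noise sd (single-ribosome plateau SNR ~ 5)",
    "noise_sigma1", 0.1, "sqrt(units)", "signal-dependent noise scale (variance sigma0^2 + sigma1^2 I)")
}

.param <- function(name) {
  p <- paper_default_parameters()
  p$value[p$parameter == name]
}

.scenarios <- c("steady_state", "harringtonine_runoff", "puromycin",
                "cycloheximide", "hippuristanol_runoff", "state_switching",
                "new_transcript_buildup", "single_ribosome",
                "xbp1_pause_runoff", "damage_stall_runoff", "emi1_mixture",
                "diffusion_free", "diffusion_tethered")

#' Configure a synthetic-data scenario
#'
#' Each scenario reproduces one experimental design at desk scale:
#' polysomal steady state, the four drug perturbations, reversible
#' shutdown/re-initiation, polysome buildup on new transcripts,
#' single-ribosome events on a weakly initiating reporter, pause-site and
#' damage runoffs, the initiation-rate mixture of the repressive 5' UTR,
#' and free/tethered 2D spot diffusion.
#'
#' @param scenario One of the scenario names (see Details).
#' @param construct Construct preset name or a [reporter_construct()].
#' @param n_mrna Number of mRNAs (tracks for the diffusion scenarios).
#' @param duration_s Imaging duration (s); scenario-specific default.
#' @param frame_interval_s Frame interval (s).
#' @param noise `c(sigma0, sigma1)` measurement noise.
#' @param seed Integer seed recorded in the output.
#' @param kinetics_overrides Named list overriding [kinetic_parameters()]
#'   fields.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(scenario, construct = NULL, n_mrna = NULL,
                            duration_s = NULL, frame_interval_s = 30,
                            noise = c(0.2, 0.1), seed = 1,
                            kinetics_overrides = list()) {
  if (!scenario %in% .scenarios)
    abort(sprintf("unknown scenario '%s'", scenario))
  defaults <- switch(scenario,
    steady_state = list(construct = "kif18b_suntag24", n_mrna = 100, duration_s = 1800),
    harringtonine_runoff = list(construct = "kif18b_suntag24", n_mrna = 300, duration_s = 900),
    puromycin = list(construct = "kif18b_suntag24", n_mrna = 50, duration_s = 900),
    cycloheximide = list(construct = "kif18b_suntag24", n_mrna = 50, duration_s = 900),
    hippuristanol_runoff = list(construct = "kif18b_suntag24", n_mrna = 300, duration_s = 900),
    state_switching = list(construct = "kif18b_suntag24", n_mrna = 200, duration_s = 3600),
    new_transcript_buildup = list(construct = "kif18b_suntag24", n_mrna = 30, duration_s = 900),
    single_ribosome = list(construct = "kif18b_suntag24", n_mrna = 150, duration_s = 7200),
    xbp1_pause_runoff = list(construct = "xbp1_pause", n_mrna = 100, duration_s = 2400),
    damage_stall_runoff = list(construct = "kif18b_suntag24", n_mrna = 100, duration_s = 2400),
    emi1_mixture = list(construct = "emi1_long_5utr", n_mrna = 300, duration_s = 1800),
    diffusion_free = list(construct = "kif18b_suntag24", n_mrna = 300, duration_s = 99),
    diffusion_tethered = list(construct = "kif18b_suntag24", n_mrna = 300, duration_s = 3570))
  if (scenario == "diffusion_free") frame_interval_s <- 1
  cfg <- list(scenario = scenario,
              construct = construct %||% defaults$construct,
              n_mrna = n_mrna %||% defaults$n_mrna,
              duration_s = duration_s %||% defaults$duration_s,
              frame_interval_s = frame_interval_s,
              noise = noise, seed = as.integer(seed),
              kinetics_overrides = kinetics_overrides)
  if (cfg$n_mrna < 1) abort("n_mrna must be >= 1")
  structure(cfg, class = "scenario_config")
}

.resolve_construct <- function(x) {
  if (inherits(x, "reporter_construct")) x else reporter_preset(x)
}

.scenario_kinetics <- function(scenario, construct, overrides) {
  base <- switch(scenario,
    steady_state = ,
    harringtonine_runoff = ,
    puromycin = ,
    cycloheximide = ,
    hippuristanol_runoff = ,
    new_transcript_buildup = kinetic_parameters(k_init = .param("k_init_steady")),
    state_switching = kinetic_parameters(
      k_init = .param("k_init_steady"),
      k_shutdown_per_hr = .param("shutdown_per_hr"),
      k_reinit_per_s = 1 / .param("off_dwell_mean_s")),
    single_ribosome = kinetic_parameters(k_init = 3e-4),
    xbp1_pause_runoff = kinetic_parameters(
      k_init = .param("k_init_steady"),
      pause_sites = list(pause_site(construct$orf_length_codons - 30L,
                                    .param("pause_short_dwell_s"),
                                    .param("pause_long_dwell_s"),
                                    .param("pause_long_fraction")))),
    damage_stall_runoff = kinetic_parameters(k_init = .param("k_init_steady")),
    emi1_mixture = kinetic_parameters(k_init = .param("k_init_steady")),
    kinetic_parameters())
  for (nm in names(overrides)) base[[nm]] <- overrides[[nm]]
  do.call(kinetic_parameters, base[setdiff(names(base), NULL)])
}

#' Generate a complete labeled synthetic dataset for one scenario
#'
#' Deterministic given the config seed.  Returns intensity traces (or 2D
#' tracks for the diffusion scenarios), one ground-truth record per mRNA,
#' and the fully resolved configuration.  With `out_dir`, writes
#' `traces.csv` (or `tracks.csv`), `truth.json` and `manifest.json`.
#'
#' @param config A [scenario_config()].
#' @param out_dir Optional output directory.
#' @return A list with `traces` (or `tracks`), `truth` (tibble, one row
#'   per mRNA), `config` (resolved), and `drug` where applicable.
#' @export
generate_dataset <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  construct <- .resolve_construct(config$construct)
  sc <- config$scenario

  if (sc %in% c("diffusion_free", "diffusion_tethered")) {
    D <- if (sc == "diffusion_free") .param("D_free") else .param("D_tethered")
    tracks <- simulate_diffusion_track(D, config$duration_s,
                                       config$frame_interval_s,
                                       n_tracks = config$n_mrna) |>
      dplyr::mutate(dataset_id = sc, .before = 1)
    truth <- tibble::tibble(mrna_id = unique(tracks$mrna_id), D_um2_per_s = D)
    out <- list(tracks = tracks, truth = truth, config = config)
    return(.write_dataset(out, out_dir))
  }

  kin <- .scenario_kinetics(sc, construct, config$kinetics_overrides)
  drug <- switch(sc,
    harringtonine_runoff = ,
    xbp1_pause_runoff = ,
    damage_stall_runoff = drug_event("harringtonine"),
    hippuristanol_runoff = drug_event("hippuristanol"),
    puromycin = drug_event("puromycin"),
    cycloheximide = drug_event("cycloheximide"),
    NULL)

  equilibrated <- !sc %in% c("new_transcript_buildup", "single_ribosome")
  L <- construct$orf_length_codons
  equil <- if (equilibrated)
    ceiling(1.5 * L / kin$k_elong / config$frame_interval_s) * config$frame_interval_s
  else 0

  traces <- vector("list", config$n_mrna)
  truth <- vector("list", config$n_mrna)
  for (i in seq_len(config$n_mrna)) {
    id <- sprintf("mrna_%04d", i)
    kin_i <- kin
    extra <- list()
    if (sc == "emi1_mixture") {
      # three-component initiation mixture: silent / weak / strong
      u <- runif(1)
      p_silent <- .param("emi1_silent_fraction")
      p_high <- .param("emi1_high_fraction")
      kin_i$k_init <- if (u < p_silent) 0
        else if (u < p_silent + p_high) .param("k_init_steady")
        else .param("emi1_low_k_init")
      extra$mixture_component <- if (u < p_silent) "silent"
        else if (u < p_silent + p_high) "high" else "low"
    }
    if (sc == "damage_stall_runoff") {
      # a lesion at a random interior position on every mRNA
      dpos <- sample(seq(100L, L - 100L), 1)
      kin_i$damage_sites <- list(damage_site(dpos, .param("damage_dwell_mean_s")))
      extra$damage_position <- dpos
    }
    dr <- if (is.null(drug)) NULL
          else drug_event(drug$drug, add_time_s = equil,
                          entry_delay_s = drug$entry_delay_s)
    traj <- simulate_translation(construct, kin_i,
                                 duration_s = equil + config$duration_s,
                                 drugs = dr,
                                 frame_interval_s = config$frame_interval_s,
                                 mrna_id = id)
    # time 0 = drug addition (drug scenarios) or start of observation;
    # keep a pre-drug window for normalization, drop the equilibration burn-in
    keep_from <- if (!equilibrated) 0 else if (is.null(drug)) 0 else -300
    tr <- render_intensity_trace(traj, noise = config$noise) |>
      dplyr::mutate(time_s = .data$time_s - equil) |>
      dplyr::filter(.data$time_s >= keep_from)
    traces[[i]] <- tr
    truth[[i]] <- tibble::as_tibble(c(
      list(mrna_id = id, k_init = kin_i$k_init, k_elong = kin_i$k_elong,
           n_shutdowns = sum(traj$state_log$state == "off"),
           n_ribosomes_initiated = nrow(traj$ribosomes)), extra))
  }
  out <- list(traces = dplyr::bind_rows(traces) |>
                dplyr::mutate(dataset_id = sc, .before = 1),
              truth = dplyr::bind_rows(truth),
              config = config, construct = construct, kinetics = kin,
              drug = drug, pre_equilibration_s = equil)
  .write_dataset(out, out_dir)
}

.write_dataset <- function(out, out_dir) {
  if (is.null(out_dir)) return(out)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_atomic <- function(writer, obj, file) {
    tmp <- file.path(out_dir, paste0(".tmp_", file))
    writer(obj, tmp)
    file.rename(tmp, file.path(out_dir, file))
  }
  if (!is.null(out$traces))
    write_atomic(function(x, p) write.csv(x, p, row.names = FALSE),
                 out$traces, "traces.csv")
  if (!is.null(out$tracks))
    write_atomic(function(x, p) write.csv(x, p, row.names = FALSE),
                 out$tracks, "tracks.csv")
  write_atomic(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                                   digits = NA, pretty = TRUE),
               out$truth, "truth.json")
  cfg <- unclass(out$config)
  cfg$construct <- if (inherits(cfg$construct, "reporter_construct"))
    cfg$construct$name else cfg$construct
  write_atomic(function(x, p) jsonlite::write_json(x, p, auto_unbox = TRUE,
                                                   pretty = TRUE),
               c(cfg, list(package_version = as.character(utils::packageVersion("ribotrace")))),
               "manifest.json")
  out
}
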