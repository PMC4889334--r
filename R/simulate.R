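#' Kinetic parameters for ribosome traffic on one mRNA
#'
#' @param k_init Initiation rate (events/s) while the mRNA is in the
#'   translating ("on") state and the start region is free.
#' @param k_elong Mean elongation rate (codons/s); each codon step has an
#'   exponential waiting time of mean `1/k_elong`.
#' @param footprint_codons Exclusion length: two ribosomes can never be
#'   closer than this many codons.
#' @param k_shutdown_per_hr Rate of entering the non-translating state
#'   (events per mRNA per hour).
#' @param k_reinit_per_s Rate of leaving the non-translating state (per
#'   second).
#' @param reinit_requires_empty If `TRUE` (default) a shut-down mRNA only
#'   re-initiates after the last ribosome has run off, so every shutdown
#'   produces a complete signal loss before the re-initiation clock runs.
#' @param pause_sites List of [pause_site()] definitions.
#' @param damage_sites List of [damage_site()] definitions.
#' @return An object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(k_init = 0.04, k_elong = 3.5,
                               footprint_codons = 10,
                               k_shutdown_per_hr = 0, k_reinit_per_s = 0,
                               reinit_requires_empty = TRUE,
                               pause_sites = list(), damage_sites = list()) {
  if (k_init < 0 || k_elong <= 0 || k_shutdown_per_hr < 0 || k_reinit_per_s < 0)
    abort("rates must be nonnegative (k_elong > 0)")
  if (footprint_codons < 1) abort("footprint_codons must be >= 1")
  structure(list(k_init = k_init, k_elong = k_elong,
                 footprint_codons = as.integer(footprint_codons),
                 k_shutdown_per_hr = k_shutdown_per_hr,
                 k_reinit_per_s = k_reinit_per_s,
                 reinit_requires_empty = isTRUE(reinit_requires_empty),
                 pause_sites = pause_sites, damage_sites = damage_sites),
            class = "kinetic_parameters")
}

#' Sequence-encoded pause site with a two-component dwell mixture
#'
#' Most ribosomes are delayed briefly; a minority stall for an extended
#' period.  Crossing the site inserts an extra exponential dwell drawn from
#' the mixture.
#'
#' @param position Codon index of the pause site.
#' @param short_dwell_mean_s,long_dwell_mean_s Mean extra dwell (s) of the
#'   two mixture components.
#' @param long_fraction Probability of drawing the long component.
#' @export
pause_site <- function(position, short_dwell_mean_s = 10,
                       long_dwell_mean_s = 800, long_fraction = 0.1) {
  if (short_dwell_mean_s <= 0 || long_dwell_mean_s <= 0) abort("dwell means must be positive")
  if (long_fraction < 0 || long_fraction > 1) abort("long_fraction must lie in [0, 1]")
  list(position = as.integer(position), short_dwell_mean_s = short_dwell_mean_s,
       long_dwell_mean_s = long_dwell_mean_s, long_fraction = long_fraction)
}

#' Chemically damaged site delaying every ribosome
#'
#' @param position Codon index of the lesion.
#' @param dwell_mean_s Mean extra exponential dwell (s) for each crossing
#'   ribosome.
#' @export
damage_site <- function(position, dwell_mean_s = 300) {
  if (dwell_mean_s <= 0) abort("dwell_mean_s must be positive")
  list(position = as.integer(position), dwell_mean_s = dwell_mean_s)
}

.drug_default_delays <- c(harringtonine = 60, hippuristanol = 60,
                          puromycin = 30, cycloheximide = 60)

#' Define a drug addition
#'
#' Effect contracts: harringtonine and hippuristanol block all initiation
#' after `add_time_s + entry_delay_s`; puromycin instantly releases all
#' nascent chains (site intensity drops to 0) and blocks initiation;
#' cycloheximide freezes all ribosome movement and initiation.
#'
#' @param drug One of `"harringtonine"`, `"puromycin"`, `"cycloheximide"`,
#'   `"hippuristanol"`.
#' @param add_time_s Time of addition (s, simulation clock).
#' @param entry_delay_s Delay before the drug reaches the ribosomes;
#'   defaults to 60 s (30 s for puromycin).
#' @export
drug_event <- function(drug = c("harringtonine", "puromycin", "cycloheximide",
                                "hippuristanol"),
                       add_time_s = 0, entry_delay_s = NULL) {
  drug <- match.arg(drug)
  entry_delay_s <- entry_delay_s %||% unname(.drug_default_delays[drug])
  if (entry_delay_s < 0) abort("entry_delay_s must be nonnegative")
  structure(list(drug = drug, add_time_s = add_time_s,
                 entry_delay_s = entry_delay_s), class = "drug_event")
}

.drug_code <- function(drug) {
  switch(drug, harringtonine = 1L, hippuristanol = 1L, puromycin = 2L,
         cycloheximide = 3L, abort("unknown drug"))
}

#' Simulate ribosome traffic on a single mRNA
#'
#' Exact event-driven stochastic simulation with per-codon exponential
#' clocks, steric exclusion, optional pause/damage dwells, two-state
#' translational switching and drug perturbations.  A deterministic mode
#' (fixed step time `1/k_elong`) is available for analytic tests, in which
#' case ribosomes must be injected explicitly via `inject_times` and
#' `k_init` must be 0.
#'
#' @param construct A [reporter_construct()].
#' @param kinetics A [kinetic_parameters()].
#' @param duration_s Simulated time (s).
#' @param drugs A single [drug_event()] or `NULL`.
#' @param frame_interval_s Sampling interval for position snapshots (s).
#' @param seed Optional integer seed (`set.seed` is called if given).
#' @param deterministic Use fixed step times instead of exponential waits.
#' @param inject_times Times at which a ribosome is force-initiated.
#' @param log_events Keep the full event log (memory-heavy for long runs).
#' @param mrna_id Identifier recorded on the output.
#' @return An object of class `ribosome_trajectory`: a list with tibbles
#'   `positions` (frame, time_s, ribosome, position), `ribosomes`
#'   (init/termination/release times), `state_log`, optional `events`, and
#'   the inputs as attributes.
#' @export
simulate_translation <- function(construct, kinetics, duration_s,
                                 drugs = NULL, frame_interval_s = 30,
                                 seed = NULL, deterministic = FALSE,
                                 inject_times = numeric(0),
                                 log_events = FALSE, mrna_id = "mrna_1") {
  if (duration_s <= 0) abort("duration_s must be positive")
  if (deterministic && kinetics$k_init > 0)
    abort("deterministic mode requires k_init = 0 (use inject_times)")
  if (!is.null(seed)) set.seed(seed)
  ps <- kinetics$pause_sites; ds <- kinetics$damage_sites
  drug_code <- 0L; drug_eff <- Inf; drug <- NULL
  if (!is.null(drugs)) {
    drug <- if (inherits(drugs, "drug_event")) drugs else drugs[[1]]
    drug_code <- .drug_code(drug$drug)
    drug_eff <- drug$add_time_s + drug$entry_delay_s
  }
  raw <- sim_translation_cpp(
    L = construct$orf_length_codons,
    k_init = kinetics$k_init, k_elong = kinetics$k_elong,
    footprint = kinetics$footprint_codons,
    k_shutdown = kinetics$k_shutdown_per_hr / 3600,
    k_reinit = kinetics$k_reinit_per_s,
    reinit_requires_empty = kinetics$reinit_requires_empty,
    pause_pos = vapply(ps, `[[`, integer(1), "position"),
    pause_short = vapply(ps, `[[`, numeric(1), "short_dwell_mean_s"),
    pause_long = vapply(ps, `[[`, numeric(1), "long_dwell_mean_s"),
    pause_frac = vapply(ps, `[[`, numeric(1), "long_fraction"),
    dmg_pos = vapply(ds, `[[`, integer(1), "position"),
    dmg_dwell = vapply(ds, `[[`, numeric(1), "dwell_mean_s"),
    duration = duration_s, frame_interval = frame_interval_s,
    drug_code = drug_code, drug_eff_time = drug_eff,
    inject_times = sort(as.numeric(inject_times)),
    deterministic = deterministic, log_events = log_events)

  positions <- tibble::tibble(frame = raw$frame,
                              time_s = raw$frame * frame_interval_s,
                              ribosome = raw$ribosome,
                              position = raw$position)
  ribosomes <- tibble::tibble(ribosome = raw$rib_id,
                              init_time_s = raw$init_time,
                              term_time_s = raw$term_time,
                              released = as.logical(raw$released))
  state_log <- tibble::tibble(time_s = raw$switch_time,
                              state = ifelse(raw$switch_state == 1, "on", "off"))
  events <- NULL
  if (log_events) {
    codes <- c("initiate", "step", "pause_enter", "pause_exit", "terminate",
               "puromycin_release")
    events <- tibble::tibble(time_s = raw$ev_time, ribosome = raw$ev_id,
                             event = codes[raw$ev_code])
  }
  structure(list(mrna_id = mrna_id, positions = positions,
                 ribosomes = ribosomes, state_log = state_log,
                 events = events, n_frames = raw$n_frames,
                 frame_interval_s = frame_interval_s,
                 construct = construct, kinetics = kinetics, drug = drug),
            class = "ribosome_trajectory")
}

#' @export
print.ribosome_trajectory <- function(x, ...) {
  cat(sprintf("<ribosome_trajectory> %s: %d frames @ %gs, %d ribosomes initiated\n",
              x$mrna_id, x$n_frames, x$frame_interval_s, nrow(x$ribosomes)))
  invisible(x)
}

#' Render a fluorescence intensity trace from a simulated trajectory
#'
#' Per frame, the green channel is the site intensity of all ribosome
#' positions plus Gaussian noise with variance affine in the signal,
#' \eqn{\sigma_0^2 + \sigma_1^2 I}; `sigma0 = sigma1 = 0` gives the exact
#' noiseless forward model.  The red (mRNA) channel is the expected label
#' ratio with small multiplicative noise.
#'
#' @param trajectory A `ribosome_trajectory`.
#' @param construct Reporter geometry; defaults to the one stored in the
#'   trajectory.
#' @param noise Length-2 numeric `c(sigma0, sigma1)`.
#' @param stoich A [label_stoichiometry()] for the red channel.
#' @param red_cv Coefficient of variation of the red channel.
#' @param seed Optional integer seed.
#' @return A tibble (`mrna_id`, `frame`, `time_s`, `green`, `red`) — an
#'   intensity trace in single-mature-protein units.
#' @export
render_intensity_trace <- function(trajectory, construct = trajectory$construct,
                                   noise = c(0.2, 0.1),
                                   stoich = label_stoichiometry(occupancy = 0.5),
                                   red_cv = 0.05, seed = NULL) {
  if (any(noise < 0)) abort("noise parameters must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  nfr <- trajectory$n_frames
  f_by_frame <- rep(0, nfr)
  if (nrow(trajectory$positions) > 0) {
    agg <- trajectory$positions |>
      dplyr::mutate(f = exposed_epitope_fraction(.data$position, construct)) |>
      dplyr::group_by(.data$frame) |>
      dplyr::summarise(I = sum(.data$f), .groups = "drop")
    f_by_frame[agg$frame + 1] <- agg$I
  }
  green <- f_by_frame
  if (noise[1] > 0 || noise[2] > 0)
    green <- green + rnorm(nfr, 0, sqrt(noise[1]^2 + noise[2]^2 * f_by_frame))
  red0 <- expected_label_ratio(stoich)
  red <- red0 * (1 + if (red_cv > 0) rnorm(nfr, 0, red_cv) else 0)
  tibble::tibble(mrna_id = trajectory$mrna_id, frame = seq_len(nfr) - 1L,
                 time_s = (seq_len(nfr) - 1) * trajectory$frame_interval_s,
                 green = green, red = red)
}

#' Simulate an ensemble of drug-runoff intensity traces
#'
#' Each mRNA is equilibrated from empty for `pre_equilibration_s` (default
#' 1.5 traversal times, enough for the ribosome density to reach steady
#' state), then the drug is added.  Returned traces are aligned so that
#' `time_s = 0` is the drug addition; pre-drug frames carry negative times.
#'
#' @inheritParams simulate_translation
#' @param n_mrna Number of mRNAs.
#' @param drug A [drug_event()] (its `add_time_s` is ignored; the drug is
#'   added at the end of equilibration).
#' @param post_drug_s Time simulated after drug addition (s).
#' @param pre_equilibration_s Equilibration time before the drug (s).
#' @param noise Passed to [render_intensity_trace()].
#' @param keep_truth If `TRUE`, attach the list of trajectories as an
#'   attribute `"trajectories"`.
#' @return A tibble of traces (`mrna_id`, `frame`, `time_s`, `green`,
#'   `red`) with drug addition at `time_s = 0`.
#' @export
simulate_runoff_ensemble <- function(construct, kinetics, n_mrna, drug,
                                     post_drug_s = 900,
                                     pre_equilibration_s = NULL,
                                     frame_interval_s = 30,
                                     noise = c(0, 0), seed = NULL,
                                     keep_truth = FALSE) {
  if (n_mrna < 1) abort("n_mrna must be >= 1")
  if (is.null(drug)) abort("a drug_event is required for a runoff ensemble")
  if (!is.null(seed)) set.seed(seed)
  L <- construct$orf_length_codons
  equil <- pre_equilibration_s %||%
    (ceiling(1.5 * L / kinetics$k_elong / frame_interval_s) * frame_interval_s)
  drug <- drug_event(drug$drug, add_time_s = equil, entry_delay_s = drug$entry_delay_s)
  trajs <- vector("list", n_mrna)
  traces <- vector("list", n_mrna)
  for (i in seq_len(n_mrna)) {
    tr <- simulate_translation(construct, kinetics,
                               duration_s = equil + post_drug_s,
                               drugs = drug, frame_interval_s = frame_interval_s,
                               mrna_id = sprintf("mrna_%03d", i))
    if (keep_truth) trajs[[i]] <- tr
    traces[[i]] <- render_intensity_trace(tr, noise = noise) |>
      dplyr::mutate(time_s = .data$time_s - equil)
  }
  out <- dplyr::bind_rows(traces)
  attr(out, "construct") <- construct
  attr(out, "kinetics") <- kinetics
  attr(out, "drug") <- drug
  attr(out, "pre_equilibration_s") <- equil
  if (keep_truth) attr(out, "trajectories") <- trajs
  out
}

#' Simulate 2D Brownian spot trajectories
#'
#' Each coordinate receives independent Gaussian increments of variance
#' \eqn{2 D \Delta t} per frame, the standard free-diffusion model for
#' single-particle tracks (MSD \eqn{= 4 D \tau} in 2D).
#'
#' @param D Diffusion coefficient (um^2/s), `>= 0`.
#' @param duration_s Track duration (s).
#' @param frame_interval_s Frame interval (s).
#' @param n_tracks Number of independent tracks.
#' @param seed Optional integer seed.
#' @return A tibble (`mrna_id`, `frame`, `time_s`, `x_um`, `y_um`).
#' @export
simulate_diffusion_track <- function(D, duration_s, frame_interval_s,
                                     n_tracks = 1, seed = NULL) {
  if (D < 0) abort("D must be nonnegative")
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration_s / frame_interval_s) + 1
  s <- sqrt(2 * D * frame_interval_s)
  purrr::map_dfr(seq_len(n_tracks), function(i) {
    tibble::tibble(mrna_id = sprintf("track_%03d", i), frame = seq_len(n) - 1L,
                   time_s = (seq_len(n) - 1) * frame_interval_s,
                   x_um = cumsum(c(0, rnorm(n - 1, 0, s))),
                   y_um = cumsum(c(0, rnorm(n - 1, 0, s))))
  })
}
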