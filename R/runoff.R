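#' Deterministic continuum runoff curve
#'
#' After initiation is blocked at `t0`, the ribosome density recedes from
#' the 5' end at the elongation speed `v` (codons/s).  With the continuum
#' ramp intensity function (0 up to codon `a`, linear to 1 at codon `b`,
#' then 1 up to `L`), the normalized site intensity is
#' \deqn{I(t) = G(v (t - t0)) / G(0), \quad G(u) = \int_u^L f(x) dx,}
#' a three-stage curve: flat while the runoff front crosses the epitope-free
#' leader, a quadratic shoulder while it crosses the epitope array, then a
#' linear decline with normalized slope \eqn{-v / (L \bar c)} until zero.
#'
#' @param t Times (s).
#' @param v Elongation speed (codons/s).
#' @param construct A [reporter_construct()]; supplies `L` and the default
#'   ramp ends `a`, `b` (first/last visible epitope positions).
#' @param t0 Time at which runoff starts (drug addition + entry delay).
#' @param a,b Ramp start/end (codons), overriding the construct geometry.
#' @return Normalized intensities in `[0, 1]`.
#' @export
runoff_model_curve <- function(t, v, construct, t0 = 0, a = NULL, b = NULL) {
  vis <- construct$epitope_positions + construct$exit_tunnel_codons
  a <- a %||% vis[1]
  b <- b %||% vis[length(vis)]
  L <- construct$orf_length_codons
  u <- pmin(pmax(v * (t - t0), 0), L)
  G0 <- (b - a) / 2 + (L - b)
  G <- ifelse(u <= a, G0,
       ifelse(u <= b, (L - b) + (b - a) / 2 * (1 - ((u - a) / (b - a))^2),
              L - u))
  G / G0
}

new_elongation_fit <- function(rate, sd, method, n_traces, stage_boundaries_s = NULL,
                               residual_norm = NA_real_, success = TRUE,
                               extra = list()) {
  structure(c(list(rate_codons_per_s = rate, sd = sd, method = method,
                   n_traces = n_traces, stage_boundaries_s = stage_boundaries_s,
                   residual_norm = residual_norm, success = success), extra),
            class = "elongation_fit")
}

#' @export
print.elongation_fit <- function(x, ...) {
  cat(sprintf("<elongation_fit> %s: %.2f +/- %.2f codons/s (n = %d%s)\n",
              x$method, x$rate_codons_per_s, x$sd, x$n_traces,
              if (x$success) "" else "; FLAGGED: no decay detected"))
  invisible(x)
}

.mean_trace <- function(traces) {
  traces |>
    dplyr::group_by(.data$time_s) |>
    dplyr::summarise(green = mean(.data$green), .groups = "drop") |>
    dplyr::arrange(.data$time_s)
}

.normalize_predrug <- function(mt, predrug_window_s = 120) {
  pre <- mt$green[mt$time_s <= 0 & mt$time_s >= -predrug_window_s]
  lev <- if (length(pre) > 0) mean(pre) else mt$green[1]
  if (lev <= 0) abort("pre-drug intensity level is not positive")
  dplyr::mutate(mt, green = .data$green / lev)
}

.fit_runoff_curve <- function(mt, construct, entry_delay_s) {
  vis <- construct$epitope_positions + construct$exit_tunnel_codons
  L <- construct$orf_length_codons
  post <- mt[mt$time_s >= 0, ]
  sse <- function(p) {
    v <- p[1]; a <- p[2]; b <- p[3]
    if (v <= 0 || a < 0 || b <= a || b > L) return(1e10)
    sum((post$green - runoff_model_curve(post$time_s, v, construct,
                                         t0 = entry_delay_s, a = a, b = b))^2)
  }
  p0 <- c(v = 3, a = vis[1], b = vis[length(vis)])
  opt <- optim(p0, sse, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-10))
  list(v = unname(opt$par[1]), a = unname(opt$par[2]), b = unname(opt$par[3]),
       sse = opt$value)
}

#' Fit the runoff intensity model to an ensemble of traces
#'
#' Normalizes the ensemble-mean trace to its pre-drug level and
#' least-squares fits the three-stage continuum curve
#' ([runoff_model_curve()]) with the elongation speed and the two stage
#' boundaries free.  The standard deviation comes from a bootstrap over
#' mRNAs.  If the mean trace barely decays (final/initial > 0.9) the fit is
#' flagged as failed rather than raising an error.
#'
#' @param traces Trace tibble (`mrna_id`, `time_s`, `green`) aligned at the
#'   drug-addition time (`time_s = 0`); pre-drug frames have negative times.
#' @param construct A [reporter_construct()].
#' @param entry_delay_s Drug entry delay (s); runoff starts at this time.
#' @param per_trace Fit each trace individually instead of the cumulative
#'   mean (the mean is the default).
#' @param n_boot Bootstrap resamples for the sd (cumulative-mean mode).
#' @param seed Optional integer seed for the bootstrap.
#' @return An `elongation_fit` (method `"model_fit"`); supports [tidy()],
#'   [glance()] and [autoplot()].
#' @export
fit_runoff_elongation <- function(traces, construct, entry_delay_s = 60,
                                  per_trace = FALSE, n_boot = 200, seed = NULL) {
  stopifnot(all(c("mrna_id", "time_s", "green") %in% names(traces)))
  ids <- unique(traces$mrna_id)
  if (length(ids) < 1) abort("at least one trace is required")
  dt <- sort(unique(round(diff(sort(unique(traces$time_s))), 6)))
  if (length(dt) > 1) abort("traces must share one frame grid")
  if (!is.null(seed)) set.seed(seed)

  if (per_trace) {
    fits <- purrr::map_dbl(ids, function(id) {
      mt <- .normalize_predrug(.mean_trace(traces[traces$mrna_id == id, ]))
      .fit_runoff_curve(mt, construct, entry_delay_s)$v
    })
    return(new_elongation_fit(mean(fits), sd(fits), "model_fit", length(ids),
                              extra = list(per_trace_rates = fits)))
  }

  mt <- .normalize_predrug(.mean_trace(traces))
  post <- mt[mt$time_s >= 0, ]
  no_decay <- tail(post$green, 1) / post$green[1] > 0.9
  fit <- .fit_runoff_curve(mt, construct, entry_delay_s)
  boot_sd <- NA_real_
  if (n_boot > 0 && length(ids) > 1) {
    by_id <- split(traces, traces$mrna_id)
    vs <- purrr::map_dbl(seq_len(n_boot), function(i) {
      take <- sample(length(ids), replace = TRUE)
      mtb <- .normalize_predrug(.mean_trace(dplyr::bind_rows(by_id[take])))
      .fit_runoff_curve(mtb, construct, entry_delay_s)$v
    })
    boot_sd <- sd(vs)
  }
  new_elongation_fit(fit$v, boot_sd, "model_fit", length(ids),
                     stage_boundaries_s = entry_delay_s + c(fit$a, fit$b) / fit$v,
                     residual_norm = sqrt(fit$sse), success = !no_decay,
                     extra = list(mean_trace = mt, a = fit$a, b = fit$b,
                                  entry_delay_s = entry_delay_s,
                                  construct = construct))
}

#' Elongation rate from total runoff times
#'
#' Uses the per-mRNA time between drug addition and final disappearance of
#' the translation-site signal: after subtracting the drug entry delay, the
#' mean runoff time is one full traversal, so
#' \eqn{k = L / \mathrm{mean}(T - \mathrm{delay})}.  The sd follows by the
#' delta method from the sample sd of `T`.
#'
#' @param disappearance_times_s Per-mRNA disappearance times (s from drug
#'   addition).
#' @param construct A [reporter_construct()].
#' @param entry_delay_s Drug entry delay (s), subtracted from all times.
#' @return An `elongation_fit` (method `"total_runoff_time"`).
#' @export
elongation_from_runoff_time <- function(disappearance_times_s, construct,
                                        entry_delay_s = 60) {
  tt <- disappearance_times_s
  if (length(tt) == 0) abort("no disappearance times supplied")
  if (any(tt <= entry_delay_s)) abort("all times must exceed the entry delay")
  L <- construct$orf_length_codons
  m <- mean(tt - entry_delay_s)
  k <- L / m
  se_m <- if (length(tt) > 1) sd(tt) / sqrt(length(tt)) else 0
  new_elongation_fit(k, L / m^2 * se_m, "total_runoff_time", length(tt))
}

#' Steady-state initiation rate from ribosome count and elongation rate
#'
#' Flux balance on the ORF: at steady state the initiation flux equals the
#' termination flux, so \eqn{k_{init} = N k_{elong} / L} (reported per
#' minute).
#'
#' @param ribosome_count Ribosomes per mRNA (vectorized).
#' @param k_elong Elongation rate (codons/s).
#' @param construct A [reporter_construct()].
#' @return Initiation rate(s) in events per minute.
#' @examples
#' rc <- reporter_preset("kif18b_suntag24")
#' estimate_initiation_rate(c(10, 25), 3.5, rc)  # ~1.4 and ~3.6 per min
#' @export
estimate_initiation_rate <- function(ribosome_count, k_elong, construct) {
  if (any(!is.finite(ribosome_count)) || !is.finite(k_elong))
    abort("inputs must be finite")
  if (any(ribosome_count < 0) || k_elong <= 0)
    abort("ribosome_count must be >= 0 and k_elong > 0")
  ribosome_count * k_elong * 60 / construct$orf_length_codons
}

#' Per-mRNA disappearance times from noiseless runoff traces
#'
#' Helper for the total-runoff-time estimator: for each mRNA, the first
#' frame at or after drug addition at which the green signal stays at (or
#' below) the detection floor for the rest of the trace.
#'
#' @param traces Trace tibble aligned at the drug time (`time_s = 0`).
#' @param floor_level Detection floor (single-protein units).
#' @return A tibble (`mrna_id`, `disappearance_s`); mRNAs whose signal
#'   never disappears are dropped.
#' @export
runoff_disappearance_times <- function(traces, floor_level = 1e-9) {
  traces |>
    dplyr::filter(.data$time_s >= 0) |>
    dplyr::arrange(.data$mrna_id, .data$time_s) |>
    dplyr::group_by(.data$mrna_id) |>
    dplyr::summarise(disappearance_s = {
      gone <- rev(cumprod(rev(.data$green <= floor_level))) == 1
      if (any(gone)) .data$time_s[which(gone)[1]] else NA_real_
    }, .groups = "drop") |>
    dplyr::filter(!is.na(.data$disappearance_s))
}
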