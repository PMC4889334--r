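#' Mean squared displacement of a 2D track
#'
#' Time-averaged MSD over all pairs at each lag.
#'
#' @param track Track tibble (`time_s`, `x_um`, `y_um`), uniform grid.
#' @param max_lag_frames Largest lag (frames).
#' @return A tibble (`lag_frames`, `lag_s`, `msd_um2`, `n_pairs`).
#' @export
track_msd <- function(track, max_lag_frames = 5) {
  track <- dplyr::arrange(track, .data$time_s)
  n <- nrow(track)
  if (n <= max_lag_frames + 1) abort("track too short for the requested lags")
  dt <- track$time_s[2] - track$time_s[1]
  purrr::map_dfr(seq_len(max_lag_frames), function(lag) {
    dx <- track$x_um[(lag + 1):n] - track$x_um[1:(n - lag)]
    dy <- track$y_um[(lag + 1):n] - track$y_um[1:(n - lag)]
    tibble::tibble(lag_frames = lag, lag_s = lag * dt,
                   msd_um2 = mean(dx^2 + dy^2), n_pairs = n - lag)
  })
}

#' Fit a diffusion coefficient from a 2D track
#'
#' Weighted linear fit of the time-averaged MSD,
#' \eqn{MSD(\tau) = 4 D \tau + b}, over lags `1..max_lag_frames` (weights
#' proportional to the number of displacement pairs per lag).  A negative
#' fitted slope is truncated to `D = 0` and flagged.
#'
#' @param track Track tibble (`time_s`, `x_um`, `y_um`).
#' @param max_lag_frames Number of lags used (must allow `>= 2` lags).
#' @return An object of class `diffusion_fit`: `D_um2_per_s`, `intercept`,
#'   `lags_used`, `truncated`, `msd` tibble.
#' @export
estimate_diffusion <- function(track, max_lag_frames = 5) {
  if (max_lag_frames < 2) abort("at least 2 lags are required")
  msd <- track_msd(track, max_lag_frames)
  fit <- lm(msd_um2 ~ lag_s, data = msd, weights = msd$n_pairs)
  slope <- unname(coef(fit)[2])
  D <- slope / 4
  truncated <- D < 0
  structure(list(D_um2_per_s = max(D, 0), intercept = unname(coef(fit)[1]),
                 lags_used = max_lag_frames, truncated = truncated, msd = msd),
            class = "diffusion_fit")
}

#' @export
print.diffusion_fit <- function(x, ...) {
  cat(sprintf("<diffusion_fit> D = %.4g um^2/s (%d lags%s)\n", x$D_um2_per_s,
              x$lags_used, if (x$truncated) ", truncated at 0" else ""))
  invisible(x)
}

#' Per-track diffusion coefficients for an ensemble of tracks
#'
#' @param tracks Track tibble with an `mrna_id` column.
#' @inheritParams estimate_diffusion
#' @return A tibble (`mrna_id`, `D_um2_per_s`, `intercept`, `truncated`).
#' @export
estimate_diffusion_ensemble <- function(tracks, max_lag_frames = 5) {
  purrr::map_dfr(split(tracks, tracks$mrna_id), function(track) {
    f <- estimate_diffusion(track, max_lag_frames)
    tibble::tibble(mrna_id = track$mrna_id[1], D_um2_per_s = f$D_um2_per_s,
                   intercept = f$intercept, truncated = f$truncated)
  })
}
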