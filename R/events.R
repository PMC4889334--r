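#' Detect single-ribosome translation events in a low-initiation trace
#'
#' On a sparsely initiating mRNA a lone ribosome produces a characteristic
#' rise–plateau–drop profile: intensity climbs while the epitope array is
#' decoded, plateaus at one mature-protein unit once all epitopes are
#' exposed, and drops abruptly at termination.  Events are found as
#' contiguous supra-threshold episodes; the appearance time is the
#' x-intercept of a linear fit to the rising phase (the moment the first
#' epitope cleared the exit tunnel), and the loss time is the interpolated
#' drop.  The single-ribosome elongation rate for an event is
#' \deqn{k = (L - (e_1 + \Delta)) / (t_{loss} - t_{appear}),}
#' the distance from the first visible epitope to the stop codon divided by
#' the event duration.  Episodes whose plateau is far from one
#' mature-protein unit (overlapping ribosomes) are flagged, not split.
#'
#' @param trace A single-mRNA trace tibble (`time_s`, `green`).
#' @param construct A [reporter_construct()].
#' @param threshold Detection threshold (single-protein units).
#' @param min_frames Minimum episode length in frames.
#' @param plateau_range Plateau intensities accepted as a single ribosome.
#' @param median_filter Odd median-filter window (1 = off).
#' @return A tibble of events: `t_appear_s`, `t_plateau_start_s`,
#'   `t_loss_s`, `plateau_intensity`, `inferred_rate_codons_per_s`,
#'   `overlapping` (logical flag).  Zero rows on a flat trace.
#' @export
detect_single_ribosome_events <- function(trace, construct, threshold = 0.4,
                                          min_frames = 5,
                                          plateau_range = c(0.6, 1.6),
                                          median_filter = 3) {
  stopifnot(all(c("time_s", "green") %in% names(trace)))
  trace <- dplyr::arrange(trace, .data$time_s)
  n <- nrow(trace)
  y_raw <- trace$green
  # episodes are detected on the filtered trace (robust to noise spikes)
  # but boundaries are measured on the raw one, since the median filter
  # widens an episode by up to one frame at each edge
  y <- y_raw
  if (median_filter > 1 && n > median_filter) y <- runmed(y_raw, median_filter)
  tt <- trace$time_s
  above <- y > threshold
  if (!any(above)) return(.empty_events())
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- which(r$values & r$lengths >= min_frames &
                  starts > 1 & ends < n)  # episodes cut by the trace edge are dropped
  if (length(keep) == 0) return(.empty_events())

  vis1 <- construct$epitope_positions[1] + construct$exit_tunnel_codons
  L <- construct$orf_length_codons
  purrr::map_dfr(keep, function(j) {
    i0 <- starts[j]; i1 <- ends[j]
    seg <- y_raw[i0:i1]
    plateau <- median(seg[seg >= 0.7 * max(seg)])
    # rising phase: from where the raw signal leaves the noise floor to the
    # first frame reaching 80% of the plateau (sub-threshold rise frames
    # carry most of the leverage for the appearance-time extrapolation)
    rise_end <- which(seg >= 0.8 * plateau)[1]
    li0 <- i0
    while (li0 > 1 && y_raw[li0 - 1] > 0.25 * threshold) li0 <- li0 - 1
    ri <- li0:(i0 + max(rise_end - 1, 1))
    t_appear <- if (length(ri) >= 2 && sd(y_raw[ri]) > 0) {
      fit <- lm(y_raw[ri] ~ tt[ri])
      as.numeric(-coef(fit)[1] / coef(fit)[2])
    } else tt[i0]
    t_appear <- min(max(t_appear, tt[1]), tt[i0])
    # abrupt loss: interpolate the raw drop below half plateau between the
    # last frame still above it and the first frame below
    li <- i1 + 1
    while (li > i0 && y_raw[li - 1] < 0.5 * plateau) li <- li - 1
    y0 <- y_raw[li - 1]; y1 <- y_raw[li]
    t_loss <- if (y0 > y1) {
      tt[li - 1] + (y0 - 0.5 * plateau) / (y0 - y1) * (tt[li] - tt[li - 1])
    } else tt[i1]
    t_plateau <- tt[i0 + rise_end - 1]
    dur <- t_loss - t_appear
    tibble::tibble(t_appear_s = t_appear, t_plateau_start_s = t_plateau,
                   t_loss_s = t_loss, plateau_intensity = plateau,
                   inferred_rate_codons_per_s = (L - vis1) / dur,
                   overlapping = plateau < plateau_range[1] |
                     plateau > plateau_range[2])
  })
}

.empty_events <- function() {
  tibble::tibble(t_appear_s = numeric(0), t_plateau_start_s = numeric(0),
                 t_loss_s = numeric(0), plateau_intensity = numeric(0),
                 inferred_rate_codons_per_s = numeric(0),
                 overlapping = logical(0))
}
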