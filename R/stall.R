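#' Classify a post-drug trace as normal runoff, roadblock burst, or slow
#' linear decay
#'
#' Operates on one trace aligned at the drug-addition time and normalized
#' to its pre-drug level (traces with pre-drug frames are normalized
#' internally).  Two signatures distinguish the stall mechanisms: a single
#' defective ribosome acts as a roadblock, so decay halts until the stall
#' resolves and then proceeds in a burst; a damaged nucleotide delays
#' every ribosome crossing it, producing a steady, abnormally slow decay.
#'
#' The classifier measures where the intensity loss happens inside the
#' decay interval (drug addition until the signal first falls below 5% of
#' its pre-drug level, or the end of the trace): frames with above-average
#' loss are merged into active segments, and a trace is a `"burst"` when
#' these segments cover less than 30% of the interval and the loss is
#' concentrated in a few of them; otherwise it is `"slow_linear"` when a
#' substantial fraction of the signal is still present at `check_time_s`,
#' and `"normal"` when the decay completed.
#'
#' @param trace A single-mRNA trace tibble (`time_s`, `green`), time 0 at
#'   drug addition.
#' @param check_time_s Time at which retention is evaluated (default 900 s
#'   = 15 min).
#' @param retain_threshold Retained fraction at `check_time_s` at or above
#'   which the mRNA is called stalled.
#' @param median_filter Odd median-filter window (1 = off).
#' @return An object of class `stall_call` with `is_stalled`,
#'   `retained_fraction_at_check`, `decay_class` and diagnostics.
#' @export
classify_stall <- function(trace, check_time_s = 900, retain_threshold = 0.5,
                           median_filter = 3) {
  stopifnot(all(c("time_s", "green") %in% names(trace)))
  trace <- dplyr::arrange(trace, .data$time_s)
  if (max(trace$time_s) < check_time_s)
    abort("trace is shorter than check_time_s")
  y <- trace$green
  n <- length(y)
  if (median_filter > 1 && n > median_filter) y <- runmed(y, median_filter)
  tt <- trace$time_s
  pre <- y[tt <= 0]
  level <- if (length(pre) > 0) mean(pre) else y[1]
  if (level <= 0) abort("pre-drug level is not positive")
  y <- y / level

  post <- which(tt >= 0)
  yp <- y[post]; tp <- tt[post]
  retained <- yp[which.min(abs(tp - check_time_s))]
  retained <- max(0, min(retained, 1.05))

  # decay interval: until the signal first stays below 5%
  low <- which(yp <= 0.05)
  iend <- if (length(low) > 0) low[1] else length(yp)
  win <- seq_len(max(iend, 3))
  d <- pmax(0, -diff(yp[win]))
  d_tot <- sum(d)
  if (d_tot < 0.05) {
    # essentially no decay at all within the trace
    return(new_stall_call(retained >= retain_threshold, retained,
                          if (retained >= 0.2) "slow_linear" else "normal",
                          active_fraction = NA_real_, n_segments = 0L))
  }
  active <- d > d_tot / length(d)
  # merge active frames separated by gaps of <= 2 frames into segments
  seg_id <- integer(length(active)); cur <- 0L; gap <- 99L
  for (i in seq_along(active)) {
    if (active[i]) {
      if (gap > 2L) cur <- cur + 1L
      seg_id[i] <- cur; gap <- 0L
    } else gap <- gap + 1L
  }
  n_seg <- max(seg_id)
  active_fraction <- mean(active)
  seg_loss <- vapply(seq_len(max(n_seg, 1)), function(s) sum(d[seg_id == s]),
                     numeric(1))
  concentrated <- active_fraction < 0.3 && n_seg <= 4 &&
    max(seg_loss) >= 0.3 * d_tot
  cls <- if (concentrated) "burst"
         else if (retained >= 0.2) "slow_linear"
         else "normal"
  new_stall_call(retained >= retain_threshold, retained, cls,
                 active_fraction, n_seg)
}

new_stall_call <- function(is_stalled, retained, decay_class,
                           active_fraction, n_segments) {
  structure(list(is_stalled = is_stalled,
                 retained_fraction_at_check = retained,
                 decay_class = decay_class,
                 active_fraction = active_fraction,
                 n_segments = n_segments),
            class = "stall_call")
}

#' @export
print.stall_call <- function(x, ...) {
  cat(sprintf("<stall_call> %s (retained %.2f at check): class %s\n",
              if (x$is_stalled) "STALLED" else "not stalled",
              x$retained_fraction_at_check, x$decay_class))
  invisible(x)
}

#' Classify every mRNA in a post-drug ensemble
#'
#' @param traces Trace tibble with `mrna_id`, aligned at the drug time.
#' @inheritParams classify_stall
#' @return A tibble with one row per mRNA (`mrna_id`, `is_stalled`,
#'   `retained_fraction_at_check`, `decay_class`).
#' @export
classify_stall_ensemble <- function(traces, check_time_s = 900,
                                    retain_threshold = 0.5, median_filter = 3) {
  purrr::map_dfr(split(traces, traces$mrna_id), function(trace) {
    s <- classify_stall(trace, check_time_s, retain_threshold, median_filter)
    tibble::tibble(mrna_id = trace$mrna_id[1], is_stalled = s$is_stalled,
                   retained_fraction_at_check = s$retained_fraction_at_check,
                   decay_class = s$decay_class)
  })
}
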