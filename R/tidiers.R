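#' Tidy an elongation fit
#'
#' @param x An `elongation_fit`.
#' @param ... Unused.
#' @return A one-row tibble (`term`, `estimate`, `std.error`).
#' @exportS3Method generics::tidy
tidy.elongation_fit <- function(x, ...) {
  tibble::tibble(term = "rate_codons_per_s",
                 estimate = x$rate_codons_per_s, std.error = x$sd)
}

#' @rdname tidy.elongation_fit
#' @exportS3Method generics::glance
glance.elongation_fit <- function(x, ...) {
  tibble::tibble(rate_codons_per_s = x$rate_codons_per_s, sd = x$sd,
                 method = x$method, n_traces = x$n_traces,
                 residual_norm = x$residual_norm, success = x$success)
}

#' @exportS3Method generics::tidy
tidy.diffusion_fit <- function(x, ...) {
  tibble::tibble(term = c("D_um2_per_s", "intercept"),
                 estimate = c(x$D_um2_per_s, x$intercept))
}

#' @exportS3Method generics::glance
glance.diffusion_fit <- function(x, ...) {
  tibble::tibble(D_um2_per_s = x$D_um2_per_s, intercept = x$intercept,
                 lags_used = x$lags_used, truncated = x$truncated)
}

#' @exportS3Method generics::tidy
tidy.state_segments <- function(x, ...) x$segments

#' @exportS3Method generics::glance
glance.state_segments <- function(x, ...) {
  tibble::tibble(cycles_per_hour = x$cycles_per_hour,
                 off_fraction = x$off_fraction,
                 n_segments = nrow(x$segments),
                 fraction_reinitiated_within_600s = x$fraction_reinitiated_within_600s,
                 tracked_s = x$tracked_s)
}

#' @exportS3Method generics::tidy
tidy.stall_call <- function(x, ...) {
  tibble::tibble(is_stalled = x$is_stalled,
                 retained_fraction_at_check = x$retained_fraction_at_check,
                 decay_class = x$decay_class)
}

#' @exportS3Method generics::glance
glance.stall_call <- function(x, ...) tidy.stall_call(x)

#' @exportS3Method generics::tidy
tidy.buildup_fit <- function(x, ...) {
  tibble::tibble(term = c("slope_units_per_s", "implied_initiation_per_min"),
                 estimate = c(x$slope_units_per_s, x$implied_initiation_per_min))
}

#' @exportS3Method generics::glance
glance.buildup_fit <- function(x, ...) {
  tibble::tibble(slope_units_per_s = x$slope_units_per_s,
                 implied_initiation_per_min = x$implied_initiation_per_min,
                 n_traces = x$n_traces,
                 p_value = x$p_value %||% NA_real_)
}

#' Plot a set of intensity traces
#'
#' @param traces Trace tibble (`mrna_id`, `time_s`, `green`).
#' @param alpha Line transparency.
#' @param mean_line Overlay the ensemble mean.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, alpha = 0.3, mean_line = TRUE) {
  p <- ggplot2::ggplot(traces, ggplot2::aes(.data$time_s, .data$green,
                                            group = .data$mrna_id)) +
    ggplot2::geom_line(alpha = alpha, colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = "intensity (mature-protein units)")
  if (mean_line && length(unique(traces$mrna_id)) > 1)
    p <- p + ggplot2::stat_summary(ggplot2::aes(group = NULL), fun = mean,
                                   geom = "line", colour = "firebrick",
                                   linewidth = 1)
  p
}

#' @exportS3Method ggplot2::autoplot
autoplot.elongation_fit <- function(object, ...) {
  if (is.null(object$mean_trace))
    abort("autoplot is only available for cumulative-mean model fits")
  mt <- object$mean_trace
  fit_curve <- tibble::tibble(
    time_s = seq(0, max(mt$time_s), length.out = 200))
  fit_curve$green <- runoff_model_curve(fit_curve$time_s,
                                        object$rate_codons_per_s,
                                        object$construct,
                                        t0 = object$entry_delay_s,
                                        a = object$a, b = object$b)
  ggplot2::ggplot(mt, ggplot2::aes(.data$time_s, .data$green)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_line(data = fit_curve, colour = "firebrick") +
    ggplot2::labs(x = "time after drug (s)", y = "normalized intensity",
                  title = sprintf("runoff fit: %.2f codons/s",
                                  object$rate_codons_per_s))
}

#' @exportS3Method ggplot2::autoplot
autoplot.diffusion_fit <- function(object, ...) {
  ggplot2::ggplot(object$msd, ggplot2::aes(.data$lag_s, .data$msd_um2)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(intercept = object$intercept,
                         slope = 4 * object$D_um2_per_s, colour = "firebrick") +
    ggplot2::labs(x = "lag (s)", y = expression(MSD ~ (mu * m^2)),
                  title = sprintf("D = %.3g um^2/s", object$D_um2_per_s))
}

#' @exportS3Method ggplot2::autoplot
autoplot.state_segments <- function(object, ...) {
  segs <- object$segments
  ggplot2::ggplot(segs) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s,
                                    ymin = 0, ymax = 1, fill = .data$state),
                       alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(on = "seagreen", off = "grey70")) +
    ggplot2::labs(x = "time (s)", y = NULL)
}

#' @exportS3Method ggplot2::autoplot
autoplot.buildup_fit <- function(object, ...) {
  ggplot2::ggplot(object$mean_curve, ggplot2::aes(.data$time_s, .data$green)) +
    ggplot2::geom_line() +
    ggplot2::geom_abline(intercept = 0, slope = object$slope_units_per_s,
                         colour = "firebrick", linetype = 2) +
    ggplot2::labs(x = "time after first detection (s)",
                  y = "intensity (mature-protein units)")
}
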