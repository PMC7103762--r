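#' Plot a replicate ensemble's density map
#'
#' Polymerase density along each gene body, one line per snapshot time,
#' faceted by gene — the standard way to look at elongation restriction and
#' initiation shutdown after damage.
#'
#' @param object A `pol_ensemble` from [run_replicates()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pol_ensemble <- function(object, ...) {
  d <- dplyr::mutate(object$density,
                     time_lab = factor(sprintf("%g min", .data$time / 60),
                                       levels = sprintf("%g min", sort(unique(.data$time)) / 60)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin_start / 1e3, y = .data$density,
                                  colour = .data$time_lab)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~ .data$gene_id, scales = "free_x") +
    ggplot2::labs(x = "distance from TSS (kb)",
                  y = "mean polymerases per bin per run",
                  colour = "time post-damage",
                  title = sprintf("RNAPII density (%d replicates)", object$n_replicates)) +
    ggplot2::theme_minimal()
}

#' Plot a half-life fit
#'
#' Observed counts with the fitted exponential, on a log count scale.
#'
#' @param object A `half_life_fit` from [fit_half_life()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.half_life_fit <- function(object, ...) {
  d <- object$data
  d$fitted <- exp(stats::fitted(object$fit))
  lab <- if (is.finite(object$half_life)) {
    sprintf("half-life %.2f h", object$half_life / 3600)
  } else "no detectable decay"
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time / 3600)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$count)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time post-damage (h)", y = "surviving polymerases",
                  title = lab) +
    ggplot2::theme_minimal()
}

#' Plot a metagene profile
#'
#' Mean signal on the relative TSS-to-TTS axis, coloured by snapshot time and
#' faceted by gene-length class when present.
#'
#' @param profile Output of [metagene_profile()].
#' @return A ggplot object.
#' @export
plot_metagene <- function(profile) {
  has_time <- "time" %in% names(profile)
  p <- ggplot2::ggplot(profile, ggplot2::aes(x = .data$rel_position,
                                             y = .data$mean_signal))
  if (has_time) {
    p <- p + ggplot2::geom_line(ggplot2::aes(
      colour = factor(sprintf("%g min", .data$time / 60))))
  } else {
    p <- p + ggplot2::geom_line()
  }
  if ("class_label" %in% names(profile)) {
    p <- p + ggplot2::facet_wrap(~ factor(.data$class_label,
                                          c("short", "medium", "long")))
  }
  p + ggplot2::labs(x = "relative position (TSS = 0, TTS = 1)",
                    y = "mean signal", colour = "time post-damage") +
    ggplot2::theme_minimal()
}
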