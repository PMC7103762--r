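#' Synthetic nascent-RNA coverage from a density map
#'
#' Emulates binned coverage from a metabolic-labelling sequencing experiment
#' (TT-seq-like) over a simulated polymerase density map: per-bin read counts
#' are Poisson with mean `depth * density * spike_scale`, where `spike_scale`
#' is the per-sample library-size factor a spike-in normalization would
#' estimate. The noise model is deliberately Poisson-only; overdispersion is
#' out of scope because these tracks exist to exercise the summarisation math,
#' not to model counts.
#'
#' @param density Density tibble (`gene_id`, `time` optional, `bin`,
#'   `bin_start`, `density`), e.g. `run_replicates(...)$density`.
#' @param depth Expected reads per unit density (>= 0).
#' @param spike_scale Positive per-sample scale factor.
#' @param seed Integer seed.
#' @param sample_label Sample name recorded on the track.
#' @return A coverage-track tibble: the input keys plus `count`,
#'   `spike_scale`, `sample_label`.
#' @examples
#' d <- tibble::tibble(gene_id = "g", bin = 0:2, bin_start = c(0, 1e3, 2e3),
#'                     density = c(2, 1, 0.5))
#' simulate_coverage(d, depth = 50, spike_scale = 1, seed = 1)
#' @export
simulate_coverage <- function(density, depth, spike_scale = 1, seed = 1L,
                              sample_label = "sample_1") {
  if (!is.numeric(depth) || depth < 0) abort("`depth` must be >= 0.")
  if (!is.numeric(spike_scale) || spike_scale <= 0) {
    abort("`spike_scale` must be positive.")
  }
  value <- intersect(c("density", "count", "signal"), names(density))[1]
  if (is.na(value)) abort("`density` needs a density/count/signal column.")
  set.seed(as.integer(seed))
  density |>
    dplyr::mutate(count = rpois(dplyr::n(), depth * .data[[value]] * spike_scale),
                  spike_scale = spike_scale,
                  sample_label = sample_label) |>
    dplyr::select(-dplyr::any_of(setdiff(value, "count")))
}

#' Spike-in scale-factor normalization
#'
#' Divides counts by each track's spike-in scale factor so that tracks
#' generated from the same underlying density at different sequencing depths
#' agree in expectation — the per-sample library-size correction that an
#' external spike-in genome provides.
#'
#' @param tracks Coverage-track tibble(s) with `count` and `spike_scale`
#'   columns (rows from several samples may be combined).
#' @return The input with a `signal = count / spike_scale` column.
#' @export
spike_in_normalize <- function(tracks) {
  if (!all(c("count", "spike_scale") %in% names(tracks))) {
    abort("`tracks` must carry count and spike_scale columns.")
  }
  if (any(is.na(tracks$spike_scale)) || any(tracks$spike_scale <= 0)) {
    abort("`spike_scale` must be known and positive for every track.")
  }
  dplyr::mutate(tracks, signal = .data$count / .data$spike_scale)
}

#' Estimate a spike-in scale factor from counts
#'
#' Ratio-of-totals estimator: the total count of a sample's spike-in track
#' over the total of a reference sample's spike-in track. This mirrors how
#' external spike-in reads are turned into per-sample size factors, without
#' re-implementing a differential-expression normalisation.
#'
#' @param spike_counts Numeric vector of the sample's spike-in bin counts.
#' @param reference_counts Spike-in bin counts of the reference sample.
#' @return A single positive scale factor.
#' @export
estimate_spike_scale <- function(spike_counts, reference_counts) {
  if (sum(reference_counts) <= 0) abort("reference spike-in track has zero total.")
  sum(spike_counts) / sum(reference_counts)
}
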