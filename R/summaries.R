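#' Binned polymerase occupancy
#'
#' Counts each engaged polymerase once in the half-open bin
#' `[k * bin_size, (k + 1) * bin_size)` containing its position, per gene and
#' per snapshot time. Bins with no polymerase are kept with a zero count, so
#' every gene contributes `ceiling(length / bin_size)` bins.
#'
#' @param x A `pol_trajectory`, or a snapshot tibble with columns `time`,
#'   `gene_id`, `position` (as produced by [simulate_transcription()]).
#' @param genes Gene ensemble tibble (needed when `x` is a bare tibble).
#' @param bin_size Bin width, nt.
#' @return A tibble: `gene_id`, `time`, `bin`, `bin_start`, `count`.
#' @export
density_profile <- function(x, genes = NULL, bin_size = 1000) {
  times <- NULL
  if (inherits(x, "pol_trajectory")) {
    genes <- x$params$genes
    snaps <- x$snapshots
    times <- sort(unique(c(0, x$params$snapshot_times)))
  } else {
    snaps <- x
    if (is.null(genes)) abort("`genes` is required when `x` is a plain snapshot tibble.")
  }
  if (is.null(times)) times <- sort(unique(snaps$time))
  if (!is.numeric(bin_size) || bin_size <= 0) abort("`bin_size` must be positive.")
  grid <- genes |>
    dplyr::rowwise() |>
    dplyr::reframe(gene_id = .data$gene_id,
                   bin = seq_len(ceiling(.data$length / bin_size)) - 1L) |>
    tidyr::crossing(time = times)
  counts <- snaps |>
    dplyr::mutate(bin = as.integer(floor(.data$position / bin_size))) |>
    dplyr::count(.data$gene_id, .data$time, .data$bin, name = "count")
  grid |>
    dplyr::left_join(counts, by = c("gene_id", "time", "bin")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L),
                  bin_start = .data$bin * bin_size) |>
    dplyr::select("gene_id", "time", "bin", "bin_start", "count") |>
    dplyr::arrange(.data$gene_id, .data$time, .data$bin)
}

#' Gene-length-stratified metagene profile
#'
#' Rescales each gene's binned signal onto a common relative axis between the
#' TSS (0) and the TTS (1) with `n_rel_bins` points, then averages genes with
#' equal weight — within each length class when `stratify = TRUE` (classes from
#' [classify_gene_length()]), otherwise over all genes.
#'
#' @param profile Tidy binned signal: columns `gene_id`, `bin_start`, a value
#'   column, and optionally `time` (profiles are computed per time).
#' @param genes Gene ensemble tibble supplying gene lengths.
#' @param value Name of the value column (default `"density"`, falling back to
#'   `"count"` or `"signal"` if absent).
#' @param stratify Average within length classes (`TRUE`) or over all genes.
#' @param n_rel_bins Number of points on the relative TSS-to-TTS axis.
#' @return A tibble: `class_label` (when stratified), `time` (when present),
#'   `rel_position` in (0, 1), `mean_signal`.
#' @export
metagene_profile <- function(profile, genes, value = NULL, stratify = TRUE,
                             n_rel_bins = 100) {
  if (is.null(value)) {
    value <- intersect(c("density", "count", "signal"), names(profile))[1]
    if (is.na(value)) abort("no value column found (expected density, count or signal).")
  }
  if (!value %in% names(profile)) abort(sprintf("no column `%s` in `profile`.", value))
  lens <- setNames(genes$length, genes$gene_id)
  cls <- setNames(classify_gene_length(genes$length), genes$gene_id)
  if (!all(profile$gene_id %in% names(lens))) {
    abort("`profile` contains genes absent from `genes`.")
  }
  has_time <- "time" %in% names(profile)
  if (!has_time) profile$time <- 0
  rel <- (seq_len(n_rel_bins) - 0.5) / n_rel_bins

  per_gene <- profile |>
    dplyr::group_by(.data$gene_id, .data$time) |>
    dplyr::group_modify(function(d, key) {
      d <- dplyr::arrange(d, .data$bin_start)
      L <- lens[[key$gene_id]]
      ctr <- (d$bin_start + c(diff(d$bin_start) / 2, (L - utils::tail(d$bin_start, 1)) / 2)) / L
      y <- d[[value]]
      if (nrow(d) == 1L) {
        out <- rep(y, n_rel_bins)
      } else {
        out <- stats::approx(ctr, y, xout = rel, rule = 2)$y
      }
      tibble(rel_position = rel, signal = out)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(class_label = unname(cls[.data$gene_id]))

  if (stratify) {
    present <- unique(per_gene$class_label)
    absent <- setdiff(c("short", "medium", "long"), present)
    if (length(absent)) {
      warn(paste0("no genes in class(es): ", paste(absent, collapse = ", "),
                  "; omitted from the metagene."))
    }
    out <- per_gene |>
      dplyr::group_by(.data$class_label, .data$time, .data$rel_position) |>
      dplyr::summarise(mean_signal = mean(.data$signal), .groups = "drop")
  } else {
    out <- per_gene |>
      dplyr::group_by(.data$time, .data$rel_position) |>
      dplyr::summarise(mean_signal = mean(.data$signal), .groups = "drop")
  }
  if (!has_time) out$time <- NULL
  out
}

#' TSS-anchored absolute-scale profile
#'
#' Mean signal over genes on an absolute axis downstream of the TSS (genes
#' shorter than `window` contribute only their own bins), mirroring coverage
#' profiles plotted over a fixed TSS window rather than a relative gene-body
#' axis.
#'
#' @inheritParams metagene_profile
#' @param window Window downstream of the TSS, nt (default 100 kb).
#' @return A tibble: `time` (when present), `bin_start`, `mean_signal`, `n_genes`.
#' @export
tss_anchored_profile <- function(profile, genes, value = NULL, window = 1e5) {
  if (is.null(value)) {
    value <- intersect(c("density", "count", "signal"), names(profile))[1]
    if (is.na(value)) abort("no value column found (expected density, count or signal).")
  }
  has_time <- "time" %in% names(profile)
  if (!has_time) profile$time <- 0
  out <- profile |>
    dplyr::filter(.data$bin_start < window) |>
    dplyr::group_by(.data$time, .data$bin_start) |>
    dplyr::summarise(mean_signal = mean(.data[[value]]),
                     n_genes = dplyr::n(), .groups = "drop")
  if (!has_time) out$time <- NULL
  out
}

#' Fit an exponential half-life
#'
#' Least-squares fit of `log(count)` against time; the half-life is
#' `ln 2 / |slope|`. If the slope is non-negative within one standard error
#' (no detectable decay), the half-life is `+Inf`.
#'
#' @param time Times, seconds (strictly increasing, length >= 3), or a
#'   two-column data frame `(time, count)`.
#' @param count Positive counts.
#' @return A `half_life_fit` object: list with `half_life` (seconds), `slope`,
#'   `slope_se`, `r_squared`, `n`, and the fitted data. Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' f <- fit_half_life(c(0, 3600, 7200, 10800), 100 * 2^(-(0:3) * 3600 / 5400))
#' f$half_life / 3600
#' @export
fit_half_life <- function(time, count = NULL) {
  if (is.data.frame(time)) {
    count <- time[[2]]
    time <- time[[1]]
  }
  if (length(time) < 3L) abort("at least 3 points are required.")
  if (any(diff(time) <= 0)) abort("`time` must be strictly increasing.")
  if (any(!is.finite(count)) || any(count <= 0)) {
    abort("`count` must be positive (log-linear fit).")
  }
  fit <- lm(log(count) ~ time)
  sm <- suppressWarnings(summary(fit)) # a perfect fit warns; zero SE is meaningful here
  slope <- unname(coef(fit)[2])
  se <- unname(sm$coefficients[2, 2])
  r2 <- sm$r.squared
  # no detectable decay: slope non-negative within its SE, or numerically zero
  hl <- if (slope + se >= 0 || abs(slope) < 1e-12) Inf else log(2) / abs(slope)
  structure(list(
    half_life = hl,
    slope = slope,
    slope_se = se,
    r_squared = r2,
    n = length(time),
    coef_table = sm$coefficients,
    data = tibble(time = time, count = count),
    fit = fit
  ), class = "half_life_fit")
}

#' @export
print.half_life_fit <- function(x, ...) {
  cat(sprintf("<half_life_fit> half-life %s s (slope %.3g +/- %.3g /s, R^2 %.3f, n = %d)\n",
              format(x$half_life, digits = 4), x$slope, x$slope_se, x$r_squared, x$n))
  invisible(x)
}

#' Tidiers for uvpolsim result objects
#'
#' broom-style [tidy()] and [glance()] methods.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.half_life_fit <- function(x, ...) {
  tibble(term = c("log_intercept", "slope"),
         estimate = unname(x$coef_table[, 1]),
         std.error = unname(x$coef_table[, 2]))
}

#' @rdname tidiers
#' @export
glance.half_life_fit <- function(x, ...) {
  tibble(half_life = x$half_life, slope = x$slope, slope_se = x$slope_se,
         r_squared = x$r_squared, n = x$n)
}

#' Late/early signal ratio per gene
#'
#' Ratio of total gene-body signal between a late and an early snapshot; 1
#' means unchanged activity, values below 1 a decline (the initiation
#' shutdown readout). A gene with zero early signal yields `NA`.
#'
#' @param density A density tibble (`gene_id`, `time`, `density` or `count`),
#'   e.g. `run_replicates(...)$density`.
#' @param t_early,t_late Snapshot times present in `density`.
#' @return A tibble: `gene_id`, `early`, `late`, `ratio`.
#' @export
shutdown_ratio <- function(density, t_early, t_late) {
  value <- intersect(c("density", "count"), names(density))[1]
  if (is.na(value)) abort("`density` needs a density or count column.")
  if (!all(c(t_early, t_late) %in% density$time)) {
    abort("both snapshot times must be present in `density`.")
  }
  out <- density |>
    dplyr::filter(.data$time %in% c(t_early, t_late)) |>
    dplyr::mutate(when = ifelse(.data$time == t_early, "early", "late")) |>
    dplyr::group_by(.data$gene_id, .data$when) |>
    dplyr::summarise(total = sum(.data[[value]]), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "when", values_from = "total") |>
    dplyr::mutate(ratio = ifelse(.data$early > 0, .data$late / .data$early, NA_real_))
  if (any(is.na(out$ratio))) {
    warn("gene(s) with zero early signal: ratio reported as NA.")
  }
  out
}

#' Queue lengths behind lesions
#'
#' For each active lesion in each snapshot, the queue length is the number of
#' halted polymerases in the contiguous head-to-tail chain ending at the
#' lesion: the polymerase stalled at the lesion itself plus followers spaced at
#' most one footprint behind the one in front. Lesions with no stalled
#' polymerase have queue length 0.
#'
#' @param x A `pol_trajectory`, or a list with `snapshots` and `lesions`
#'   tibbles in the same layout.
#' @param footprint Exclusion footprint, nt; taken from the trajectory's
#'   parameters when available.
#' @return A tibble: `time`, `gene_id`, `lesion_position`, `queue_length`.
#' @export
queue_statistics <- function(x, footprint = NULL) {
  if (inherits(x, "pol_trajectory")) {
    footprint <- x$params$footprint
    snaps <- x$snapshots
    lesions <- x$lesions
  } else {
    snaps <- x$snapshots
    lesions <- x$lesions
    if (is.null(footprint)) abort("`footprint` is required for plain snapshot input.")
  }
  if (nrow(lesions) == 0) {
    return(tibble(time = numeric(), gene_id = character(),
                  lesion_position = numeric(), queue_length = integer()))
  }
  active <- dplyr::filter(lesions, .data$active)
  stalled <- dplyr::filter(snaps, .data$status %in% c("stalled_lesion", "stalled_queue"))
  purrr::pmap_dfr(
    dplyr::select(active, "time", "gene_id", "position"),
    function(time, gene_id, position) {
      here <- stalled[stalled$time == time & stalled$gene_id == gene_id, ]
      pos <- sort(here$position, decreasing = TRUE)
      n <- 0L
      anchor <- position
      for (p in pos) {
        if (p <= anchor + 1e-6 && p >= anchor - footprint - 1e-6) {
          n <- n + 1L
          anchor <- p
        } else if (p < anchor - footprint - 1e-6) {
          break
        }
      }
      tibble(time = time, gene_id = gene_id,
             lesion_position = position, queue_length = n)
    }
  )
}

#' Distance between two normalized profiles
#'
#' The L1 distance between unit-mass-normalised profiles, in \[0, 2\] (0 for
#' identical shapes, 2 for disjoint ones). When `a` carries per-replicate
#' profiles (a matrix with one row per replicate, or a tibble with a
#' `replicate` column), a bootstrap null band is attached: the distribution of
#' the L1 distance between two independent bootstrap means drawn from `a`'s
#' replicates — the distance expected when both profiles estimate the same
#' underlying shape.
#'
#' @param a,b Profiles over identical bins: numeric vectors, matrices
#'   (replicates in rows), or tibbles with columns `replicate` (optional) and a
#'   value column (last column used).
#' @param n_boot Bootstrap draws for the null band (default 1000).
#' @param level Null-band coverage (default 0.99).
#' @return A `profile_distance` object: list with `statistic`, `null_band`
#'   (quantiles of the null, `NA` without replicate information), `n_boot`,
#'   `inside_null`.
#' @export
profile_distance <- function(a, b, n_boot = 1000, level = 0.99) {
  as_mat <- function(x) {
    if (is.matrix(x)) return(x)
    if (is.data.frame(x)) {
      if ("replicate" %in% names(x)) {
        vcol <- setdiff(names(x), "replicate")
        vcol <- vcol[length(vcol)]
        m <- x |>
          dplyr::group_by(.data$replicate) |>
          dplyr::group_map(~ .x[[vcol]])
        return(do.call(rbind, m))
      }
      return(matrix(x[[ncol(x)]], nrow = 1))
    }
    matrix(as.numeric(x), nrow = 1)
  }
  A <- as_mat(a); B <- as_mat(b)
  if (ncol(A) != ncol(B)) abort("profiles must share the same binning.")
  normalise <- function(v) {
    s <- sum(v)
    if (!is.finite(s) || s <= 0) abort("zero-mass profile.")
    v / s
  }
  pa <- normalise(colMeans(A))
  pb <- normalise(colMeans(B))
  statistic <- sum(abs(pa - pb))
  null_band <- c(NA_real_, NA_real_)
  inside <- NA
  if (nrow(A) > 1) {
    null <- vapply(seq_len(n_boot), function(i) {
      i1 <- sample.int(nrow(A), replace = TRUE)
      i2 <- sample.int(nrow(A), replace = TRUE)
      p1 <- colMeans(A[i1, , drop = FALSE])
      p2 <- colMeans(A[i2, , drop = FALSE])
      if (sum(p1) <= 0 || sum(p2) <= 0) return(NA_real_)
      sum(abs(p1 / sum(p1) - p2 / sum(p2)))
    }, numeric(1))
    null <- null[is.finite(null)]
    null_band <- unname(quantile(null, c((1 - level) / 2, 1 - (1 - level) / 2)))
    inside <- statistic <= null_band[2]
  }
  structure(list(statistic = statistic, null_band = null_band,
                 n_boot = n_boot, level = level, inside_null = inside),
            class = "profile_distance")
}

#' @export
print.profile_distance <- function(x, ...) {
  cat(sprintf("<profile_distance> L1 = %.4f", x$statistic))
  if (!is.na(x$null_band[2])) {
    cat(sprintf("  (null band [%.4f, %.4f] at %.0f%%; inside: %s)",
                x$null_band[1], x$null_band[2], 100 * x$level, x$inside_null))
  }
  cat("\n")
  invisible(x)
}

#' @rdname tidiers
#' @export
glance.profile_distance <- function(x, ...) {
  tibble(statistic = x$statistic, null_lo = x$null_band[1],
         null_hi = x$null_band[2], n_boot = x$n_boot, inside_null = x$inside_null)
}
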