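#' Simulation scenarios
#'
#' A scenario bundles a parameter set with a biological regime and a replicate
#' count. The regime sets the two fate toggles and nothing else:
#'
#' * `"wt"` — degradation on, dissociation on: stalled polymerases dissociate
#'   and are degraded with probability `1 - removal_recycle_prob` (the
#'   wild-type response, where the polymerase pool shrinks after damage).
#' * `"no_degradation"` — removed polymerases are always recycled
#'   (`removal_recycle_prob = 1`); dissociation stays on. This emulates a
#'   non-degradable polymerase (the RPB1 K1268R mutant).
#' * `"no_dissociation"` — halted polymerases can never leave the template
#'   (`stalled_removal_hazard = 0`) and nothing is degraded: the pile-up
#'   thought experiment in which polymerases accumulate head-to-tail at
#'   lesions.
#' * `"undamaged"` — no lesions (`lesion_density = 0`).
#'
#' @param params A [sim_params()] object (regime toggles will be overridden).
#' @param regime One of `"wt"`, `"no_degradation"`, `"no_dissociation"`,
#'   `"undamaged"`.
#' @param n_replicates Number of independent replicate runs (default 100, the
#'   standard replicate count for density estimation).
#' @param name Optional scenario name; defaults to `<ensemble>_<regime>`.
#' @return A `pol_scenario` object.
#' @examples
#' sc <- scenario(sim_params(preset_ensemble("three_gene")), "no_degradation")
#' sc$regime
#' @export
scenario <- function(params,
                     regime = c("wt", "no_degradation", "no_dissociation", "undamaged"),
                     n_replicates = 100,
                     name = NULL) {
  regime <- match.arg(regime)
  params <- validate_sim_params(params)
  params <- switch(regime,
    wt = {
      params$degradation_enabled <- TRUE
      params$dissociation_enabled <- TRUE
      params
    },
    no_degradation = {
      params$degradation_enabled <- FALSE
      params$dissociation_enabled <- TRUE
      params
    },
    no_dissociation = {
      params$degradation_enabled <- FALSE
      params$dissociation_enabled <- FALSE
      params
    },
    undamaged = {
      params$lesion_density <- 0
      params
    }
  )
  params <- validate_sim_params(params)
  if (!is.numeric(n_replicates) || n_replicates < 1) {
    abort("`n_replicates` must be a positive integer.")
  }
  if (is.null(name)) name <- regime
  structure(list(name = name, params = params, regime = regime,
                 n_replicates = as.integer(n_replicates)),
            class = "pol_scenario")
}

#' Preset scenarios
#'
#' Named combinations of the two preset gene ensembles with a regime, e.g.
#' `"single_100kb_wt"`, `"three_gene_no_degradation"`,
#' `"single_100kb_no_dissociation"`, `"three_gene_undamaged"`.
#'
#' @param name Scenario name: `<single_100kb|three_gene>_<regime>`.
#' @param ... Overrides passed to [sim_params()].
#' @return A `pol_scenario`.
#' @examples
#' preset_scenario("single_100kb_wt")$regime
#' @export
preset_scenario <- function(name, ...) {
  regimes <- c("wt", "no_degradation", "no_dissociation", "undamaged")
  ensembles <- c("single_100kb", "three_gene")
  ok <- FALSE
  for (e in ensembles) for (r in regimes) {
    if (identical(name, paste(e, r, sep = "_"))) {
      ens <- e; reg <- r; ok <- TRUE
    }
  }
  if (!ok) {
    abort(sprintf("unknown scenario preset \"%s\"; expected <%s>_<%s>.",
                  name, paste(ensembles, collapse = "|"),
                  paste(regimes, collapse = "|")))
  }
  p <- sim_params(genes = preset_ensemble(ens), ...)
  scenario(p, regime = reg, n_replicates = p$n_replicates, name = name)
}

#' @export
print.pol_scenario <- function(x, ...) {
  cat(sprintf("<pol_scenario> %s (regime %s, %d replicates)\n",
              x$name, x$regime, x$n_replicates))
  print(x$params)
  invisible(x)
}

#' Run replicate simulations and average occupancy
#'
#' Runs `n_replicates` independent simulations (replicate `i` uses seed
#' `seed + i`), bins the engaged-polymerase occupancy of every snapshot, and
#' averages across replicates into a density map — the in silico analogue of a
#' population coverage profile. Per-replicate scalar series (free pool,
#' degraded count, cumulative mRNA) are kept unaveraged.
#'
#' @param scen A [scenario()].
#' @param seed Root seed; defaults to the scenario's `params$seed`.
#' @param series_times Optional extra scalar-series times (s post-damage).
#' @return A `pol_ensemble` object with `density` (tibble: `gene_id`, `time`,
#'   `bin`, `bin_start`, `density` = mean polymerases per bin per run),
#'   `series` and `mrna` (per-replicate tibbles), `queues` (per-replicate,
#'   per-lesion queue lengths at every snapshot), `n_replicates`, `bin_size`
#'   and the scenario.
#' @examples
#' sc <- scenario(sim_params(preset_ensemble("single_100kb"), pool_size = 30,
#'                           snapshot_times = c(300, 600)), "wt",
#'                n_replicates = 3)
#' ens <- run_replicates(sc)
#' head(ens$density)
#' @export
run_replicates <- function(scen, seed = scen$params$seed, series_times = NULL) {
  stopifnot(inherits(scen, "pol_scenario"))
  params <- scen$params
  n <- scen$n_replicates
  runs <- purrr::map(seq_len(n), function(i) {
    tr <- tryCatch(
      simulate_transcription(params, seed = as.integer(seed) + i,
                             series_times = series_times),
      error = function(e) abort(sprintf("replicate %d failed: %s", i, conditionMessage(e)))
    )
    tr
  })
  occ <- purrr::map2_dfr(runs, seq_len(n),
                         ~ dplyr::mutate(.x$snapshots, replicate = .y))
  dens <- density_profile(occ, genes = params$genes, bin_size = params$bin_size) |>
    dplyr::mutate(density = .data$count / n) |>
    dplyr::select(-"count")
  series <- purrr::map2_dfr(runs, seq_len(n),
                            ~ dplyr::mutate(.x$series, replicate = .y, .before = 1))
  mrna <- purrr::map2_dfr(runs, seq_len(n),
                          ~ dplyr::mutate(.x$mrna, replicate = .y, .before = 1))
  queues <- purrr::map2_dfr(runs, seq_len(n), function(tr, i) {
    dplyr::mutate(queue_statistics(tr), replicate = i, .before = 1)
  })
  structure(list(
    density = dens,
    series = series,
    mrna = mrna,
    queues = queues,
    n_replicates = n,
    bin_size = params$bin_size,
    scenario = scen,
    seed = as.integer(seed)
  ), class = "pol_ensemble")
}

#' @export
print.pol_ensemble <- function(x, ...) {
  cat(sprintf("<pol_ensemble> %s: %d replicates, %g-nt bins\n",
              x$scenario$name, x$n_replicates, x$bin_size))
  cat(sprintf("  snapshots (s post-damage): %s\n",
              paste(sort(unique(x$density$time)), collapse = ", ")))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.pol_ensemble <- function(x, ...) x$density

#' Predicted mRNA output per gene
#'
#' Cumulative completed transcripts per gene produced between damage onset and
#' `horizon` seconds later, per replicate, summarised as mean and standard
#' deviation. Run against an `"undamaged"` scenario to obtain the baseline for
#' damage-to-baseline output ratios.
#'
#' @param scen A [scenario()].
#' @param horizon Seconds after damage onset (default 4 h).
#' @param seed Root seed; defaults to the scenario seed.
#' @return A tibble: `gene_id`, `class_label`, `mean_count`, `sd_count`,
#'   `n_replicates`.
#' @export
predicted_mrna_counts <- function(scen, horizon = 14400, seed = scen$params$seed) {
  stopifnot(inherits(scen, "pol_scenario"))
  if (!is.numeric(horizon) || horizon < 0) abort("`horizon` must be >= 0 seconds.")
  params <- scen$params
  if (horizon > max(params$snapshot_times)) {
    params$snapshot_times <- sort(unique(c(params$snapshot_times, horizon)))
    scen$params <- validate_sim_params(params)
  }
  ens <- run_replicates(scen, seed = seed, series_times = horizon)
  prod <- ens$mrna |>
    dplyr::filter(.data$time %in% c(0, horizon)) |>
    tidyr::pivot_wider(names_from = "time", values_from = "count",
                       names_prefix = "t") |>
    dplyr::mutate(produced = .data[[paste0("t", format(horizon, scientific = FALSE))]] - .data$t0)
  prod |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(mean_count = mean(.data$produced),
                     sd_count = sd(.data$produced), .groups = "drop") |>
    dplyr::left_join(dplyr::select(scen$params$genes, "gene_id", "class_label"),
                     by = "gene_id") |>
    dplyr::relocate("class_label", .after = "gene_id") |>
    dplyr::mutate(n_replicates = scen$n_replicates)
}

#' Calibrate the stalled-polymerase removal hazard
#'
#' Log-scale bisection over `stalled_removal_hazard` so that the exponential
#' half-life fitted to the mean surviving polymerase count (pool size minus
#' degraded count, the whole-extract analogue of a western-blot signal) over
#' `0..window` seconds after damage matches `target_halflife` within `tol`.
#' Each bisection iterate uses `n_cal` replicates; the returned hazard is
#' re-verified with `n_final` fresh replicates.
#'
#' @param scen A `"wt"`-regime [scenario()] (degradation must be enabled).
#' @param target_halflife Target half-life, seconds (e.g. `1.5 * 3600`).
#' @param tol Relative tolerance on the achieved half-life (default 0.1).
#' @param bracket Hazard bracket, per second (default `c(1e-5, 0.1)`).
#' @param window Fit window after damage onset, seconds (default 4 h).
#' @param sample_every Sampling interval of the survivor series (default 15 min).
#' @param n_cal,n_final Replicates per bisection iterate / per verification.
#' @param seed Root seed.
#' @param max_iter Maximum bisection iterations.
#'
#' @details Bisection iterates share one set of replicate seeds (common random
#' numbers), which makes the half-life-versus-hazard response smooth and
#' monotone so the bracket updates are reliable despite replicate noise. When
#' an iterate lands within `tol`, the hazard is re-measured with `n_final`
#' *fresh* replicates; if that verification misses the tolerance, its value
#' replaces the iterate's and bisection continues. The reported half-life is
#' therefore always an independent `n_final`-replicate measurement at the
#' returned hazard.
#'
#' @return A `degradation_calibration` object: list with `hazard`,
#'   `achieved_halflife` (verified, seconds), `target_halflife`, `tol`,
#'   `iterations` (tibble of the bisection path) and the verification fit.
#' @export
calibrate_degradation <- function(scen, target_halflife, tol = 0.1,
                                  bracket = c(1e-5, 0.1), window = 14400,
                                  sample_every = 900, n_cal = 30, n_final = 100,
                                  seed = scen$params$seed, max_iter = 25) {
  stopifnot(inherits(scen, "pol_scenario"))
  if (scen$regime != "wt" || !scen$params$degradation_enabled ||
      scen$params$removal_recycle_prob >= 1) {
    abort("calibration requires a wt regime with degradation enabled (removal_recycle_prob < 1).")
  }
  if (!is.numeric(target_halflife) || target_halflife <= 0) {
    abort("`target_halflife` must be positive (seconds).")
  }
  if (!is.numeric(tol) || tol <= 0) abort("`tol` must be positive.")
  times <- seq(0, window, by = sample_every)

  measure <- function(hazard, rep_seeds) {
    p <- scen$params
    p$stalled_removal_hazard <- hazard
    p <- validate_sim_params(p)
    surv <- purrr::map_dfr(rep_seeds, function(s) {
      tr <- simulate_transcription(p, seed = s, series_times = times)
      dplyr::transmute(tr$series, time = .data$time,
                       surviving = p$pool_size - .data$degraded)
    })
    mean_surv <- surv |>
      dplyr::filter(.data$time %in% times) |>
      dplyr::group_by(.data$time) |>
      dplyr::summarise(count = mean(.data$surviving), .groups = "drop")
    fit_half_life(mean_surv$time, mean_surv$count)
  }

  seed <- as.integer(seed)
  cal_seeds <- seed + seq_len(n_cal)            # shared across iterates (CRN)
  verify_seeds <- function(k) seed + 100000L * k + seq_len(n_final)

  lo <- bracket[1]; hi <- bracket[2]
  hl_lo <- measure(lo, cal_seeds)$half_life
  hl_hi <- measure(hi, cal_seeds)$half_life
  iters <- tibble(iteration = c(0, 0), hazard = c(lo, hi),
                  half_life = c(hl_lo, hl_hi), verified = c(FALSE, FALSE))
  if (!(hl_lo >= target_halflife && hl_hi <= target_halflife)) {
    abort(sprintf(
      paste0("calibration target unreachable in bracket [%g, %g] /s: ",
             "half-lives [%.0f, %.0f] s do not straddle the %.0f-s target."),
      lo, hi, hl_hi, hl_lo, target_halflife))
  }
  hazard <- NA_real_
  verification <- NULL
  n_verify <- 0L
  for (it in seq_len(max_iter)) {
    mid <- sqrt(lo * hi)
    hl <- measure(mid, cal_seeds)$half_life
    ver <- FALSE
    if (is.finite(hl) && abs(hl - target_halflife) <= tol * target_halflife) {
      n_verify <- n_verify + 1L
      vfit <- measure(mid, verify_seeds(n_verify))
      hl <- vfit$half_life
      ver <- TRUE
      if (is.finite(hl) && abs(hl - target_halflife) <= tol * target_halflife) {
        hazard <- mid
        verification <- vfit
      }
    }
    iters <- dplyr::bind_rows(iters,
      tibble(iteration = it, hazard = mid, half_life = hl, verified = ver))
    if (!is.na(hazard)) break
    if (hl > target_halflife) lo <- mid else hi <- mid
  }
  if (is.na(hazard)) {
    abort(sprintf(
      "calibration did not converge in %d iterations (bracket now [%g, %g] /s).",
      max_iter, lo, hi))
  }
  structure(list(
    hazard = hazard,
    achieved_halflife = verification$half_life,
    target_halflife = target_halflife,
    tol = tol,
    iterations = iters,
    verification_fit = verification,
    n_cal = n_cal,
    n_final = n_final
  ), class = "degradation_calibration")
}

#' @export
print.degradation_calibration <- function(x, ...) {
  cat(sprintf(
    "<degradation_calibration> hazard %.3g /s -> half-life %.0f s (target %.0f s +/- %.0f%%)\n",
    x$hazard, x$achieved_halflife, x$target_halflife, 100 * x$tol))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.degradation_calibration <- function(x, ...) x$iterations

#' @rdname tidiers
#' @export
glance.degradation_calibration <- function(x, ...) {
  tibble(hazard = x$hazard, achieved_halflife = x$achieved_halflife,
         target_halflife = x$target_halflife, tol = x$tol,
         n_iterations = max(x$iterations$iteration),
         n_cal = x$n_cal, n_final = x$n_final)
}
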