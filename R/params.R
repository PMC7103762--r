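#' Simulation parameters
#'
#' Collects and validates the full tunable parameter set of the simulator.
#' Internal units are nucleotides and seconds throughout; configuration files
#' additionally accept unit-suffixed strings (see [read_sim_config()]).
#'
#' The defaults are package defaults, not values taken from any particular
#' experiment: elongation at 33.3 nt/s (about 2 kb/min); one transcription-
#' blocking lesion per 25 kb of template strand, the lesion load of a moderate
#' UV dose that restricts elongation to the promoter-proximal 20-30 kb; a 24-h
#' lesion half-life, matching the slow bulk removal kinetics of cyclobutane
#' pyrimidine dimers; a 40-nt head-to-tail
#' exclusion footprint; a negligible removal hazard for productively elongating
#' polymerases; and a 5-min mean residence time for stalled polymerases before
#' dissociation. All of them are ordinary arguments and can be overridden.
#'
#' Two biological toggles map onto the removal-fate parameters:
#' `degradation_enabled = FALSE` (a non-degradable polymerase, the RPB1 K1268R
#' regime) forces `removal_recycle_prob = 1`, and `dissociation_enabled = FALSE`
#' (stalled polymerases can never leave the template) forces
#' `stalled_removal_hazard = 0`.
#'
#' @param genes A gene ensemble tibble from [gene_ensemble()],
#'   [preset_ensemble()] or [random_gene_ensemble()].
#' @param pool_size Total number of polymerases in the system.
#' @param initiation_rate Initiation attempt rate per *free* polymerase, per
#'   second; the aggregate attempt rate is `initiation_rate * free_pool` (mass
#'   action), so initiation declines smoothly as the pool depletes.
#' @param elongation_speed Elongation speed, nt/s.
#' @param pause_site_offset,pause_mean_dwell Optional promoter-proximal pause:
#'   distance of the pause site from the TSS (nt) and mean pause dwell time (s).
#'   `NA` (default) disables pausing.
#' @param footprint Minimum head-to-tail spacing between polymerases, nt.
#' @param lesion_density Expected lesions per template-strand nucleotide at
#'   damage onset.
#' @param lesion_halflife Half-life of a lesion (repair clock), seconds.
#' @param moving_removal_hazard Removal hazard of a moving polymerase, per s.
#' @param stalled_removal_hazard Removal hazard of a halted polymerase (at a
#'   lesion or queued behind one), per second.
#' @param removal_recycle_prob Probability that a removed polymerase returns to
#'   the free pool; otherwise it is degraded.
#' @param completion_recycle_prob Same fate probability for polymerases that
#'   complete transcription.
#' @param degradation_enabled If `FALSE`, removed polymerases are always
#'   recycled (`removal_recycle_prob` forced to 1).
#' @param dissociation_enabled If `FALSE`, halted polymerases are never removed
#'   (`stalled_removal_hazard` forced to 0).
#' @param burn_in_time Pre-damage burn-in, seconds. `NULL` (default) uses five
#'   transit times of the longest gene.
#' @param snapshot_times Snapshot times in seconds *relative to damage onset*;
#'   strictly increasing. A snapshot at damage onset is always recorded.
#' @param n_replicates Default number of independent replicate runs used when
#'   estimating density maps.
#' @param bin_size Bin width for density maps, nt.
#' @param seed Integer root seed; replicate `i` uses `seed + i`.
#'
#' @return A validated `sim_params` object (a named list).
#' @examples
#' p <- sim_params(preset_ensemble("single_100kb"), pool_size = 100)
#' p$pool_size
#' @export
sim_params <- function(genes = preset_ensemble("single_100kb"),
                       pool_size = 1000,
                       initiation_rate = 2e-3,
                       elongation_speed = 33.3,
                       pause_site_offset = NA_real_,
                       pause_mean_dwell = NA_real_,
                       footprint = 40,
                       lesion_density = 1 / 25000,
                       lesion_halflife = 86400,
                       moving_removal_hazard = 1e-5,
                       stalled_removal_hazard = 1 / 300,
                       removal_recycle_prob = 0.5,
                       completion_recycle_prob = 1,
                       degradation_enabled = TRUE,
                       dissociation_enabled = TRUE,
                       burn_in_time = NULL,
                       snapshot_times = c(2700, 10800, 14400),
                       n_replicates = 100,
                       bin_size = 1000,
                       seed = 1L) {
  params <- list(
    genes = genes,
    pool_size = pool_size,
    initiation_rate = initiation_rate,
    elongation_speed = elongation_speed,
    pause_site_offset = pause_site_offset,
    pause_mean_dwell = pause_mean_dwell,
    footprint = footprint,
    lesion_density = lesion_density,
    lesion_halflife = lesion_halflife,
    moving_removal_hazard = moving_removal_hazard,
    stalled_removal_hazard = stalled_removal_hazard,
    removal_recycle_prob = removal_recycle_prob,
    completion_recycle_prob = completion_recycle_prob,
    degradation_enabled = degradation_enabled,
    dissociation_enabled = dissociation_enabled,
    burn_in_time = burn_in_time,
    snapshot_times = snapshot_times,
    n_replicates = n_replicates,
    bin_size = bin_size,
    seed = seed
  )
  validate_sim_params(params)
}

#' Validate simulation parameters
#'
#' Checks every type invariant (rates and hazards non-negative, probabilities
#' in \[0, 1\], footprint smaller than the shortest gene, snapshot times
#' strictly increasing, initiation weights summing to 1) and applies the two
#' regime toggles. The error message names the offending field.
#'
#' @param params A named list with the fields of [sim_params()].
#' @return A validated `sim_params` object, unchanged up to weight
#'   renormalisation and toggle application.
#' @export
validate_sim_params <- function(params) {
  need <- c("genes", "pool_size", "initiation_rate", "elongation_speed",
            "footprint", "lesion_density", "lesion_halflife",
            "moving_removal_hazard", "stalled_removal_hazard",
            "removal_recycle_prob", "completion_recycle_prob",
            "snapshot_times", "n_replicates", "bin_size", "seed")
  missing <- setdiff(need, names(params))
  if (length(missing)) {
    abort(paste0("missing parameter field(s): ", paste(missing, collapse = ", ")))
  }
  g <- params$genes
  if (!is.data.frame(g) || !all(c("gene_id", "length", "initiation_weight") %in% names(g))) {
    abort("`genes`: must be a gene ensemble with gene_id, length, initiation_weight.")
  }
  params$genes <- gene_ensemble(g$length, g$initiation_weight, g$gene_id)

  chk_scalar <- function(x, field, lo = 0, hi = Inf, lo_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
        x < lo || x > hi || (lo_open && x <= lo)) {
      abort(sprintf("`%s`: invalid value.", field))
    }
  }
  chk_scalar(params$pool_size, "pool_size")
  if (params$pool_size != round(params$pool_size)) abort("`pool_size`: must be an integer count.")
  chk_scalar(params$initiation_rate, "initiation_rate")
  chk_scalar(params$elongation_speed, "elongation_speed", lo_open = TRUE)
  chk_scalar(params$footprint, "footprint", lo_open = TRUE)
  if (params$footprint >= min(params$genes$length)) {
    abort("`footprint`: must be smaller than the shortest gene.")
  }
  chk_scalar(params$lesion_density, "lesion_density")
  chk_scalar(params$lesion_halflife, "lesion_halflife", lo_open = TRUE)
  chk_scalar(params$moving_removal_hazard, "moving_removal_hazard")
  chk_scalar(params$stalled_removal_hazard, "stalled_removal_hazard")
  chk_scalar(params$removal_recycle_prob, "removal_recycle_prob", 0, 1)
  chk_scalar(params$completion_recycle_prob, "completion_recycle_prob", 0, 1)
  for (f in c("degradation_enabled", "dissociation_enabled")) {
    if (!is.logical(params[[f]]) || length(params[[f]]) != 1L || is.na(params[[f]])) {
      abort(sprintf("`%s`: must be TRUE or FALSE.", f))
    }
  }
  pso <- params$pause_site_offset
  pmd <- params$pause_mean_dwell
  pause_on <- !is.null(pso) && !is.na(pso)
  if (pause_on) {
    chk_scalar(pso, "pause_site_offset", lo_open = TRUE)
    if (is.null(pmd) || is.na(pmd)) abort("`pause_mean_dwell`: required when pausing is enabled.")
    chk_scalar(pmd, "pause_mean_dwell", lo_open = TRUE)
    if (pso >= min(params$genes$length)) abort("`pause_site_offset`: beyond the shortest gene.")
  } else {
    params$pause_site_offset <- NA_real_
    params$pause_mean_dwell <- NA_real_
  }
  if (!is.null(params$burn_in_time)) {
    chk_scalar(params$burn_in_time, "burn_in_time")
  }
  st <- params$snapshot_times
  if (!is.numeric(st) || length(st) < 1L || any(!is.finite(st)) || any(st < 0) ||
      any(diff(st) <= 0)) {
    abort("`snapshot_times`: must be non-negative and strictly increasing.")
  }
  chk_scalar(params$n_replicates, "n_replicates", lo_open = TRUE)
  chk_scalar(params$bin_size, "bin_size", lo_open = TRUE)
  if (!is.numeric(params$seed) || length(params$seed) != 1L || !is.finite(params$seed)) {
    abort("`seed`: must be a single integer.")
  }

  # regime toggles
  if (!params$degradation_enabled) params$removal_recycle_prob <- 1
  if (!params$dissociation_enabled) params$stalled_removal_hazard <- 0

  structure(params, class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  genes: %d (%s)\n", nrow(x$genes),
              paste(sprintf("%s %.0f nt w=%.2f", x$genes$gene_id, x$genes$length,
                            x$genes$initiation_weight), collapse = "; ")))
  cat(sprintf("  pool_size: %d   initiation_rate: %g /free pol/s   speed: %g nt/s\n",
              x$pool_size, x$initiation_rate, x$elongation_speed))
  cat(sprintf("  lesions: density %g /nt, half-life %g s\n",
              x$lesion_density, x$lesion_halflife))
  cat(sprintf("  removal hazards: moving %g, stalled %g /s;  recycle prob: removal %g, completion %g\n",
              x$moving_removal_hazard, x$stalled_removal_hazard,
              x$removal_recycle_prob, x$completion_recycle_prob))
  cat(sprintf("  toggles: degradation %s, dissociation %s\n",
              x$degradation_enabled, x$dissociation_enabled))
  cat(sprintf("  snapshots (s post-damage): %s;  replicates: %d;  bin: %g nt;  seed: %d\n",
              paste(x$snapshot_times, collapse = ", "), x$n_replicates,
              x$bin_size, as.integer(x$seed)))
  invisible(x)
}

# longest-gene transit time, the natural time scale of a parameter set
transit_time <- function(params) max(params$genes$length) / params$elongation_speed

# burn-in duration actually used
burn_in_duration <- function(params) {
  if (is.null(params$burn_in_time)) 5 * transit_time(params) else params$burn_in_time
}

# parameter list handed to the C++ kernel
engine_par_list <- function(params) {
  list(
    gene_length = params$genes$length,
    gene_weight = params$genes$initiation_weight,
    pool_size = as.integer(params$pool_size),
    initiation_rate = params$initiation_rate,
    elongation_speed = params$elongation_speed,
    footprint = params$footprint,
    pause_site_offset = params$pause_site_offset,
    pause_mean_dwell = params$pause_mean_dwell,
    lesion_density = params$lesion_density,
    lesion_halflife = params$lesion_halflife,
    moving_removal_hazard = params$moving_removal_hazard,
    stalled_removal_hazard = params$stalled_removal_hazard,
    removal_recycle_prob = params$removal_recycle_prob,
    completion_recycle_prob = params$completion_recycle_prob
  )
}
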