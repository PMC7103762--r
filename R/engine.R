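#' @describeIn sim_state Internal status and event-kind code tables.
#' @noRd
.status_labels <- c("1" = "moving", "2" = "stalled_lesion", "3" = "stalled_queue",
                    "4" = "paused")
.event_labels <- c("0" = "none", "1" = "initiation", "2" = "initiation_blocked",
                   "3" = "stall", "4" = "stall", "5" = "pause", "6" = "pause_release",
                   "7" = "release", "8" = "repair", "9" = "removal",
                   "10" = "removal", "11" = "completion", "12" = "damage_onset")
.stop_labels <- c("0" = "none", "1" = "stall", "2" = "stall", "3" = "completion",
                  "4" = "pause", "5" = "pause_release")

#' Initialise a simulation state
#'
#' Creates a fresh simulation state: clock at zero, every polymerase in the
#' free pool, no lesions, and the first initiation attempt scheduled. The state
#' is a mutable handle; the engine operations ([advance_positions()],
#' [step_simulation()], [burn_in()], [apply_damage()], [run_until()]) modify it
#' in place. All randomness flows from R's RNG, seeded here, so two states
#' built from the same `(params, seed)` evolve identically.
#'
#' @param params A validated [sim_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @param log_events If `TRUE`, every handled event is recorded and can be
#'   retrieved with [event_log()].
#' @return A `sim_state` object.
#' @examples
#' st <- sim_state(sim_params(pool_size = 10), seed = 1)
#' state_snapshot(st)$free_pool
#' @export
sim_state <- function(params, seed = params$seed, log_events = FALSE) {
  params <- validate_sim_params(params)
  set.seed(as.integer(seed))
  ptr <- .engine_new(engine_par_list(params))
  if (log_events) .engine_set_log(ptr, TRUE)
  structure(
    new.env(parent = emptyenv()),
    class = "sim_state"
  ) -> st
  st$ptr <- ptr
  st$params <- params
  st$seed <- as.integer(seed)
  st
}

#' @export
print.sim_state <- function(x, ...) {
  cts <- .engine_counts(x$ptr)
  cat(sprintf("<sim_state> clock %.1f s | free %d engaged %d degraded %d | %d events handled\n",
              cts[["clock"]], cts[["free_pool"]], cts[["engaged"]],
              cts[["degraded"]], as.integer(cts[["n_events"]])))
  invisible(x)
}

#' Inspect a simulation state
#'
#' Materialises the current state as plain tibbles: engaged polymerases with
#' their positions and statuses, the lesion list, pool counters, cumulative
#' per-gene mRNA counts and event counters.
#'
#' @param state A `sim_state`.
#' @return A list with elements `time`, `polymerases` (tibble), `lesions`
#'   (tibble), `free_pool`, `degraded`, `engaged`, `mrna` (tibble) and
#'   `counters` (named numeric).
#' @export
state_snapshot <- function(state) {
  s <- .engine_snapshot(state$ptr)
  genes <- state$params$genes$gene_id
  pol <- tibble(
    pol_id = as.integer(s$pol_id),
    gene_id = genes[s$pol_gene],
    position = as.numeric(s$pol_position),
    status = unname(.status_labels[as.character(s$pol_status)])
  )
  les <- tibble(
    gene_id = genes[s$lesion_gene],
    position = as.numeric(s$lesion_position),
    repair_time = as.numeric(s$lesion_repair_time),
    active = as.logical(s$lesion_active)
  )
  list(
    time = s$clock,
    polymerases = pol,
    lesions = les,
    free_pool = as.integer(s$free_pool),
    degraded = as.integer(s$degraded),
    engaged = nrow(pol),
    mrna = tibble(gene_id = genes, count = as.numeric(s$mrna)),
    damaged = isTRUE(s$damaged),
    damage_time = s$damage_time,
    counters = .engine_counts(state$ptr)
  )
}

#' Advance polymerase positions between events
#'
#' Moves the clock forward by `dt` seconds; every moving polymerase advances by
#' `elongation_speed * dt`, stalled and paused polymerases stay put. `dt` must
#' not carry the state past the next pending event (that would skip a scheduled
#' stall, repair or completion), in which case an error is raised.
#'
#' @param state A `sim_state` (modified in place).
#' @param dt Time increment in seconds (>= 0).
#' @return The state, invisibly.
#' @export
advance_positions <- function(state, dt) {
  .engine_advance(state$ptr, dt)
  invisible(state)
}

#' Peek at the next pending event
#'
#' @param state A `sim_state`.
#' @return A one-row tibble with `time` and `kind` (`"repair"`, `"stall"`,
#'   `"completion"`, `"pause"`, `"removal"`, `"initiation"`, or `"none"` when
#'   nothing is pending).
#' @export
peek_next_event <- function(state) {
  p <- .engine_peek(state$ptr)
  kind <- switch(as.character(p$type),
    "0" = "none", "1" = "repair",
    "2" = unname(.stop_labels[as.character(p$b)]),
    "3" = "removal", "4" = "initiation")
  tibble(time = as.numeric(p$time), kind = kind)
}

#' Handle the earliest pending event
#'
#' Advances the clock to the earliest pending event, applies it (initiation,
#' stall, pause, repair, removal, completion), and reschedules whatever the
#' event invalidated: queued followers are re-targeted when their blocker
#' resumes or is removed, moving polymerases re-aim when a lesion appears or
#' disappears ahead of them, and removal clocks are redrawn on every status
#' change.
#'
#' @param state A `sim_state` (modified in place).
#' @return A one-row tibble describing the handled event (`time`, `kind`,
#'   `pol_id`, `gene_id`); `kind = "none"` if no event was pending.
#' @export
step_simulation <- function(state) {
  r <- .engine_step(state$ptr)
  genes <- state$params$genes$gene_id
  tibble(
    time = as.numeric(r$time),
    kind = unname(.event_labels[as.character(r$kind)]),
    pol_id = if (is.na(r$pol)) NA_integer_ else as.integer(r$pol),
    gene_id = if (is.na(r$gene)) NA_character_ else genes[r$gene]
  )
}

#' Next stop of a moving polymerase
#'
#' Computes, without modifying the state, the earliest of: reaching the nearest
#' unrepaired lesion downstream, reaching a stalled (or paused) downstream
#' neighbour minus the exclusion footprint, the promoter-proximal pause site,
#' or the gene end (a completion). The event time is distance over speed.
#'
#' @param state A `sim_state`.
#' @param pol_id Integer id of a *moving* polymerase.
#' @return A one-row tibble with `time`, `position` and `kind` (`"stall"`,
#'   `"pause"` or `"completion"`).
#' @export
next_stop_event <- function(state, pol_id) {
  r <- .engine_next_stop(state$ptr, as.integer(pol_id))
  tibble(time = as.numeric(r$time), position = as.numeric(r$position),
         kind = unname(.stop_labels[as.character(r$kind)]))
}

#' Retrieve the event log
#'
#' Available when the state was created with `log_events = TRUE`.
#'
#' @param state A `sim_state`.
#' @return A tibble with `time`, `kind`, `fate` (for removals: `"recycled"` or
#'   `"degraded"`), `pol_id`, `gene_id`, `position`.
#' @export
event_log <- function(state) {
  lg <- .engine_get_log(state$ptr)
  genes <- state$params$genes$gene_id
  tibble(
    time = lg$time,
    kind = unname(.event_labels[as.character(lg$kind)]),
    fate = dplyr::case_when(lg$kind == 9 ~ "recycled",
                            lg$kind == 10 ~ "degraded",
                            TRUE ~ NA_character_),
    pol_id = lg$pol_id,
    gene_id = ifelse(is.na(lg$gene), NA_character_, genes[lg$gene]),
    position = lg$position
  )
}

#' Run a state forward to an absolute time
#'
#' Handles every pending event up to `time`, then advances the clock exactly
#' to `time` (a zero-duration snapshot point).
#'
#' @param state A `sim_state` (modified in place).
#' @param time Absolute time, seconds.
#' @return The state, invisibly.
#' @export
run_until <- function(state, time) {
  .engine_run_until(state$ptr, time)
  invisible(state)
}

#' Pre-damage burn-in to steady state
#'
#' Runs the undamaged system for the configured burn-in time, then keeps
#' extending the run, one transit time of the longest gene at a time, until
#' the initiation flux and the departure flux (completions plus removals) over
#' the last window agree within `tol`. Fails if balance is not reached within
#' `hard_cap` (default 20 longest-gene transit times).
#'
#' @param state A `sim_state` (modified in place), with no lesions yet.
#' @param tol Relative flux-balance tolerance (default 0.05).
#' @param hard_cap Maximum total burn-in, seconds; default
#'   `20 * transit_time`. Exceeding it is an error, not a warning.
#' @param steady_check If `FALSE`, skip the flux-balance check and return right
#'   after the fixed burn-in time (used when mirroring a fixed-horizon
#'   reference simulation).
#' @return The state, invisibly, at the pre-damage steady state.
#' @export
burn_in <- function(state, tol = 0.05, hard_cap = NULL, steady_check = TRUE) {
  snap <- state_snapshot(state)
  if (nrow(snap$lesions) > 0) abort("burn_in: lesions already present.")
  params <- state$params
  bt <- burn_in_duration(params)
  window <- transit_time(params)
  if (is.null(hard_cap)) hard_cap <- 20 * window
  run_until(state, bt)
  if (!steady_check) return(invisible(state))
  repeat {
    c0 <- .engine_counts(state$ptr)
    if (c0[["clock"]] > max(bt, hard_cap) + 1e-9) {
      abort(sprintf(
        "burn_in: initiation/completion flux did not balance within %.0f s.", hard_cap))
    }
    run_until(state, c0[["clock"]] + window)
    c1 <- .engine_counts(state$ptr)
    placed <- c1[["placed"]] - c0[["placed"]]
    departed <- (c1[["completions"]] + c1[["removals"]]) -
      (c0[["completions"]] + c0[["removals"]])
    # relative tolerance, floored by counting noise so small systems can balance
    slack <- max(tol * max(placed, departed, 1), 2 * sqrt(max(placed, departed, 1)))
    if (abs(placed - departed) <= slack) break
  }
  invisible(state)
}

#' Introduce UV damage
#'
#' For each gene, draws a Poisson number of lesions with mean
#' `length * lesion_density`, places them uniformly along the gene body
#' (strictly inside it; the TSS itself is never lesioned), assigns each an
#' exponential repair time with mean `lesion_halflife / ln 2`, and reschedules
#' the stall targets of every moving polymerase. May be called once per run;
#' its time defines the zero point of the snapshot clock.
#'
#' @param state A `sim_state` (modified in place).
#' @return The state, invisibly.
#' @export
apply_damage <- function(state) {
  .engine_apply_damage(state$ptr)
  invisible(state)
}

#' Place a single lesion deterministically
#'
#' Adds one transcription-blocking lesion at a chosen position with a fixed
#' repair time — the deterministic counterpart of [apply_damage()] for bespoke
#' damage layouts and unit-level reasoning about stalling and queueing.
#'
#' @param state A `sim_state` (modified in place).
#' @param gene_id Gene identifier.
#' @param position Position in nt, strictly inside the gene body.
#' @param repair_time Absolute repair time in seconds (default: never within
#'   any realistic run).
#' @return The state, invisibly.
#' @export
add_lesion <- function(state, gene_id, position, repair_time = Inf) {
  g <- match(gene_id, state$params$genes$gene_id)
  if (is.na(g)) abort(sprintf("unknown gene_id \"%s\".", gene_id))
  if (!is.finite(repair_time)) repair_time <- 1e18
  .engine_add_lesion(state$ptr, g, position, repair_time)
  invisible(state)
}

#' Check the structural invariants of a state
#'
#' Verifies conservation (`free + engaged + degraded == pool_size`), the
#' footprint exclusion along every gene, position bounds, and that no moving
#' polymerase targets a position beyond an unrepaired lesion ahead of it.
#' Errors on the first violation.
#'
#' @param state A `sim_state`.
#' @return `TRUE`, invisibly.
#' @export
check_state_invariants <- function(state) {
  invisible(.engine_validate(state$ptr))
}

# scalar + occupancy record at the current clock, relative to a time origin
.take_snapshot <- function(state, origin) {
  s <- state_snapshot(state)
  time_rel <- s$time - origin
  list(
    occupancy = dplyr::mutate(s$polymerases, time = time_rel, .before = 1),
    lesions = dplyr::mutate(s$lesions, time = time_rel, .before = 1),
    scalars = tibble(time = time_rel, free_pool = s$free_pool,
                     degraded = s$degraded, engaged = s$engaged),
    mrna = dplyr::mutate(s$mrna, time = time_rel, .before = 1)
  )
}

#' Run a full simulation
#'
#' The complete protocol: initialise, burn in to the pre-damage steady state,
#' introduce lesions, then run through the requested snapshot times (seconds
#' after damage onset), recording the full occupancy at each snapshot and, at
#' `series_times`, the scalar pool counters only. A snapshot at damage onset
#' (relative time 0) is always recorded. Fully reproducible from
#' `(params, seed)`.
#'
#' @param params A validated [sim_params()] object.
#' @param seed Integer seed; defaults to `params$seed`.
#' @param series_times Optional extra times (s post-damage) at which only the
#'   scalar series (free pool, degraded count, engaged count, mRNA counts) is
#'   recorded.
#' @param steady_check Passed to [burn_in()].
#' @return A `pol_trajectory` object: a list with `snapshots` (tibble: `time`,
#'   `pol_id`, `gene_id`, `position`, `status`), `lesions`, `series`, `mrna`
#'   (all tibbles keyed by time post-damage), `damage_time` (absolute), the
#'   parameters and the seed.
#' @examples
#' p <- sim_params(preset_ensemble("single_100kb"), pool_size = 50,
#'                 snapshot_times = c(600, 1200))
#' tr <- simulate_transcription(p, seed = 7)
#' head(tr$snapshots)
#' @export
simulate_transcription <- function(params, seed = params$seed, series_times = NULL,
                                   steady_check = TRUE) {
  params <- validate_sim_params(params)
  st <- sim_state(params, seed = seed)
  burn_in(st, steady_check = steady_check)
  apply_damage(st)
  origin <- state_snapshot(st)$time

  record_times <- sort(unique(c(0, params$snapshot_times)))
  series_only <- setdiff(sort(unique(series_times)), record_times)
  timeline <- sort(unique(c(record_times, series_only)))

  snaps <- list(); les <- list(); scal <- list(); mr <- list()
  for (tt in timeline) {
    run_until(st, origin + tt)
    rec <- .take_snapshot(st, origin)
    scal[[length(scal) + 1L]] <- rec$scalars
    mr[[length(mr) + 1L]] <- rec$mrna
    if (tt %in% record_times) {
      snaps[[length(snaps) + 1L]] <- rec$occupancy
      les[[length(les) + 1L]] <- rec$lesions
    }
  }
  structure(list(
    snapshots = dplyr::bind_rows(snaps),
    lesions = dplyr::bind_rows(les),
    series = dplyr::bind_rows(scal),
    mrna = dplyr::bind_rows(mr),
    damage_time = origin,
    counters = .engine_counts(st$ptr),
    params = params,
    seed = as.integer(seed)
  ), class = "pol_trajectory")
}

#' @export
print.pol_trajectory <- function(x, ...) {
  cat(sprintf("<pol_trajectory> %d gene(s), pool %d, seed %d\n",
              nrow(x$params$genes), x$params$pool_size, x$seed))
  cat(sprintf("  damage at %.1f s (absolute); snapshots at %s s post-damage\n",
              x$damage_time, paste(unique(x$snapshots$time), collapse = ", ")))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.pol_trajectory <- function(x, ...) x$snapshots

#' @rdname tidiers
#' @export
glance.pol_trajectory <- function(x, ...) {
  tibble(
    n_genes = nrow(x$params$genes),
    pool_size = x$params$pool_size,
    damage_time = x$damage_time,
    final_degraded = utils::tail(x$series$degraded, 1),
    total_mrna = sum(dplyr::filter(x$mrna, .data$time == max(.data$time))$count),
    n_events = unname(x$counters[["n_events"]]),
    seed = x$seed
  )
}
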