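test_that("a fresh state holds the whole pool free and is reproducible", {
  p <- clean_params(pool = 500)
  st <- sim_state(p, seed = 1)
  s <- state_snapshot(st)
  expect_equal(s$free_pool, 500)
  expect_equal(s$engaged, 0)
  expect_equal(s$degraded, 0)
  expect_equal(nrow(s$lesions), 0)
  expect_equal(peek_next_event(st)$kind, "initiation")

  a <- sim_state(p, seed = 9); run_until(a, 50)
  b <- sim_state(p, seed = 9); run_until(b, 50)
  expect_identical(state_snapshot(a)$polymerases, state_snapshot(b)$polymerases)
  expect_identical(state_snapshot(a)$counters, state_snapshot(b)$counters)
})

test_that("an empty pool never schedules initiation", {
  st <- sim_state(clean_params(pool = 0), seed = 1)
  expect_equal(peek_next_event(st)$kind, "none")
  run_until(st, 1000)
  expect_equal(state_snapshot(st)$engaged, 0)
})

test_that("positions advance as speed times dt, stalled polymerases stay put", {
  p <- clean_params(length = 1e5, pool = 1, rate = 10, speed = 20)
  st <- sim_state(p, seed = 2)
  place_pols(st, 1)
  x0 <- state_snapshot(st)$polymerases$position
  advance_positions(st, 10)
  expect_equal(state_snapshot(st)$polymerases$position, x0 + 20 * 10)
  advance_positions(st, 0)
  expect_equal(state_snapshot(st)$polymerases$position, x0 + 200)
  expect_error(advance_positions(st, 1e9), "past the next pending event")
  expect_error(advance_positions(st, -1), "non-negative")

  # stalled polymerase: park it at a lesion, advance, position unchanged
  pid <- state_snapshot(st)$polymerases$pol_id
  xs <- state_snapshot(st)$polymerases$position
  add_lesion(st, "g1", xs + 100)
  run_until(st, state_snapshot(st)$time + 100 / 20 + 1)
  s <- state_snapshot(st)
  expect_equal(s$polymerases$status, "stalled_lesion")
  expect_equal(s$polymerases$position, xs + 100)
  advance_positions(st, min(5, peek_next_event(st)$time - s$time))
  expect_equal(state_snapshot(st)$polymerases$position, xs + 100)
})

test_that("the next stop is the nearest of lesion, stalled neighbour - footprint, gene end", {
  p <- sim_params(genes = gene_ensemble(1e5, 1, "g1"), pool_size = 1,
                  initiation_rate = 5, elongation_speed = 33.33, footprint = 40,
                  lesion_density = 0, moving_removal_hazard = 0,
                  stalled_removal_hazard = 0, burn_in_time = 0,
                  snapshot_times = 10)
  st <- sim_state(p, seed = 4)
  place_pols(st, 1)
  pid1 <- state_snapshot(st)$polymerases$pol_id[1]
  # no lesion, no neighbour: completion at the gene end, time = distance / speed
  ns <- next_stop_event(st, pid1)
  x <- state_snapshot(st)$polymerases$position[1]
  expect_equal(ns$kind, "completion")
  expect_equal(ns$position, 1e5)
  expect_equal(ns$time - state_snapshot(st)$time, (1e5 - x) / 33.33, tolerance = 1e-9)

  # lesion 1 kb ahead of a polymerase at ~10 kb: stall in 1000/33.33 s
  run_until(st, 10000 / 33.33 + 0.2)
  x <- state_snapshot(st)$polymerases$position[1]
  add_lesion(st, "g1", x + 1000)
  ns <- next_stop_event(st, pid1)
  expect_equal(ns$kind, "stall")
  expect_equal(ns$position, x + 1000)
  expect_equal(ns$time - state_snapshot(st)$time, 1000 / 33.33, tolerance = 1e-6)

  # stalled neighbour wins over a farther lesion: target = neighbour - footprint
  p2 <- sim_params(genes = gene_ensemble(1e5, 1, "g1"), pool_size = 2,
                   initiation_rate = 0.02, elongation_speed = 33.33, footprint = 40,
                   lesion_density = 0, moving_removal_hazard = 0,
                   stalled_removal_hazard = 0, burn_in_time = 0,
                   snapshot_times = 10)
  st2 <- sim_state(p2, seed = 21)
  add_lesion(st2, "g1", 20000)
  add_lesion(st2, "g1", 29000)
  run_until(st2, 620) # leader (placed 14.3 s) stalled at 614.5 s; follower still moving
  s <- state_snapshot(st2)
  expect_equal(nrow(s$polymerases), 2)
  lead <- s$polymerases[which.max(s$polymerases$position), ]
  trail <- s$polymerases[which.min(s$polymerases$position), ]
  expect_equal(lead$status, "stalled_lesion")
  expect_equal(lead$position, 20000)
  expect_equal(trail$status, "moving")
  ns2 <- next_stop_event(st2, trail$pol_id)
  expect_equal(ns2$kind, "stall")
  expect_equal(ns2$position, 20000 - 40)
})

test_that("stall, queueing, repair and release follow the event rules", {
  p <- sim_params(genes = gene_ensemble(2e4, 1, "g1"), pool_size = 3,
                  initiation_rate = 50, elongation_speed = 100, footprint = 40,
                  lesion_density = 0, moving_removal_hazard = 0,
                  stalled_removal_hazard = 0, burn_in_time = 0,
                  snapshot_times = 10)
  st <- sim_state(p, seed = 8)
  add_lesion(st, "g1", 5000, repair_time = 120)
  run_until(st, 110)
  s <- state_snapshot(st)
  expect_equal(nrow(s$polymerases), 3)
  expect_equal(sort(s$polymerases$status),
               sort(c("stalled_lesion", "stalled_queue", "stalled_queue")))
  expect_equal(sort(s$polymerases$position, decreasing = TRUE),
               c(5000, 4960, 4920))
  q <- queue_statistics(list(snapshots = dplyr::mutate(s$polymerases, time = 0),
                             lesions = dplyr::mutate(s$lesions, time = 0)),
                        footprint = 40)
  expect_equal(q$queue_length, 3L)
  # repair at t = 120 releases the stalled polymerase and, implicitly, the queue
  run_until(st, 130)
  s2 <- state_snapshot(st)
  expect_false(any(s2$lesions$active))
  expect_true(all(s2$polymerases$status == "moving"))
  expect_true(all(diff(sort(s2$polymerases$position, decreasing = TRUE)) <= -40 + 1e-9))
  # the released trio completes before any newly initiated polymerase can
  run_until(st, 330)
  expect_equal(sum(state_snapshot(st)$mrna$count), 3)
  check_state_invariants(st)
})

test_that("conservation and exclusion hold after every event in a damaged run", {
  p <- sim_params(genes = gene_ensemble(2e4, 1, "g1"), pool_size = 30,
                  initiation_rate = 0.02, elongation_speed = 50, footprint = 40,
                  lesion_density = 1 / 4000, lesion_halflife = 300,
                  moving_removal_hazard = 1e-3, stalled_removal_hazard = 5e-3,
                  removal_recycle_prob = 0.5, burn_in_time = 200,
                  snapshot_times = 400)
  st <- sim_state(p, seed = 10)
  run_until(st, 200)
  apply_damage(st)
  for (k in 1:3000) {
    info <- step_simulation(st)
    if (info$kind == "none") break
    check_state_invariants(st)
    if (state_snapshot(st)$time > 800) break
  }
  expect_gt(k, 100)
})

test_that("apply_damage draws Poisson lesion counts and exponential repair times", {
  p <- sim_params(genes = gene_ensemble(1e5, 1, "g1"), pool_size = 1,
                  initiation_rate = 0, lesion_density = 1 / 25000,
                  lesion_halflife = 3600, burn_in_time = 0, snapshot_times = 10)
  counts <- numeric(400)
  reps <- c()
  set.seed(99)
  seeds <- sample.int(1e6, 400)
  for (i in seq_along(seeds)) {
    st <- sim_state(p, seed = seeds[i])
    apply_damage(st)
    les <- state_snapshot(st)$lesions
    counts[i] <- nrow(les)
    reps <- c(reps, les$repair_time)
    if (i == 1) expect_error(apply_damage(st), "already")
  }
  expect_lt(abs(mean(counts) - 4), 3 * sqrt(4 / 400))       # Poisson mean L * density
  expect_true(all(reps >= 0))
  n <- length(reps)
  med_se <- 1.2533 * (3600 / log(2)) / sqrt(n)              # asymptotic SE of the median
  expect_lt(abs(median(reps) - 3600), 3 * med_se)           # median = half-life
  # zero density leaves the state lesion-free
  p0 <- sim_params(genes = gene_ensemble(1e5, 1, "g1"), lesion_density = 0,
                   burn_in_time = 0, snapshot_times = 10, pool_size = 1,
                   initiation_rate = 0)
  st0 <- sim_state(p0, seed = 1)
  apply_damage(st0)
  expect_equal(nrow(state_snapshot(st0)$lesions), 0)
})

test_that("removal clocks are exponential with the status-specific hazard", {
  # moving polymerases, hazard 1/50 per s, everything recycles
  p <- sim_params(genes = gene_ensemble(1e6, 1, "g1"), pool_size = 60,
                  initiation_rate = 1, elongation_speed = 100, footprint = 40,
                  lesion_density = 0, moving_removal_hazard = 1 / 50,
                  stalled_removal_hazard = 0, removal_recycle_prob = 1,
                  burn_in_time = 0, snapshot_times = 10)
  st <- sim_state(p, seed = 31, log_events = TRUE)
  run_until(st, 12000)
  lg <- event_log(st)
  waits <- lg |>
    dplyr::filter(.data$kind %in% c("initiation", "removal"), !is.na(.data$pol_id)) |>
    dplyr::arrange(.data$pol_id, .data$time) |>
    dplyr::group_by(.data$pol_id) |>
    dplyr::mutate(prev_kind = dplyr::lag(kind), wait = time - dplyr::lag(time)) |>
    dplyr::ungroup() |>
    dplyr::filter(kind == "removal", prev_kind == "initiation")
  expect_gt(nrow(waits), 2000)
  expect_lt(abs(mean(waits$wait) - 50), 3 * 50 / sqrt(nrow(waits)))
  # hazard 0 never removes
  expect_equal(sum(event_log(st)$kind == "stall"), 0)
})

test_that("stalled polymerases are removed faster when their hazard is higher", {
  p <- sim_params(genes = gene_ensemble(5e4, 1, "g1"), pool_size = 40,
                  initiation_rate = 0.5, elongation_speed = 100, footprint = 40,
                  lesion_density = 0, moving_removal_hazard = 1 / 400,
                  stalled_removal_hazard = 1 / 40, removal_recycle_prob = 1,
                  burn_in_time = 0, snapshot_times = 10)
  st <- sim_state(p, seed = 77, log_events = TRUE)
  add_lesion(st, "g1", 2e4)
  run_until(st, 20000)
  lg <- event_log(st)
  ev <- lg |>
    dplyr::filter(kind %in% c("initiation", "stall", "release", "removal"),
                  !is.na(pol_id)) |>
    dplyr::arrange(pol_id, time) |>
    dplyr::group_by(pol_id) |>
    dplyr::mutate(prev_kind = dplyr::lag(kind), wait = time - dplyr::lag(time)) |>
    dplyr::ungroup() |>
    dplyr::filter(kind == "removal", prev_kind %in% c("initiation", "stall", "release"))
  stalled_w <- ev$wait[ev$prev_kind == "stall"]
  moving_w <- ev$wait[ev$prev_kind != "stall"]
  expect_gt(length(stalled_w), 100)
  expect_gt(length(moving_w), 30)
  expect_lt(stats::wilcox.test(stalled_w, moving_w, alternative = "less")$p.value, 1e-4)
})

test_that("removal fates are Bernoulli with the recycle probability", {
  run_fates <- function(p_rec, seed) {
    p <- sim_params(genes = gene_ensemble(1e6, 1, "g1"), pool_size = 50,
                    initiation_rate = 1, elongation_speed = 100,
                    lesion_density = 0, moving_removal_hazard = 1 / 30,
                    stalled_removal_hazard = 0, removal_recycle_prob = p_rec,
                    completion_recycle_prob = 1, burn_in_time = 0,
                    snapshot_times = 10)
    st <- sim_state(p, seed = seed)
    run_until(st, 4000)
    cts <- state_snapshot(st)$counters
    c(removals = unname(cts["removals"]), recycled = unname(cts["removals_recycled"]),
      degraded = unname(cts["degraded"]))
  }
  f1 <- run_fates(1, 5)
  expect_equal(unname(f1["degraded"]), 0)
  expect_equal(unname(f1["recycled"]), unname(f1["removals"]))
  f0 <- run_fates(0, 6)
  expect_equal(unname(f0["recycled"]), 0)
  f5 <- run_fates(0.5, 7)
  n <- f5[["removals"]]
  expect_gt(n, 50) # with half the removals degrading, ~2x pool_size removals occur

  expect_lt(abs(f5[["recycled"]] / n - 0.5), 3 * sqrt(0.25 / n))
})

test_that("burn-in reaches flux balance and a flat gene-body profile", {
  # zero initiation converges immediately with nothing engaged
  p0 <- clean_params(rate = 0)
  st0 <- sim_state(p0, seed = 1)
  burn_in(st0)
  expect_equal(state_snapshot(st0)$engaged, 0)

  # flux balance: steady-state occupancy per bin is flat at initiation flux / speed
  p <- sim_params(genes = gene_ensemble(5e4, 1, "g1"), pool_size = 400,
                  initiation_rate = 5e-4, elongation_speed = 50, footprint = 40,
                  lesion_density = 0, moving_removal_hazard = 0,
                  stalled_removal_hazard = 0, burn_in_time = NULL,
                  snapshot_times = 10, bin_size = 1000)
  bins <- purrr::map_dfr(1:40, function(i) {
    st <- sim_state(p, seed = 1000 + i)
    burn_in(st)
    s <- state_snapshot(st)
    cts <- s$counters
    expect_equal(s$free_pool + s$engaged + s$degraded, 400)
    density_profile(dplyr::mutate(s$polymerases, time = 0),
                    genes = p$genes, bin_size = 1000)
  })
  prof <- bins |>
    dplyr::group_by(bin) |>
    dplyr::summarise(m = mean(count), .groups = "drop") |>
    dplyr::filter(bin > 0, bin < 49) # away from TSS and TTS edges
  expect_lt(sd(prof$m) / mean(prof$m), 0.15)
})

test_that("a full run is reproducible and snapshots the damage-onset state", {
  p <- tiny_damage_params()
  a <- simulate_transcription(p, seed = 3)
  b <- simulate_transcription(p, seed = 3)
  expect_identical(a$snapshots, b$snapshots)
  expect_identical(a$series, b$series)
  expect_identical(a$mrna, b$mrna)
  expect_true(0 %in% a$series$time)
  expect_setequal(unique(a$series$time), c(0, 120))
  # damage onset snapshot: same occupancy as the pre-damage state, plus lesions
  st <- sim_state(p, seed = 3)
  burn_in(st)
  pre <- state_snapshot(st)$polymerases
  apply_damage(st)
  post <- state_snapshot(st)$polymerases
  expect_identical(pre, post)
})

test_that("with no damage and no removal, completions balance initiations", {
  p <- sim_params(genes = gene_ensemble(2e4, 1, "g1"), pool_size = 100,
                  initiation_rate = 2e-3, elongation_speed = 50,
                  lesion_density = 0, moving_removal_hazard = 0,
                  stalled_removal_hazard = 0, completion_recycle_prob = 1,
                  burn_in_time = 2000, snapshot_times = 10)
  st <- sim_state(p, seed = 12)
  burn_in(st)
  c0 <- state_snapshot(st)$counters
  window <- 10 * 2e4 / 50 # ten transit times
  run_until(st, c0[["clock"]] + window)
  c1 <- state_snapshot(st)$counters
  placed <- c1[["placed"]] - c0[["placed"]]
  completed <- c1[["completions"]] - c0[["completions"]]
  expect_equal(c1[["degraded"]], 0)
  expect_lt(abs(placed - completed) / max(placed, completed), 0.05)
})
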