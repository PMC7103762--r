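test_that("scenario presets resolve and unknown names fail", {
  sc <- preset_scenario("three_gene_no_degradation")
  expect_equal(sc$regime, "no_degradation")
  expect_equal(sc$n_replicates, 100L)
  expect_equal(sc$params$removal_recycle_prob, 1)
  expect_error(preset_scenario("three_gene_super"), "unknown scenario")
  und <- preset_scenario("single_100kb_undamaged")
  expect_equal(und$params$lesion_density, 0)
  nod <- preset_scenario("single_100kb_no_dissociation")
  expect_equal(nod$params$stalled_removal_hazard, 0)
})

test_that("replicate ensembles are deterministic and average single runs", {
  p <- sim_params(genes = gene_ensemble(5e3, 1, "g1"), pool_size = 15,
                  initiation_rate = 5e-3, elongation_speed = 50,
                  lesion_density = 1 / 2500, lesion_halflife = 600,
                  stalled_removal_hazard = 1 / 100, removal_recycle_prob = 1,
                  degradation_enabled = FALSE, burn_in_time = 200,
                  snapshot_times = c(60, 300), bin_size = 500)
  sc1 <- scenario(p, "no_degradation", n_replicates = 1)
  ens1 <- run_replicates(sc1, seed = 40)
  single <- simulate_transcription(sc1$params, seed = 41)
  dp <- density_profile(single, bin_size = 500)
  expect_equal(ens1$density$density, as.numeric(dp$count))

  sc <- scenario(p, "no_degradation", n_replicates = 8)
  a <- run_replicates(sc, seed = 40)
  b <- run_replicates(sc, seed = 40)
  expect_identical(a$density, b$density)
  expect_identical(a$series, b$series)
  expect_equal(dplyr::n_distinct(a$series$replicate), 8)
  # the map conserves mean engaged counts
  tot <- a$density |>
    dplyr::group_by(time) |>
    dplyr::summarise(total = sum(density), .groups = "drop")
  eng <- a$series |>
    dplyr::group_by(time) |>
    dplyr::summarise(engaged = mean(engaged), .groups = "drop")
  expect_equal(tot$total, eng$engaged[match(tot$time, eng$time)])
})

test_that("doubling replicates moves per-bin means by less than twice their SE", {
  p <- sim_params(genes = gene_ensemble(5e3, 1, "g1"), pool_size = 15,
                  initiation_rate = 5e-3, elongation_speed = 50,
                  lesion_density = 1 / 2500, lesion_halflife = 600,
                  stalled_removal_hazard = 1 / 100, removal_recycle_prob = 1,
                  degradation_enabled = FALSE, burn_in_time = 200,
                  snapshot_times = 300, bin_size = 500)
  reps <- purrr::map_dfr(1:50, function(i) {
    tr <- simulate_transcription(p, seed = 500 + i)
    dplyr::mutate(density_profile(tr, bin_size = 500), replicate = i)
  }) |> dplyr::filter(time == 300)
  halfm <- reps |> dplyr::filter(replicate <= 25) |>
    dplyr::group_by(bin) |> dplyr::summarise(m = mean(count), .groups = "drop")
  fullm <- reps |>
    dplyr::group_by(bin) |>
    dplyr::summarise(m = mean(count), se = sd(count) / sqrt(dplyr::n()),
                     .groups = "drop")
  dev <- abs(fullm$m - halfm$m)
  expect_true(mean(dev <= 2 * pmax(fullm$se, 0.05)) > 0.9)
})

test_that("mRNA production over a zero horizon is zero", {
  p <- sim_params(genes = gene_ensemble(5e3, 1, "g1"), pool_size = 10,
                  initiation_rate = 5e-3, elongation_speed = 50,
                  burn_in_time = 150, snapshot_times = 60)
  sc <- scenario(p, "undamaged", n_replicates = 3)
  out <- predicted_mrna_counts(sc, horizon = 0, seed = 2)
  expect_equal(out$mean_count, 0)
  expect_equal(out$n_replicates, 3L)
})

test_that("calibration rejects regimes in which nothing can degrade", {
  sck <- preset_scenario("single_100kb_no_degradation")
  expect_error(calibrate_degradation(sck, 5400), "degradation enabled")
  scw <- preset_scenario("single_100kb_wt")
  expect_error(calibrate_degradation(scw, -1), "positive")
  expect_error(calibrate_degradation(scw, 5400, tol = 0), "positive")
})

test_that("an unreachable calibration target reports the bracket", {
  # a 1-s target half-life is far below what even instant removal can produce
  sc <- preset_scenario("single_100kb_wt", pool_size = 40, n_replicates = 100)
  sc$n_replicates <- 5L
  expect_error(
    calibrate_degradation(sc, target_halflife = 1, tol = 0.1,
                          bracket = c(1e-4, 1e-3), n_cal = 3, n_final = 3,
                          window = 3600, sample_every = 900),
    "bracket")
})
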