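# Small parameter sets used across tests. Kept fast: short genes, small pools.

tiny_gene <- function(length = 10000, id = "g1") {
  gene_ensemble(length, 1, gene_ids = id)
}

# a clean transport-only system: no lesions, no removal, everything recycles
clean_params <- function(length = 10000, pool = 20, rate = 0.05, speed = 100, ...) {
  sim_params(
    genes = tiny_gene(length),
    pool_size = pool,
    initiation_rate = rate,
    elongation_speed = speed,
    lesion_density = 0,
    moving_removal_hazard = 0,
    stalled_removal_hazard = 0,
    burn_in_time = 0,
    snapshot_times = c(10, 20),
    n_replicates = 2,
    ...
  )
}

# the tiny damaged instance used for oracle comparison:
# one 2-kb gene, 5 polymerases, about one lesion
tiny_damage_params <- function(...) {
  sim_params(
    genes = gene_ensemble(2000, 1, "tiny"),
    pool_size = 5,
    initiation_rate = 0.02,
    elongation_speed = 40,
    footprint = 40,
    lesion_density = 1 / 2000,
    lesion_halflife = 60,
    moving_removal_hazard = 0.002,
    stalled_removal_hazard = 0.01,
    removal_recycle_prob = 0.5,
    completion_recycle_prob = 1,
    burn_in_time = 150,
    snapshot_times = 120,
    n_replicates = 1,
    bin_size = 100,
    ...
  )
}

# step a state until n polymerases have been placed (returns the state)
place_pols <- function(state, n = 1, max_steps = 10000) {
  for (k in seq_len(max_steps)) {
    info <- step_simulation(state)
    if (state_snapshot(state)$engaged >= n) return(invisible(state))
    if (info$kind == "none") break
  }
  stop("failed to place polymerases")
}
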