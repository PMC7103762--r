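# Independent fixed-step reference simulator.
#
# Re-implements the model with none of the event machinery: time advances in
# small steps dt, hazards act as per-step probabilities 1 - exp(-lambda dt),
# movement is capped by the nearest active lesion / stalled neighbour minus
# footprint / gene end, repair fires when the clock passes each lesion's
# drawn repair time. Single gene only; used for distribution-level comparison
# with the event-driven kernel on a tiny instance.

oracle_simulate <- function(params, seed, dt = 0.01) {
  stopifnot(nrow(params$genes) == 1)
  set.seed(as.integer(seed))
  L <- params$genes$length
  v <- params$elongation_speed
  fp <- params$footprint
  r <- params$initiation_rate
  p_rec_rem <- params$removal_recycle_prob
  p_rec_com <- params$completion_recycle_prob
  hz_m <- params$moving_removal_hazard
  hz_s <- params$stalled_removal_hazard
  burn <- params$burn_in_time
  horizon <- max(params$snapshot_times)
  t_end <- burn + horizon

  pos <- numeric(0)       # engaged, descending order (downstream first)
  stalled <- logical(0)
  free <- params$pool_size
  degraded <- 0L
  mrna <- 0
  lesion_pos <- numeric(0)
  lesion_rep <- numeric(0)
  damaged <- FALSE

  p_rem_m <- 1 - exp(-hz_m * dt)
  p_rem_s <- 1 - exp(-hz_s * dt)

  t <- 0
  nstep <- round(t_end / dt)
  for (k in seq_len(nstep)) {
    t <- k * dt
    if (!damaged && t >= burn) {
      n_les <- rpois(1, L * params$lesion_density)
      lesion_pos <- runif(n_les, 0, L)
      lesion_rep <- t + stats::rexp(n_les, rate = log(2) / params$lesion_halflife)
      damaged <- TRUE
    }
    # repair
    if (length(lesion_pos)) {
      done <- lesion_rep <= t
      if (any(done)) {
        lesion_pos <- lesion_pos[!done]
        lesion_rep <- lesion_rep[!done]
      }
    }
    # removal (memoryless; status from the previous step)
    if (length(pos)) {
      p_rem <- ifelse(stalled, p_rem_s, p_rem_m)
      gone <- runif(length(pos)) < p_rem
      if (any(gone)) {
        n_gone <- sum(gone)
        rec <- sum(runif(n_gone) < p_rec_rem)
        free <- free + rec
        degraded <- degraded + (n_gone - rec)
        pos <- pos[!gone]
        stalled <- stalled[!gone]
      }
    }
    # movement, downstream first so a follower sees its leader's updated position
    if (length(pos)) {
      finished <- logical(length(pos))
      for (i in seq_along(pos)) {
        cap <- L
        if (length(lesion_pos)) {
          # a lesion at the current position still blocks (>= with tolerance)
          ahead <- lesion_pos[lesion_pos > pos[i] - 1e-9]
          if (length(ahead)) cap <- min(cap, min(ahead))
        }
        if (i > 1 && !finished[i - 1]) cap <- min(cap, pos[i - 1] - fp)
        newp <- min(pos[i] + v * dt, cap)
        stalled[i] <- (newp < pos[i] + v * dt - 1e-12) && (newp < L - 1e-12)
        pos[i] <- newp
        finished[i] <- newp >= L - 1e-12
      }
      if (any(finished)) {
        n_fin <- sum(finished)
        mrna <- mrna + n_fin
        rec <- sum(runif(n_fin) < p_rec_com)
        free <- free + rec
        degraded <- degraded + (n_fin - rec)
        pos <- pos[!finished]
        stalled <- stalled[!finished]
      }
    }
    # initiation (at most one attempt per step)
    if (free > 0 && r > 0 && runif(1) < 1 - exp(-r * free * dt)) {
      tss_clear <- !length(pos) || min(pos) >= fp
      if (tss_clear) {
        pos <- c(pos, 0)
        stalled <- c(stalled, FALSE)
        free <- free - 1L
      }
    }
  }
  list(positions = pos, free = free, degraded = degraded, mrna = mrna,
       n_lesions = length(lesion_pos))
}
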