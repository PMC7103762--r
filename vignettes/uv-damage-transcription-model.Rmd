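---
title: "Modelling RNAPII transcription under UV damage: the uvpolsim engine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling RNAPII transcription under UV damage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvpolsim)
library(dplyr)
```

## The model

`uvpolsim` simulates RNA polymerase II (RNAPII) transcription on a small
ensemble of model genes that compete for one finite pool of polymerases. The
simulation is continuous in time and position but discrete in events — a
process-oriented, event-driven design. The state is: a free pool of
polymerases; per gene, an ordered list of engaged polymerases (each moving at
the common elongation speed or halted) and a list of unrepaired lesions; a
degraded-polymerase counter; and cumulative completed-transcript counters.

Between events every moving polymerase advances as position plus speed times
elapsed time. Events are:

* **Initiation.** Attempts arrive as a Poisson process with rate
  `initiation_rate * free_pool` (mass action): initiation slows smoothly as
  the pool empties, which is the mechanism by which pool depletion becomes an
  *initiation shutdown*. Each attempt is assigned to a gene multinomially by
  its initiation weight; if the first `footprint` nucleotides of that gene are
  occupied the attempt is dropped, otherwise a free polymerase is placed at
  the TSS.
* **Stalling.** A moving polymerase halts when it reaches the nearest
  unrepaired lesion, or the position of a halted downstream neighbour minus
  the exclusion footprint (head-to-tail queueing), whichever comes first.
* **Repair.** Each lesion carries an exponential repair clock with mean
  `lesion_halflife / ln 2`. On repair, the polymerase stalled at the lesion
  resumes instantly and the contiguous queue behind it is released; any moving
  polymerase that was aiming at the repaired lesion is re-targeted.
* **Removal.** Engaged polymerases carry an exponential removal clock whose
  hazard depends on status — `moving_removal_hazard` while elongating,
  `stalled_removal_hazard` while halted (at a lesion *or* queued behind one;
  we apply the elevated hazard to the whole queue, since a queue is itself a
  damage-induced arrest). Clocks are redrawn on every status change
  (memoryless). A removed polymerase is recycled to the free pool with
  probability `removal_recycle_prob`, otherwise degraded and permanently lost.
* **Completion.** A polymerase reaching the gene end increments that gene's
  mRNA counter; its fate is governed by `completion_recycle_prob`.
* **Damage onset.** After burn-in, each gene receives a Poisson number of
  lesions (mean `length * lesion_density`) at uniform positions strictly
  inside the gene body; this instant defines time zero for all snapshots.

Pending events live in a priority queue with lazy invalidation: every
polymerase carries revision counters for its stop and removal schedules, and
events referencing an outdated revision are discarded when popped. Ties are
broken deterministically (repair before completion before stall before
removal before initiation). All randomness flows through R's RNG, so a run is
fully reproducible from `(params, seed)`; replicate `i` of an ensemble uses
`seed + i`.

### Burn-in and steady state

A run starts with every polymerase free and no lesions, and is burned in for
`burn_in_time` (default: five transit times of the longest gene). The run is
then extended, one transit time at a time, until the initiation flux and the
departure flux (completions plus removals) over the last window agree within
5% — with an absolute floor of twice the counting noise, so that small test
systems can balance. We compare initiation against *departures* rather than
completions alone because with a non-zero moving-removal hazard the true
stationarity condition involves all exits from the template; with the default
(near-zero) moving hazard the two criteria coincide. Failure to balance
within a hard cap (20 transit times) is an error, not a warning.

### Regimes

Two biological toggles connect the model to the experimental genotypes:

| regime | toggles | biology |
|---|---|---|
| `wt` | degradation on, dissociation on | stalled RNAPII is removed and half of removals are degraded; the pool shrinks and initiation shuts down |
| `no_degradation` | every removal recycles | a non-degradable polymerase (RPB1 K1268R-like); dissociation still clears stalls, so profiles stay stationary and short genes keep firing |
| `no_dissociation` | stalled polymerases can never leave | the pile-up thought experiment: polymerases accumulate head-to-tail behind lesions and the free pool drains |
| `undamaged` | lesion density zero | baseline for output ratios |

## Default parameters and why

The supplementary parameter values of the study this model emulates are not
printed in its text, so the defaults here are the package's own choices —
ordinary arguments, all overridable, fixed once on the following reasoning:

* **Elongation speed 33.3 nt/s** (~2 kb/min): a standard mammalian RNAPII
  elongation rate; a 100-kb gene takes ~50 min to traverse, which is what
  makes the 45-min post-damage snapshot informative.
* **Lesion density 1/25,000 nt** ("moderate UV dose equivalent"): the mean
  distance from the TSS to the first blocking lesion is then ~25 kb, which
  reproduces the observed restriction of elongation to the promoter-proximal
  20–30 kb shortly after irradiation.
* **Lesion half-life 24 h**: transcription-blocking cyclobutane pyrimidine
  dimers are removed slowly (bulk half-life on the order of a day, faster on
  transcribed strands). Just as important, the observed *stationarity* of
  damage-restricted profiles between 45 min and 3 h implies that lesion
  persistence over that window is high: the distance to the first active
  lesion is exponential with rate `lesion_density * f(t)` (`f` the surviving
  fraction), so a half-life of only a few hours would visibly shift the
  profile downstream between the two snapshots.
* **Initiation rate 2e-3 per free polymerase per second** (mean ~8 min from
  entering the pool to the next attempt): fast enough that the polymerase
  cycle (initiation wait, travel to the first lesion, stall residence) is
  short relative to 45 min, so the system reaches its post-damage
  quasi-steady state before the first snapshot — again a requirement implied
  by the stationary profiles.
* **Stalled-removal hazard 1/300 s⁻¹** (5-min mean residence of a halted
  polymerase before dissociation): minutes-scale clearance of damage-stalled
  polymerase, short enough that queues do not back up to the promoter in the
  recycling regime. In the `wt` regime this hazard is the natural calibration
  knob (below).
* **Moving-removal hazard 1e-5 s⁻¹**: productive elongation is highly
  processive; premature termination is rare (~3% per 100-kb transit). A large
  moving hazard would also make the burn-in flux balance unreachable.
* **Footprint 40 nt**: the RNAPII head-to-tail exclusion length.
* **Pool size 1000**: an in-silico scale factor, not a biological count. It
  is large enough that replicate-averaged density maps are smooth, and small
  enough that the pool is genuinely limiting — engaged polymerases are a
  substantial fraction of the total, which is what couples damage on one gene
  to initiation on all genes.
* **Removal recycle probability 0.5** in the `wt` regime: removals split
  evenly between recycling and degradation; the degradation *rate* is then
  set by the stalled-removal hazard, which is what `calibrate_degradation()`
  tunes.
* **Snapshots at 45 min, 3 h and 4 h** after damage; **100 replicates**;
  **1-kb bins**.

## Calibrating degradation

`calibrate_degradation()` adjusts `stalled_removal_hazard` so that the fitted
exponential half-life of the surviving pool (pool size minus degraded count —
the whole-extract, western-blot-like readout) over 0–4 h post-damage matches
a target (default use: ~1.5 h). It is a log-scale bisection with two
variance-control measures, both needed because a single 100-kb gene carries
only ~4 lesions per replicate and the replicate-to-replicate spread of decay
trajectories is large:

* **Common random numbers**: every bisection iterate re-uses the same
  replicate seeds, which makes the half-life-versus-hazard response smooth
  and monotone so bracket updates are reliable at 30 replicates per iterate.
* **Verification-coupled stopping**: when an iterate lands inside the
  tolerance, the hazard is re-measured with 100 fresh replicates; if that
  independent measurement misses, it replaces the iterate's value and the
  bisection continues. The reported half-life is therefore always an
  independent 100-replicate measurement at the returned hazard.

The response of the half-life to the hazard is shallow (roughly
`t½ ∝ hazard^-0.2` near the operating point) because at high hazard the decay
rate saturates at the stall-arrival rate; the achievable half-life is bounded
below by the polymerase cycle time.

## Summaries

* `density_profile()` bins engaged polymerases into half-open 1-kb bins;
  `run_replicates()` averages the maps over replicates (counts are conserved:
  bins sum to the mean engaged count).
* `metagene_profile()` rescales gene bodies onto a common relative TSS→TTS
  axis (100 points) and averages genes with equal weight, stratified by the
  length classes short (< 30 kb), medium (30–100 kb) and long (≥ 100 kb);
  `tss_anchored_profile()` gives the absolute-scale view.
* `fit_half_life()` is a log-linear least-squares fit; a slope non-negative
  within one standard error reports an infinite half-life. It is exact on
  closed-form exponential input and scale-invariant.
* `shutdown_ratio()` is the late/early total-signal ratio per gene;
  `queue_statistics()` counts the contiguous halted chain ending at each
  lesion.
* `profile_distance()` is the L1 distance between unit-mass-normalised
  profiles (in [0, 2]), with a bootstrap null band: the distribution of the
  distance between two bootstrap means drawn from one profile's replicates,
  i.e. the distance expected between two estimates of the *same* shape.

A caution on hard thresholds for the L1 statistic: on sparse maps it has a
noise floor. At the default study scale (one 100-kb gene, whose occupancy is
bounded by the TSS exclusion flux limit of roughly `speed/footprint`
initiations per second, 100 replicates, 1-kb bins), two snapshots of the
*same* quasi-stationary distribution taken 15 min apart measure an L1 of
~0.12–0.14. Stationarity claims should therefore be judged against the
bootstrap null band, which calibrates that floor, rather than against a fixed
small constant.

## Synthetic coverage and spike-in normalization

`simulate_coverage()` turns a density map into TT-seq-like binned read
counts: Poisson with mean `depth * density * spike_scale`, where
`spike_scale` plays the role of the per-sample library-size factor an
external spike-in genome provides. `spike_in_normalize()` divides counts by
that factor; `estimate_spike_scale()` is the ratio-of-totals estimator over a
spike-in track. The noise model is deliberately Poisson-only — these tracks
exist to exercise the summarisation math (normalization, metagenes,
ratios), not to model biological count dispersion; overdispersion is a
documented extension point. The self-consistency loop (simulate → normalize →
metagene) recovers the density map's shape with correlation > 0.95 at
moderate depth.

What the generator does *not* emulate: read-level sampling, fragment-length
and positional bias, labeling-efficiency variation, multi-mapping, or any
alignment artefact. Tests passing on these tracks validate the summary
computations, not the upstream sequencing workflow.

## Numerical choices and degenerate inputs

* Positions are 0-based continuous offsets from the TSS; bins are half-open
  `[k·bin, (k+1)·bin)`, matching the bedGraph convention of the exporters.
* Event ties are resolved by a fixed priority (repair, completion, stall,
  removal, initiation) and then entity id — any fixed order is defensible;
  this one maximises consistency of downstream reschedules.
* Lesion positions are strictly inside `(0, L)`: the TSS itself is never
  lesioned, so damage restricts elongation rather than promoter access.
* A zero initiation rate burns in immediately (nothing engaged); a zero pool
  never schedules initiation; zero lesion density makes `apply_damage()` a
  timestamp-only event.
* `validate_sim_params()` rejects out-of-range fields by name; initiation
  weights are renormalised only when they sum to 1 within 1e-6.
* Configs serialise numbers at full precision, so write → read round-trips
  reproduce the exact parameter set (and its hash).

## Problem sizes used by the test suite

The tests run the full study scale where the behaviour under test demands it
(100 replicates of the 100-kb presets for the regime contrasts; the
three-gene competition at 100 replicates for transcript-output ratios; the
calibration at 30 replicates per iterate with 100-replicate verification) and
deliberately small instances elsewhere (a 2-kb gene with 5 polymerases for
the fixed-step cross-check at `dt = 0.01 s`, 500 runs per arm; kilobase-scale
genes for unit-level event semantics). These sizes are the package's own
choices, stated here so results are interpretable; all of them are ordinary
arguments.

## Known limitations

* One abstract lesion type with a single exponential repair clock; no
  distinction between photoproduct classes, no dose–response model (other UV
  doses are expressed only through `lesion_density`).
* Single transcribed strand per gene; no antisense transcription, no
  two-strand damage.
* No chromatin, pausing-site biology beyond an optional single exponential
  pause, backtracking, or repair-factor recruitment kinetics; dissociation
  aggregates every degradation-independent clearance route into one hazard.
* The free pool is well-mixed (no nuclear geometry or diffusion).
* Transcript counts ignore RNA processing and decay: "mRNA" is cumulative
  completed transcription.
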