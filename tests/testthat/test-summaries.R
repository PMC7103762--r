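make_snap <- function(pos, time = 0, gene = "g") {
  tibble::tibble(time = time, pol_id = seq_along(pos), gene_id = gene,
                 position = pos, status = "moving")
}

test_that("density bins are half-open and conserve counts", {
  genes <- gene_ensemble(20000, 1, "g")
  d <- density_profile(make_snap(10500), genes = genes, bin_size = 1000)
  expect_equal(d$count[d$bin == 10], 1L)
  expect_equal(sum(d$count), 1L)
  expect_equal(nrow(d), 20)
  # boundary position lands in the bin it opens
  d2 <- density_profile(make_snap(10000), genes = genes, bin_size = 1000)
  expect_equal(d2$count[d2$bin == 10], 1L)
  expect_equal(d2$count[d2$bin == 9], 0L)
  # empty snapshot tibble: no times, so no bins (all-zero maps for empty
  # snapshots of a full trajectory are covered by the conservation join below)
  d3 <- density_profile(make_snap(numeric(0)), genes = genes, bin_size = 1000)
  expect_true(all(d3$count == 0))
  expect_equal(nrow(d3), 0)
  # counts conserved for a real trajectory
  tr <- simulate_transcription(tiny_damage_params(), seed = 5)
  dp <- density_profile(tr, bin_size = 100)
  per_time <- dp |>
    dplyr::group_by(time) |>
    dplyr::summarise(total = sum(count), .groups = "drop")
  engaged <- tr$snapshots |> dplyr::count(time, name = "engaged")
  joined <- dplyr::left_join(per_time, engaged, by = "time") |>
    dplyr::mutate(engaged = dplyr::coalesce(engaged, 0L))
  expect_equal(joined$total, joined$engaged)
})

test_that("metagene profiles average on a relative axis and stratify by class", {
  genes <- gene_ensemble(c(1e5, 63e3, 5e3), c(0.1, 0.2, 0.7),
                         c("long", "med", "short"))
  prof <- tidyr::crossing(gene_id = genes$gene_id, bin = 0:99) |>
    dplyr::left_join(genes, by = "gene_id") |>
    dplyr::mutate(bin_start = bin / 100 * length, density = 1.0) |>
    dplyr::select(gene_id, bin_start, density)
  m <- metagene_profile(prof, genes)
  expect_setequal(unique(m$class_label), c("short", "medium", "long"))
  expect_equal(nrow(m), 300)
  expect_true(all(abs(m$mean_signal - 1) < 1e-9))

  # single gene, unstratified: the metagene is the gene's own profile
  g1 <- gene_ensemble(10000, 1, "solo")
  p1 <- tibble::tibble(gene_id = "solo", bin_start = seq(0, 9000, 1000),
                       density = 1:10)
  m1 <- metagene_profile(p1, g1, stratify = FALSE, n_rel_bins = 10)
  expect_equal(m1$mean_signal, as.numeric(1:10))

  # duplicating a gene within its class leaves the class mean unchanged
  g2 <- gene_ensemble(c(10000, 10000), c(0.5, 0.5), c("a", "b"))
  p2 <- dplyr::bind_rows(dplyr::mutate(p1, gene_id = "a"),
                         dplyr::mutate(p1, gene_id = "b"))
  m2 <- metagene_profile(p2, g2, stratify = FALSE, n_rel_bins = 10)
  expect_equal(m2$mean_signal, m1$mean_signal)

  # gene input order is irrelevant
  m3 <- metagene_profile(p2[sample(nrow(p2)), ], g2, stratify = FALSE, n_rel_bins = 10)
  expect_equal(m3, m2)

  # a class with no genes is omitted with a warning
  expect_warning(metagene_profile(p1, g1, n_rel_bins = 10), "medium")
})

test_that("half-life fitting recovers closed-form decay and flags no-decay series", {
  tt <- c(0, 3600, 7200, 10800)
  f <- fit_half_life(tt, 500 * 2^(-tt / 5400))
  expect_equal(f$half_life, 5400, tolerance = 1e-6)
  expect_equal(glance(f)$half_life, f$half_life)
  # scale invariance
  f2 <- fit_half_life(tt, 7.3 * 500 * 2^(-tt / 5400))
  expect_equal(f2$half_life, f$half_life, tolerance = 1e-9)
  # constant series: infinite half-life
  expect_equal(fit_half_life(tt, rep(100, 4))$half_life, Inf)
  # errors
  expect_error(fit_half_life(c(0, 3600), c(2, 1)), "3 points")
  expect_error(fit_half_life(c(0, 3600, 3600), c(3, 2, 1)), "increasing")
  expect_error(fit_half_life(tt, c(4, 3, 0, 1)), "positive")
  expect_s3_class(tidy(f), "tbl_df")
})

test_that("shutdown ratios compare late to early totals per gene", {
  d <- tibble::tibble(gene_id = rep("g", 4), time = c(0, 0, 100, 100),
                      bin = c(0, 1, 0, 1), density = c(2, 2, 1, 1))
  r <- shutdown_ratio(d, 0, 100)
  expect_equal(r$ratio, 0.5)
  expect_equal(shutdown_ratio(dplyr::mutate(d, density = rep(c(2, 2), 2)), 0, 100)$ratio, 1)
  d0 <- dplyr::mutate(d, density = c(0, 0, 1, 1))
  expect_warning(r0 <- shutdown_ratio(d0, 0, 100), "zero early")
  expect_true(is.na(r0$ratio))
  late0 <- dplyr::mutate(d, density = c(2, 2, 0, 0))
  expect_equal(shutdown_ratio(late0, 0, 100)$ratio, 0)
  expect_error(shutdown_ratio(d, 0, 999), "present")
})

test_that("queue lengths count contiguous stalled chains ending at a lesion", {
  snap <- tibble::tibble(
    time = 0, pol_id = 1:5, gene_id = "g",
    position = c(5000, 4960, 4920, 3000, 1000),
    status = c("stalled_lesion", "stalled_queue", "stalled_queue", "moving", "moving"))
  les <- tibble::tibble(time = 0, gene_id = "g", position = c(5000, 8000),
                        repair_time = 1e9, active = TRUE)
  q <- queue_statistics(list(snapshots = snap, lesions = les), footprint = 40)
  expect_equal(q$queue_length[q$lesion_position == 5000], 3L)
  expect_equal(q$queue_length[q$lesion_position == 8000], 0L)
  # no stalled polymerases at all
  q0 <- queue_statistics(list(snapshots = dplyr::mutate(snap, status = "moving"),
                              lesions = les), footprint = 40)
  expect_true(all(q0$queue_length == 0L))
})

test_that("profile distance is a normalized pseudometric with a bootstrap null", {
  a <- c(1, 2, 3, 4)
  expect_equal(profile_distance(a, 10 * a)$statistic, 0)
  expect_equal(profile_distance(c(1, 0, 0), c(0, 0, 2))$statistic, 2)
  expect_error(profile_distance(c(0, 0), c(1, 1)), "zero-mass")
  # symmetry and triangle inequality on random triples
  set.seed(42)
  for (k in 1:25) {
    x <- runif(8); y <- runif(8); z <- runif(8)
    dxy <- profile_distance(x, y)$statistic
    dyx <- profile_distance(y, x)$statistic
    dxz <- profile_distance(x, z)$statistic
    dzy <- profile_distance(z, y)$statistic
    expect_equal(dxy, dyx, tolerance = 1e-12)
    expect_lte(dxy, dxz + dzy + 1e-12)
  }
  # replicate matrices produce a null band that covers a same-distribution draw
  set.seed(7)
  A <- matrix(rpois(50 * 20, lambda = rep(c(8, 4, 2, 1, 1), each = 4)),
              nrow = 50, byrow = TRUE)
  B <- matrix(rpois(50 * 20, lambda = rep(c(8, 4, 2, 1, 1), each = 4)),
              nrow = 50, byrow = TRUE)
  pd <- profile_distance(A, B, n_boot = 400)
  expect_false(any(is.na(pd$null_band)))
  expect_true(pd$inside_null)
})
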