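fake_profile <- function(total, w = 10, n_sites = 1) {
  structure(
    list(positions = seq_len(w) - 5, forward = rep(total / (2 * w), w),
         reverse = rep(total / (2 * w), w), n_sites = n_sites),
    class = "footprint_profile")
}

test_that("the empirical coverage p-value follows the add-one formula", {
  nulls <- lapply(1:50, function(i) fake_profile(i))
  above <- coverage_pvalue(fake_profile(100), nulls)
  expect_equal(above$p_value, 1 / 51)
  expect_equal(above$enrichment, 100 / 25.5)

  below <- coverage_pvalue(fake_profile(0.5), nulls)
  expect_equal(below$p_value, 1)

  mid <- coverage_pvalue(fake_profile(40.5), nulls)
  expect_equal(mid$p_value, (1 + 10) / 51)
  expect_error(coverage_pvalue(fake_profile(1), list()), "null")

  # normalization: the statistic is per-site mean coverage
  expect_equal(coverage_pvalue(fake_profile(100, n_sites = 4), nulls)$p_value,
               coverage_pvalue(fake_profile(25), nulls)$p_value)
})

test_that("coherence reflects the order of strand-wise maxima", {
  w <- 41
  pos <- -20:20
  mk <- function(fmax, rmax) {
    f <- numeric(w); f[match(fmax, pos)] <- 5
    r <- numeric(w); r[match(rmax, pos)] <- 5
    structure(list(positions = pos, forward = f, reverse = r, n_sites = 1),
              class = "footprint_profile")
  }
  expect_true(profile_coherence(mk(-10, 9)))
  expect_false(profile_coherence(mk(4, -4)))
  expect_false(profile_coherence(mk(0, 0)))
})

test_that("permutation envelopes are seeded, summarized by quartiles, and flag empty scans", {
  cfg <- sym_sim_config(n_peaks = 40, seed = 3,
                        motif = rand_high_ic_pwm(10, seed = 19),
                        plant = "consensus")
  sim <- simulate_genome_with_sites(cfg)
  reads <- simulate_exo_reads(sim)
  idx <- build_five_prime_index(reads,
                                seqlengths = c(chrS = cfg$genome_length))
  env1 <- suppressMessages(
    permutation_envelope(sim$genome, sim$peaks, idx, cfg$motif,
                         p = 1e-3, n_perm = 10, seed = 5))
  env2 <- suppressMessages(
    permutation_envelope(sim$genome, sim$peaks, idx, cfg$motif,
                         p = 1e-3, n_perm = 10, seed = 5))
  expect_identical(env1$median, env2$median)
  expect_identical(env1$null_totals, env2$null_totals)
  expect_true(all(env1$q1 <= env1$median + 1e-12))
  expect_true(all(env1$median <= env1$q3 + 1e-12))
  expect_equal(length(env1$profiles), 10L)
  # permutations of a high-IC planted motif rarely match: expect the
  # zero-hit message path to be exercised
  expect_message(
    permutation_envelope(sim$genome, sim$peaks, idx, cfg$motif,
                         p = 1e-5, n_perm = 3, seed = 6),
    "zero hits")
  expect_error(
    permutation_envelope(sim$genome, sim$peaks, idx, cfg$motif, n_perm = 1),
    "n_perm")
})

test_that("a motif of identical columns gives a degenerate envelope", {
  col <- c(10, 3, 2, 1)
  pwm <- new_pwm(matrix(rep(col, 5), nrow = 4), "flat")
  g <- make_genome(c(chrS = rand_dna(5000, seed = 71)))
  regions <- GRanges("chrS", IRanges(seq(1, 4500, by = 500), width = 400))
  idx <- build_five_prime_index(uniform_reads(500, 5000, seed = 72),
                                seqlengths = c(chrS = 5000))
  env <- permutation_envelope(g, regions, idx, pwm, p = 0.05, n_perm = 5,
                              seed = 9)
  expect_equal(env$q1, env$median)
  expect_equal(env$q3, env$median)
})

test_that("under uniform reads the true-motif profile sits inside the null band", {
  pwm <- rand_soft_pwm(8, seed = 81)
  fracs <- vapply(1:5, function(rep) {
    g <- make_genome(c(chrS = rand_dna(20000, seed = 500 + rep)))
    regions <- GRanges("chrS", IRanges(seq(1, 19000, by = 1000),
                                       width = 600))
    idx <- build_five_prime_index(
      uniform_reads(2000, 20000, seed = 600 + rep),
      seqlengths = c(chrS = 20000))
    hits <- scan_regions(g, regions, pwm, 1e-3)
    prof <- aggregate_footprint(site_coverage_matrix(idx, hits, 30))
    np <- list(forward = prof$forward / prof$n_sites,
               reverse = prof$reverse / prof$n_sites)
    env <- suppressMessages(
      permutation_envelope(g, regions, idx, pwm, p = 1e-3, n_perm = 30,
                           seed = 700 + rep))
    inside <- c(np$forward >= env$q1["forward", ] &
                  np$forward <= env$q3["forward", ],
                np$reverse >= env$q1["reverse", ] &
                  np$reverse <= env$q3["reverse", ])
    mean(inside)
  }, numeric(1))
  expect_gte(mean(fracs), 0.35)
})

test_that("subsampling is seeded and degenerates correctly at the extremes", {
  cfg <- sym_sim_config(n_peaks = 60, seed = 45)
  sim <- simulate_genome_with_sites(cfg)
  reads <- simulate_exo_reads(sim)
  idx <- build_five_prime_index(reads,
                                seqlengths = c(chrS = cfg$genome_length))
  m <- site_coverage_matrix(idx, sim$sites, flank = 30)

  full <- aggregate_footprint(m)
  all_of_them <- subsample_profile(m, n_sites(m), seed = 1)
  expect_equal(all_of_them$forward, full$forward)
  expect_equal(all_of_them$reverse, full$reverse)

  one <- subsample_profile(m, 1, seed = 4)
  expect_equal(sum(one$forward) + sum(one$reverse) >= 0, TRUE)
  expect_equal(one$n_sites, 1L)

  s1 <- subsample_profile(m, 20, seed = 8)
  s2 <- subsample_profile(m, 20, seed = 8)
  expect_identical(s1, s2)
  expect_error(subsample_profile(m, n_sites(m) + 1), "between")
})

test_that("profile differences are antisymmetric, zero on identity, and scale invariant", {
  cfg <- sym_sim_config(n_peaks = 40, seed = 53)
  sim <- simulate_genome_with_sites(cfg)
  reads <- simulate_exo_reads(sim)
  idx <- build_five_prime_index(reads,
                                seqlengths = c(chrS = cfg$genome_length))
  m <- site_coverage_matrix(idx, sim$sites, flank = 30)
  a <- subsample_profile(m, 15, seed = 2)
  b <- aggregate_footprint(m)

  zero <- profile_difference(a, a)
  expect_true(all(zero$forward == 0) && all(zero$reverse == 0))

  d_ab <- profile_difference(a, b)
  d_ba <- profile_difference(b, a)
  expect_equal(d_ab$forward, -d_ba$forward)
  expect_equal(d_ab$reverse, -d_ba$reverse)

  # duplicating every site of a leaves the per-site-normalized diff unchanged
  sel <- withr::with_seed(2, sample.int(n_sites(m), 15))
  dup <- m
  dup$values <- m$values[c(sel, sel), , , drop = FALSE]
  dup$hits <- m$hits[c(sel, sel)]
  a2 <- aggregate_footprint(dup)
  d2 <- profile_difference(a2, b)
  expect_equal(d2$forward, d_ab$forward)
  expect_equal(d2$reverse, d_ab$reverse)

  short <- a
  short$positions <- a$positions + 1L
  expect_error(profile_difference(short, b), "axes")
})

test_that("motif ranking is invariant to global read-count scaling", {
  pwm <- rand_high_ic_pwm(11, seed = 57, id = "true")
  cfg <- sym_sim_config(n_peaks = 60, seed = 59, motif = pwm,
                        plant = "consensus")
  sim <- simulate_genome_with_sites(cfg)
  reads <- simulate_exo_reads(sim)
  decoys <- lapply(1:2, function(i) {
    d <- permute_columns(pwm, 900 + i)
    d$motif_id <- paste0("decoy", i)
    d
  })
  lib <- c(list(pwm), decoys)
  idx1 <- build_five_prime_index(reads,
                                 seqlengths = c(chrS = cfg$genome_length))
  idx3 <- build_five_prime_index(rep(reads, 3),
                                 seqlengths = c(chrS = cfg$genome_length))
  r1 <- suppressMessages(rank_motifs(sim$genome, sim$peaks, idx1, lib,
                                     p = 1e-4, n_perm = 15, seed = 8))
  r3 <- suppressMessages(rank_motifs(sim$genome, sim$peaks, idx3, lib,
                                     p = 1e-4, n_perm = 15, seed = 8))
  expect_equal(r1$motif_id, r3$motif_id)
  expect_equal(r1$p_value, r3$p_value)
  expect_equal(r1$enrichment, r3$enrichment)
  expect_equal(r3$observed, 3 * r1$observed)
  expect_equal(r1$motif_id[1], "true")
  expect_true(all(r1$p_value > 0 & r1$p_value <= 1, na.rm = TRUE))
})
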