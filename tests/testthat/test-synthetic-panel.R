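test_that("configuration validation rejects out-of-range parameters", {
  expect_error(sim_config(F_k = 1.2), "F_k")
  expect_error(sim_config(F_k = c(0.1, 0.2)), "length K")
  expect_error(sim_config(K = 0), "K")
  expect_error(sim_config(L = 10, n_private = 20), "n_private")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
})

test_that("Balding-Nichols frequencies have the prescribed moments", {
  cfg <- sim_config(K = 1, L = 10000, F_k = 0.2, seed = 1)
  withr::with_seed(1, fr <- simulate_frequencies(cfg))
  expect_true(all(fr$f >= 1e-6 & fr$f <= 1 - 1e-6))
  # E[f] = p: regress f on p, mean deviation should be tiny
  expect_lt(mean(fr$f[1, ] - fr$p), 0.01)
  # Var[f | p] = F p (1 - p): Monte-Carlo at p ~ 0.5, F = 0.2 -> ~0.05
  withr::with_seed(2, {
    p <- 0.5; F_ <- 0.2
    draws <- rbeta(1e4, p * (1 - F_) / F_, (1 - p) * (1 - F_) / F_)
  })
  expect_equal(var(draws), F_ * p * (1 - p), tolerance = 0.15)
  # F -> 0 limit: f concentrates on p
  cfg0 <- sim_config(K = 1, L = 2000, F_k = 1e-4, seed = 1)
  withr::with_seed(3, fr0 <- simulate_frequencies(cfg0))
  expect_lt(max(abs(fr0$f[1, ] - fr0$p)), 0.1)
})

test_that("the panel is reproducible from its seed and respects missing_rate", {
  cfg <- sim_config(K = 2, n_per_pop = 10, L = 200, seed = 9)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth$Q_true, b$truth$Q_true)

  cfg0 <- sim_config(K = 2, n_per_pop = 10, L = 200, missing_rate = 0,
                     seed = 9)
  expect_false(anyNA(simulate_panel(cfg0)$genotypes$dosage))
})

test_that("membership rows sum to one and truth files round-trip", {
  sim <- simulate_panel(sim_config(K = 3, n_per_pop = 10, L = 100,
                                   admixed_fraction = 0.3, n_private = 5,
                                   seed = 4))
  expect_true(all(abs(rowSums(sim$truth$Q_true) - 1) < 1e-12))
  expect_true(all(sim$truth$private_locus_indices >= 1 &
                    sim$truth$private_locus_indices <= 100))
  dir <- tempfile()
  export_truth(sim$truth, dir)
  back <- read_truth(dir)
  expect_equal(back$Q_true, sim$truth$Q_true, tolerance = 1e-12)
  expect_equal(length(back$pop_labels), 30L)
  expect_equal(back$private_locus_indices,
               sim$truth$private_locus_indices)
  expect_equal(unname(back$duplicate_pairs),
               unname(sim$truth$duplicate_pairs))
})

test_that("per-sample heterozygosity sits in the inbred-crop band", {
  sim <- simulate_panel(sim_config(K = 6, n_per_pop = 30, L = 2000,
                                   F_k = 0.3, seed = 1))
  het <- sample_stats(sim$genotypes)$het_pct
  expect_gt(mean(het), 1)
  expect_lt(mean(het), 8)
})

test_that("adjacent-locus LD responds monotonically to the switch rate", {
  near_far <- function(rate, seed) {
    cfg <- sim_config(K = 1, n_per_pop = 60, L = 1000,
                      switch_rate_per_bp = rate, missing_rate = 0,
                      n_private = 0, n_duplicates = 0, seed = seed,
                      chrom_lengths = rep(2e5, 4))
    gm <- simulate_panel(cfg)$genotypes
    dc <- decay_curve(gm, max_dist_bp = 5e4, breaks = seq(0, 5e4, 2500))
    ok <- dc$n_pairs > 0 & !is.na(dc$mean_r2)
    c(near = dc$mean_r2[ok][1], far = tail(dc$mean_r2[ok], 1))
  }
  rates <- c(1e-5, 2e-4, 1)  # strong linkage -> desk default -> unlinked
  res <- sapply(rates, near_far, seed = 21)
  # near-bin r2 decreases as switching intensifies
  expect_true(all(diff(res["near", ]) < 0))
  # in the LD regime the near bin exceeds the far bin
  expect_gt(res["near", 1], res["far", 1])
  expect_gt(res["near", 2], res["far", 2])
})

test_that("planted private loci satisfy the MAF contrast in >= 90% of plantings", {
  ok <- 0L; total <- 0L
  for (s in 1:3) {
    cfg <- sim_config(K = 2, n_per_pop = 30, L = 2000, n_private = 20,
                      status_probs = c(da_serbo = 0.5, cultivar = 0.5),
                      seed = s)
    sim <- simulate_panel(cfg)
    mf <- group_maf(sim$genotypes, sim$meta, "da_serbo")
    mr <- group_maf(sim$genotypes, sim$meta, "da_serbo", complement = TRUE)
    idx <- sim$truth$private_locus_indices
    ok <- ok + sum(mf$maf_group[idx] > 0.4 & mr$maf_group[idx] < 0.1,
                   na.rm = TRUE)
    total <- total + length(idx)
  }
  expect_gte(ok / total, 0.9)
})

test_that("planted duplicate pairs are near-identical", {
  sim <- simulate_panel(sim_config(K = 2, n_per_pop = 20, L = 1000,
                                   n_duplicates = 3, missing_rate = 0,
                                   seed = 6))
  d <- dissimilarity(sim$genotypes)
  dp <- sim$truth$duplicate_pairs
  for (m in seq_len(nrow(dp))) {
    expect_lt(d[dp[m, 1], dp[m, 2]], 0.005)
  }
})

test_that("empirical Hudson F_ST recovers the Balding-Nichols divergence", {
  # Hardy-Weinberg sampling regime: no selfing, founder pool as large as
  # the allele count, unlinked loci
  cfg <- sim_config(K = 2, n_per_pop = 100, L = 5000, F_k = 0.2,
                    selfing = 0, missing_rate = 0, n_private = 0,
                    n_duplicates = 0, admixed_fraction = 0,
                    n_founders = 200, switch_rate_per_bp = 1, seed = 8)
  sim <- simulate_panel(cfg)
  fst <- hudson_fst(sim$genotypes, sim$truth$pop_labels)
  expect_equal(fst, 0.2, tolerance = 0.03 / 0.2)
})
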