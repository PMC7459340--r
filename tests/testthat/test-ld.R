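test_that("composite r2 matches hand-computed Pearson values", {
  expect_equal(composite_r2(c(0, 1, 2, 0), c(0, 1, 2, 0)), 1)
  # perfect repulsion is still r2 = 1 (sign-blind)
  a <- c(0, 1, 2, 0, 2)
  expect_equal(composite_r2(a, 2 - a), 1)
  # hand computation: cov = 2, var_a = 4, var_b = 2 -> r = 2/sqrt(8)
  expect_equal(composite_r2(c(0, 0, 1, 2, 2), c(0, 1, 1, 1, 2)),
               (2 / sqrt(8))^2)
  # undefined cases
  expect_true(is.na(composite_r2(c(0, NA, 1), c(NA, 0, 1))))
  expect_true(is.na(composite_r2(c(1, 1, 1), c(0, 1, 2))))
})

test_that("r2 is invariant to REF/ALT orientation of either locus", {
  withr::with_seed(61, {
    for (trial in 1:10) {
      a <- sample(0:2, 30, replace = TRUE)
      b <- sample(0:2, 30, replace = TRUE)
      if (sd(a) == 0 || sd(b) == 0) next
      r <- composite_r2(a, b)
      expect_equal(composite_r2(2 - a, b), r)
      expect_equal(composite_r2(a, 2 - b), r)
    }
  })
})

test_that("decay curve bin means agree with a brute-force all-pairs oracle", {
  withr::with_seed(63, gm <- random_gm(20, 50, miss = 0.1))
  breaks <- seq(0, 5000, 500)
  dc <- decay_curve(gm, max_dist_bp = 5000, breaks = breaks)
  # brute force: enumerate all pairs, bin by hand
  pos <- gm$loci$pos
  r2s <- dists <- c()
  for (a in 1:49) for (b in (a + 1):50) {
    dist_ab <- abs(pos[b] - pos[a])
    if (dist_ab > 5000) next
    r2 <- composite_r2(gm$dosage[, a], gm$dosage[, b])
    if (is.na(r2)) next
    r2s <- c(r2s, r2); dists <- c(dists, dist_ab)
  }
  for (i in seq_len(nrow(dc))) {
    sel <- dists > dc$bin_lo[i] & dists <= dc$bin_hi[i]
    if (i == 1) sel <- sel | dists == 0
    if (!any(sel)) {
      expect_equal(dc$n_pairs[i], 0L)
    } else {
      expect_equal(dc$mean_r2[i], mean(r2s[sel]))
      expect_equal(dc$n_pairs[i], sum(sel))
    }
  }
})

test_that("a two-locus chromosome yields exactly one pair", {
  gm <- make_gm(rbind(c(0, 0), c(1, 2), c(2, 1), c(0, 1)),
                pos = c(100, 400))
  dc <- decay_curve(gm, max_dist_bp = 1000, breaks = c(0, 500, 1000))
  expect_equal(sum(dc$n_pairs), 1L)
})

test_that("unlinked loci show a flat ~1/n background", {
  cfg <- sim_config(K = 1, n_per_pop = 100, L = 1000, selfing = 0,
                    n_founders = 200, switch_rate_per_bp = 10,
                    missing_rate = 0, n_private = 0, n_duplicates = 0,
                    seed = 67)
  gm <- simulate_panel(cfg)$genotypes
  dc <- decay_curve(gm, max_dist_bp = 5e4, breaks = seq(0, 5e4, 5e3))
  got <- dc$mean_r2[dc$n_pairs > 0]
  expect_equal(mean(got), 0.01, tolerance = 0.5)
  # flat in distance: first and last occupied bins within noise
  expect_lt(abs(got[1] - tail(got, 1)), 0.01)
})

test_that("half-decay lands at the kb scale the mosaic rate implies", {
  cfg <- sim_config(K = 1, n_per_pop = 80, L = 2000,
                    chrom_lengths = rep(2e5, 4), missing_rate = 0,
                    n_private = 0, seed = 71)
  gm <- simulate_panel(cfg)$genotypes
  dc <- decay_curve(gm, max_dist_bp = 2e4, breaks = seq(0, 2e4, 500))
  expect_gte(attr(dc, "half_decay_bp"), 1000)
  expect_lte(attr(dc, "half_decay_bp"), 5000)
})

test_that("pruning removes duplicated loci, spares independent ones, and is idempotent", {
  withr::with_seed(73, {
    gm <- random_gm(40, 30, miss = 0)
    # duplicate locus 5 at an adjacent position
    d2 <- cbind(gm$dosage, gm$dosage[, 5])
    gm2 <- make_gm(d2, pos = c(gm$loci$pos, gm$loci$pos[5] + 1))
  })
  pruned <- ld_prune(gm2, r2_max = 0.5)
  expect_equal(n_loci(pruned), n_loci(gm2) - 1L)
  # exactly one member of the duplicated pair survives
  dup_pos <- c(gm$loci$pos[5], gm$loci$pos[5] + 1)
  expect_equal(sum(pruned$loci$pos %in% dup_pos), 1L)
  # idempotence
  again <- ld_prune(pruned, r2_max = 0.5)
  expect_identical(again$loci$id, pruned$loci$id)
  # independent loci: nothing removed at a lenient threshold
  withr::with_seed(74, gm3 <- random_gm(60, 20, miss = 0))
  expect_equal(n_loci(ld_prune(gm3, r2_max = 0.5)), 20L)
})

test_that("pruning drops the lower-MAF member of a correlated pair", {
  withr::with_seed(75, {
    base <- sample(0:2, 60, replace = TRUE, prob = c(0.4, 0.2, 0.4))
    rare <- base
    rare[sample(60, 8)] <- 0  # degrade towards REF: lower MAF, still r2 > 0.2
  })
  gm <- make_gm(cbind(base, rare), pos = c(100, 200))
  maf <- locus_stats(gm)$maf
  pruned <- ld_prune(gm, r2_max = 0.2)
  expect_equal(n_loci(pruned), 1L)
  expect_equal(pruned$loci$id, gm$loci$id[which.max(maf)])
})

test_that("nearest-bin r2 exceeds the farthest bin in the LD regime", {
  for (s in c(81, 82, 83)) {
    cfg <- sim_config(K = 1, n_per_pop = 50, L = 800,
                      chrom_lengths = rep(2e5, 4), missing_rate = 0,
                      n_private = 0, seed = s)
    gm <- simulate_panel(cfg)$genotypes
    dc <- decay_curve(gm, max_dist_bp = 5e4, breaks = seq(0, 5e4, 2500))
    ok <- which(dc$n_pairs > 0)
    expect_gt(dc$mean_r2[ok[1]], dc$mean_r2[tail(ok, 1)])
  }
})
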