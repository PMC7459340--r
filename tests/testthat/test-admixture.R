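# closed-form binomial log-likelihood at per-locus MLE frequencies
loglik_k1 <- function(gm) {
  sum(vapply(seq_len(n_loci(gm)), function(j) {
    g <- gm$dosage[, j]
    g <- g[!is.na(g)]
    p <- min(max(sum(g) / (2 * length(g)), 1e-6), 1 - 1e-6)
    sum(g * log(p) + (2 - g) * log(1 - p))
  }, 0))
}

test_that("K = 1 reduces to the closed-form binomial optimum", {
  withr::with_seed(41, gm <- random_gm(15, 60, miss = 0.1))
  fit <- fit_admixture(gm, K = 1, restarts = 1, seed = 1)
  expect_equal(unname(fit$Q[, 1]), rep(1, 15))
  ls <- locus_stats(gm)
  expect_equal(unname(fit$F[1, ]), pmin(pmax(ls$p_alt, 1e-6), 1 - 1e-6),
               tolerance = 1e-6)
  expect_equal(tail(fit$loglik, 1), loglik_k1(gm), tolerance = 1e-6)
})

test_that("a fully separable two-population fixture is solved to the optimum", {
  # two groups fixed for opposite alleles at every locus
  d <- rbind(matrix(0L, 6, 40), matrix(2L, 6, 40))
  gm <- make_gm(d)
  fit <- fit_admixture(gm, K = 2, restarts = 3, seed = 2)
  hard <- round(fit$Q)
  expect_true(all(abs(fit$Q - hard) < 1e-3))
  expect_equal(unname(hard[1:6, ]), matrix(rep(hard[1, ], each = 6), 6))
  expect_true(all(hard[1, ] != hard[12, ]))
  # analytic maximum: every entry fits perfectly up to the F clamp
  ll_max <- 12 * 40 * 2 * log(1 - 1e-6)
  expect_equal(tail(fit$loglik, 1), ll_max, tolerance = 1e-6)
})

test_that("the EM log-likelihood trace is monotone non-decreasing", {
  sim <- simulate_panel(sim_config(K = 3, n_per_pop = 15, L = 300,
                                   seed = 43))
  fit <- fit_admixture(sim$genotypes, K = 3, restarts = 1, seed = 3)
  expect_true(all(diff(fit$loglik) > -1e-6))
})

test_that("Q rows stay exactly stochastic and respect sample permutation", {
  sim <- simulate_panel(sim_config(K = 2, n_per_pop = 12, L = 250,
                                   admixed_fraction = 0.3, seed = 47))
  gm <- sim$genotypes
  fit <- fit_admixture(gm, K = 2, restarts = 1, seed = 4)
  expect_true(all(abs(rowSums(fit$Q) - 1) < 1e-9))
  # permutation equivariance: same seed, permuted samples
  perm <- rev(seq_len(n_samples(gm)))
  fit_p <- fit_admixture(gm[perm, ], K = 2, restarts = 1, seed = 4)
  al <- align_clusters(fit_p$Q, fit$Q[perm, ])
  expect_lt(attr(al, "mae"), 1e-3)
})

test_that("admixture recovery on a structured simulated panel", {
  cfg <- sim_config(K = 3, F_k = 0.3, alpha = 0.1, n_per_pop = 30,
                    L = 1000, seed = 2)
  sim <- simulate_panel(cfg)
  fit <- fit_admixture(sim$genotypes, K = 3, restarts = 2, seed = 11)
  perm <- align_clusters(fit$Q, sim$truth$Q_true)
  expect_lte(attr(perm, "mae"), 0.05)
})

test_that("membership classification follows the q >= 0.5 rule with ties admixed", {
  fit <- structure(list(K = 3, Q = rbind(a = c(0.9, 0.1, 0),
                                         b = c(0.45, 0.35, 0.20),
                                         c = c(0.5, 0.5, 0),
                                         d = c(0.5, 0.3, 0.2))),
                   class = "admixture_fit")
  colnames(fit$Q) <- paste0("K", 1:3)
  out <- classify_membership(fit)
  expect_equal(unname(out$cluster), c("K1", "admixed", "admixed", "K1"))
})

test_that("cluster F_ST has its fixed points and recovers divergence", {
  F_ <- rbind(rep(0.3, 10), rep(0.3, 10))
  expect_equal(cluster_fst(F_)[1, 2], 0)
  F2 <- rbind(rep(1 - 1e-6, 10), rep(1e-6, 10))
  expect_equal(cluster_fst(F2)[1, 2], 1, tolerance = 1e-4)
  expect_error(cluster_fst(F_[1, , drop = FALSE]), "K >= 2")
  # two Balding-Nichols populations at F = 0.2: fitted-F Hudson ratio
  cfg <- sim_config(K = 2, n_per_pop = 100, L = 5000, F_k = 0.2,
                    selfing = 0, missing_rate = 0, n_private = 0,
                    n_duplicates = 0, admixed_fraction = 0,
                    n_founders = 200, switch_rate_per_bp = 1, seed = 13)
  sim <- simulate_panel(cfg)
  fit <- fit_admixture(sim$genotypes, K = 2, restarts = 1, seed = 5,
                       tol = 1e-3)
  fst <- cluster_fst(fit)[1, 2]
  expect_equal(fst, 0.2, tolerance = 0.03 / 0.2)
})

test_that("two-fold cross-validation plumbing returns per-fold scores", {
  withr::with_seed(51, gm <- random_gm(10, 60, miss = 0.1))
  cv <- cross_validate_K(gm, K_range = 1:2, folds = 2, seed = 6,
                         max_iter = 200)
  expect_equal(nrow(cv$fold_scores), 4L)
  expect_equal(sort(unique(cv$fold_scores$fold)), 1:2)
  expect_true(all(is.finite(cv$cv$cv_error)))
  expect_true(cv$best_K %in% 1:2)
})

test_that("cross-validation is flat-to-increasing on an unstructured panel", {
  cfg <- sim_config(K = 1, n_per_pop = 60, L = 600, selfing = 0,
                    n_founders = 120, switch_rate_per_bp = 1,
                    missing_rate = 0, n_private = 0, n_duplicates = 0,
                    seed = 53)
  gm <- simulate_panel(cfg)$genotypes
  cv <- cross_validate_K(gm, K_range = 1:3, folds = 4, seed = 7)
  expect_equal(cv$best_K, 1L)
})

test_that("bootstrap standard errors are small for well-separated populations", {
  d <- rbind(matrix(0L, 5, 60), matrix(2L, 5, 60))
  gm <- make_gm(d)
  fit <- fit_admixture(gm, K = 2, restarts = 2, seed = 8)
  se <- bootstrap_q_se(gm, fit, n_boot = 10, seed = 9, max_iter = 200)
  expect_equal(dim(se), dim(fit$Q))
  expect_lt(max(se), 0.05)
})
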