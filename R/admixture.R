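#' Fit the admixture model by EM
#'
#' Maximum-likelihood estimation of the unsupervised admixture model: each
#' genotype is `g_ij ~ Binomial(2, pi_ij)` with `pi_ij = sum_k q_ik f_kj`,
#' where `Q` holds per-accession membership proportions and `F` per-cluster
#' allele frequencies. Parameters are estimated by block EM (allele-copy
#' responsibilities), which makes the log-likelihood non-decreasing at every
#' iteration; the best of `restarts` random initialisations is returned.
#' Clusters are ordered by total membership for reporting, so labels are
#' deterministic given the seed.
#'
#' @param gm A [geno_matrix()] with at least one polymorphic locus.
#' @param K Number of ancestral clusters (1 <= K <= n).
#' @param max_iter Maximum EM iterations (default 2000).
#' @param tol Convergence tolerance on the log-likelihood change.
#' @param restarts Number of random initialisations.
#' @param seed Optional seed.
#' @return An object of class `admixture_fit`: list with `K`, `Q` (n x K,
#'   rows sum to 1), `F` (K x L in `[1e-6, 1-1e-6]`), `loglik` (trace),
#'   `converged`, `n_iter`, `seed`, `samples`, `loci`.
#' @export
fit_admixture <- function(gm, K, max_iter = 2000, tol = 1e-4, restarts = 3,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- as.integer(K)
  n <- n_samples(gm)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K cannot exceed the number of samples")
  G <- gm$dosage
  G[is.na(G)] <- -1L
  storage.mode(G) <- "integer"
  p_obs <- colMeans(gm$dosage, na.rm = TRUE) / 2
  if (all(p_obs %in% c(0, 1) | is.na(p_obs))) {
    stop("matrix has no polymorphic locus")
  }
  p_obs[is.na(p_obs)] <- 0.5
  best <- NULL
  for (r in seq_len(restarts)) {
    if (r == 1L && K > 1L) {
      # spectral warm start: k-means partition on leading PCs seeds F with
      # distinct frequency profiles, avoiding the symmetric EM saddle
      init <- init_partition(gm, K)
      Q0 <- matrix(0.1 / K, n, K)
      Q0[cbind(seq_len(n), init)] <- 0.9 + 0.1 / K
      F0 <- t(vapply(seq_len(K), function(k) {
        dk <- gm$dosage[init == k, , drop = FALSE]
        fk <- colMeans(dk, na.rm = TRUE) / 2
        fk[is.na(fk)] <- p_obs[is.na(fk)]
        fk
      }, numeric(ncol(G))))
    } else {
      g0 <- matrix(rgamma(n * K, shape = 1), n, K)
      Q0 <- g0 / rowSums(g0)
      if (K == 1L) Q0 <- matrix(1, n, 1)
      noise <- matrix(runif(K * length(p_obs), -0.1, 0.1), K)
      F0 <- matrix(rep(p_obs, each = K) + noise, K)
    }
    F0 <- matrix(pmin(pmax(F0, 1e-6), 1 - 1e-6), K)
    fit <- admix_em_cpp(G, Q0, F0, max_iter, tol)
    if (is.null(best) || tail(fit$loglik, 1) > tail(best$loglik, 1)) {
      best <- fit
    }
  }
  o <- order(colSums(best$Q), decreasing = TRUE)
  Q <- best$Q[, o, drop = FALSE]
  F_ <- best$F[o, , drop = FALSE]
  dimnames(Q) <- list(gm$samples, paste0("K", seq_len(K)))
  dimnames(F_) <- list(paste0("K", seq_len(K)), gm$loci$id)
  structure(list(K = K, Q = Q, F = F_, loglik = best$loglik,
                 converged = best$converged,
                 n_iter = length(best$loglik), seed = seed,
                 samples = gm$samples, loci = gm$loci$id),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf(
    "<admixture_fit> K = %d, %d samples x %d loci\n  loglik = %.2f (%d iterations, %s)\n",
    x$K, nrow(x$Q), ncol(x$F), tail(x$loglik, 1), x$n_iter,
    if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

#' Cross-validated choice of the number of ancestral clusters
#'
#' The non-missing genotype entries are partitioned at random into `folds`
#' masks. For each fold the masked entries are hidden, the model refitted,
#' and the held-out entries scored by their mean binomial deviance
#' `-[g log(pi) + (2 - g) log(1 - pi)] / 2`; `CV(K)` is the mean over folds
#' and the selected `K` minimises it. This is the entry-masking
#' cross-validation scheme of the ADMIXTURE software (ten folds by default).
#'
#' @param gm A [geno_matrix()].
#' @param K_range Candidate values of K.
#' @param folds Number of folds (>= 2).
#' @param seed Optional seed.
#' @param restarts,max_iter,tol Passed to [fit_admixture()].
#' @return An object of class `cv_result`: list with `cv` (tibble `K`,
#'   `cv_error`, `se`), `fold_scores` (tibble `K`, `fold`, `score`), `folds`,
#'   `best_K`.
#' @export
cross_validate_K <- function(gm, K_range = 1:8, folds = 10, seed = NULL,
                             restarts = 1, max_iter = 2000, tol = 1e-4) {
  if (!is.null(seed)) set.seed(seed)
  if (folds < 2L) stop("folds must be >= 2")
  G <- gm$dosage
  nm_idx <- which(!is.na(G), arr.ind = TRUE)
  if (nrow(nm_idx) < folds) stop("fewer non-missing entries than folds")
  fold_id <- sample(rep(seq_len(folds), length.out = nrow(nm_idx)))
  Gint <- G; Gint[is.na(Gint)] <- -1L
  storage.mode(Gint) <- "integer"
  scores <- purrr::map_dfr(seq_len(folds), function(f) {
    mask <- nm_idx[fold_id == f, , drop = FALSE]
    if (nrow(mask) == 0L) stop("fold ", f, " has zero masked entries")
    Gf <- gm$dosage
    Gf[mask] <- NA_integer_
    gm_f <- gm
    gm_f$dosage <- Gf
    purrr::map_dfr(K_range, function(K) {
      fit <- fit_admixture(gm_f, K, max_iter = max_iter, tol = tol,
                           restarts = restarts)
      tibble(K = K, fold = f,
             score = admix_heldout_deviance_cpp(
               Gint, fit$Q, fit$F, mask))
    })
  })
  cv <- scores |>
    dplyr::group_by(.data$K) |>
    dplyr::summarise(cv_error = mean(.data$score),
                     se = sd(.data$score) / sqrt(dplyr::n()),
                     .groups = "drop")
  structure(list(cv = cv, fold_scores = scores, folds = folds,
                 best_K = cv$K[which.min(cv$cv_error)]),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d-fold CV over K in {%s}; best K = %d\n",
              x$folds, paste(range(x$cv$K), collapse = ".."), x$best_K))
  invisible(x)
}

#' Classify accessions by their highest membership coefficient
#'
#' An accession is assigned to its argmax cluster when the highest membership
#' coefficient reaches `q_min`; below that (or on an exact tie between top
#' clusters) it is classified `"admixed"`, matching the q < 0.5 rule.
#'
#' @param fit An [fit_admixture()] result.
#' @param q_min Minimum top membership for assignment (default 0.5).
#' @return A tibble with `sample_id`, `cluster` (e.g. `"K1"` or
#'   `"admixed"`), `q_max`.
#' @export
classify_membership <- function(fit, q_min = 0.5) {
  Q <- fit$Q
  q_max <- apply(Q, 1, max)
  top <- apply(Q, 1, function(r) {
    w <- which(r == max(r))
    if (length(w) > 1L) NA_integer_ else w  # tie -> admixed
  })
  cluster <- ifelse(!is.na(top) & q_max >= q_min,
                    colnames(Q)[replace(top, is.na(top), 1L)], "admixed")
  tibble(sample_id = rownames(Q), cluster = unname(cluster),
         q_max = unname(q_max))
}

#' Pairwise F_ST between inferred clusters
#'
#' Hudson-type ratio of averages computed directly from the inferred cluster
#' allele frequencies (which are model parameters, not samples, so no
#' finite-sample correction applies):
#' `F_ST(k, l) = sum_j (f_kj - f_lj)^2 / sum_j [f_kj (1 - f_lj) + f_lj (1 - f_kj)]`.
#'
#' @param fit An [fit_admixture()] result with `K >= 2`, or a K x L
#'   frequency matrix.
#' @return A symmetric K x K matrix with zero diagonal (`NA` where the
#'   denominator vanishes).
#' @export
cluster_fst <- function(fit) {
  F_ <- if (inherits(fit, "admixture_fit")) fit$F else as.matrix(fit)
  K <- nrow(F_)
  if (K < 2L) stop("cluster_fst needs K >= 2")
  out <- matrix(0, K, K, dimnames = list(rownames(F_), rownames(F_)))
  for (k in seq_len(K - 1)) {
    for (l in (k + 1):K) {
      num <- sum((F_[k, ] - F_[l, ])^2)
      den <- sum(F_[k, ] * (1 - F_[l, ]) + F_[l, ] * (1 - F_[k, ]))
      out[k, l] <- out[l, k] <- if (den > 0) num / den else NA_real_
    }
  }
  out
}

#' Align cluster labels between two fits (or fit and truth)
#'
#' Greedy matching on the correlation of cluster allele-frequency vectors
#' (or, if `by = "Q"`, on membership-column correlation); for `K <= 7` an
#' exhaustive search over permutations minimising mean |Q - Q_ref| is used.
#' Resolves label switching before comparing memberships across restarts,
#' folds, or against simulator truth.
#'
#' @param Q Membership matrix to align (n x K).
#' @param Q_ref Reference membership matrix (n x K).
#' @return The permutation `perm` (such that `Q[, perm]` aligns with
#'   `Q_ref`) with attribute `"mae"` (mean absolute error after alignment).
#' @export
align_clusters <- function(Q, Q_ref) {
  K <- ncol(Q)
  stopifnot(ncol(Q_ref) == K, nrow(Q_ref) == nrow(Q))
  if (K <= 7L) {
    perms <- permutations_of(K)
    maes <- vapply(perms, function(p) mean(abs(Q[, p] - Q_ref)), 0)
    best <- perms[[which.min(maes)]]
    attr(best, "mae") <- min(maes)
    return(best)
  }
  # greedy: repeatedly match the most-correlated remaining column pair
  cm <- suppressWarnings(cor(Q, Q_ref))
  cm[is.na(cm)] <- -Inf
  perm <- integer(K)
  used_q <- used_r <- rep(FALSE, K)
  for (step in seq_len(K)) {
    idx <- which(cm == max(cm[!used_q, !used_r, drop = FALSE]),
                 arr.ind = TRUE)
    idx <- idx[!used_q[idx[, 1]] & !used_r[idx[, 2]], , drop = FALSE][1, ]
    perm[idx[2]] <- idx[1]
    used_q[idx[1]] <- used_r[idx[2]] <- TRUE
    cm[idx[1], ] <- -Inf
    cm[, idx[2]] <- -Inf
  }
  attr(perm, "mae") <- mean(abs(Q[, perm] - Q_ref))
  perm
}

# k-means partition of samples on leading principal components of the
# mean-imputed dosage matrix (initialisation helper)
init_partition <- function(gm, K) {
  X <- gm$dosage
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.na(mu)] <- 1
  idx <- which(is.na(X))
  if (length(idx)) X[idx] <- mu[(idx - 1) %/% nrow(X) + 1]
  X <- sweep(X, 2, colMeans(X))
  ndim <- min(max(K - 1, 2), 10, nrow(X) - 1)
  pcs <- tryCatch(svd(X, nu = ndim, nv = 0)$u[, seq_len(ndim),
                                              drop = FALSE] ,
                  error = function(e) matrix(rowMeans(X), ncol = 1))
  km <- tryCatch(
    suppressWarnings(kmeans(pcs, centers = kmeanspp_centers(pcs, K),
                            iter.max = 50, algorithm = "Lloyd")),
    error = function(e) NULL)
  if (is.null(km)) return(sample.int(K, nrow(X), replace = TRUE))
  km$cluster
}

# all permutations of 1..k as a list
permutations_of <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- permutations_of(k - 1L)
  out <- vector("list", k * length(sub))
  m <- 0L
  for (p in sub) {
    for (pos in seq_len(k)) {
      m <- m + 1L
      out[[m]] <- c(if (pos > 1) p[seq_len(pos - 1)], k,
                    if (pos <= length(p)) p[pos:length(p)])
    }
  }
  out
}

#' Bootstrap standard errors for membership coefficients
#'
#' Optional loci-bootstrap: refits the model on panels resampled over loci
#' and reports per-entry standard errors of Q after label alignment to the
#' original fit. Off by default in analyses because it is expensive.
#'
#' @param gm A [geno_matrix()].
#' @param fit The original [fit_admixture()] result.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Optional seed.
#' @param ... Passed to [fit_admixture()].
#' @return A matrix of standard errors, same shape as `fit$Q`.
#' @export
bootstrap_q_se <- function(gm, fit, n_boot = 100, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  L <- n_loci(gm)
  reps <- array(NA_real_, c(nrow(fit$Q), fit$K, n_boot))
  for (b in seq_len(n_boot)) {
    jj <- sample.int(L, L, replace = TRUE)
    gm_b <- gm[, jj]
    fb <- fit_admixture(gm_b, fit$K, restarts = 1, ...)
    perm <- align_clusters(fb$Q, fit$Q)
    reps[, , b] <- fb$Q[, perm]
  }
  se <- apply(reps, c(1, 2), sd)
  dimnames(se) <- dimnames(fit$Q)
  se
}
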