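#' Ward dendrogram on an allele-sharing distance
#'
#' Agglomerative clustering with the Ward.D2 convention (Lance-Williams
#' update on squared distances); merge heights are non-decreasing.
#'
#' @param d Symmetric dissimilarity matrix (from [dissimilarity()]) or a
#'   `dist` object.
#' @return An [stats::hclust] object.
#' @export
ward_tree <- function(d) {
  if (!inherits(d, "dist")) d <- as.dist(d)
  if (attr(d, "Size") < 2L) stop("need at least two accessions")
  hclust(d, method = "ward.D2")
}

#' Export a dendrogram as Newick
#'
#' Branch lengths are merge-height differences (via [ape::as.phylo]).
#'
#' @param hc An [stats::hclust] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(hc, path) {
  if (!requireNamespace("ape", quietly = TRUE)) {
    stop("the 'ape' package is required for Newick export")
  }
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}

#' Classical multidimensional scaling (principal coordinates)
#'
#' Double-centres the squared distance matrix, eigendecomposes, and returns
#' coordinates `eigenvector * sqrt(eigenvalue)` for the leading positive
#' eigenvalues. Negative eigenvalues are reported but never used; if fewer
#' positive eigenvalues exist than `dims`, the embedding is truncated with a
#' warning. Sign convention: on each axis the largest-magnitude loading is
#' made positive, so output is reproducible across platforms.
#'
#' @param d Symmetric distance matrix or `dist`.
#' @param dims Number of requested dimensions (>= 1).
#' @return An object of class `radpop_mds`: list with `points` (tibble
#'   `sample_id`, `A1`, `A2`, ...), `eig` (all eigenvalues) and `dims`.
#' @export
classical_mds <- function(d, dims = 2) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  n <- nrow(d)
  fit <- cmdscale(as.dist(d), k = min(dims, n - 1), eig = TRUE)
  eig <- fit$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (npos < dims) {
    warning("only ", npos, " positive eigenvalue(s); embedding truncated")
  }
  k <- min(dims, max(npos, 1L), ncol(fit$points))
  pts <- fit$points[, seq_len(k), drop = FALSE]
  for (a in seq_len(ncol(pts))) {
    if (pts[which.max(abs(pts[, a])), a] < 0) pts[, a] <- -pts[, a]
  }
  colnames(pts) <- paste0("A", seq_len(ncol(pts)))
  structure(list(
    points = dplyr::bind_cols(tibble(sample_id = rownames(d)),
                              as_tibble(pts)),
    eig = eig, dims = ncol(pts)
  ), class = "radpop_mds")
}

#' @export
print.radpop_mds <- function(x, ...) {
  pos <- x$eig[x$eig > 0]
  cat(sprintf("<radpop_mds> %d samples, %d axes\n",
              nrow(x$points), x$dims))
  cat(sprintf("  variance on kept axes: %.1f%%\n",
              100 * sum(x$eig[seq_len(x$dims)]) / sum(pos)))
  invisible(x)
}

# k-means++ seeding (Arthur & Vassilvitskii) on a coordinate matrix
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x),
                              byrow = TRUE))^2)
    for (m in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[m] <- sample.int(n, 1, prob = prob)
      d2m <- rowSums((x - matrix(x[centers[m], ], n, ncol(x),
                                 byrow = TRUE))^2)
      d2 <- pmin(d2, d2m)
    }
  }
  x[centers, , drop = FALSE]
}

#' K-means over a range of k with BIC model selection
#'
#' For each `k`, the best of `restarts` Lloyd k-means runs seeded by
#' k-means++ is kept and scored by the spherical-Gaussian
#' hard-assignment BIC (the X-means criterion): with a pooled variance
#' `sigma2 = WSS / (d (n - k))`, the model log-likelihood is
#' `sum_c n_c log(n_c / n) - (n d / 2) log(2 pi sigma2) - d (n - k) / 2`
#' and `BIC = -2 loglik + (k - 1 + k d + 1) log(n)`; the selected number of
#' clusters minimises BIC. The multinomial assignment term is what stops a
#' pure within-cluster-variance criterion from splitting indefinitely. This
#' is the non-parametric structure analysis (AWclust-style) applied to
#' leading MDS coordinates of the allele-sharing distance.
#'
#' @param coords Numeric matrix or data frame of coordinates (samples x
#'   dims), e.g. `classical_mds(d, 10)$points` without the ID column.
#' @param k_range Integer vector of candidate cluster numbers.
#' @param restarts Random restarts per `k`.
#' @param seed Optional seed for reproducibility.
#' @return An object of class `kmeans_bic`: list with `solutions` (tibble
#'   `k`, `wss`, `bic`, list column `assignment`), `best_k`, and `best`
#'   (assignment vector for `best_k`).
#' @export
kmeans_bic <- function(coords, k_range = 1:10, restarts = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- as.matrix(dplyr::select(as.data.frame(coords),
                               dplyr::where(is.numeric)))
  n <- nrow(x); dd <- ncol(x)
  k_range <- k_range[k_range >= 1 & k_range < n]
  sols <- purrr::map_dfr(k_range, function(k) {
    if (k == 1L) {
      wss <- sum(scale(x, scale = FALSE)^2)
      assign <- rep(1L, n)
    } else {
      best <- NULL
      for (r in seq_len(restarts)) {
        km <- tryCatch(
          suppressWarnings(kmeans(x, centers = kmeanspp_centers(x, k),
                                  iter.max = 100, algorithm = "Lloyd")),
          error = function(e) NULL)  # empty-cluster collapse: restart
        if (is.null(km)) next
        if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
      }
      if (is.null(best)) {
        # persistent collapse: this k is not realisable on these coordinates
        return(tibble(k = k, wss = NA_real_, bic = NA_real_,
                      assignment = list(rep(NA_integer_, n))))
      }
      wss <- best$tot.withinss
      assign <- best$cluster
    }
    sizes <- tabulate(assign, nbins = k)
    sigma2 <- max(wss / (dd * max(n - k, 1L)), .Machine$double.eps)
    ll <- sum(sizes[sizes > 0] * log(sizes[sizes > 0] / n)) -
      n * dd / 2 * log(2 * pi * sigma2) - dd * (n - k) / 2
    n_par <- (k - 1) + k * dd + 1
    tibble(k = k, wss = wss, bic = -2 * ll + n_par * log(n),
           assignment = list(assign))
  })
  best_k <- sols$k[which.min(sols$bic)]
  structure(list(solutions = sols, best_k = best_k,
                 best = sols$assignment[[which.min(sols$bic)]]),
            class = "kmeans_bic")
}

#' @export
print.kmeans_bic <- function(x, ...) {
  cat(sprintf("<kmeans_bic> k in {%s}; best k = %d (BIC)\n",
              paste(range(x$solutions$k), collapse = ".."), x$best_k))
  invisible(x)
}
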