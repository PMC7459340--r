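#' Composite r-squared between two loci
#'
#' Squared Pearson correlation of dosages over co-non-missing samples (the
#' composite, phase-free LD estimator; in highly homozygous material it
#' coincides with the haplotype r2). Undefined (`NA`) when fewer than two
#' samples are co-called or either locus is monomorphic on the shared subset.
#'
#' @param col_a,col_b Dosage vectors (0/1/2/NA) of equal length.
#' @return r2 in \[0, 1\], or `NA`.
#' @export
composite_r2 <- function(col_a, col_b) {
  ok <- !is.na(col_a) & !is.na(col_b)
  if (sum(ok) < 2L) return(NA_real_)
  a <- col_a[ok]; b <- col_b[ok]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)^2
}

# all intra-chromosomal pairs within max_dist_bp, with r2 (NA dropped)
ld_pairs <- function(gm, max_dist_bp = 3e5) {
  purrr::map_dfr(unique(gm$loci$chrom), function(ch) {
    jj <- which(gm$loci$chrom == ch)
    if (length(jj) < 2L) return(tibble())
    pos <- gm$loci$pos[jj]
    r2m <- suppressWarnings(
      cor(gm$dosage[, jj, drop = FALSE],
          use = "pairwise.complete.obs"))^2
    idx <- which(upper.tri(r2m), arr.ind = TRUE)
    dist_bp <- abs(pos[idx[, 2]] - pos[idx[, 1]])
    keep <- dist_bp <= max_dist_bp
    tibble(chrom = ch,
           locus_a = gm$loci$id[jj][idx[keep, 1]],
           locus_b = gm$loci$id[jj][idx[keep, 2]],
           dist_bp = dist_bp[keep],
           r2 = r2m[idx[keep, , drop = FALSE]])
  })
}

#' LD decay curve
#'
#' Scores every intra-chromosomal locus pair up to `max_dist_bp` within the
#' selected samples, bins pairs by distance and reports per-bin mean r2 and
#' pair counts. The default binning uses 100 bp bins up to 10 kb and 1 kb
#' bins beyond. A half-decay distance is also reported: the smallest bin
#' midpoint at which the smoothed (3-bin running mean) curve drops to the
#' midpoint between its maximum bin mean and the far-field level (mean of
#' the last decile of bins).
#'
#' @param gm A [geno_matrix()] with sorted loci.
#' @param max_dist_bp Maximum pair distance (default 300 kb).
#' @param breaks Bin edges in bp, or `NULL` for the default scheme.
#' @param group_mask Optional logical/index vector selecting the samples of
#'   one germplasm group (>= 2 samples).
#' @param group_label Label stored on the curve.
#' @return A tibble of class `decay_curve` with `bin_lo`, `bin_hi`, `mid`,
#'   `mean_r2`, `n_pairs`, `group`; attributes `half_decay_bp` and
#'   `background_r2` (far-field mean).
#' @export
decay_curve <- function(gm, max_dist_bp = 3e5, breaks = NULL,
                        group_mask = NULL, group_label = "all") {
  if (!is.null(group_mask)) {
    gm <- gm[group_mask, ]
    if (n_samples(gm) < 2L) stop("group must contain at least two samples")
  }
  if (is.null(breaks)) {
    breaks <- unique(c(seq(0, min(1e4, max_dist_bp), by = 100),
                       if (max_dist_bp > 1e4)
                         seq(1.1e4, max_dist_bp, by = 1e3),
                       max_dist_bp))
    breaks <- sort(unique(pmin(breaks, max_dist_bp)))
  }
  pairs <- ld_pairs(gm, max_dist_bp)
  pairs <- pairs[!is.na(pairs$r2), , drop = FALSE]
  bin <- cut(pairs$dist_bp, breaks, include.lowest = TRUE, right = TRUE)
  lv <- levels(cut(numeric(), breaks, include.lowest = TRUE, right = TRUE))
  mean_r2 <- tapply(pairs$r2, factor(bin, levels = lv), mean)
  n_pairs <- tapply(rep(1, nrow(pairs)), factor(bin, levels = lv), sum)
  n_pairs[is.na(n_pairs)] <- 0
  out <- tibble(
    bin_lo = head(breaks, -1), bin_hi = tail(breaks, -1),
    mid = (head(breaks, -1) + tail(breaks, -1)) / 2,
    mean_r2 = as.numeric(mean_r2), n_pairs = as.integer(n_pairs),
    group = group_label
  )
  # half-decay: smoothed curve falling to midway between peak and far field
  sm <- smooth3(out$mean_r2)
  far_n <- max(1L, floor(nrow(out) / 10))
  far <- mean(tail(sm[!is.na(sm)], far_n))
  peak <- max(sm, na.rm = TRUE)
  target <- (peak + far) / 2
  below <- which(!is.na(sm) & sm <= target)
  half <- if (length(below)) out$mid[min(below)] else NA_real_
  attr(out, "half_decay_bp") <- half
  attr(out, "background_r2") <- far
  class(out) <- c("decay_curve", class(out))
  out
}

smooth3 <- function(x) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    w <- max(1, i - 1):min(n, i + 1)
    if (all(is.na(x[w]))) NA_real_ else mean(x[w], na.rm = TRUE)
  }, 0)
}

#' Prune loci in high linkage disequilibrium
#'
#' Sliding-window pruning: within each window of `window_snps` surviving
#' loci, while any pair exceeds `r2_max`, the pair member with the lower MAF
#' is removed (tie: the higher locus index); the window then advances by
#' `step_snps`. Deterministic and idempotent.
#'
#' @param gm A [geno_matrix()] with sorted loci.
#' @param window_snps Window size in SNPs (default 50).
#' @param step_snps Step size in SNPs (default 5).
#' @param r2_max Maximum tolerated composite r2 (default 0.2).
#' @return The pruned [geno_matrix()].
#' @export
ld_prune <- function(gm, window_snps = 50, step_snps = 5, r2_max = 0.2) {
  keep <- rep(TRUE, n_loci(gm))
  ls <- locus_stats(gm)
  maf <- ls$maf
  maf[is.na(maf)] <- 0
  for (ch in unique(gm$loci$chrom)) {
    jj <- which(gm$loci$chrom == ch)
    start <- 1L
    repeat {
      alive <- jj[keep[jj]]
      if (length(alive) < 2L || start > length(alive)) break
      win <- alive[start:min(start + window_snps - 1L, length(alive))]
      if (length(win) >= 2L) {
        r2m <- suppressWarnings(
          cor(gm$dosage[, win, drop = FALSE],
              use = "pairwise.complete.obs"))^2
        r2m[is.na(r2m)] <- 0
        diag(r2m) <- 0
        repeat {
          mx <- max(r2m)
          if (mx <= r2_max) break
          ij <- which(r2m == mx, arr.ind = TRUE)[1, ]
          a <- win[ij[1]]; b <- win[ij[2]]
          drop_loc <- if (maf[a] < maf[b]) a
                      else if (maf[b] < maf[a]) b
                      else max(a, b)
          keep[drop_loc] <- FALSE
          w <- which(win == drop_loc)
          r2m[w, ] <- 0
          r2m[, w] <- 0
        }
      }
      if (start + window_snps - 1L >= length(alive)) break
      start <- start + step_snps
    }
  }
  gm[, keep]
}
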