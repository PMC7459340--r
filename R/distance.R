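#' Allele-sharing dissimilarity matrix
#'
#' The dissimilarity index between two accessions is the proportion of
#' unmatching alleles over their co-non-missing loci:
#' `mean(|g_a - g_b| / 2)`. It equals 1 minus the allele-sharing proportion,
#' is 0 exactly for genotypically identical (redundant) accessions and 1 for
#' accessions homozygous for opposite alleles everywhere.
#'
#' @param gm A [geno_matrix()].
#' @param allow_undefined Return `NA` for pairs that share no co-non-missing
#'   locus instead of erroring.
#' @return A symmetric `n x n` numeric matrix with zero diagonal and sample
#'   IDs as dimnames.
#' @export
dissimilarity <- function(gm, allow_undefined = FALSE) {
  d <- gm$dosage
  A0 <- (!is.na(d) & d == 0L) + 0
  A1 <- (!is.na(d) & d == 1L) + 0
  A2 <- (!is.na(d) & d == 2L) + 0
  M <- A0 + A1 + A2                       # non-missing indicator
  shared <- M %*% t(M)
  # sum over shared loci of |g_a - g_b|
  absdiff <- (A0 %*% t(A1) + A1 %*% t(A0)) +
    2 * (A0 %*% t(A2) + A2 %*% t(A0)) +
    (A1 %*% t(A2) + A2 %*% t(A1))
  D <- absdiff / (2 * shared)
  if (any(shared == 0)) {
    bad <- which(shared == 0 & upper.tri(shared), arr.ind = TRUE)
    if (!allow_undefined && nrow(bad)) {
      stop("pairs with no co-non-missing locus: ",
           paste(apply(bad, 1, function(ij)
             paste(gm$samples[ij], collapse = "/")), collapse = ", "))
    }
    D[shared == 0] <- NA_real_
  }
  diag(D) <- 0
  dimnames(D) <- list(gm$samples, gm$samples)
  D
}

#' Scan a dissimilarity matrix for (near-)redundant accession pairs
#'
#' @param d Symmetric dissimilarity matrix (from [dissimilarity()]).
#' @param threshold Report all unordered pairs with dissimilarity strictly
#'   below this value. Default 0.005 flags near-duplicates; exact zeros are
#'   additionally labelled redundant.
#' @return A tibble sorted by ascending dissimilarity: `sample_a`,
#'   `sample_b`, `dissimilarity`, `redundant`.
#' @export
redundancy_scan <- function(d, threshold = 0.005) {
  idx <- which(upper.tri(d) & !is.na(d) & d < threshold, arr.ind = TRUE)
  out <- tibble(
    sample_a = rownames(d)[idx[, 1]],
    sample_b = colnames(d)[idx[, 2]],
    dissimilarity = d[idx],
    redundant = d[idx] == 0
  )
  dplyr::arrange(out, .data$dissimilarity, .data$sample_a)
}
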