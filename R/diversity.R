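#' ALT allele frequency of a dosage vector
#'
#' `p = sum(dosage) / (2 * number of non-missing calls)`. Errors on an
#' all-missing column.
#'
#' @param column Dosage vector (0/1/2/NA).
#' @return The ALT allele frequency.
#' @export
allele_freq <- function(column) {
  nm <- sum(!is.na(column))
  if (nm == 0L) stop("allele frequency undefined: all calls missing")
  sum(column, na.rm = TRUE) / (2 * nm)
}

#' Polymorphic information content (biallelic)
#'
#' Botstein's PIC for a biallelic locus:
#' `1 - (p^2 + q^2) - 2 p^2 q^2` with `q = 1 - p`. Symmetric in `p` and `q`;
#' its maximum, 0.375, is attained at `p = 0.5`.
#'
#' @param p Allele frequency (vectorised), in \[0, 1\].
#' @return PIC value(s).
#' @examples
#' pic(0.5)  # 0.375, the biallelic maximum
#' @export
pic <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  q <- 1 - p
  1 - (p^2 + q^2) - 2 * p^2 * q^2
}

#' Nei gene diversity (expected heterozygosity, biallelic)
#'
#' `1 - p^2 - q^2 = 2 p q`; maximum 0.5 at `p = 0.5`. Note the analytic
#' ranges differ: gene diversity spans \[0, 0.5\] while biallelic PIC spans
#' \[0, 0.375\].
#'
#' @inheritParams pic
#' @return Gene diversity value(s).
#' @export
gene_diversity <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  2 * p * (1 - p)
}

#' Observed heterozygosity of a locus
#'
#' Fraction of heterozygous calls among non-missing calls at one locus.
#'
#' @param column Dosage vector (0/1/2/NA).
#' @return Fraction in \[0, 1\].
#' @export
observed_het <- function(column) {
  nm <- sum(!is.na(column))
  if (nm == 0L) stop("observed heterozygosity undefined: all calls missing")
  sum(column == 1L, na.rm = TRUE) / nm
}

#' Per-sample heterozygosity (percent)
#'
#' `100 * #(dosage == 1) / #non-missing` for one accession's dosage row.
#'
#' @param row Dosage vector (0/1/2/NA).
#' @return Percentage in \[0, 100\].
#' @export
sample_heterozygosity <- function(row) {
  nm <- sum(!is.na(row))
  if (nm == 0L) stop("sample heterozygosity undefined: all calls missing")
  100 * sum(row == 1L, na.rm = TRUE) / nm
}

#' Per-locus diversity statistics
#'
#' @param gm A [geno_matrix()].
#' @return A tibble with one row per locus: `chrom`, `pos`, `id`, `p_alt`,
#'   `maf`, `pic`, `gene_diversity`, `ho` (observed heterozygosity) and
#'   `call_rate`.
#' @export
locus_stats <- function(gm) {
  d <- gm$dosage
  nm <- unname(colSums(!is.na(d)))
  p <- ifelse(nm > 0, unname(colSums(d, na.rm = TRUE)) / (2 * nm),
              NA_real_)
  tibble(
    chrom = gm$loci$chrom, pos = gm$loci$pos, id = gm$loci$id,
    p_alt = p, maf = pmin(p, 1 - p),
    pic = pic(p), gene_diversity = gene_diversity(p),
    ho = ifelse(nm > 0, unname(colSums(d == 1L, na.rm = TRUE)) / nm,
                NA_real_),
    call_rate = nm / n_samples(gm)
  )
}

#' Per-sample summary statistics
#'
#' @param gm A [geno_matrix()].
#' @return A tibble with one row per accession: `sample_id`, `n_nonmissing`,
#'   `n_alt_carrying` (loci with at least one ALT allele) and `het_pct`.
#'   Samples with zero non-missing calls are flagged with `NA` heterozygosity.
#' @export
sample_stats <- function(gm) {
  d <- gm$dosage
  nm <- unname(rowSums(!is.na(d)))
  tibble(
    sample_id = gm$samples,
    n_nonmissing = nm,
    n_alt_carrying = unname(rowSums(d >= 1L, na.rm = TRUE)),
    het_pct = ifelse(nm > 0,
                     100 * unname(rowSums(d == 1L, na.rm = TRUE)) / nm,
                     NA_real_)
  )
}

#' Within-group frequency of the panel-global minor allele
#'
#' Allele orientation (which allele counts as minor) is fixed once from the
#' full panel, then that same allele's frequency is reported within the
#' group — so cross-group contrasts compare the same allele, and a group's
#' value may exceed 0.5. Loci with no non-missing calls in the group are
#' `NA`.
#'
#' @param gm A [geno_matrix()].
#' @param meta Metadata tibble ([read_metadata()]).
#' @param group A status label (see [status_levels]), or `NULL` for the whole
#'   panel.
#' @param complement Use the complement of `group` instead of the group.
#' @return A tibble with `chrom`, `pos`, `id`, `minor_is_alt`, `maf_group`
#'   (group frequency of the panel-global minor allele) and `n_calls`.
#' @export
group_maf <- function(gm, meta = NULL, group = NULL, complement = FALSE) {
  d <- gm$dosage
  p_all <- unname(colMeans(d, na.rm = TRUE)) / 2
  minor_is_alt <- is.na(p_all) | p_all <= 0.5
  if (is.null(group)) {
    sel <- rep(TRUE, n_samples(gm))
  } else {
    st <- meta$status[match(gm$samples, meta$sample_id)]
    sel <- !is.na(st) & st == group
    if (complement) sel <- !sel
    if (!any(sel)) stop("group selection is empty")
  }
  dg <- d[sel, , drop = FALSE]
  nm <- unname(colSums(!is.na(dg)))
  p_g <- ifelse(nm > 0, unname(colSums(dg, na.rm = TRUE)) / (2 * nm),
                NA_real_)
  tibble(
    chrom = gm$loci$chrom, pos = gm$loci$pos, id = gm$loci$id,
    minor_is_alt = minor_is_alt,
    maf_group = ifelse(minor_is_alt, p_g, 1 - p_g),
    n_calls = nm
  )
}

#' Hudson-type pairwise F_ST between two sample groups
#'
#' Ratio-of-averages Hudson estimator from sample allele frequencies with the
#' finite-sample correction on the numerator:
#' per locus `N = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D = p1(1-p2) + p2(1-p1)`, with `n` counted in alleles; F_ST is
#' `sum(N) / sum(D)` over loci where both groups have at least two alleles
#' called.
#'
#' @param gm A [geno_matrix()].
#' @param groups A vector over samples defining two groups (its two unique
#'   non-NA values), e.g. simulator population labels.
#' @return The Hudson F_ST estimate (scalar).
#' @export
hudson_fst <- function(gm, groups) {
  g <- as.factor(groups)
  lv <- levels(droplevels(g[!is.na(g)]))
  if (length(lv) != 2L) stop("hudson_fst needs exactly two groups")
  d1 <- gm$dosage[which(g == lv[1]), , drop = FALSE]
  d2 <- gm$dosage[which(g == lv[2]), , drop = FALSE]
  n1 <- 2 * colSums(!is.na(d1))
  n2 <- 2 * colSums(!is.na(d2))
  p1 <- colSums(d1, na.rm = TRUE) / n1
  p2 <- colSums(d2, na.rm = TRUE) / n2
  ok <- n1 >= 2 & n2 >= 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num[ok]) / sum(den[ok])
}
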