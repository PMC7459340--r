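#' Locus-presence filter
#'
#' Keeps loci genotyped in at least a fraction `r` of the accessions (the
#' Stacks `populations -r` criterion; `r = 0.75` retains loci represented in
#' at least 75% of the panel).
#'
#' @param gm A [geno_matrix()].
#' @param r Minimum fraction of non-missing calls, in (0, 1\].
#' @return A [geno_matrix()] with the surviving loci; sample set unchanged.
#' @export
presence_filter <- function(gm, r = 0.75) {
  stopifnot(r > 0, r <= 1)
  if (n_loci(gm) == 0L) return(gm)
  called <- colMeans(!is.na(gm$dosage))
  gm[, called >= r]
}

#' MAF and missingness filters
#'
#' Applies the staged quality control used for the high-quality SNP set:
#' minor allele frequency at least `maf_min` (computed on non-missing calls;
#' the threshold is inclusive) and then missing-call fraction at most
#' `miss_max`, each stage operating on the previous stage's survivors.
#'
#' @param gm A [geno_matrix()] (typically after [presence_filter()]).
#' @param maf_min Minimum minor allele frequency (inclusive), default 0.05.
#' @param miss_max Maximum missing fraction (inclusive), default 0.20.
#' @return A list with `genotypes` (filtered [geno_matrix()]) and `report`
#'   (tibble: one row per stage with `stage`, `n_in`, `n_out` and a list
#'   column `dropped` of locus IDs).
#' @export
maf_missing_filter <- function(gm, maf_min = 0.05, miss_max = 0.20) {
  stopifnot(maf_min >= 0, maf_min <= 1, miss_max >= 0, miss_max <= 1)
  d <- gm$dosage
  n_in <- n_loci(gm)
  p <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_maf <- !is.na(maf) & maf >= maf_min
  gm_maf <- gm[, keep_maf]
  miss <- colMeans(is.na(gm_maf$dosage))
  if (n_loci(gm_maf) == 0L) miss <- numeric()
  keep_miss <- miss <= miss_max
  gm_out <- gm_maf[, keep_miss]
  report <- tibble(
    stage = c("maf", "missingness"),
    n_in = c(n_in, n_loci(gm_maf)),
    n_out = c(n_loci(gm_maf), n_loci(gm_out)),
    dropped = list(gm$loci$id[!keep_maf], gm_maf$loci$id[!keep_miss])
  )
  list(genotypes = gm_out, report = report)
}

#' Full staged variant-filtering pipeline
#'
#' Presence filter, then MAF, then missingness, each on the survivor set of
#' the previous stage; the composition is idempotent.
#'
#' @inheritParams presence_filter
#' @inheritParams maf_missing_filter
#' @return A list with `genotypes` and a three-stage `report` tibble.
#' @export
filter_variants <- function(gm, r = 0.75, maf_min = 0.05, miss_max = 0.20) {
  n0 <- n_loci(gm)
  gm_p <- presence_filter(gm, r)
  dropped_p <- setdiff(gm$loci$id, gm_p$loci$id)
  mm <- maf_missing_filter(gm_p, maf_min, miss_max)
  report <- dplyr::bind_rows(
    tibble(stage = "presence", n_in = n0, n_out = n_loci(gm_p),
           dropped = list(dropped_p)),
    mm$report
  )
  list(genotypes = mm$genotypes, report = report)
}

#' Classify substitutions as transitions or transversions
#'
#' Transitions are purine-purine (A/G) or pyrimidine-pyrimidine (C/T)
#' exchanges; every other single-base exchange is a transversion.
#'
#' @param ref,alt Character vectors of single bases in A/C/G/T.
#' @return Character vector, `"transition"` or `"transversion"`.
#' @examples
#' classify_substitution("C", "T")  # transition
#' classify_substitution("G", "T")  # transversion
#' @export
classify_substitution <- function(ref, alt) {
  ref <- toupper(ref); alt <- toupper(alt)
  bad <- setdiff(unique(c(ref, alt)), c("A", "C", "G", "T"))
  if (length(bad)) stop("non-ACGT allele: ", paste(bad, collapse = ", "))
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- c("A", "G")
  ifelse((ref %in% purine) == (alt %in% purine),
         "transition", "transversion")
}

#' Transition/transversion tally for a panel
#'
#' @param gm A [geno_matrix()].
#' @return A tibble with `class`, `n` and the Ts/Tv ratio as attribute
#'   `ts_tv_ratio`.
#' @export
ts_tv <- function(gm) {
  cls <- classify_substitution(gm$loci$ref, gm$loci$alt)
  n_ts <- sum(cls == "transition")
  n_tv <- sum(cls == "transversion")
  out <- tibble(class = c("transition", "transversion"), n = c(n_ts, n_tv))
  attr(out, "ts_tv_ratio") <- if (n_tv > 0) n_ts / n_tv else NA_real_
  out
}

#' Per-chromosome SNP counts and mean inter-SNP spacing
#'
#' Mean spacing is defined per chromosome as
#' `(max position - min position) / (count - 1)`, reported in kb; it is
#' undefined (`NA`) for chromosomes carrying fewer than two loci, and is
#' independent of the sample set.
#'
#' @param gm A [geno_matrix()] with sorted loci.
#' @param chrom_lengths Optional named vector of chromosome lengths (bp); if
#'   given, a `snps_per_kb` density column is added.
#' @return A tibble with `chrom`, `n_snps`, `mean_spacing_kb` (and optionally
#'   `snps_per_kb`).
#' @export
snp_density <- function(gm, chrom_lengths = NULL) {
  out <- gm$loci |>
    dplyr::group_by(.data$chrom) |>
    dplyr::summarise(
      n_snps = dplyr::n(),
      mean_spacing_kb = ifelse(
        dplyr::n() < 2L, NA_real_,
        (max(.data$pos) - min(.data$pos)) / (dplyr::n() - 1L) / 1000),
      .groups = "drop")
  if (!is.null(chrom_lengths)) {
    out$snps_per_kb <- out$n_snps /
      (chrom_lengths[out$chrom] / 1000)
  }
  out
}
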