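#' Construct a genotype matrix
#'
#' The central container of the package: an accessions x loci diploid dosage
#' matrix. Dosage counts copies of the ALT allele (0, 1, 2) with `NA` for
#' missing calls. Loci are kept sorted by chromosome then position; dosage is
#' stored ALT-oriented so that I/O is deterministic and independent of allele
#' frequencies (minor-allele orientation happens in the diversity statistics).
#'
#' @param dosage Integer matrix, samples in rows, loci in columns. Entries
#'   must be 0, 1, 2 or `NA`.
#' @param samples Character vector of unique accession IDs (row labels).
#' @param loci A data frame with columns `chrom`, `pos` (1-based bp), `id`,
#'   `ref`, `alt`; one row per dosage column. `ref`/`alt` must be distinct
#'   single bases in A/C/G/T.
#' @param sort_loci Reorder loci (and dosage columns) by `(chrom, pos)`.
#'
#' @return An object of class `geno_matrix`: a list with elements `dosage`,
#'   `samples` and `loci` (a tibble).
#' @examples
#' gm <- geno_matrix(
#'   dosage  = rbind(a = c(0, 1), b = c(2, NA)),
#'   samples = c("a", "b"),
#'   loci    = data.frame(chrom = "chr1", pos = c(100, 200),
#'                        id = c("s1", "s2"), ref = "A", alt = "G")
#' )
#' n_loci(gm)
#' @export
geno_matrix <- function(dosage, samples, loci, sort_loci = TRUE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  samples <- as.character(samples)
  loci <- as_tibble(loci)
  stopifnot(nrow(dosage) == length(samples), ncol(dosage) == nrow(loci))
  if (anyDuplicated(samples)) {
    stop("duplicate sample IDs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  }
  need <- c("chrom", "pos", "id", "ref", "alt")
  missing_cols <- setdiff(need, names(loci))
  if (length(missing_cols)) {
    stop("loci table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  loci$chrom <- as.character(loci$chrom)
  loci$pos <- as.integer(loci$pos)
  loci$id <- as.character(loci$id)
  if (any(loci$pos < 1L, na.rm = TRUE)) stop("locus positions must be >= 1")
  bad <- !is.na(dosage) & !(dosage %in% 0:2)
  if (any(bad)) stop("dosage entries must be 0, 1, 2 or NA")
  if (nrow(loci) && any(loci$ref == loci$alt)) {
    stop("ref and alt alleles must differ")
  }
  if (sort_loci && nrow(loci) > 1L) {
    o <- order(loci$chrom, loci$pos)
    loci <- loci[o, , drop = FALSE]
    dosage <- dosage[, o, drop = FALSE]
  }
  rownames(dosage) <- samples
  colnames(dosage) <- loci$id
  structure(list(dosage = dosage, samples = samples, loci = loci),
            class = "geno_matrix")
}

#' Number of samples / loci in a genotype matrix
#' @param gm A [geno_matrix()].
#' @return An integer scalar.
#' @export
n_samples <- function(gm) length(gm$samples)

#' @rdname n_samples
#' @export
n_loci <- function(gm) nrow(gm$loci)

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("<geno_matrix> %d accessions x %d loci\n",
              n_samples(x), n_loci(x)))
  miss <- mean(is.na(x$dosage))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$loci$chrom), collapse = ", ")))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' Subset a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @param i Sample index (logical, integer or character).
#' @param j Locus index (logical or integer, in locus order).
#' @param ... Unused.
#' @return A [geno_matrix()].
#' @export
`[.geno_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$loci))
  if (is.character(i)) i <- match(i, x$samples)
  geno_matrix(x$dosage[i, j, drop = FALSE], x$samples[i],
              x$loci[j, , drop = FALSE], sort_loci = FALSE)
}

#' Convert a genotype matrix to a long tibble
#'
#' One row per (sample, locus) call; convenient for dplyr/ggplot2 work on
#' small panels.
#'
#' @param gm A [geno_matrix()].
#' @return A tibble with columns `sample_id`, `chrom`, `pos`, `id`, `dosage`.
#' @export
geno_tbl <- function(gm) {
  tibble(
    sample_id = rep(gm$samples, times = n_loci(gm)),
    chrom = rep(gm$loci$chrom, each = n_samples(gm)),
    pos = rep(gm$loci$pos, each = n_samples(gm)),
    id = rep(gm$loci$id, each = n_samples(gm)),
    dosage = as.integer(gm$dosage)
  )
}
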