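#' Read a multi-sample VCF into a genotype matrix
#'
#' Parses GT fields of a VCF v4.x file into an ALT-allele dosage matrix.
#' Phased (`0|1`) and unphased (`0/1`) separators are treated identically;
#' `./.` (or `.`) becomes a missing call. Records that are not biallelic
#' single-base SNPs are dropped (with a message) when `biallelic_only` is
#' `TRUE`.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param biallelic_only Drop multi-allelic and indel records instead of
#'   erroring.
#' @return A [geno_matrix()] with loci sorted by `(chrom, pos)`.
#' @export
read_vcf <- function(path, biallelic_only = TRUE) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    smp <- colnames(v@gt)[-1]
    if (is.null(smp)) smp <- character()
    return(geno_matrix(matrix(integer(), length(smp), 0), smp,
                       tibble(chrom = character(), pos = integer(),
                              id = character(), ref = character(),
                              alt = character())))
  }
  snp <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (n_drop > 0L) {
    if (!biallelic_only) {
      stop(n_drop, " records are not biallelic single-base SNPs")
    }
    message("read_vcf: dropped ", n_drop,
            " non-biallelic/non-SNP record(s)")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  fix <- fix[snp, , drop = FALSE]
  samples <- colnames(gt)
  dosage <- gt_to_dosage(gt)
  ids <- fix$ID
  blank <- is.na(ids) | ids == "."
  ids[blank] <- paste0(fix$CHROM[blank], "_", fix$POS[blank])
  geno_matrix(
    t(dosage), samples,
    tibble(chrom = fix$CHROM, pos = as.integer(fix$POS), id = ids,
           ref = fix$REF, alt = fix$ALT)
  )
}

# GT strings (loci x samples) -> integer dosage matrix, NA for missing.
# Errors on non-diploid calls, naming the offending locus.
gt_to_dosage <- function(gt) {
  u <- unique(as.vector(gt))
  u <- u[!is.na(u)]
  val <- vapply(u, function(s) {
    al <- strsplit(s, "[/|]")[[1]]
    if (all(al == ".")) return(NA_integer_)
    if (length(al) != 2L) return(-1L)
    if (any(al == ".")) return(NA_integer_)  # half-missing treated as missing
    a <- suppressWarnings(as.integer(al))
    if (anyNA(a) || any(a < 0L) || any(a > 1L)) return(-1L)
    sum(a)
  }, integer(1))
  d <- matrix(val[match(as.vector(gt), u)], nrow = nrow(gt),
              dimnames = dimnames(gt))
  bad <- which(d == -1L, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("non-diploid or malformed GT at record '",
         rownames(gt)[bad[1, 1]], "' (sample ",
         colnames(gt)[bad[1, 2]], "): ", gt[bad[1, , drop = FALSE]])
  }
  d
}

#' Write a genotype matrix as a VCF file
#'
#' Emits a minimal VCF v4.2 with a GT-only FORMAT. Round-trips through
#' [read_vcf()] reproduce the dosage, sample order and locus order exactly.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radpop",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", gm$samples), collapse = "\t")
  )
  writeLines(header, con)
  if (n_loci(gm) > 0L) {
    gt_codes <- c("0/0", "0/1", "1/1")
    gt <- matrix("./.", nrow = n_loci(gm), ncol = n_samples(gm))
    ok <- !is.na(t(gm$dosage))
    gt[ok] <- gt_codes[t(gm$dosage)[ok] + 1L]
    body <- paste(gm$loci$chrom, gm$loci$pos, gm$loci$id, gm$loci$ref,
                  gm$loci$alt, ".", "PASS", ".", "GT",
                  apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
    writeLines(body, con)
  }
  invisible(path)
}
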