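# Shared fixtures, all built in code.

# small deterministic genotype matrix
make_gm <- function(dosage, chrom = "chr01", pos = NULL, ref = "A",
                    alt = "G", samples = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage); L <- ncol(dosage)
  if (is.null(pos)) pos <- seq(100, by = 100, length.out = L)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(n))
  if (length(chrom) == 1L) chrom <- rep(chrom, L)
  if (length(ref) == 1L) ref <- rep(ref, L)
  if (length(alt) == 1L) alt <- rep(alt, L)
  geno_matrix(dosage, samples,
              data.frame(chrom = chrom, pos = pos,
                         id = sprintf("L%03d", seq_len(L)),
                         ref = ref, alt = alt))
}

# random matrix with missingness, for property tests
random_gm <- function(n = 20, L = 100, miss = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- matrix(sample(0:2, n * L, replace = TRUE,
                     prob = c(0.55, 0.1, 0.35)), n, L)
  d[runif(n * L) < miss] <- NA
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  make_gm(d, ref = ref, alt = alt)
}

# write a hand-constructed 3-sample 2-locus VCF; returns the path
write_tiny_vcf <- function(path = tempfile(fileext = ".vcf"),
                           extra_records = character()) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", "ind1", "ind2", "ind3"), collapse = "\t"),
    "chr02\t500\tsnpB\tC\tT\t.\tPASS\t.\tGT\t0|0\t./.\t1/1",
    "chr01\t100\tsnpA\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    extra_records
  )
  writeLines(lines, path)
  path
}

write_tiny_meta <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# metadata assigning the first k samples of gm to the focus group
focus_meta <- function(gm, k, focus = "da_serbo", rest = "cultivar") {
  tibble::tibble(
    sample_id = gm$samples,
    status = factor(c(rep(focus, k),
                      rep(rest, n_samples(gm) - k)),
                    levels = radpop::status_levels),
    origin = "test")
}
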