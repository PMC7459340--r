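test_that("VCF GT fields parse to ALT-allele dosage with missing convention", {
  path <- write_tiny_vcf()
  gm <- read_vcf(path)
  expect_s3_class(gm, "geno_matrix")
  expect_equal(gm$samples, c("ind1", "ind2", "ind3"))
  # loci re-sorted by (chrom, pos): snpA on chr01 comes first
  expect_equal(gm$loci$id, c("snpA", "snpB"))
  expect_equal(unname(gm$dosage[, "snpA"]), c(0L, 1L, 2L))
  expect_equal(unname(gm$dosage[, "snpB"]), c(0L, NA, 2L))  # phased + missing
})

test_that("multi-allelic and indel records are dropped with a message", {
  path <- write_tiny_vcf(extra_records = c(
    "chr01\t200\tmulti\tA\tG,T\t.\tPASS\t.\tGT\t0/1\t0/2\t0/0",
    "chr01\t300\tindel\tAT\tA\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0"))
  expect_message(gm <- read_vcf(path), "dropped 2")
  expect_equal(n_loci(gm), 2L)
  expect_error(read_vcf(path, biallelic_only = FALSE), "not biallelic")
})

test_that("non-diploid GT calls raise a record-level error", {
  path <- write_tiny_vcf(extra_records =
    "chr03\t900\ttrip\tA\tC\t.\tPASS\t.\tGT\t0/1/1\t0/0\t0/0")
  expect_error(read_vcf(path), "trip")
})

test_that("VCF round-trip is the identity on samples, loci and dosage", {
  withr::with_seed(11, {
    gm <- random_gm(10, 50, miss = 0.2)
    path <- tempfile(fileext = ".vcf")
    write_vcf(gm, path)
    gm2 <- read_vcf(path)
    expect_equal(gm2$samples, gm$samples)
    expect_equal(gm2$loci$pos, gm$loci$pos)
    expect_equal(unname(gm2$dosage), unname(gm$dosage))
    expect_true(all(is.na(gm2$dosage) | gm2$dosage %in% 0:2))
  })
})

test_that("an empty matrix writes a valid header-only VCF", {
  gm <- geno_matrix(matrix(integer(), 2, 0), c("a", "b"),
                    data.frame(chrom = character(), pos = integer(),
                               id = character(), ref = character(),
                               alt = character()))
  path <- tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  lines <- readLines(path)
  expect_match(lines[1], "fileformat=VCFv4.2")
  expect_match(lines[length(lines)], "^#CHROM")
})

test_that("metadata reading maps unknown statuses and rejects duplicates", {
  path <- write_tiny_meta(data.frame(
    id = c("DS8", "X1"), status = c("da_serbo", "weird"), origin = "Italy"))
  expect_warning(meta <- read_metadata(path), "weird")
  expect_equal(as.character(meta$status), c("da_serbo", "unknown"))
  expect_equal(meta$sample_id[1], "DS8")

  dup <- write_tiny_meta(data.frame(
    id = c("A", "A"), status = "cultivar", origin = "x"))
  expect_error(read_metadata(dup), "A")
})

test_that("a full-size synthetic metadata table carries the panel composition", {
  sim <- simulate_panel(sim_config(K = 6, n_per_pop = 48, L = 50,
                                   n_private = 5, seed = 3))
  path <- write_tiny_meta(data.frame(id = sim$meta$sample_id,
                                     status = as.character(sim$meta$status),
                                     origin = sim$meta$origin))
  meta <- read_metadata(path)
  expect_equal(nrow(meta), 288L)
  expect_equal(sum(meta$status == "da_serbo"), 77L)
  expect_equal(sum(meta$status == "fresh_landrace"), 75L)
  expect_equal(sum(meta$status == "breeding_line"), 14L)
})

test_that("region queries respect the 0-based half-open BED convention", {
  gm <- make_gm(rbind(c(0, 1), c(1, 2)), pos = c(100, 200))
  # [99, 100) in BED covers 1-based position 100 exactly
  r_hit <- tibble::tibble(chrom = "chr01", start = 99, end = 100, name = "R")
  expect_equal(nrow(variants_in_regions(gm, r_hit)), 1L)
  # [100, 101) does NOT cover position 100
  r_miss <- tibble::tibble(chrom = "chr01", start = 100, end = 101,
                           name = "R")
  expect_equal(nrow(variants_in_regions(gm, r_miss)), 0L)
  # empty region and unknown chromosome
  r_none <- tibble::tibble(chrom = c("chr01", "chrZZ"),
                           start = c(900, 0), end = c(950, 100),
                           name = c("empty", "offpanel"))
  expect_message(out <- variants_in_regions(gm, r_none), "chrZZ")
  expect_equal(nrow(out), 0L)
})

test_that("region queries count minor-allele carriers per status group", {
  # locus inside each of 3 regions, planted carriers in the focus group
  d <- rbind(c(2, 0, 0), c(1, 0, 0), c(0, 0, 1), c(0, 0, 0))
  gm <- make_gm(d, pos = c(100, 500, 900))
  meta <- focus_meta(gm, 2)
  regions <- tibble::tibble(chrom = "chr01",
                            start = c(50, 450, 850),
                            end = c(150, 550, 950),
                            name = c("g1", "g2", "g3"))
  out <- variants_in_regions(gm, regions, meta)
  expect_equal(sort(unique(out$region)), c("g1", "g2", "g3"))
  # locus 1: ALT minor (p = 3/8); carriers: both da_serbo, no cultivar
  g1 <- out[out$region == "g1", ]
  expect_equal(g1$n_carriers[g1$status == "da_serbo"], 2L)
  expect_equal(g1$n_carriers[g1$status == "cultivar"], 0L)
})

test_that("genotype matrices validate their invariants", {
  expect_error(make_gm(rbind(c(0, 3))), "dosage")
  expect_error(geno_matrix(rbind(c(0, 1)), "a",
                           data.frame(chrom = "c", pos = c(1, 2),
                                      id = c("x", "y"), ref = "A",
                                      alt = "A")), "differ")
  expect_error(make_gm(rbind(0, 0), samples = c("a", "a")), "duplicate")
  # loci come out sorted by (chrom, pos)
  gm <- geno_matrix(cbind(c(0, 1), c(1, 2)), c("a", "b"),
                    data.frame(chrom = c("chr02", "chr01"), pos = c(5, 9),
                               id = c("x", "y"), ref = "A", alt = "G"))
  expect_equal(gm$loci$id, c("y", "x"))
  expect_equal(unname(gm$dosage[, 1]), c(1L, 2L))
})
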