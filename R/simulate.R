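#' Configuration for the structured panel simulator
#'
#' Defines the generative conditions for a synthetic germplasm panel:
#' `K` diverged subpopulations under a Balding-Nichols allele-frequency model,
#' founder-mosaic haplotypes that induce distance-dependent LD, partial
#' selfing to reproduce the low heterozygosity of an inbreeding crop,
#' a labelled long-shelf-life ('da serbo') group carrying planted
#' contrasting-frequency loci, planted near-duplicate accessions, and MCAR
#' missingness. Defaults emulate a Mediterranean tomato landrace collection:
#' six subpopulations, 288 accessions with the observed status composition
#' (77 'da serbo', 75 fresh-consumption landraces, 46 heirlooms, 76 cultivars,
#' 14 breeding lines), ~2-5% heterozygosity, MAF spectra surviving a 0.05
#' floor, and LD decaying within a few kb.
#'
#' @param K Number of ancestral populations.
#' @param n_per_pop Samples drawn per population.
#' @param L Number of SNP loci.
#' @param F_k Balding-Nichols divergence per population, scalar or length-`K`,
#'   each in (0, 1).
#' @param alpha Dirichlet concentration for admixed membership rows.
#' @param admixed_fraction Fraction of samples drawn admixed.
#' @param missing_rate Missing-completely-at-random call rate in \[0, 1).
#' @param n_founders Founder haplotypes per population.
#' @param switch_rate_per_bp Founder-mosaic switch intensity; the probability
#'   of switching founders across a gap of `d` bp is `1 - exp(-rate * d)`.
#' @param chrom_lengths Named or unnamed vector of chromosome lengths (bp).
#' @param n_private Number of planted contrasting-MAF loci (private to the
#'   'da serbo' group).
#' @param n_duplicates Number of planted near-duplicate accession pairs.
#' @param selfing Per-locus probability that the second allele copies the
#'   first (inbreeding knob; 0 gives Hardy-Weinberg sampling).
#' @param status_probs Named numeric of expected biological-status
#'   proportions; apportioned to exact counts by largest remainder.
#' @param seed Integer RNG seed; every stochastic draw flows from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(K = 6, n_per_pop = 48, L = 2000, F_k = 0.3,
                       alpha = 0.1, admixed_fraction = 0.03,
                       missing_rate = 0.05, n_founders = 10,
                       switch_rate_per_bp = 2e-4,
                       chrom_lengths = stats::setNames(
                         rep(6e5, 12), sprintf("chr%02d", 1:12)),
                       n_private = 20, n_duplicates = 2, selfing = 0.9,
                       status_probs = c(da_serbo = 77, fresh_landrace = 75,
                                        heirloom = 46, cultivar = 76,
                                        breeding_line = 14) / 288,
                       seed = 1) {
  if (length(F_k) == 1L) F_k <- rep(F_k, K)
  cfg <- list(K = as.integer(K), n_per_pop = as.integer(n_per_pop),
              L = as.integer(L), F_k = F_k, alpha = alpha,
              admixed_fraction = admixed_fraction,
              missing_rate = missing_rate,
              n_founders = as.integer(n_founders),
              switch_rate_per_bp = switch_rate_per_bp,
              chrom_lengths = chrom_lengths,
              n_private = as.integer(n_private),
              n_duplicates = as.integer(n_duplicates),
              selfing = selfing, status_probs = status_probs,
              seed = as.integer(seed))
  if (cfg$K < 1L) stop("K must be >= 1")
  if (length(cfg$F_k) != cfg$K) stop("F_k must be scalar or length K")
  if (any(cfg$F_k <= 0 | cfg$F_k >= 1)) stop("F_k must lie in (0, 1)")
  if (cfg$L < cfg$n_private) stop("n_private cannot exceed L")
  for (nm in c("alpha", "switch_rate_per_bp")) {
    if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  }
  for (nm in c("admixed_fraction", "missing_rate", "selfing")) {
    if (cfg[[nm]] < 0 || cfg[[nm]] >= 1) stop(nm, " must lie in [0, 1)")
  }
  if (is.null(names(cfg$chrom_lengths))) {
    names(cfg$chrom_lengths) <-
      sprintf("chr%02d", seq_along(cfg$chrom_lengths))
  }
  if (2L * cfg$n_duplicates > cfg$K * cfg$n_per_pop) {
    stop("too many duplicate pairs for the panel size")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Draw ancestral and per-population allele frequencies
#'
#' Ancestral frequencies are Uniform(0.05, 0.95) — a spectrum whose common
#' alleles survive a 0.05 MAF floor — and each population's frequencies
#' diverge from them under the Balding-Nichols Beta model with parameter
#' `F_k`: `f_kj ~ Beta(p_j (1-F_k)/F_k, (1-p_j)(1-F_k)/F_k)`, so that
#' `E[f_kj] = p_j` and `Var[f_kj] = F_k p_j (1-p_j)`.
#'
#' @param cfg A [sim_config()].
#' @return A list with `p` (length-`L` ancestral frequencies) and `f`
#'   (`K x L` population frequencies, clamped to `[1e-6, 1-1e-6]`).
#' @export
simulate_frequencies <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  p <- runif(cfg$L, 0.05, 0.95)
  f <- matrix(0, cfg$K, cfg$L)
  for (k in seq_len(cfg$K)) {
    Fk <- cfg$F_k[k]
    f[k, ] <- rbeta(cfg$L, p * (1 - Fk) / Fk, (1 - p) * (1 - Fk) / Fk)
  }
  f <- pmin(pmax(f, 1e-6), 1 - 1e-6)
  list(p = p, f = f)
}

# Largest-remainder apportionment of n among proportions
apportion <- function(n, probs) {
  probs <- probs / sum(probs)
  raw <- n * probs
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    o <- order(raw - counts, decreasing = TRUE)
    counts[o[seq_len(rem)]] <- counts[o[seq_len(rem)]] + 1
  }
  as.integer(counts)
}

# One mosaic haplotype for sample with membership row q.
# switch_p: per-gap switch probabilities (length L, first entry 1).
mosaic_haplotype <- function(q, switch_p, founders, L) {
  K <- length(founders)
  sw <- runif(L) < switch_p
  seg <- cumsum(sw)
  nseg <- seg[L]
  pop_seg <- sample.int(K, nseg, replace = TRUE, prob = q)
  nf <- nrow(founders[[1]])
  fdr_seg <- sample.int(nf, nseg, replace = TRUE)
  hap <- integer(L)
  pop_j <- pop_seg[seg]
  fdr_j <- fdr_seg[seg]
  for (k in unique(pop_j)) {
    jj <- which(pop_j == k)
    hap[jj] <- founders[[k]][cbind(fdr_j[jj], jj)]
  }
  hap
}

#' Simulate a structured genotype panel with known truth
#'
#' Builds the panel described by [sim_config()]: per-population founder
#' haplotypes drawn Bernoulli from Balding-Nichols frequencies; each sample
#' haplotype is a founder mosaic whose founder switches between adjacent loci
#' with probability `1 - exp(-switch_rate_per_bp * gap)` (inducing r2 that
#' decays with distance); genotypes are the sum of two haplotypes, the second
#' copying the first per locus with probability `selfing`; a fraction of
#' samples is admixed with Dirichlet(`alpha`) membership; planted private loci
#' are resampled so the 'da serbo' group's minor-allele frequency is high
#' (~0.55) while the complement's is low (~0.02); duplicate accessions copy an
#' existing sample with a 1e-3 per-locus perturbation; MCAR missingness is
#' applied last. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `genotypes` (a [geno_matrix()]), `meta`
#'   (accession metadata tibble) and `truth` (list: `Q_true`, `pop_labels`,
#'   `group_labels`, `private_locus_indices`, `duplicate_pairs`,
#'   `founder_haplotypes`, `freqs`).
#' @export
simulate_panel <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$K * cfg$n_per_pop
  L <- cfg$L

  # locus coordinates: multinomial split over chromosomes, uniform positions
  n_chr <- length(cfg$chrom_lengths)
  chr_of <- sort(sample.int(n_chr, L, replace = TRUE,
                            prob = cfg$chrom_lengths))
  pos <- integer(L)
  for (c in unique(chr_of)) {
    jj <- which(chr_of == c)
    pos[jj] <- sort(sample.int(cfg$chrom_lengths[c], length(jj)))
  }
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, L, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  loci <- tibble(chrom = names(cfg$chrom_lengths)[chr_of], pos = pos,
                 id = sprintf("snp%05d", seq_len(L)), ref = ref, alt = alt)

  freqs <- simulate_frequencies(cfg)
  founders <- lapply(seq_len(cfg$K), function(k) {
    matrix(as.integer(runif(cfg$n_founders * L) < rep(freqs$f[k, ],
                                                      each = cfg$n_founders)),
           nrow = cfg$n_founders)
  })

  # membership rows
  pop_labels <- rep(seq_len(cfg$K), each = cfg$n_per_pop)
  Q <- matrix(0, n, cfg$K)
  Q[cbind(seq_len(n), pop_labels)] <- 1
  n_adm <- floor(cfg$admixed_fraction * n)
  adm_idx <- if (n_adm > 0) sort(sample.int(n, n_adm)) else integer()
  for (i in adm_idx) {
    g <- rgamma(cfg$K, shape = cfg$alpha)
    Q[i, ] <- g / sum(g)
  }

  # per-gap switch probabilities (forced switch at chromosome starts)
  gap <- c(Inf, diff(pos))
  gap[c(TRUE, diff(chr_of) != 0)] <- Inf
  switch_p <- 1 - exp(-cfg$switch_rate_per_bp * gap)

  dosage <- matrix(0L, n, L)
  for (i in seq_len(n)) {
    hapA <- mosaic_haplotype(Q[i, ], switch_p, founders, L)
    hapB <- mosaic_haplotype(Q[i, ], switch_p, founders, L)
    copyA <- runif(L) < cfg$selfing
    hapB[copyA] <- hapA[copyA]
    dosage[i, ] <- hapA + hapB
  }

  # biological statuses, apportioned to the configured composition
  counts <- apportion(n, cfg$status_probs)
  status <- sample(rep(names(cfg$status_probs), counts))
  ds <- status == "da_serbo"
  if (!any(ds)) {
    stop("status composition yields no 'da serbo' samples; ",
         "the private-locus planting contract needs a focus group")
  }

  # planted contrasting-MAF loci: ALT is the global minor allele, frequent
  # in the focus group (0.55) and rare elsewhere (0.02)
  private_idx <- sort(sample.int(L, cfg$n_private))
  for (j in private_idx) {
    dosage[ds, j] <- rbinom(sum(ds), 2L, 0.55)
    dosage[!ds, j] <- rbinom(sum(!ds), 2L, 0.02)
  }

  # planted near-duplicates: overwrite target with a perturbed copy of source
  duplicate_pairs <- NULL
  if (cfg$n_duplicates > 0) {
    src <- sample.int(n, cfg$n_duplicates)
    # duplicates are the same variety: draw the target from the source's
    # status group so the configured composition is preserved
    dst <- integer(cfg$n_duplicates)
    used <- src
    for (m in seq_len(cfg$n_duplicates)) {
      pool <- setdiff(which(status == status[src[m]]), used)
      if (!length(pool)) pool <- setdiff(seq_len(n), used)
      dst[m] <- pool[sample.int(length(pool), 1)]
      used <- c(used, dst[m])
    }
    for (m in seq_len(cfg$n_duplicates)) {
      g <- dosage[src[m], ]
      flip <- which(runif(L) < 1e-3)
      if (length(flip)) {
        g[flip] <- vapply(g[flip],
                          function(x) sample(setdiff(0:2, x), 1L), 0L)
      }
      dosage[dst[m], ] <- g
      Q[dst[m], ] <- Q[src[m], ]
      pop_labels[dst[m]] <- pop_labels[src[m]]
    }
    duplicate_pairs <- cbind(source = src, duplicate = dst)
  }
  ds <- status == "da_serbo"

  if (cfg$missing_rate > 0) {
    dosage[runif(n * L) < cfg$missing_rate] <- NA_integer_
  }

  samples <- sprintf("S%03d", seq_len(n))
  origin_pool <- list(
    da_serbo = c("Italy", "Spain"),
    fresh_landrace = c("Italy", "Spain", "Greece"),
    heirloom = c("USA", "France", "Germany"),
    cultivar = c("USA", "France", "Netherlands", "Japan"),
    breeding_line = c("USA", "Peru"),
    unknown = "unknown")
  origin <- vapply(status, function(s) {
    pool <- origin_pool[[s]]
    pool[sample.int(length(pool), 1)]
  }, "")
  meta <- tibble(sample_id = samples,
                 status = factor(status, levels = status_levels),
                 origin = origin)

  gm <- geno_matrix(dosage, samples, loci, sort_loci = FALSE)
  truth <- list(
    Q_true = `dimnames<-`(Q, list(samples, paste0("K", seq_len(cfg$K)))),
    pop_labels = setNames(pop_labels, samples),
    group_labels = setNames(ifelse(ds, "da_serbo", "other"), samples),
    private_locus_indices = private_idx,
    duplicate_pairs = duplicate_pairs,
    founder_haplotypes = founders,
    freqs = freqs
  )
  list(genotypes = gm, meta = meta, truth = truth)
}

#' Export simulator ground truth as plain-text tables
#'
#' Writes `Q_true.txt` (whitespace table, full precision), `labels.tsv`
#' (sample, population, group), `private_loci.txt` (one 1-based locus index
#' per line) and `duplicate_pairs.tsv`. [read_truth()] round-trips them.
#'
#' @param truth The `truth` element of [simulate_panel()] output.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
export_truth <- function(truth, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  qf <- file.path(dir, "Q_true.txt")
  q <- truth$Q_true
  write.table(format(as.data.frame(q), digits = 17, scientific = TRUE),
              qf, quote = FALSE, col.names = TRUE, row.names = TRUE)
  write.table(
    data.frame(sample_id = names(truth$pop_labels),
               population = truth$pop_labels,
               group = truth$group_labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  writeLines(as.character(truth$private_locus_indices),
             file.path(dir, "private_loci.txt"))
  dp <- truth$duplicate_pairs
  if (is.null(dp)) dp <- cbind(source = integer(), duplicate = integer())
  write.table(as.data.frame(dp), file.path(dir, "duplicate_pairs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read back exported simulator truth
#' @param dir Directory written by [export_truth()].
#' @return A list with `Q_true`, `pop_labels`, `group_labels`,
#'   `private_locus_indices`, `duplicate_pairs`.
#' @export
read_truth <- function(dir) {
  q <- as.matrix(read.table(file.path(dir, "Q_true.txt"), header = TRUE,
                            row.names = 1, check.names = FALSE))
  lab <- read.delim(file.path(dir, "labels.tsv"))
  dp <- as.matrix(read.delim(file.path(dir, "duplicate_pairs.tsv")))
  list(Q_true = q,
       pop_labels = setNames(lab$population, lab$sample_id),
       group_labels = setNames(lab$group, lab$sample_id),
       private_locus_indices =
         as.integer(readLines(file.path(dir, "private_loci.txt"))),
       duplicate_pairs = if (nrow(dp)) dp else NULL)
}
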