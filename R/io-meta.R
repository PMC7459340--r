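#' Accession status vocabulary
#'
#' The closed vocabulary of biological statuses used throughout the package:
#' long-shelf-life 'da serbo' landraces, landraces for fresh consumption,
#' heirlooms, elite cultivars, breeding lines, plus `unknown`.
#' @export
status_levels <- c("da_serbo", "fresh_landrace", "heirloom", "cultivar",
                   "breeding_line", "unknown")

#' Read an accession metadata table
#'
#' Expects a TSV with header columns `id`, `status`, `origin`. Status tokens
#' outside the closed vocabulary ([status_levels]) are mapped to `"unknown"`
#' with a warning; duplicated IDs are an error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `sample_id`, `status` (factor over
#'   [status_levels]) and `origin`.
#' @export
read_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "status", "origin")
  if (!all(need %in% names(df))) {
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$id)) {
    stop("duplicated accession IDs in metadata: ",
         paste(unique(df$id[duplicated(df$id)]), collapse = ", "))
  }
  bad <- !(df$status %in% status_levels)
  if (any(bad)) {
    warning("unknown status token(s) mapped to 'unknown': ",
            paste(unique(df$status[bad]), collapse = ", "))
    df$status[bad] <- "unknown"
  }
  tibble(sample_id = as.character(df$id),
         status = factor(df$status, levels = status_levels),
         origin = as.character(df$origin))
}

#' Write an accession metadata table
#' @param meta Tibble as returned by [read_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  out <- data.frame(id = meta$sample_id, status = as.character(meta$status),
                    origin = meta$origin)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED4 region table
#'
#' BED intervals are 0-based, half-open `[start, end)`; they are kept in that
#' convention and converted only at the overlap test (see
#' [variants_in_regions()]).
#'
#' @param path Path to a BED file with 4 columns (chrom, start, end, name),
#'   no header.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`.
#' @export
read_regions <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L) stop("BED4 requires 4 columns (chrom, start, end, name)")
  tibble(chrom = as.character(df[[1]]), start = as.numeric(df[[2]]),
         end = as.numeric(df[[3]]), name = as.character(df[[4]]))
}

# The single place where BED (0-based half-open) meets VCF (1-based) positions:
# a 1-based position p overlaps [start, end) iff start < p <= end.
bed_overlaps_pos <- function(start, end, pos) {
  start < pos & pos <= end
}

#' Query variants inside named regions, with per-group carrier counts
#'
#' For each region (BED convention: 0-based half-open) the loci falling inside
#' it are listed together with, per biological-status group, the number of
#' accessions carrying at least one copy of the panel-global minor allele.
#'
#' @param gm A [geno_matrix()].
#' @param regions Tibble of regions (`chrom`, `start`, `end`, `name`), as
#'   from [read_regions()].
#' @param meta Optional metadata tibble ([read_metadata()]); when `NULL` all
#'   samples form a single group `"all"`.
#' @return A tibble with one row per (region, locus, group): columns
#'   `region`, `chrom`, `pos`, `id`, `minor_allele`, `status`, `n_carriers`,
#'   `n_called`.
#' @export
variants_in_regions <- function(gm, regions, meta = NULL) {
  regions <- as_tibble(regions)
  if (is.null(meta)) {
    grp <- factor(rep("all", n_samples(gm)))
  } else {
    grp <- meta$status[match(gm$samples, meta$sample_id)]
  }
  unknown_chr <- setdiff(unique(regions$chrom), unique(gm$loci$chrom))
  if (length(unknown_chr)) {
    message("variants_in_regions: no loci on chromosome(s) ",
            paste(unknown_chr, collapse = ", "))
  }
  out <- purrr::pmap_dfr(regions, function(chrom, start, end, name) {
    hit <- which(gm$loci$chrom == chrom &
                   bed_overlaps_pos(start, end, gm$loci$pos))
    if (!length(hit)) return(tibble())
    purrr::map_dfr(hit, function(j) {
      d <- gm$dosage[, j]
      p_alt <- mean(d, na.rm = TRUE) / 2
      minor_is_alt <- is.na(p_alt) || p_alt <= 0.5
      carrier <- if (minor_is_alt) d >= 1L else d <= 1L
      tibble(
        region = name, chrom = chrom, pos = gm$loci$pos[j],
        id = gm$loci$id[j],
        minor_allele = if (minor_is_alt) gm$loci$alt[j] else gm$loci$ref[j],
        status = levels(factor(grp)),
        n_carriers = as.integer(tapply(carrier, factor(grp), sum,
                                       na.rm = TRUE)),
        n_called = as.integer(tapply(!is.na(d), factor(grp), sum))
      )
    })
  })
  out
}
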