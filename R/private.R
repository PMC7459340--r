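#' Minor-allele-frequency contrast screen
#'
#' Finds loci whose panel-global minor allele is frequent in a focus group
#' but rare elsewhere: a hit requires group MAF strictly greater than
#' `t_focus` in the focus group and strictly less than `t_rest` in the
#' complement (the printed thresholds are strict); hits whose complement MAF
#' is additionally below `t_tight` form the `most_contrasting` tier.
#' Orientation is panel-global (see [group_maf()]) so both group values
#' refer to the same allele; loci with an undefined group frequency (or
#' fewer than `min_group_calls` calls in either group) are excluded.
#'
#' @param gm A [geno_matrix()].
#' @param meta Metadata tibble ([read_metadata()]).
#' @param focus_status Focus group label (default `"da_serbo"`).
#' @param t_focus Focus-group MAF threshold (strict >, default 0.4).
#' @param t_rest Complement MAF threshold (strict <, default 0.2).
#' @param t_tight Complement threshold for the top tier (strict <, 0.1).
#' @param min_group_calls Minimum non-missing calls per group at a locus.
#' @param add_fisher Add a two-sided Fisher exact p-value on allele counts
#'   (descriptive extra output; the screen itself is the threshold rule).
#' @return A tibble of class `contrast_hits` sorted by (chrom, pos):
#'   `chrom`, `pos`, `id`, `maf_focus`, `maf_rest`, `tier`.
#' @export
contrast_screen <- function(gm, meta, focus_status = "da_serbo",
                            t_focus = 0.4, t_rest = 0.2, t_tight = 0.1,
                            min_group_calls = 1, add_fisher = FALSE) {
  st <- meta$status[match(gm$samples, meta$sample_id)]
  if (!any(st == focus_status, na.rm = TRUE)) {
    stop("focus group '", focus_status, "' is empty")
  }
  mf <- group_maf(gm, meta, focus_status)
  mr <- group_maf(gm, meta, focus_status, complement = TRUE)
  ok <- !is.na(mf$maf_group) & !is.na(mr$maf_group) &
    mf$n_calls >= min_group_calls & mr$n_calls >= min_group_calls
  hit <- ok & mf$maf_group > t_focus & mr$maf_group < t_rest
  out <- tibble(
    chrom = gm$loci$chrom[hit], pos = gm$loci$pos[hit],
    id = gm$loci$id[hit],
    maf_focus = mf$maf_group[hit], maf_rest = mr$maf_group[hit],
    tier = ifelse(mr$maf_group[hit] < t_tight,
                  "most_contrasting", "contrasting")
  )
  if (add_fisher && nrow(out)) {
    focus_sel <- !is.na(st) & st == focus_status
    out$p_fisher <- vapply(match(out$id, gm$loci$id), function(j) {
      d <- gm$dosage[, j]
      cnt <- function(sel) {
        alt <- sum(d[sel], na.rm = TRUE)
        tot <- 2 * sum(!is.na(d[sel]))
        c(alt, tot - alt)
      }
      fisher.test(rbind(cnt(focus_sel), cnt(!focus_sel)))$p.value
    }, 0)
  }
  out <- dplyr::arrange(out, .data$chrom, .data$pos)
  class(out) <- c("contrast_hits", class(out))
  out
}

#' Annotate contrast hits with genic/intergenic position
#'
#' A hit is genic when its position falls inside any gene interval (BED
#' 0-based half-open against 1-based positions, the same boundary convention
#' as [variants_in_regions()]); all overlapping gene names are reported,
#' comma-separated.
#'
#' @param hits A [contrast_screen()] result (needs `chrom`, `pos`).
#' @param regions Gene intervals tibble (`chrom`, `start`, `end`, `name`),
#'   e.g. from [read_regions()].
#' @return `hits` with added `genic` (logical) and `gene` columns.
#' @export
annotate_hits <- function(hits, regions) {
  regions <- as_tibble(regions)
  genes <- purrr::map2(hits$chrom, hits$pos, function(ch, p) {
    regions$name[regions$chrom == ch &
                   bed_overlaps_pos(regions$start, regions$end, p)]
  })
  hits$genic <- lengths(genes) > 0
  hits$gene <- vapply(genes, function(g)
    if (length(g)) paste(g, collapse = ",") else NA_character_, "")
  hits
}

#' Recall of planted private loci
#'
#' Convenience check of a contrast screen against simulator truth: the
#' fraction of planted contrasting-MAF loci recovered as hits.
#'
#' @param hits A [contrast_screen()] result.
#' @param gm The screened [geno_matrix()].
#' @param planted_idx Integer locus indices planted by [simulate_panel()].
#' @return A list with `recall`, `n_hits`, `n_planted`, `false_hits`.
#' @export
screen_recall <- function(hits, gm, planted_idx) {
  planted_ids <- gm$loci$id[planted_idx]
  list(recall = mean(planted_ids %in% hits$id),
       n_hits = nrow(hits), n_planted = length(planted_ids),
       false_hits = sum(!hits$id %in% planted_ids))
}
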