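# objective for a candidate core: entry-to-nearest-entry (E-NE) is the mean,
# over selected accessions, of the distance to the closest other selected
# accession; entry-to-entry (E-E) is the mean pairwise distance.
core_objective <- function(d, sel, objective = c("ene", "ee")) {
  objective <- match.arg(objective)
  sub <- d[sel, sel, drop = FALSE]
  if (objective == "ene") {
    diag(sub) <- Inf
    mean(apply(sub, 1, min))
  } else {
    mean(sub[upper.tri(sub)])
  }
}

#' Select a diversity-maximising mini-core collection
#'
#' Picks a subset of accessions maximising the mean entry-to-nearest-entry
#' (E-NE) distance on the allele-sharing dissimilarity matrix — the
#' canonical spread criterion of core-collection samplers. Optimisation is
#' steepest-ascent local search over single swaps (the best improving
#' in/out exchange is applied each step; termination when no swap improves),
#' restarted from `restarts` random subsets; the best restart is returned.
#' Deterministic given `seed`.
#'
#' @param d Symmetric dissimilarity matrix (from [dissimilarity()]).
#' @param intensity Sampling intensity; core size is `round(intensity * n)`
#'   (default 0.2, e.g. 58 accessions from a panel of 288).
#' @param restarts Number of random starts.
#' @param seed Optional seed.
#' @param size Explicit core size, overriding `intensity`.
#' @param objective `"ene"` (default) or `"ee"` (mean entry-to-entry).
#' @return An object of class `core_set`: list with `selected` (sample IDs),
#'   `size`, `intensity`, `objective`, `objective_type` and `trace` (the
#'   strictly increasing objective values of the winning restart).
#' @export
select_core <- function(d, intensity = 0.2, restarts = 10, seed = NULL,
                        size = NULL, objective = c("ene", "ee")) {
  objective <- match.arg(objective)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(d)
  if (is.null(size)) size <- round(intensity * n)
  size <- as.integer(size)
  if (size < 2L) stop("core size must be at least 2")
  if (size > n) stop("core size cannot exceed the panel size")
  best <- NULL
  for (r in seq_len(restarts)) {
    sel <- sort(sample.int(n, size))
    obj <- core_objective(d, sel, objective)
    trace <- obj
    if (size < n) {
      repeat {
        out_pool <- setdiff(seq_len(n), sel)
        best_swap <- NULL
        for (s_out in sel) {
          for (s_in in out_pool) {
            cand <- c(setdiff(sel, s_out), s_in)
            val <- core_objective(d, cand, objective)
            if (val > obj + 1e-12 &&
                (is.null(best_swap) || val > best_swap$val)) {
              best_swap <- list(sel = sort(cand), val = val)
            }
          }
        }
        if (is.null(best_swap)) break
        sel <- best_swap$sel
        obj <- best_swap$val
        trace <- c(trace, obj)
      }
    }
    if (is.null(best) || obj > best$obj) {
      best <- list(sel = sel, obj = obj, trace = trace)
    }
  }
  structure(list(selected = rownames(d)[best$sel], size = size,
                 intensity = size / n, objective = best$obj,
                 objective_type = objective, trace = best$trace),
            class = "core_set")
}

#' @export
print.core_set <- function(x, ...) {
  cat(sprintf(
    "<core_set> %d accessions (intensity %.2f), %s objective = %.5f\n",
    x$size, x$intensity, toupper(x$objective_type), x$objective))
  invisible(x)
}

#' Representation of a core set across statuses and ancestry clusters
#'
#' Contingency counts of the core members by biological status and by
#' ancestry cluster (including `"admixed"`), next to the whole-panel counts;
#' clusters present in the panel but absent from the core are flagged.
#'
#' @param core A [select_core()] result.
#' @param meta Metadata tibble ([read_metadata()]).
#' @param memberships Optional [classify_membership()] tibble.
#' @return A tibble with `dimension` (`"status"`/`"cluster"`), `level`,
#'   `n_core`, `n_panel`, `empty_in_core`.
#' @export
representation_report <- function(core, meta, memberships = NULL) {
  in_core <- meta$sample_id %in% core$selected
  count_dim <- function(values, dimension) {
    lv <- unique(as.character(values[!is.na(values)]))
    tibble(
      dimension = dimension, level = lv,
      n_core = vapply(lv, function(v)
        sum(values == v & in_core, na.rm = TRUE), 0L),
      n_panel = vapply(lv, function(v)
        sum(values == v, na.rm = TRUE), 0L)
    )
  }
  out <- count_dim(droplevels(factor(meta$status)), "status")
  if (!is.null(memberships)) {
    cl <- memberships$cluster[match(meta$sample_id,
                                    memberships$sample_id)]
    out <- dplyr::bind_rows(out, count_dim(cl, "cluster"))
  }
  out$empty_in_core <- out$n_panel > 0 & out$n_core == 0
  out
}
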