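#' Tidy an admixture fit into long membership form
#'
#' @param x An [fit_admixture()] result.
#' @param ... Unused.
#' @return A tibble with `sample_id`, `cluster`, `q`.
#' @export
tidy.admixture_fit <- function(x, ...) {
  as_tibble(x$Q, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "cluster",
                        values_to = "q")
}

#' One-row summary of an admixture fit
#' @inheritParams tidy.admixture_fit
#' @return A tibble with `K`, `loglik`, `n_iter`, `converged`.
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(K = x$K, loglik = tail(x$loglik, 1), n_iter = x$n_iter,
         converged = x$converged)
}

#' Tidy a cross-validation result
#' @param x A [cross_validate_K()] result.
#' @param ... Unused.
#' @return The per-K tibble (`K`, `cv_error`, `se`).
#' @export
tidy.cv_result <- function(x, ...) x$cv

#' One-row summary of a cross-validation result
#' @inheritParams tidy.cv_result
#' @return A tibble with `best_K`, `folds`, `min_cv_error`.
#' @export
glance.cv_result <- function(x, ...) {
  tibble(best_K = x$best_K, folds = x$folds,
         min_cv_error = min(x$cv$cv_error))
}

#' Tidy a k-means/BIC scan
#' @param x A [kmeans_bic()] result.
#' @param ... Unused.
#' @return A tibble with `k`, `wss`, `bic`.
#' @export
tidy.kmeans_bic <- function(x, ...) {
  dplyr::select(x$solutions, "k", "wss", "bic")
}

#' One-row summary of a k-means/BIC scan
#' @inheritParams tidy.kmeans_bic
#' @return A tibble with `best_k` and its `bic`.
#' @export
glance.kmeans_bic <- function(x, ...) {
  tibble(best_k = x$best_k,
         bic = x$solutions$bic[x$solutions$k == x$best_k])
}

#' Tidy an MDS embedding
#' @param x A [classical_mds()] result.
#' @param ... Unused.
#' @return The coordinate tibble (`sample_id`, `A1`, `A2`, ...).
#' @export
tidy.radpop_mds <- function(x, ...) x$points

#' One-row summary of an MDS embedding
#' @inheritParams tidy.radpop_mds
#' @return A tibble with `dims`, `var_explained` (fraction of positive
#'   eigenvalue mass on the kept axes) and `n_negative_eig`.
#' @export
glance.radpop_mds <- function(x, ...) {
  pos <- x$eig[x$eig > 0]
  tibble(dims = x$dims,
         var_explained = sum(x$eig[seq_len(x$dims)]) / sum(pos),
         n_negative_eig = sum(x$eig < 0))
}

#' Tidy a core set
#' @param x A [select_core()] result.
#' @param ... Unused.
#' @return A tibble with the selected `sample_id`s.
#' @export
tidy.core_set <- function(x, ...) tibble(sample_id = x$selected)

#' One-row summary of a core set
#' @inheritParams tidy.core_set
#' @return A tibble with `size`, `intensity`, `objective`,
#'   `objective_type`, `n_steps`.
#' @export
glance.core_set <- function(x, ...) {
  tibble(size = x$size, intensity = x$intensity, objective = x$objective,
         objective_type = x$objective_type, n_steps = length(x$trace))
}
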