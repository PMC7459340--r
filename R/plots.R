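#' Stacked membership bar plot for an admixture fit
#'
#' The classic structure plot: one bar per accession, partitioned into K
#' coloured segments proportional to the membership coefficients.
#'
#' @param object An [fit_admixture()] result.
#' @param order_by Order bars by dominant cluster then membership
#'   (`"cluster"`, default) or keep sample order (`"sample"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.admixture_fit <- function(object, order_by = c("cluster", "sample"),
                                   ...) {
  order_by <- match.arg(order_by)
  df <- tidy(object)
  if (order_by == "cluster") {
    dom <- classify_membership(object, q_min = 0)
    lev <- dom$sample_id[order(dom$cluster, -dom$q_max)]
  } else {
    lev <- rownames(object$Q)
  }
  df$sample_id <- factor(df$sample_id, levels = lev)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id, y = .data$q,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::scale_y_continuous(expand = c(0, 0)) +
    ggplot2::labs(x = NULL, y = "membership coefficient (q)",
                  fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Cross-validation error against K
#'
#' @param object A [cross_validate_K()] result.
#' @param ... Unused.
#' @return A ggplot object with the CV curve and the selected K marked.
#' @export
autoplot.cv_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$cv_error)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_K, linetype = "dashed") +
    ggplot2::labs(x = "number of ancestral clusters (K)",
                  y = "cross-validation error") +
    ggplot2::theme_minimal()
}

#' MDS scatter plot
#'
#' @param object A [classical_mds()] result.
#' @param colour_by Optional vector (aligned with samples) used to colour
#'   points, e.g. metadata status or cluster assignments.
#' @param axes Which two axes to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radpop_mds <- function(object, colour_by = NULL, axes = c(1, 2),
                                ...) {
  df <- object$points
  ax <- paste0("A", axes)
  if (!all(ax %in% names(df))) stop("requested axes not in embedding")
  if (!is.null(colour_by)) df$group <- colour_by
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[ax[1]]],
                                        y = .data[[ax[2]]])) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = ax[1], y = ax[2])
  if (is.null(colour_by)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group)) +
      ggplot2::labs(colour = NULL)
  }
}

#' LD decay curve plot
#'
#' @param object A [decay_curve()] tibble (or several row-bound curves with
#'   distinct `group` labels).
#' @param ... Unused.
#' @return A ggplot object of mean r2 against distance (kb).
#' @export
autoplot.decay_curve <- function(object, ...) {
  df <- as_tibble(object)
  df <- df[!is.na(df$mean_r2), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid / 1000, y = .data$mean_r2,
                                   colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (kb)", y = expression(mean ~ r^2),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
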