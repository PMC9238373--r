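#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ordination into a long tibble
#'
#' @param x A `treecoda_ordination`.
#' @param matrix Which component to tidy: sample `"scores"` (default),
#'   feature/node `"loadings"`, or the `"eigenvalues"` summary.
#' @param ... Unused.
#' @return A tibble: for scores/loadings one row per (id, component) with the
#'   value; for eigenvalues one row per component with `eigenvalue` and
#'   `proportion_explained`.
#' @export
tidy.treecoda_ordination <- function(x, matrix = c("scores", "loadings", "eigenvalues"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "eigenvalues") {
    return(tibble::tibble(component = paste0("PC", seq_len(x$rank)),
                          eigenvalue = x$eigenvalues,
                          proportion_explained = x$proportion_explained))
  }
  m <- if (matrix == "scores") x$sample_scores else x$feature_loadings
  idcol <- if (matrix == "scores") "sample" else "node_id"
  out <- tibble::tibble(
    id = rep(rownames(m), ncol(m)),
    component = rep(colnames(m), each = nrow(m)),
    value = as.vector(m))
  names(out)[1] <- idcol
  out
}

#' One-row model summary of an ordination
#'
#' @param x A `treecoda_ordination`.
#' @param ... Unused.
#' @return Tibble with `rank`, `total_proportion_explained`, `n_samples`,
#'   `n_features`, `phylogenetic`.
#' @export
glance.treecoda_ordination <- function(x, ...) {
  tibble::tibble(rank = x$rank,
                 total_proportion_explained = sum(x$proportion_explained),
                 n_samples = nrow(x$sample_scores),
                 n_features = nrow(x$feature_loadings),
                 phylogenetic = isTRUE(x$phylogenetic))
}

#' Compositional biplot of an ordination
#'
#' Samples as points and the strongest feature/node loadings as arrows, on
#' two chosen components.
#'
#' @param object A `treecoda_ordination`.
#' @param axes Two component indices (default 1:2).
#' @param groups Optional group label per sample (named vector or aligned)
#'   used for point color.
#' @param n_arrows Number of highest-magnitude loadings to draw.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.treecoda_ordination <- function(object, axes = c(1, 2), groups = NULL,
                                         n_arrows = 8, ...) {
  axes <- axes[seq_len(min(2, object$rank))]
  if (length(axes) < 2) axes <- c(1, 1)
  sc <- object$sample_scores[, axes, drop = FALSE]
  lab <- sprintf("PC%d (%.1f%%)", axes, 100 * object$proportion_explained[axes])
  df <- data.frame(x = sc[, 1], y = sc[, 2], sample = rownames(sc))
  if (!is.null(groups)) {
    if (!is.null(names(groups))) groups <- groups[rownames(sc)]
    df$group <- as.factor(groups)
  }
  ld <- object$feature_loadings[, axes, drop = FALSE]
  mag <- sqrt(rowSums(ld^2))
  top <- order(mag, decreasing = TRUE)[seq_len(min(n_arrows, nrow(ld)))]
  scale <- 0.8 * max(abs(sc)) / max(mag[top])
  ad <- data.frame(x = ld[top, 1] * scale, y = ld[top, 2] * scale,
                   node_id = rownames(ld)[top])
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(data = ad,
                          ggplot2::aes(x = 0, y = 0, xend = .data$x, yend = .data$y),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          color = "grey50", inherit.aes = FALSE) +
    ggplot2::geom_text(data = ad, ggplot2::aes(label = .data$node_id),
                       size = 2.5, color = "grey30", vjust = -0.5,
                       inherit.aes = FALSE) +
    ggplot2::labs(x = lab[1], y = lab[2]) +
    ggplot2::theme_minimal()
  if (!is.null(groups))
    p <- p + ggplot2::geom_point(ggplot2::aes(color = .data$group))
  else p <- p + ggplot2::geom_point()
  p
}

#' Plot a benchmark sweep
#'
#' PERMANOVA F (log scale) against tip-shuffle proportion, one line per
#' method, faceted by sequencing depth.
#'
#' @param results Tibble from [benchmark()].
#' @param metric Column to plot (default `"F_statistic"`).
#' @return A ggplot object.
#' @export
plot_benchmark <- function(results, metric = "F_statistic") {
  stopifnot(metric %in% colnames(results))
  p <- ggplot2::ggplot(results,
                       ggplot2::aes(x = factor(.data$shuffle_proportion),
                                    y = .data[[metric]],
                                    color = .data$method)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::facet_wrap(~depth, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "tip shuffle proportion", y = metric) +
    ggplot2::theme_minimal()
  if (metric == "F_statistic") p <- p + ggplot2::scale_y_log10()
  p
}
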