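#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' BIC curve of a cluster solution
#'
#' @param object An `ssr_clusters`.
#' @param ... Unused.
#' @return A ggplot: BIC against K, selected K highlighted.
#' @export
autoplot.ssr_clusters <- function(object, ...) {
  ggplot2::ggplot(object$bic, ggplot2::aes(x = .data$K, y = .data$bic)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_point(
      data = object$bic[object$bic$K == object$K, ],
      colour = "red", size = 3
    ) +
    ggplot2::labs(
      x = "Number of clusters (K)", y = "BIC",
      title = paste0("BIC model selection (K = ", object$K, ")")
    ) +
    ggplot2::theme_minimal()
}

#' DAPC scatter on the first two discriminant axes
#'
#' @param object An `ssr_dapc`.
#' @param ... Unused.
#' @return A ggplot of individuals coloured by group.
#' @export
autoplot.ssr_dapc <- function(object, ...) {
  d <- object$coords
  if (!"LD2" %in% names(d)) d$LD2 <- 0
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$LD1, y = .data$LD2,
    colour = .data$group
  )) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::stat_ellipse(level = 0.67, linewidth = 0.3, na.rm = TRUE) +
    ggplot2::labs(
      x = sprintf("LD1 (%.1f%%)", 100 * object$prop_var[1]),
      y = if (length(object$prop_var) > 1) {
        sprintf("LD2 (%.1f%%)", 100 * object$prop_var[2])
      } else {
        "LD2"
      },
      colour = "Group"
    ) +
    ggplot2::theme_minimal()
}

#' Migration network heat map
#'
#' @param object An `ssr_migration`.
#' @param ... Unused.
#' @return A ggplot tile map of directed relative migration.
#' @export
autoplot.ssr_migration <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$to, y = .data$from,
    fill = .data$migration
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$migration)),
      colour = "white"
    ) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(
      x = "To", y = "From",
      fill = paste0("m (", object$statistic, ")")
    ) +
    ggplot2::theme_minimal()
}

#' Model-checking PCA plot
#'
#' @param mc Result of [model_check()].
#' @return A ggplot: reference cloud, posterior-predictive cloud, observed
#'   point.
#' @export
plot_model_check <- function(mc) {
  d <- mc$pca
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::geom_point(
      data = d[d$type == "reference", ],
      colour = "grey70", alpha = 0.4, size = 0.8
    ) +
    ggplot2::geom_point(
      data = d[d$type == "predictive", ],
      colour = "steelblue", alpha = 0.6, size = 1.2
    ) +
    ggplot2::geom_point(
      data = d[d$type == "observed", ],
      colour = "red", size = 3, shape = 17
    ) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * mc$prop_var[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * mc$prop_var[2])
    ) +
    ggplot2::theme_minimal()
}
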