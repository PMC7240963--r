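# ggplot2 views of the main result types. These are working plots for
# analysis notebooks, not publication layouts.

#' Plot a trait correlation network
#'
#' Force-directed layout (Fruchterman-Reingold via igraph, fixed seed for a
#' reproducible arrangement); edges coloured by correlation sign, nodes by
#' annotation group.
#'
#' @param object A `trait_network`.
#' @param layout_seed Seed for the layout.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trait_network
#' @export
autoplot.trait_network <- function(object, layout_seed = 42L, ...) {
  g <- as_igraph(object)
  xy <- with_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  seg <- dplyr::mutate(
    object$edges,
    x = nodes$x[match(.data$from, nodes$trait)],
    y = nodes$y[match(.data$from, nodes$trait)],
    xend = nodes$x[match(.data$to, nodes$trait)],
    yend = nodes$y[match(.data$to, nodes$trait)],
    sign = factor(ifelse(.data$sign > 0, "positive", "negative"),
                  levels = c("positive", "negative"))
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, colour = .data$sign),
      linewidth = 0.2, alpha = 0.5) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$group),
      shape = 21, size = 2) +
    ggplot2::scale_colour_manual(values = c(positive = "#2166ac",
                                            negative = "#b2182b")) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = "edge sign", fill = "trait group")
}

#' Heatmap of a metabolite-transcript correlation panel
#'
#' @param mat Matrix from [select_heatmap()].
#' @return A ggplot object (tile heatmap, diverging fill centred at 0).
#' @export
plot_heatmap <- function(mat) {
  long <- tibble(
    trait = rep(rownames(mat), times = ncol(mat)),
    transcript = rep(colnames(mat), each = nrow(mat)),
    r = as.vector(mat)
  )
  long$trait <- factor(long$trait, levels = rev(rownames(mat)))
  long$transcript <- factor(long$transcript, levels = colnames(mat))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$transcript, y = .data$trait,
                                     fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#b2182b", mid = "white",
                                  high = "#2166ac", limits = c(-1, 1)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Percent-positive tile plot of a class-pair summary
#'
#' @param object A `class_pair_summary`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot class_pair_summary
#' @export
autoplot.class_pair_summary <- function(object, ...) {
  both <- dplyr::bind_rows(
    object,
    dplyr::rename(object[object$class_a != object$class_b, ],
                  class_a = "class_b", class_b = "class_a")
  )
  ggplot2::ggplot(both, ggplot2::aes(x = .data$class_a, y = .data$class_b,
                                     fill = .data$pct_positive)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = round(.data$pct_positive)),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "#b2182b", high = "#2166ac",
                                 limits = c(0, 100)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "% positive")
}

#' Bar chart of group means for one transcript
#'
#' Raw-scale group means with standard-error bars, the standard view for
#' genotype-group expression comparisons.
#'
#' @param data Replicate table.
#' @param transcript Transcript id.
#' @return A ggplot object.
#' @export
plot_group_means <- function(data, transcript) {
  gm <- group_means(data, transcript)
  ggplot2::ggplot(gm, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$se, ymax = .data$mean + .data$se),
      width = 0.2) +
    ggplot2::theme_classic() +
    ggplot2::labs(x = NULL, y = "abundance", title = transcript)
}
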