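#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Heatmap of a PLI connectivity matrix
#'
#' @param object A `pli_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pli_matrix <- function(object, ...) {
  labels <- rownames(object)
  df <- tidyr::expand_grid(row = labels, col = labels)
  df$pli <- as.vector(unclass(object)[cbind(match(df$row, labels),
                                            match(df$col, labels))])
  df$row <- factor(df$row, levels = rev(labels))
  df$col <- factor(df$col, levels = labels)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$pli)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), name = "PLI") +
    ggplot2::labs(
      x = NULL, y = NULL,
      title = sprintf("PLI connectivity (%s, %s)",
                      attr(object, "band"),
                      as.character(attr(object, "epoch_index")))
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}

# Radial layout for a tree: hub (max degree) at the origin, nodes placed on
# rings by hop distance, each subtree fanned into its angular sector.
tree_layout <- function(tree) {
  n <- tree$n
  adj <- vector("list", n)
  for (e in seq_len(nrow(tree$edges))) {
    u <- tree$edges$u[e]; v <- tree$edges$v[e]
    adj[[u]] <- c(adj[[u]], v)
    adj[[v]] <- c(adj[[v]], u)
  }
  deg <- lengths(adj)
  root <- which.max(deg)
  # subtree sizes by post-order
  parent <- rep(NA_integer_, n)
  order_ <- integer(0)
  stack <- root
  seen <- logical(n); seen[root] <- TRUE
  while (length(stack) > 0) {
    x <- stack[length(stack)]; stack <- stack[-length(stack)]
    order_ <- c(order_, x)
    for (y in adj[[x]]) if (!seen[y]) {
      seen[y] <- TRUE; parent[y] <- x; stack <- c(stack, y)
    }
  }
  size <- rep(1, n)
  for (x in rev(order_)) if (!is.na(parent[x])) {
    size[parent[x]] <- size[parent[x]] + size[x]
  }
  ang_lo <- rep(0, n); ang_hi <- rep(2 * pi, n)
  depth <- rep(0L, n)
  xs <- numeric(n); ys <- numeric(n)
  for (x in order_) {
    mid <- (ang_lo[x] + ang_hi[x]) / 2
    xs[x] <- depth[x] * cos(mid); ys[x] <- depth[x] * sin(mid)
    kids <- adj[[x]][vapply(adj[[x]], function(y) {
      identical(parent[y], x)
    }, logical(1))]
    if (length(kids) > 0) {
      tot <- sum(size[kids])
      a <- ang_lo[x]
      for (k in kids) {
        w <- (ang_hi[x] - ang_lo[x]) * size[k] / tot
        ang_lo[k] <- a; ang_hi[k] <- a + w
        depth[k] <- depth[x] + 1L
        a <- a + w
      }
    }
  }
  tibble::tibble(node = tree$labels, x = xs, y = ys, degree = deg)
}

#' Plot a spanning tree
#'
#' Radial layout with the highest-degree node at the centre; node size scales
#' with degree so star-like vs line-like topology is visible at a glance.
#'
#' @param object An `mst_tree`.
#' @param label Draw channel labels.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mst_tree <- function(object, label = TRUE, ...) {
  lay <- tree_layout(object)
  seg <- dplyr::left_join(object$edges, lay, by = c("from" = "node")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(lay, by = c("to" = "node")) |>
    dplyr::rename(x1 = "x", y1 = "y")
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey50") +
    ggplot2::geom_point(data = lay,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$degree),
                        colour = "steelblue") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::guides(size = "none")
  if (label) {
    p <- p + ggplot2::geom_text(data = lay,
                                ggplot2::aes(x = .data$x, y = .data$y,
                                             label = .data$node),
                                vjust = -1, size = 3)
  }
  p
}

#' Group comparison of a global measure
#'
#' Box-and-jitter plot of a metric-table measure by group, faceted by band.
#'
#' @param metrics The `metrics` tibble of [analyze_cohort()].
#' @param measure Measure column name.
#' @return A ggplot.
#' @export
plot_group_measure <- function(metrics, measure) {
  ggplot2::ggplot(metrics, ggplot2::aes(x = .data$group,
                                        y = .data[[measure]],
                                        colour = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::facet_wrap(~band) +
    ggplot2::theme_minimal() +
    ggplot2::guides(colour = "none") +
    ggplot2::labs(x = NULL, y = measure)
}
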