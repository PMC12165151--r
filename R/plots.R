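#' Plot a disconnectivity tree
#'
#' Classic disconnectivity-graph rendering: leaves (local minima) hang at
#' their energies, horizontal bars join subtrees at the energy threshold
#' where they disconnect.
#'
#' @param object A [build_disconnectivity()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.disconnectivity <- function(object, ...) {
  tree <- object
  m <- nrow(tree$leaves)
  x <- numeric(m)
  # leaf order: left-to-right in-order traversal of the merge structure
  order_leaves <- function(id) {
    if (id < 0L) -id else c(
      order_leaves(tree$merge[id, 1]), order_leaves(tree$merge[id, 2])
    )
  }
  leaf_order <- if (length(tree$height)) order_leaves(length(tree$height)) else 1L
  x[leaf_order] <- seq_len(m)
  node_x <- function(id) {
    if (id < 0L) x[-id] else mean(c(node_x(tree$merge[id, 1]), node_x(tree$merge[id, 2])))
  }
  node_y <- function(id) if (id < 0L) tree$leaves$energy[-id] else tree$height[id]
  segs <- list()
  for (i in seq_along(tree$height)) {
    kids <- tree$merge[i, ]
    xs <- vapply(kids, node_x, numeric(1))
    ys <- vapply(kids, node_y, numeric(1))
    segs[[length(segs) + 1L]] <- tibble::tibble(
      x = xs, xend = xs, y = ys, yend = tree$height[i]
    )
    segs[[length(segs) + 1L]] <- tibble::tibble(
      x = min(xs), xend = max(xs), y = tree$height[i], yend = tree$height[i]
    )
  }
  seg_df <- if (length(segs)) dplyr::bind_rows(segs) else
    tibble::tibble(x = numeric(), xend = numeric(), y = numeric(), yend = numeric())
  leaf_df <- tibble::tibble(
    x = x, y = tree$leaves$energy,
    label = sprintf("m%d", tree$leaves$minimum)
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg_df,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)
    ) +
    ggplot2::geom_point(data = leaf_df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_text(
      data = leaf_df,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      vjust = 1.8, size = 3
    ) +
    ggplot2::scale_x_continuous(breaks = NULL) +
    ggplot2::labs(x = NULL, y = "Energy") +
    ggplot2::theme_minimal()
}

#' Scatter the two polarization indices across inputs
#'
#' One point per analyzed input, transition-frequency Gini against
#' dwelling-time Gini, colored by group — the classification surface on
#' which polarized and uniform landscape regimes separate.
#'
#' @param object An [run_pipeline()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.elscape_results <- function(object, ...) {
  ggplot2::ggplot(
    object$indices,
    ggplot2::aes(x = .data$gini_trans, y = .data$gini_dwell, color = .data$group)
  ) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::labs(
      x = "Gini coefficient of transition frequencies",
      y = "Gini coefficient of dwelling times",
      color = "Group"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
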