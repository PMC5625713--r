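#' Heatmap of neighbour-preference enrichments
#'
#' Over-represented contexts above 1, under-represented below 1, on a
#' log2 colour scale.
#'
#' @param object A [build_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motif_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$base,
                                   fill = log2(.data$enrichment))) +
    ggplot2::geom_tile(colour = "grey30") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$enrichment)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  midpoint = 0, name = "log2 enrichment") +
    ggplot2::labs(x = "position relative to edited site", y = NULL,
                  title = "Neighbour preference around edited sites") +
    ggplot2::theme_minimal()
}

#' Bar chart of normalized hyper-editing signal across datasets
#'
#' The A-to-G signal with the G-to-A false-positive signal alongside.
#'
#' @param reports Tibble of [signal_report()] rows (or a
#'   [compare_datasets()] table).
#' @return A ggplot.
#' @export
plot_signal <- function(reports) {
  df <- reports |>
    tidyr::pivot_longer(c("normalized_signal", "false_positive_signal"),
                        names_to = "kind", values_to = "signal") |>
    mutate(kind = ifelse(.data$kind == "normalized_signal",
                         "A-to-G", "G-to-A (false positive)"))
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, -.data$signal),
                                   y = .data$signal, fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_fill_manual(values = c("A-to-G" = "firebrick",
                                          "G-to-A (false positive)" = "grey60"),
                               name = NULL) +
    ggplot2::labs(x = NULL, y = "editing events per million mapped bases",
                  title = "Normalized hyper-editing signal") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Histogram of per-site editing levels
#'
#' Colour-coded by tier: strong (> 30\%), moderate (1-30\%), weak (< 1\%).
#'
#' @param site_levels `site_levels` tibble from [unedited_expression()].
#' @return A ggplot.
#' @export
plot_site_levels <- function(site_levels) {
  ggplot2::ggplot(site_levels[!is.na(site_levels$level), ],
                  ggplot2::aes(x = .data$level, fill = .data$tier)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::scale_fill_manual(values = c(strong = "firebrick",
                                          moderate = "orange", weak = "grey60")) +
    ggplot2::labs(x = "editing level (edited / covering reads)", y = "sites",
                  title = "Per-site editing levels") +
    ggplot2::theme_minimal()
}

#' Dendrogram of motif-profile clustering
#'
#' @param object A [cluster_profiles()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.motif_clustering <- function(object, ...) {
  hc <- object$hclust
  dend <- stats::as.dendrogram(hc)
  # simple segment extraction
  segs <- dendro_segments(dend, x0 = 0)
  labs <- tibble(label = hc$labels[hc$order],
                 x = seq_along(hc$order), y = 0) |>
    left_join(object$groups, by = "label")
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend)) +
    ggplot2::geom_text(data = labs,
                       ggplot2::aes(x = .data$x, y = -0.02 * max(segs$y),
                                    label = .data$label,
                                    colour = factor(.data$group)),
                       angle = 90, hjust = 1) +
    ggplot2::scale_colour_brewer(palette = "Set1", name = "group") +
    ggplot2::labs(x = NULL, y = "distance",
                  title = "Clustering of neighbour-preference profiles") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

# recursively convert a dendrogram into plot segments; returns tibble and
# the subtree's x centre via attribute
dendro_segments <- function(node, x0) {
  if (stats::is.leaf(node)) {
    x <- attr(node, "x_leaf") %||% NA
    return(structure(tibble(x = numeric(0), y = numeric(0),
                            xend = numeric(0), yend = numeric(0)),
                     centre = attr(node, "leaf_index")))
  }
  # assign leaf indices in order
  leaves <- stats::order.dendrogram(node)
  idx <- 0
  assign_x <- function(nd) {
    if (stats::is.leaf(nd)) {
      idx <<- idx + 1
      attr(nd, "leaf_index") <- idx
      return(nd)
    }
    for (i in seq_along(nd)) nd[[i]] <- assign_x(nd[[i]])
    nd
  }
  node <- assign_x(node)
  segs <- tibble(x = numeric(0), y = numeric(0), xend = numeric(0), yend = numeric(0))
  centre_of <- function(nd) {
    if (stats::is.leaf(nd)) return(attr(nd, "leaf_index"))
    h <- attr(nd, "height")
    centres <- vapply(seq_along(nd), function(i) {
      c_i <- centre_of(nd[[i]])
      h_i <- if (stats::is.leaf(nd[[i]])) 0 else attr(nd[[i]], "height")
      segs <<- bind_rows(segs, tibble(x = c_i, y = h_i, xend = c_i, yend = h))
      c_i
    }, numeric(1))
    segs <<- bind_rows(segs, tibble(x = min(centres), y = h,
                                    xend = max(centres), yend = h))
    mean(range(centres))
  }
  centre_of(node)
  segs
}
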