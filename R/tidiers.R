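#' Tidy a fuzzy clustering into a long membership table
#'
#' @param x an `fcm_clustering`.
#' @param ... unused.
#' @return tibble: gene, cluster, membership, hard (argmax flag).
#' @export
tidy.fcm_clustering <- function(x, ...) {
  hard <- hard_assignment(x)
  as_tibble(x$membership, rownames = "gene") |>
    tidyr::pivot_longer(-"gene", names_to = "cluster",
                        values_to = "membership") |>
    mutate(cluster = as.integer(sub("^C", "", .data$cluster)),
           hard = .data$cluster == hard[.data$gene])
}

#' @rdname tidy.fcm_clustering
#' @return `glance()`: one-row tibble with k, m, n_genes, objective, n_iter.
#' @export
glance.fcm_clustering <- function(x, ...) {
  tibble(k = x$k, m = x$m, n_genes = nrow(x$membership),
         objective = x$objective, n_iter = x$n_iter,
         n_excluded = length(x$excluded_genes))
}

#' Tidy an inferred importance network into its edge table
#'
#' @param x an `importance_network` or `direct_network`.
#' @param ... unused.
#' @return tibble: regulator, target, importance.
#' @export
tidy.importance_network <- function(x, ...) x$edges

#' @rdname tidy.importance_network
#' @export
tidy.direct_network <- function(x, ...) x$edges

#' @rdname tidy.importance_network
#' @return `glance()`: one-row summary tibble.
#' @export
glance.importance_network <- function(x, ...) {
  tibble(n_edges = nrow(x$edges), n_regulators = length(x$regulators),
         n_trees = x$n_trees, k_mode = as.character(x$k_mode))
}

#' @rdname tidy.importance_network
#' @export
glance.direct_network <- function(x, ...) {
  tibble(n_edges = nrow(x$edges), n_nodes = length(x$node_class),
         window_up = x$window$up, window_down = x$window$down,
         n_dropped_missing_tss = x$dropped$missing_tss)
}

#' Tidy a momentum comparison
#'
#' @param x a `momentum_comparison`.
#' @param ... unused.
#' @return the pairwise rank-test table.
#' @export
tidy.momentum_comparison <- function(x, ...) x$tests

#' @rdname tidy.momentum_comparison
#' @export
glance.momentum_comparison <- function(x, ...) {
  tibble(n_groups = nrow(x$summary), bw = x$bw)
}

#' Centroid-profile plot of a fuzzy clustering
#'
#' @param object an `fcm_clustering`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.fcm_clustering <- function(object, ...) {
  cen <- as_tibble(object$centroids, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "timepoint",
                        values_to = "z") |>
    mutate(day = as.numeric(sub("^d", "", .data$timepoint)))
  ggplot2::ggplot(cen, ggplot2::aes(x = .data$day, y = .data$z,
                                    colour = .data$cluster)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "day after treatment start", y = "centroid (z-score)",
                  colour = "cluster",
                  title = sprintf("Fuzzy c-means centroids (k = %d, m = %.2f)",
                                  object$k, object$m)) +
    ggplot2::theme_minimal()
}

#' Density plot of momentum distributions per group
#'
#' @param object a `momentum_comparison`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.momentum_comparison <- function(object, ...) {
  ggplot2::ggplot(object$density,
                  ggplot2::aes(x = .data$momentum, y = .data$density,
                               colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "transcriptional momentum (|v|^2)", y = "density") +
    ggplot2::theme_minimal()
}

#' Growth-curve plot coloured by response call
#'
#' @param curves long growth-curve tibble (mouse_id, day, area_mm2).
#' @param calls optional tibble from [classify_response()].
#' @param progression_area horizontal reference line.
#' @return a ggplot.
#' @export
plot_growth_curves <- function(curves, calls = NULL, progression_area = 100) {
  d <- curves
  if (!is.null(calls)) {
    d <- left_join(d, calls[, c("mouse_id", "call")], by = "mouse_id")
  } else {
    d$call <- "unclassified"
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$day, y = .data$area_mm2,
                                  group = .data$mouse_id,
                                  colour = .data$call)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = progression_area, linetype = "dashed") +
    ggplot2::labs(x = "day after treatment start",
                  y = expression(tumour~area~(mm^2)), colour = "call") +
    ggplot2::theme_minimal()
}

#' Heatmap of TF-to-ISG importance scores
#'
#' @param score_matrix matrix from [tf_to_isg_matrix()].
#' @return a ggplot.
#' @export
plot_tf_isg_scores <- function(score_matrix) {
  d <- as_tibble(score_matrix, rownames = "tf") |>
    tidyr::pivot_longer(-"tf", names_to = "isg", values_to = "importance")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$isg, y = .data$tf,
                                  fill = .data$importance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "interferon-stimulated gene", y = "transcription factor",
                  fill = "importance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}
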