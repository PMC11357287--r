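#' Scree plot of a Laplace-Beltrami spectrum
#'
#' @param object a [eigendecompose()] result.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.spectral_decomposition <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$eigenvalue)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(
      x = "eigenvalue index",
      y = expression(lambda[k] ~ (ring(A)^-2)),
      title = "Laplace-Beltrami spectrum"
    ) +
    ggplot2::theme_minimal()
}

#' Cluster-quality metrics across cluster counts
#'
#' One panel per validity index, plotted against `K` — the shape of the
#' usual metrics-by-K comparison tables.
#'
#' @param report a [metric_report()] tibble.
#' @return A ggplot.
#' @export
plot_metric_report <- function(report) {
  long <- tidyr::pivot_longer(
    report,
    cols = c("calinski_harabasz", "davies_bouldin", "dunn", "r_squared",
             "silhouette", "std_deviation"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$K, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "number of clusters K", y = NULL,
                  title = "Internal cluster-validity indices") +
    ggplot2::theme_minimal()
}

#' Histograms of topological descriptors
#'
#' Distribution of each descriptor over a molecule library.
#'
#' @param descriptors a [descriptor_table()] tibble.
#' @param bins histogram bin count.
#' @return A ggplot.
#' @export
plot_descriptor_distributions <- function(descriptors, bins = 30) {
  long <- tidyr::pivot_longer(descriptors, cols = -"id",
                              names_to = "descriptor", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = bins, fill = "steelblue",
                            colour = "white") +
    ggplot2::facet_wrap(~descriptor, scales = "free") +
    ggplot2::labs(x = NULL, y = "count",
                  title = "Topological descriptor distributions") +
    ggplot2::theme_minimal()
}

#' Latent embedding coloured by cluster
#'
#' Scatter of the first two latent coordinates (or principal components
#' when the latent space has more than two dimensions), coloured by the
#' cluster assignment.
#'
#' @param Z latent matrix.
#' @param assignment a [kmeans_fit()] result.
#' @return A ggplot.
#' @export
plot_latent_clusters <- function(Z, assignment) {
  Z <- as.matrix(Z)
  if (ncol(Z) > 2) {
    Z <- stats::prcomp(Z)$x[, 1:2]
  }
  df <- tibble::tibble(
    x = Z[, 1], y = Z[, 2],
    cluster = factor(assignment$labels)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$cluster)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "latent 1", y = "latent 2",
                  title = "Latent space clustering") +
    ggplot2::theme_minimal()
}
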