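#' Plot cluster centroids across age steps
#'
#' Line plot of each cluster's centroid trajectory over the seven age
#' steps, coloured by pattern label. Requires ggplot2.
#'
#' @param clusters A `devsurv_clusters` result.
#' @return A ggplot object.
#' @export
plot_centroids <- function(clusters) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_centroids() needs the ggplot2 package", call. = FALSE)
  }
  df <- as.data.frame(clusters$centroids)
  df$cluster <- factor(seq_len(nrow(df)))
  df$label <- clusters$labels
  long <- tidyr::pivot_longer(df, dplyr::starts_with("step"),
                              names_to = "step", values_to = "dss")
  long$step <- factor(long$step, levels = paste0("step", 1:7),
                      labels = STEP_LABELS)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$step, y = .data$dss,
                                     colour = .data$label,
                                     group = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "age step (months)", y = "mean DSS",
                  colour = "pattern") +
    ggplot2::theme_minimal()
}
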