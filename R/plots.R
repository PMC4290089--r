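# ggplot2 visualisations of the pipeline's result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot observed vs expected chromosomal distribution
#'
#' Side-by-side bars of observed and expected counts per chromosome, in
#' the order supplied.
#'
#' @param object A `chrom_dist` from [chisq_uniformity()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chrom_dist <- function(object, ...) {
  d <- tidyr::pivot_longer(object$table, c("observed", "expected"),
                           names_to = "kind", values_to = "count")
  d$category <- factor(d$category, levels = object$table$category)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$count,
                                  fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(
      x = "chromosome", y = "count", fill = NULL,
      subtitle = sprintf("X² = %.1f, df = %d, p = %.2g (%s)",
                         object$statistic, object$df, object$p_value,
                         object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot block size distribution
#'
#' Histogram of block spans; facet by tier.
#'
#' @param object A `block_set`.
#' @param binwidth Histogram bin width in bp (default 20 kb).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.block_set <- function(object, binwidth = 20000, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$span)) +
    ggplot2::geom_histogram(binwidth = binwidth, boundary = 0,
                            fill = "grey30") +
    ggplot2::facet_wrap(~tier) +
    ggplot2::labs(x = sprintf("block span in %s (bp)", attr(object, "species")),
                  y = "blocks") +
    ggplot2::theme_minimal()
}

#' Plot a permutation null distribution
#'
#' Histogram of the null statistic over control sets with the observed
#' value marked.
#'
#' @param object A `permutation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.permutation_result <- function(object, ...) {
  d <- tibble::tibble(null = object$null_total)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$observed, colour = "red") +
    ggplot2::labs(x = "genes with ≥ 1 term (null sets)", y = "sets",
                  subtitle = sprintf("observed = %g, two-sided p = %.3g",
                                     object$observed, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Plot cumulative block spans per species
#'
#' Step curve of the cumulative span of qualifying blocks, ordered by
#' block size, for each species in a pipeline report.
#'
#' @param report A `loss_report` from [run_full_pipeline()].
#' @return A ggplot object.
#' @export
plot_cumulative_spans <- function(report) {
  d <- dplyr::bind_rows(lapply(names(report$spans), function(s) {
    pb <- report$spans[[s]]$per_block
    pb <- pb[pb$in_cumulative, , drop = FALSE]
    pb <- pb[order(pb$span), , drop = FALSE]
    tibble::tibble(species = s, rank = seq_len(nrow(pb)),
                   cumulative = cumsum(pb$span))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$cumulative,
                                  colour = .data$species)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "blocks (smallest first)", y = "cumulative span (bp)") +
    ggplot2::theme_minimal()
}
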