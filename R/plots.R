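# ggplot2 presentation of the main result types.

#' Manhattan-style plot of an association scan
#'
#' @param object An `assoc_scan` (or `meta_scan`) tibble.
#' @param threshold Significance line (default 5e-8).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.assoc_scan <- function(object, threshold = 5e-8, ...) {
  df <- dplyr::mutate(as_tibble(object), log10p = -log10(.data$p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$log10p,
                                   colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = length(unique(df$chrom)) > 1) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Position (Mb)", y = expression(-log[10]~italic(P))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.meta_scan <- function(object, threshold = 5e-8, ...) {
  autoplot.assoc_scan(object, threshold = threshold, ...)
}

#' Haplotype effect estimates with standard-error bars
#'
#' Mirrors the conventional presentation of window-haplotype analyses:
#' per-copy effect of each haplotype relative to the reference (at 0), one
#' panel per population.
#'
#' @param object A `hap_effects` tibble from [estimate_haplotype_effects()]
#'   (rows from several populations may be bound together).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.hap_effects <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$haplotype, y = .data$beta)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$beta - .data$se, ymax = .data$beta + .data$se)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$population), scales = "free_x") +
    ggplot2::labs(x = NULL, y = "Effect per haplotype copy") +
    ggplot2::theme_minimal()
}

#' Plot a neighbor-joining haplotype tree
#'
#' @param x An `nj_tree` from [neighbor_joining()].
#' @param ... Passed to `ape::plot.phylo()`.
#' @return The `phylo` object, invisibly.
#' @export
plot.nj_tree <- function(x, ...) {
  tr <- as_phylo(x)
  ape::plot.phylo(tr, type = "unrooted", ...)
  invisible(tr)
}
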