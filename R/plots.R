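# ggplot2 views of the result types.

#' Plot binned coverage (or normalized ratio) along chromosomes
#'
#' @param profiles A [coverage_profile()] or [normalize_profiles()] tibble.
#' @param what `"ratio"` (if present) or `"mean_depth"`.
#' @param accessions Optional accession subset.
#' @export
plot_coverage <- function(profiles, what = NULL, accessions = NULL) {
  if (is.null(what)) what <- if ("ratio" %in% names(profiles)) "ratio" else "mean_depth"
  if (!is.null(accessions)) {
    profiles <- profiles[profiles$accession %in% accessions, ]
  }
  ggplot2::ggplot(profiles,
                  ggplot2::aes(x = (.data$bin_start + .data$bin_end) / 2e6,
                               y = .data[[what]],
                               colour = .data$accession)) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$accession),
                        cols = ggplot2::vars(.data$chrom),
                        scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = what) +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal()
}

#' Plot probe density along chromosomes
#' @param probes A `probe_set` tibble.
#' @param binwidth Histogram bin width in bp.
#' @export
plot_probe_density <- function(probes, binwidth = 1e5) {
  ggplot2::ggplot(probes, ggplot2::aes(x = .data$start / 1e6)) +
    ggplot2::geom_histogram(binwidth = binwidth / 1e6, boundary = 0) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "probes") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.attribution_table <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$label, y = .data$fraction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "fraction of reads") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.drop_calls <- function(object, ...) {
  ggplot2::ggplot(ungroup(object),
                  ggplot2::aes(y = .data$accession)) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$start / 1e6,
                                       xend = .data$end / 1e6,
                                       yend = .data$accession),
                          linewidth = 3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$chrom), ncol = 1,
                        scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}
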