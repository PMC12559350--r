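#' Plot building-block frequencies among hits
#'
#' Bar charts of building-block hit counts per scaffold position — the
#' at-a-glance view of which blocks a selection enriched.
#'
#' @param hits Hit tibble with `bb1..bbP` columns.
#' @param bb_table Building-block table.
#' @param top_n Show at most this many blocks per position (default 25).
#' @return A ggplot object, faceted by position.
#' @export
plot_bb_frequencies <- function(hits, bb_table, top_n = 25) {
  freq <- bb_frequencies(hits, bb_table) |>
    dplyr::group_by(.data$position) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::ungroup() |>
    dplyr::mutate(bb_id = stats::reorder(.data$bb_id, -.data$n_hits))
  ggplot2::ggplot(freq, ggplot2::aes(x = .data$bb_id, y = .data$n_hits)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~position, scales = "free_x",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "building block", y = "hits containing block") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1,
                                                       size = 6))
}

#' Plot library mass degeneracy
#'
#' @param library A `sel_library`.
#' @param bin_ppm Resolution (default 5 ppm).
#' @return A ggplot: compounds per resolvable mass group vs mass.
#' @export
plot_mass_degeneracy <- function(library, bin_ppm = 5) {
  deg <- mass_degeneracy(library, bin_ppm)
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$mass_lo, y = .data$n_compounds)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(x = "monoisotopic mass (Da)",
                  y = sprintf("compounds within %.0f ppm", bin_ppm)) +
    ggplot2::theme_minimal()
}

#' Plot an extracted-ion chromatogram
#'
#' @param run An [ms_run()].
#' @param mz Target m/z.
#' @param ppm Window (default 5 ppm).
#' @return A ggplot of intensity vs retention time.
#' @export
plot_xic <- function(run, mz, ppm = 5) {
  xic <- extract_ion_chromatogram(run, mz, ppm)
  ggplot2::ggplot(xic, ggplot2::aes(x = .data$rt, y = .data$intensity)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "retention time (s)", y = "intensity",
                  title = sprintf("XIC m/z %.4f (+/- %.0f ppm)", mz, ppm)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot an enrichment report
#'
#' Volcano-style view: fold enrichment vs -log10 p, significant blocks
#' highlighted.
#'
#' @param object A `sel_enrichment` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.sel_enrichment <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$fold_enrichment,
                               y = -.data$log10_p,
                               color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60",
                                           `TRUE` = "firebrick")) +
    ggplot2::labs(x = "fold enrichment", y = "-log10 p",
                  color = "significant") +
    ggplot2::theme_minimal()
}
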