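#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an annotation table
#'
#' Already tabular; `tidy()` strips the class and attributes down to a plain
#' tibble of per-scan candidate annotations.
#'
#' @param x A `sel_annotations` from [comet_filter()].
#' @param ... Ignored.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.sel_annotations <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of an annotation run
#'
#' @param x A `sel_annotations`.
#' @param ... Ignored.
#' @return Tibble `n_scans_total, n_scans_retained, retained_fraction,
#'   n_compounds, n_accepted_scans`.
#' @exportS3Method generics::glance
glance.sel_annotations <- function(x, ...) {
  tibble::tibble(
    n_scans_total = attr(x, "n_scans_total"),
    n_scans_retained = attr(x, "n_scans_retained"),
    retained_fraction = attr(x, "retained_fraction"),
    n_compounds = length(unique(x$compound_id[x$accepted])),
    n_accepted_scans = sum(x$accepted))
}

#' Tidy an enrichment report
#'
#' @param x A `sel_enrichment` from [enrichment_report()].
#' @param ... Ignored.
#' @return A plain tibble.
#' @exportS3Method generics::tidy
tidy.sel_enrichment <- function(x, ...) {
  tibble::as_tibble(x)
}

#' One-row summary of an enrichment report
#'
#' @param x A `sel_enrichment`.
#' @param ... Ignored.
#' @return Tibble `n_tested, n_significant, alpha, min_p`.
#' @exportS3Method generics::glance
glance.sel_enrichment <- function(x, ...) {
  tibble::tibble(n_tested = nrow(x),
                 n_significant = sum(x$significant),
                 alpha = attr(x, "alpha"),
                 min_p = min(x$p_value))
}

#' @importFrom rlang .data
#' @importFrom dplyr n
NULL
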