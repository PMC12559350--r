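#' Maximum enrichment of an affinity selection
#'
#' The enrichment of a selection is the binder fraction after selection over
#' the binder fraction in the full library:
#' `(found_binders / compounds_after_selection) / (total_binders / total_library)`.
#' Because the true number of binders in a library is unknown, the *maximum*
#' enrichment postulates the total binders equal to the found binders, in
#' which case the statistic reduces to `total_library / compounds_after_selection`.
#'
#' @param found_binders Number of binders identified after selection.
#' @param compounds_after_selection Number of compounds annotated after
#'   selection.
#' @param total_binders Total binders in the library; defaults to
#'   `found_binders` (the maximum-enrichment postulate).
#' @param total_library Library size.
#' @return Fold enrichment (vectorized).
#' @examples
#' max_enrichment(74, 228, total_library = 499720) # 2191.75 ~ 2.2e3
#' @export
max_enrichment <- function(found_binders, compounds_after_selection,
                           total_binders = found_binders, total_library) {
  if (any(compounds_after_selection <= 0) || any(total_library <= 0) ||
      any(total_binders <= 0)) {
    stop("Counts must be positive", call. = FALSE)
  }
  if (any(found_binders > compounds_after_selection) ||
      any(total_binders > total_library)) {
    stop("found_binders <= compounds_after_selection and ",
         "total_binders <= total_library required", call. = FALSE)
  }
  (found_binders / compounds_after_selection) /
    (total_binders / total_library)
}

#' Building-block frequencies in a hit table
#'
#' Tallies how often each building block occurs among hits, per position.
#'
#' @param hits Tibble with `bb1..bbP` columns (e.g. from [hit_table()]).
#' @param bb_table Building-block table; counts are reported for every block
#'   (zeros included) and unknown hit blocks raise an error.
#' @return Tibble `position, bb_id, n_hits, hits_total, frequency`, sorted by
#'   descending count within position.
#' @export
bb_frequencies <- function(hits, bb_table) {
  bb_table <- building_blocks(bb_table)
  bb_cols <- grep("^bb[0-9]+$", names(hits), value = TRUE)
  if (!length(bb_cols)) stop("Hit table has no bb<position> columns", call. = FALSE)
  purrr::map_dfr(seq_along(bb_cols), function(p) {
    ids <- bb_table$bb_id[bb_table$position == p]
    obs <- hits[[bb_cols[p]]]
    bad <- setdiff(obs, ids)
    if (length(bad)) {
      stop("Hit references unknown bb_id '", bad[1], "' at position ", p,
           call. = FALSE)
    }
    cnt <- table(factor(obs, levels = ids))
    tibble::tibble(position = p, bb_id = ids, n_hits = as.integer(cnt[ids]),
                   hits_total = nrow(hits),
                   frequency = as.integer(cnt[ids]) / nrow(hits))
  }) |>
    dplyr::arrange(.data$position, dplyr::desc(.data$n_hits), .data$bb_id)
}

#' One-sided hypergeometric enrichment of a building block
#'
#' Tests whether hits containing a building block are over-represented
#' relative to the block's share of the library: the upper-tail probability
#' `P(X >= hits_with_bb)` when drawing `hits_total` compounds without
#' replacement from a library with `library_with_bb` block-containing members
#' (Fisher's exact test, one-sided, computed in log space so p-values far
#' below 1e-300 keep a finite log).
#'
#' @param hits_with_bb,hits_total Hit counts with/overall.
#' @param library_with_bb,library_total Library counts with/overall.
#' @return Tibble `fold_enrichment, p_value, log10_p`; degenerate margins
#'   (block in no or every library compound, or no hits) give p = 1.
#' @export
fisher_enrichment <- function(hits_with_bb, hits_total, library_with_bb,
                              library_total) {
  stopifnot(hits_with_bb <= hits_total, library_with_bb <= library_total,
            hits_with_bb >= 0, library_with_bb >= 0)
  if (hits_total > library_total || hits_with_bb > library_with_bb) {
    stop("Hit counts exceed library counts; hits must be distinct library ",
         "compounds", call. = FALSE)
  }
  lib_frac <- library_with_bb / library_total
  fold <- if (hits_total > 0 && lib_frac > 0) {
    (hits_with_bb / hits_total) / lib_frac
  } else {
    NA_real_
  }
  if (hits_total == 0 || library_with_bb == 0 ||
      library_with_bb == library_total || hits_with_bb == 0) {
    return(tibble::tibble(fold_enrichment = fold, p_value = 1, log10_p = 0))
  }
  logp <- stats::phyper(hits_with_bb - 1, library_with_bb,
                        library_total - library_with_bb, hits_total,
                        lower.tail = FALSE, log.p = TRUE)
  tibble::tibble(fold_enrichment = fold,
                 p_value = max(exp(logp), .Machine$double.xmin),
                 log10_p = logp / log(10))
}

#' Per-building-block enrichment report
#'
#' Runs [fisher_enrichment()] for every building block at every position,
#' attaches Benjamini-Hochberg q-values across all tested blocks, and sorts
#' by p-value.
#'
#' @param hits Hit tibble with `bb1..bbP` columns.
#' @param library The `sel_library` the hits were decoded against.
#' @param alpha Significance level for the `significant` flag on q (default
#'   0.05).
#' @return A `sel_enrichment` tibble `position, bb_id, hits_with_bb,
#'   hits_total, library_with_bb, library_total, library_fraction,
#'   fold_enrichment, p_value, log10_p, q_value, significant`.
#' @export
enrichment_report <- function(hits, library, alpha = 0.05) {
  if (!nrow(hits)) stop("Empty hit table", call. = FALSE)
  bb_table <- attr(library, "bb_table")
  freq <- bb_frequencies(hits, bb_table)
  bb_cols <- grep("^bb[0-9]+$", names(library), value = TRUE)
  lib_counts <- purrr::map_dfr(seq_along(bb_cols), function(p) {
    tab <- table(library[[bb_cols[p]]])
    tibble::tibble(position = p, bb_id = names(tab),
                   library_with_bb = as.integer(tab))
  })
  out <- freq |>
    dplyr::left_join(lib_counts, by = c("position", "bb_id")) |>
    dplyr::mutate(library_with_bb = dplyr::coalesce(.data$library_with_bb, 0L),
                  library_total = nrow(library),
                  library_fraction = .data$library_with_bb / .data$library_total)
  stats <- purrr::pmap_dfr(
    list(out$n_hits, out$hits_total, out$library_with_bb, out$library_total),
    fisher_enrichment)
  out <- dplyr::bind_cols(
    dplyr::rename(out, hits_with_bb = "n_hits"), stats)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out$significant <- out$q_value <= alpha
  out <- out[order(out$p_value, -out$fold_enrichment, out$bb_id), ]
  out$frequency <- NULL
  structure(out, alpha = alpha,
            class = c("sel_enrichment", class(out)))
}
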