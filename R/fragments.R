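#' Parse a fragment-type grammar string
#'
#' The grammar describes which pieces of an assembled library member are
#' expected as MS2 fragment ions. Tokens are comma-separated:
#' * `S[i;j]` — the contiguous building-block span at 0-based positions
#'   `i..j` *plus* the scaffold offset formula (`S[i:j]` is accepted as an
#'   alias);
#' * a bare integer `k` — the building block at position `k` alone, without
#'   the scaffold offset.
#'
#' @param spec Grammar string, e.g. `"S[0;1], S[1;2],0,2"`; `""` gives an
#'   empty list.
#' @param n_positions Design arity for bounds checking (optional; pass the
#'   design's position count to reject out-of-range tokens at parse time).
#' @return Tibble `token, kind, start, end` in input order; `kind` is
#'   `"span_with_scaffold"` or `"single_position"`.
#' @examples
#' parse_fragment_types("S[0;1], S[1;2],0,2")
#' @export
parse_fragment_types <- function(spec, n_positions = NULL) {
  stopifnot(is.character(spec), length(spec) == 1L)
  spec <- gsub("\\s", "", spec)
  empty <- tibble::tibble(token = character(0), kind = character(0),
                          start = integer(0), end = integer(0))
  if (!nzchar(spec)) return(empty)
  toks <- strsplit(spec, ",", fixed = TRUE)[[1]]
  out <- purrr::map_dfr(toks, function(tok) {
    if (grepl("^S\\[[0-9]+[;:][0-9]+\\]$", tok)) {
      ij <- as.integer(strsplit(gsub("^S\\[|\\]$", "", tok), "[;:]")[[1]])
      if (ij[1] > ij[2]) {
        stop("Fragment-type token '", tok, "': start > end", call. = FALSE)
      }
      tibble::tibble(token = tok, kind = "span_with_scaffold",
                     start = ij[1], end = ij[2])
    } else if (grepl("^[0-9]+$", tok)) {
      k <- as.integer(tok)
      tibble::tibble(token = tok, kind = "single_position", start = k, end = k)
    } else {
      stop("Malformed fragment-type token '", tok, "'", call. = FALSE)
    }
  })
  if (!is.null(n_positions) && nrow(out) &&
      any(out$end >= n_positions)) {
    bad <- out$token[out$end >= n_positions][1]
    stop("Fragment-type token '", bad, "' outside design positions 0..",
         n_positions - 1L, call. = FALSE)
  }
  out
}

.H_ATOM_MASS <- 1.0078250319  # hydrogen-atom transfer per shift unit

#' Predict fragment ions for one library compound
#'
#' For each fragment type, the neutral fragment formula is the sum of the
#' contribution formulas of the covered positions (plus the scaffold offset
#' formula for span types). Each type is emitted at `2H + 1` hydrogen-shift
#' variants (`-H..+H` hydrogen-atom rearrangements, 1.0078250 Da per unit),
#' ionized with the configured adduct at charge 1.
#'
#' @param bb_formulas Character vector of contribution formulas, one per
#'   position, in position order (e.g. the row of a library member joined to
#'   its building-block table).
#' @param design A [scaffold_design()].
#' @param types Parsed fragment types ([parse_fragment_types()]) or a grammar
#'   string; defaults to the design's own `fragment_types`.
#' @param hydrogen_shifts Max hydrogen shift H (default 1, giving shift
#'   variants -1, 0, +1).
#' @param adduct Ionization adduct (default the design's).
#' @return Tibble `fragment_type, h_shift, formula, mz`, sorted by m/z and
#'   deduplicated within 1e-6 Da. Fragments whose shifted formula would have a
#'   negative atom count are skipped with a warning.
#' @export
predict_fragments <- function(bb_formulas, design, types = NULL,
                              hydrogen_shifts = 1, adduct = NULL) {
  if (is.null(types)) types <- design$fragment_types
  if (is.character(types)) {
    types <- parse_fragment_types(types, design$n_positions)
  }
  adduct <- adduct %||% design$adduct
  a_mass <- adduct_mass(adduct)
  empty <- tibble::tibble(fragment_type = character(0), h_shift = integer(0),
                          formula = character(0), mz = numeric(0))
  if (!nrow(types)) return(empty)
  if (length(bb_formulas) != design$n_positions) {
    stop("Expected ", design$n_positions, " building-block formulas, got ",
         length(bb_formulas), call. = FALSE)
  }
  offset <- parse_formula(design$scaffold_offset)
  shifts <- seq.int(-hydrogen_shifts, hydrogen_shifts)
  rows <- purrr::map_dfr(seq_len(nrow(types)), function(i) {
    tp <- types[i, ]
    pos <- (tp$start:tp$end) + 1L  # grammar is 0-based
    f <- do.call(formula_combine, lapply(bb_formulas[pos], parse_formula))
    if (tp$kind == "span_with_scaffold") f <- formula_combine(f, offset)
    purrr::map_dfr(shifts, function(h) {
      fh <- formula_combine(f, c(H = 1L), coef = c(1L, as.integer(h)))
      if (any(fh < 0L)) {
        warning("Skipping fragment ", tp$token, " at h=", h,
                ": negative atom count", call. = FALSE)
        return(NULL)
      }
      tibble::tibble(fragment_type = tp$token, h_shift = as.integer(h),
                     formula = formula_to_string(fh),
                     mz = monoisotopic_mass(fh) + a_mass)
    })
  })
  if (!nrow(rows)) return(empty)
  rows <- rows[order(rows$mz), ]
  # drop ions indistinguishable at numeric precision
  keep <- c(TRUE, diff(rows$mz) > 1e-6)
  rows[keep, ]
}

# Fragment m/z vectors for a set of compounds, memoized by compound_id.
# Used by the annotator so isobaric candidates reuse predictions.
fragment_cache <- function(library, design, types = NULL,
                           hydrogen_shifts = 1, adduct = NULL) {
  bb_table <- attr(library, "bb_table")
  bb_cols <- grep("^bb[0-9]+$", names(library), value = TRUE)
  form_lookup <- lapply(seq_along(bb_cols), function(p) {
    sub <- bb_table[bb_table$position == p, ]
    stats::setNames(sub$formula, sub$bb_id)
  })
  cache <- new.env(parent = emptyenv())
  function(compound_id) {
    hit <- get0(compound_id, envir = cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    row <- library[library$compound_id == compound_id, ][1, ]
    forms <- vapply(seq_along(bb_cols),
                    function(p) form_lookup[[p]][[row[[bb_cols[p]]]]],
                    character(1))
    fr <- predict_fragments(forms, design, types, hydrogen_shifts, adduct)
    cache[[compound_id]] <- fr
    fr
  }
}

#' Predict fragment lists for every compound in a library
#'
#' @param library A `sel_library`.
#' @param design Defaults to the library's own design.
#' @param ... Passed to [predict_fragments()].
#' @return Tibble `compound_id, fragment_type, h_shift, formula, mz` (the TSV
#'   export layout).
#' @export
predict_fragment_table <- function(library, design = attr(library, "design"), ...) {
  getter <- fragment_cache(library, design, ...)
  purrr::map_dfr(library$compound_id, function(id) {
    dplyr::mutate(getter(id), compound_id = id, .before = 1)
  })
}

#' Estimate fragmentation frequencies from annotated spectra
#'
#' Given MS2 scans paired with their known (true) compounds, computes for each
#' candidate fragment type the fraction of spectra containing at least one
#' peak matching a predicted ion of that type within the tolerance. This is
#' the empirical basis for choosing which fragment types the annotation filter
#' should consider for a scaffold.
#'
#' @param scans Tibble with `scan_id`, `peaks` (list column of
#'   `mz`/`intensity` tibbles) and `compound_id` (the true compound).
#' @param library A `sel_library` containing those compounds.
#' @param types Candidate fragment types (string or parsed).
#' @param ppm MS2 matching tolerance in ppm (default 5).
#' @param hydrogen_shifts,adduct Passed to [predict_fragments()].
#' @return Tibble `fragment_type, n_matched, n_spectra, frequency`.
#' @export
estimate_fragmentation_frequencies <- function(scans, library, types,
                                               ppm = 5, hydrogen_shifts = 1,
                                               adduct = NULL) {
  if (!nrow(scans)) stop("Empty spectrum set", call. = FALSE)
  design <- attr(library, "design")
  if (is.character(types)) types <- parse_fragment_types(types, design$n_positions)
  getter <- fragment_cache(library, design, types, hydrogen_shifts, adduct)
  counts <- stats::setNames(integer(nrow(types)), types$token)
  for (i in seq_len(nrow(scans))) {
    fr <- getter(scans$compound_id[i])
    pk_mz <- scans$peaks[[i]]$mz
    if (!length(pk_mz)) next
    for (tok in unique(fr$fragment_type)) {
      pred <- fr$mz[fr$fragment_type == tok]
      hit <- any(vapply(pred, function(p) any(abs(pk_mz - p) / p * 1e6 <= ppm),
                        logical(1)))
      if (hit) counts[[tok]] <- counts[[tok]] + 1L
    }
  }
  tibble::tibble(fragment_type = types$token,
                 n_matched = as.integer(counts[types$token]),
                 n_spectra = nrow(scans),
                 frequency = as.numeric(counts[types$token]) / nrow(scans))
}
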