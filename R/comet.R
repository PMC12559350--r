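#' Annotation filter configuration
#'
#' Bundles the tolerances and filter settings for matching MS2 scans against
#' an enumerated library. The defaults are the workflow's standard settings:
#' 5 ppm precursor and fragment accuracy, at least 1 predicted fragment among
#' the 5 most intense MS2 peaks, hydrogen shifts up to +-1, singly protonated
#' positive ions, 10 s / 3-fold background-subtraction thresholds.
#'
#' @param ms1_ppm Precursor (MS1) mass accuracy, ppm.
#' @param ms2_ppm Fragment (MS2) mass accuracy, ppm.
#' @param rt_tol_s Retention-time tolerance for background subtraction, s.
#' @param max_intensity_ratio Background-subtraction intensity-ratio cutoff.
#' @param min_matching_peaks Minimum number of distinct top-N peaks that must
#'   match predicted fragments for a scan to be retained.
#' @param n_considered_peaks Number of most intense MS2 peaks considered.
#' @param hydrogen_shifts Max hydrogen shift for fragment prediction.
#' @param adduct Ionization adduct.
#' @param fragment_types Optional grammar string overriding the design's.
#' @param scaffold_formula Optional scaffold formula overriding the design's.
#' @return A `comet_config` list.
#' @export
comet_config <- function(ms1_ppm = 5, ms2_ppm = 5, rt_tol_s = 10,
                         max_intensity_ratio = 3, min_matching_peaks = 1,
                         n_considered_peaks = 5, hydrogen_shifts = 1,
                         adduct = "[M+H]+", fragment_types = NULL,
                         scaffold_formula = NULL) {
  stopifnot(ms1_ppm > 0, ms2_ppm > 0, min_matching_peaks >= 1,
            n_considered_peaks >= min_matching_peaks, hydrogen_shifts >= 0)
  structure(list(ms1_ppm = ms1_ppm, ms2_ppm = ms2_ppm, rt_tol_s = rt_tol_s,
                 max_intensity_ratio = max_intensity_ratio,
                 min_matching_peaks = as.integer(min_matching_peaks),
                 n_considered_peaks = as.integer(n_considered_peaks),
                 hydrogen_shifts = as.integer(hydrogen_shifts),
                 adduct = adduct, fragment_types = fragment_types,
                 scaffold_formula = scaffold_formula),
            class = "comet_config")
}

#' Library compounds consistent with a precursor
#'
#' Converts the observed precursor m/z to a neutral mass
#' (`(mz - adduct_mass) * charge`) and returns every library compound within
#' the MS1 tolerance, nearest first.
#'
#' @param precursor_mz Observed precursor m/z.
#' @param library A `sel_library`.
#' @param ms1_ppm Tolerance in ppm.
#' @param adduct Adduct assumed for the precursor.
#' @param charge Precursor charge (default 1).
#' @return Library subset with `delta_ppm`, sorted by `|delta_ppm|`.
#' @export
precursor_candidates <- function(precursor_mz, library, ms1_ppm = 5,
                                 adduct = "[M+H]+", charge = 1L) {
  neutral <- (precursor_mz - adduct_mass(adduct)) * charge
  library_mass_window(library, neutral, ms1_ppm)
}

#' Count predicted-fragment matches in a scan
#'
#' Among the `n_considered` most intense peaks, a peak matches when it lies
#' within `ms2_ppm` of a predicted ion (predicted m/z as the ppm reference).
#' Peak-ion pairs are assigned greedily by ascending ppm error, each peak and
#' each predicted ion used at most once; the count is the number of distinct
#' matched peaks.
#'
#' @param peaks Scan peak tibble (`mz, intensity`).
#' @param fragment_mz Numeric vector of predicted ion m/z values.
#' @param ms2_ppm Fragment tolerance, ppm.
#' @param n_considered Number of top peaks considered (default 5).
#' @return List with `count` and `detail` (tibble `peak_mz, peak_intensity,
#'   fragment_mz, delta_ppm`).
#' @export
count_fragment_matches <- function(peaks, fragment_mz, ms2_ppm = 5,
                                   n_considered = 5) {
  top <- top_n_peaks(peaks, n_considered)
  detail <- tibble::tibble(peak_mz = numeric(0), peak_intensity = numeric(0),
                           fragment_mz = numeric(0), delta_ppm = numeric(0))
  if (!nrow(top) || !length(fragment_mz)) {
    return(list(count = 0L, detail = detail))
  }
  # all in-tolerance peak x ion pairs, greedy by |delta ppm|
  pairs <- expand.grid(p = seq_len(nrow(top)), f = seq_along(fragment_mz))
  dppm <- abs(top$mz[pairs$p] - fragment_mz[pairs$f]) /
    fragment_mz[pairs$f] * 1e6
  ok <- dppm <= ms2_ppm
  pairs <- pairs[ok, , drop = FALSE]
  dppm <- dppm[ok]
  ord <- order(dppm)
  used_p <- logical(nrow(top)); used_f <- logical(length(fragment_mz))
  for (k in ord) {
    if (used_p[pairs$p[k]] || used_f[pairs$f[k]]) next
    used_p[pairs$p[k]] <- TRUE; used_f[pairs$f[k]] <- TRUE
    detail <- dplyr::bind_rows(detail, tibble::tibble(
      peak_mz = top$mz[pairs$p[k]], peak_intensity = top$intensity[pairs$p[k]],
      fragment_mz = fragment_mz[pairs$f[k]], delta_ppm = dppm[k]))
  }
  list(count = sum(used_p), detail = detail)
}

.empty_annotations <- function() {
  tibble::tibble(scan_id = character(0), rt = numeric(0),
                 precursor_mz = numeric(0), compound_id = character(0),
                 precursor_delta_ppm = numeric(0), n_matched = integer(0),
                 score = numeric(0), rank = integer(0), accepted = logical(0))
}

#' Filter and annotate MS2 scans against a library
#'
#' The core decoding filter: a scan is retained iff its precursor neutral
#' mass matches a library compound within the MS1 tolerance *and* at least
#' `min_matching_peaks` of its `n_considered_peaks` most intense MS2 peaks
#' match that compound's predicted fragment ions within the MS2 tolerance.
#' Retained scans carry all qualifying candidates, scored and ranked (see
#' [rank_candidates()]); the rank-1 candidate of each retained scan is marked
#' accepted.
#'
#' @param run An [ms_run()] (background-subtracted, or not — the filter does
#'   not subtract).
#' @param library A `sel_library`.
#' @param config A [comet_config()].
#' @return A `sel_annotations` tibble `scan_id, rt, precursor_mz,
#'   compound_id, precursor_delta_ppm, n_matched, score, rank, accepted` with
#'   attributes `n_scans_total`, `n_scans_retained`, `retained_fraction` and
#'   `run_id`.
#' @export
comet_filter <- function(run, library, config = comet_config()) {
  design <- attr(library, "design")
  types <- config$fragment_types %||% design$fragment_types
  if (!is.null(config$scaffold_formula)) {
    design$scaffold_offset <- config$scaffold_formula
  }
  getter <- fragment_cache(library, design, types,
                           config$hydrogen_shifts, config$adduct)
  scans <- run$scans
  out <- purrr::map_dfr(seq_len(nrow(scans)), function(i) {
    cand <- precursor_candidates(scans$precursor_mz[i], library,
                                 config$ms1_ppm, config$adduct,
                                 scans$precursor_charge[i])
    if (!nrow(cand)) return(NULL)
    rows <- purrr::map_dfr(seq_len(nrow(cand)), function(j) {
      fr <- getter(cand$compound_id[j])
      m <- count_fragment_matches(scans$peaks[[i]], fr$mz, config$ms2_ppm,
                                  config$n_considered_peaks)
      if (m$count < config$min_matching_peaks) return(NULL)
      top <- top_n_peaks(scans$peaks[[i]], config$n_considered_peaks)
      tot <- sum(top$intensity)
      score <- if (tot > 0) sum(m$detail$peak_intensity) / tot else 0
      score <- min(1, score + 1e-6 * m$count)
      tibble::tibble(compound_id = cand$compound_id[j],
                     precursor_delta_ppm = cand$delta_ppm[j],
                     n_matched = m$count, score = score)
    })
    if (!nrow(rows) || !ncol(rows)) return(NULL)
    rows <- rows[order(-rows$score, rows$compound_id), ]
    rows$rank <- seq_len(nrow(rows))
    rows$accepted <- rows$rank == 1L
    dplyr::mutate(rows, scan_id = scans$scan_id[i], rt = scans$rt[i],
                  precursor_mz = scans$precursor_mz[i], .before = 1)
  })
  if (!nrow(out) || !ncol(out)) out <- .empty_annotations()
  out <- out[, names(.empty_annotations())]
  n_ret <- length(unique(out$scan_id))
  structure(out,
            n_scans_total = nrow(scans), n_scans_retained = n_ret,
            retained_fraction = if (nrow(scans)) n_ret / nrow(scans) else NA_real_,
            run_id = run$run_id,
            class = c("sel_annotations", class(out)))
}

#' Score and rank isobaric candidates for one scan
#'
#' The candidate score is the intensity-weighted fragment coverage: the
#' summed intensity of matched top-N peaks over the summed intensity of all
#' top-N peaks, with a `1e-6 * n_matched` tie-nudge, clipped to \[0, 1\].
#' Candidates are returned in descending score order (deterministic; ties
#' after the nudge break by compound id).
#'
#' @param peaks Scan peak tibble.
#' @param candidates Tibble with `compound_id` and a `fragment_mz` list
#'   column of predicted ion m/z vectors.
#' @param config A [comet_config()].
#' @return Tibble `compound_id, n_matched, score, rank`.
#' @export
rank_candidates <- function(peaks, candidates, config = comet_config()) {
  stopifnot(nrow(candidates) > 0)
  top <- top_n_peaks(peaks, config$n_considered_peaks)
  tot <- sum(top$intensity)
  rows <- purrr::map_dfr(seq_len(nrow(candidates)), function(j) {
    m <- count_fragment_matches(peaks, candidates$fragment_mz[[j]],
                                config$ms2_ppm, config$n_considered_peaks)
    score <- if (tot > 0) sum(m$detail$peak_intensity) / tot else 0
    tibble::tibble(compound_id = candidates$compound_id[j],
                   n_matched = m$count,
                   score = min(1, score + 1e-6 * m$count))
  })
  rows <- rows[order(-rows$score, rows$compound_id), ]
  rows$rank <- seq_len(nrow(rows))
  rows
}

#' Merge annotations across replicate runs
#'
#' @param annotation_list List of `sel_annotations` (one per run).
#' @param mode `"union"` keeps every accepted annotation with run provenance;
#'   `"intersection"` keeps compounds accepted in all runs.
#' @return Tibble `compound_id, n_runs, runs, best_score` with attribute
#'   `jaccard` (pairwise Jaccard matrix of accepted compound sets).
#' @export
merge_replicates <- function(annotation_list, mode = c("union", "intersection")) {
  mode <- match.arg(mode)
  stopifnot(length(annotation_list) >= 1)
  run_ids <- purrr::map_chr(seq_along(annotation_list), function(i) {
    attr(annotation_list[[i]], "run_id") %||% paste0("run", i)
  })
  acc <- purrr::map2_dfr(annotation_list, run_ids, function(a, id) {
    a <- a[a$accepted, c("compound_id", "score")]
    a$run_id <- rep(id, nrow(a))
    a
  })
  sets <- lapply(annotation_list, function(a) unique(a$compound_id[a$accepted]))
  jac <- outer(seq_along(sets), seq_along(sets),
               Vectorize(function(i, j) {
                 u <- length(union(sets[[i]], sets[[j]]))
                 if (u == 0) 1 else length(intersect(sets[[i]], sets[[j]])) / u
               }))
  dimnames(jac) <- list(run_ids, run_ids)
  if (!nrow(acc)) {
    out <- tibble::tibble(compound_id = character(0), n_runs = integer(0),
                          runs = character(0), best_score = numeric(0))
    return(structure(out, jaccard = jac, mode = mode))
  }
  out <- acc |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(n_runs = dplyr::n_distinct(.data$run_id),
                     runs = paste(sort(unique(.data$run_id)), collapse = ";"),
                     best_score = max(.data$score), .groups = "drop")
  if (mode == "intersection") {
    out <- out[out$n_runs == length(annotation_list), ]
  }
  out <- out[order(-out$best_score, out$compound_id), ]
  structure(out, jaccard = jac, mode = mode)
}

#' Accepted compound hits from an annotation table
#'
#' Deduplicates accepted (rank-1) scan annotations to one row per compound,
#' joining back the building-block columns from the library.
#'
#' @param annotations A `sel_annotations` tibble.
#' @param library The `sel_library` used for annotation.
#' @return Tibble `compound_id, bb1..bbP, n_scans, best_score`.
#' @export
hit_table <- function(annotations, library) {
  acc <- annotations[annotations$accepted, ]
  bb_cols <- grep("^bb[0-9]+$", names(library), value = TRUE)
  if (!nrow(acc)) {
    out <- tibble::tibble(compound_id = character(0))
    for (b in bb_cols) out[[b]] <- character(0)
    out$n_scans <- integer(0); out$best_score <- numeric(0)
    return(out)
  }
  hits <- acc |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(n_scans = dplyr::n(), best_score = max(.data$score),
                     .groups = "drop")
  dplyr::left_join(hits,
                   tibble::as_tibble(library)[, c("compound_id", bb_cols)],
                   by = "compound_id") |>
    dplyr::relocate(dplyr::all_of(bb_cols), .after = "compound_id")
}
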