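#' Construct an LC-MS/MS run container
#'
#' A run holds centroided MS1 spectra, MS2 scans (with their precursor m/z and
#' retention time) and MS1 features. Retention times are seconds everywhere.
#'
#' @param run_id Run identifier string.
#' @param scans Tibble of MS2 scans: `scan_id, precursor_mz, precursor_charge,
#'   rt, peaks` where `peaks` is a list column of `mz`/`intensity` tibbles
#'   sorted by m/z.
#' @param ms1 Tibble of MS1 spectra: `scan_id, rt, peaks` (same peak layout).
#' @param features Tibble of MS1 features: `feature_id, mz, rt_apex, rt_lo,
#'   rt_hi, intensity, ms2_scan_ids` (list column of linked scan ids), or
#'   `NULL` to build them from the MS1 spectra with [find_features()].
#' @param polarity `"positive"` (default) or `"negative"`.
#' @param source Provenance string (file path, simulator tag, ...).
#' @return An `ms_run` object.
#' @export
ms_run <- function(run_id, scans = NULL, ms1 = NULL, features = NULL,
                   polarity = "positive", source = NA_character_) {
  scans <- scans %||% tibble::tibble(scan_id = character(0),
                                     precursor_mz = numeric(0),
                                     precursor_charge = integer(0),
                                     rt = numeric(0), peaks = list())
  ms1 <- ms1 %||% tibble::tibble(scan_id = character(0), rt = numeric(0),
                                 peaks = list())
  scans$peaks <- lapply(scans$peaks, .validate_peaks)
  ms1$peaks <- lapply(ms1$peaks, .validate_peaks)
  if (is.null(features)) features <- find_features(ms1, ms2 = scans)
  missing_link <- setdiff(unlist(features$ms2_scan_ids), scans$scan_id)
  if (length(missing_link)) {
    stop("Feature links reference unknown MS2 scan id(s): ",
         paste(utils::head(missing_link, 3), collapse = ", "), call. = FALSE)
  }
  structure(list(run_id = run_id, scans = scans, ms1 = ms1,
                 features = features, polarity = polarity, source = source),
            class = "ms_run")
}

.validate_peaks <- function(p) {
  p <- tibble::as_tibble(p)
  if (!nrow(p)) {
    return(tibble::tibble(mz = numeric(0), intensity = numeric(0)))
  }
  stopifnot(all(p$mz > 0), all(p$intensity >= 0))
  p[order(p$mz), c("mz", "intensity")]
}

#' @export
print.ms_run <- function(x, ...) {
  cat("<ms_run> ", x$run_id, ": ", nrow(x$ms1), " MS1 spectra, ",
      nrow(x$scans), " MS2 scans, ", nrow(x$features), " features (",
      x$polarity, " mode)\n", sep = "")
  invisible(x)
}

.empty_features <- function() {
  tibble::tibble(feature_id = character(0), mz = numeric(0),
                 rt_apex = numeric(0), rt_lo = numeric(0), rt_hi = numeric(0),
                 intensity = numeric(0), ms2_scan_ids = list())
}

#' Detect MS1 features in a run
#'
#' A deliberately transparent finder: MS1 peaks are grouped across spectra
#' when their m/z values chain within `ppm` and their retention times within
#' `rt_gap_s` of a group member. The feature m/z and intensity are taken at
#' the apex (most intense member). MS2 scans are linked to the feature whose
#' m/z window contains the precursor and whose retention-time span (padded by
#' `rt_gap_s`) covers the scan; ties go to the nearest m/z.
#'
#' @param ms1 Tibble of MS1 spectra (`scan_id, rt, peaks`).
#' @param ppm m/z grouping tolerance (default 5).
#' @param rt_gap_s Max retention-time gap within a feature, seconds (default 6).
#' @param ms2 Optional tibble of MS2 scans to link.
#' @return Feature tibble (see [ms_run()]).
#' @export
find_features <- function(ms1, ppm = 5, rt_gap_s = 6, ms2 = NULL) {
  if (is.null(ms1) || !nrow(ms1)) return(.empty_features())
  pk <- purrr::map_dfr(seq_len(nrow(ms1)), function(i) {
    p <- ms1$peaks[[i]]
    if (!nrow(p)) return(NULL)
    tibble::tibble(rt = ms1$rt[i], mz = p$mz, intensity = p$intensity)
  })
  if (is.null(pk) || !nrow(pk)) return(.empty_features())
  pk <- pk[order(pk$mz), ]
  mz_grp <- cumsum(c(1L, diff(pk$mz) > ppm * 1e-6 * pk$mz[-nrow(pk)]))
  feats <- pk |>
    dplyr::mutate(mz_grp = mz_grp) |>
    dplyr::group_by(.data$mz_grp) |>
    dplyr::arrange(.data$rt, .by_group = TRUE) |>
    dplyr::mutate(rt_grp = cumsum(c(1L, diff(.data$rt) > rt_gap_s))) |>
    dplyr::group_by(.data$mz_grp, .data$rt_grp) |>
    dplyr::summarise(mz = .data$mz[which.max(.data$intensity)],
                     rt_apex = .data$rt[which.max(.data$intensity)],
                     rt_lo = min(.data$rt), rt_hi = max(.data$rt),
                     intensity = max(.data$intensity), .groups = "drop") |>
    dplyr::arrange(.data$mz, .data$rt_apex)
  feats$feature_id <- sprintf("F%04d", seq_len(nrow(feats)))
  feats <- feats[, c("feature_id", "mz", "rt_apex", "rt_lo", "rt_hi", "intensity")]
  feats$ms2_scan_ids <- replicate(nrow(feats), character(0), simplify = FALSE)
  if (!is.null(ms2) && nrow(ms2)) {
    for (i in seq_len(nrow(ms2))) {
      dmz <- abs(ms2$precursor_mz[i] - feats$mz) / feats$mz * 1e6
      ok <- dmz <= ppm &
        ms2$rt[i] >= feats$rt_lo - rt_gap_s &
        ms2$rt[i] <= feats$rt_hi + rt_gap_s
      if (any(ok)) {
        j <- which(ok)[which.min(dmz[ok])]
        feats$ms2_scan_ids[[j]] <- c(feats$ms2_scan_ids[[j]], ms2$scan_id[i])
      }
    }
  }
  feats
}

#' Read a centroided mzML file
#'
#' Parses all spectra via mzR. MS2 scans must carry a precursor m/z (scans
#' without one are skipped with a warning); profile-mode data are rejected
#' with advice to centroid first. MS1 features are built with
#' [find_features()] unless a sidecar feature table is supplied.
#'
#' @param path mzML file.
#' @param feature_table Optional path to a sidecar feature TSV (see
#'   [write_feature_table()]); overrides feature finding.
#' @param ppm,rt_gap_s Feature-finder parameters.
#' @return An [ms_run()].
#' @export
read_mzml <- function(path, feature_table = NULL, ppm = 5, rt_gap_s = 6) {
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  if (!nrow(hdr)) {
    return(ms_run(run_id = basename(path), source = path))
  }
  if (any(!is.na(hdr$centroided) & !hdr$centroided)) {
    stop("Profile-mode spectra in '", path,
         "': centroid the data before import", call. = FALSE)
  }
  pk <- mzR::peaks(ms)
  if (is.matrix(pk)) pk <- list(pk)
  peak_tbl <- lapply(pk, function(m) {
    tibble::tibble(mz = m[, 1], intensity = m[, 2])
  })
  rt <- hdr$retentionTime
  is_ms2 <- hdr$msLevel >= 2L
  no_prec <- is_ms2 & (is.na(hdr$precursorMZ) | hdr$precursorMZ <= 0)
  if (any(no_prec)) {
    warning(sum(no_prec), " MS2 scan(s) without precursor m/z skipped",
            call. = FALSE)
  }
  keep2 <- which(is_ms2 & !no_prec)
  scans <- tibble::tibble(
    scan_id = paste0("scan", hdr$acquisitionNum[keep2]),
    precursor_mz = hdr$precursorMZ[keep2],
    precursor_charge = {
      z <- hdr$precursorCharge[keep2]
      as.integer(ifelse(is.na(z) | z == 0L, 1L, z))
    },
    rt = rt[keep2],
    peaks = peak_tbl[keep2])
  keep1 <- which(hdr$msLevel == 1L)
  ms1 <- tibble::tibble(scan_id = paste0("scan", hdr$acquisitionNum[keep1]),
                        rt = rt[keep1], peaks = peak_tbl[keep1])
  features <- if (!is.null(feature_table)) {
    read_feature_table(feature_table)
  } else {
    find_features(ms1, ppm = ppm, rt_gap_s = rt_gap_s, ms2 = scans)
  }
  pol <- if (all(hdr$polarity <= 0, na.rm = TRUE)) "negative" else "positive"
  ms_run(run_id = sub("\\.mzML$", "", basename(path), ignore.case = TRUE),
         scans = scans, ms1 = ms1, features = features,
         polarity = pol, source = path)
}

#' Write a run to mzML
#'
#' Spectra (MS1 then MS2, ordered by retention time) are written via mzR.
#' Reading the file back reproduces every scan's m/z (1e-6), intensity (1e-3)
#' and retention time (1e-3).
#'
#' @param run An [ms_run()].
#' @param path Output path (`.mzML`).
#' @export
write_mzml <- function(run, path) {
  ms1 <- run$ms1
  ms2 <- run$scans
  n1 <- nrow(ms1); n2 <- nrow(ms2)
  n <- n1 + n2
  if (n == 0L) {
    # mzR cannot write a 0-spectrum file; emit one empty MS1 spectrum
    ms1 <- tibble::tibble(scan_id = "scan1", rt = 0,
                          peaks = list(tibble::tibble(mz = numeric(0),
                                                      intensity = numeric(0))))
    n1 <- 1L; n <- 1L
  }
  rt <- c(ms1$rt, ms2$rt)
  lvl <- c(rep(1L, n1), rep(2L, n2))
  ord <- order(rt, lvl)
  peaks_all <- c(ms1$peaks, ms2$peaks)[ord]
  rt <- rt[ord]; lvl <- lvl[ord]
  prec_mz <- c(rep(NA_real_, n1), ms2$precursor_mz)[ord]
  prec_z <- c(rep(NA_integer_, n1), ms2$precursor_charge)[ord]
  npk <- vapply(peaks_all, nrow, integer(1))
  tic <- vapply(peaks_all, function(p) sum(p$intensity), numeric(1))
  bp_i <- vapply(peaks_all, function(p) if (nrow(p)) max(p$intensity) else 0, numeric(1))
  bp_mz <- vapply(peaks_all, function(p) {
    if (nrow(p)) p$mz[which.max(p$intensity)] else 0
  }, numeric(1))
  pol <- if (identical(run$polarity, "negative")) 0L else 1L
  is2 <- lvl == 2L
  # precursor scan = most recent MS1 spectrum
  last_ms1 <- cummax(ifelse(is2, 0L, seq_len(n)))
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = lvl,
    polarity = pol, peaksCount = npk, totIonCurrent = tic,
    retentionTime = rt, basePeakMZ = bp_mz, basePeakIntensity = bp_i,
    collisionEnergy = ifelse(is2, 25, 0), ionisationEnergy = 0,
    lowMZ = vapply(peaks_all, function(p) if (nrow(p)) min(p$mz) else 0, numeric(1)),
    highMZ = vapply(peaks_all, function(p) if (nrow(p)) max(p$mz) else 0, numeric(1)),
    precursorScanNum = ifelse(is2, last_ms1, 0L),
    precursorMZ = ifelse(is2, prec_mz, 0),
    precursorCharge = ifelse(is2, prec_z, 0L),
    precursorIntensity = ifelse(is2, 100, 0),
    mergedScan = 0L, mergedResultScanNum = 0L,
    mergedResultStartScanNum = 0L, mergedResultEndScanNum = 0L,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = ifelse(is2, prec_mz, NA_real_),
    isolationWindowLowerOffset = ifelse(is2, 1, NA_real_),
    isolationWindowUpperOffset = ifelse(is2, 1, NA_real_),
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE)
  pk_list <- lapply(peaks_all, function(p) {
    cbind(mz = p$mz, intensity = p$intensity)
  })
  mzR::writeMSData(object = pk_list, file = path, header = hdr,
                   outformat = "mzml")
  invisible(path)
}

#' Write / read a sidecar feature table
#'
#' TSV with columns `feature_id, mz, rt_s, rt_lo, rt_hi, intensity,
#' ms2_scan_ids` (scan ids semicolon-joined).
#'
#' @param features Feature tibble from an [ms_run()].
#' @param path TSV path.
#' @export
write_feature_table <- function(features, path) {
  out <- features
  out$ms2_scan_ids <- vapply(out$ms2_scan_ids, paste, character(1),
                             collapse = ";")
  names(out)[names(out) == "rt_apex"] <- "rt_s"
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE)
  names(x)[names(x) == "rt_s"] <- "rt_apex"
  x$ms2_scan_ids <- lapply(strsplit(
    ifelse(is.na(x$ms2_scan_ids), "", x$ms2_scan_ids), ";", fixed = TRUE),
    function(v) v[nzchar(v)])
  tibble::as_tibble(x)
}

#' Most intense peaks of a scan
#'
#' Selects the `n` most intense peaks (all peaks if fewer), breaking intensity
#' ties in favor of the lower m/z. The returned sublist preserves the
#' original ascending m/z order.
#'
#' @param peaks Tibble `mz, intensity` sorted by m/z.
#' @param n Number of peaks to keep (the annotation default is 5).
#' @return Peak tibble, subset of the input.
#' @export
top_n_peaks <- function(peaks, n) {
  stopifnot(n >= 1)
  if (nrow(peaks) <= n) return(peaks)
  ord <- order(-peaks$intensity, peaks$mz)
  peaks[sort(ord[seq_len(n)]), ]
}

#' Extracted-ion chromatogram
#'
#' Per MS1 spectrum, the summed intensity of peaks within `ppm` of the target
#' m/z (target as the ppm reference).
#'
#' @param run An [ms_run()].
#' @param mz Target m/z.
#' @param ppm Window half-width in ppm (default 5).
#' @return Tibble `rt, intensity`, one row per MS1 spectrum.
#' @export
extract_ion_chromatogram <- function(run, mz, ppm = 5) {
  stopifnot(ppm > 0)
  tibble::tibble(
    rt = run$ms1$rt,
    intensity = vapply(run$ms1$peaks, function(p) {
      sum(p$intensity[abs(p$mz - mz) / mz * 1e6 <= ppm])
    }, numeric(1)))
}
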