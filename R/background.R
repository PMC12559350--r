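#' Match sample features to control features
#'
#' Each sample feature is paired with the nearest-in-m/z control feature lying
#' within both the ppm and retention-time tolerances (one match per sample
#' feature; unmatched features are absent from the result).
#'
#' @param sample,control [ms_run()] objects with features.
#' @param ppm_tol m/z tolerance in ppm (default 5; control feature m/z is the
#'   reference).
#' @param rt_tol_s Retention-time tolerance in seconds (default 10).
#' @return Tibble `sample_feature_id, control_feature_id, delta_ppm,
#'   delta_rt_s, intensity_ratio` (sample/control; `Inf` when the control
#'   intensity is 0).
#' @export
match_features <- function(sample, control, ppm_tol = 5, rt_tol_s = 10) {
  sf <- sample$features
  cf <- control$features
  empty <- tibble::tibble(sample_feature_id = character(0),
                          control_feature_id = character(0),
                          delta_ppm = numeric(0), delta_rt_s = numeric(0),
                          intensity_ratio = numeric(0))
  if (!nrow(sf) || !nrow(cf)) return(empty)
  out <- purrr::map_dfr(seq_len(nrow(sf)), function(i) {
    dppm <- abs(sf$mz[i] - cf$mz) / cf$mz * 1e6
    drt <- abs(sf$rt_apex[i] - cf$rt_apex)
    ok <- dppm <= ppm_tol & drt <= rt_tol_s
    if (!any(ok)) return(NULL)
    j <- which(ok)[which.min(dppm[ok])]
    tibble::tibble(sample_feature_id = sf$feature_id[i],
                   control_feature_id = cf$feature_id[j],
                   delta_ppm = dppm[j], delta_rt_s = drt[j],
                   intensity_ratio = sf$intensity[i] / cf$intensity[j])
  })
  if (!nrow(out) || !ncol(out)) empty else out
}

#' Remove control-run background from a sample run
#'
#' A sample feature is removed iff it matches a feature in *any* bead-only
#' control run (within the m/z and retention-time tolerances) and its
#' sample/control intensity ratio falls below `max_intensity_ratio` — i.e.
#' features genuinely enriched in the sample (ratio at or above the
#' threshold) survive. MS2 scans linked to removed features are removed with
#' them; everything else is preserved. A removal log is attached as the
#' `"removal_log"` attribute.
#'
#' @param sample An [ms_run()].
#' @param controls A single [ms_run()] or list of control runs.
#' @param ppm_tol,rt_tol_s Matching tolerances (defaults 5 ppm, 10 s).
#' @param max_intensity_ratio Features with sample/control ratio below this
#'   are considered background (default 3).
#' @return The filtered [ms_run()].
#' @export
subtract_background <- function(sample, controls, ppm_tol = 5, rt_tol_s = 10,
                                max_intensity_ratio = 3) {
  stopifnot(ppm_tol > 0, rt_tol_s > 0, max_intensity_ratio > 0)
  if (inherits(controls, "ms_run")) controls <- list(controls)
  log <- purrr::map_dfr(controls, function(ctrl) {
    m <- match_features(sample, ctrl, ppm_tol, rt_tol_s)
    m$control_run_id <- rep(ctrl$run_id, nrow(m))
    m
  })
  removed_ids <- unique(log$sample_feature_id[log$intensity_ratio < max_intensity_ratio])
  keep <- !(sample$features$feature_id %in% removed_ids)
  removed_scans <- unique(unlist(sample$features$ms2_scan_ids[!keep]))
  out <- sample
  out$features <- sample$features[keep, ]
  out$scans <- sample$scans[!(sample$scans$scan_id %in% removed_scans), ]
  log$removed <- if (nrow(log)) log$intensity_ratio < max_intensity_ratio else logical(0)
  attr(out, "removal_log") <- log
  out
}
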