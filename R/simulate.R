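#' Synthetic building-block sets
#'
#' Generates plausible contribution formulas (amino-acid / carboxylic-acid
#' sized residues: C3-12 H5-20 N0-3 O1-4 S0-1) for a combinatorial design, for
#' benchmarking the decoder without any measured data. Deterministic given
#' the seed; clearly synthetic (ids `P<position>B<k>`).
#'
#' @param sizes Integer vector: number of blocks per position (length P).
#' @param seed Random seed.
#' @return Building-block tibble (see [building_blocks()]).
#' @export
synthetic_building_blocks <- function(sizes, seed = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  purrr::map_dfr(seq_along(sizes), function(p) {
    n <- sizes[p]
    # sample distinct formulas so ids encode distinct masses where possible
    f <- character(n)
    seen <- character(0)
    for (i in seq_len(n)) {
      repeat {
        v <- c(C = sample(3:12, 1), H = sample(5:20, 1),
               N = sample(0:3, 1), O = sample(1:4, 1),
               S = sample(0:1, 1, prob = c(0.85, 0.15)))
        s <- formula_to_string(v[v > 0])
        if (!s %in% seen || length(seen) >= 200) break
      }
      seen <- c(seen, s)
      f[i] <- s
    }
    tibble::tibble(bb_id = sprintf("P%dB%03d", p, seq_len(n)),
                   position = p,
                   name = sprintf("synthetic block %d/%d", p, seq_len(n)),
                   formula = f)
  }) |> building_blocks()
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Simulation configuration
#'
#' Parameters of the ground-truthed experiment generator. Defaults emulate a
#' small affinity-selection measurement: a few-hundred-member sublibrary in
#' which a subset of members are true binders, data-dependent acquisition
#' with one MS2 scan per binder feature, log-normal intensities, Gaussian
#' relative m/z jitter, noise scans with precursors rejection-sampled at
#' least 50 ppm away from every library mass, and background features
#' injected into both sample and control at intensity ratios below the
#' subtraction threshold.
#'
#' @param n_binders Number of true binder compounds drawn from the library.
#' @param binder_ids Explicit binder compound ids (overrides `n_binders`).
#' @param emission_prob Per-fragment-type emission probability; a single
#'   value, or a named vector by fragment-type token.
#' @param n_noise_scans Number of decoy MS2 scans.
#' @param noise_peaks_lambda Poisson mean of noise peaks per scan.
#' @param intensity_meanlog,intensity_sdlog Log-normal intensity parameters
#'   (arbitrary counts; defaults exp(10) median, ~2.7-fold spread).
#' @param ppm_jitter_sd Gaussian m/z jitter, ppm (applied to theoretical
#'   values; 0 gives exact masses).
#' @param rt_window_s Retention-time window (features uniform in it).
#' @param n_background Number of background features shared with the control.
#' @param background_ratio_range Sample/control intensity ratio range for
#'   background features (uniform; keep below the subtraction threshold for
#'   removable background).
#' @param decoy_offset_ppm Minimum distance of noise precursors from any
#'   library mass, ppm.
#' @param ms2_per_binder MS2 scans per binder feature.
#' @param seed Random seed; the same seed reproduces identical runs and
#'   truth tables.
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_binders = 50, binder_ids = NULL,
                              emission_prob = 1, n_noise_scans = 500,
                              noise_peaks_lambda = 8,
                              intensity_meanlog = 10, intensity_sdlog = 1,
                              ppm_jitter_sd = 0, rt_window_s = c(60, 1800),
                              n_background = 100,
                              background_ratio_range = c(0.5, 2.5),
                              decoy_offset_ppm = 50, ms2_per_binder = 1,
                              seed = 1L) {
  stopifnot(all(emission_prob >= 0), all(emission_prob <= 1),
            decoy_offset_ppm > 0, ms2_per_binder >= 1)
  structure(list(n_binders = n_binders, binder_ids = binder_ids,
                 emission_prob = emission_prob,
                 n_noise_scans = n_noise_scans,
                 noise_peaks_lambda = noise_peaks_lambda,
                 intensity_meanlog = intensity_meanlog,
                 intensity_sdlog = intensity_sdlog,
                 ppm_jitter_sd = ppm_jitter_sd, rt_window_s = rt_window_s,
                 n_background = n_background,
                 background_ratio_range = background_ratio_range,
                 decoy_offset_ppm = decoy_offset_ppm,
                 ms2_per_binder = ms2_per_binder, seed = seed),
            class = "sim_config")
}

.jitter_mz <- function(mz, ppm_sd) {
  if (ppm_sd <= 0) return(mz)
  mz * (1 + stats::rnorm(length(mz), 0, ppm_sd * 1e-6))
}

#' Simulate a ground-truthed affinity-selection experiment
#'
#' Produces a sample run, a bead-only control run and a truth table. Each
#' true binder receives an MS1 feature at its adduct m/z (jittered), a random
#' retention time and `ms2_per_binder` MS2 scans whose peaks are the
#' compound's predicted fragment ions, each emitted independently with the
#' configured per-type probability, plus Poisson noise peaks. Noise scans get
#' precursors rejection-sampled away from all library masses. Background
#' features appear in both runs at sample/control ratios drawn from the
#' configured range, each with one MS2 scan of pure noise in the sample run.
#'
#' @param library A `sel_library`.
#' @param config A [simulation_config()].
#' @return List `sample` ([ms_run()]), `control` ([ms_run()]), `truth` (list
#'   of `scans` and `features` label tibbles), `config`.
#' @export
simulate_experiment <- function(library, config = simulation_config()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  design <- attr(library, "design")
  a_mass <- adduct_mass(design$adduct)
  types <- parse_fragment_types(design$fragment_types, design$n_positions)
  if (!nrow(types)) stop("Design has no fragment types to emit", call. = FALSE)
  getter <- fragment_cache(library, design)

  binders <- config$binder_ids %||%
    sample(library$compound_id, config$n_binders)
  if (!all(binders %in% library$compound_id)) {
    stop("Binder id(s) not in library: ",
         paste(utils::head(setdiff(binders, library$compound_id), 3),
               collapse = ", "), call. = FALSE)
  }
  eprob <- config$emission_prob
  prob_for <- function(tok) {
    if (length(eprob) == 1L && is.null(names(eprob))) return(unname(eprob))
    if (!tok %in% names(eprob)) {
      stop("No emission probability for fragment type '", tok, "'",
           call. = FALSE)
    }
    unname(eprob[[tok]])
  }
  rint <- function(n) stats::rlnorm(n, config$intensity_meanlog,
                                    config$intensity_sdlog)
  rrt <- function(n) stats::runif(n, config$rt_window_s[1], config$rt_window_s[2])

  scan_counter <- 0L
  new_scan_id <- function() {
    scan_counter <<- scan_counter + 1L
    sprintf("S%05d", scan_counter)
  }
  noise_peaks <- function() {
    k <- stats::rpois(1, config$noise_peaks_lambda)
    if (k == 0L) {
      return(tibble::tibble(mz = numeric(0), intensity = numeric(0)))
    }
    tibble::tibble(mz = stats::runif(k, 80, 1200), intensity = rint(k))
  }

  truth_scans <- list(); truth_feats <- list()
  smp_ms1 <- list(); smp_ms2 <- list(); ctl_ms1 <- list()

  # --- binder features + MS2 scans (sample only)
  for (b in binders) {
    mass <- library$monoisotopic_mass[library$compound_id == b]
    fmz <- .jitter_mz(mass + a_mass, config$ppm_jitter_sd)
    rt <- rrt(1)
    inten <- rint(1)
    smp_ms1[[length(smp_ms1) + 1L]] <- tibble::tibble(
      rt = rt, mz = fmz, intensity = inten, origin = b)
    fr <- getter(b)
    for (s in seq_len(config$ms2_per_binder)) {
      # one emission decision per fragment type; an emitted type contributes
      # all its hydrogen-shift variants (all-or-none, so observed per-type
      # frequencies estimate the emission probabilities directly)
      toks <- unique(fr$fragment_type)
      emitted_toks <- toks[vapply(toks, function(tok) {
        stats::runif(1) < prob_for(tok)
      }, logical(1))]
      emit <- fr$fragment_type %in% emitted_toks
      pk <- tibble::tibble(mz = .jitter_mz(fr$mz[emit], config$ppm_jitter_sd),
                           intensity = rint(sum(emit)))
      pk <- dplyr::bind_rows(pk, noise_peaks())
      sid <- new_scan_id()
      smp_ms2[[length(smp_ms2) + 1L]] <- tibble::tibble(
        scan_id = sid, precursor_mz = fmz, precursor_charge = 1L,
        rt = rt + stats::runif(1, 0, 2), peaks = list(pk))
      truth_scans[[length(truth_scans) + 1L]] <- tibble::tibble(
        scan_id = sid, label = "binder", compound_id = b)
    }
    truth_feats[[length(truth_feats) + 1L]] <- tibble::tibble(
      mz = fmz, rt = rt, label = "binder", compound_id = b)
  }

  # --- noise scans: precursors kept >= decoy_offset_ppm from any library mass
  lib_mass <- library$monoisotopic_mass
  for (i in seq_len(config$n_noise_scans)) {
    repeat {
      pm <- stats::runif(1, min(lib_mass) + a_mass - 50,
                         max(lib_mass) + a_mass + 50)
      neutral <- pm - a_mass
      near <- library_mass_window(library, neutral, config$decoy_offset_ppm)
      if (!nrow(near)) break
    }
    sid <- new_scan_id()
    smp_ms2[[length(smp_ms2) + 1L]] <- tibble::tibble(
      scan_id = sid, precursor_mz = pm, precursor_charge = 1L,
      rt = rrt(1), peaks = list(noise_peaks()))
    truth_scans[[length(truth_scans) + 1L]] <- tibble::tibble(
      scan_id = sid, label = "noise", compound_id = NA_character_)
  }

  # --- background features, shared between sample and control
  for (i in seq_len(config$n_background)) {
    repeat {
      bmz <- stats::runif(1, 150, 1500)
      near <- library_mass_window(library, bmz - a_mass,
                                  config$decoy_offset_ppm)
      if (!nrow(near)) break
    }
    rt <- rrt(1)
    s_int <- rint(1)
    ratio <- stats::runif(1, config$background_ratio_range[1],
                          config$background_ratio_range[2])
    smp_ms1[[length(smp_ms1) + 1L]] <- tibble::tibble(
      rt = rt, mz = bmz, intensity = s_int, origin = "background")
    ctl_ms1[[length(ctl_ms1) + 1L]] <- tibble::tibble(
      rt = rt, mz = bmz, intensity = s_int / ratio, origin = "background")
    sid <- new_scan_id()
    smp_ms2[[length(smp_ms2) + 1L]] <- tibble::tibble(
      scan_id = sid, precursor_mz = bmz, precursor_charge = 1L,
      rt = rt + stats::runif(1, 0, 2), peaks = list(noise_peaks()))
    truth_scans[[length(truth_scans) + 1L]] <- tibble::tibble(
      scan_id = sid, label = "background", compound_id = NA_character_)
    truth_feats[[length(truth_feats) + 1L]] <- tibble::tibble(
      mz = bmz, rt = rt, label = "background", compound_id = NA_character_)
  }

  pack_ms1 <- function(rows, prefix) {
    if (!length(rows)) {
      return(tibble::tibble(scan_id = character(0), rt = numeric(0),
                            peaks = list()))
    }
    df <- dplyr::bind_rows(rows)
    df |>
      dplyr::group_by(.data$rt) |>
      dplyr::summarise(peaks = list(dplyr::pick("mz", "intensity")),
                       .groups = "drop") |>
      dplyr::mutate(scan_id = sprintf("%s%04d", prefix, dplyr::row_number()),
                    .before = 1)
  }
  smp_scans <- if (length(smp_ms2)) dplyr::bind_rows(smp_ms2) else NULL
  sample_run <- ms_run("sample", scans = smp_scans,
                       ms1 = pack_ms1(smp_ms1, "M1S"),
                       source = "selms simulator")
  control_run <- ms_run("control", ms1 = pack_ms1(ctl_ms1, "M1C"),
                        source = "selms simulator")
  truth <- list(
    scans = if (length(truth_scans)) dplyr::bind_rows(truth_scans) else
      tibble::tibble(scan_id = character(0), label = character(0),
                     compound_id = character(0)),
    features = if (length(truth_feats)) dplyr::bind_rows(truth_feats) else
      tibble::tibble(mz = numeric(0), rt = numeric(0), label = character(0),
                     compound_id = character(0)))
  list(sample = sample_run, control = control_run, truth = truth,
       config = config)
}

#' Evaluate decoding against simulation ground truth
#'
#' @param annotations A `sel_annotations` tibble from [comet_filter()] on a
#'   simulated sample run.
#' @param truth The `truth` element of [simulate_experiment()].
#' @return Tibble (one row) `recall, precision, n_true, n_detected,
#'   n_correct, n_false_annotations`: recall is correctly annotated true
#'   compounds over detectable (scanned) true compounds; a false annotation
#'   is an accepted compound absent from the truth.
#' @export
evaluate_decoding <- function(annotations, truth) {
  ts <- truth$scans
  if (nrow(annotations) &&
      length(setdiff(unique(annotations$scan_id), ts$scan_id))) {
    stop("Annotations reference scan ids absent from the truth table; ",
         "run mismatch?", call. = FALSE)
  }
  true_compounds <- unique(ts$compound_id[ts$label == "binder"])
  acc <- annotations[annotations$accepted, ]
  acc <- dplyr::left_join(acc, ts, by = "scan_id", suffix = c("", "_true"))
  correct <- unique(acc$compound_id[!is.na(acc$compound_id_true) &
                                      acc$compound_id == acc$compound_id_true])
  false_comp <- unique(acc$compound_id[!acc$compound_id %in% true_compounds])
  tibble::tibble(
    recall = if (length(true_compounds)) {
      length(correct) / length(true_compounds)
    } else {
      NA_real_
    },
    precision = if (nrow(acc)) {
      length(correct) / length(unique(acc$compound_id))
    } else {
      NA_real_
    },
    n_true = length(true_compounds),
    n_detected = length(unique(acc$compound_id)),
    n_correct = length(correct),
    n_false_annotations = length(false_comp))
}
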