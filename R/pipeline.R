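.COMET_DEFAULTS <- list(ms1_ppm = 5, ms2_ppm = 5, rt_tol_s = 10,
                        max_intensity_ratio = 3, min_matching_peaks = 1,
                        n_considered_peaks = 5, hydrogen_shifts = 1,
                        adduct = "[M+H]+")

#' Validate and normalize a pipeline configuration
#'
#' Reads a YAML pipeline config (or takes an equivalent list), fills every
#' omitted annotation setting with the workflow defaults (5 ppm MS1/MS2,
#' min 1 matching peak, 5 considered peaks, 1 hydrogen shift, 10 s / 3-fold
#' background subtraction), rejects unknown keys, and reports *all* schema
#' violations at once. Normalization is idempotent.
#'
#' @param config Path to a YAML file, or a config list.
#' @return The normalized config list (class `pipeline_config`).
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("Config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  errors <- character(0)
  known <- c("design", "building_blocks", "comet", "simulation", "runs",
             "output_dir", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    errors <- c(errors, paste0("unknown key(s): ", paste(unknown, collapse = ", ")))
  }
  if (is.null(config$design)) {
    errors <- c(errors, "missing 'design' (design_id, n_positions, ...)")
  } else {
    for (k in c("design_id", "n_positions")) {
      if (is.null(config$design[[k]])) {
        errors <- c(errors, paste0("design: missing '", k, "'"))
      }
    }
    config$design$scaffold_offset <- config$design$scaffold_offset %||% ""
    config$design$fragment_types <- config$design$fragment_types %||% ""
    config$design$adduct <- config$design$adduct %||% "[M+H]+"
  }
  if (is.null(config$building_blocks)) {
    errors <- c(errors, "missing 'building_blocks' (path: or synthetic: {sizes, seed})")
  } else if (!is.null(config$building_blocks$path)) {
    if (!file.exists(config$building_blocks$path)) {
      errors <- c(errors, paste0("building_blocks path does not exist: ",
                                 config$building_blocks$path))
    }
  } else if (is.null(config$building_blocks$synthetic)) {
    errors <- c(errors, "building_blocks needs 'path' or 'synthetic'")
  }
  cfg_comet <- config$comet %||% list()
  unknown_c <- setdiff(names(cfg_comet),
                       c(names(.COMET_DEFAULTS), "fragment_types",
                         "scaffold_formula"))
  if (length(unknown_c)) {
    errors <- c(errors, paste0("comet: unknown key(s): ",
                               paste(unknown_c, collapse = ", ")))
  }
  config$comet <- utils::modifyList(.COMET_DEFAULTS, cfg_comet)
  if (!is.null(config$runs)) {
    for (p in c(config$runs$sample, unlist(config$runs$controls))) {
      if (!file.exists(p)) {
        errors <- c(errors, paste0("run file does not exist: ", p))
      }
    }
  } else if (is.null(config$simulation)) {
    errors <- c(errors, "need either 'runs' (mzML paths) or 'simulation'")
  }
  config$output_dir <- config$output_dir %||% "selms_out"
  config$seed <- config$seed %||% 1L
  if (length(errors)) {
    stop("Invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "),
         call. = FALSE)
  }
  structure(config, class = "pipeline_config")
}

#' Run the full decoding pipeline
#'
#' Stages, in order: enumerate the library from the building-block table;
#' obtain runs (simulate a ground-truthed experiment, or read mzML files);
#' subtract control background; filter and annotate MS2 scans; build the hit
#' table and per-building-block enrichment report; evaluate against truth
#' when simulating. Every output file is listed in a manifest with its MD5
#' hash; identical config + seed reproduces identical manifests.
#'
#' @param config A [validate_config()]-normalized config (or path/list, which
#'   will be validated).
#' @param dry_run Print the stage plan and write nothing.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the in-memory results and the `manifest`
#'   tibble (`file, md5`).
#' @export
run_pipeline <- function(config, dry_run = FALSE, quiet = FALSE) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  say <- function(...) if (!quiet) message("[selms] ", ...)
  stages <- c("enumerate", if (is.null(config$runs)) "simulate" else "ingest",
              "subtract", "annotate", "enrich",
              if (is.null(config$runs)) "evaluate")
  if (dry_run) {
    say("plan: ", paste(stages, collapse = " -> "),
        " (output dir: ", config$output_dir, "); nothing written")
    return(invisible(list(plan = stages, manifest = tibble::tibble(
      file = character(0), md5 = character(0)))))
  }
  out_dir <- config$output_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outfile <- function(...) file.path(out_dir, ...)
  written <- character(0)
  emit <- function(path) written <<- c(written, path)

  design <- scaffold_design(config$design$design_id,
                            config$design$n_positions,
                            config$design$scaffold_offset,
                            config$design$fragment_types,
                            config$design$adduct)
  bb <- if (!is.null(config$building_blocks$path)) {
    read_building_blocks(config$building_blocks$path)
  } else {
    synthetic_building_blocks(
      unlist(config$building_blocks$synthetic$sizes),
      config$building_blocks$synthetic$seed %||% config$seed)
  }
  lib <- enumerate_library(bb, design)
  say("enumerate: ", nrow(lib), " compounds")
  emit(write_library(lib, outfile("library.tsv")))

  truth <- NULL
  if (is.null(config$runs)) {
    sim_args <- config$simulation %||% list()
    sim_args$seed <- sim_args$seed %||% config$seed
    sim <- simulate_experiment(lib, do.call(simulation_config, sim_args))
    say("simulate: ", nrow(sim$sample$scans), " sample MS2 scans, ",
        nrow(sim$sample$features), " features")
    emit(write_mzml(sim$sample, outfile("sample.mzML")))
    emit(write_mzml(sim$control, outfile("control.mzML")))
    readr::write_tsv(sim$truth$scans, outfile("truth_scans.tsv"))
    emit(outfile("truth_scans.tsv"))
    yaml::write_yaml(unclass(sim$config), outfile("sim_config.yaml"))
    emit(outfile("sim_config.yaml"))
    sample_run <- sim$sample; controls <- list(sim$control)
    truth <- sim$truth
  } else {
    sample_run <- read_mzml(config$runs$sample)
    controls <- lapply(unlist(config$runs$controls), read_mzml)
    say("ingest: ", nrow(sample_run$scans), " sample MS2 scans")
  }

  cc <- do.call(comet_config, config$comet)
  sub <- subtract_background(sample_run, controls, cc$ms1_ppm, cc$rt_tol_s,
                             cc$max_intensity_ratio)
  say("subtract: ", nrow(sample_run$features) - nrow(sub$features),
      " background features removed")
  ann <- comet_filter(sub, lib, cc)
  say("annotate: ", attr(ann, "n_scans_retained"), "/",
      attr(ann, "n_scans_total"), " scans retained")
  readr::write_tsv(tibble::as_tibble(ann), outfile("annotations.tsv"))
  emit(outfile("annotations.tsv"))
  hits <- hit_table(ann, lib)
  readr::write_tsv(hits, outfile("hits.tsv"))
  emit(outfile("hits.tsv"))
  enr <- NULL
  if (nrow(hits)) {
    enr <- enrichment_report(hits, lib)
    readr::write_tsv(tibble::as_tibble(enr), outfile("enrichment.tsv"))
    emit(outfile("enrichment.tsv"))
    say("enrich: ", sum(enr$significant), " significant building blocks")
  }
  metrics <- NULL
  if (!is.null(truth)) {
    metrics <- evaluate_decoding(ann, truth)
    readr::write_tsv(metrics, outfile("metrics.tsv"))
    emit(outfile("metrics.tsv"))
    say("evaluate: recall ", round(metrics$recall, 3), ", ",
        metrics$n_false_annotations, " false annotations")
  }
  manifest <- tibble::tibble(file = basename(written),
                             md5 = unname(tools::md5sum(written)))
  readr::write_tsv(manifest, outfile("manifest.tsv"))
  invisible(list(library = lib, annotations = ann, hits = hits,
                 enrichment = enr, metrics = metrics, manifest = manifest))
}
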