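test_that("simulation is deterministic given the seed", {
  lib <- toy_library()
  cfg <- simulation_config(n_binders = 4, n_noise_scans = 20,
                           n_background = 10, ppm_jitter_sd = 2, seed = 77)
  s1 <- simulate_experiment(lib, cfg)
  s2 <- simulate_experiment(lib, cfg)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$sample$scans, s2$sample$scans)
  expect_identical(s1$control$ms1, s2$control$ms1)
  # and byte-identical mzML payloads
  f1 <- withr::local_tempfile(fileext = ".mzML")
  f2 <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(s1$sample, f1); write_mzml(s2$sample, f2)
  expect_identical(readBin(f1, "raw", file.size(f1) * 1.1),
                   readBin(f2, "raw", file.size(f2) * 1.1))
})

test_that("truth tables account for every emitted scan and feature", {
  lib <- random_library(c(4, 4, 4))
  sim <- simulate_experiment(lib, simulation_config(
    n_binders = 10, n_noise_scans = 50, n_background = 15, seed = 7))
  tr <- sim$truth
  expect_equal(nrow(tr$scans), 10 + 50 + 15)
  expect_setequal(tr$scans$scan_id, sim$sample$scans$scan_id)
  expect_equal(sum(tr$scans$label == "binder"), 10)
  expect_equal(sum(tr$scans$label == "noise"), 50)
  expect_equal(sum(tr$features$label == "background"), 15)
  # background features present in both runs
  expect_equal(nrow(sim$control$features), 15)
  expect_equal(nrow(sim$sample$features), 10 + 15)
})

test_that("clean emission reproduces the full predicted fragment list", {
  lib <- toy_library()
  sim <- simulate_experiment(lib, simulation_config(
    n_binders = 3, n_noise_scans = 0, n_background = 0,
    emission_prob = 1, ppm_jitter_sd = 0, noise_peaks_lambda = 0, seed = 5))
  getter_tbl <- predict_fragment_table(lib)
  for (i in seq_len(nrow(sim$sample$scans))) {
    sid <- sim$sample$scans$scan_id[i]
    cid <- sim$truth$scans$compound_id[sim$truth$scans$scan_id == sid]
    want <- sort(getter_tbl$mz[getter_tbl$compound_id == cid])
    expect_equal(sort(sim$sample$scans$peaks[[i]]$mz), want, tolerance = 1e-9)
  }
})

test_that("end-to-end clean pipeline reaches full recall with no false calls", {
  lib <- random_library(c(5, 5, 5))
  sim <- simulate_experiment(lib, simulation_config(
    n_binders = 20, n_noise_scans = 100, n_background = 20,
    emission_prob = 1, ppm_jitter_sd = 0, seed = 13))
  sub <- subtract_background(sim$sample, sim$control)
  ann <- comet_filter(sub, lib)
  m <- evaluate_decoding(ann, sim$truth)
  expect_equal(m$recall, 1)
  expect_equal(m$n_false_annotations, 0)
})

test_that("sub-threshold background features are all removed, binders kept", {
  lib <- random_library(c(5, 5, 5))
  sim <- simulate_experiment(lib, simulation_config(
    n_binders = 15, n_noise_scans = 50, n_background = 40,
    background_ratio_range = c(0.5, 2.5), seed = 21))
  sub <- subtract_background(sim$sample, sim$control,
                             max_intensity_ratio = 3)
  # removed = exactly the background features (matched by m/z against truth)
  removed <- setdiff(sim$sample$features$feature_id, sub$features$feature_id)
  removed_mz <- sim$sample$features$mz[
    sim$sample$features$feature_id %in% removed]
  bg_mz <- sim$truth$features$mz[sim$truth$features$label == "background"]
  binder_mz <- sim$truth$features$mz[sim$truth$features$label == "binder"]
  expect_equal(length(removed), length(bg_mz))
  expect_true(all(vapply(removed_mz, function(m) {
    any(abs(bg_mz - m) < 1e-9)
  }, logical(1))))
  expect_true(all(vapply(binder_mz, function(m) {
    any(abs(sub$features$mz - m) < 1e-9)
  }, logical(1))))
})

test_that("recall degrades monotonically with noise peak density", {
  # mass-degeneracy-free library so the only failure channel is noise
  # crowding predicted fragments out of the considered top-N peaks;
  # averaged over a family of 10 seeds per noise level
  lib <- toy_library()
  mean_recall <- function(lam) {
    mean(vapply(1:10, function(s) {
      sim <- simulate_experiment(lib, simulation_config(
        n_binders = 8, n_noise_scans = 0, n_background = 0,
        emission_prob = 1, noise_peaks_lambda = lam,
        ppm_jitter_sd = 0, seed = 1000 + s))
      ann <- comet_filter(sim$sample, lib)
      evaluate_decoding(ann, sim$truth)$recall
    }, numeric(1)))
  }
  recalls <- vapply(c(0, 60, 250), mean_recall, numeric(1))
  expect_equal(recalls[1], 1)
  expect_true(all(diff(recalls) <= 0))
  expect_lt(recalls[3], recalls[1])
})

test_that("decoder evaluation arithmetic matches hand counting", {
  # hand-built truth + annotations
  truth <- list(scans = tibble::tibble(
    scan_id = c("s1", "s2", "s3", "s4"),
    label = c("binder", "binder", "noise", "binder"),
    compound_id = c("A", "B", NA, "C")))
  ann <- tibble::tibble(
    scan_id = c("s1", "s2", "s3"), rt = 0, precursor_mz = 0,
    compound_id = c("A", "X", "Y"), precursor_delta_ppm = 0,
    n_matched = 1L, score = 1, rank = 1L, accepted = TRUE)
  m <- evaluate_decoding(ann, truth)
  expect_equal(m$n_true, 3)        # A, B, C
  expect_equal(m$n_correct, 1)     # A
  expect_equal(m$recall, 1 / 3)
  expect_equal(m$n_false_annotations, 2)  # X, Y not in truth
  # decoder that accepts nothing: recall 0
  m0 <- evaluate_decoding(ann[0, ], truth)
  expect_equal(m0$recall, 0)
  # mismatched run is refused
  bad <- ann; bad$scan_id <- c("zz", "s2", "s3")
  expect_error(evaluate_decoding(bad, truth), "mismatch")
})

test_that("binders outside the library are rejected", {
  lib <- toy_library()
  expect_error(simulate_experiment(lib, simulation_config(
    binder_ids = "not+a+compound", seed = 1)), "not in library")
})
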