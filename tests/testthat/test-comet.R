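test_that("precursor candidates match a linear scan, nearest first", {
  lib <- toy_library()
  # exact protonated mass: that compound at delta 0
  m <- lib$monoisotopic_mass[3]
  got <- precursor_candidates(m + 1.00727646688, lib, 5)
  expect_equal(got$compound_id[1], lib$compound_id[3])
  expect_equal(got$delta_ppm[1], 0, tolerance = 1e-9)
  # 50 ppm off everything: empty
  expect_equal(nrow(precursor_candidates(m * (1 + 6e-5) + 1.00727646688,
                                         lib, 5)), 0)
  # degenerate isobars: all returned, order matches brute force
  bb <- building_blocks(data.frame(
    bb_id = c(sprintf("a%d", 1:7), "b1"), position = c(rep(1, 7), 2),
    formula = c(rep("C3H5NO", 7), "C2H3O")))
  libi <- enumerate_library(bb, scaffold_design("iso", 2))
  pm <- libi$monoisotopic_mass[1] + 1.00727646688
  got7 <- precursor_candidates(pm, libi, 5)
  expect_equal(nrow(got7), 7)
  neutral <- pm - 1.00727646688
  want <- libi$compound_id[order(abs(neutral - libi$monoisotopic_mass) /
                                   libi$monoisotopic_mass * 1e6)]
  expect_equal(got7$compound_id, want[1:7])
})

test_that("fragment-match counting equals the greedy bipartite oracle", {
  frag <- c(100.0000, 200.0000, 300.0000, 400.0000, 500.0000)
  # all top peaks exactly on predicted ions
  p <- peaks_tbl(frag, c(5, 4, 3, 2, 1))
  expect_equal(count_fragment_matches(p, frag, 5, 5)$count, 5)
  # nothing in tolerance
  p0 <- peaks_tbl(frag * 1.01, rep(1, 5))
  expect_equal(count_fragment_matches(p0, frag, 5, 5)$count, 0)
  # randomized sets vs independent greedy assignment
  set.seed(66)
  for (rep in 1:20) {
    np <- sample(3:10, 1); nf <- sample(1:8, 1)
    p <- peaks_tbl(sort(runif(np, 100, 600)), runif(np, 1, 100))
    fr <- runif(nf, 100, 600) * (1 + rnorm(nf, 0, 3e-6))
    nc <- sample(3:6, 1)
    got <- count_fragment_matches(p, fr, 5, nc)
    # oracle
    topo <- order(-p$intensity, p$mz)[seq_len(min(nc, np))]
    top <- p[sort(topo), ]
    cand <- expand.grid(i = seq_len(nrow(top)), j = seq_len(nf))
    cand$d <- abs(top$mz[cand$i] - fr[cand$j]) / fr[cand$j] * 1e6
    cand <- cand[cand$d <= 5, ]
    cand <- cand[order(cand$d), ]
    ui <- uj <- integer(0); cnt <- 0
    for (r in seq_len(nrow(cand))) {
      if (cand$i[r] %in% ui || cand$j[r] %in% uj) next
      ui <- c(ui, cand$i[r]); uj <- c(uj, cand$j[r]); cnt <- cnt + 1
    }
    expect_equal(got$count, cnt)
  }
})

test_that("clean simulated scans are retained and noise scans are not", {
  lib <- random_library(c(4, 4, 4))
  sim <- simulate_experiment(lib, simulation_config(
    n_binders = 12, n_noise_scans = 100, n_background = 0,
    emission_prob = 1, ppm_jitter_sd = 0, seed = 8))
  ann <- comet_filter(sim$sample, lib)
  truth <- sim$truth$scans
  binder_scans <- truth$scan_id[truth$label == "binder"]
  noise_scans <- truth$scan_id[truth$label == "noise"]
  expect_setequal(intersect(unique(ann$scan_id), binder_scans), binder_scans)
  expect_length(intersect(unique(ann$scan_id), noise_scans), 0)
})

test_that("retention is monotone in min_matching_peaks and ppm tolerance", {
  lib <- random_library(c(3, 3, 3))
  sim <- simulate_experiment(lib, simulation_config(
    n_binders = 10, n_noise_scans = 30, n_background = 0,
    emission_prob = 0.6, ppm_jitter_sd = 1, seed = 9))
  ret <- function(mmp, ppm) {
    unique(comet_filter(sim$sample, lib,
                        comet_config(ms1_ppm = ppm, ms2_ppm = ppm,
                                     min_matching_peaks = mmp))$scan_id)
  }
  r1 <- ret(1, 5); r2 <- ret(2, 5); r3 <- ret(3, 5)
  expect_true(all(r2 %in% r1))
  expect_true(all(r3 %in% r2))
  # shrinking tolerance shrinks the retained set
  rt_tight <- ret(1, 0.5)
  expect_true(all(rt_tight %in% r1))
})

test_that("decoy precursors 50 ppm off-library never pass the MS1 filter", {
  lib <- random_library(c(4, 4, 4))
  sim <- simulate_experiment(lib, simulation_config(
    n_binders = 5, n_noise_scans = 200, n_background = 0,
    emission_prob = 1, seed = 10))
  noise <- sim$truth$scans$scan_id[sim$truth$scans$label == "noise"]
  for (sid in sample(noise, 25)) {
    i <- which(sim$sample$scans$scan_id == sid)
    expect_equal(nrow(precursor_candidates(
      sim$sample$scans$precursor_mz[i], lib, 5)), 0)
  }
})

test_that("accepted annotations stay within the MS2 tolerance post-hoc", {
  lib <- random_library(c(4, 4, 4))
  sim <- simulate_experiment(lib, simulation_config(
    n_binders = 10, n_noise_scans = 20, n_background = 0,
    emission_prob = 0.8, ppm_jitter_sd = 2, seed = 12))
  cfg <- comet_config()
  ann <- comet_filter(sim$sample, lib, cfg)
  design <- attr(lib, "design")
  bb <- attr(lib, "bb_table")
  for (i in which(ann$accepted)) {
    row <- lib[lib$compound_id == ann$compound_id[i], ]
    forms <- c(bb$formula[bb$position == 1 & bb$bb_id == row$bb1],
               bb$formula[bb$position == 2 & bb$bb_id == row$bb2],
               bb$formula[bb$position == 3 & bb$bb_id == row$bb3])
    fr <- predict_fragments(forms, design)
    pk <- sim$sample$scans$peaks[[which(sim$sample$scans$scan_id == ann$scan_id[i])]]
    m <- count_fragment_matches(pk, fr$mz, cfg$ms2_ppm, cfg$n_considered_peaks)
    expect_gte(m$count, cfg$min_matching_peaks)
    expect_true(all(m$detail$delta_ppm <= cfg$ms2_ppm))
  }
})

test_that("candidate ranking is the intensity-weighted coverage order", {
  cfg <- comet_config()
  # candidate matching all top-N intensity scores 1 and ranks first
  p <- peaks_tbl(c(100, 200, 300), c(10, 20, 30))
  cand <- tibble::tibble(compound_id = c("full", "part"),
                         fragment_mz = list(c(100, 200, 300), c(100)))
  r <- rank_candidates(p, cand, cfg)
  expect_equal(r$compound_id[r$rank == 1], "full")
  expect_equal(r$score[1], 1, tolerance = 1e-5)
  # disjoint subsets at 80% vs 20% of intensity
  p2 <- peaks_tbl(c(100, 200), c(80, 20))
  cand2 <- tibble::tibble(compound_id = c("a", "b"),
                          fragment_mz = list(100, 200))
  r2 <- rank_candidates(p2, cand2, cfg)
  expect_equal(r2$compound_id, c("a", "b"))
  expect_equal(r2$score, c(0.8, 0.2), tolerance = 1e-4)
  # random cases: order equals direct recomputation
  set.seed(77)
  for (rep in 1:10) {
    p <- peaks_tbl(sort(runif(8, 100, 900)), runif(8, 1, 100))
    cand <- tibble::tibble(
      compound_id = sprintf("c%d", 1:4),
      fragment_mz = lapply(1:4, function(i) sample(p$mz, sample(1:5, 1))))
    r <- rank_candidates(p, cand, cfg)
    top <- top_n_peaks(p, cfg$n_considered_peaks)
    want <- vapply(seq_len(nrow(cand)), function(j) {
      m <- count_fragment_matches(p, cand$fragment_mz[[j]], cfg$ms2_ppm,
                                  cfg$n_considered_peaks)
      min(1, sum(m$detail$peak_intensity) / sum(top$intensity) +
            1e-6 * m$count)
    }, numeric(1))
    ord <- order(-want, cand$compound_id)
    expect_equal(r$compound_id, cand$compound_id[ord])
  }
})

test_that("replicate merging follows set algebra with Jaccard overlap", {
  mk <- function(ids, run_id) {
    structure(tibble::tibble(
      scan_id = paste0("s", seq_along(ids)), rt = 0, precursor_mz = 0,
      compound_id = ids, precursor_delta_ppm = 0,
      n_matched = 1L, score = 0.5, rank = 1L, accepted = TRUE),
      run_id = run_id, class = c("sel_annotations", "tbl_df", "tbl", "data.frame"))
  }
  a <- mk(c("x", "y"), "r1"); b <- mk(c("y", "z"), "r2")
  u <- merge_replicates(list(a, b), "union")
  expect_setequal(u$compound_id, c("x", "y", "z"))
  i <- merge_replicates(list(a, b), "intersection")
  expect_equal(i$compound_id, "y")
  expect_equal(attr(u, "jaccard")["r1", "r2"], 1 / 3)
  # identical annotations in both runs: union == intersection
  a2 <- mk(c("x", "y"), "r2")
  u2 <- merge_replicates(list(a, a2), "union")
  i2 <- merge_replicates(list(a, a2), "intersection")
  expect_setequal(u2$compound_id, i2$compound_id)
  # disjoint runs: empty intersection
  d <- merge_replicates(list(mk("p", "r1"), mk("q", "r2")), "intersection")
  expect_equal(nrow(d), 0)
  # 3-run toy vs set algebra
  r3 <- mk(c("x", "z"), "r3")
  u3 <- merge_replicates(list(a, b, r3), "union")
  i3 <- merge_replicates(list(a, b, r3), "intersection")
  expect_setequal(u3$compound_id,
                  Reduce(union, list(c("x", "y"), c("y", "z"), c("x", "z"))))
  expect_setequal(i3$compound_id,
                  Reduce(intersect, list(c("x", "y"), c("y", "z"), c("x", "z"))))
})

test_that("empty runs annotate to an empty table with zero retention", {
  lib <- toy_library()
  ann <- comet_filter(ms_run("empty"), lib)
  expect_equal(nrow(ann), 0)
  expect_equal(attr(ann, "n_scans_retained"), 0)
})
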