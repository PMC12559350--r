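test_that("enumeration is the exact cross product with additive masses", {
  lib <- toy_library()
  expect_s3_class(lib, "sel_library")
  expect_equal(nrow(lib), 2 * 2 * 3)
  expect_false(any(duplicated(lib$compound_id)))
  # each member mass = sum of contributions + offset, any summation order
  bb <- toy_bb_table()
  off <- monoisotopic_mass("NH3")
  for (i in seq_len(nrow(lib))) {
    parts <- c(bb$mass[bb$position == 1 & bb$bb_id == lib$bb1[i]],
               bb$mass[bb$position == 2 & bb$bb_id == lib$bb2[i]],
               bb$mass[bb$position == 3 & bb$bb_id == lib$bb3[i]])
    for (ord in list(1:3, 3:1, c(2, 1, 3))) {
      expect_equal(lib$monoisotopic_mass[i], sum(parts[ord]) + off,
                   tolerance = 1e-9)
    }
  }
  expect_false(is.unsorted(lib$monoisotopic_mass))
})

test_that("library size equals the product of set sizes (random designs)", {
  set.seed(11)
  for (rep in 1:8) {
    sizes <- sample(1:20, sample(2:4, 1), replace = TRUE)
    bb <- synthetic_building_blocks(sizes, seed = rep)
    lib <- enumerate_library(bb, scaffold_design("r", length(sizes)))
    expect_equal(nrow(lib), prod(sizes))
  }
})

test_that("a 1x1x1 design yields one compound of the summed mass", {
  bb <- building_blocks(data.frame(bb_id = c("a", "b", "c"), position = 1:3,
                                   formula = c("C2H3NO", "C3H5NO", "C2H3O")))
  lib <- enumerate_library(bb, scaffold_design("one", 3, "NH3"))
  expect_equal(nrow(lib), 1)
  expect_equal(lib$monoisotopic_mass,
               oracle_mass("C2H3NO") + oracle_mass("C3H5NO") +
                 oracle_mass("C2H3O") + oracle_mass("NH3"),
               tolerance = 1e-9)
})

test_that("duplicate building-block ids within a position are rejected", {
  bb <- data.frame(bb_id = c("a", "a", "b"), position = c(1, 1, 2),
                   formula = c("C2H3NO", "C3H5NO", "C2H3O"))
  expect_error(building_blocks(bb), "Duplicate bb_id")
})

test_that("mass-window queries match a linear scan", {
  set.seed(23)
  for (rep in 1:5) {
    lib <- random_library(c(5, 5, 5))
    for (q in 1:20) {
      centre <- sample(lib$monoisotopic_mass, 1) *
        (1 + stats::runif(1, -2e-5, 2e-5))
      ppm <- sample(c(1, 5, 20, 100), 1)
      got <- library_mass_window(lib, centre, ppm)
      want <- lib$compound_id[
        abs(centre - lib$monoisotopic_mass) / lib$monoisotopic_mass * 1e6 <= ppm]
      expect_setequal(got$compound_id, want)
      expect_false(is.unsorted(abs(got$delta_ppm)))
    }
  }
})

test_that("Lipinski points count satisfied parameters and are monotone", {
  d <- tibble::tibble(MW = c(400, 600, 400), logP = c(3, 7, 3),
                      HBD = c(2, 8, 2), HBA = c(5, 12, 11),
                      TPSA = c(100, 200, 100))
  expect_equal(lipinski_points(d), c(5L, 0L, 4L))
  # exactly MW and TPSA satisfied
  d2 <- tibble::tibble(MW = 450, logP = 9, HBD = 9, HBA = 20, TPSA = 120)
  expect_equal(lipinski_points(d2), 2L)
  # relaxing any threshold never decreases points
  set.seed(5)
  base_thr <- list(MW = 500, logP = 5, HBD = 5, HBA = 10, TPSA = 140)
  dr <- tibble::tibble(MW = runif(40, 100, 900), logP = runif(40, -2, 10),
                       HBD = sample(0:12, 40, TRUE),
                       HBA = sample(0:20, 40, TRUE),
                       TPSA = runif(40, 0, 250))
  p0 <- lipinski_points(dr, base_thr)
  for (k in names(base_thr)) {
    thr <- base_thr; thr[[k]] <- thr[[k]] * 1.5
    expect_true(all(lipinski_points(dr, thr) >= p0))
  }
})

test_that("building-block ranking averages member points per block", {
  # 2x2 toy: a1 only in 5-point members, a2 only in 0-point members
  members <- tibble::tibble(bb1 = c("a1", "a1", "a2", "a2"),
                            bb2 = c("b1", "b2", "b1", "b2"),
                            points = c(5, 5, 0, 0))
  r <- rank_building_blocks(members)
  r1 <- r[r$position == 1, ]
  expect_equal(r1$bb_id[r1$rank == 1], "a1")
  expect_equal(r1$mean_points[r1$bb_id == "a1"], 5)
  expect_equal(r1$mean_points[r1$bb_id == "a2"], 0)
  # uniform points: ties broken by bb_id order
  members$points <- 3
  ru <- rank_building_blocks(members)
  expect_equal(ru$bb_id[ru$position == 2], c("b1", "b2"))
  # 3x2 toy against exhaustive averaging
  m2 <- tidyr::expand_grid(bb1 = c("x", "y", "z"), bb2 = c("u", "v"))
  set.seed(3)
  m2$points <- sample(0:5, nrow(m2), TRUE)
  r2 <- rank_building_blocks(m2)
  for (id in c("x", "y", "z")) {
    expect_equal(r2$mean_points[r2$position == 1 & r2$bb_id == id],
                 mean(m2$points[m2$bb1 == id]))
  }
  expect_error(rank_building_blocks(m2[0, ]), "Empty")
})

test_that("mass degeneracy matches a pairwise brute-force grouping", {
  # wide spacing: all singletons
  lib1 <- toy_library()
  expect_equal(attr(mass_degeneracy(lib1, 5), "max_group_size"), 1)
  # permutation isobars group together
  bb <- building_blocks(data.frame(
    bb_id = c("a1", "a2", "b1", "b2"), position = c(1, 1, 2, 2),
    formula = c("C2H3NO", "C3H5NO", "C3H5NO", "C2H3NO")))
  libi <- enumerate_library(bb, scaffold_design("iso", 2))
  expect_gte(attr(mass_degeneracy(libi, 5), "max_group_size"), 2)
  # random toy vs O(n^2) single-linkage oracle
  set.seed(31)
  for (rep in 1:3) {
    lib <- random_library(c(4, 4, 4))
    ppm <- 50
    deg <- mass_degeneracy(lib, ppm)
    m <- lib$monoisotopic_mass
    adj <- outer(m, m, function(x, y) abs(x - y) <= ppm * 1e-6 * pmin(x, y))
    g <- igraph_free_components(adj)
    expect_equal(sort(deg$n_compounds), sort(as.integer(table(g))))
  }
})

test_that("oversize virtual libraries are refused with guidance", {
  bb <- synthetic_building_blocks(c(3, 3), seed = 1)
  expect_error(enumerate_library(bb, scaffold_design("big", 2), max_size = 5),
               "sample")
})
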