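# Shared toy fixtures, built in code.

# Independent atomic-mass table for oracle checks (typed in separately from
# the package's table; NIST monoisotopic values).
ORACLE_MASS <- c(C = 12, H = 1.00782503207, N = 14.0030740048,
                 O = 15.9949146196, S = 31.97207100, P = 30.97376163,
                 F = 18.99840322, Cl = 34.96885268)
ORACLE_PROTON <- 1.00727646688

# Atom-by-atom mass: expand a Hill formula into single atoms and add them
# one at a time (deliberately naive; independent of the package arithmetic).
oracle_mass <- function(formula) {
  if (!nzchar(formula)) return(0)
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  total <- 0
  for (t in toks) {
    el <- sub("[0-9]*$", "", t)
    n <- sub("^[A-Za-z]+", "", t)
    n <- if (nzchar(n)) as.integer(n) else 1L
    for (i in seq_len(n)) total <- total + ORACLE_MASS[[el]]
  }
  total
}

toy_bb_table <- function() {
  building_blocks(data.frame(
    bb_id = c("a1", "a2", "b1", "b2", "c1", "c2", "c3"),
    position = c(1, 1, 2, 2, 3, 3, 3),
    formula = c("C2H3NO", "C3H5NO", "C2H3O", "C4H7NO",
                "C6H4O2S", "C7H5NO2", "C5H8O2")))
}

toy_design <- function(fragment_types = "S[0;1], S[1;2],0,2",
                       offset = "NH3") {
  scaffold_design("toy", 3, offset, fragment_types)
}

toy_library <- function(...) {
  enumerate_library(toy_bb_table(), toy_design(...))
}

# Random formula string over CHNOS with non-negative counts (C>=1, H>=1).
random_formula <- function() {
  v <- c(C = sample(1:15, 1), H = sample(1:25, 1), N = sample(0:4, 1),
         O = sample(0:5, 1), S = sample(0:1, 1))
  formula_to_string(v[v > 0])
}

# Random small library for oracle-equivalence tests.
random_library <- function(sizes = c(4, 4, 4)) {
  bb <- do.call(rbind, lapply(seq_along(sizes), function(p) {
    data.frame(bb_id = sprintf("p%db%d", p, seq_len(sizes[p])), position = p,
               formula = replicate(sizes[p], random_formula()))
  }))
  enumerate_library(building_blocks(bb),
                    scaffold_design("rand", length(sizes), "",
                                    "S[0;1],0,2"))
}

# Brute-force hypergeometric upper tail: P(X >= k) by direct summation of
# (log-)binomial-coefficient products (independent of phyper).
oracle_tail <- function(k, K, N, n) {
  xs <- k:min(n, K)
  xs <- xs[n - xs <= N - K]
  sum(exp(lchoose(K, xs) + lchoose(N - K, n - xs) - lchoose(N, n)))
}

# Compound ids whose monoisotopic mass is unique in the library at the given
# resolution (no neighbour within ppm) -- MS1-resolvable members.
mass_unique_ids <- function(lib, ppm = 10) {
  m <- lib$monoisotopic_mass  # sorted ascending
  gap_prev <- c(Inf, diff(m)) / m * 1e6
  gap_next <- c(diff(m), Inf) / m * 1e6
  lib$compound_id[gap_prev > ppm & gap_next > ppm]
}

# Connected components of a logical adjacency matrix by plain BFS
# (brute-force oracle for mass-degeneracy grouping).
igraph_free_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  k <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    k <- k + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- k
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

# A minimal hand-built run: peaks placed explicitly.
peaks_tbl <- function(mz, intensity) tibble::tibble(mz = mz, intensity = intensity)
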