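#' Validate (or read) a building-block table
#'
#' A building-block table has one row per monomer and position, with the
#' elemental *contribution* formula: the atoms the building block adds to the
#' assembled molecule after condensation losses (e.g. -H2O per amide bond)
#' have been applied. Scaffold terminal atoms live in the design's offset
#' formula, so assembling a molecule is pure formula addition.
#'
#' @param x A data frame with columns `bb_id`, `position` (1-based), `formula`
#'   (Hill notation) and optionally `name`, `smiles`, plus any descriptor
#'   columns (`logP`, `HBD`, `HBA`, `TPSA`).
#' @return A tibble with a `mass` column added (contribution monoisotopic
#'   mass, Da), validated: ids unique within a position, all masses > 0.
#' @export
building_blocks <- function(x) {
  x <- tibble::as_tibble(x)
  req <- c("bb_id", "position", "formula")
  missing_cols <- setdiff(req, names(x))
  if (length(missing_cols)) {
    stop("Building-block table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"name" %in% names(x)) x$name <- x$bb_id
  x$position <- as.integer(x$position)
  dup <- x |>
    dplyr::count(.data$position, .data$bb_id) |>
    dplyr::filter(.data$n > 1L)
  if (nrow(dup)) {
    stop("Duplicate bb_id within position: ",
         paste(unique(dup$bb_id), collapse = ", "), call. = FALSE)
  }
  x$mass <- monoisotopic_mass(x$formula)
  if (any(x$mass <= 0)) {
    stop("Building-block contribution mass must be > 0 (offending id: ",
         x$bb_id[which(x$mass <= 0)[1]], ")", call. = FALSE)
  }
  x
}

#' Read a building-block CSV
#'
#' Expected columns: `bb_id, position, name, smiles, formula` (formula in Hill
#' notation); extra descriptor columns are carried through.
#'
#' @param path CSV file path.
#' @return Validated building-block tibble (see [building_blocks()]).
#' @export
read_building_blocks <- function(path) {
  building_blocks(readr::read_csv(path, show_col_types = FALSE))
}

#' Define a combinatorial scaffold design
#'
#' @param design_id Design name, e.g. `"SEL1"`.
#' @param n_positions Number of building-block positions (P >= 2 for real
#'   designs; 1 is allowed for toys).
#' @param scaffold_offset Elemental formula of the scaffold core / terminal
#'   atoms shared by every member (may be `""`). For a benzimidazole-core
#'   design this is the core formula (e.g. `"C8H3N2O"`); for pure condensation
#'   scaffolds it carries terminal atoms only.
#' @param fragment_types Fragment-type grammar string, e.g.
#'   `"S[0;1], S[1;2],0,2"` (see [parse_fragment_types()]).
#' @param adduct Ionization adduct, default `"[M+H]+"`.
#' @return A `scaffold_design` object.
#' @export
scaffold_design <- function(design_id, n_positions, scaffold_offset = "",
                            fragment_types = "", adduct = "[M+H]+") {
  stopifnot(is.character(design_id), n_positions >= 1)
  parse_formula(scaffold_offset)  # validate early
  adduct_mass(adduct)
  structure(
    list(design_id = design_id,
         n_positions = as.integer(n_positions),
         scaffold_offset = scaffold_offset,
         fragment_types = fragment_types,
         adduct = adduct),
    class = "scaffold_design")
}

#' @export
print.scaffold_design <- function(x, ...) {
  cat("<scaffold_design> ", x$design_id, ": ", x$n_positions, " positions",
      if (nzchar(x$scaffold_offset)) paste0(", offset ", x$scaffold_offset),
      if (nzchar(x$fragment_types)) paste0(", fragment types '", x$fragment_types, "'"),
      "\n", sep = "")
  invisible(x)
}

#' Enumerate the full combinatorial library
#'
#' Takes the cross product of the building-block sets at each position,
#' computing each member's molecular formula (sum of contributions plus the
#' scaffold offset) and exact monoisotopic mass. The returned tibble is sorted
#' by mass so that precursor lookups are range queries.
#'
#' @param bb_table Building-block table (see [building_blocks()]) covering all
#'   design positions.
#' @param design A [scaffold_design()].
#' @param max_size Guard against accidental materialization of huge libraries
#'   (default 1e7 members); score larger virtual libraries on a sample instead.
#' @return A `sel_library` tibble with columns `compound_id`, `bb1..bbP`,
#'   `formula`, `monoisotopic_mass`, sorted ascending by mass. The design and
#'   BB table ride along as attributes.
#' @examples
#' bbs <- building_blocks(data.frame(
#'   bb_id = c("a1", "a2", "b1"), position = c(1, 1, 2),
#'   formula = c("C2H3NO", "C3H5NO", "C2H3O")))
#' lib <- enumerate_library(bbs, scaffold_design("toy", 2, "NH3"))
#' nrow(lib) # 2
#' @export
enumerate_library <- function(bb_table, design, max_size = 1e7) {
  bb_table <- building_blocks(bb_table)
  pos <- sort(unique(bb_table$position))
  if (!identical(pos, seq_len(design$n_positions))) {
    stop("Building-block table covers positions ",
         paste(pos, collapse = ","), " but design has ",
         design$n_positions, call. = FALSE)
  }
  sets <- lapply(pos, function(p) bb_table[bb_table$position == p, ])
  sizes <- vapply(sets, nrow, integer(1))
  n <- prod(sizes)
  if (n > max_size) {
    stop("Library has ", format(n, big.mark = ","), " members, above max_size = ",
         format(max_size, big.mark = ","),
         "; score large virtual libraries on a sample instead", call. = FALSE)
  }
  elements <- unique(unlist(lapply(bb_table$formula, function(f) names(parse_formula(f)))))
  offset_vec <- parse_formula(design$scaffold_offset)
  elements <- unique(c(elements, names(offset_vec)))

  idx <- expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE)
  counts <- matrix(0L, nrow = n, ncol = length(elements),
                   dimnames = list(NULL, elements))
  mass <- rep(monoisotopic_mass(offset_vec %||% integer(0)), n)
  if (length(offset_vec)) counts[, names(offset_vec)] <-
      matrix(offset_vec, nrow = n, ncol = length(offset_vec), byrow = TRUE)
  bb_cols <- vector("list", length(sets))
  for (p in seq_along(sets)) {
    fm <- formula_matrix(sets[[p]]$formula, elements)
    counts <- counts + fm[idx[[p]], , drop = FALSE]
    mass <- mass + sets[[p]]$mass[idx[[p]]]
    bb_cols[[p]] <- sets[[p]]$bb_id[idx[[p]]]
  }
  names(bb_cols) <- paste0("bb", seq_along(sets))
  lib <- tibble::as_tibble(bb_cols)
  lib$compound_id <- do.call(paste, c(bb_cols, sep = "+"))
  lib$formula <- matrix_to_formula(counts)
  lib$monoisotopic_mass <- mass
  lib <- lib[order(lib$monoisotopic_mass, lib$compound_id),
             c("compound_id", names(bb_cols), "formula", "monoisotopic_mass")]
  structure(lib, design = design, bb_table = bb_table,
            class = c("sel_library", class(lib)))
}

#' @export
print.sel_library <- function(x, ...) {
  d <- attr(x, "design")
  cat("<sel_library> ", format(nrow(x), big.mark = ","), " compounds",
      if (!is.null(d)) paste0(" (design ", d$design_id, ", ", d$n_positions,
                              " positions)"), "\n", sep = "")
  NextMethod()
}

#' Compounds whose mass falls in a ppm window
#'
#' Range query on the mass-sorted library: all compounds with
#' `|m - monoisotopic_mass| / monoisotopic_mass * 1e6 <= ppm`, sorted by
#' absolute ppm deviation.
#'
#' @param library A `sel_library`.
#' @param mass Neutral query mass in Da.
#' @param ppm Tolerance in ppm (library mass is the reference).
#' @return Subset tibble with a `delta_ppm` column, sorted by `|delta_ppm|`.
#' @export
library_mass_window <- function(library, mass, ppm) {
  m <- library$monoisotopic_mass
  # window bounds: compound masses c with |mass - c|/c*1e6 <= ppm
  lo <- mass / (1 + ppm * 1e-6)
  hi <- mass / (1 - ppm * 1e-6)
  i0 <- findInterval(lo, m, left.open = TRUE) + 1L
  i1 <- findInterval(hi, m)
  if (i0 > i1) {
    out <- library[0, ]
    out$delta_ppm <- numeric(0)
    return(out)
  }
  out <- library[i0:i1, ]
  out$delta_ppm <- (mass - out$monoisotopic_mass) / out$monoisotopic_mass * 1e6
  out[order(abs(out$delta_ppm)), ]
}

#' Export a library as TSV
#'
#' Columns `compound_id, bb1..bbP, formula, monoisotopic_mass[, smiles]`.
#'
#' @param library A `sel_library`.
#' @param path Output TSV path.
#' @export
write_library <- function(library, path) {
  readr::write_tsv(tibble::as_tibble(library), path)
  invisible(path)
}

#' Lipinski rule-of-five points
#'
#' One point per satisfied drug-likeness parameter (0..5): MW, logP, hydrogen
#' bond donors, hydrogen bond acceptors, topological polar surface area.
#'
#' @param descriptors Data frame with columns `MW`, `logP`, `HBD`, `HBA`,
#'   `TPSA` (MW in Da, TPSA in squared Angstrom).
#' @param thresholds Named list of upper bounds; defaults are the rule-of-five
#'   cut-offs MW <= 500, logP <= 5, HBD <= 5, HBA <= 10, TPSA <= 140.
#' @return Integer vector of points, one per row.
#' @export
lipinski_points <- function(descriptors,
                            thresholds = list(MW = 500, logP = 5, HBD = 5,
                                              HBA = 10, TPSA = 140)) {
  missing_cols <- setdiff(names(thresholds), names(descriptors))
  if (length(missing_cols)) {
    stop("Descriptor table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  pts <- rep(0L, nrow(descriptors))
  for (p in names(thresholds)) {
    pts <- pts + as.integer(descriptors[[p]] <= thresholds[[p]])
  }
  pts
}

#' Rank building blocks by mean member score
#'
#' Aggregates a per-member points column into a per-building-block score: the
#' mean points over all members containing the block, per position. Means
#' (rather than sums) keep positions with different set sizes comparable.
#'
#' @param members Data frame of library members with `bb1..bbP` columns and a
#'   `points` column (e.g. from [lipinski_points()]). Works on a full
#'   enumeration or on a uniform sample of a large virtual library.
#' @param statistic `"mean"` (default) or `"sum"`.
#' @return Tibble `position, bb_id, n_members, total_points, mean_points,
#'   rank` — rank 1 is best within each position; ties broken by `bb_id`.
#' @export
rank_building_blocks <- function(members, statistic = c("mean", "sum")) {
  statistic <- match.arg(statistic)
  if (!nrow(members)) stop("Empty member table", call. = FALSE)
  if (!"points" %in% names(members)) {
    stop("Member table needs a 'points' column", call. = FALSE)
  }
  bb_cols <- grep("^bb[0-9]+$", names(members), value = TRUE)
  if (!length(bb_cols)) stop("No bb<position> columns found", call. = FALSE)
  purrr::map_dfr(seq_along(bb_cols), function(p) {
    members |>
      dplyr::group_by(bb_id = .data[[bb_cols[p]]]) |>
      dplyr::summarise(n_members = dplyr::n(),
                       total_points = sum(.data$points),
                       mean_points = mean(.data$points),
                       .groups = "drop") |>
      dplyr::mutate(position = p, .before = 1)
  }) |>
    dplyr::group_by(.data$position) |>
    dplyr::arrange(
      dplyr::desc(if (statistic == "mean") .data$mean_points else .data$total_points),
      .data$bb_id, .by_group = TRUE) |>
    dplyr::mutate(rank = dplyr::row_number()) |>
    dplyr::ungroup()
}

#' Mass degeneracy of a library
#'
#' Groups compounds whose masses are indistinguishable at a given relative
#' resolution: single-linkage chaining on the sorted masses, starting a new
#' group whenever the gap to the previous mass exceeds `bin_ppm` of it.
#' Isobaric compounds (e.g. permutations of the same building-block multiset)
#' land in the same group and can only be told apart at the MS2 level.
#'
#' @param library A `sel_library` (or any tibble with `monoisotopic_mass`).
#' @param bin_ppm Resolution in ppm (default 5, the precursor tolerance).
#' @return Tibble `group, mass_lo, mass_hi, n_compounds`, plus attribute
#'   `max_group_size`.
#' @export
mass_degeneracy <- function(library, bin_ppm = 5) {
  if (!nrow(library)) stop("Empty library", call. = FALSE)
  m <- sort(library$monoisotopic_mass)
  gap_ok <- diff(m) <= bin_ppm * 1e-6 * m[-length(m)]
  grp <- cumsum(c(1L, !gap_ok))
  out <- tibble::tibble(mass = m, group = grp) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(mass_lo = min(.data$mass), mass_hi = max(.data$mass),
                     n_compounds = dplyr::n(), .groups = "drop")
  attr(out, "max_group_size") <- max(out$n_compounds)
  out
}

#' Lipinski descriptors from SMILES (optional cheminformatics backend)
#'
#' Computes MW, logP, HBD, HBA and TPSA from SMILES via ChemmineR/ChemmineOB
#' when those packages are installed. When SMILES are not available, supply
#' descriptors directly in the building-block table and derive MW from the
#' molecular formula.
#'
#' @param smiles Character vector of SMILES.
#' @return Tibble with columns `smiles, MW, logP, HBD, HBA, TPSA`.
#' @export
smiles_descriptors <- function(smiles) {
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("smiles_descriptors() needs ChemmineR + ChemmineOB; ",
         "supply descriptors in the building-block table instead",
         call. = FALSE)
  }
  sdf <- ChemmineR::smiles2sdf(smiles)
  pr <- ChemmineR::propOB(sdf)
  tibble::tibble(smiles = smiles, MW = pr$MW, logP = pr$logP,
                 HBD = pr$HBD, HBA = pr$HBA1, TPSA = pr$TPSA)
}
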