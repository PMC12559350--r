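# Monoisotopic masses of the most abundant isotope (NIST/CODATA), Da.
.MONOISOTOPIC <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.97207100,
  P  = 30.97376163,
  F  = 18.99840322,
  Cl = 34.96885268,
  Br = 78.9183371,
  I  = 126.904473,
  Na = 22.9897692809,
  K  = 38.96370668,
  B  = 11.0093054,
  Si = 27.9769265325,
  Se = 73.9224764
)

# Mass of a proton; [M+H]+ observes m/z = M + .PROTON_MASS at charge 1.
.PROTON_MASS <- 1.00727646688

# Mass added by the adduct at charge 1 (positive mode).
.ADDUCT_MASS <- c(
  "[M+H]+"  = 1.00727646688,
  "[M+Na]+" = 22.9897692809 - 5.48579909e-4,
  "[M+K]+"  = 38.96370668 - 5.48579909e-4
)

#' Mass of an ionization adduct
#'
#' @param adduct Adduct name, e.g. `"[M+H]+"` (the default throughout the
#'   package; singly protonated positive ions).
#' @return Adduct mass in Da added to the neutral monoisotopic mass.
#' @export
adduct_mass <- function(adduct = "[M+H]+") {
  if (!adduct %in% names(.ADDUCT_MASS)) {
    stop("Unknown adduct '", adduct, "'. Known: ",
         paste(names(.ADDUCT_MASS), collapse = ", "), call. = FALSE)
  }
  unname(.ADDUCT_MASS[[adduct]])
}

#' Parse a molecular formula in Hill notation
#'
#' Parses strings such as `"C8H3N2O"` into a named integer vector of element
#' counts. The empty string parses to an empty formula (mass 0).
#'
#' @param x A single formula string.
#' @return Named integer vector, elements as names.
#' @examples
#' parse_formula("C7H14N3O3")
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- gsub("\\s", "", x)
  if (!nzchar(x)) return(stats::setNames(integer(0), character(0)))
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", x)) {
    stop("Malformed formula: '", x, "'", call. = FALSE)
  }
  m <- gregexpr("[A-Z][a-z]?[0-9]*", x)[[1]]
  toks <- regmatches(x, list(m))[[1]]
  el <- sub("[0-9]*$", "", toks)
  n <- as.integer(sub("^[A-Za-z]+", "", toks))
  n[is.na(n)] <- 1L
  unknown <- setdiff(el, names(.MONOISOTOPIC))
  if (length(unknown)) {
    stop("Unknown element symbol(s): ", paste(unknown, collapse = ", "),
         " in formula '", x, "'", call. = FALSE)
  }
  out <- tapply(n, el, sum)
  stats::setNames(as.integer(out), names(out))
}

# Combine parsed formulas with integer coefficients; may hold negative counts
# internally (e.g. while subtracting condensation losses).
formula_combine <- function(..., coef = NULL) {
  fs <- list(...)
  if (is.null(coef)) coef <- rep(1L, length(fs))
  els <- unique(unlist(lapply(fs, names)))
  out <- stats::setNames(integer(length(els)), els)
  for (i in seq_along(fs)) {
    f <- fs[[i]]
    if (length(f)) out[names(f)] <- out[names(f)] + coef[i] * f
  }
  out[out != 0L]
}

#' Add molecular formulas
#'
#' @param ... Formula strings or named count vectors from [parse_formula()].
#' @return A formula string in Hill notation (C, H first, rest alphabetical).
#' @examples
#' formula_add("C2H3NO", "C3H5NO") # "C5H8N2O2"
#' @export
formula_add <- function(...) {
  fs <- lapply(list(...), .as_formula_vec)
  formula_to_string(do.call(formula_combine, fs))
}

#' Subtract one formula from another
#'
#' @param x,y Formula strings or named count vectors.
#' @return A formula string; errors if any resulting count is negative.
#' @export
formula_subtract <- function(x, y) {
  out <- formula_combine(.as_formula_vec(x), .as_formula_vec(y), coef = c(1L, -1L))
  if (any(out < 0L)) {
    stop("Formula subtraction yields negative atom count: ",
         formula_to_string(abs(out[out < 0L])), call. = FALSE)
  }
  formula_to_string(out)
}

.as_formula_vec <- function(x) {
  if (is.character(x)) parse_formula(x) else x
}

#' Write a formula count vector in Hill notation
#'
#' @param f Named integer vector of element counts.
#' @return Formula string; `""` for the empty formula.
#' @export
formula_to_string <- function(f) {
  f <- f[f != 0L]
  if (!length(f)) return("")
  els <- names(f)
  ord <- if ("C" %in% els) {
    c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    sort(els)
  }
  f <- f[ord]
  paste0(names(f), ifelse(f == 1L, "", f), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' Sums standard monoisotopic atomic masses over the formula's element counts.
#'
#' @param formula Character vector of Hill-notation formulas (vectorized), or a
#'   single named count vector.
#' @return Numeric vector of masses in Da; the empty formula has mass 0.
#' @examples
#' monoisotopic_mass("C7H14N3O3") # 188.1035
#' @export
monoisotopic_mass <- function(formula) {
  if (!is.character(formula)) {
    f <- formula
    if (any(f < 0L)) stop("Negative atom counts in formula", call. = FALSE)
    return(sum(.MONOISOTOPIC[names(f)] * f))
  }
  vapply(formula, function(s) {
    f <- parse_formula(s)
    sum(.MONOISOTOPIC[names(f)] * f)
  }, numeric(1), USE.NAMES = FALSE)
}

# Element-count matrix (rows = formulas, cols = union of elements) for
# vectorized enumeration of large libraries.
formula_matrix <- function(formulas, elements = NULL) {
  parsed <- lapply(formulas, parse_formula)
  if (is.null(elements)) elements <- unique(unlist(lapply(parsed, names)))
  if (!length(elements)) elements <- "C"
  m <- matrix(0L, nrow = length(formulas), ncol = length(elements),
              dimnames = list(NULL, elements))
  for (i in seq_along(parsed)) {
    f <- parsed[[i]]
    if (length(f)) m[i, names(f)] <- f
  }
  m
}

# Row-wise Hill strings from an element-count matrix.
matrix_to_formula <- function(m) {
  els <- colnames(m)
  ord <- if ("C" %in% els) {
    c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    sort(els)
  }
  m <- m[, ord, drop = FALSE]
  out <- rep("", nrow(m))
  for (j in seq_len(ncol(m))) {
    cnt <- m[, j]
    tok <- ifelse(cnt == 0L, "",
                  paste0(colnames(m)[j], ifelse(cnt == 1L, "", cnt)))
    out <- paste0(out, tok)
  }
  out
}

#' Relative mass deviation in parts per million
#'
#' Uses the theoretical (library) mass as the reference:
#' \eqn{|m_{obs} - m_{ref}| / m_{ref} \times 10^6}.
#'
#' @param observed,reference Masses in Da (vectorized).
#' @return Absolute deviation in ppm.
#' @export
ppm_error <- function(observed, reference) {
  abs(observed - reference) / reference * 1e6
}
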