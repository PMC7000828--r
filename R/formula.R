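#' Parse a molecular formula in Hill notation
#'
#' Parses strings such as `"C28H43N3O4"` into a named count vector. Element
#' symbols are one capital letter optionally followed by one lowercase letter;
#' an omitted count means 1.
#'
#' @param text Character vector of formula strings.
#' @return For a single string, a `chem_formula` (named integer vector of
#'   element counts); for several, a list of them.
#' @export
#' @examples
#' parse_formula("H2O")
#' parse_formula("C28H43N3O4")
parse_formula <- function(text) {
  if (length(text) > 1L) return(lapply(text, parse_formula))
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  s <- gsub("[[:space:]]", "", text)
  if (s == "") return(chem_formula(integer(0)))
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s)) {
    stop("malformed formula string: '", text, "'")
  }
  elems <- sub("[0-9]*$", "", tokens)
  counts <- sub("^[A-Z][a-z]?", "", tokens)
  counts <- ifelse(counts == "", 1L, suppressWarnings(as.integer(counts)))
  if (anyNA(counts)) stop("malformed formula string: '", text, "'")
  unknown <- setdiff(elems, names(.MONOISOTOPIC))
  if (length(unknown)) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  out <- tapply(counts, elems, sum)
  chem_formula(setNames(as.integer(out), names(out)))
}

#' Construct a chemical formula from element counts
#'
#' @param counts Named integer vector, element symbol -> count (>= 0).
#' @return A `chem_formula` object (counts stored in Hill order: C, H, then
#'   alphabetical; zero counts dropped).
#' @export
chem_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) stop("negative element count")
  if (length(counts)) {
    unknown <- setdiff(names(counts), names(.MONOISOTOPIC))
    if (length(unknown)) {
      stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
    }
    counts <- counts[hill_order(names(counts))]
  }
  structure(setNames(as.integer(counts), names(counts)), class = "chem_formula")
}

hill_order <- function(elems) {
  rest <- sort(setdiff(elems, c("C", "H")))
  match(c(intersect(c("C", "H"), elems), rest), elems)
}

#' @export
format.chem_formula <- function(x, ...) {
  if (!length(x)) return("")
  paste0(names(x), ifelse(unclass(x) == 1L, "", unclass(x)), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "  (", round(monoisotopic_mass(x), 5),
      " Da)\n", sep = "")
  invisible(x)
}

#' @export
`+.chem_formula` <- function(e1, e2) {
  all_elems <- union(names(e1), names(e2))
  a <- setNames(integer(length(all_elems)), all_elems)
  a[names(e1)] <- a[names(e1)] + unclass(e1)
  a[names(e2)] <- a[names(e2)] + unclass(e2)
  chem_formula(a)
}

#' @export
`-.chem_formula` <- function(e1, e2) {
  all_elems <- union(names(e1), names(e2))
  a <- setNames(integer(length(all_elems)), all_elems)
  a[names(e1)] <- a[names(e1)] + unclass(e1)
  a[names(e2)] <- a[names(e2)] - unclass(e2)
  if (any(a < 0)) {
    stop("formula subtraction yields negative count for: ",
         paste(names(a)[a < 0], collapse = ", "))
  }
  chem_formula(a)
}

#' Monoisotopic mass of a formula
#'
#' Sum over elements of count times the mass of the element's most abundant
#' isotope, using the packaged atomic-mass table.
#'
#' @param formula A `chem_formula`, a formula string, or a list of either.
#' @return Monoisotopic mass in Da (0 for the empty formula).
#' @export
#' @examples
#' monoisotopic_mass("H2O")    # 18.010565
monoisotopic_mass <- function(formula) {
  if (is.list(formula)) return(vapply(formula, monoisotopic_mass, numeric(1)))
  if (is.character(formula)) formula <- parse_formula(formula)
  if (!length(formula)) return(0)
  sum(.MONOISOTOPIC[names(formula)] * unclass(formula))
}

#' Isotope envelope under the carbon-binomial model
#'
#' Approximates the isotopologue pattern by the binomial distribution of 13C
#' substitutions only. Adequate for S/Cl-free Ugi products, whose heavier
#' isotope contributions are dominated by carbon. Peak 0 is the monoisotopic
#' peak, normalized to abundance 1.
#'
#' @param formula `chem_formula` or formula string.
#' @param n_peaks Number of envelope peaks to return (>= 1).
#' @return Data frame with columns `offset` (Da, k times the 13C-12C shift)
#'   and `abundance` (relative to peak 0).
#' @export
#' @examples
#' isotope_envelope("CH4", 2)   # M+1 about 1.08% of M
isotope_envelope <- function(formula, n_peaks = 3L) {
  stopifnot(n_peaks >= 1L)
  if (is.character(formula)) formula <- parse_formula(formula)
  n_c <- if ("C" %in% names(formula)) unclass(formula)[["C"]] else 0L
  k <- seq_len(n_peaks) - 1L
  r <- .C13_ABUNDANCE / (1 - .C13_ABUNDANCE)
  ab <- ifelse(k <= n_c, choose(n_c, k) * r^k, 0)
  data.frame(offset = k * .C13_SHIFT, abundance = ab)
}

#' m/z of a singly charged cation adduct
#'
#' Computes `[M+X]+` m/z for X in H, Na, K: the neutral monoisotopic mass plus
#' the cation mass (atomic mass minus one electron mass; the electron
#' subtraction can be disabled for coarse matching).
#'
#' @param M Neutral monoisotopic mass(es), Da (>= 0).
#' @param adduct `"H"`, `"Na"` or `"K"`.
#' @param electron Subtract the electron mass (default TRUE; FT-ICR mass
#'   accuracy resolves it).
#' @return m/z value(s).
#' @export
#' @examples
#' adduct_mz(485.3254, "Na")   # 508.3146
adduct_mz <- function(M, adduct = c("Na", "H", "K"), electron = TRUE) {
  adduct <- match.arg(adduct)
  if (any(M < 0)) stop("M must be non-negative")
  M + .MONOISOTOPIC[[adduct]] - if (electron) .ELECTRON_MASS else 0
}
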