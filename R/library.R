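WATER <- c(H = 2L, O = 1L)

#' Condense four Ugi reagents into one product
#'
#' The four-component Ugi reaction combines an amine, an aldehyde (or ketone),
#' a carboxylic acid and an isocyanide into a single peptide-like bis-amide
#' plus water, so the product formula is the elementwise sum of the four
#' reagent formulas minus H2O.
#'
#' @param amine,aldehyde,acid,isocyanide Rows of a [read_reagents()] table
#'   (lists with `name`, `role`, `formula`) or objects from `reagent()`.
#' @return List with `reagents` (the four names), `formula` (`chem_formula`)
#'   and `M` (monoisotopic mass, Da).
#' @export
ugi_condense <- function(amine, aldehyde, acid, isocyanide) {
  parts <- list(amine = amine, aldehyde = aldehyde, acid = acid,
                isocyanide = isocyanide)
  for (pos in names(parts)) {
    if (!identical(parts[[pos]]$role, pos)) {
      stop("reagent in ", pos, " position has role '", parts[[pos]]$role, "'")
    }
  }
  fs <- lapply(parts, function(p) {
    f <- p$formula
    if (is.character(f)) parse_formula(f) else f
  })
  prod <- fs[[1]] + fs[[2]] + fs[[3]] + fs[[4]] - chem_formula(WATER)
  list(reagents = vapply(parts, `[[`, "", "name"),
       formula = prod, M = monoisotopic_mass(prod))
}

#' Enumerate the full combinatorial Ugi library
#'
#' Forms the Cartesian product of all reagents over the four roles. The
#' enumeration order is frozen: nested loops amine -> aldehyde -> acid ->
#' isocyanide with the amine index slowest and the isocyanide fastest, so the
#' library index is a bijection with reagent quadruples. Indices are 1-based
#' in all user-facing I/O.
#'
#' @param reagents A `reagent_table` from [read_reagents()].
#' @return Data frame of class `ugi_library`: columns `index`, `amine`,
#'   `aldehyde`, `acid`, `isocyanide` (reagent names), `formula` (string) and
#'   `M` (monoisotopic mass, Da), one row per product.
#' @export
#' @examples
#' lib <- enumerate_library(read_reagents())
#' nrow(lib)  # 5 * 5 * 12 * 5 = 1500
enumerate_library <- function(reagents) {
  by_role <- split(seq_len(nrow(reagents)), factor(reagents$role, UGI_ROLES))
  n <- vapply(by_role, length, integer(1))
  if (any(n == 0L)) {
    stop("empty reagent group(s): ", paste(names(n)[n == 0L], collapse = ", "))
  }
  # isocyanide varies fastest, amine slowest
  grid <- expand.grid(isocyanide = by_role$isocyanide, acid = by_role$acid,
                      aldehyde = by_role$aldehyde, amine = by_role$amine,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(names(grid))]

  # vectorized element bookkeeping: counts matrix (reagent x element)
  fs <- parse_formula(reagents$formula)
  elems <- sort(unique(unlist(lapply(fs, names))))
  cnt <- matrix(0L, nrow(reagents), length(elems),
                dimnames = list(NULL, elems))
  for (i in seq_along(fs)) cnt[i, names(fs[[i]])] <- unclass(fs[[i]])
  pc <- cnt[grid$amine, , drop = FALSE] + cnt[grid$aldehyde, , drop = FALSE] +
    cnt[grid$acid, , drop = FALSE] + cnt[grid$isocyanide, , drop = FALSE]
  pc[, "H"] <- pc[, "H"] - 2L
  pc[, "O"] <- pc[, "O"] - 1L
  if (any(pc < 0L)) stop("condensation yields a negative element count")
  M <- as.numeric(pc %*% .MONOISOTOPIC[elems])

  ord <- hill_order(elems)
  fstr <- apply(pc[, ord, drop = FALSE], 1L, function(r) {
    r <- r[r > 0L]
    paste0(names(r), ifelse(r == 1L, "", r), collapse = "")
  })
  out <- data.frame(index = seq_len(nrow(grid)),
                    amine = reagents$name[grid$amine],
                    aldehyde = reagents$name[grid$aldehyde],
                    acid = reagents$name[grid$acid],
                    isocyanide = reagents$name[grid$isocyanide],
                    formula = fstr, M = M, stringsAsFactors = FALSE)
  attr(out, "reagents") <- reagents
  class(out) <- c("ugi_library", "data.frame")
  out
}

#' Group library products with indistinguishable monoisotopic masses
#'
#' Partitions products into mass-collision groups: connected components of the
#' graph joining any two products whose relative mass difference
#' `|M1 - M2| / mean(M1, M2)` is at most `tol` ppm. Singletons are omitted.
#'
#' @param library A `ugi_library`.
#' @param tol Tolerance in ppm (> 0).
#' @return List of integer vectors of product indices (each of length >= 2).
#' @export
mass_collisions <- function(library, tol = 5) {
  stopifnot(tol > 0)
  n <- nrow(library)
  if (n == 0L) return(list())
  M <- library$M
  ord <- order(M)
  # union-find over a sorted sliding window (transitive closure of the ppm graph)
  parent <- seq_len(n)
  find <- function(i) { r <- i; while (parent[r] != r) r <- parent[r]; r }
  for (a in seq_len(n - 1L)) {
    i <- ord[a]
    b <- a + 1L
    while (b <= n) {
      j <- ord[b]
      if (2 * abs(M[j] - M[i]) / (M[i] + M[j]) * 1e6 > tol) break
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
      b <- b + 1L
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  groups <- groups[lengths(groups) >= 2L]
  names(groups) <- NULL
  lapply(groups, as.integer)
}

#' Export a library table with adduct m/z columns
#'
#' Writes `index`, the four reagent names, `formula`, `M`, and the m/z of the
#' protonated, sodiated and potassiated singly charged adducts.
#'
#' @param library A `ugi_library`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
export_library <- function(library, path) {
  df <- as.data.frame(library)
  df$mz_H <- adduct_mz(df$M, "H")
  df$mz_Na <- adduct_mz(df$M, "Na")
  df$mz_K <- adduct_mz(df$M, "K")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.ugi_library <- function(x, ...) {
  cat("<ugi_library> ", nrow(x), " products, M in [",
      round(min(x$M), 2), ", ", round(max(x$M), 2), "] Da\n", sep = "")
  print(head(as.data.frame(x)), ...)
  invisible(x)
}
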