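UGI_ROLES <- c("amine", "aldehyde", "acid", "isocyanide")

#' Read a reagent table
#'
#' Reads a CSV with columns `name`, `role`, `formula` into a reagent table.
#' Roles must be one of amine, aldehyde, acid, isocyanide. Monoisotopic masses
#' are derived from the formulas.
#'
#' @param path CSV path. The default is the packaged 27-reagent table
#'   (5 amines, 5 aldehydes, 12 carboxylic acids, 5 isocyanides) of the
#'   1500-product Ugi library, with formulas derived from the standard
#'   structures of the named chemicals.
#' @return Data frame of class `reagent_table` with columns `name`, `role`,
#'   `formula` (character) and `mass` (Da).
#' @export
#' @examples
#' rg <- read_reagents()
#' table(rg$role)
read_reagents <- function(path = system.file("extdata", "ugi_reagents.csv",
                                             package = "ugimem")) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "role", "formula")
  if (!all(need %in% names(df))) {
    stop("reagent CSV must have columns: ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$role), UGI_ROLES)
  if (length(bad)) stop("unknown reagent role(s): ", paste(bad, collapse = ", "))
  df$mass <- monoisotopic_mass(parse_formula(df$formula))
  class(df) <- c("reagent_table", "data.frame")
  df
}

reagent <- function(name, role, formula) {
  role <- match.arg(role, UGI_ROLES)
  if (is.character(formula)) formula <- parse_formula(formula)
  list(name = name, role = role, formula = formula,
       mass = monoisotopic_mass(formula))
}
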