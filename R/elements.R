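#' Atomic property tables for descriptor weighting
#'
#' Returns the table of per-element constants backing the three atomic
#' weighting schemes used by the descriptor engine: atomic mass (`m`),
#' Sanderson electronegativity (`e`) and van der Waals volume (`v`, the
#' volume of a sphere with the Bondi van der Waals radius, in cubic
#' Angstrom). Values are also shipped as plain text in
#' `inst/extdata/element_properties.tsv`, which documents the sources and can
#' be edited and passed back through `table` arguments to override defaults.
#'
#' @param path Optional path to a delimited override table with columns
#'   `element`, `mass`, `sanderson_en`, `vdw_volume`.
#' @return A data.frame with columns `element`, `mass`, `sanderson_en`,
#'   `vdw_volume`, one row per supported element.
#' @export
element_properties <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "element_properties.tsv", package = "triqsar",
                        mustWork = TRUE)
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("element", "mass", "sanderson_en", "vdw_volume")
  if (!all(need %in% names(tab))) {
    stop("property table must have columns: ", paste(need, collapse = ", "))
  }
  num <- tab[, c("mass", "sanderson_en", "vdw_volume")]
  if (any(!vapply(num, is.numeric, logical(1))) || any(unlist(num) <= 0)) {
    stop("all property values must be strictly positive numbers")
  }
  if (!"C" %in% tab$element) stop("property table must include carbon")
  tab
}

.scheme_column <- function(scheme) {
  switch(match.arg(scheme, c("m", "e", "v")),
         m = "mass", e = "sanderson_en", v = "vdw_volume")
}

#' Carbon-scaled atomic weights
#'
#' Dragon-style atomic weights: the tabulated property of each atom's element
#' divided by the carbon value, so carbon atoms weigh exactly 1. Used by the
#' Moran autocorrelations, the radial distribution function and the GETAWAY
#' R-indices.
#'
#' @param mol A [molecule].
#' @param scheme `"m"` (mass), `"e"` (Sanderson electronegativity) or `"v"`
#'   (van der Waals volume).
#' @param table Property table, defaults to [element_properties()].
#' @param indices Atom indices to weight (default: all atoms).
#' @return Numeric vector of weights, one per requested atom.
#' @export
scaled_weights <- function(mol, scheme = c("m", "e", "v"),
                           table = element_properties(), indices = NULL) {
  col <- .scheme_column(scheme)
  stopifnot(inherits(mol, "molecule"))
  if (is.null(indices)) indices <- seq_len(nrow(mol$atoms))
  elems <- mol$atoms$element[indices]
  pos <- match(elems, table$element)
  if (anyNA(pos)) {
    missing <- sort(unique(elems[is.na(pos)]))
    stop("element(s) not tabulated for scheme '", col, "': ",
         paste(missing, collapse = ", "))
  }
  carbon <- table[[col]][match("C", table$element)]
  table[[col]][pos] / carbon
}
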