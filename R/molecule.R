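#' Molecular structure container
#'
#' A light container for one small molecule: an ordered atom table (element,
#' Cartesian coordinates in Angstrom, aromatic flag) and a bond table (pairs
#' of 1-based atom indices with bond order; order 4 denotes aromatic).
#' Molecules read from SMILES carry no coordinates until
#' [embed_coordinates()] is applied; `has_coords(mol)` reports the state.
#'
#' @param atoms data.frame with columns `element` (character), `x`, `y`, `z`
#'   (numeric, may be NA when not yet embedded) and optionally `aromatic`
#'   (logical, default FALSE).
#' @param bonds data.frame with columns `i`, `j` (1-based atom indices) and
#'   `order` (1, 2, 3 or 4 = aromatic). May have zero rows for a single atom.
#' @param id Text identifier.
#' @return An object of class `molecule`.
#' @export
molecule <- function(atoms, bonds = NULL, id = "mol") {
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$aromatic)) atoms$aromatic <- FALSE
  atoms$element <- as.character(atoms$element)
  if (nrow(atoms) < 1) stop("molecule needs at least one atom")
  if (is.null(bonds) || nrow(as.data.frame(bonds)) == 0) {
    bonds <- data.frame(i = integer(0), j = integer(0), order = integer(0))
  } else {
    bonds <- as.data.frame(bonds)
    stopifnot(all(c("i", "j") %in% names(bonds)))
    if (is.null(bonds$order)) bonds$order <- 1L
    bad <- bonds$i < 1 | bonds$i > nrow(atoms) | bonds$j < 1 |
      bonds$j > nrow(atoms) | bonds$i == bonds$j
    if (any(bad)) stop("bond endpoints must be distinct valid atom indices")
  }
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(is.finite(coords)) && !all(is.finite(coords))) {
    stop("coordinates must be all finite or all absent")
  }
  m <- structure(list(id = as.character(id),
                      atoms = atoms[, c("element", "x", "y", "z", "aromatic")],
                      bonds = bonds[, c("i", "j", "order")]),
                 class = "molecule")
  hv <- heavy_indices(m)
  if (length(hv) < 1) stop("molecule must contain at least one heavy atom")
  if (length(hv) > 1 && !.is_connected(m, hv)) {
    stop("heavy-atom graph must be connected (molecule '", id, "')")
  }
  m
}

#' @export
print.molecule <- function(x, ...) {
  cat(sprintf("<molecule '%s': %d atoms (%d heavy), %d bonds, coords: %s>\n",
              x$id, nrow(x$atoms), length(heavy_indices(x)), nrow(x$bonds),
              if (has_coords(x)) "yes" else "no"))
  invisible(x)
}

#' @rdname molecule
#' @param mol A molecule.
#' @export
has_coords <- function(mol) all(is.finite(as.matrix(mol$atoms[, c("x", "y", "z")])))

#' Indices of non-hydrogen atoms
#' @param mol A [molecule].
#' @return Integer vector of 1-based atom indices.
#' @export
heavy_indices <- function(mol) which(mol$atoms$element != "H")

coords_matrix <- function(mol, indices = seq_len(nrow(mol$atoms))) {
  as.matrix(mol$atoms[indices, c("x", "y", "z"), drop = FALSE])
}

.mol_graph <- function(mol, indices = seq_len(nrow(mol$atoms))) {
  keep <- mol$bonds$i %in% indices & mol$bonds$j %in% indices
  remap <- match(seq_len(nrow(mol$atoms)), indices)
  ev <- rbind(remap[mol$bonds$i[keep]], remap[mol$bonds$j[keep]])
  igraph::make_graph(as.vector(ev), n = length(indices), directed = FALSE)
}

.is_connected <- function(mol, indices) {
  g <- .mol_graph(mol, indices)
  igraph::is_connected(g)
}

#' Topological distance matrix
#'
#' Shortest-path bond counts between atoms, on either the full graph or the
#' hydrogen-depleted (heavy-atom) graph. This is the lag metric used by the
#' Moran autocorrelations and the GETAWAY R-indices.
#'
#' @param mol A [molecule].
#' @param hydrogen_depleted If TRUE (default) distances are computed on the
#'   heavy-atom subgraph; row/column order follows [heavy_indices()].
#' @return A symmetric integer matrix with zero diagonal.
#' @export
topological_distances <- function(mol, hydrogen_depleted = TRUE) {
  idx <- if (hydrogen_depleted) heavy_indices(mol) else seq_len(nrow(mol$atoms))
  if (length(idx) == 1) return(matrix(0L, 1, 1))
  g <- .mol_graph(mol, idx)
  if (!igraph::is_connected(g)) {
    stop("requested graph view is disconnected")
  }
  d <- igraph::distances(g)
  storage.mode(d) <- "integer"
  dimnames(d) <- NULL
  d
}

#' Heavy-atom graph degrees
#' @keywords internal
.heavy_degrees <- function(mol) {
  idx <- heavy_indices(mol)
  g <- .mol_graph(mol, idx)
  igraph::degree(g)
}

#' Perceive aromatic rings from Kekule input
#'
#' Marks atoms of rings whose bonds are all flagged aromatic (order 4), or
#' six-membered rings with alternating single/double bonds, as aromatic.
#' Readers call this so that downstream pattern matching (aromatic ester
#' counting) works on both aromatic-bond and Kekule-encoded input.
#'
#' @param mol A [molecule].
#' @return The molecule with updated `aromatic` atom flags.
#' @export
perceive_aromaticity <- function(mol) {
  idx <- heavy_indices(mol)
  if (length(idx) < 3) return(mol)
  g <- .mol_graph(mol, idx)
  # bond order lookup keyed on heavy-subgraph vertex pairs
  remap <- match(seq_len(nrow(mol$atoms)), idx)
  keep <- mol$bonds$i %in% idx & mol$bonds$j %in% idx
  bi <- remap[mol$bonds$i[keep]]; bj <- remap[mol$bonds$j[keep]]
  ord <- mol$bonds$order[keep]
  okey <- paste(pmin(bi, bj), pmax(bi, bj))
  getord <- function(a, b) ord[match(paste(min(a, b), max(a, b)), okey)]
  arom <- mol$atoms$aromatic
  arom[mol$bonds$i[mol$bonds$order == 4]] <- TRUE
  arom[mol$bonds$j[mol$bonds$order == 4]] <- TRUE
  for (ring in .simple_rings(g)) {
    n <- length(ring)
    orders <- vapply(seq_len(n), function(k) {
      getord(ring[k], ring[k %% n + 1])
    }, numeric(1))
    aromatic_ring <- all(orders == 4) ||
      (n == 6 && all(sort(unique(orders)) == c(1, 2)) &&
         all(abs(diff(c(orders, orders[1]))) == 1))
    if (aromatic_ring) arom[idx[ring]] <- TRUE
  }
  mol$atoms$aromatic <- arom
  mol
}

# minimal cycle basis as vertex sequences (small molecules only)
.simple_rings <- function(g) {
  out <- list()
  for (sz in 3:8) {
    # enumerate chordless cycles of size sz via simple DFS from each vertex
    n <- igraph::vcount(g)
    adj <- igraph::as_adj_list(g)
    seen <- character(0)
    walk <- function(path) {
      last <- path[length(path)]
      for (nb in as.integer(adj[[last]])) {
        if (length(path) == sz && nb == path[1]) {
          key <- paste(sort(path), collapse = "-")
          if (!key %in% seen) {
            seen <<- c(seen, key)
            out[[length(out) + 1]] <<- path
          }
        } else if (length(path) < sz && !(nb %in% path) && nb > path[1]) {
          walk(c(path, nb))
        }
      }
    }
    for (v in seq_len(n)) walk(v)
  }
  out
}
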