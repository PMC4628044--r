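#' Moran spatial autocorrelation over the molecular graph (MATS)
#'
#' The Moran index at topological lag \eqn{k} over the hydrogen-depleted
#' graph with carbon-scaled atomic weights \eqn{w}:
#' \deqn{I(k) = \frac{\frac{1}{\Delta}\sum_{i<j,\,d_{ij}=k}(w_i-\bar w)(w_j-\bar w)}
#'             {\frac{1}{A}\sum_i (w_i-\bar w)^2}}
#' where \eqn{\Delta} is the number of atom pairs at that lag and \eqn{A} the
#' heavy-atom count. `MATS7m` is lag 7 with mass weights, `MATS8v` lag 8 with
#' van der Waals volume weights. Lags beyond the graph diameter return 0 with
#' a warning ("no pairs" convention); an all-equal weight vector is an error
#' because the index is then undefined.
#'
#' @param mol A [molecule] with a connected heavy-atom graph of >= 2 atoms.
#' @param lag Positive integer topological distance.
#' @param scheme Weighting scheme (`"m"`, `"e"`, `"v"`).
#' @param table Property table override.
#' @param weights Optional explicit per-heavy-atom weights (bypasses
#'   `scheme`/`table`); the index is invariant to affine transforms of these.
#' @return The Moran index (unitless scalar).
#' @export
moran_autocorrelation <- function(mol, lag, scheme = c("m", "e", "v"),
                                  table = element_properties(),
                                  weights = NULL) {
  if (!is.numeric(lag) || lag < 1 || lag != round(lag)) {
    stop("lag must be a positive integer")
  }
  idx <- heavy_indices(mol)
  if (length(idx) < 2) stop("need at least 2 heavy atoms")
  w <- if (is.null(weights)) scaled_weights(mol, scheme, table, indices = idx)
       else {
         if (length(weights) != length(idx)) stop("weights length mismatch")
         weights
       }
  wc <- w - mean(w)
  denom <- mean(wc^2)
  if (denom < 1e-14) {
    stop("zero weight variance: all scaled weights equal, Moran index undefined")
  }
  D <- topological_distances(mol, hydrogen_depleted = TRUE)
  pairs <- which(upper.tri(D) & D == lag, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    warning("no atom pairs at lag ", lag, "; returning 0 by convention")
    return(0)
  }
  num <- mean(wc[pairs[, 1]] * wc[pairs[, 2]])
  num / denom
}

#' Radial distribution function descriptor (RDF)
#'
#' Smoothed, weighted count of interatomic distances at a probe radius
#' \eqn{R}: \deqn{RDF(R) = \sum_{i<j} w_i w_j\, e^{-\beta (R - r_{ij})^2}}
#' over the included atoms (hydrogens included by default, matching the 3D
#' descriptor convention). `RDF105m` is \eqn{R = 10.5} Angstrom with mass
#' weights.
#'
#' @param mol A [molecule] with coordinates.
#' @param radius Probe radius in Angstrom.
#' @param scheme Weighting scheme.
#' @param beta Smoothing parameter in 1/Angstrom^2, default 100.
#' @param include_hydrogens Include H atoms (default TRUE).
#' @param table Property table override.
#' @return Non-negative scalar.
#' @export
rdf_descriptor <- function(mol, radius, scheme = c("m", "e", "v"), beta = 100,
                           include_hydrogens = TRUE,
                           table = element_properties()) {
  if (!is.numeric(beta) || beta <= 0) stop("beta must be positive")
  if (!is.numeric(radius) || radius <= 0) stop("radius must be positive")
  if (!has_coords(mol)) stop("molecule has no 3D coordinates")
  idx <- if (include_hydrogens) seq_len(nrow(mol$atoms)) else heavy_indices(mol)
  if (length(idx) < 2) stop("need at least 2 atoms in the included view")
  w <- scaled_weights(mol, scheme, table, indices = idx)
  r <- as.matrix(stats::dist(coords_matrix(mol, idx)))
  ut <- upper.tri(r)
  sum((w %o% w)[ut] * exp(-beta * (radius - r[ut])^2))
}

#' GETAWAY context: leverages, geometric and topological distances
#'
#' Builds the ingredients of the GETAWAY descriptor class: atomic leverages
#' \eqn{h_i} (the diagonal of the molecular influence matrix
#' \eqn{H = M(M'M)^{-1}M'} with \eqn{M} the centred coordinate matrix;
#' pseudoinverse for planar/linear geometries), Euclidean distances
#' \eqn{r_{ij}} and topological distances \eqn{d_{ij}} over the same atom
#' set.
#'
#' @param mol A [molecule] with coordinates.
#' @param include_hydrogens Include H atoms (default TRUE).
#' @return An object of class `getaway_context` with elements `leverage`,
#'   `geom_dist`, `topo_dist`, `rank`, `indices`.
#' @export
getaway_context <- function(mol, include_hydrogens = TRUE) {
  if (!has_coords(mol)) stop("molecule has no 3D coordinates")
  idx <- if (include_hydrogens) seq_len(nrow(mol$atoms)) else heavy_indices(mol)
  M <- scale(coords_matrix(mol, idx), center = TRUE, scale = FALSE)
  sv <- svd(M)
  tol <- max(dim(M)) * max(sv$d, 0) * .Machine$double.eps * 100
  r <- sum(sv$d > tol)
  if (r == 0) stop("all atoms coincident: influence matrix undefined")
  U <- sv$u[, seq_len(r), drop = FALSE]
  h <- rowSums(U^2)
  structure(list(leverage = h,
                 geom_dist = as.matrix(stats::dist(coords_matrix(mol, idx))),
                 topo_dist = topological_distances(mol,
                                                   hydrogen_depleted = !include_hydrogens),
                 rank = r,
                 indices = idx),
            class = "getaway_context")
}

#' GETAWAY R autocorrelation (Rk / Rk+ indices)
#'
#' Over atom pairs at topological lag \eqn{k}, each pair contributes
#' \eqn{\sqrt{h_i h_j}\, w_i w_j / r_{ij}}. Mode `"sum"` totals the terms
#' (the `R7m` descriptor at lag 7 with mass weights); mode `"max"` takes the
#' largest single term (the `R5e+` descriptor at lag 5 with Sanderson
#' electronegativity weights). No pairs at the lag yields 0 with a warning.
#'
#' @param ctx A [getaway_context].
#' @param weights Per-atom scaled weights matching the context's atom set.
#' @param lag Positive integer topological distance.
#' @param mode `"sum"` or `"max"`.
#' @return Non-negative scalar.
#' @export
getaway_r_autocorrelation <- function(ctx, weights, lag, mode = c("sum", "max")) {
  mode <- match.arg(mode)
  if (!inherits(ctx, "getaway_context")) stop("ctx must be a getaway_context")
  if (!is.numeric(lag) || lag < 1 || lag != round(lag)) {
    stop("lag must be a positive integer")
  }
  if (length(weights) != length(ctx$leverage)) {
    stop("weight vector length (", length(weights),
         ") does not match atom count (", length(ctx$leverage), ")")
  }
  pairs <- which(upper.tri(ctx$topo_dist) & ctx$topo_dist == lag, arr.ind = TRUE)
  if (nrow(pairs) == 0) {
    warning("no atom pairs at lag ", lag, "; returning 0 by convention")
    return(0)
  }
  i <- pairs[, 1]; j <- pairs[, 2]
  term <- sqrt(ctx$leverage[i] * ctx$leverage[j]) / ctx$geom_dist[pairs] *
    weights[i] * weights[j]
  if (mode == "sum") sum(term) else max(term)
}

#' Lopping centric index (Lop)
#'
#' Information-theoretic centric index over the partition of heavy atoms by
#' iterative pruning: at each step all terminal (degree <= 1) vertices are
#' removed; if a pruning step finds no terminal vertices but vertices remain
#' (a pure cycle), the final step removes them all as one class. With
#' \eqn{n_g} atoms removed at step \eqn{g} out of \eqn{A} heavy atoms,
#' \deqn{Lop = -\sum_g \frac{n_g}{A}\log_2\frac{n_g}{A}.}
#'
#' @param mol A [molecule] with a connected heavy-atom graph.
#' @return Non-negative scalar in bits; 0 for a single heavy atom.
#' @export
lopping_centric_index <- function(mol) {
  idx <- heavy_indices(mol)
  A <- length(idx)
  if (A == 1) return(0)
  g <- .mol_graph(mol, idx)
  if (!igraph::is_connected(g)) stop("heavy-atom graph is disconnected")
  counts <- integer(0)
  while (igraph::vcount(g) > 0) {
    deg <- igraph::degree(g)
    leaves <- which(deg <= 1)
    if (length(leaves) == 0) {          # pure cycle: one terminal class
      counts <- c(counts, igraph::vcount(g))
      break
    }
    counts <- c(counts, length(leaves))
    g <- igraph::delete_vertices(g, leaves)
  }
  p <- counts / A
  -sum(p * log2(p))
}

#' Count aromatic esters (nArCOOR)
#'
#' Counts distinct ester groups C(=O)-O-C whose carbonyl carbon is bonded to
#' an aromatic atom (aryl esters, Ar-COOR). The acyl side defines
#' aromaticity: methyl benzoate counts 1, phenyl acetate counts 0. Each
#' ester group is counted once regardless of how many aromatic substituents
#' it carries.
#'
#' @param mol A [molecule] with perceived aromaticity (readers do this; for
#'   hand-built molecules call [perceive_aromaticity()] first).
#' @return Non-negative integer.
#' @export
count_aromatic_esters <- function(mol) {
  atoms <- mol$atoms; bonds <- mol$bonds
  nbrs <- function(a) {
    rows <- bonds$i == a | bonds$j == a
    data.frame(other = ifelse(bonds$i[rows] == a, bonds$j[rows], bonds$i[rows]),
               order = bonds$order[rows])
  }
  count <- 0L
  for (c1 in which(atoms$element == "C")) {
    nb <- nbrs(c1)
    o_dbl <- nb$other[atoms$element[nb$other] == "O" & nb$order == 2]
    o_sng <- nb$other[atoms$element[nb$other] == "O" & nb$order == 1]
    if (!length(o_dbl) || !length(o_sng)) next
    ar <- any(atoms$aromatic[nb$other])
    if (!ar) next
    # ester (not acid): the single-bonded O must carry a carbon substituent
    esterified <- any(vapply(o_sng, function(o) {
      onb <- nbrs(o)
      any(atoms$element[onb$other] == "C" & onb$other != c1)
    }, logical(1)))
    if (esterified) count <- count + 1L
  }
  count
}

#' The seven-descriptor feature vector of the published models
#'
#' Computes `R5e+` (GETAWAY max R-index, lag 5, electronegativity weights),
#' `nArCOOR`, `RDF105m` (RDF at 10.5 Angstrom, mass weights), `MATS7m` and
#' `MATS8v` (Moran lags 7 and 8, mass / van der Waals volume weights), `Lop`
#' and `R7m` (GETAWAY sum R-index, lag 7, mass weights). Lags beyond the
#' graph diameter yield 0 and are flagged in the provenance attribute.
#'
#' @param mol A [molecule] with coordinates, or NULL when `supplied` is given.
#' @param beta RDF smoothing parameter (1/Angstrom^2).
#' @param include_hydrogens Hydrogen handling for the 3D descriptors (RDF,
#'   GETAWAY); the 2D descriptors (MATS, Lop) always use the heavy-atom graph.
#' @param table Property table override.
#' @param supplied Optional named numeric vector of externally computed
#'   descriptor values (e.g. from the original study's tables); returned
#'   as-is with provenance `"supplied"`.
#' @return Named numeric vector of class `descriptor_vector` with a
#'   `provenance` attribute (`"computed"`, `"supplied"`, or
#'   `"computed:no-pairs"` per entry).
#' @export
compute_descriptors <- function(mol = NULL, beta = 100,
                                include_hydrogens = TRUE,
                                table = element_properties(),
                                supplied = NULL) {
  nm <- descriptor_names()
  if (!is.null(supplied)) {
    miss <- setdiff(nm, names(supplied))
    if (length(miss)) stop("supplied vector missing descriptor(s): ",
                           paste(miss, collapse = ", "))
    v <- as.numeric(supplied[nm]); names(v) <- nm
    return(structure(v, provenance = stats::setNames(rep("supplied", 7), nm),
                     class = "descriptor_vector"))
  }
  stopifnot(inherits(mol, "molecule"))
  prov <- stats::setNames(rep("computed", 7), nm)
  grab <- function(name, expr) {
    withCallingHandlers(expr, warning = function(w) {
      if (grepl("no atom pairs", conditionMessage(w))) {
        prov[name] <<- "computed:no-pairs"
        invokeRestart("muffleWarning")
      }
    })
  }
  # homogeneous weights (e.g. an all-carbon skeleton) leave the Moran index
  # undefined; the composed vector records 0 with a degenerate flag instead
  # of failing the whole molecule
  moran_or_zero <- function(name, lag, scheme) {
    tryCatch(grab(name, moran_autocorrelation(mol, lag, scheme, table)),
             error = function(e) {
               if (grepl("zero weight variance", conditionMessage(e))) {
                 prov[name] <<- "computed:degenerate"
                 0
               } else stop(name, ": ", conditionMessage(e), call. = FALSE)
             })
  }
  wrap <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  ctx <- wrap("GETAWAY", getaway_context(mol, include_hydrogens))
  we <- scaled_weights(mol, "e", table, indices = ctx$indices)
  wm <- scaled_weights(mol, "m", table, indices = ctx$indices)
  v <- c(
    `R5e+`    = wrap("R5e+", grab("R5e+",
                 getaway_r_autocorrelation(ctx, we, 5, "max"))),
    nArCOOR   = wrap("nArCOOR", as.numeric(count_aromatic_esters(mol))),
    RDF105m   = wrap("RDF105m",
                 rdf_descriptor(mol, 10.5, "m", beta, include_hydrogens, table)),
    MATS7m    = moran_or_zero("MATS7m", 7, "m"),
    MATS8v    = moran_or_zero("MATS8v", 8, "v"),
    Lop       = wrap("Lop", lopping_centric_index(mol)),
    R7m       = wrap("R7m", grab("R7m",
                 getaway_r_autocorrelation(ctx, wm, 7, "sum")))
  )
  names(v) <- nm
  structure(v, provenance = prov, class = "descriptor_vector")
}

#' Names of the modeled descriptors, in canonical column order
#' @export
descriptor_names <- function() {
  c("R5e+", "nArCOOR", "RDF105m", "MATS7m", "MATS8v", "Lop", "R7m")
}

#' @export
print.descriptor_vector <- function(x, ...) {
  df <- data.frame(descriptor = names(x), value = as.numeric(x),
                   provenance = attr(x, "provenance"))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Descriptor table for a set of molecules
#'
#' @param mols List of molecules.
#' @inheritParams compute_descriptors
#' @return data.frame with `compound_id` plus the seven descriptor columns.
#' @export
descriptor_table <- function(mols, beta = 100, include_hydrogens = TRUE,
                             table = element_properties()) {
  rows <- lapply(mols, function(m) {
    v <- compute_descriptors(m, beta, include_hydrogens, table)
    cbind(data.frame(compound_id = m$id), as.data.frame(t(as.numeric(v))))
  })
  out <- do.call(rbind, rows)
  names(out) <- c("compound_id", descriptor_names())
  out
}
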