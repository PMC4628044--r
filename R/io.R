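#' Read molecular structures
#'
#' Reads one or more molecules from an SDF (V2000), XYZ, or SMILES file.
#'
#' Dialects: SDF records are MDL V2000 connection tables separated by `$$$$`;
#' fixed-width atom and bond blocks are honoured so files with more than 99
#' atoms parse correctly. XYZ files may carry the usual `natoms`/comment
#' header or be bare `element x y z` lines; bonds are inferred from covalent
#' radii (a bond when the distance is below 1.3 times the radius sum). SMILES
#' files hold one record per line with an optional whitespace-separated
#' identifier; a pragmatic subset of the grammar is supported (organic-subset
#' and simple bracket atoms, branches, ring closures including `%nn`, bond
#' symbols `- = # :`), implicit hydrogens are added by standard valence
#' rules, and the resulting molecules carry no coordinates until
#' [embed_coordinates()] is applied.
#'
#' @param path File to read.
#' @param format `"sdf"`, `"xyz"` or `"smiles"`. Defaults to the file
#'   extension.
#' @return A list of [molecule] objects, atom order as in the file.
#' @export
read_structures <- function(path, format = c("auto", "sdf", "xyz", "smiles")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", mol = "sdf", xyz = "xyz",
                     smi = "smiles", smiles = "smiles",
                     stop("cannot infer format from extension '", ext, "'"))
  }
  lines <- readLines(path, warn = FALSE)
  switch(format,
         sdf = .read_sdf(lines),
         xyz = .read_xyz(lines),
         smiles = .read_smiles_file(lines))
}

.known_elements <- c("H", "B", "C", "N", "O", "F", "P", "S", "Cl", "Br", "I")

.check_element <- function(el, where) {
  bad <- setdiff(unique(el), .known_elements)
  if (length(bad)) stop("unknown element symbol(s) in ", where, ": ",
                        paste(bad, collapse = ", "))
}

.read_sdf <- function(lines) {
  recs <- split(lines, cumsum(c(0, head(lines, -1) == "$$$$")))
  recs <- Filter(function(r) any(nzchar(trimws(r))), recs)
  out <- vector("list", length(recs))
  for (k in seq_along(recs)) {
    r <- recs[[k]]
    r <- r[r != "$$$$"]
    if (length(r) < 4) stop("SDF record ", k, ": truncated header")
    counts <- r[4]
    na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
    nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
    if (is.na(na) || is.na(nb) || na < 1 ||
        length(r) < 4 + na + nb) {
      stop("SDF record ", k, ": unparseable counts line")
    }
    aline <- r[5:(4 + na)]
    x <- as.numeric(substr(aline, 1, 10))
    y <- as.numeric(substr(aline, 11, 20))
    z <- as.numeric(substr(aline, 21, 30))
    el <- trimws(substr(aline, 32, 34))
    if (anyNA(x) || anyNA(y) || anyNA(z) || any(!nzchar(el))) {
      stop("SDF record ", k, ": unparseable atom block")
    }
    .check_element(el, paste0("SDF record ", k))
    bonds <- NULL
    if (nb > 0) {
      bline <- r[(5 + na):(4 + na + nb)]
      bonds <- data.frame(
        i = as.integer(substr(bline, 1, 3)),
        j = as.integer(substr(bline, 4, 6)),
        order = as.integer(substr(bline, 7, 9)))
      if (anyNA(bonds)) stop("SDF record ", k, ": unparseable bond block")
    }
    id <- trimws(r[1])
    if (!nzchar(id)) id <- paste0("record_", k)
    mol <- molecule(data.frame(element = el, x = x, y = y, z = z,
                               stringsAsFactors = FALSE), bonds, id = id)
    out[[k]] <- perceive_aromaticity(mol)
  }
  out
}

# covalent radii (Angstrom, Cordero 2008) for bond inference and embedding
.covalent_radius <- c(H = 0.31, B = 0.84, C = 0.76, N = 0.71, O = 0.66,
                      F = 0.57, P = 1.07, S = 1.05, Cl = 1.02, Br = 1.20,
                      I = 1.39)

.infer_bonds <- function(el, xyz) {
  n <- length(el)
  bonds <- list()
  if (n > 1) {
    d <- as.matrix(stats::dist(xyz))
    rc <- .covalent_radius[el]
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (d[i, j] < 1.3 * (rc[i] + rc[j])) {
        bonds[[length(bonds) + 1]] <- c(i, j)
      }
    }
  }
  if (!length(bonds)) return(NULL)
  m <- do.call(rbind, bonds)
  data.frame(i = m[, 1], j = m[, 2], order = 1L)
}

.read_xyz <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  id <- "xyz_mol"
  first <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(first) == 1 && grepl("^[0-9]+$", first)) {
    n <- as.integer(first)
    if (length(lines) >= 2 && nzchar(trimws(lines[2])) &&
        !grepl("^[A-Z]", trimws(lines[2]))) id <- trimws(lines[2])
    body <- lines[-(1:2)]
    if (length(body) < n) stop("XYZ record 1: fewer atom lines than declared")
    body <- body[seq_len(n)]
  } else {
    body <- lines
  }
  toks <- strsplit(trimws(body), "\\s+")
  if (any(lengths(toks) < 4)) stop("XYZ record 1: need element + 3 coordinates per line")
  el <- vapply(toks, `[[`, character(1), 1)
  .check_element(el, "XYZ record 1")
  xyz <- t(vapply(toks, function(t) as.numeric(t[2:4]), numeric(3)))
  if (anyNA(xyz)) stop("XYZ record 1: non-numeric coordinates")
  mol <- molecule(data.frame(element = el, x = xyz[, 1], y = xyz[, 2],
                             z = xyz[, 3], stringsAsFactors = FALSE),
                  .infer_bonds(el, xyz), id = id)
  list(perceive_aromaticity(mol))
}

.read_smiles_file <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    toks <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    id <- if (length(toks) > 1) toks[2] else paste0("smiles_", k)
    out[[k]] <- tryCatch(parse_smiles(toks[1], id = id),
                         error = function(e) {
                           stop("SMILES record ", k, ": ", conditionMessage(e))
                         })
  }
  out
}

# default valences for implicit-hydrogen filling
.default_valence <- c(B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
                      F = 1, Cl = 1, Br = 1, I = 1, H = 1)

#' Parse a single SMILES string
#'
#' Supports the organic subset (`B C N O P S F Cl Br I` and aromatic
#' `b c n o p s`), branches, ring-closure digits and `%nn`, bond symbols
#' `- = # :`, and simple bracket atoms (element, optional `H` count, charge
#' signs are tolerated and ignored). Implicit hydrogens are appended as
#' explicit H atoms by standard valence rules. Coordinates are left NA.
#'
#' @param smiles SMILES string.
#' @param id Identifier for the molecule.
#' @return A [molecule] without coordinates.
#' @export
parse_smiles <- function(smiles, id = "smiles_mol") {
  chars <- strsplit(smiles, "")[[1]]
  el <- character(0); arom <- logical(0); hfix <- integer(0)
  bi <- integer(0); bj <- integer(0); bo <- integer(0)
  stack <- integer(0); prev <- 0L; pending <- NA_integer_
  rings <- list()  # closure label -> c(atom, pending bond)
  addatom <- function(sym, aromatic, hcount = NA_integer_) {
    el <<- c(el, sym); arom <<- c(arom, aromatic); hfix <<- c(hfix, hcount)
    this <- length(el)
    if (prev > 0) {
      ord <- pending
      if (is.na(ord)) ord <- if (aromatic && arom[prev]) 4L else 1L
      bi <<- c(bi, prev); bj <<- c(bj, this); bo <<- c(bo, ord)
    }
    pending <<- NA_integer_
    prev <<- this
  }
  closering <- function(label) {
    if (!is.null(rings[[label]])) {
      open <- rings[[label]]
      ord <- pending
      if (is.na(ord)) ord <- open[2]
      if (is.na(ord)) ord <- if (arom[prev] && arom[open[1]]) 4L else 1L
      bi <<- c(bi, open[1]); bj <<- c(bj, prev); bo <<- c(bo, ord)
      rings[[label]] <<- NULL
    } else {
      rings[[label]] <<- c(prev, pending)
    }
    pending <<- NA_integer_
  }
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    two <- if (i < n) paste0(ch, chars[i + 1]) else ""
    if (two %in% c("Cl", "Br")) { addatom(two, FALSE); i <- i + 2L; next }
    if (ch %in% c("B", "C", "N", "O", "P", "S", "F", "I")) {
      addatom(ch, FALSE); i <- i + 1L; next
    }
    if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      addatom(toupper(ch), TRUE); i <- i + 1L; next
    }
    if (ch == "[") {
      close_pos <- i + which(chars[(i + 1):n] == "]")[1]
      if (is.na(close_pos)) stop("unterminated bracket atom")
      body <- paste(chars[(i + 1):(close_pos - 1)], collapse = "")
      m <- regmatches(body, regexec("^([0-9]*)([A-Za-z][a-z]?)(H([0-9]*))?([+-]*[0-9]*)$", body))[[1]]
      if (!length(m)) stop("unparseable bracket atom [", body, "]")
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s")
      if (aromatic) sym <- toupper(sym)
      hc <- if (nzchar(m[4])) { if (nzchar(m[5])) as.integer(m[5]) else 1L } else 0L
      addatom(sym, aromatic, hc)
      i <- close_pos + 1L; next
    }
    if (ch == "(") { stack <- c(stack, prev); i <- i + 1L; next }
    if (ch == ")") {
      if (!length(stack)) stop("unbalanced parenthesis")
      prev <- stack[length(stack)]; stack <- stack[-length(stack)]
      i <- i + 1L; next
    }
    if (ch %in% c("-", "/", "\\")) { pending <- 1L; i <- i + 1L; next }
    if (ch == "=") { pending <- 2L; i <- i + 1L; next }
    if (ch == "#") { pending <- 3L; i <- i + 1L; next }
    if (ch == ":") { pending <- 4L; i <- i + 1L; next }
    if (grepl("[0-9]", ch)) { closering(ch); i <- i + 1L; next }
    if (ch == "%") {
      closering(paste(chars[(i + 1):(i + 2)], collapse = "")); i <- i + 3L; next
    }
    if (ch == ".") stop("disconnected SMILES components are not supported")
    stop("unsupported SMILES token '", ch, "'")
  }
  if (length(Filter(Negate(is.null), rings))) stop("unclosed ring bond")
  .check_element(el, "SMILES")
  # implicit hydrogens
  nheavy <- length(el)
  bsum <- numeric(nheavy)
  for (k in seq_along(bi)) {
    o <- if (bo[k] == 4) 1.5 else bo[k]
    bsum[bi[k]] <- bsum[bi[k]] + o
    bsum[bj[k]] <- bsum[bj[k]] + o
  }
  nH <- ifelse(is.na(hfix),
               pmax(0, floor(.default_valence[el] - bsum + 1e-9)),
               hfix)
  for (k in seq_len(nheavy)) {
    if (nH[k] > 0) for (h in seq_len(nH[k])) {
      el <- c(el, "H"); arom <- c(arom, FALSE)
      bi <- c(bi, k); bj <- c(bj, length(el)); bo <- c(bo, 1L)
    }
  }
  mol <- molecule(data.frame(element = el, x = NA_real_, y = NA_real_,
                             z = NA_real_, aromatic = arom,
                             stringsAsFactors = FALSE),
                  data.frame(i = bi, j = bj, order = bo), id = id)
  mol
}

#' Write molecules to an SDF (V2000) file
#'
#' @param mols A molecule or list of molecules (must have coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(mols, path) {
  if (inherits(mols, "molecule")) mols <- list(mols)
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in mols) {
    if (!has_coords(mol)) stop("molecule '", mol$id, "' has no coordinates")
    na <- nrow(mol$atoms); nb <- nrow(mol$bonds)
    writeLines(c(mol$id, "  triqsar", ""), con)
    writeLines(sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb), con)
    writeLines(sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                       mol$atoms$x, mol$atoms$y, mol$atoms$z, mol$atoms$element), con)
    if (nb > 0) {
      writeLines(sprintf("%3d%3d%3d  0", mol$bonds$i, mol$bonds$j,
                         mol$bonds$order), con)
    }
    writeLines(c("M  END", "$$$$"), con)
  }
  invisible(path)
}
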