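# Independent brute-force oracles. These deliberately avoid the package's
# code paths (igraph, svd-based leverages, hat-matrix LOO) so that agreement
# is evidence, not tautology.

# all-pairs shortest path by repeated BFS over an adjacency list
oracle_bfs_distances <- function(n, edges) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  D <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    D[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (u in adj[[v]]) {
        if (is.infinite(D[s, u])) {
          D[s, u] <- D[s, v] + 1
          queue <- c(queue, u)
        }
      }
    }
  }
  D
}

mol_edges <- function(mol) as.matrix(mol$bonds[, c("i", "j")])

# heavy-atom BFS distance matrix for a molecule
oracle_topo <- function(mol, hydrogen_depleted = TRUE) {
  idx <- if (hydrogen_depleted) heavy_indices(mol) else seq_len(nrow(mol$atoms))
  e <- mol$bonds[mol$bonds$i %in% idx & mol$bonds$j %in% idx, c("i", "j")]
  e <- cbind(match(e$i, idx), match(e$j, idx))
  oracle_bfs_distances(length(idx), e)
}

oracle_moran <- function(w, D, lag) {
  A <- length(w); wb <- mean(w)
  num <- 0; cnt <- 0
  for (i in seq_len(A - 1)) for (j in (i + 1):A) {
    if (D[i, j] == lag) {
      num <- num + (w[i] - wb) * (w[j] - wb)
      cnt <- cnt + 1
    }
  }
  if (cnt == 0) return(0)
  (num / cnt) / (sum((w - wb)^2) / A)
}

oracle_rdf <- function(w, xyz, radius, beta) {
  n <- nrow(xyz); v <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    v <- v + w[i] * w[j] * exp(-beta * (radius - r)^2)
  }
  v
}

# leverages via eigendecomposition of M'M (different route than the
# package's SVD of M)
oracle_leverages <- function(xyz) {
  M <- sweep(xyz, 2, colMeans(xyz))
  eg <- eigen(t(M) %*% M, symmetric = TRUE)
  keep <- eg$values > max(eg$values) * 1e-10
  Vi <- eg$vectors[, keep, drop = FALSE]
  H <- M %*% Vi %*% diag(1 / eg$values[keep], sum(keep)) %*% t(Vi) %*% t(M)
  diag(H)
}

oracle_getaway_r <- function(h, xyz, D, w, lag, mode = "sum") {
  n <- length(h); terms <- numeric(0)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (D[i, j] == lag) {
      r <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
      terms <- c(terms, sqrt(h[i] * h[j]) / r * w[i] * w[j])
    }
  }
  if (!length(terms)) return(0)
  if (mode == "sum") sum(terms) else max(terms)
}

# lopping centric index by adjacency-matrix pruning
oracle_lop <- function(n, edges) {
  if (n == 1) return(0)
  adj <- matrix(FALSE, n, n)
  for (k in seq_len(nrow(edges))) {
    adj[edges[k, 1], edges[k, 2]] <- TRUE
    adj[edges[k, 2], edges[k, 1]] <- TRUE
  }
  alive <- rep(TRUE, n)
  counts <- integer(0)
  while (any(alive)) {
    deg <- rowSums(adj[, alive, drop = FALSE]) * alive
    leaves <- which(alive & deg <= 1)
    if (!length(leaves)) {  # pure cycle remainder: one class
      counts <- c(counts, sum(alive))
      break
    }
    counts <- c(counts, length(leaves))
    alive[leaves] <- FALSE
    adj[leaves, ] <- FALSE; adj[, leaves] <- FALSE
  }
  p <- counts / n
  -sum(p * log2(p))
}

# naive leave-one-out: literally delete each row and refit with lm
oracle_loo <- function(table, descriptors, response = "pic50") {
  fml <- stats::as.formula(paste0("`", response, "` ~ ",
                                  paste(sprintf("`%s`", descriptors),
                                        collapse = " + ")))
  n <- nrow(table)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- stats::lm(fml, data = table[-i, , drop = FALSE])
    pred[i] <- stats::predict(fit, newdata = table[i, , drop = FALSE])
  }
  pred
}

# fixed test molecules -------------------------------------------------------

# three heavy atoms in a line, distinct elements so weights differ
mol_chain3 <- function() {
  molecule(data.frame(element = c("C", "N", "O"),
                      x = c(0, 1.5, 3), y = 0, z = 0),
           data.frame(i = c(1, 2), j = c(2, 3), order = 1), id = "chain3")
}

# property table giving scaled weights exactly (1, 2, 3) for (C, N, O)
table_123 <- function() {
  data.frame(element = c("C", "N", "O"),
             mass = c(12, 24, 36),
             sanderson_en = c(1, 2, 3),
             vdw_volume = c(5, 10, 15))
}

# flat hexagonal benzene skeleton (heavy atoms only), aromatic flags set
mol_benzene <- function() {
  ang <- (0:5) * pi / 3
  m <- molecule(data.frame(element = "C", x = 1.39 * cos(ang),
                           y = 1.39 * sin(ang), z = 0, aromatic = TRUE),
                data.frame(i = 1:6, j = c(2:6, 1), order = 4), id = "benzene")
  m
}

random_rigid_motion <- function(xyz, seed) {
  set.seed(seed)
  A <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(A))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  t(Q %*% t(xyz)) + matrix(rnorm(3, sd = 5), nrow(xyz), 3, byrow = TRUE)
}

apply_motion <- function(mol, seed) {
  xyz <- random_rigid_motion(as.matrix(mol$atoms[, c("x", "y", "z")]), seed)
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

# agreement to `digits` significant digits. `floor` sets the smallest scale
# the comparison is relative to: positive-sum descriptors (RDF, GETAWAY,
# Lop) use a tiny floor, while Moran -- a normalized index whose numerator
# is a near-cancelling sum, so no two summation orders can agree to 12
# digits OF THE RESULT when the result itself is cancellation residue --
# is compared on its natural O(1) scale (floor = 1), i.e. to 12 decimals.
expect_rel_equal <- function(actual, expected, digits = 12, floor = 1e-10) {
  scale <- pmax(abs(expected), floor)
  expect_lt(max(abs(actual - expected) / scale), 10^(-digits) * 5)
}

# shared toy-molecule pool (generated once per test run)
toy_pool <- local({
  pool <- NULL
  function(n = 100, seed = 421L) {
    if (is.null(pool) || length(pool) < n) {
      pool <<- generate_toy_molecules(n, seed = seed)
    }
    pool[seq_len(n)]
  }
})
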