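#' Specification for a synthetic descriptor-activity table
#'
#' Describes a linear-model world of the same shape as the real modeling
#' tables: `n` compounds, named informative coefficients over descriptor
#' columns, Gaussian noise of standard deviation `sigma`, and per-column
#' uniform sampling ranges mimicking the scales of the real descriptor
#' table (defaults: informative columns on the `MATS8v`-like scale
#' [0.02, 0.4], noise columns standard uniform). Generation is reproducible
#' from (spec, seed): the RNG stream is keyed by a hash of the serialized
#' spec XOR the seed, so adding fields re-keys rather than silently shifting
#' existing streams.
#'
#' Default coefficients (4.4 per informative column over a [0.02, 0.4]
#' range, i.e. a contribution standard deviation of about 0.48 in response
#' units against noise sigma 0.4) and the informative-pair correlation
#' `rho = 0.5` are calibrated once to the training performance band of the
#' reference models (R_Tr about 0.75-0.96): each published model's two
#' descriptors share an atomic weighting scheme and are correlated in real
#' descriptor tables, and without that correlation a marginal |r| >= 0.6
#' screen could not retain two equally informative independent columns (the
#' marginal correlation of each is capped at 1/sqrt(2)). See the methods
#' vignette.
#'
#' @param n Number of rows (>= 3).
#' @param coefficients Named numeric vector of informative coefficients
#'   (names become column names).
#' @param intercept Model intercept B0.
#' @param sigma Noise standard deviation (>= 0).
#' @param n_noise Number of pure-noise descriptor columns.
#' @param rho Gaussian-copula correlation among the informative columns
#'   (0 = independent; only used when there are >= 2 informative columns).
#' @param ranges Optional named list of c(lo, hi) sampling ranges per column.
#' @param seed Integer seed.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n = 24,
                           coefficients = c(X1 = 4.4, X2 = 4.4),
                           intercept = -1.8, sigma = 0.4, n_noise = 8,
                           rho = 0.5, ranges = NULL, seed = 1L) {
  stopifnot(n >= 3, sigma >= 0, n_noise >= 0, length(coefficients) >= 0,
            rho >= 0, rho < 1)
  if (is.null(names(coefficients)) && length(coefficients)) {
    names(coefficients) <- paste0("X", seq_along(coefficients))
  }
  cols <- c(names(coefficients),
            if (n_noise > 0) paste0("noise", seq_len(n_noise)))
  if (is.null(ranges)) {
    ranges <- stats::setNames(rep(list(c(0.02, 0.4)), length(names(coefficients))),
                              names(coefficients))
  }
  for (nm in setdiff(cols, names(ranges))) ranges[[nm]] <- c(0, 1)
  bad <- vapply(ranges, function(r) length(r) != 2 || r[1] >= r[2], logical(1))
  if (any(bad)) stop("invalid range(s) for: ",
                     paste(names(ranges)[bad], collapse = ", "))
  structure(list(n = as.integer(n), coefficients = coefficients,
                 intercept = intercept, sigma = sigma,
                 n_noise = as.integer(n_noise), rho = rho, columns = cols,
                 ranges = ranges, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# FNV-style 31-bit string hash (stable across sessions)
.fnv1a <- function(s) {
  h <- 216613626
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(b))
    h <- (h * 16777619) %% 2147483647
  }
  as.integer(h)
}

.spec_stream_seed <- function(spec, offset = 0L) {
  key <- paste(deparse(spec[setdiff(names(spec), "seed")]), collapse = "")
  mixed <- (spec$seed * 2654435761) %% 2147483647
  (bitwXor(.fnv1a(key), as.integer(mixed)) + offset) %% 2147483629
}

#' Generate a synthetic linear descriptor-activity table
#'
#' Draws descriptor columns from their declared ranges (uniform marginals;
#' informative columns share a Gaussian copula with correlation `rho`) and
#' the response as `Y = B0 + sum(Bn * Xn) + eps`, `eps ~ N(0, sigma)`.
#'
#' @param spec A [synthetic_spec].
#' @return data.frame with `compound_id`, descriptor columns and `pic50`;
#'   attributes `truth` (list of intercept, coefficients, sigma, support)
#'   record the generating model.
#' @export
generate_linear_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  .with_seed(.spec_stream_seed(spec), {
    info <- names(spec$coefficients)
    X <- vapply(spec$columns, function(nm) {
      r <- spec$ranges[[nm]]
      stats::runif(spec$n, r[1], r[2])
    }, numeric(spec$n))
    X <- matrix(X, nrow = spec$n,
                dimnames = list(NULL, spec$columns))
    if (length(info) >= 2 && spec$rho > 0) {
      # Gaussian copula: correlated normals -> uniform marginals in range
      z0 <- stats::rnorm(spec$n)
      for (nm in info) {
        z <- sqrt(spec$rho) * z0 + sqrt(1 - spec$rho) * stats::rnorm(spec$n)
        r <- spec$ranges[[nm]]
        X[, nm] <- r[1] + (r[2] - r[1]) * stats::pnorm(z)
      }
    }
    beta <- stats::setNames(numeric(length(spec$columns)), spec$columns)
    beta[names(spec$coefficients)] <- spec$coefficients
    y <- spec$intercept + as.vector(X %*% beta) +
      stats::rnorm(spec$n, sd = spec$sigma)
    out <- cbind(data.frame(compound_id = sprintf("S%03d", seq_len(spec$n))),
                 as.data.frame(X), data.frame(pic50 = y))
    attr(out, "truth") <- list(intercept = spec$intercept,
                               coefficients = spec$coefficients,
                               sigma = spec$sigma,
                               support = names(spec$coefficients))
    out
  })
}

#' Generate random small test molecules
#'
#' Random connected heavy-atom structures (3-12 atoms over C/N/O/S/F):
#' uniform random trees with an optional ring-closing edge, embedded to 3D
#' with the deterministic embedder. These exercise every descriptor without
#' real chemistry; they are synthetic test articles, not drug-like
#' molecules.
#'
#' @param count Number of molecules (>= 1).
#' @param seed Integer seed.
#' @param min_atoms,max_atoms Heavy-atom count range.
#' @return List of [molecule] objects with coordinates.
#' @export
generate_toy_molecules <- function(count, seed = 1L, min_atoms = 3,
                                   max_atoms = 12) {
  stopifnot(count >= 1, min_atoms >= 2, max_atoms >= min_atoms)
  elements <- c("C", "C", "C", "N", "O", "S", "F")  # carbon-biased
  .with_seed(seed, {
    lapply(seq_len(count), function(k) {
      n <- sample(min_atoms:max_atoms, 1)
      el <- sample(elements, n, replace = TRUE)
      # fluorine is terminal; keep interior positions heavier
      el[1] <- "C"
      parent <- c(NA, vapply(2:n, function(i) {
        cand <- which(el[seq_len(i - 1)] != "F")
        cand[sample.int(length(cand), 1)]
      }, integer(1)))
      bonds <- data.frame(i = parent[-1], j = 2:n, order = 1L)
      # close one ring on ~half of molecules with enough non-terminal atoms
      if (n >= 5 && stats::runif(1) < 0.5) {
        nonF <- which(el != "F")
        pair <- sample(nonF, 2)
        already <- any((bonds$i == min(pair) & bonds$j == max(pair)) |
                         (bonds$i == max(pair) & bonds$j == min(pair)))
        if (!already) {
          bonds <- rbind(bonds, data.frame(i = pair[1], j = pair[2], order = 1L))
        }
      }
      mol <- molecule(data.frame(element = el, x = NA_real_, y = NA_real_,
                                 z = NA_real_, stringsAsFactors = FALSE),
                      bonds, id = sprintf("toy_%03d", k))
      embed_coordinates(mol, seed = seed + k)
    })
  })
}
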