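# descriptor engine: hand-derived examples, brute-force equivalence,
# invariance properties

test_that("Moran autocorrelation: hand-derived chain values and conventions", {
  m <- mol_chain3()          # scaled weights (1, 2, 3) under table_123
  tab <- table_123()
  expect_equal(moran_autocorrelation(m, 1, "e", tab), 0)
  expect_equal(moran_autocorrelation(m, 2, "e", tab), -1.5)
  expect_warning(v <- moran_autocorrelation(m, 9, "e", tab), "no atom pairs")
  expect_equal(v, 0)
  expect_error(moran_autocorrelation(m, 0, "e", tab), "positive integer")
  allc <- molecule(data.frame(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0),
                   data.frame(i = 1, j = 2, order = 1))
  expect_error(moran_autocorrelation(allc, 1, "m"), "zero weight variance")
})

test_that("Moran index is invariant to affine weight transforms", {
  for (mol in toy_pool(25)) {
    D <- topological_distances(mol)
    w <- scaled_weights(mol, "m", indices = heavy_indices(mol))
    if (stats::sd(w) < 1e-12) next
    for (lag in 1:3) {
      if (!any(D[upper.tri(D)] == lag)) next
      base <- moran_autocorrelation(mol, lag, weights = w)
      expect_equal(moran_autocorrelation(mol, lag, weights = 3.7 * w - 1.2),
                   base, tolerance = 1e-12)
      expect_equal(moran_autocorrelation(mol, lag, weights = -0.4 * w + 9),
                   base, tolerance = 1e-12)
    }
  }
})

test_that("RDF: closed forms, parameter guards", {
  d2 <- molecule(data.frame(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0),
                 data.frame(i = 1, j = 2, order = 1))
  expect_equal(rdf_descriptor(d2, 1.5, "m", beta = 100), 1.0)
  expect_equal(rdf_descriptor(d2, 1.5, "m", beta = 7), 1.0)   # beta-free at r = R
  expect_equal(rdf_descriptor(d2, 2.0, "m", beta = 100), exp(-25))
  expect_error(rdf_descriptor(d2, 1.5, "m", beta = -1), "beta")
  expect_error(rdf_descriptor(d2, -2, "m"), "radius")
})

test_that("RDF positivity and locality", {
  for (mol in toy_pool(15)) {
    expect_gt(rdf_descriptor(mol, 3.0, "m"), 0)
    # probe >= 5/sqrt(beta) beyond the largest pair distance: essentially zero
    dmax <- max(stats::dist(as.matrix(mol$atoms[, c("x", "y", "z")])))
    far <- rdf_descriptor(mol, dmax + 5 / sqrt(100) + 0.5, "m", beta = 100)
    expect_lt(far, 1e-8)
  }
})

test_that("GETAWAY context: leverage conservation and hand values", {
  d2 <- molecule(data.frame(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0),
                 data.frame(i = 1, j = 2, order = 1))
  ctx <- getaway_context(d2)
  expect_equal(ctx$leverage, c(0.5, 0.5))   # x_i^2 / sum x^2, centered diatomic
  expect_equal(ctx$rank, 1)
  expect_equal(sum(ctx$leverage), ctx$rank)

  for (mol in toy_pool(25)) {
    ctx <- getaway_context(mol)
    expect_true(ctx$rank %in% 1:3)
    expect_equal(sum(ctx$leverage), ctx$rank, tolerance = 1e-10)
    expect_true(all(ctx$leverage >= -1e-12 & ctx$leverage <= 1 + 1e-12))
  }

  pt <- molecule(data.frame(element = c("C", "C"), x = 1, y = 2, z = 3),
                 data.frame(i = 1, j = 2, order = 1))
  expect_error(getaway_context(pt), "coincident")
})

test_that("GETAWAY R-index: closed form, dominance, weight-length guard", {
  d2 <- molecule(data.frame(element = c("C", "C"), x = c(0, 1.5), y = 0, z = 0),
                 data.frame(i = 1, j = 2, order = 1))
  ctx <- getaway_context(d2)
  expect_equal(getaway_r_autocorrelation(ctx, c(1, 1), 1, "sum"),
               sqrt(0.25) / 1.5)
  expect_error(getaway_r_autocorrelation(ctx, c(1, 1, 1), 1), "length")
  expect_error(getaway_r_autocorrelation(ctx, c(1, 1), 0), "positive integer")

  for (mol in toy_pool(20)) {
    ctx <- getaway_context(mol)
    w <- scaled_weights(mol, "m")
    for (lag in 1:max(ctx$topo_dist)) {
      if (!any(ctx$topo_dist[upper.tri(ctx$topo_dist)] == lag)) next
      s <- getaway_r_autocorrelation(ctx, w, lag, "sum")
      mx <- getaway_r_autocorrelation(ctx, w, lag, "max")
      expect_lte(mx, s + 1e-15)
    }
  }
})

test_that("RDF and GETAWAY are invariant under rigid motion (10 sig digits)", {
  for (k in 1:10) {
    mol <- toy_pool(10)[[k]]
    moved <- apply_motion(mol, seed = 900 + k)
    expect_rel_equal(rdf_descriptor(moved, 3.0, "m"),
                     rdf_descriptor(mol, 3.0, "m"), digits = 10)
    ctx <- getaway_context(mol); ctx2 <- getaway_context(moved)
    expect_rel_equal(ctx2$leverage, ctx$leverage, digits = 10)
    w <- scaled_weights(mol, "m")
    lag <- 2
    if (any(ctx$topo_dist[upper.tri(ctx$topo_dist)] == lag)) {
      expect_rel_equal(getaway_r_autocorrelation(ctx2, w, lag, "sum"),
                       getaway_r_autocorrelation(ctx, w, lag, "sum"),
                       digits = 10)
    }
  }
})

test_that("lopping centric index: hand values and pruning conventions", {
  single <- molecule(data.frame(element = "C", x = 0, y = 0, z = 0))
  expect_equal(lopping_centric_index(single), 0)
  # 3-chain: partition {2, 1} -> 0.9183
  expect_equal(round(lopping_centric_index(mol_chain3()), 4), 0.9183)
  # pure cycle: removed in a single step -> one class -> 0
  expect_equal(lopping_centric_index(mol_benzene()), 0)
})

test_that("aromatic ester counting follows the acyl-side rule", {
  mb <- parse_smiles("O=C(OC)c1ccccc1", "methyl_benzoate")
  expect_equal(count_aromatic_esters(mb), 1)
  pa <- parse_smiles("CC(=O)Oc1ccccc1", "phenyl_acetate")
  expect_equal(count_aromatic_esters(pa), 0)
  hex <- parse_smiles("CCCCCC", "hexane")
  expect_equal(count_aromatic_esters(hex), 0)
  # two aromatic esters count twice; phenyl benzoate (aromatic both sides)
  # still counts once
  dimb <- parse_smiles("O=C(OC)c1ccc(C(=O)OC)cc1", "dimethyl_terephthalate")
  expect_equal(count_aromatic_esters(dimb), 2)
  pb <- parse_smiles("O=C(Oc1ccccc1)c1ccccc1", "phenyl_benzoate")
  expect_equal(count_aromatic_esters(pb), 1)
  # benzoic acid is not an ester
  ba <- parse_smiles("OC(=O)c1ccccc1", "benzoic_acid")
  expect_equal(count_aromatic_esters(ba), 0)
})

test_that("compute_descriptors composes, flags conventions, passes supplied", {
  bz <- embed_coordinates(parse_smiles("c1ccccc1", "benzene"), seed = 5)
  v <- compute_descriptors(bz)
  expect_true(all(is.finite(as.numeric(v))))
  expect_equal(unname(v["nArCOOR"]), 0)
  expect_equal(unname(v["Lop"]), 0)
  prov <- attr(v, "provenance")
  # all-carbon skeleton: Moran degenerate, flagged not fatal
  expect_equal(unname(prov["MATS7m"]), "computed:degenerate")

  # small molecule: lags 7/8 beyond diameter -> 0, flagged
  small <- embed_coordinates(parse_smiles("CCO", "ethanol"), seed = 2)
  vs <- compute_descriptors(small)
  expect_equal(unname(vs["MATS8v"]), 0)
  expect_equal(unname(attr(vs, "provenance")["MATS8v"]), "computed:no-pairs")

  sup <- c(`R5e+` = 0.022, nArCOOR = 1, RDF105m = 10, MATS7m = 0.01,
           MATS8v = 0.1, Lop = 0.9, R7m = 0.5)
  vsup <- compute_descriptors(supplied = sup)
  expect_equal(as.numeric(vsup), unname(sup[descriptor_names()]))
  expect_true(all(attr(vsup, "provenance") == "supplied"))
  expect_error(compute_descriptors(supplied = sup[-2]), "nArCOOR")
})

test_that("descriptor engine matches brute-force oracles on random molecules", {
  # deeper 100-molecule sweep lives in test-acceptance.R; this is the
  # fast per-module check
  for (mol in toy_pool(25)) {
    idxH <- heavy_indices(mol)
    Dh <- topological_distances(mol, TRUE)
    wm <- scaled_weights(mol, "m", indices = idxH)
    if (stats::sd(wm) > 1e-12) {
      for (lag in 1:3) {
        got <- withCallingHandlers(
          moran_autocorrelation(mol, lag, "m"),
          warning = function(w) invokeRestart("muffleWarning"))
        expect_rel_equal(got, oracle_moran(wm, Dh, lag), floor = 1)
      }
    }
    xyz <- as.matrix(mol$atoms[, c("x", "y", "z")])
    wall <- scaled_weights(mol, "m")
    expect_rel_equal(rdf_descriptor(mol, 2.5, "m"),
                     oracle_rdf(wall, xyz, 2.5, 100))
    ctx <- getaway_context(mol)
    expect_rel_equal(ctx$leverage, oracle_leverages(xyz))
    D <- ctx$topo_dist
    for (lag in 1:2) {
      for (md in c("sum", "max")) {
        got <- withCallingHandlers(
          getaway_r_autocorrelation(ctx, wall, lag, md),
          warning = function(w) invokeRestart("muffleWarning"))
        expect_rel_equal(got, oracle_getaway_r(ctx$leverage, xyz, D, wall,
                                               lag, md))
      }
    }
    expect_rel_equal(lopping_centric_index(mol),
                     oracle_lop(length(idxH),
                                cbind(match(mol$bonds$i, idxH),
                                      match(mol$bonds$j, idxH))))
  }
})
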