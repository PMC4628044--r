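# feature selection, MLR fitting, LOO-CV, metrics, published models, ranking

test_that("correlation filter: retention rules and boundary", {
  set.seed(31)
  n <- 100
  y <- rnorm(n)
  d <- data.frame(pic50 = y, self = y, noise = rnorm(n), flat = 1)
  expect_warning(tr <- correlation_filter(d), "constant")
  sv <- tr$survivors
  expect_true(sv$retained[sv$descriptor == "self"])
  expect_equal(sv$r[sv$descriptor == "self"], 1)
  expect_false(sv$retained[sv$descriptor == "noise"])
  expect_lt(abs(sv$r[sv$descriptor == "noise"]), 0.3)

  # |r| exactly at the threshold is retained (>= rule)
  u <- c(1, -1, 0, 0) / sqrt(2); v <- c(0, 0, 1, -1) / sqrt(2)
  d2 <- data.frame(pic50 = u, x = 0.6 * u + 0.8 * v)
  tr2 <- correlation_filter(d2, threshold = 0.6)
  expect_true(tr2$survivors$retained[1])
  expect_equal(tr2$survivors$r[1], 0.6, tolerance = 1e-12)

  expect_error(correlation_filter(d[1:2, ]), "3 rows")
  expect_error(correlation_filter(data.frame(x = 1:5)), "response")
})

test_that("stepwise selection: ground-truth recovery, empty case, collinearity", {
  # one informative descriptor (beta = 1, sigma = 0.1, n = 30, 4 noise)
  spec <- synthetic_spec(n = 30, coefficients = c(X1 = 1), intercept = 0,
                         sigma = 0.1, n_noise = 4, rho = 0,
                         ranges = list(X1 = c(0, 1)), seed = 1)
  d <- generate_linear_dataset(spec)
  tr <- stepwise_mlr_select(d)
  expect_identical(tr$selected, "X1")
  expect_identical(tr$log$action[1], "enter")

  # pure-noise response: nothing passes p_enter, trace still valid
  set.seed(99)
  d0 <- data.frame(pic50 = rnorm(30), a = rnorm(30), b = rnorm(30))
  tr0 <- stepwise_mlr_select(d0)
  expect_length(tr0$selected, 0)
  expect_s3_class(tr0, "selection_trace")

  # perfectly collinear duplicate: exactly one of the pair, first by order
  d$X1_copy <- d$X1
  tr2 <- stepwise_mlr_select(d, candidates = c("X1", "X1_copy"))
  expect_identical(tr2$selected, "X1")

  expect_error(stepwise_mlr_select(d, p_enter = 0.2, p_remove = 0.1),
               "below p_remove")
})

test_that("stepwise soundness: final p-values below p_remove, trace replays", {
  for (s in 1:10) {
    d <- generate_linear_dataset(synthetic_spec(seed = s))
    tr <- stepwise_mlr_select(d)
    if (!length(tr$selected)) next
    fit <- summary(lm(reformulate(sprintf("`%s`", tr$selected), "pic50"),
                      data = d))$coefficients
    pvals <- fit[-1, 4]
    expect_true(all(pvals < 0.10))
    # replaying the logged enter/remove actions reproduces the selection
    replay <- character(0)
    for (k in seq_len(nrow(tr$log))) {
      if (tr$log$action[k] == "enter") replay <- c(replay, tr$log$descriptor[k])
      if (tr$log$action[k] == "remove") replay <- setdiff(replay, tr$log$descriptor[k])
    }
    expect_setequal(replay, tr$selected)
    # determinism
    expect_identical(stepwise_mlr_select(d)$selected, tr$selected)
  }
})

test_that("fit_mlr: exact data, guards, self-consistency of predictions", {
  d <- data.frame(x = 1:10, pic50 = 2 * (1:10) - 3)
  res <- fit_mlr(d, "x")
  expect_equal(res$model$intercept, -3, tolerance = 1e-10)
  expect_equal(unname(res$model$coefficients["x"]), 2, tolerance = 1e-10)
  expect_equal(res$report$RMSE_Tr, 0, tolerance = 1e-10)
  expect_equal(res$report$R_Tr, 1, tolerance = 1e-10)

  # predict() on each row reproduces the stored fitted values
  d2 <- generate_linear_dataset(synthetic_spec(seed = 4))
  res2 <- fit_mlr(d2, c("X1", "X2"))
  manual <- predict(res2$model, d2[, c("X1", "X2")])
  expect_equal(manual, res2$report$fitted, tolerance = 1e-12)

  expect_error(fit_mlr(d2[1:3, ], c("X1", "X2", "noise1")), "at least")
  d2$dup <- d2$X1
  expect_error(fit_mlr(d2, c("X1", "dup")), "dup")
  expect_error(predict(res2$model, c(X1 = 1)), "X2")
})

test_that("fit_mlr parameter recovery: 500 replicates, mean within 3 SE", {
  est <- matrix(NA_real_, 500, 3)
  for (s in 1:500) {
    d <- generate_linear_dataset(synthetic_spec(n = 24, n_noise = 0, seed = s))
    truth <- attr(d, "truth")
    fit <- fit_mlr(d, names(truth$coefficients))
    est[s, ] <- c(fit$model$intercept, fit$model$coefficients)
  }
  truth_vec <- c(-1.8, 4.4, 4.4)
  se <- apply(est, 2, sd) / sqrt(nrow(est))
  expect_true(all(abs(colMeans(est) - truth_vec) < 3 * se))
})

test_that("LOO-CV: noiseless data, determinism, reference RMSE", {
  d <- data.frame(x = 1:12, pic50 = 0.5 * (1:12) + 1)
  rep0 <- loo_cross_validate(d, "x")
  expect_equal(unname(rep0$R_CV), 1, tolerance = 1e-10)
  expect_equal(unname(rep0$RMSE_CV), 0, tolerance = 1e-10)

  d2 <- generate_linear_dataset(synthetic_spec(seed = 10))
  r1 <- loo_cross_validate(d2, c("X1", "X2"))
  r2 <- loo_cross_validate(d2, c("X1", "X2"))
  expect_identical(r1$loo_predicted, r2$loo_predicted)   # bitwise

  # equivalence with the naive delete-and-refit oracle (deep 50-table sweep
  # in test-acceptance.R)
  for (s in 1:8) {
    d3 <- generate_linear_dataset(synthetic_spec(n = 15, seed = 100 + s))
    got <- loo_cross_validate(d3, c("X1", "X2"))$loo_predicted
    expect_equal(got, oracle_loo(d3, c("X1", "X2")), tolerance = 1e-10)
  }
})

test_that("regression metrics reproduce the reference CV statistics", {
  fx <- reference_fixture()
  pp <- function(cl) fx$pic50_pairs[fx$pic50_pairs$cell_line == cl, ]
  hu <- regression_metrics(pp("HuCCA-1")$pic50_exp, pp("HuCCA-1")$pic50_pred)
  expect_equal(unname(hu["R"]), 0.8957, tolerance = 1e-3)
  expect_equal(unname(hu["RMSE"]), 0.2562, tolerance = 1e-3)
  mo <- regression_metrics(pp("MOLT-3")$pic50_exp, pp("MOLT-3")$pic50_pred)
  expect_equal(unname(mo["RMSE"]), 0.2070, tolerance = 1e-3)

  expect_equal(unname(regression_metrics(1:5, 1:5)), c(1, 0))
})

test_that("metrics invariances and guards", {
  set.seed(7)
  o <- rnorm(20); p <- o + rnorm(20, sd = 0.3)
  m1 <- regression_metrics(o, p)
  perm <- sample(20)
  expect_equal(regression_metrics(o[perm], p[perm])["RMSE"], m1["RMSE"])
  # R invariant to positive affine transform of predictions
  expect_equal(regression_metrics(o, 2.5 * p + 1)["R"], m1["R"],
               tolerance = 1e-12)
  expect_error(regression_metrics(rep(1, 5), rnorm(5)), "constant")
  expect_equal(unname(regression_metrics(rep(1, 5), rep(1.1, 5),
                                         rmse_only = TRUE)), 0.1,
               tolerance = 1e-12)
  expect_error(regression_metrics(1:3, 1:4), "mismatch")
})

test_that("published models carry the reference coefficients and structure", {
  ms <- published_models()
  expect_named(ms, cell_lines())
  expect_equal(unname(ms[["HuCCA-1"]]$coefficients["R5e+"]), -84.0157)
  expect_equal(unname(ms[["HuCCA-1"]]$coefficients["nArCOOR"]), 1.0288)
  expect_equal(ms[["HuCCA-1"]]$intercept, 0.8738)
  expect_equal(ms[["HepG2"]]$intercept, -1.7524)
  expect_match(ms[["HepG2"]]$notes, "sign")
  expect_equal(unname(ms[["MOLT-3"]]$coefficients),
               c(1.0649, 10.3977))
  for (m in ms) {
    expect_length(m$coefficients, 2)
    expect_identical(m$source, "published")
  }
  st <- attr(ms[["A549"]], "stats")
  expect_equal(unname(st["N"]), 16)
  expect_equal(unname(st["RMSE_CV"]), 0.4211)
})

test_that("published-equation predictions reproduce the printed worked values", {
  ms <- published_models()
  expect_equal(round(predict(ms[["HuCCA-1"]], c(`R5e+` = 0.057, nArCOOR = 0)), 3),
               -3.915)   # ketone 7D
  expect_equal(round(predict(ms[["HuCCA-1"]], c(`R5e+` = 0.022, nArCOOR = 1)), 3),
               0.054)    # ester 8N
  expect_equal(round(predict(ms[["MOLT-3"]], c(Lop = 0.983, R7m = 0.537)), 3),
               0.947)    # ester 8Q
})

test_that("candidate ranking matches the reference ordering", {
  fx <- reference_fixture()
  ranked <- rank_candidates(fx$printed_predictions[, c("compound_id",
                                                       "cell_line", "pic50")])
  top <- function(cl, k = 1) {
    r <- ranked[ranked$cell_line == cl, ]
    r$compound_id[r$rank == k]
  }
  expect_equal(top("HuCCA-1"), "8N")         # most potent modified compound
  expect_equal(top("HepG2", 1), "1P")
  expect_equal(top("HepG2", 2), "7F")
  expect_equal(top("MOLT-3", 1), "8Q")
  # class labels ride along
  r8n <- ranked[ranked$compound_id == "8N" & ranked$cell_line == "HuCCA-1", ]
  expect_equal(r8n$predicted_class, "highly active")

  single <- rank_candidates(data.frame(compound_id = "z", cell_line = "A549",
                                       pic50 = -0.5))
  expect_equal(single$rank, 1)
  # ties break by ascending compound id
  tie <- rank_candidates(data.frame(compound_id = c("b", "a"),
                                    cell_line = "A549", pic50 = c(0.3, 0.3)))
  expect_identical(tie$compound_id, c("a", "b"))
  expect_error(rank_candidates(data.frame(compound_id = character(0),
                                          cell_line = character(0),
                                          pic50 = numeric(0))), "no predictions")
})

test_that("model JSON round trip", {
  m <- published_models("MOLT-3")
  f <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, f)
  back <- read_model_json(f)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$intercept, m$intercept)
  expect_identical(back$source, "published")
})
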