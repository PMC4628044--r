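#' Univariate correlation filter
#'
#' First stage of feature selection: keep descriptors whose absolute Pearson
#' correlation with the response is at least `threshold` (default 0.6; a
#' value exactly at the threshold is retained). Constant columns cannot be
#' correlated and are dropped with a warning.
#'
#' @param table data.frame with a response column and candidate descriptor
#'   columns (any `compound_id` column is ignored).
#' @param threshold Absolute-correlation cutoff in (0, 1).
#' @param response Response column name, default `"pic50"`.
#' @return A `selection_trace` list: `survivors` (data.frame of descriptor,
#'   r, retained), `selected` (character vector), `threshold`.
#' @export
correlation_filter <- function(table, threshold = 0.6, response = "pic50") {
  if (!response %in% names(table)) stop("response column '", response, "' absent")
  if (nrow(table) < 3) stop("need at least 3 rows for a correlation filter")
  cand <- setdiff(names(table), c(response, "compound_id"))
  y <- table[[response]]
  rows <- lapply(cand, function(nm) {
    x <- table[[nm]]
    if (!is.numeric(x)) return(NULL)
    if (stats::sd(x) < 1e-12) {
      warning("dropping constant descriptor column '", nm, "'")
      return(data.frame(descriptor = nm, r = NA_real_, retained = FALSE))
    }
    r <- stats::cor(x, y)
    # >= boundary, with an epsilon so an exact-threshold correlation is
    # not lost to floating-point round-off
    data.frame(descriptor = nm, r = r, retained = abs(r) >= threshold - 1e-12)
  })
  survivors <- do.call(rbind, rows)
  structure(list(survivors = survivors,
                 selected = survivors$descriptor[survivors$retained %in% TRUE],
                 threshold = threshold),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  cat("<selection_trace>\n")
  if (!is.null(x$survivors)) print(x$survivors, row.names = FALSE)
  if (!is.null(x$log)) print(x$log, row.names = FALSE)
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

# partial F p-value for adding `cand` to the model on `current`
.partial_f <- function(table, response, current, cand) {
  n <- nrow(table)
  f0 <- stats::lm(.model_formula(response, current), data = table)
  f1 <- stats::lm(.model_formula(response, c(current, cand)), data = table)
  if (anyNA(stats::coef(f1))) return(c(F = NA_real_, p = NA_real_))
  rss0 <- sum(stats::residuals(f0)^2)
  rss1 <- sum(stats::residuals(f1)^2)
  df2 <- n - length(current) - 2
  if (df2 < 1 || rss1 < 1e-300) return(c(F = Inf, p = 0))
  Fst <- (rss0 - rss1) / (rss1 / df2)
  c(F = Fst, p = stats::pf(Fst, 1, df2, lower.tail = FALSE))
}

.model_formula <- function(response, terms) {
  rhs <- if (length(terms)) paste(sprintf("`%s`", terms), collapse = " + ") else "1"
  stats::as.formula(paste(sprintf("`%s`", response), "~", rhs))
}

#' Stepwise MLR feature selection
#'
#' Forward entry of the candidate with the smallest partial-F p-value at or
#' below `p_enter`, followed by backward removal of any included descriptor
#' whose partial p-value reaches `p_remove`, iterated to stability. Ties
#' break by candidate column order. A candidate whose entry would leave the
#' model with as many parameters as rows, or that is perfectly collinear
#' with the current model, is refused (logged). Defaults match the common
#' statistical-package convention (enter 0.05, remove 0.10).
#'
#' @param table data.frame with response and candidate columns.
#' @param p_enter Entry p-value threshold.
#' @param p_remove Removal p-value threshold (must exceed `p_enter`).
#' @param response Response column name.
#' @param candidates Candidate names, default all numeric non-response columns.
#' @return A `selection_trace` with `log` (step, action, descriptor, F, p)
#'   and `selected`.
#' @export
stepwise_mlr_select <- function(table, p_enter = 0.05, p_remove = 0.10,
                                response = "pic50", candidates = NULL) {
  if (!response %in% names(table)) stop("response column '", response, "' absent")
  if (p_enter >= p_remove) stop("p_enter must be below p_remove")
  if (is.null(candidates)) {
    candidates <- setdiff(names(table), c(response, "compound_id"))
    candidates <- candidates[vapply(table[candidates], is.numeric, logical(1))]
  }
  n <- nrow(table)
  current <- character(0)
  log <- list()
  note <- function(action, d, F = NA, p = NA) {
    log[[length(log) + 1]] <<- data.frame(step = length(log) + 1,
                                          action = action, descriptor = d,
                                          F = F, p = p)
  }
  repeat {
    changed <- FALSE
    # forward
    pool <- setdiff(candidates, current)
    if (length(pool)) {
      if (n - length(current) - 2 < 1) {
        note("refuse", paste(pool, collapse = ","))
      } else {
        stats <- vapply(pool, function(d) .partial_f(table, response, current, d),
                        numeric(2))
        ps <- stats["p", ]
        ok <- which(is.finite(ps) & ps <= p_enter)
        if (length(ok)) {
          best <- ok[which.min(ps[ok])]  # ties: first in column order
          current <- c(current, pool[best])
          note("enter", pool[best], stats["F", best], ps[best])
          changed <- TRUE
        }
      }
    }
    # backward
    if (length(current) > 0) {
      fit <- stats::lm(.model_formula(response, current), data = table)
      sm <- summary(fit)$coefficients
      pv <- stats::setNames(rep(NA_real_, length(current)), current)
      keyed <- intersect(sprintf("`%s`", current), rownames(sm))
      pv[gsub("`", "", keyed)] <- sm[keyed, 4]
      plain <- intersect(current, rownames(sm))
      pv[plain] <- sm[plain, 4]
      worst <- which.max(pv)
      if (length(worst) && is.finite(pv[worst]) && pv[worst] >= p_remove) {
        note("remove", current[worst], NA, pv[worst])
        current <- setdiff(current, current[worst])
        changed <- TRUE
      }
    }
    if (!changed || length(log) > 200) break
  }
  structure(list(log = if (length(log)) do.call(rbind, log) else
                   data.frame(step = integer(0), action = character(0),
                              descriptor = character(0), F = numeric(0),
                              p = numeric(0)),
                 selected = current,
                 p_enter = p_enter, p_remove = p_remove),
            class = "selection_trace")
}

#' Fit an ordinary least squares QSAR model
#'
#' Fits `Y = B0 + sum(Bn * Xn)` by OLS and reports training statistics:
#' `R_Tr` is the Pearson correlation between fitted and observed values and
#' `RMSE_Tr = sqrt(sum((y - yhat)^2) / N)` (denominator N, matching the
#' reference reporting convention).
#'
#' @param table Modeling table.
#' @param descriptors Selected descriptor names.
#' @param response Response column name.
#' @param cell_line Optional label stored on the model.
#' @return List with `model` (a `qsar_model`) and `report` (a
#'   `validation_report` with the training part filled in).
#' @export
fit_mlr <- function(table, descriptors, response = "pic50", cell_line = NA) {
  n <- nrow(table)
  if (n < length(descriptors) + 2) {
    stop("need at least ", length(descriptors) + 2, " rows to fit ",
         length(descriptors), " descriptors")
  }
  fit <- stats::lm(.model_formula(response, descriptors), data = table)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    bad <- gsub("`", "", names(cf)[is.na(cf)])
    stop("rank-deficient design; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  coefs <- cf[-1]; names(coefs) <- gsub("`", "", names(coefs))
  model <- qsar_model(cell_line = cell_line, intercept = unname(cf[1]),
                      coefficients = coefs, source = "fitted")
  y <- table[[response]]; yhat <- unname(stats::fitted(fit))
  report <- structure(list(N = n,
                           compound_id = table$compound_id,
                           observed = y,
                           fitted = yhat,
                           loo_predicted = NULL,
                           R_Tr = if (stats::sd(yhat) < 1e-12) NA_real_
                                  else stats::cor(yhat, y),
                           RMSE_Tr = sqrt(mean((y - yhat)^2)),
                           R_CV = NA_real_, RMSE_CV = NA_real_),
                      class = "validation_report")
  list(model = model, report = report, lm = fit)
}

#' Construct a QSAR model object
#'
#' @param cell_line Cell line label (or NA).
#' @param intercept Intercept B0.
#' @param coefficients Named numeric vector of descriptor coefficients.
#' @param source `"fitted"` or `"published"`.
#' @param notes Optional provenance notes.
#' @return Object of class `qsar_model`.
#' @export
qsar_model <- function(cell_line, intercept, coefficients,
                       source = c("fitted", "published"), notes = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1,
            is.numeric(coefficients), !is.null(names(coefficients)))
  structure(list(cell_line = cell_line, intercept = unname(intercept),
                 coefficients = coefficients, source = match.arg(source),
                 notes = notes),
            class = "qsar_model")
}

#' @export
print.qsar_model <- function(x, ...) {
  terms <- paste(sprintf("%+.4f(%s)", x$coefficients, names(x$coefficients)),
                 collapse = " ")
  cat(sprintf("<qsar_model %s [%s]> pIC50 = %s %+.4f\n",
              x$cell_line, x$source, terms, x$intercept))
  invisible(x)
}

#' Predict pIC50 from a QSAR model
#'
#' @param object A `qsar_model`.
#' @param newdata Named numeric vector, `descriptor_vector`, list, or
#'   data.frame of descriptor values covering all model terms.
#' @param ... Unused.
#' @return Numeric predictions (one per row for data.frame input).
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    miss <- setdiff(names(object$coefficients), names(newdata))
    if (length(miss)) stop("missing descriptor(s): ", paste(miss, collapse = ", "))
    X <- as.matrix(newdata[, names(object$coefficients), drop = FALSE])
    return(unname(object$intercept + X %*% object$coefficients)[, 1])
  }
  vals <- unlist(newdata)
  miss <- setdiff(names(object$coefficients), names(vals))
  if (length(miss)) stop("missing descriptor(s): ", paste(miss, collapse = ", "))
  unname(object$intercept +
           sum(object$coefficients * vals[names(object$coefficients)]))
}

#' Leave-one-out cross-validation
#'
#' For each row, the model is refit on the remaining N-1 rows and the
#' held-out row predicted; `R_CV` and `RMSE_CV` are computed over the pooled
#' held-out predictions. Implemented through the PRESS identity
#' (e_i / (1 - h_ii)) on the full-fit hat matrix, which is exactly
#' equivalent to delete-one refitting for OLS and fully deterministic.
#'
#' @param table Modeling table.
#' @param descriptors Selected descriptor names.
#' @param response Response column name.
#' @param cell_line Optional label.
#' @return A `validation_report` with training and CV parts.
#' @export
loo_cross_validate <- function(table, descriptors, response = "pic50",
                               cell_line = NA) {
  n <- nrow(table)
  if (n < length(descriptors) + 3) {
    stop("need at least ", length(descriptors) + 3, " rows for LOO-CV with ",
         length(descriptors), " descriptors")
  }
  base <- fit_mlr(table, descriptors, response, cell_line)
  h <- unname(stats::lm.influence(base$lm, do.coef = FALSE)$hat)
  if (any(h > 1 - 1e-10)) {
    stop("LOO fold(s) rank-deficient (leverage 1) at row(s): ",
         paste(which(h > 1 - 1e-10), collapse = ", "))
  }
  e <- base$report$observed - base$report$fitted
  loo <- base$report$observed - e / (1 - h)
  rep <- base$report
  rep$loo_predicted <- loo
  m <- regression_metrics(rep$observed, loo)
  rep$R_CV <- m["R"]; rep$RMSE_CV <- m["RMSE"]
  rep
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report N=%d  R_Tr=%.4f RMSE_Tr=%.4f  R_CV=%.4f RMSE_CV=%.4f>\n",
              x$N, x$R_Tr, x$RMSE_Tr, x$R_CV, x$RMSE_CV))
  invisible(x)
}

#' Correlation and root-mean-square error of prediction
#'
#' `R` is the Pearson correlation of observed and predicted values; `RMSE`
#' uses denominator N. A constant observed vector leaves R undefined and is
#' an error unless `rmse_only = TRUE`.
#'
#' @param observed,predicted Numeric vectors of equal length (>= 2).
#' @param rmse_only Return only RMSE (allows constant observed).
#' @return Named vector `c(R = ..., RMSE = ...)` (or just RMSE).
#' @export
regression_metrics <- function(observed, predicted, rmse_only = FALSE) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) < 2) stop("need at least 2 pairs")
  rmse <- sqrt(mean((observed - predicted)^2))
  if (rmse_only) return(c(RMSE = rmse))
  if (stats::sd(observed) < 1e-14) {
    stop("observed values are constant: R undefined (use rmse_only = TRUE)")
  }
  c(R = stats::cor(observed, predicted), RMSE = rmse)
}

#' The four published per-cell-line MLR models
#'
#' Returns the reference equations with their reported coefficients and
#' performance statistics:
#' \itemize{
#'   \item HuCCA-1: pIC50 = -84.0157 R5e+ + 1.0288 nArCOOR + 0.8738
#'   \item HepG2:   pIC50 = 0.0784 RDF105m + 5.1878 MATS7m - 1.7524
#'   \item A549:    pIC50 = 1.5979 MATS8v + 0.9251 nArCOOR - 1.7829
#'   \item MOLT-3:  pIC50 = 1.0649 Lop + 10.3977 R7m - 5.6832
#' }
#' The HepG2 intercept is printed with conflicting sign in different places
#' of the source report; the negative sign is used here (only it is
#' consistent with the positive descriptor values producing the reported
#' predicted range), and the discrepancy is recorded in the model notes.
#'
#' @param cell_line Optional: return just one model.
#' @return A named list of `qsar_model` objects (or a single model); each
#'   carries a `stats` attribute with N, R_Tr, RMSE_Tr, R_CV, RMSE_CV.
#' @export
published_models <- function(cell_line = NULL) {
  fx <- reference_fixture()
  mk <- function(row) {
    cf <- stats::setNames(c(row$coef1, row$coef2), c(row$term1, row$term2))
    m <- qsar_model(row$cell_line, row$intercept, cf, source = "published",
                    notes = row$notes)
    attr(m, "stats") <- c(N = row$N, R_Tr = row$R_Tr, RMSE_Tr = row$RMSE_Tr,
                          R_CV = row$R_CV, RMSE_CV = row$RMSE_CV)
    m
  }
  models <- lapply(seq_len(nrow(fx$models)), function(k) mk(fx$models[k, ]))
  names(models) <- fx$models$cell_line
  if (!is.null(cell_line)) {
    .check_cell_line(cell_line)
    return(models[[cell_line]])
  }
  models
}

#' Rank candidate compounds by predicted potency
#'
#' Orders predictions within each cell line by descending pIC50 (ties break
#' by ascending compound id) and attaches the predicted activity class.
#'
#' @param predictions data.frame with `compound_id`, `cell_line`, `pic50`.
#' @return data.frame with added `predicted_class` and `rank` (per cell
#'   line), sorted by cell line then rank.
#' @export
rank_candidates <- function(predictions) {
  need <- c("compound_id", "cell_line", "pic50")
  miss <- setdiff(need, names(predictions))
  if (length(miss)) stop("predictions missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(predictions) == 0) stop("no predictions to rank")
  .check_cell_line(predictions$cell_line)
  parts <- lapply(split(predictions, predictions$cell_line), function(p) {
    o <- order(-p$pic50, p$compound_id)
    p <- p[o, , drop = FALSE]
    p$predicted_class <- classify_predicted(p$pic50)
    p$rank <- seq_len(nrow(p))
    p
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

#' Serialize / deserialize a QSAR model as JSON
#'
#' @param model A `qsar_model`.
#' @param path Output (or input) path.
#' @return `path` for write; a `qsar_model` for read.
#' @export
write_model_json <- function(model, path) {
  obj <- list(cell_line = model$cell_line, intercept = model$intercept,
              coefficients = as.list(model$coefficients),
              source = model$source, notes = model$notes)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  qsar_model(obj$cell_line, obj$intercept, unlist(obj$coefficients),
             source = obj$source, notes = obj$notes)
}
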