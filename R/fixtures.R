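.fixture_env <- new.env(parent = emptyenv())

#' Reference data fixture
#'
#' Loads the machine-readable transcription of the reference study's data
#' shipped under `inst/extdata`: the IC50 activity table (32 compounds x 4
#' cell lines, with inactive flags), the experimental/LOO-predicted pIC50
#' pairs, the four published model equations with their performance
#' statistics, and the single descriptor and prediction values printed in
#' the SAR discussion for modified compounds. Every fixture row carries a
#' `citation` string naming its source table or section; internal
#' consistency (73 active records, per-cell-line Ns 13/24/16/20, IC50 to
#' pIC50 round trip at 3 decimals) is validated on first load and by the
#' test suite.
#'
#' @return A list with elements `activity`, `pic50_pairs`, `models`,
#'   `printed_descriptors`, `printed_predictions`.
#' @export
reference_fixture <- function() {
  if (!is.null(.fixture_env$fx)) return(.fixture_env$fx)
  ext <- function(f) system.file("extdata", f, package = "triqsar", mustWork = TRUE)
  rd <- function(f) utils::read.delim(ext(f), comment.char = "#",
                                      stringsAsFactors = FALSE,
                                      colClasses = c(compound_id = "character"))
  activity <- rd("table1_activity.tsv")
  pairs <- rd("table4_pic50.tsv")
  printed_desc <- rd("printed_descriptors.tsv")
  printed_pred <- rd("printed_predictions.tsv")
  models <- as.data.frame(jsonlite::read_json(ext("table3_models.json"),
                                              simplifyVector = TRUE)$models)
  # completeness: every value cited
  for (df in list(activity, pairs, printed_desc, printed_pred)) {
    stopifnot("citation" %in% names(df), all(nzchar(df$citation)))
  }
  stopifnot(all(nzchar(models$citation)))
  # internal consistency
  act <- activity[!activity$inactive, ]
  stopifnot(nrow(act) == 73, nrow(pairs) == 73)
  nn <- table(factor(act$cell_line, cell_lines()))
  stopifnot(all(nn == c(13, 24, 16, 20)))
  key <- paste(act$compound_id, act$cell_line)
  m <- match(key, paste(pairs$compound_id, pairs$cell_line))
  stopifnot(!anyNA(m),
            max(abs(round(ic50_to_pic50(act$ic50_uM), 3) -
                      pairs$pic50_exp[m])) < 5e-4)
  fx <- list(activity = activity, pic50_pairs = pairs, models = models,
             printed_descriptors = printed_desc,
             printed_predictions = printed_pred)
  .fixture_env$fx <- fx
  fx
}

#' Look up a printed descriptor value by compound
#'
#' @param compound_id Compound label (e.g. `"8N"`).
#' @param descriptor Descriptor name (e.g. `"R5e+"`).
#' @return The printed value (scalar).
#' @export
printed_descriptor <- function(compound_id, descriptor) {
  pd <- reference_fixture()$printed_descriptors
  hit <- pd$value[pd$compound_id == compound_id & pd$descriptor == descriptor]
  if (!length(hit)) stop("no printed value for ", descriptor, " of ", compound_id)
  hit
}
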