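#' Cell lines of the reference assay panel
#' @export
cell_lines <- function() c("HuCCA-1", "HepG2", "A549", "MOLT-3")

.check_cell_line <- function(cl) {
  bad <- setdiff(unique(cl), cell_lines())
  if (length(bad)) {
    stop("unknown cell line(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(cell_lines(), collapse = ", "), ")")
  }
  invisible(cl)
}

#' Convert IC50 (micromolar) to pIC50
#'
#' pIC50 = -log10(IC50 in uM); strictly decreasing in IC50, so larger pIC50
#' means more potent.
#'
#' @param ic50 Positive IC50 value(s) in micromolar.
#' @return pIC50 value(s).
#' @export
ic50_to_pic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("IC50 must be finite and positive (uM)")
  }
  -log10(ic50)
}

#' Classify experimental cytotoxic activity
#'
#' IC50 < 1 uM: highly active; 1-10 uM: moderately active; > 10 uM: weakly
#' active. The inactive class comes only from the input annotation (in the
#' source assay it was defined on a mass-concentration threshold that cannot
#' be recomputed from micromolar values without molar masses). Boundary
#' values (exactly 1 or 10 uM) map to the more active class.
#'
#' @param ic50 IC50 in uM (may be NA when `inactive` is TRUE).
#' @param inactive Logical flag(s) from the input annotation.
#' @return Character vector: `"highly active"`, `"moderately active"`,
#'   `"weakly active"` or `"inactive"`.
#' @export
classify_experimental <- function(ic50, inactive = FALSE) {
  n <- max(length(ic50), length(inactive))
  ic50 <- rep_len(ic50, n); inactive <- rep_len(inactive, n)
  out <- character(n)
  for (k in seq_len(n)) {
    out[k] <- if (isTRUE(inactive[k])) "inactive"
    else if (!is.finite(ic50[k]) || ic50[k] <= 0)
      stop("active record needs a positive IC50")
    else if (ic50[k] <= 1) "highly active"
    else if (ic50[k] <= 10) "moderately active"
    else "weakly active"
  }
  out
}

#' Classify predicted activity from pIC50
#'
#' pIC50 > 0: highly active; -1 < pIC50 < 0: moderately active; pIC50 < -1:
#' weakly to inactive. Boundaries (exactly 0 or -1) map to the more active
#' class.
#'
#' @param pic50 Finite predicted pIC50 value(s).
#' @return Character vector of class labels.
#' @export
classify_predicted <- function(pic50) {
  if (any(!is.finite(pic50))) stop("pIC50 must be finite")
  ifelse(pic50 >= 0, "highly active",
         ifelse(pic50 >= -1, "moderately active", "weakly to inactive"))
}

#' Read an activity table
#'
#' Delimited text with header `compound_id`, `cell_line`, `ic50_uM` (empty
#' allowed for inactive records) and `inactive` (true/false). Derived
#' `pic50` and `experimental_class` columns are added.
#'
#' @param path File path (tab- or comma-delimited, sniffed from the header).
#' @return data.frame of activity records.
#' @export
read_activities <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("compound_id", "cell_line", "ic50_uM", "inactive")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("activity table missing column(s): ",
                         paste(miss, collapse = ", "))
  df$compound_id <- as.character(df$compound_id)
  df$inactive <- as.logical(df$inactive)
  .check_cell_line(df$cell_line)
  if (any(!df$inactive & !is.finite(df$ic50_uM))) {
    stop("active records must carry a numeric ic50_uM")
  }
  df$pic50 <- ifelse(df$inactive, NA_real_, ic50_to_pic50(ifelse(df$inactive, 1, df$ic50_uM)))
  df$experimental_class <- classify_experimental(df$ic50_uM, df$inactive)
  df
}

# order compound ids naturally: numeric prefix, then suffix (e.g. 8B < 10)
.order_ids <- function(ids) {
  num <- suppressWarnings(as.numeric(sub("^([0-9]+).*$", "\\1", ids)))
  suf <- sub("^[0-9]+", "", ids)
  order(num, suf, ids)
}

#' Assemble a per-cell-line modeling table
#'
#' Joins activity records with a descriptor table for one cell line,
#' excluding inactive compounds (the exclusion rule of the source protocol),
#' and orders rows by compound id. The result feeds the QSAR fitting stack.
#'
#' @param activities data.frame as from [read_activities()] (or with a
#'   `pic50`/`inactive` pair already present).
#' @param descriptors data.frame with `compound_id` plus descriptor columns.
#' @param cell_line One of [cell_lines()].
#' @return data.frame with `compound_id`, descriptor columns and `pic50`;
#'   attribute `N` is the row count.
#' @export
assemble_modeling_table <- function(activities, descriptors, cell_line) {
  .check_cell_line(cell_line)
  act <- activities[activities$cell_line == cell_line, , drop = FALSE]
  if (is.null(act$pic50)) {
    act$pic50 <- ifelse(act$inactive, NA_real_, ic50_to_pic50(ifelse(act$inactive, 1, act$ic50_uM)))
  }
  act <- act[!act$inactive, , drop = FALSE]
  if (nrow(act) == 0) {
    warning("no active compounds for cell line ", cell_line)
    out <- cbind(data.frame(compound_id = character(0)),
                 descriptors[0, setdiff(names(descriptors), "compound_id"),
                             drop = FALSE],
                 data.frame(pic50 = numeric(0)))
    attr(out, "N") <- 0L
    return(out)
  }
  pos <- match(act$compound_id, descriptors$compound_id)
  if (anyNA(pos)) {
    stop("active compound(s) missing descriptors for ", cell_line, ": ",
         paste(act$compound_id[is.na(pos)], collapse = ", "))
  }
  dcols <- setdiff(names(descriptors), "compound_id")
  out <- cbind(data.frame(compound_id = act$compound_id,
                          stringsAsFactors = FALSE),
               descriptors[pos, dcols, drop = FALSE],
               data.frame(pic50 = act$pic50))
  out <- out[.order_ids(out$compound_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N") <- nrow(out)
  out
}
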