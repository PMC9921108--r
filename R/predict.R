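#' Per-family interaction confidences for one compound
#'
#' Descriptors are computed once from the SMILES; for each enzyme subclass
#' in the bundle the (MD, <MD>, DMD) vector against that subclass's profile
#' is fed to the network, and the interacting-class probability is reported
#' as the confidence for that family.
#'
#' @param smiles SMILES string.
#' @param bundle a `model_bundle` (see [load_model()]), or the equivalent
#'   in-memory list with `model`, `profiles`, `selected`.
#' @return named numeric vector, one confidence in [0, 1] per subclass, in
#'   EC sort order. Malformed SMILES raise `malformed_smiles_error`.
#' @export
predict_one <- function(smiles, bundle) {
  dv <- compute_descriptors(parse_smiles(smiles))
  fams <- sort_ec_families(bundle$profiles$ec_family)
  X <- t(vapply(fams, function(cl) {
    featurize_pair(dv, bundle$profiles[cl, , drop = FALSE], bundle$selected)
  }, numeric(3L * length(bundle$selected))))
  stats::setNames(predict(bundle$model, X)[, "interacting"], fams)
}

#' Batch prediction over a SMILES file
#'
#' One output row per input row, order preserved. Rows whose SMILES cannot
#' be parsed are flagged `malformed` with an error message and empty
#' confidences — never fatal — so one bad compound does not abort the batch.
#'
#' @param batch a `smiles_batch` (see [read_smiles_batch()]; already capped
#'   at 100 rows), or a data.frame with columns `row_id`, `smiles`.
#' @param bundle a `model_bundle`.
#' @return `prediction_table`: data.frame with `row_id`, `smiles`, `status`
#'   (`"ok"`/`"malformed"`), `message`, then one confidence column per
#'   subclass in EC sort order (NA on malformed rows).
#' @export
predict_batch <- function(batch, bundle) {
  fams <- sort_ec_families(bundle$profiles$ec_family)
  rows <- lapply(seq_len(nrow(batch)), function(i) {
    conf <- tryCatch(
      list(status = "ok", message = "",
           values = predict_one(batch$smiles[i], bundle)[fams]),
      malformed_smiles_error = function(e)
        list(status = "malformed", message = conditionMessage(e),
             values = stats::setNames(rep(NA_real_, length(fams)), fams))
    )
    cbind(data.frame(row_id = batch$row_id[i], smiles = batch$smiles[i],
                     status = conf$status, message = conf$message,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(conf$values), check.names = FALSE))
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else {
    empty <- data.frame(row_id = character(0), smiles = character(0),
                        status = character(0), message = character(0),
                        stringsAsFactors = FALSE)
    for (f in fams) empty[[f]] <- numeric(0)
    empty
  }
  rownames(out) <- NULL
  structure(out, families = fams, class = c("prediction_table", "data.frame"))
}

#' Write a prediction table to TSV or CSV
#'
#' Header: `id`, `smiles`, `status`, then one column per enzyme subclass in
#' EC sort order. Confidences are written with 6 decimals; malformed rows
#' get empty confidence cells.
#'
#' @param table a `prediction_table`.
#' @param path output file.
#' @param format `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_table <- function(table, path, format = c("tsv", "csv")) {
  format <- match.arg(format)
  fams <- attr(table, "families") %||%
    setdiff(colnames(table), c("row_id", "smiles", "status", "message"))
  out <- data.frame(id = table$row_id, smiles = table$smiles,
                    status = table$status, stringsAsFactors = FALSE,
                    check.names = FALSE)
  for (f in fams)
    out[[f]] <- ifelse(is.na(table[[f]]), "", sprintf("%.6f", table[[f]]))
  write.table(out, path, sep = if (format == "tsv") "\t" else ",",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back an exported prediction table
#'
#' @param path file written by [export_table()].
#' @param format `"tsv"` or `"csv"` (default: from the file extension).
#' @return `prediction_table` (confidences at the exported 6-decimal
#'   precision; `message` column is empty).
#' @export
read_prediction_table <- function(path, format = NULL) {
  format <- format %||% (if (tolower(tools::file_ext(path)) == "csv") "csv" else "tsv")
  df <- read.delim(path, sep = if (format == "tsv") "\t" else ",",
                   header = TRUE, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  fams <- setdiff(colnames(df), c("id", "smiles", "status"))
  out <- data.frame(row_id = df$id, smiles = df$smiles, status = df$status,
                    message = "", stringsAsFactors = FALSE, check.names = FALSE)
  for (f in fams) out[[f]] <- suppressWarnings(as.numeric(df[[f]]))
  structure(out, families = fams, class = c("prediction_table", "data.frame"))
}

#' Sort or filter a prediction table without modifying it
#'
#' @param table a `prediction_table`.
#' @param by column to sort by (a family label or `row_id`/`smiles`/`status`);
#'   `NULL` keeps the current order. The sort is stable.
#' @param decreasing sort direction.
#' @param query substring; only rows whose SMILES contains it are kept.
#' @param columns optional subset of confidence columns to keep visible.
#' @return a new `prediction_table` view; the input is unchanged.
#' @export
sort_filter <- function(table, by = NULL, decreasing = TRUE, query = NULL,
                        columns = NULL) {
  view <- table
  if (!is.null(query))
    view <- view[grepl(query, view$smiles, fixed = TRUE), , drop = FALSE]
  if (!is.null(by)) {
    if (!by %in% colnames(view))
      mtq_stop("unknown_column_error", sprintf("unknown column '%s'", by))
    ord <- order(xtfrm(view[[by]]) * if (decreasing) -1 else 1, method = "radix")
    view <- view[ord, , drop = FALSE]
  }
  fams <- attr(table, "families")
  if (!is.null(columns)) {
    bad <- setdiff(columns, colnames(view))
    if (length(bad) > 0L)
      mtq_stop("unknown_column_error",
               sprintf("unknown column(s): %s", paste(bad, collapse = ", ")))
    keep <- c("row_id", "smiles", "status", "message", columns)
    view <- view[, intersect(colnames(view), keep), drop = FALSE]
    fams <- intersect(fams, columns)
  }
  rownames(view) <- NULL
  structure(view, families = fams, class = c("prediction_table", "data.frame"))
}
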