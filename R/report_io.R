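#' Write result tables deterministically as TSV or JSON
#'
#' Tables are written with fixed column order, rows sorted by the first
#' column, and floats rendered with 4 decimals, so identical inputs give
#' byte-identical files.
#'
#' @param tables A data frame, or a named list of data frames (JSON
#'   only; for TSV a single table).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(tables, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (is.null(tables)) stop("tables must be non-null")
  canon <- function(df) {
    df <- as.data.frame(df)
    if (nrow(df) > 1L) df <- df[order(df[[1]]), , drop = FALSE]
    rownames(df) <- NULL
    for (cn in names(df)) if (is.double(df[[cn]])) df[[cn]] <- round(df[[cn]], 4)
    df
  }
  if (format == "tsv") {
    if (!is.data.frame(tables)) stop("TSV reports take a single data frame")
    df <- canon(tables)
    for (cn in names(df)) if (is.double(df[[cn]])) df[[cn]] <- format_float(df[[cn]])
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    obj <- if (is.data.frame(tables)) canon(tables) else lapply(tables, canon)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a JSON report back into tables
#'
#' @param path Path written by [write_report].
#' @return Data frame or named list of data frames.
#' @export
read_report_json <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
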