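#' Write a set of result tables as TSV reports
#'
#' Each table is written as `<name>.tsv` with a header row, floats rendered
#' at a fixed number of significant digits, and rows in the order given by
#' the caller (pipeline stages sort by position / cluster id before calling
#' this). A `run_metadata.tsv` key/value file records the seed and any
#' parameters passed in `metadata`, so identical inputs and configuration
#' give byte-identical report directories.
#'
#' @param tables Named list of data.frames.
#' @param path Output directory (created if needed).
#' @param precision Significant digits for numeric columns.
#' @param metadata Named list of run parameters (seed, switches, ...).
#' @return Character vector of files written, invisibly.
#' @export
write_report <- function(tables, path, precision = 6L, metadata = list()) {
  stopifnot(is.list(tables), !is.null(names(tables)), all(nzchar(names(tables))))
  if (!dir.exists(path)) {
    ok <- dir.create(path, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create report directory: ", path)
  }
  written <- character(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    for (j in seq_along(df)) {
      if (is.double(df[[j]])) {
        df[[j]] <- formatC(df[[j]], digits = precision, format = "g")
      }
      if (is.list(df[[j]])) {
        df[[j]] <- vapply(df[[j]], function(x) paste(x, collapse = ","), "")
      }
    }
    f <- file.path(path, paste0(nm, ".tsv"))
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  meta <- data.frame(
    key = c("package_version", names(metadata)),
    value = c(
      as.character(utils::packageVersion("ltrconv")),
      vapply(metadata, function(x) paste(format(x), collapse = ","), "")
    ),
    stringsAsFactors = FALSE
  )
  f <- file.path(path, "run_metadata.tsv")
  write.table(meta, f, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(written, f))
}
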