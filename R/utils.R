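# shared internal helpers

# canonical matching form: UTF-8, trimmed, case-folded.
canon <- function(x) tolower(trimws(enc2utf8(as.character(x))))

`%||%` <- function(a, b) if (is.null(a)) b else a

# strict TSV reader: everything character, "" preserved, no quoting
read_tsv_strict <- function(path) {
  if (!file.exists(path)) {
    stop_medkg("format", "file not found: ", path)
  }
  utils::read.delim(path,
    sep = "\t", quote = "", stringsAsFactors = FALSE,
    check.names = FALSE, colClasses = "character",
    na.strings = character(0), fileEncoding = "UTF-8",
    comment.char = ""
  )
}

write_tsv_strict <- function(df, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.table(df,
    con,
    sep = "\t", quote = FALSE, row.names = FALSE,
    col.names = TRUE, fileEncoding = "UTF-8"
  )
  invisible(path)
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_medkg(
      "format", what, " is missing mandatory column(s): ",
      paste(missing, collapse = ", ")
    )
  }
  invisible(df)
}

# condition constructors ------------------------------------------------

stop_medkg <- function(subclass, ...) {
  msg <- paste0(...)
  stop(structure(
    class = c(paste0("medkg_", subclass, "_error"), "medkg_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Path to a packaged example data file
#'
#' Convenience wrapper around `system.file()` for the files shipped
#' under `extdata/` (ontology tables, worked-example quintuple tables,
#' lexicons and standardization rules).
#'
#' @param file File name within `extdata/`; with no argument, lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @examples
#' medkg_extdata()
#' medkg_extdata("bb_amt.tsv")
#' @export
medkg_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "medkg")
  if (is.null(file)) {
    return(list.files(dir))
  }
  path <- file.path(dir, file)
  if (!file.exists(path)) {
    stop_medkg("not_found", "no packaged data file named '", file, "'")
  }
  path
}

split_semicolon <- function(x) {
  lapply(strsplit(as.character(x), ";", fixed = TRUE), function(p) {
    p <- trimws(p)
    p[nzchar(p)]
  })
}

join_semicolon <- function(x) {
  vapply(x, function(p) paste(p, collapse = ";"), character(1))
}
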