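# Internal condition helper: all package errors carry class "swapdata_error"
# plus an optional subclass so callers can branch on failure kind.
stop_swapdata <- function(msg, subclass = NULL, call. = FALSE) {
  cond <- structure(
    class = c(subclass, "swapdata_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  )
  stop(cond)
}

#' Table name of a relational table
#'
#' Relational tables are plain `data.frame`s whose columns are all
#' character vectors (values are never type-coerced) and whose name is
#' carried in the `"table_name"` attribute.
#'
#' @param tab A relational table.
#' @return The table name, a length-one character vector.
#' @export
table_name <- function(tab) {
  nm <- attr(tab, "table_name", exact = TRUE)
  if (is.null(nm)) stop_swapdata("table has no 'table_name' attribute")
  nm
}

#' Construct a relational table
#'
#' @param df A data.frame; all columns are coerced to character. `NA`
#'   values become empty strings (missingness is represented uniformly
#'   as `""`).
#' @param name Table name.
#' @return A character-valued data.frame with a `table_name` attribute.
#' @export
relational_table <- function(df, name) {
  stopifnot(is.data.frame(df), is.character(name), length(name) == 1L)
  if (anyDuplicated(names(df)))
    stop_swapdata(sprintf("table '%s' has duplicate field names: %s", name,
                          paste(unique(names(df)[duplicated(names(df))]), collapse = ", ")))
  out <- as.data.frame(lapply(df, function(x) {
    x <- as.character(x)
    x[is.na(x)] <- ""
    x
  }), stringsAsFactors = FALSE, optional = TRUE)
  names(out) <- names(df)
  rownames(out) <- NULL
  attr(out, "table_name") <- name
  out
}

#' Read one relational table from a delimited text file
#'
#' Files are UTF-8 comma-delimited text with RFC-4180 quoting and a
#' header row of field names. All values are read as text; nothing is
#' interpreted as `NA` (the literal string "NA" survives a round trip).
#'
#' @param path Path to the file; the filename stem becomes the table name
#'   unless `name` is given.
#' @param name Optional explicit table name.
#' @return A relational table.
#' @export
read_table_file <- function(path, name = NULL) {
  if (!file.exists(path)) stop_swapdata(sprintf("no such table file: %s", path))
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, colClasses = "character",
                        na.strings = character(0),
                        check.names = FALSE, fileEncoding = "UTF-8")
  relational_table(df, name)
}

#' Write one relational table to a delimited text file
#'
#' Output uses the same format as the input contract of
#' [read_table_file()]: UTF-8, comma-delimited, RFC-4180 quoting, header
#' row, one file per table.
#'
#' @param tab A relational table.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_table_file <- function(tab, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(tab, con, row.names = FALSE, quote = TRUE, na = "",
                   eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read every table in a directory
#'
#' @param dir Directory holding one `.csv` file per table.
#' @return A named list of relational tables (names = table names), in
#'   lexicographic filename order.
#' @export
read_table_dir <- function(dir) {
  if (!dir.exists(dir)) stop_swapdata(sprintf("no such input directory: %s", dir))
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  tabs <- lapply(files, read_table_file)
  names(tabs) <- vapply(tabs, table_name, "")
  if (anyDuplicated(names(tabs)))
    stop_swapdata(sprintf("duplicate table names in %s: %s", dir,
                          paste(unique(names(tabs)[duplicated(names(tabs))]), collapse = ", ")))
  tabs
}

#' Write a collection of tables to a directory
#'
#' @param tables Named list of relational tables.
#' @param dir Destination directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_table_dir <- function(tables, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (tab in tables) {
    write_table_file(tab, file.path(dir, paste0(table_name(tab), ".csv")))
  }
  invisible(dir)
}
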