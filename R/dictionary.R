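#' Privacy measures
#'
#' The four field-level privacy measures that drive the pipeline:
#' `NO_ACTION` (field passes through untouched), `DELETION` (every value
#' erased, column kept), `PSEUDONYMIZATION` (values replaced by salted
#' SHA3-256 tokens), `DATE_RANDOMIZATION` (dates shifted by a bounded
#' random number of days). Any other measure string in a dictionary file
#' is a validation error.
#'
#' @format Character vector of the four canonical measure names.
#' @export
MEASURES <- c("NO_ACTION", "DELETION", "PSEUDONYMIZATION", "DATE_RANDOMIZATION")

EXCLUDED_MARKER <- "EXCLUDED"
DATE_ROLES <- c("day", "month", "year")

DICT_COLUMNS <- c("table_name", "field_name", "description",
                  "measure", "date_group", "date_role")

# Case-insensitive, whitespace/spelling tolerant measure normalization:
# "Date randomization" -> "DATE_RANDOMIZATION".
normalize_measure <- function(x) {
  toupper(gsub("[ -]+", "_", trimws(x)))
}

#' Construct a data dictionary
#'
#' A data dictionary (the "data record description") has one entry per
#' (table, field) pair carrying a free-text description and the privacy
#' measure to apply, plus a set of excluded tables that are dropped from
#' the output entirely. Split dates — calendar dates stored as three
#' adjacent day/month/year columns — are bound together by a shared
#' `date_group` label with a `date_role` of `"day"`, `"month"` or
#' `"year"` per column.
#'
#' @param entries A data.frame with columns `table_name`, `field_name`,
#'   `description`, `measure`, and optionally `date_group`, `date_role`.
#' @param excluded_tables Character vector of table names to exclude.
#' @return A validated `data_dictionary` object.
#' @export
data_dictionary <- function(entries, excluded_tables = character()) {
  stopifnot(is.data.frame(entries))
  for (col in setdiff(DICT_COLUMNS, names(entries))) {
    if (col %in% c("date_group", "date_role")) entries[[col]] <- rep("", nrow(entries))
    else stop_swapdata(sprintf("dictionary entries lack column '%s'", col))
  }
  entries <- entries[, DICT_COLUMNS, drop = FALSE]
  for (col in DICT_COLUMNS) {
    entries[[col]] <- as.character(entries[[col]])
    entries[[col]][is.na(entries[[col]])] <- ""
  }
  entries$measure <- normalize_measure(entries$measure)
  rownames(entries) <- NULL
  d <- structure(list(entries = entries,
                      excluded_tables = sort(unique(as.character(excluded_tables)))),
                 class = "data_dictionary")
  check_dictionary(d)
  d
}

# Structural validation shared by every constructor/loader.
check_dictionary <- function(d) {
  e <- d$entries
  bad <- !(e$measure %in% MEASURES)
  if (any(bad))
    stop_swapdata(sprintf("unknown measure(s): %s (entry row %s)",
                          paste(unique(e$measure[bad]), collapse = ", "),
                          paste(which(bad), collapse = ", ")),
                  "swapdata_dictionary_error")
  key <- paste(e$table_name, e$field_name, sep = "\r")
  if (anyDuplicated(key))
    stop_swapdata(sprintf("duplicate dictionary entries: %s",
                          paste(unique(sub("\r", ".", key[duplicated(key)])), collapse = ", ")),
                  "swapdata_dictionary_error")
  if (any(e$table_name == "" | e$field_name == ""))
    stop_swapdata("entries must have non-empty table_name and field_name",
                  "swapdata_dictionary_error")
  overlap <- intersect(d$excluded_tables, unique(e$table_name))
  if (length(overlap))
    stop_swapdata(sprintf("excluded tables also have field entries: %s",
                          paste(overlap, collapse = ", ")),
                  "swapdata_dictionary_error")
  # Split-date groups: measure must be DATE_RANDOMIZATION and each group
  # must hold exactly one day, one month and one year column of one table.
  has_group <- e$date_group != ""
  if (any(has_group & e$measure != "DATE_RANDOMIZATION"))
    stop_swapdata("date_group is only valid on DATE_RANDOMIZATION fields",
                  "swapdata_dictionary_error")
  if (any(has_group & !(e$date_role %in% DATE_ROLES)))
    stop_swapdata("date_role must be one of day/month/year for grouped fields",
                  "swapdata_dictionary_error")
  if (any(!has_group & e$date_role != ""))
    stop_swapdata("date_role set without date_group", "swapdata_dictionary_error")
  for (g in unique(e$date_group[has_group])) {
    sub <- e[e$date_group == g, , drop = FALSE]
    if (length(unique(sub$table_name)) != 1L)
      stop_swapdata(sprintf("date_group '%s' spans multiple tables", g),
                    "swapdata_dictionary_error")
    if (!identical(sort(sub$date_role), sort(DATE_ROLES)))
      stop_swapdata(sprintf(
        "date_group '%s' must contain exactly one day, one month and one year column", g),
        "swapdata_dictionary_error")
  }
  invisible(d)
}

#' @export
print.data_dictionary <- function(x, ...) {
  tab <- table(factor(x$entries$measure, levels = MEASURES))
  cat(sprintf("<data_dictionary: %d entries over %d tables, %d excluded table(s)>\n",
              nrow(x$entries), length(unique(x$entries$table_name)),
              length(x$excluded_tables)))
  for (m in MEASURES) cat(sprintf("  %-20s %d\n", m, tab[[m]]))
  invisible(x)
}

#' @export
format.data_dictionary <- function(x, ...) {
  sprintf("<data_dictionary: %d entries>", nrow(x$entries))
}

#' Extract a dictionary skeleton from a set of tables
#'
#' Builds the data record description automatically from the source
#' tables: one entry per (table, field), ordered by table then by column
#' position, with empty descriptions and measure `NO_ACTION`. The
#' skeleton is then reviewed by hand — descriptions added and measures
#' assigned — before driving a pipeline run.
#'
#' @param tables Named list of relational tables.
#' @return A `data_dictionary` with one `NO_ACTION` entry per field and
#'   no excluded tables.
#' @export
extract_schema <- function(tables) {
  nms <- vapply(tables, table_name, "")
  if (anyDuplicated(nms))
    stop_swapdata(sprintf("duplicate table names: %s",
                          paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  if (any(vapply(tables, ncol, 0L) == 0L))
    stop_swapdata("every table must have a non-empty header")
  entries <- do.call(rbind, lapply(tables, function(tab) {
    if (anyDuplicated(names(tab)))
      stop_swapdata(sprintf("table '%s' has duplicate field names", table_name(tab)))
    data.frame(table_name = table_name(tab), field_name = names(tab),
               description = "", measure = "NO_ACTION",
               date_group = "", date_role = "",
               stringsAsFactors = FALSE)
  }))
  data_dictionary(entries)
}

#' Load a data dictionary from a delimited text file
#'
#' The file is UTF-8 comma-delimited with header
#' `table_name,field_name,description,measure,date_group,date_role`
#' (the last two optional). Measure strings are matched
#' case-insensitively with surrounding whitespace stripped. A row with
#' an empty `field_name` and measure `Excluded` marks the whole table as
#' excluded from the anonymized output.
#'
#' @param path Path to the dictionary file.
#' @return A `data_dictionary`.
#' @export
load_dictionary <- function(path) {
  if (!file.exists(path)) stop_swapdata(sprintf("no such dictionary file: %s", path))
  raw <- utils::read.csv(path, colClasses = "character",
                         na.strings = character(0),
                         check.names = FALSE, fileEncoding = "UTF-8")
  need <- c("table_name", "field_name", "description", "measure")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop_swapdata(sprintf("dictionary file lacks column(s): %s",
                          paste(miss, collapse = ", ")), "swapdata_dictionary_error")
  if (!"date_group" %in% names(raw)) raw$date_group <- ""
  if (!"date_role" %in% names(raw)) raw$date_role <- ""
  measure_norm <- normalize_measure(raw$measure)
  is_excl <- trimws(raw$field_name) == "" & measure_norm == EXCLUDED_MARKER
  unknown <- !is_excl & !(measure_norm %in% MEASURES)
  if (any(unknown))
    stop_swapdata(sprintf("unknown measure '%s' at file row %d",
                          raw$measure[which(unknown)[1]],
                          which(unknown)[1] + 1L),  # +1 for the header line
                  "swapdata_dictionary_error")
  entries <- raw[!is_excl, , drop = FALSE]
  data_dictionary(entries, excluded_tables = trimws(raw$table_name[is_excl]))
}

#' Save a data dictionary to a delimited text file
#'
#' Serialization is the exact inverse of [load_dictionary()]:
#' `load_dictionary(save_dictionary(d, path))` reproduces `d`, and
#' saving the same dictionary twice yields byte-identical files.
#'
#' @param dict A `data_dictionary`.
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
save_dictionary <- function(dict, path) {
  stopifnot(inherits(dict, "data_dictionary"))
  check_dictionary(dict)
  rows <- dict$entries
  if (length(dict$excluded_tables)) {
    excl <- data.frame(table_name = dict$excluded_tables, field_name = "",
                       description = "", measure = "Excluded",
                       date_group = "", date_role = "",
                       stringsAsFactors = FALSE)
    rows <- rbind(rows, excl)
  }
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  con <- file(path, open = "wb", encoding = "UTF-8")
  on.exit(close(con))
  utils::write.csv(rows, con, row.names = FALSE, quote = TRUE, na = "",
                   eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Validate a dictionary against the actual data
#'
#' Cross-checks the data record description against the tables it is
#' meant to drive. Every (table, field) present in the data must be
#' either covered by an entry or belong to an excluded table; entries
#' referring to tables or fields absent from the data indicate a stale
#' dictionary and abort. Fields present in the data but missing from the
#' dictionary — fields of unknown meaning — are handled per
#' `unknown_policy`: `"error"` aborts listing all offenders, `"delete"`
#' synthesizes a `DELETION` entry for each so that unknown content is
#' truncated rather than leaked.
#'
#' @param dict A `data_dictionary`.
#' @param tables Named list of relational tables.
#' @param unknown_policy `"error"` or `"delete"`.
#' @return The validated (possibly extended) `data_dictionary`.
#' @export
validate_dictionary <- function(dict, tables, unknown_policy = c("error", "delete")) {
  stopifnot(inherits(dict, "data_dictionary"))
  unknown_policy <- match.arg(unknown_policy)
  check_dictionary(dict)
  tab_names <- vapply(tables, table_name, "")
  names(tables) <- tab_names
  e <- dict$entries
  # Stale-entry check: every entry must point at an existing table/field.
  stale <- character(0)
  for (i in seq_len(nrow(e))) {
    tn <- e$table_name[i]
    if (!tn %in% tab_names || !e$field_name[i] %in% names(tables[[tn]]))
      stale <- c(stale, paste0(tn, ".", e$field_name[i]))
  }
  if (length(stale))
    stop_swapdata(sprintf("stale dictionary entries (not in data): %s",
                          paste(stale, collapse = ", ")),
                  "swapdata_dictionary_error")
  # Coverage check on non-excluded tables.
  covered <- paste(e$table_name, e$field_name, sep = "\r")
  uncovered <- character(0)
  extra <- list()
  for (tn in setdiff(tab_names, dict$excluded_tables)) {
    fields <- names(tables[[tn]])
    missing <- fields[!(paste(tn, fields, sep = "\r") %in% covered)]
    if (length(missing)) {
      uncovered <- c(uncovered, paste0(tn, ".", missing))
      extra[[tn]] <- data.frame(table_name = tn, field_name = missing,
                                description = "", measure = "DELETION",
                                date_group = "", date_role = "",
                                stringsAsFactors = FALSE)
    }
  }
  if (length(uncovered)) {
    if (unknown_policy == "error")
      stop_swapdata(sprintf("fields present in data but not described: %s",
                            paste(uncovered, collapse = ", ")),
                    "swapdata_dictionary_error")
    e <- rbind(e, do.call(rbind, extra))
  }
  data_dictionary(e, dict$excluded_tables)
}
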