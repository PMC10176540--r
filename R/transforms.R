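# Admissible signed day offsets. Combined-format dates ("DD.MM.YYYY")
# shift by +/-3..6 days; split-format dates (three adjacent day/month/year
# columns) shift by +/-2..10 days. Zero is never admissible.
OFFSETS_COMBINED <- c(-6:-3, 3:6)
OFFSETS_SPLIT <- c(-10:-2, 2:10)

COMBINED_DATE_RE <- "^[0-9]{2}\\.[0-9]{2}\\.[0-9]{4}$"

# Strict DD.MM.YYYY parse: zero-padded and a real Gregorian date
# (as.Date rejects 31.02. etc.). Returns Date with NA where invalid.
parse_combined_date <- function(x) {
  d <- as.Date(ifelse(grepl(COMBINED_DATE_RE, x), x, NA_character_),
               format = "%d.%m.%Y")
  # as.Date("%d.%m.%Y") tolerates some junk only when the regex would
  # already have failed, so the regex gate is the format authority.
  d
}

parse_split_date <- function(day, month, year) {
  num <- function(v) ifelse(grepl("^[0-9]+$", v), suppressWarnings(as.integer(v)), NA_integer_)
  d <- num(day); m <- num(month); y <- num(year)
  iso <- sprintf("%04d-%02d-%02d", y, m, d)
  iso[is.na(d) | is.na(m) | is.na(y)] <- NA_character_
  as.Date(iso, format = "%Y-%m-%d")
}

#' Delete a column's values
#'
#' The deletion measure completely erases every value from the column
#' while keeping the column itself in place, so the output table has the
#' same header and shape as the input.
#'
#' @param table A relational table.
#' @param field Field name to erase.
#' @return The table with that column all-empty.
#' @export
delete_column <- function(table, field) {
  if (!field %in% names(table))
    stop_swapdata(sprintf("no field '%s' in table '%s'", field, table_name(table)))
  table[[field]] <- rep("", nrow(table))
  table
}

# Salted SHA3-256 of one UTF-8 string: hex digest of bytes(value) || salt.
sha3_token <- function(value, salt) {
  paste(as.character(openssl::sha3(c(charToRaw(enc2utf8(value)), salt),
                                   size = 256L)), collapse = "")
}

#' Pseudonymize a column with salted SHA-3
#'
#' Every non-empty value `v` is replaced by the lowercase hexadecimal
#' SHA3-256 digest of the UTF-8 bytes of `v` followed by the run's
#' 16-byte secret salt. Equal inputs map to equal tokens within one run,
#' so identifiers that connect tables stay referentially consistent up
#' to the swapping stage; across runs the fresh salt makes tokens
#' incomparable, and because no key list is ever stored the mapping is
#' one-way. Empty values stay empty so missingness is preserved.
#'
#' @param table A relational table.
#' @param field Field name to pseudonymize.
#' @param secrets The run's [run_secrets()].
#' @return The table with that column tokenized.
#' @export
pseudonymize_column <- function(table, field, secrets) {
  if (!field %in% names(table))
    stop_swapdata(sprintf("no field '%s' in table '%s'", field, table_name(table)))
  stopifnot(inherits(secrets, "run_secrets"))
  x <- table[[field]]
  nonempty <- unique(x[x != ""])
  if (length(nonempty)) {
    tokens <- vapply(nonempty, sha3_token, "", salt = secrets$salt, USE.NAMES = FALSE)
    idx <- match(x, nonempty)
    out <- x
    out[!is.na(idx)] <- tokens[idx[!is.na(idx)]]
    table[[field]] <- out
  }
  table
}

#' Shift combined-format dates by a bounded random number of days
#'
#' Each value must be a valid zero-padded `DD.MM.YYYY` date. A signed
#' offset is drawn anew for every value, uniformly over the 8 admissible
#' offsets with absolute value between 3 and 6 days; the shifted date is
#' re-serialized as zero-padded `DD.MM.YYYY` with correct calendar
#' rollover across month and year boundaries.
#'
#' @param x Character vector of `DD.MM.YYYY` dates.
#' @param secrets The run's [run_secrets()] (randomness source).
#' @return Character vector of shifted dates, same length.
#' @export
shift_date_combined <- function(x, secrets) {
  d <- parse_combined_date(x)
  if (anyNA(d))
    stop_swapdata(sprintf("unparsable combined date at position %d",
                          which(is.na(d))[1]), "swapdata_date_parse_error")
  s <- OFFSETS_COMBINED[draw_int(secrets, length(d), length(OFFSETS_COMBINED))]
  format(d + s, "%d.%m.%Y")
}

#' Shift split-format dates by a bounded random number of days
#'
#' A date stored as three adjacent columns `[DD][MM][YYYY]` is
#' concatenated to a single date, shifted by a signed offset drawn
#' uniformly over the 18 admissible offsets with absolute value between
#' 2 and 10 days, and redistributed to the three columns. Each output
#' component keeps its input's zero-padding width.
#'
#' @param day,month,year Character vectors of equal length.
#' @param secrets The run's [run_secrets()].
#' @return A list with components `day`, `month`, `year`.
#' @export
shift_date_split <- function(day, month, year, secrets) {
  stopifnot(length(day) == length(month), length(month) == length(year))
  d <- parse_split_date(day, month, year)
  if (anyNA(d))
    stop_swapdata(sprintf("unparsable split date at position %d",
                          which(is.na(d))[1]), "swapdata_date_parse_error")
  s <- OFFSETS_SPLIT[draw_int(secrets, length(d), length(OFFSETS_SPLIT))]
  d2 <- d + s
  pad <- function(v, ref) {
    s <- as.character(v)
    paste0(strrep("0", pmax(nchar(ref) - nchar(s), 0L)), s)
  }
  list(day   = pad(as.integer(format(d2, "%d")), day),
       month = pad(as.integer(format(d2, "%m")), month),
       year  = pad(as.integer(format(d2, "%Y")), year))
}

# --- shift audit ------------------------------------------------------------

# The audit intentionally records only offset frequencies and counts of
# blanked unparsable values — never row indices, original values or
# shifted values — so it cannot serve as a de-anonymization key.
new_shift_audit <- function() {
  structure(list(), class = "shift_audit")
}

audit_add <- function(audit, key, offsets, unparsable) {
  tab <- table(offsets)
  audit[[key]] <- list(
    offsets = stats::setNames(as.integer(tab), names(tab)),
    unparsable = as.integer(unparsable)
  )
  audit
}

#' Combine shift audits from several tables
#'
#' @param ... `shift_audit` objects.
#' @return One merged `shift_audit`.
#' @export
merge_shift_audits <- function(...) {
  parts <- list(...)
  out <- new_shift_audit()
  for (p in parts) for (k in names(p)) out[[k]] <- p[[k]]
  out
}

#' @export
print.shift_audit <- function(x, ...) {
  cat(sprintf("<shift_audit: %d audited date field(s)/group(s)>\n", length(x)))
  for (k in names(x)) {
    cat(sprintf("  %s: %d shifts, %d unparsable blanked\n",
                k, sum(x[[k]]$offsets), x[[k]]$unparsable))
  }
  invisible(x)
}

# --- apply_measures ---------------------------------------------------------

#' Apply every dictionary measure to one table
#'
#' Transforms each field of `table` according to its measure in the
#' dictionary: `NO_ACTION` fields are byte-identical, `DELETION` columns
#' are blanked, `PSEUDONYMIZATION` columns are tokenized, and
#' `DATE_RANDOMIZATION` fields are shifted — combined-format fields by
#' ±3..6 days, split-date triples (bound by `date_group`) atomically by
#' ±2..10 days. Empty values always pass through empty. Row order, row
#' count and the column set are unchanged at this stage.
#'
#' Unparsable non-empty dates are handled per `bad_date_policy`:
#' `"blank"` replaces them with the empty value and counts them in the
#' audit; `"error"` aborts naming only the table and field (never the
#' offending value, which must not leak into logs).
#'
#' @param table A relational table.
#' @param dict A validated `data_dictionary`.
#' @param secrets The run's [run_secrets()].
#' @param bad_date_policy `"blank"` or `"error"`.
#' @return A list with components `table` (transformed) and `audit`
#'   (a `shift_audit`).
#' @export
apply_measures <- function(table, dict, secrets,
                           bad_date_policy = c("blank", "error")) {
  bad_date_policy <- match.arg(bad_date_policy)
  stopifnot(inherits(dict, "data_dictionary"), inherits(secrets, "run_secrets"))
  tn <- table_name(table)
  e <- dict$entries[dict$entries$table_name == tn, , drop = FALSE]
  missing <- setdiff(e$field_name, names(table))
  if (length(missing))
    stop_swapdata(sprintf("dictionary names field(s) absent from '%s': %s",
                          tn, paste(missing, collapse = ", ")))
  audit <- new_shift_audit()

  shift_field <- function(values, key, shifter) {
    empty <- values == ""
    parsed_ok <- !empty & !is.na(shifter$parse(values))
    bad <- !empty & !parsed_ok
    if (any(bad) && bad_date_policy == "error")
      stop_swapdata(sprintf("unparsable date in %s", key), "swapdata_date_parse_error")
    out <- values
    out[bad] <- ""
    if (any(parsed_ok)) out[parsed_ok] <- shifter$shift(values[parsed_ok])
    list(values = out, n_bad = sum(bad),
         offsets = if (any(parsed_ok))
           as.integer(shifter$days(out[parsed_ok]) - shifter$days(values[parsed_ok]))
         else integer(0))
  }

  # Combined-format single date fields.
  for (i in which(e$measure == "DATE_RANDOMIZATION" & e$date_group == "")) {
    f <- e$field_name[i]
    res <- shift_field(table[[f]], paste0(tn, ".", f), list(
      parse = parse_combined_date,
      shift = function(v) shift_date_combined(v, secrets),
      days = parse_combined_date))
    table[[f]] <- res$values
    audit <- audit_add(audit, paste0(tn, ".", f), res$offsets, res$n_bad)
  }

  # Split-date triples, processed atomically per date_group.
  for (g in unique(e$date_group[e$date_group != ""])) {
    sub <- e[e$date_group == g, , drop = FALSE]
    fd <- sub$field_name[sub$date_role == "day"]
    fm <- sub$field_name[sub$date_role == "month"]
    fy <- sub$field_name[sub$date_role == "year"]
    day <- table[[fd]]; month <- table[[fm]]; year <- table[[fy]]
    empty <- day == "" & month == "" & year == ""
    parsed <- parse_split_date(day, month, year)
    ok <- !empty & !is.na(parsed)
    bad <- !empty & !ok
    key <- paste0(tn, ".", g)
    if (any(bad) && bad_date_policy == "error")
      stop_swapdata(sprintf("unparsable date in %s", key), "swapdata_date_parse_error")
    day[bad] <- ""; month[bad] <- ""; year[bad] <- ""
    offsets <- integer(0)
    if (any(ok)) {
      shifted <- shift_date_split(day[ok], month[ok], year[ok], secrets)
      offsets <- as.integer(parse_split_date(shifted$day, shifted$month, shifted$year) -
                              parsed[ok])
      day[ok] <- shifted$day; month[ok] <- shifted$month; year[ok] <- shifted$year
    }
    table[[fd]] <- day; table[[fm]] <- month; table[[fy]] <- year
    audit <- audit_add(audit, key, offsets, sum(bad))
  }

  for (i in which(e$measure == "DELETION"))
    table <- delete_column(table, e$field_name[i])
  for (i in which(e$measure == "PSEUDONYMIZATION"))
    table <- pseudonymize_column(table, e$field_name[i], secrets)

  list(table = table, audit = audit)
}
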