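#' Pipeline configuration
#'
#' @param input_dir Directory holding one delimited text file per table.
#' @param dictionary_path Path to the data record description file.
#' @param output_dir Directory the anonymized tables and reports are
#'   written to.
#' @param swap A [swap_config()].
#' @param mode `"production"` (secure, non-seedable randomness; fresh
#'   salt; no intermediates) or `"test"` (seeded, reproducible).
#' @param test_seed,test_salt Seed / 16-byte raw salt, permitted only in
#'   test mode.
#' @param keep_intermediates Write the pre-swap (measured) and
#'   post-swap (unsampled) tables under `output_dir/intermediates/` for
#'   verification. Permitted only in test mode: intermediates retain
#'   pre-swap linkage and must never exist alongside a production export.
#' @param bad_date_policy `"blank"` (unparsable dates blanked and
#'   counted) or `"error"`.
#' @param unknown_policy `"error"` or `"delete"` for fields missing from
#'   the dictionary; see [validate_dictionary()].
#' @return A `pipeline_config` object.
#' @export
pipeline_config <- function(input_dir, dictionary_path, output_dir,
                            swap = swap_config(),
                            mode = c("production", "test"),
                            test_seed = NULL, test_salt = NULL,
                            keep_intermediates = FALSE,
                            bad_date_policy = c("blank", "error"),
                            unknown_policy = c("error", "delete")) {
  mode <- match.arg(mode)
  bad_date_policy <- match.arg(bad_date_policy)
  unknown_policy <- match.arg(unknown_policy)
  if (mode == "production" &&
      (!is.null(test_seed) || !is.null(test_salt) || isTRUE(keep_intermediates)))
    stop_swapdata(
      "test_seed, test_salt and keep_intermediates are only allowed in test mode",
      "swapdata_config_error")
  if (mode == "test" && is.null(test_seed))
    stop_swapdata("test mode requires test_seed", "swapdata_config_error")
  structure(list(input_dir = input_dir, dictionary_path = dictionary_path,
                 output_dir = output_dir, swap = swap, mode = mode,
                 test_seed = test_seed, test_salt = test_salt,
                 keep_intermediates = isTRUE(keep_intermediates),
                 bad_date_policy = bad_date_policy,
                 unknown_policy = unknown_policy),
            class = "pipeline_config")
}

#' Run the full anonymization pipeline
#'
#' Orchestrates dictionary validation, per-field measures, within-group
#' value swapping, exact-fraction row sampling, and output. The run is
#' fail-closed: all tables are read, validated and transformed in
#' memory first, and nothing is written unless every stage succeeded —
#' a partially anonymized export never reaches disk. Excluded tables
#' produce no output file. One salt and one randomness source serve the
#' whole run, so cross-table identifiers remain consistent up to the
#' swap stage. Output tables are written in exactly the input format
#' (same delimiter, quoting, header and column order).
#'
#' @param config A [pipeline_config()].
#' @return The run's `audit_report` (also written to
#'   `output_dir/report.json` and `report.txt`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dict <- load_dictionary(config$dictionary_path)
  tables <- read_table_dir(config$input_dir)
  dict <- validate_dictionary(dict, tables, config$unknown_policy)
  secrets <- run_secrets(config$mode, seed = config$test_seed,
                         salt = config$test_salt)
  message(sprintf("swapdata: %d table(s) read, %d excluded, %d dictionary entries",
                  length(tables), length(dict$excluded_tables), nrow(dict$entries)))

  out_tables <- list()
  measured_tables <- list()
  swapped_tables <- list()
  audit <- new_shift_audit()
  per_table <- list()
  for (tn in names(tables)) {
    if (tn %in% dict$excluded_tables) {
      per_table[[tn]] <- data.frame(table = tn, excluded = TRUE,
                                    rows_in = nrow(tables[[tn]]), rows_out = 0L,
                                    n_groups = 0L, min_group = NA_integer_,
                                    max_group = NA_integer_, n_merged_pools = 0L,
                                    stringsAsFactors = FALSE)
      next
    }
    meas <- apply_measures(tables[[tn]], dict, secrets, config$bad_date_policy)
    audit <- merge_shift_audits(audit, meas$audit)
    grouping <- build_entity_groups(meas$table, config$swap)
    swapped <- swap_within_groups(meas$table, grouping, secrets)
    sampled <- sample_rows(swapped, config$swap, secrets)
    measured_tables[[tn]] <- meas$table
    swapped_tables[[tn]] <- swapped
    out_tables[[tn]] <- sampled
    per_table[[tn]] <- data.frame(
      table = tn, excluded = FALSE,
      rows_in = nrow(tables[[tn]]), rows_out = nrow(sampled),
      n_groups = nrow(grouping$registry),
      min_group = if (nrow(grouping$registry)) min(grouping$registry$size) else NA_integer_,
      max_group = if (nrow(grouping$registry)) max(grouping$registry$size) else NA_integer_,
      n_merged_pools = sum(grouping$registry$merged),
      stringsAsFactors = FALSE)
    message(sprintf("swapdata: table %s: %d -> %d rows, %d group(s)",
                    tn, nrow(tables[[tn]]), nrow(sampled), nrow(grouping$registry)))
  }

  report <- build_audit_report(dict, do.call(rbind, per_table), audit, config)

  # All computation succeeded; only now touch the output directory.
  write_table_dir(out_tables, config$output_dir)
  if (config$keep_intermediates) {
    write_table_dir(measured_tables, file.path(config$output_dir, "intermediates", "measured"))
    write_table_dir(swapped_tables, file.path(config$output_dir, "intermediates", "swapped"))
  }
  save_audit_report(report, config$output_dir)
  invisible(report)
}

build_audit_report <- function(dict, per_table, audit, config) {
  rownames(per_table) <- NULL
  e <- dict$entries
  measure_counts <- vapply(MEASURES, function(m) sum(e$measure == m), 0L)
  totals <- list(
    tables_described = length(unique(e$table_name)) + length(dict$excluded_tables),
    tables_excluded = length(dict$excluded_tables),
    tables_output = sum(!per_table$excluded),
    fields_total = nrow(e),
    fields_modified = sum(e$measure != "NO_ACTION"))
  structure(list(tables = per_table, measure_counts = as.list(measure_counts),
                 shift_audit = audit, totals = totals,
                 k_min = config$swap$k_min,
                 sample_fraction = config$swap$sample_fraction,
                 icd_fields = as.list(config$swap$icd_fields),
                 icd_prefix_len = config$swap$icd_prefix_len,
                 mode = config$mode),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, ...) {
  t <- x$totals
  cat("<audit_report>\n")
  cat(sprintf("  tables: %d described, %d excluded, %d output\n",
              t$tables_described, t$tables_excluded, t$tables_output))
  cat(sprintf("  fields: %d total, %d modified (DEL %d / PSE %d / DATE %d), %d untouched\n",
              t$fields_total, t$fields_modified,
              x$measure_counts$DELETION, x$measure_counts$PSEUDONYMIZATION,
              x$measure_counts$DATE_RANDOMIZATION, x$measure_counts$NO_ACTION))
  cat(sprintf("  sampling: fraction %.2f; swap k_min %d\n", x$sample_fraction, x$k_min))
  for (i in seq_len(nrow(x$tables))) {
    r <- x$tables[i, ]
    cat(sprintf("  %s%s: %d -> %d rows\n", r$table,
                if (r$excluded) " (excluded)" else "", r$rows_in, r$rows_out))
  }
  invisible(x)
}

save_audit_report <- function(report, dir) {
  json <- list(tables = report$tables, measure_counts = report$measure_counts,
               shift_audit = lapply(unclass(report$shift_audit), function(a)
                 list(offsets = as.list(a$offsets), unparsable = a$unparsable)),
               totals = report$totals, k_min = report$k_min,
               sample_fraction = report$sample_fraction,
               icd_fields = report$icd_fields,
               icd_prefix_len = report$icd_prefix_len, mode = report$mode)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(report)
}

#' Load a saved audit report
#'
#' @param path Path to a `report.json` written by [run_pipeline()].
#' @return An `audit_report`.
#' @export
load_audit_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  audit <- new_shift_audit()
  for (k in names(j$shift_audit)) {
    a <- j$shift_audit[[k]]
    audit[[k]] <- list(offsets = unlist(a$offsets),
                       unparsable = as.integer(a$unparsable))
  }
  structure(list(tables = as.data.frame(j$tables),
                 measure_counts = as.list(j$measure_counts),
                 shift_audit = audit, totals = as.list(j$totals),
                 k_min = as.integer(j$k_min),
                 sample_fraction = as.numeric(j$sample_fraction),
                 icd_fields = unlist(j$icd_fields),
                 icd_prefix_len = as.integer(j$icd_prefix_len),
                 mode = j$mode),
            class = "audit_report")
}
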