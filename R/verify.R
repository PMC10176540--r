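#' Verify a completed anonymization run
#'
#' Independently audits the output of [run_pipeline()] against the
#' inputs and the data record description. Checks:
#'
#' * `deletion_columns_empty` — every `DELETION` column in every output
#'   table is entirely empty;
#' * `no_raw_identifier_leak` — no non-empty value from any input
#'   `DELETION` or `PSEUDONYMIZATION` column appears anywhere in any
#'   output table;
#' * `row_counts` — each output table has exactly
#'   `n - floor(sample_fraction * n)` rows;
#' * `excluded_absent` — excluded tables produced no output file;
#' * `multiset_conservation` (test-mode intermediates only) — for every
#'   entity group and column, the swapped table holds exactly the same
#'   value multiset as the measured (pre-swap) table;
#' * `shift_bounds` (intermediates only) — every applied date shift lies
#'   in its admissible offset set (±3..6 combined, ±2..10 split);
#' * `group_min_size` — no ICD-grouped table has an entity group below
#'   `k_min` (when the table has at least `k_min` rows);
#' * `headers_identical` — output headers and column order match the
#'   input exactly.
#'
#' Checks that need intermediates are reported as `skip` when none are
#' available (the production case), never as failures.
#'
#' @param input_dir,output_dir The run's input and output directories.
#' @param dictionary_path Path to the dictionary file used for the run.
#' @param report The run's `audit_report` (object or path to
#'   `report.json`).
#' @param intermediates Optional path to `output_dir/intermediates`.
#' @return A `verification_report`: data.frame of (check, table, status,
#'   detail) with attribute `passed` (TRUE iff no check failed).
#' @export
verify_output <- function(input_dir, output_dir, dictionary_path, report,
                          intermediates = NULL) {
  if (is.character(report)) report <- load_audit_report(report)
  stopifnot(inherits(report, "audit_report"))
  dict <- load_dictionary(dictionary_path)
  input <- read_table_dir(input_dir)
  output_files <- list.files(output_dir, pattern = "\\.csv$")
  output <- read_table_dir(output_dir)
  e <- dict$entries
  rows <- list()
  note <- function(check, table, status, detail = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      check = check, table = table, status = status, detail = detail,
      stringsAsFactors = FALSE)
  }

  # (a) deletion columns empty
  for (tn in names(output)) {
    del_fields <- e$field_name[e$table_name == tn & e$measure == "DELETION"]
    for (f in intersect(del_fields, names(output[[tn]]))) {
      bad <- sum(output[[tn]][[f]] != "")
      note("deletion_columns_empty", tn,
           if (bad == 0L) "pass" else "fail",
           if (bad > 0L) sprintf("column %s has %d non-empty value(s)", f, bad) else f)
    }
  }

  # (b) raw-identifier leak scan: no protected input value survives anywhere
  protected <- unique(unlist(lapply(names(input), function(tn) {
    fields <- e$field_name[e$table_name == tn &
                             e$measure %in% c("DELETION", "PSEUDONYMIZATION")]
    unlist(lapply(intersect(fields, names(input[[tn]])),
                  function(f) input[[tn]][[f]]))
  }), use.names = FALSE))
  protected <- protected[protected != ""]
  for (tn in names(output)) {
    leak_cols <- names(output[[tn]])[vapply(output[[tn]], function(col)
      any(col %in% protected), TRUE)]
    note("no_raw_identifier_leak", tn,
         if (!length(leak_cols)) "pass" else "fail",
         if (length(leak_cols))
           sprintf("raw protected value(s) found in column(s): %s",
                   paste(leak_cols, collapse = ", ")) else "")
  }

  # (c) exact-fraction row counts
  f <- report$sample_fraction
  for (tn in names(output)) {
    if (!tn %in% names(input)) next
    n_in <- nrow(input[[tn]])
    expect <- n_in - floor(f * n_in)
    note("row_counts", tn,
         if (nrow(output[[tn]]) == expect) "pass" else "fail",
         sprintf("expected %d, found %d", expect, nrow(output[[tn]])))
  }

  # (d) excluded tables absent
  for (tn in dict$excluded_tables) {
    present <- paste0(tn, ".csv") %in% output_files
    note("excluded_absent", tn, if (!present) "pass" else "fail",
         if (present) "excluded table present in output" else "")
  }

  # (e) multiset conservation + shift bounds (need test-mode intermediates)
  swap_cfg <- swap_config(
    icd_fields = if (length(report$icd_fields))
      unlist(report$icd_fields) else character(),
    k_min = report$k_min, sample_fraction = report$sample_fraction,
    icd_prefix_len = report$icd_prefix_len)
  if (!is.null(intermediates) && dir.exists(file.path(intermediates, "measured"))) {
    measured <- read_table_dir(file.path(intermediates, "measured"))
    swapped <- read_table_dir(file.path(intermediates, "swapped"))
    for (tn in names(measured)) {
      grouping <- build_entity_groups(measured[[tn]], swap_cfg)
      ok <- TRUE; why <- ""
      for (g in unique(grouping$assignment)) {
        idx <- which(grouping$assignment == g)
        for (col in names(measured[[tn]])) {
          if (!identical(sort(measured[[tn]][[col]][idx]),
                         sort(swapped[[tn]][[col]][idx]))) {
            ok <- FALSE
            why <- sprintf("multiset differs in group %s, column %s", g, col)
            break
          }
        }
        if (!ok) break
      }
      note("multiset_conservation", tn, if (ok) "pass" else "fail", why)
    }
    for (tn in names(measured)) {
      et <- e[e$table_name == tn & e$measure == "DATE_RANDOMIZATION", , drop = FALSE]
      for (i in seq_len(nrow(et))) {
        if (et$date_group[i] != "" && et$date_role[i] != "day") next
        if (et$date_group[i] == "") {
          d_in <- parse_combined_date(input[[tn]][[et$field_name[i]]])
          d_out <- parse_combined_date(measured[[tn]][[et$field_name[i]]])
          admissible <- OFFSETS_COMBINED
          key <- paste0(tn, ".", et$field_name[i])
        } else {
          g <- et$date_group[i]
          sub <- e[e$table_name == tn & e$date_group == g, , drop = FALSE]
          fd <- sub$field_name[sub$date_role == "day"]
          fm <- sub$field_name[sub$date_role == "month"]
          fy <- sub$field_name[sub$date_role == "year"]
          d_in <- parse_split_date(input[[tn]][[fd]], input[[tn]][[fm]],
                                   input[[tn]][[fy]])
          d_out <- parse_split_date(measured[[tn]][[fd]], measured[[tn]][[fm]],
                                    measured[[tn]][[fy]])
          admissible <- OFFSETS_SPLIT
          key <- paste0(tn, ".", g)
        }
        both <- !is.na(d_in) & !is.na(d_out)
        shifts <- as.integer(d_out[both] - d_in[both])
        bad <- sum(!(shifts %in% admissible))
        note("shift_bounds", tn, if (bad == 0L) "pass" else "fail",
             sprintf("%s: %d shift(s) outside admissible set", key, bad))
      }
    }
  } else {
    note("multiset_conservation", "*", "skip", "no intermediates available")
    note("shift_bounds", "*", "skip", "no intermediates available")
  }

  # (f) minimum entity-group size on ICD-grouped tables
  grouped_tables <- names(swap_cfg$icd_fields)
  for (i in seq_len(nrow(report$tables))) {
    r <- report$tables[i, ]
    if (r$excluded || !r$table %in% grouped_tables) next
    if (is.na(r$min_group) || r$rows_in < report$k_min) {
      note("group_min_size", r$table, "skip", "table smaller than k_min")
    } else {
      note("group_min_size", r$table,
           if (r$min_group >= report$k_min) "pass" else "fail",
           sprintf("min group size %d (k_min %d)", r$min_group, report$k_min))
    }
  }

  # (g) headers and column order identical to input
  for (tn in names(output)) {
    if (!tn %in% names(input)) {
      note("headers_identical", tn, "fail", "output table has no input counterpart")
      next
    }
    same <- identical(names(input[[tn]]), names(output[[tn]]))
    note("headers_identical", tn, if (same) "pass" else "fail",
         if (!same) "column names/order differ from input" else "")
  }

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("verification_report", "data.frame"),
            passed = !any(out$status == "fail"))
}

#' @export
print.verification_report <- function(x, ...) {
  agg <- table(factor(x$status, levels = c("pass", "fail", "skip")))
  cat(sprintf("<verification_report: %d pass, %d fail, %d skip>\n",
              agg[["pass"]], agg[["fail"]], agg[["skip"]]))
  shown <- x[x$status != "pass", , drop = FALSE]
  for (i in seq_len(nrow(shown)))
    cat(sprintf("  [%s] %s %s: %s\n", shown$status[i], shown$check[i],
                shown$table[i], shown$detail[i]))
  invisible(x)
}

#' Did a verification pass?
#'
#' @param v A `verification_report`.
#' @return TRUE iff no check failed.
#' @export
verification_passed <- function(v) isTRUE(attr(v, "passed"))
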