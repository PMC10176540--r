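test_that("extract_schema builds one NO_ACTION entry per field, in table order", {
  tables <- list(make_table("TZVS", TZ_P_PID = character(0)),
                 make_table("NPAT", Nname = character(0)))
  d <- extract_schema(tables)
  expect_s3_class(d, "data_dictionary")
  expect_equal(d$entries$table_name, c("TZVS", "NPAT"))
  expect_equal(d$entries$field_name, c("TZ_P_PID", "Nname"))
  expect_true(all(d$entries$measure == "NO_ACTION"))
  expect_length(d$excluded_tables, 0)

  # Schema extraction ignores rows: a zero-row table still yields entries.
  empty3 <- make_table("E", a = character(0), b = character(0), c = character(0))
  expect_equal(nrow(extract_schema(list(empty3))$entries), 3)
})

test_that("extract_schema entry count equals the independent column count", {
  set.seed(4)
  tables <- lapply(1:10, function(i) {
    ncols <- sample(2:8, 1)
    df <- as.data.frame(setNames(replicate(ncols, "x", simplify = FALSE),
                                 paste0("f", seq_len(ncols))))
    relational_table(df, paste0("TAB", i))
  })
  # Oracle: count headers directly, independent of the dictionary code.
  expected <- sum(vapply(tables, function(t) length(names(t)), 0L))
  expect_equal(nrow(extract_schema(tables)$entries), expected)
})

test_that("extract_schema rejects duplicate table and field names", {
  t1 <- make_table("A", x = "1")
  expect_error(extract_schema(list(t1, t1)), "duplicate table names")
  df <- data.frame(x = "1", y = "2")
  names(df) <- c("x", "x")
  expect_error(extract_schema(list(relational_table(df, "B"))), "duplicate field")
})

test_that("load_dictionary parses measures case-insensitively and maps exclusions", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(
    "table_name,field_name,description,measure,date_group,date_role",
    "TZTH,TZTH_A_BDD,Start of therapy,Date randomization,,",
    "NPAT,Nname,Last name,Deletion,,",
    "TZVS,TZ_P_PID,Patient ID, pseudonymization ,,",
    "TZES,TZ_LOEKZ,Deletion indicator,No Action,,",
    "3CTDOKU,,,Excluded,,"), path)
  d <- load_dictionary(path)
  e <- d$entries
  expect_equal(e$measure[e$field_name == "TZTH_A_BDD"], "DATE_RANDOMIZATION")
  expect_equal(e$measure[e$field_name == "Nname"], "DELETION")
  expect_equal(e$measure[e$field_name == "TZ_P_PID"], "PSEUDONYMIZATION")
  expect_equal(e$measure[e$field_name == "TZ_LOEKZ"], "NO_ACTION")
  expect_equal(d$excluded_tables, "3CTDOKU")
})

test_that("load_dictionary reports unknown measures with the file row", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("table_name,field_name,description,measure",
               "A,x,,No Action",
               "A,y,,Redaction"), path)
  expect_error(load_dictionary(path), "unknown measure 'Redaction' at file row 3")
})

test_that("load_dictionary rejects malformed split-date groups", {
  path <- withr::local_tempfile(fileext = ".csv")
  # Cross-table group
  writeLines(c("table_name,field_name,description,measure,date_group,date_role",
               "A,d,,Date Randomization,g1,day",
               "A,m,,Date Randomization,g1,month",
               "B,y,,Date Randomization,g1,year"), path)
  expect_error(load_dictionary(path), "spans multiple tables")
  # Missing role
  writeLines(c("table_name,field_name,description,measure,date_group,date_role",
               "A,d,,Date Randomization,g1,day",
               "A,m,,Date Randomization,g1,month"), path)
  expect_error(load_dictionary(path), "exactly one day, one month and one year")
})

test_that("empty dictionary file loads as an empty dictionary", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("table_name,field_name,description,measure,date_group,date_role", path)
  d <- load_dictionary(path)
  expect_equal(nrow(d$entries), 0)
  expect_length(d$excluded_tables, 0)
})

test_that("dictionary save/load round trip is the identity, including date groups", {
  d <- data_dictionary(data.frame(
    table_name = c("P", "P", "P", "P", "T"),
    field_name = c("id", "bd", "bm", "by", "code"),
    description = c("Patient ID", "Birth day", "Birth month", "Birth year", "ICD"),
    measure = c("PSEUDONYMIZATION", rep("DATE_RANDOMIZATION", 3), "NO_ACTION"),
    date_group = c("", "birth", "birth", "birth", ""),
    date_role = c("", "day", "month", "year", ""),
    stringsAsFactors = FALSE), excluded_tables = "SYS")
  path <- withr::local_tempfile(fileext = ".csv")
  save_dictionary(d, path)
  expect_identical(load_dictionary(path), d)
  # Saving twice is byte-identical.
  path2 <- withr::local_tempfile(fileext = ".csv")
  save_dictionary(d, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})

test_that("validate_dictionary covers, synthesizes DELETION entries, and is idempotent", {
  tables <- list(make_table("A", x = "1", y = "2"))
  full <- extract_schema(tables)
  expect_identical(validate_dictionary(full, tables), full)

  # Field of unknown meaning: truncated under the delete policy.
  partial <- data_dictionary(full$entries[full$entries$field_name != "y", ])
  expect_error(validate_dictionary(partial, tables, "error"), "A\\.y")
  fixed <- validate_dictionary(partial, tables, "delete")
  new_entry <- fixed$entries[fixed$entries$field_name == "y", ]
  expect_equal(new_entry$measure, "DELETION")
  expect_equal(new_entry$description, "")
  expect_identical(validate_dictionary(fixed, tables, "delete"), fixed)

  # Stale entry referencing a field absent from the data.
  stale <- data_dictionary(rbind(full$entries, data.frame(
    table_name = "A", field_name = "ghost", description = "",
    measure = "NO_ACTION", date_group = "", date_role = "")))
  expect_error(validate_dictionary(stale, tables), "stale")
})

test_that("extract_schema then validate_dictionary never errors", {
  for (seed in 1:5) {
    set.seed(seed)
    tables <- lapply(1:3, function(i) {
      ncols <- sample(1:6, 1)
      df <- as.data.frame(setNames(replicate(ncols, "v", simplify = FALSE),
                                   paste0("c", seq_len(ncols))))
      relational_table(df, paste0("T", i))
    })
    expect_no_error(validate_dictionary(extract_schema(tables), tables))
  }
})

test_that("excluded tables must be disjoint from described tables", {
  e <- data.frame(table_name = "A", field_name = "x", description = "",
                  measure = "NO_ACTION", date_group = "", date_role = "")
  expect_error(data_dictionary(e, excluded_tables = "A"), "excluded tables")
})
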