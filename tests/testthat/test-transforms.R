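test_that("deletion erases every value but keeps the column", {
  t <- make_table("NPAT", first_name = c("Max", "Daniel", "Julia"),
                  last_name = c("Mustermann", "Nasseh", "Kasprzak"))
  out <- delete_column(t, "first_name")
  expect_equal(out$first_name, c("", "", ""))
  expect_equal(out$last_name, t$last_name)
  expect_equal(names(out), names(t))
  # Idempotent, and row count never changes.
  expect_identical(delete_column(out, "first_name"), out)
  big <- make_table("N", full_name = sprintf("name%04d", 1:1000))
  wiped <- delete_column(big, "full_name")
  expect_equal(nrow(wiped), 1000)
  expect_equal(sum(wiped$full_name != ""), 0)
  expect_error(delete_column(t, "nope"), "no field")
})

test_that("pseudonymization is salted SHA3-256 of value bytes followed by the salt", {
  # Frozen oracle: hex digest of utf8("0022113344") || 16 zero bytes,
  # computed with an independent SHA-3 implementation.
  t <- make_table("TZVS", pid = c("0022113344", "0022113344", ""))
  out <- pseudonymize_column(t, "pid", test_secrets(salt = as.raw(rep(0L, 16L))))
  expect_equal(out$pid[1],
    "d8d3cec459008576d146c5211b2cc90a95bc4187bd22e46d325572bd997bfd80")
  # Determinism within a run; empty stays empty; token format.
  expect_equal(out$pid[1], out$pid[2])
  expect_equal(out$pid[3], "")
  expect_match(out$pid[1], "^[0-9a-f]{64}$")
})

test_that("pseudonym tokens differ across fresh production runs", {
  t <- make_table("TZVS", pid = c("0022113344", "0012345678"))
  a <- pseudonymize_column(t, "pid", run_secrets("production"))
  b <- pseudonymize_column(t, "pid", run_secrets("production"))
  expect_false(any(a$pid == b$pid))
})

test_that("combined-format shifts stay within 3..6 days and remain format-preserving", {
  secrets <- test_secrets(seed = 10)
  dates <- random_combined_dates(2000)
  shifted <- shift_date_combined(dates, secrets)
  s <- days_between(dates, shifted)
  expect_true(all(abs(s) >= 3 & abs(s) <= 6))
  expect_true(any(s > 0) && any(s < 0))
  expect_true(setequal(unique(s), c(-6:-3, 3:6)))
  expect_true(all(grepl("^\\d{2}\\.\\d{2}\\.\\d{4}$", shifted)))
  # Uniformity over the 8 admissible offsets: chi-square should not
  # reject at alpha = 0.001.
  p <- stats::chisq.test(table(factor(s, levels = c(-6:-3, 3:6))))$p.value
  expect_gt(p, 0.001)
})

test_that("combined shifts roll over month and year boundaries correctly", {
  secrets <- test_secrets(seed = 3)
  out <- shift_date_combined(rep("27.12.2015", 200), secrets)
  # Every outcome must re-parse; the +5 outcome is the year rollover.
  d <- as.Date(out, "%d.%m.%Y")
  expect_false(anyNA(d))
  expect_true("01.01.2016" %in% out)
  expect_error(shift_date_combined("00.13.2020", secrets),
               class = "swapdata_date_parse_error")
  expect_error(shift_date_combined("31.02.2019", secrets),
               class = "swapdata_date_parse_error")
  expect_error(shift_date_combined("1.4.2021", secrets),  # not zero-padded
               class = "swapdata_date_parse_error")
})

test_that("split-format shifts stay within 2..10 days and preserve column padding", {
  secrets <- test_secrets(seed = 11)
  n <- 2000
  base <- as.Date("2000-01-15") + sample.int(8000, n, replace = TRUE)
  day <- format(base, "%d"); month <- format(base, "%m"); year <- format(base, "%Y")
  out <- shift_date_split(day, month, year, secrets)
  d2 <- as.Date(sprintf("%s-%s-%s", out$year, out$month, out$day))
  expect_false(anyNA(d2))
  s <- as.integer(d2 - base)
  expect_true(all(abs(s) >= 2 & abs(s) <= 10))
  expect_true(setequal(unique(s), c(-10:-2, 2:10)))
  expect_true(all(nchar(out$day) == 2 & nchar(out$month) == 2 & nchar(out$year) == 4))
  # Unpadded inputs keep their own width where possible.
  one <- shift_date_split("5", "4", "2018", test_secrets(seed = 2))
  expect_true(nchar(one$month) >= 1)
  expect_error(shift_date_split("32", "01", "2020", secrets),
               class = "swapdata_date_parse_error")
})

test_that("apply_measures transforms exactly the flagged columns", {
  n <- 50
  set.seed(8)
  df <- as.data.frame(setNames(lapply(1:10, function(i) sprintf("v%d_%03d", i, 1:n)),
                               paste0("f", 1:10)))
  df$f4 <- random_combined_dates(n)
  t <- relational_table(df, "T")
  e <- extract_schema(list(t))$entries
  e$measure[e$field_name %in% c("f1", "f2")] <- "DELETION"
  e$measure[e$field_name == "f3"] <- "PSEUDONYMIZATION"
  e$measure[e$field_name == "f4"] <- "DATE_RANDOMIZATION"
  res <- apply_measures(t, data_dictionary(e), test_secrets())
  changed <- names(t)[vapply(names(t), function(f) !identical(t[[f]], res$table[[f]]), TRUE)]
  expect_setequal(changed, c("f1", "f2", "f3", "f4"))
  expect_equal(nrow(res$table), n)
  expect_equal(names(res$table), names(t))

  # All-NO_ACTION dictionary: output identical to input.
  res0 <- apply_measures(t, extract_schema(list(t)), test_secrets())
  expect_identical(res0$table, t)
})

test_that("apply_measures blanks unparsable dates and audits them without values", {
  t <- make_table("T", d = c("01.04.2021", "00.13.2020", ""))
  e <- extract_schema(list(t))$entries
  e$measure <- "DATE_RANDOMIZATION"
  dict <- data_dictionary(e)
  res <- apply_measures(t, dict, test_secrets(), bad_date_policy = "blank")
  expect_equal(res$table$d[2], "")
  expect_equal(res$table$d[3], "")  # empty in, empty out, not counted
  expect_equal(res$audit[["T.d"]]$unparsable, 1L)
  # Audit holds only offset frequencies, never values or row indices.
  expect_named(res$audit[["T.d"]], c("offsets", "unparsable"))
  expect_false(any(grepl("2021", names(res$audit[["T.d"]]$offsets))))

  # Error policy aborts naming table/field but never the value itself.
  err <- tryCatch(apply_measures(t, dict, test_secrets(), bad_date_policy = "error"),
                  error = identity)
  expect_s3_class(err, "swapdata_date_parse_error")
  expect_match(conditionMessage(err), "T\\.d")
  expect_false(grepl("00.13.2020", conditionMessage(err), fixed = TRUE))
})

test_that("split date triples are processed atomically per date_group", {
  base <- as.Date("2014-01-10") + c(0, 250, 4000)
  t <- make_table("P",
                  id = c("a", "b", "c"),
                  bd = format(base, "%d"), bm = format(base, "%m"),
                  by = format(base, "%Y"))
  e <- extract_schema(list(t))$entries
  e$measure[2:4] <- "DATE_RANDOMIZATION"
  e$date_group[2:4] <- "birth"
  e$date_role[2:4] <- c("day", "month", "year")
  res <- apply_measures(t, data_dictionary(e), test_secrets(seed = 5))
  d2 <- as.Date(sprintf("%s-%s-%s", res$table$by, res$table$bm, res$table$bd))
  s <- as.integer(d2 - base)
  expect_true(all(abs(s) >= 2 & abs(s) <= 10))
  expect_equal(sum(res$audit[["P.birth"]]$offsets), 3)
})

test_that("apply_measures is bit-reproducible with fixed seed and salt", {
  reg <- generate_registry(registry_config(n_patients = 60, seed = 7))
  for (tn in names(reg$tables)) {
    a <- apply_measures(reg$tables[[tn]], reg$dictionary, test_secrets(seed = 42))
    b <- apply_measures(reg$tables[[tn]], reg$dictionary, test_secrets(seed = 42))
    expect_identical(a, b)
  }
})

test_that("pseudonymization shows no collisions on a large distinct corpus", {
  secrets <- test_secrets()
  n <- 50000
  t <- relational_table(data.frame(v = sprintf("subject-%07d", seq_len(n))), "T")
  out <- pseudonymize_column(t, "v", secrets)
  expect_equal(length(unique(out$v)), n)
})
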