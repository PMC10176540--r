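# Small in-code fixtures shared across test files.

make_table <- function(name, ...) {
  relational_table(data.frame(..., stringsAsFactors = FALSE), name)
}

test_secrets <- function(seed = 1L, salt = as.raw(rep(0L, 16L))) {
  run_secrets("test", seed = seed, salt = salt)
}

# A small registry with pathologies, written to disk; returns paths.
write_small_registry <- function(dir, n_patients = 250L, seed = 99L,
                                 inject = TRUE) {
  cfg <- registry_config(n_patients = n_patients, seed = seed)
  reg <- generate_registry(cfg)
  tabs <- if (inject) inject_pathologies(reg$tables, cfg) else reg$tables
  input <- file.path(dir, "input")
  write_table_dir(tabs, input)
  dict_path <- file.path(dir, "dictionary.csv")
  save_dictionary(reg$dictionary, dict_path)
  list(input = input, dictionary = dict_path, tables = tabs,
       dict = reg$dictionary, config = cfg)
}

# Day-difference oracle between two DD.MM.YYYY strings.
days_between <- function(from, to) {
  as.integer(as.Date(to, "%d.%m.%Y") - as.Date(from, "%d.%m.%Y"))
}

# Random valid DD.MM.YYYY dates (uses the current RNG state).
random_combined_dates <- function(n, from = "1950-01-01", to = "2022-12-31") {
  span <- as.integer(as.Date(to) - as.Date(from))
  format(as.Date(from) + sample.int(span + 1L, n, replace = TRUE) - 1L,
         "%d.%m.%Y")
}
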