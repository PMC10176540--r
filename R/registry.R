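# Deterministic seed scoping: run code under a given seed and restore
# the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Default ICD-10 code frequency distribution
#'
#' A tumor-entity mix with a handful of frequent categories (breast
#' `C50`, lung `C34`, colon `C18`, prostate `C61`, pancreas `C25`, ...)
#' and a long tail of rare codes whose 3-character groups stay well
#' below the k = 25 merge threshold at the default registry size, so
#' the small-group merging logic is always exercised.
#'
#' @return A data.frame with columns `code` and `weight`.
#' @export
default_icd_distribution <- function() {
  common <- data.frame(
    code = c("C50.1", "C50.4", "C50.8", "C50.9",
             "C34.1", "C34.2", "C34.8", "C34.9",
             "C18.2", "C18.7", "C18.9",
             "C61", "C25.0", "C25.9", "C20", "C16.9", "C64",
             "C67.9", "C43.9", "C56", "C71.9", "C15.9", "C92.0"),
    weight = c(0.030, 0.060, 0.030, 0.060,
               0.035, 0.035, 0.020, 0.050,
               0.030, 0.030, 0.040,
               0.080, 0.030, 0.030, 0.050, 0.040, 0.040,
               0.030, 0.030, 0.030, 0.020, 0.020, 0.020),
    stringsAsFactors = FALSE)
  rare <- data.frame(
    code = c("C17.9", "C22.1", "C23", "C24.9", "C26.0",
             "C30.0", "C31.9", "C37", "C38.4", "C40.2",
             "C41.9", "C45.0", "C46.9", "C48.2", "C49.9",
             "C58", "C62.9", "C69.9", "C73", "C74.9"),
    weight = rep(0.0015, 20L),
    stringsAsFactors = FALSE)
  rbind(common, rare)
}

#' Synthetic registry configuration
#'
#' @param n_patients Number of patients to generate (each has one or
#'   more tumors). Default 2000.
#' @param icd_distribution Data.frame with `code` and positive `weight`
#'   columns; see [default_icd_distribution()].
#' @param missingness Named list mapping field names to the probability
#'   that a value is empty. Fields not listed are always present.
#' @param date_window Length-2 `Date` (or `DD.MM.YYYY` character)
#'   vector: earliest and latest diagnosis/therapy date.
#' @param seed Integer seed; generation is fully deterministic given the
#'   configuration.
#' @return A `registry_config` object.
#' @export
registry_config <- function(n_patients = 2000L,
                            icd_distribution = default_icd_distribution(),
                            missingness = list(
                              first_name = 0.01, last_name = 0.01,
                              address = 0.05, birth = 0.02,
                              diagnosis_date = 0.03,
                              therapy_start_date = 0.05, therapy_type = 0.20,
                              gene = 0.10, variant = 0.15),
                            date_window = as.Date(c("2005-01-01", "2022-12-31")),
                            seed = 1905L) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) stop_swapdata("n_patients must be >= 1", "swapdata_config_error")
  stopifnot(is.data.frame(icd_distribution),
            all(c("code", "weight") %in% names(icd_distribution)))
  if (any(icd_distribution$weight <= 0))
    stop_swapdata("icd_distribution weights must be positive", "swapdata_config_error")
  if (is.character(date_window)) date_window <- as.Date(date_window, format = "%d.%m.%Y")
  if (anyNA(date_window) || length(date_window) != 2L || date_window[1] >= date_window[2])
    stop_swapdata("date_window must be two dates with earliest < latest",
                  "swapdata_config_error")
  structure(list(n_patients = n_patients, icd_distribution = icd_distribution,
                 missingness = missingness, date_window = date_window,
                 seed = as.integer(seed)),
            class = "registry_config")
}

# Deterministic fake-identity pools. All names and places are invented;
# no real-person data enters any fixture.
FAKE_FIRST <- c("Anton", "Berta", "Clara", "Dorian", "Elif", "Fritz", "Greta",
                "Hanno", "Ines", "Jorin", "Katja", "Lenz", "Mira", "Nuri",
                "Ottilie", "Pavel", "Quirin", "Ronja", "Sören", "Tilda",
                "Udo", "Vera", "Wim", "Xenia", "Yunus", "Zora")
FAKE_LAST <- c("Ackermann", "Brandt", "Claussen", "Dreyer", "Eckstein",
               "Falkner", "Grünwald", "Hartmann", "Ilgner", "Jessen",
               "Kästner", "Lindner", "Moosbauer", "Nehring", "Oberle",
               "Pfeiffer", "Quast", "Rothe", "Steinbach", "Tannberg",
               "Ullmann", "Vogelsang", "Wendland", "Ysenburg", "Zöllner")
FAKE_STREET <- c("Ahornweg", "Birkenallee", "Dorfstraße", "Eichenpfad",
                 "Feldgasse", "Gartenring", "Hauptstraße", "Lindenhof",
                 "Mühlenweg", "Nelkenweg", "Parkallee", "Rosenpfad",
                 "Schulstraße", "Talweg", "Ufergasse", "Wiesenweg")
FAKE_CITY <- c("Altdorf", "Buchheim", "Dornstadt", "Eschenau", "Falkensee",
               "Grünberg", "Hohenfels", "Lindau", "Mosbach", "Neuwied",
               "Obertal", "Rodenbach", "Seeheim", "Talheim", "Unterfeld",
               "Weilburg")
THERAPY_TYPES <- c("Chemotherapy", "Radiotherapy", "Surgery", "Immunotherapy",
                   "Hormone therapy", "Targeted therapy", "Watchful waiting")
GENES <- c("TP53", "KRAS", "EGFR", "BRAF", "PIK3CA", "BRCA1", "BRCA2",
           "ERBB2", "ALK", "MET", "NRAS", "APC", "PTEN", "ATM", "RET")
VARIANTS <- c("p.G12D", "p.G12V", "p.V600E", "p.L858R", "p.E545K",
              "c.68_69del", "c.5266dup", "amplification", "exon 19 deletion",
              "p.R175H", "p.Q61K", "splice site", "frameshift", "wild type")

fmt_combined <- function(d) format(d, "%d.%m.%Y")

rand_dates <- function(n, window) {
  window[1] + sample.int(as.integer(window[2] - window[1]) + 1L, n, replace = TRUE) - 1L
}

apply_missing <- function(x, p) {
  if (is.null(p) || p <= 0) return(x)
  x[stats::runif(length(x)) < p] <- ""
  x
}

#' Generate a linked synthetic tumor registry
#'
#' Emulates the multi-table structure of a hospital tumor-documentation
#' system plus a molecular-pathology database, so the whole anonymization
#' pipeline can be developed and tested without any real patient data.
#' Four referentially consistent tables are produced:
#'
#' * `PATIENTS` — patient ID, first/last name, birth date as three split
#'   columns (day/month/year), address;
#' * `TUMORS` — tumor ID, patient ID, ICD-10 code drawn from the
#'   configured distribution, diagnosis date in combined `DD.MM.YYYY`
#'   format;
#' * `THERAPIES` — therapy ID, tumor ID, start date (combined format),
#'   therapy-type text;
#' * `MOLPATH` — sample ID, tumor ID, gene symbol, variant text.
#'
#' The matching data dictionary assigns names/addresses to `DELETION`,
#' all cross-table IDs to `PSEUDONYMIZATION`, all dates to
#' `DATE_RANDOMIZATION` (the birth-date columns bound into one split
#' `date_group`), and everything else to `NO_ACTION`.
#'
#' @param config A [registry_config()].
#' @return A list with components `tables` (named list of relational
#'   tables) and `dictionary` (a `data_dictionary`).
#' @export
generate_registry <- function(config) {
  stopifnot(inherits(config, "registry_config"))
  with_seed(config$seed, {
    np <- config$n_patients
    miss <- config$missingness

    patient_id <- sprintf("%010d", sample.int(999999999L, np))
    birth <- as.Date("1930-01-01") +
      sample.int(as.integer(as.Date("1995-12-31") - as.Date("1930-01-01")) + 1L,
                 np, replace = TRUE) - 1L
    birth_gone <- stats::runif(np) < (if (is.null(miss$birth)) 0 else miss$birth)
    patients <- relational_table(data.frame(
      patient_id = patient_id,
      first_name = apply_missing(sample(FAKE_FIRST, np, replace = TRUE), miss$first_name),
      last_name = apply_missing(sample(FAKE_LAST, np, replace = TRUE), miss$last_name),
      birth_day = ifelse(birth_gone, "", format(birth, "%d")),
      birth_month = ifelse(birth_gone, "", format(birth, "%m")),
      birth_year = ifelse(birth_gone, "", format(birth, "%Y")),
      address = apply_missing(
        paste0(sample(FAKE_STREET, np, replace = TRUE), " ",
               sample.int(120L, np, replace = TRUE), ", ",
               sprintf("%05d", sample.int(99999L, np, replace = TRUE)), " ",
               sample(FAKE_CITY, np, replace = TRUE)),
        miss$address),
      stringsAsFactors = FALSE), "PATIENTS")

    n_tum_per <- 1L + stats::rpois(np, 0.5)
    nt <- sum(n_tum_per)
    tum_patient <- rep(patient_id, n_tum_per)
    w <- config$icd_distribution$weight / sum(config$icd_distribution$weight)
    tumors <- relational_table(data.frame(
      tumor_id = sprintf("T%09d", sample.int(999999999L, nt)),
      patient_id = tum_patient,
      icd10_code = sample(config$icd_distribution$code, nt, replace = TRUE, prob = w),
      diagnosis_date = apply_missing(fmt_combined(rand_dates(nt, config$date_window)),
                                     miss$diagnosis_date),
      stringsAsFactors = FALSE), "TUMORS")

    n_th_per <- stats::rpois(nt, 1.0)
    nh <- sum(n_th_per)
    therapies <- relational_table(data.frame(
      therapy_id = sprintf("H%09d", sample.int(999999999L, nh)),
      tumor_id = rep(tumors$tumor_id, n_th_per),
      therapy_start_date = apply_missing(fmt_combined(rand_dates(nh, config$date_window)),
                                         miss$therapy_start_date),
      therapy_type = apply_missing(sample(THERAPY_TYPES, nh, replace = TRUE),
                                   miss$therapy_type),
      stringsAsFactors = FALSE), "THERAPIES")

    n_mp_per <- stats::rbinom(nt, 2L, 0.35)
    nm <- sum(n_mp_per)
    molpath <- relational_table(data.frame(
      sample_id = sprintf("M%08d", sample.int(99999999L, nm)),
      tumor_id = rep(tumors$tumor_id, n_mp_per),
      gene = apply_missing(sample(GENES, nm, replace = TRUE), miss$gene),
      variant = apply_missing(sample(VARIANTS, nm, replace = TRUE), miss$variant),
      stringsAsFactors = FALSE), "MOLPATH")

    tables <- list(PATIENTS = patients, TUMORS = tumors,
                   THERAPIES = therapies, MOLPATH = molpath)
    list(tables = tables, dictionary = registry_dictionary())
  })
}

# The measure assignment mirroring a reviewed tumor-registry data record
# description: identity text deleted, linking IDs pseudonymized, every
# date randomized (birth date as a bound split-date triple).
registry_dictionary <- function() {
  entry <- function(tab, field, desc, measure, group = "", role = "") {
    data.frame(table_name = tab, field_name = field, description = desc,
               measure = measure, date_group = group, date_role = role,
               stringsAsFactors = FALSE)
  }
  data_dictionary(rbind(
    entry("PATIENTS", "patient_id", "Patient ID", "PSEUDONYMIZATION"),
    entry("PATIENTS", "first_name", "First name", "DELETION"),
    entry("PATIENTS", "last_name", "Last name", "DELETION"),
    entry("PATIENTS", "birth_day", "Birth day", "DATE_RANDOMIZATION", "birth", "day"),
    entry("PATIENTS", "birth_month", "Birth month", "DATE_RANDOMIZATION", "birth", "month"),
    entry("PATIENTS", "birth_year", "Birth year", "DATE_RANDOMIZATION", "birth", "year"),
    entry("PATIENTS", "address", "Home address", "DELETION"),
    entry("TUMORS", "tumor_id", "Tumor ID", "PSEUDONYMIZATION"),
    entry("TUMORS", "patient_id", "Patient ID", "PSEUDONYMIZATION"),
    entry("TUMORS", "icd10_code", "ICD-10 diagnosis code", "NO_ACTION"),
    entry("TUMORS", "diagnosis_date", "Date of diagnosis", "DATE_RANDOMIZATION"),
    entry("THERAPIES", "therapy_id", "Therapy ID", "PSEUDONYMIZATION"),
    entry("THERAPIES", "tumor_id", "Tumor ID", "PSEUDONYMIZATION"),
    entry("THERAPIES", "therapy_start_date", "Start of therapy", "DATE_RANDOMIZATION"),
    entry("THERAPIES", "therapy_type", "Therapy modality", "NO_ACTION"),
    entry("MOLPATH", "sample_id", "Sample ID", "PSEUDONYMIZATION"),
    entry("MOLPATH", "tumor_id", "Tumor ID", "PSEUDONYMIZATION"),
    entry("MOLPATH", "gene", "Gene symbol", "NO_ACTION"),
    entry("MOLPATH", "variant", "Variant description", "NO_ACTION")
  ))
}

#' Plant pathological edge cases into a synthetic registry
#'
#' Deterministically (from `config$seed`) injects the messiness the
#' pipeline must survive on routine data: a handful of malformed
#' diagnosis dates, ICD codes shorter than 3 characters (which fall into
#' the reserved UNKNOWN swap group), duplicated therapy rows (repeated
#' IDs, as produced by duplicate visit documentation), and five extra
#' rare ICD codes with only 2 tumors each so that small-group merging is
#' always exercised.
#'
#' @param tables Tables from [generate_registry()].
#' @param config The same [registry_config()].
#' @return The modified list of tables.
#' @export
inject_pathologies <- function(tables, config) {
  stopifnot(inherits(config, "registry_config"))
  with_seed(config$seed + 1L, {
    tum <- tables$TUMORS
    nt <- nrow(tum)
    bad_dates <- c("00.13.2020", "31.02.2019", "2020-05-07")
    i <- sample.int(nt, length(bad_dates))
    tum$diagnosis_date[i] <- bad_dates
    short_icd <- c("C", "K7", "")
    j <- sample(setdiff(seq_len(nt), i), length(short_icd))
    tum$icd10_code[j] <- short_icd
    # Five rare codes, 2 tumors each, attached to existing patients.
    rare <- c("Q85.9", "D32.0", "E10.9", "K22.2", "L40.5")
    extra <- data.frame(
      tumor_id = sprintf("T9%08d", sample.int(99999999L, 2L * length(rare))),
      patient_id = rep(tum$patient_id[seq_len(2L * length(rare))]),
      icd10_code = rep(rare, each = 2L),
      diagnosis_date = fmt_combined(rand_dates(2L * length(rare), config$date_window)),
      stringsAsFactors = FALSE)
    tables$TUMORS <- relational_table(rbind(tum, extra), "TUMORS")
    th <- tables$THERAPIES
    dup <- th[sample.int(nrow(th), 4L), , drop = FALSE]
    tables$THERAPIES <- relational_table(rbind(th, dup), "THERAPIES")
    tables
  })
}
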