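# swapdata

Hospitals hold rich routine-care data — tumor documentation, molecular
pathology — that external partners could use to develop analytical
algorithms, but that can rarely be shared: without patient consent,
European data-protection law permits secondary use only after genuine
anonymization. `swapdata` implements a pragmatic answer: a **swapping
data set**, a release that is structurally identical to the source
(same tables, columns, formats, value frequencies, missingness) but
analytically meaningless on its own, because every cross-column link
between values has been destroyed. Partners develop code against the
swapped release; the code is then executed in-house on the real data.

The package is aimed at data managers of clinical registries who need a
reviewable, dictionary-driven anonymization pipeline for relational
tables exported as delimited text files, and at methodologists who want
to study value swapping on synthetic data.

## Method

A hand-reviewed *data record description* assigns each field one of
four measures, which the pipeline applies automatically:

1. **No action** — the field passes through unchanged.
2. **Deletion** — every value in the column is erased (the column
   itself remains, preserving the schema).
3. **Pseudonymization** — each non-empty value *v* is replaced by
   `hex(SHA3-256(utf8(v) ‖ salt))`, with a secret 16-byte salt drawn
   fresh from a cryptographically secure source at the start of every
   run and discarded afterwards. No key list is stored, so tokens are
   one-way; within one run equal identifiers map to equal tokens, so
   table links remain usable by downstream steps.
4. **Date randomization** — every date, a classic quasi-identifier, is
   shifted by a signed number of days drawn anew per value:
   `DD.MM.YYYY` fields by |s| ∈ {3,…,6}, dates split across three
   day/month/year columns (re-assembled, shifted, redistributed) by
   |s| ∈ {2,…,10}; sign and magnitude uniform over the admissible set.

Then the two destructive stages run, per table:

5. **Value swapping** — each column is independently permuted within
   *entity groups*, the sets of rows sharing a 3-character ICD-10
   category (e.g. all `C50.x` breast-cancer rows). Per-column marginals
   survive exactly inside each group; tuples become fakes. Groups with
   fewer than *k* = 25 observations are merged so no swap pool is small
   enough to leak.
6. **Sampling** — exactly ⌊0.30 · n⌋ rows of each table are deleted
   uniformly at random, so true record counts and frequencies cannot be
   recovered.

An audit report (field counts per measure, shift-offset histogram with
no row-level mapping, group sizes, rows in/out) and a verification
module (deletion completeness, raw-identifier leak scan, exact row
counts, multiset conservation, shift bounds, group-size floor) document
every run.

## Worked example

Everything runs on synthetic data — the package ships a generator for a
linked four-table tumor registry (patients with split birth dates,
tumors with ICD-10 codes and combined-format diagnosis dates,
therapies, molecular pathology) plus its matching dictionary:

```r
library(swapdata)

cfg <- registry_config(n_patients = 2000, seed = 1905)
reg <- generate_registry(cfg)
tabs <- inject_pathologies(reg$tables, cfg)   # malformed dates, rare codes, ...
write_table_dir(tabs, "demo/input")
save_dictionary(reg$dictionary, "demo/dictionary.csv")

pc <- pipeline_config("demo/input", "demo/dictionary.csv", "demo/output",
  swap = swap_config(icd_fields = c(TUMORS = "icd10_code")),
  mode = "test", test_seed = 7, keep_intermediates = TRUE)
report <- run_pipeline(pc)
print(report)
#> <audit_report>
#>   tables: 4 described, 0 excluded, 4 output
#>   fields: 19 total, 15 modified (DEL 3 / PSE 7 / DATE 5), 4 untouched
#>   sampling: fraction 0.30; swap k_min 25
#>   MOLPATH: 2049 -> 1435 rows
#>   PATIENTS: 2000 -> 1400 rows
#>   THERAPIES: 2985 -> 2090 rows
#>   TUMORS: 2986 -> 2091 rows
```

Of the 19 described fields, 15 were modified (3 deleted, 7
pseudonymized, 5 date-randomized); each table lost exactly 30% of its
rows (2986 → 2091 = 2986 − ⌊0.3·2986⌋). The released `TUMORS` table
holds 64-character hex tokens instead of IDs, shifted dates, and ICD
codes swapped only within their category:

```r
head(read_table_file("demo/output/TUMORS.csv"), 2)
#>                                                           tumor_id ... icd10_code diagnosis_date
#> 1 fc76dae9172bdf8db0d7418f6bad6c678...                                  C18.9         16.03.2022
#> 2 03d93cac6a4cd0596c11cc5b203d21bef...                                  C18.7         14.12.2007

v <- verify_output("demo/input", "demo/output", "demo/dictionary.csv",
                   report, "demo/output/intermediates")
print(v)
#> <verification_report: 23 pass, 0 fail, 0 skip>
```

In production mode (`mode = "production"`, the default) the salt and
all permutations come from a non-seedable cryptographically secure
source, intermediates cannot be written, and two runs over the same
input share no pseudonym token.

A command-line front end wraps the same functions:

```sh
exec/swapdata simulate --out demo --n-patients 2000 --seed 1905
exec/swapdata run --input demo/tables --dictionary demo/dictionary.csv \
    --out demo/output --icd-field TUMORS=icd10_code
exec/swapdata verify --input demo/tables --output demo/output \
    --dictionary demo/dictionary.csv
```

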