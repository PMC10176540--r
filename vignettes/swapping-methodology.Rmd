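---
title: "Dictionary-driven value swapping: model, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dictionary-driven value swapping: model, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swapdata)
```

## The anonymization model

`swapdata` produces a *swapping data set*: a release whose tables,
columns, formats, per-column value distributions and missingness match
the source, but in which the joint distribution across columns is
deliberately destroyed. The privacy argument is layered:

* **Formal anonymization** removes directly identifying data (IDAT):
  names and addresses are deleted outright; linking identifiers are
  replaced by salted one-way hash tokens.
* **Quasi-identifier hardening** perturbs every date by a bounded
  random shift, so background knowledge of an admission or diagnosis
  day no longer pins down a record.
* **Linkage destruction** permutes each column independently within
  entity groups. After swapping, a row is a *fake tuple*: each cell is
  a real marginal value, but the combination never belonged to one
  person. Rare-combination attacks (two rare diagnoses in one row, an
  unusual therapy pattern) lose their target because the combinations
  themselves are artifacts.
* **Frequency masking** deletes a fixed 30% of rows, so even exact
  counts of values cannot be read off the release.

The stages run strictly in that order — field measures, then swapping,
then sampling — because swapping must operate on already-pseudonymized
and shifted values (so intermediate states never mix raw and protected
content), and sampling last ensures counts are thinned after all
within-group invariants are fixed.

Utility survives in exactly the properties the release is meant to
convey: schema, formats, per-field completeness, per-field value
distributions, and — thanks to group-confined swapping — per-disease
documentation density.

## Parameters that matter

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| combined-date shift | ±3…6 | days | wide enough to break day-level linkage, narrow enough to keep month/season structure |
| split-date shift | ±2…10 | days | split dates (birth dates) tolerate a wider window |
| `k_min` | 25 | rows | minimum entity-group size; pools below this merge |
| `sample_fraction` | 0.30 | — | share of rows deleted, exact count `floor(0.3 n)` |
| `icd_prefix_len` | 3 | chars | ICD-10 category level (`C50`), the disease-class grain |
| salt | 16 fresh random bytes/run | — | defeats dictionary attacks; discarded, so hashing is one-way |

Shift offsets are drawn **uniformly over the admissible signed set**
({±3,…,±6} and {±2,…,±10}), a fresh draw per value. Uniformity is the
least-assumption reading of a bounded random shift; zero and
sub-minimum offsets are excluded by construction, so no date ever
survives unshifted. Boundaries are inclusive.

The SHA-3 variant is SHA3-256 with the full 64-character lowercase hex
digest, and the salt is appended to the value bytes
(`utf8(value) ‖ salt`). A fixed concatenation order and full-length
digest make the construction reproducible across implementations and
maximize collision resistance; truncated tokens would add collision
risk with no benefit.

## Randomness contract

A run owns one `run_secrets` object. In **production** mode the salt
and every permutation and offset come from a cryptographically secure,
non-seedable source (OpenSSL's CSPRNG; uniform integers via rejection
sampling so there is no modulo bias). Seeds, injected salts and
intermediate outputs are rejected at configuration time: an
intermediates directory retains pre-swap linkage and must never exist
next to a production export. In **test** mode a caller-supplied seed
(and optional salt) makes the entire run bit-reproducible, which is
what the test suite and the acceptance script rely on.

## The merge rule for small groups

Swapping within a group of 3 rows would barely perturb anything, so
groups under `k_min` merge. The packing rule is deterministic given the
group counts: sort small groups by size (largest first, ties
alphabetically), accumulate greedily into pools, close a pool when it
reaches `k_min`; fold a final under-sized pool into the smallest closed
pool, or, when no pool closed, into the smallest large group. A table
with fewer than `k_min` rows in total keeps one under-sized pool — the
floor is only guaranteed when it is achievable. Codes shorter than the
prefix length (and empty codes) collect in a reserved `UNKNOWN` group
that participates in merging like any other small group. Tables with
no ICD column are swapped as one whole-table group.

## Degenerate inputs and numerical choices

* **Empty values** are never hashed or shifted: empty in, empty out,
  and they *do* participate in swapping, so per-group missingness
  marginals are conserved. Hashing `""` would fabricate one frequent
  fake token and distort completeness, which the release exists to
  convey.
* **Unparsable dates** (e.g. `00.13.2020`, `31.02.2019`, wrong
  delimiter) default to blank-with-audit: routine data are messy, and
  a failed export is worse than a blanked cell. The strict policy
  (`bad_date_policy = "error"`) aborts naming only table and field —
  never the value, which would leak data into logs. Date validity is
  decided by a strict format regular expression plus real calendar
  parsing, so `29.02.2021` is invalid while `29.02.2020` shifts
  normally across the leap boundary.
* **Split-date reassembly** preserves each column's zero-padding width,
  so `05 | 04 | 2018` comes back zero-padded and an unpadded source
  keeps its own style where widths allow.
* **Group-size-one** swap groups are fixed points (only one permutation
  exists); the code skips them rather than drawing.
* **Fail-closed orchestration**: the pipeline validates and transforms
  everything in memory and only then writes. A validation error
  therefore never leaves a partially anonymized export on disk.
* **Audit minimalism**: the shift audit stores only offset *frequencies*
  and unparsable counts per field — no row indices, no values — so the
  run report itself can never serve as a de-anonymization key.

## The data dictionary format

The data record description is a plain UTF-8 CSV
(`table_name,field_name,description,measure,date_group,date_role`).
Two artifact decisions fill gaps a human-readable table leaves open:
split-date triples are bound by a machine-checkable `date_group` label
with one `day`/`month`/`year` role per column, and table exclusion is
encoded as a row with empty `field_name` and measure `Excluded` rather
than as free text in the description. Measure matching is
case-insensitive with whitespace stripped, because these files are
hand-edited. Fields found in the data but missing from the dictionary
are either an error or — under `unknown_policy = "delete"` — truncated
via a synthesized `DELETION` entry: unknown content is the one thing a
privacy pipeline must not pass through.

## What the synthetic registry emulates — and what it does not

`generate_registry()` emits four linked tables (patients with split
birth dates, tumors with ICD-10 codes and combined-format diagnosis
dates, therapies, molecular pathology) with referential integrity,
configurable per-field missingness, and an ICD mix containing a long
tail of rare categories so that small-group merging always triggers.
`inject_pathologies()` adds the mess a pipeline meets in practice:
malformed dates, under-length ICD codes, duplicated therapy rows and
five guaranteed sub-threshold codes. Names and addresses come from
deterministic invented pools; no real-person data exists anywhere in
the package.

The default scale is 2,000 patients (~3,000 tumors). The pipeline is
linear in rows and the correctness properties (multiset conservation,
exact sampling counts, group floors, shift bounds) are scale-free, so
the suite runs in about two minutes; the acceptance script measures
shift bounds on 10,000 draws per format, and the hashing injectivity
check runs on 10^6 distinct values.

What the generator does **not** emulate: tumor biology (stage/grade
coherence, survival structure), temporal coherence between diagnosis
and therapy dates, realistic inter-field correlations, or the scale of
a production registry. Passing tests therefore demonstrate the
*transformational* guarantees of the pipeline on realistic structure —
they say nothing about the clinical plausibility of the synthetic
content, which is irrelevant to the anonymizer.

## Verification

`verify_output()` re-derives, from the released files alone (plus
test-mode intermediates when present): deletion completeness, a
raw-identifier leak scan (no non-empty value of any deleted or
pseudonymized input column may appear anywhere in the output), exact
`n − floor(f·n)` row counts, absence of excluded tables, header and
column-order fidelity, the group-size floor, per-group per-column
multiset conservation, and that every applied date shift lies in its
admissible set. The linkage-dependent checks need the pre-swap
intermediates and are reported as *skipped* — never failed — on
production output, where intermediates rightly do not exist.

## Known limitations

* Value swapping is not a formal privacy model: no k-anonymity,
  l-diversity or t-closeness certificate is computed, and the package
  deliberately does not claim one.
* Entity-group swapping requires an ICD column in the table; linked
  tables without one are swapped as a single whole-table group. A
  pre-swap join to propagate group keys through identifiers would be
  possible but is not enabled: it widens the attack surface of the
  intermediate state for modest utility gain.
* Pseudonym frequency analysis can, with effort and expert background
  knowledge, hint at which token is which frequent category; the 30%
  sampling is the designed mitigation, not an elimination.
* The audit report intentionally contains too little to reverse
  anything — which also means a lost salt can never be recovered; that
  is the point, but it rules out any re-identification service.
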