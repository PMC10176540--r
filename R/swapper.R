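#' Swapping-stage configuration
#'
#' @param icd_fields Named character vector mapping table names to the
#'   field that holds the ICD-10 code in that table. Tables without a
#'   mapping are swapped as one whole-table group.
#' @param k_min Minimum entity-group size; groups with fewer
#'   observations are merged with other small groups. Default 25.
#' @param sample_fraction Fraction of rows randomly deleted from each
#'   table after swapping. Default 0.30.
#' @param icd_prefix_len Number of leading ICD-10 characters that define
#'   an entity group (3 = the ICD-10 category, e.g. `C50`).
#' @return A `swap_config` object.
#' @export
swap_config <- function(icd_fields = character(), k_min = 25L,
                        sample_fraction = 0.30, icd_prefix_len = 3L) {
  k_min <- as.integer(k_min)
  icd_prefix_len <- as.integer(icd_prefix_len)
  if (length(icd_fields) && is.null(names(icd_fields)))
    stop_swapdata("icd_fields must be a named vector (table = field)",
                  "swapdata_config_error")
  if (!(sample_fraction >= 0 && sample_fraction < 1))
    stop_swapdata("sample_fraction must be in [0, 1)", "swapdata_config_error")
  if (k_min < 1L) stop_swapdata("k_min must be >= 1", "swapdata_config_error")
  if (icd_prefix_len < 1L) stop_swapdata("icd_prefix_len must be >= 1",
                                         "swapdata_config_error")
  structure(list(icd_fields = icd_fields, k_min = k_min,
                 sample_fraction = sample_fraction,
                 icd_prefix_len = icd_prefix_len),
            class = "swap_config")
}

UNKNOWN_GROUP <- "UNKNOWN"

# Normalize an ICD value to its grouping key: trim, uppercase, take the
# first icd_prefix_len characters; too-short or empty codes fall into the
# reserved UNKNOWN group.
icd_group_key <- function(x, prefix_len) {
  y <- toupper(trimws(x))
  key <- substr(y, 1L, prefix_len)
  key[nchar(y) < prefix_len] <- UNKNOWN_GROUP
  key
}

#' Assign rows to swap entity groups
#'
#' An entity group is the set of rows sharing one `icd_prefix_len`-character
#' ICD-10 prefix (by default the 3-character category). Groups smaller
#' than `k_min` are merged with other small groups by a deterministic
#' packing rule so that, whenever the table has at least `k_min` rows,
#' every resulting group reaches the minimum size: small groups are
#' sorted by size (largest first, ties by key) and accumulated greedily
#' into pools, closing each pool once it reaches `k_min`; a final
#' under-sized pool is folded into the smallest closed pool, or — if no
#' pool was closed — into the smallest large group. Tables with no ICD
#' field form a single whole-table group.
#'
#' @param table A relational table.
#' @param config A [swap_config()]; the table's ICD field is looked up
#'   by table name in `config$icd_fields`.
#' @return An `entity_grouping` with per-row `assignment`, a group
#'   `registry` (key, size, merged flag) and `member_prefixes`.
#' @export
build_entity_groups <- function(table, config) {
  stopifnot(inherits(config, "swap_config"))
  tn <- table_name(table)
  n <- nrow(table)
  icd_field <- if (tn %in% names(config$icd_fields)) config$icd_fields[[tn]] else NULL
  if (is.null(icd_field)) {
    return(structure(list(
      assignment = rep("ALL", n),
      registry = data.frame(key = "ALL", size = n, merged = FALSE,
                            stringsAsFactors = FALSE),
      member_prefixes = list(ALL = character(0)),
      k_min = config$k_min, icd_field = NULL), class = "entity_grouping"))
  }
  if (!icd_field %in% names(table))
    stop_swapdata(sprintf("ICD field '%s' not in table '%s'", icd_field, tn))
  key <- icd_group_key(table[[icd_field]], config$icd_prefix_len)
  sizes <- table(key)
  keys <- names(sizes)
  small <- keys[as.integer(sizes) < config$k_min]
  large <- setdiff(keys, small)
  assignment <- key
  member_prefixes <- stats::setNames(as.list(keys), keys)
  merged <- stats::setNames(rep(FALSE, length(keys)), keys)

  if (length(small)) {
    # Deterministic packing: largest small groups first, ties by key.
    ord <- small[order(-as.integer(sizes[small]), small)]
    pools <- list(); current <- character(0); current_size <- 0L
    for (g in ord) {
      current <- c(current, g)
      current_size <- current_size + as.integer(sizes[[g]])
      if (current_size >= config$k_min) {
        pools[[length(pools) + 1L]] <- current
        current <- character(0); current_size <- 0L
      }
    }
    if (length(current)) {
      if (length(pools)) {
        # Fold the leftover into the smallest closed pool.
        pool_sizes <- vapply(pools, function(p) sum(as.integer(sizes[p])), 0L)
        i <- which.min(pool_sizes)
        pools[[i]] <- c(pools[[i]], current)
      } else if (length(large)) {
        # No closed pool: fold into the smallest large group.
        g <- large[order(as.integer(sizes[large]), large)][1]
        pools[[1L]] <- c(g, current)
        large <- setdiff(large, g)
      } else {
        # Whole table smaller than k_min: one under-sized pool remains.
        pools[[1L]] <- current
      }
    }
    registry_keys <- large
    for (i in seq_along(pools)) {
      pk <- sprintf("MERGED_%d", i)
      assignment[key %in% pools[[i]]] <- pk
      member_prefixes[[pk]] <- sort(setdiff(pools[[i]], UNKNOWN_GROUP))
      merged[pk] <- TRUE
      member_prefixes[pools[[i]]] <- NULL
      merged <- merged[setdiff(names(merged), pools[[i]])]
    }
  }
  final_sizes <- table(assignment)
  registry <- data.frame(key = names(final_sizes),
                         size = as.integer(final_sizes),
                         merged = unname(merged[names(final_sizes)]),
                         stringsAsFactors = FALSE)
  structure(list(assignment = assignment, registry = registry,
                 member_prefixes = member_prefixes[registry$key],
                 k_min = config$k_min, icd_field = icd_field),
            class = "entity_grouping")
}

#' @export
print.entity_grouping <- function(x, ...) {
  cat(sprintf("<entity_grouping: %d rows, %d group(s), %d merged pool(s), k_min=%d>\n",
              length(x$assignment), nrow(x$registry), sum(x$registry$merged), x$k_min))
  invisible(x)
}

#' Swap values within entity groups
#'
#' The value-swapping step: for each entity group and each column
#' independently, the values at that group's row positions are replaced
#' by a uniform random permutation of themselves (fresh draw per column
#' per group). Every column participates — including pseudonymized IDs
#' and the ICD column itself — and empty values take part in the
#' permutation, so per-column per-group value multisets (and hence
#' marginal missingness) are exactly preserved while cross-column row
#' linkage is destroyed.
#'
#' @param table A relational table.
#' @param grouping An [build_entity_groups()] result covering all rows.
#' @param secrets The run's [run_secrets()].
#' @return The swapped table (same shape, same per-group column multisets).
#' @export
swap_within_groups <- function(table, grouping, secrets) {
  stopifnot(inherits(grouping, "entity_grouping"),
            inherits(secrets, "run_secrets"))
  if (length(grouping$assignment) != nrow(table))
    stop_swapdata("grouping does not cover all rows of the table")
  for (g in sort(unique(grouping$assignment))) {
    idx <- which(grouping$assignment == g)
    if (length(idx) < 2L) next
    for (col in names(table)) {
      perm <- rand_perm(secrets, length(idx))
      table[[col]][idx] <- table[[col]][idx][perm]
    }
  }
  table
}

#' Randomly delete an exact fraction of rows
#'
#' As the final hardening step, exactly `floor(sample_fraction * n)`
#' rows are removed, chosen uniformly without replacement; surviving
#' rows keep their relative order. Deleting a fixed share of rows
#' changes the observable value frequencies so that true record counts
#' cannot be recovered from the released tables.
#'
#' @param table A relational table.
#' @param config A [swap_config()] (uses `sample_fraction`).
#' @param secrets The run's [run_secrets()].
#' @return The thinned table.
#' @export
sample_rows <- function(table, config, secrets) {
  stopifnot(inherits(config, "swap_config"), inherits(secrets, "run_secrets"))
  n <- nrow(table)
  n_del <- floor(config$sample_fraction * n)
  if (n_del == 0L) return(table)
  drop <- rand_take(secrets, n, n_del)
  out <- table[-drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "table_name") <- table_name(table)
  out
}
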