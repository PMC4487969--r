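#' Names of the 12 canonical count cells of a hut-night record
#'
#' Every hut-night collection is cross-classified three ways: gonotrophic
#' status (`fed` / `unfed`), 24-h survival (`dead` / `alive`), and where the
#' mosquito was found (`room`, `verandah` trap, `window` trap). Column names
#' are `<feeding>_<survival>_<location>`.
#'
#' @return Character vector of the 12 cell/column names, in canonical order.
#' @export
hut_count_cells <- function() {
  g <- expand.grid(
    location = c("room", "verandah", "window"),
    survival = c("dead", "alive"),
    feeding = c("fed", "unfed"),
    stringsAsFactors = FALSE
  )
  paste(g$feeding, g$survival, g$location, sep = "_")
}

hut_key_cols <- function() {
  c("night", "period", "hut", "sleeper", "arm", "species")
}

hut_required_cols <- function() c(hut_key_cols(), hut_count_cells())

#' Read per-hut-night trial records from CSV
#'
#' Reads the canonical long-format hut-records file: one row per hut x night
#' x species, with the 12 count cells named as in [hut_count_cells()].
#' Missing cells are an error, not a silent zero: a gap in the file usually
#' means a collection gap, which must be audited, not imputed.
#'
#' @param path Path to a UTF-8, comma-separated file with one header row.
#' @return A tibble of validated records. Columns beyond the required schema
#'   are preserved untouched.
#' @seealso [write_hut_records()], [validate_hut_records()]
#' @export
read_hut_records <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(hut_required_cols(), names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "hut-records schema error: missing required column(s): %s",
      paste(missing, collapse = ", ")
    ))
  }
  for (cc in hut_count_cells()) {
    v <- df[[cc]]
    if (nrow(df) == 0) { # header-only file: column types are indeterminate
      df[[cc]] <- integer(0)
      next
    }
    if (!is.numeric(v)) {
      abort(sprintf("hut-records schema error: column `%s` is not numeric", cc))
    }
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      abort(sprintf(
        "hut-records validation error: column `%s`, row %d: count must be a non-negative integer (got %s)",
        cc, bad[1], as.character(v[bad[1]])
      ))
    }
    df[[cc]] <- as.integer(v)
  }
  for (kc in c("night", "period")) {
    if (nrow(df) > 0 && (!is.numeric(df[[kc]]) || any(is.na(df[[kc]])) ||
                         any(df[[kc]] < 1))) {
      abort(sprintf("hut-records schema error: column `%s` must be a positive integer", kc))
    }
    df[[kc]] <- if (nrow(df) == 0) integer(0) else as.integer(df[[kc]])
  }
  for (kc in c("hut", "sleeper", "arm", "species")) df[[kc]] <- as.character(df[[kc]])
  extra <- setdiff(names(df), hut_required_cols())
  df[, c(hut_required_cols(), extra)]
}

#' Write hut-trial records to the canonical CSV
#'
#' @param records A tibble of hut records (see [read_hut_records()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_hut_records <- function(records, path) {
  readr::write_csv(records, path, progress = FALSE)
  invisible(path)
}

#' Aggregate hut-night records into arm-level summaries
#'
#' Produces one row per treatment arm x species carrying the marginal totals
#' on which every trial endpoint is built: total caught (T), total dead at
#' 24 h (K), total blood-fed (B) and total exiting into verandah or window
#' traps (E), together with the number of distinct nights contributing.
#'
#' @param records A tibble of hut records.
#' @param species Optional species label(s) to restrict to. A species absent
#'   from the records yields an empty summary, not an error.
#' @return A tibble with columns `species`, `arm`, `n_nights`,
#'   `total_caught`, `total_dead`, `total_fed`, `total_exited`.
#' @export
aggregate_arms <- function(records, species = NULL) {
  cells <- hut_count_cells()
  if (!is.null(species)) {
    records <- records[records$species %in% species, , drop = FALSE]
  }
  dead_cells <- grep("_dead_", cells, value = TRUE)
  fed_cells <- grep("^fed_", cells, value = TRUE)
  exit_cells <- grep("_(verandah|window)$", cells, value = TRUE)
  records |>
    dplyr::group_by(.data$species, .data$arm) |>
    dplyr::summarise(
      n_nights = dplyr::n_distinct(.data$night),
      total_caught = sum(dplyr::pick(dplyr::all_of(cells))),
      total_dead = sum(dplyr::pick(dplyr::all_of(dead_cells))),
      total_fed = sum(dplyr::pick(dplyr::all_of(fed_cells))),
      total_exited = sum(dplyr::pick(dplyr::all_of(exit_cells))),
      .groups = "drop"
    )
}

#' Validate a set of hut-trial records
#'
#' Checks structural invariants beyond per-cell parsing: all 12 cells present
#' and non-negative, no duplicated (hut, night) pair within a species' record
#' set, no sleeper occupying two huts on the same night, and rotation
#' coverage (every arm should visit every hut at least once; a gap is a
#' warning, since partial datasets are legitimate mid-trial).
#'
#' @param records A tibble of hut records.
#' @return A [validation_report()].
#' @export
validate_hut_records <- function(records) {
  entries <- list()
  add <- function(locator, rule, message, severity = "error") {
    entries[[length(entries) + 1]] <<- tibble::tibble(
      locator = locator, rule = rule, message = message, severity = severity
    )
  }
  missing <- setdiff(hut_required_cols(), names(records))
  if (length(missing) > 0) {
    add("header", "required_columns",
        paste("missing column(s):", paste(missing, collapse = ", ")))
    return(validation_report(dplyr::bind_rows(entries)))
  }
  for (cc in hut_count_cells()) {
    v <- records[[cc]]
    bad <- which(is.na(v) | v < 0 | v != floor(v))
    if (length(bad) > 0) {
      add(sprintf("row %d, column %s", bad[1], cc), "nonnegative_counts",
          "count cells must be non-negative integers")
    }
  }
  if (nrow(records) > 0) {
    key <- paste(records$species, records$hut, records$night, sep = "\r")
    dup <- which(duplicated(key))
    if (length(dup) > 0) {
      add(sprintf("row %d (species %s, hut %s, night %d)", dup[1],
                  records$species[dup[1]], records$hut[dup[1]],
                  records$night[dup[1]]),
          "unique_hut_night", "duplicated (hut, night) pair within a species")
    }
    skey <- unique(records[, c("species", "night", "sleeper", "hut")])
    sdup <- skey |>
      dplyr::count(.data$species, .data$night, .data$sleeper) |>
      dplyr::filter(.data$n > 1)
    if (nrow(sdup) > 0) {
      add(sprintf("species %s, night %d, sleeper %s", sdup$species[1],
                  sdup$night[1], sdup$sleeper[1]),
          "sleeper_single_hut",
          "a sleeper is recorded in more than one hut on the same night")
    }
    for (sp in unique(records$species)) {
      rs <- records[records$species == sp, ]
      huts <- sort(unique(rs$hut))
      visited <- table(rs$arm, factor(rs$hut, levels = huts))
      gaps <- which(visited == 0, arr.ind = TRUE)
      if (nrow(gaps) > 0) {
        add(sprintf("species %s, arm %s, hut %s", sp,
                    rownames(visited)[gaps[1, 1]], huts[gaps[1, 2]]),
            "rotation_coverage",
            "an arm never visits one of the huts in the rotation",
            severity = "warning")
      }
    }
  }
  validation_report(if (length(entries) > 0) dplyr::bind_rows(entries) else NULL)
}
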