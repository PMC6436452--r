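#' Cohort-table column schema
#'
#' A cohort table holds one row per participant. Required columns: `id`,
#' `age`, the per-ear audiogram columns for at least the standard-PTA
#' frequencies (`L_0.5`, `L_1`, `L_2`, `L_4` and the `R_` counterparts), and
#' the four per-run thresholds `colocated_1`, `colocated_2`, `separated_1`,
#' `separated_2` (dB TMR). Optional columns: `gender`, `hearing_aid`,
#' `retest_delay` (days), `srt_L`, `srt_R` (dB), the remaining audiogram
#' frequencies, and stored `pta_st` / `pta_hf` / `asym_max` summaries.
#' Derived columns (`colocated_avg`, `separated_avg`, `srm_1`, `srm_2`,
#' `srm_avg`, and recomputed `pta_st` / `pta_hf` / asymmetry) are always
#' rebuilt from the primary data; a stored PTA that disagrees with the
#' recomputed value by more than 0.05 dB triggers a warning, because derived
#' values must be reproducible while stored ones may be rounded.
#'
#' Missing optional values are empty CSV cells and surface as `NA`, never as
#' zero.
#'
#' @return `cohort_schema()` returns a tibble describing every recognized
#'   column (`column`, `required`, `role`).
#' @examples
#' cohort_schema()
#' @export
cohort_schema <- function() {
  aud <- audiogram_cols()
  req_aud <- audiogram_cols(freqs = pta_freqs$standard)
  tibble::tibble(
    column = c("id", "age", "gender", "hearing_aid", "retest_delay",
               aud, "srt_L", "srt_R", "pta_st", "pta_hf", "asym_max",
               threshold_cols(), derived_cols()),
    required = c(TRUE, TRUE, FALSE, FALSE, FALSE,
                 aud %in% req_aud, FALSE, FALSE, FALSE, FALSE, FALSE,
                 rep(TRUE, length(threshold_cols())),
                 rep(FALSE, length(derived_cols()))),
    role = c("identity", "demographic", "demographic", "demographic",
             "demographic", rep("audiogram", length(aud)),
             "audiometric", "audiometric", "derived", "derived", "derived",
             rep("threshold", length(threshold_cols())),
             rep("derived", length(derived_cols())))
  )
}

threshold_cols <- function() {
  c("colocated_1", "colocated_2", "separated_1", "separated_2")
}

derived_cols <- function() {
  c("colocated_avg", "separated_avg", "srm_1", "srm_2", "srm_avg")
}

#' Recompute the derived columns of a cohort table
#'
#' Rebuilds run averages and SRM from the per-run thresholds, and bilateral
#' PTA / asymmetry summaries from the audiogram when audiogram columns are
#' present. Stored summaries that disagree with the recomputed values by
#' more than `tol` dB produce a warning.
#'
#' @param cohort A data frame with at least the per-run threshold columns.
#' @param tol Tolerance (dB) for agreement between stored and recomputed
#'   PTA columns.
#' @return The cohort as a tibble with derived columns refreshed.
#' @export
derive_cohort <- function(cohort, tol = 0.05) {
  cohort <- tibble::as_tibble(cohort)
  have <- intersect(threshold_cols(), names(cohort))
  if (all(c("colocated_1", "colocated_2") %in% have)) {
    cohort$colocated_avg <- average_runs(cohort$colocated_1, cohort$colocated_2)
  }
  if (all(c("separated_1", "separated_2") %in% have)) {
    cohort$separated_avg <- average_runs(cohort$separated_1, cohort$separated_2)
  }
  for (run in c("1", "2", "avg")) {
    co <- paste0("colocated_", run)
    se <- paste0("separated_", run)
    if (all(c(co, se) %in% names(cohort))) {
      cohort[[paste0("srm_", run)]] <- cohort[[co]] - cohort[[se]]
    }
  }
  std_cols <- audiogram_cols(freqs = pta_freqs$standard)
  if (all(std_cols %in% names(cohort))) {
    new_pta <- pta(cohort, "standard")
    if ("pta_st" %in% names(cohort)) {
      off <- which(is.finite(cohort$pta_st) & abs(cohort$pta_st - new_pta) > tol)
      if (length(off)) {
        warning(sprintf("Stored pta_st disagrees with the audiogram by > %.2f dB in %d row(s) (first: row %d, stored %.3f vs recomputed %.3f); using the recomputed value.",
                        tol, length(off), off[1], cohort$pta_st[off[1]],
                        new_pta[off[1]]), call. = FALSE)
      }
    }
    cohort$pta_st <- new_pta
  }
  hf_cols <- audiogram_cols(freqs = pta_freqs$high_frequency)
  if (all(hf_cols %in% names(cohort))) {
    new_hf <- pta(cohort, "high_frequency")
    if ("pta_hf" %in% names(cohort)) {
      off <- which(is.finite(cohort$pta_hf) & abs(cohort$pta_hf - new_hf) > tol)
      if (length(off)) {
        warning(sprintf("Stored pta_hf disagrees with the audiogram by > %.2f dB in %d row(s); using the recomputed value.",
                        tol, length(off)), call. = FALSE)
      }
    }
    cohort$pta_hf <- new_hf
  }
  if (any(grepl("^L_", names(cohort)))) {
    asym <- bilateral_asymmetry(cohort)
    cohort$asym_max <- asym$asym_max
    cohort$asym_max_below_2k <- asym$asym_max_below_2k
  }
  cohort
}

#' Validate a cohort table
#'
#' Checks every row against the cohort invariants: ages within the supported
#' 18-80-year range, audiogram thresholds within [-10, 120] dB HL, bilateral
#' standard PTA at or below the study's 45 dB HL inclusion criterion,
#' single-run TMR thresholds integer-valued within [-10, 10], and derived
#' columns consistent with the primary data. Violations are reported as
#' warnings naming the row and column - never silent drops and never a
#' crash.
#'
#' @param cohort A cohort table.
#' @param warn Emit a summarizing warning when problems are found
#'   (default `TRUE`).
#' @return The cohort, invisibly, with a `problems` attribute: a tibble of
#'   (`row`, `column`, `value`, `message`), zero-row when the table is clean.
#' @export
validate_cohort <- function(cohort, warn = TRUE) {
  probs <- list()
  note <- function(rows, column, values, msg) {
    if (length(rows)) {
      probs[[length(probs) + 1L]] <<- tibble::tibble(
        row = as.integer(rows), column = column,
        value = as.numeric(values), message = msg)
    }
  }
  if ("age" %in% names(cohort)) {
    bad <- which(!is.na(cohort$age) & (cohort$age < 18 | cohort$age > 80))
    note(bad, "age", cohort$age[bad], "age outside the supported range [18, 80]")
  }
  for (col in intersect(audiogram_cols(), names(cohort))) {
    x <- cohort[[col]]
    bad <- which(!is.na(x) & (x < -10 | x > 120))
    note(bad, col, x[bad], "audiogram threshold outside [-10, 120] dB HL")
  }
  std_cols <- audiogram_cols(freqs = pta_freqs$standard)
  if (all(std_cols %in% names(cohort))) {
    p <- pta(cohort, "standard")
    bad <- which(is.finite(p) & p > 45)
    note(bad, "pta_st", p[bad],
         "bilateral standard PTA exceeds the 45 dB HL inclusion criterion")
  }
  for (col in intersect(c(threshold_cols(), derived_cols()), names(cohort))) {
    x <- cohort[[col]]
    # SRM is a difference of two thresholds, so its attainable range is twice
    # as wide as a single track's
    lim <- if (startsWith(col, "srm")) 20 else 10
    bad <- which(!is.na(x) & (x < -lim | x > lim))
    note(bad, col, x[bad],
         sprintf("threshold outside the attainable range [-%d, %d]", lim, lim))
    if (col %in% threshold_cols()) {
      frac <- which(!is.na(x) & abs(x - round(x)) > 1e-8)
      note(frac, col, x[frac], "single-run threshold is not an integer")
    }
  }
  if (all(c("colocated_1", "colocated_2", "colocated_avg") %in% names(cohort))) {
    d <- cohort$colocated_avg - average_runs(cohort$colocated_1, cohort$colocated_2)
    bad <- which(is.finite(d) & abs(d) > 1e-8)
    note(bad, "colocated_avg", cohort$colocated_avg[bad],
         "run average is not the mean of runs 1 and 2")
  }
  if (all(c("srm_1", "colocated_1", "separated_1") %in% names(cohort))) {
    d <- cohort$srm_1 - (cohort$colocated_1 - cohort$separated_1)
    bad <- which(is.finite(d) & abs(d) > 1e-8)
    note(bad, "srm_1", cohort$srm_1[bad],
         "SRM is not colocated minus separated for the matched run")
  }
  if ("retest_delay" %in% names(cohort)) {
    x <- cohort$retest_delay
    bad <- which(!is.na(x) & x < 0)
    note(bad, "retest_delay", x[bad], "retest delay is negative")
  }
  problems <- if (length(probs)) dplyr::bind_rows(probs) else
    tibble::tibble(row = integer(), column = character(),
                   value = numeric(), message = character())
  if (warn && nrow(problems)) {
    head_msg <- problems |>
      dplyr::slice_head(n = 5) |>
      dplyr::mutate(txt = sprintf("row %d, %s: %s (value %g)",
                                  .data$row, .data$column, .data$message,
                                  .data$value)) |>
      dplyr::pull("txt")
    warning(sprintf("Cohort validation found %d problem(s):\n  %s%s",
                    nrow(problems), paste(head_msg, collapse = "\n  "),
                    if (nrow(problems) > 5) "\n  ..." else ""),
            call. = FALSE)
  }
  attr(cohort, "problems") <- problems
  invisible(cohort)
}

#' Read a cohort CSV
#'
#' Reads a comma-separated, UTF-8, header-first cohort file (`.` decimal
#' separator), optionally renaming columns through `schema`, then recomputes
#' derived columns and validates every row. Spreadsheet exports must be
#' converted to this CSV layout first; `cohort_schema()` documents the
#' column map.
#'
#' @param path Path to the CSV file.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(age = "Age_years", colocated_1 = "Col1")`.
#' @return A validated cohort tibble with a `problems` attribute (see
#'   [validate_cohort()]).
#' @export
read_cohort <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    stop("Cohort file not found: ", path, call. = FALSE)
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!is.null(schema)) {
    for (canon in names(schema)) {
      if (!schema[[canon]] %in% names(raw)) {
        stop(sprintf("Schema maps '%s' to column '%s', which is absent from %s.",
                     canon, schema[[canon]], path), call. = FALSE)
      }
      names(raw)[names(raw) == schema[[canon]]] <- canon
    }
  }
  spec <- cohort_schema()
  required <- spec$column[spec$required]
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols)) {
    stop("Cohort file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  numeric_cols <- setdiff(intersect(spec$column, names(raw)),
                          c("id", "gender", "hearing_aid"))
  for (col in numeric_cols) {
    x <- raw[[col]]
    parsed <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & is.na(parsed))
    if (length(bad)) {
      stop(sprintf("Non-numeric value '%s' in column '%s', row %d of %s.",
                   x[bad[1]], col, bad[1], path), call. = FALSE)
    }
    raw[[col]] <- parsed
  }
  if ("age" %in% names(raw)) raw$age <- as.integer(round(raw$age))
  if ("retest_delay" %in% names(raw)) {
    raw$retest_delay <- as.integer(round(raw$retest_delay))
  }
  if ("hearing_aid" %in% names(raw)) {
    raw$hearing_aid <- as.logical(raw$hearing_aid)
  }
  if ("gender" %in% names(raw)) raw$gender[raw$gender == ""] <- NA_character_
  cohort <- derive_cohort(raw)
  validate_cohort(cohort)
}

#' Write a cohort table to CSV
#'
#' Writes a cohort with a stable column order (schema columns first, extras
#' after) at full floating-point precision, so that
#' `read_cohort(write_cohort(x))` reproduces `x` exactly.
#'
#' @param cohort A cohort table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  cohort <- tibble::as_tibble(cohort)
  ordered <- c(intersect(cohort_schema()$column, names(cohort)),
               setdiff(names(cohort), cohort_schema()$column))
  readr::write_csv(cohort[ordered], path, progress = FALSE)
  invisible(path)
}
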