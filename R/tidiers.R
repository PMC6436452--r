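#' @importFrom broom tidy glance
#' @export
broom::tidy

#' @export
broom::glance

#' Tidy a normative model
#'
#' @param x An `sr2_model`.
#' @param ... Unused.
#' @return A one-row tibble in the layout of the published coefficient
#'   table: `condition`, `run`, `adj_r2`, `constant`, `beta_age`,
#'   `beta_pta`, `model_error`, `n`.
#' @export
tidy.sr2_model <- function(x, ...) {
  tibble::tibble(
    condition = x$condition, run = x$run, adj_r2 = x$adj_r2,
    constant = x$constant, beta_age = x$beta_age, beta_pta = x$beta_pta,
    model_error = x$model_error, n = x$n
  )
}

#' @rdname tidy.sr2_model
#' @method glance sr2_model
#' @export
glance.sr2_model <- function(x, ...) {
  tibble::tibble(
    adj_r2 = x$adj_r2, model_error = x$model_error, n = x$n,
    n_predictors = length(x$predictors),
    error_method = x$error_method
  )
}

#' Tidy a set of normative models
#'
#' @param x An `sr2_modelset`.
#' @param ... Unused.
#' @return One row per model, in the coefficient-table layout.
#' @method tidy sr2_modelset
#' @export
tidy.sr2_modelset <- function(x, ...) {
  purrr::map_dfr(unclass(x), tidy)
}

#' Threshold summary in the published table layout
#'
#' Means and standard deviations of the TMR thresholds and SRM per
#' condition and run (1, 2, average).
#'
#' @param cohort A cohort table with derived columns.
#' @return A tibble: `condition`, `run`, `mean_db`, `sd_db`, `n`.
#' @examples
#' threshold_summary(simulate_cohort(sim_config(n = 82, seed = 1)))
#' @export
threshold_summary <- function(cohort) {
  cols <- c(threshold_cols(), derived_cols())
  cols <- cols[cols %in% names(cohort)]
  purrr::map_dfr(cols, function(col) {
    parts <- strsplit(col, "_", fixed = TRUE)[[1]]
    tibble::tibble(
      condition = parts[1], run = parts[2],
      mean_db = mean(cohort[[col]], na.rm = TRUE),
      sd_db = stats::sd(cohort[[col]], na.rm = TRUE),
      n = sum(is.finite(cohort[[col]]))
    )
  }) |>
    dplyr::arrange(factor(.data$condition,
                          levels = c("colocated", "separated", "srm")),
                   factor(.data$run, levels = c("1", "2", "avg")))
}
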