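#' The fixed SR2 progressive-track TMR schedule
#'
#' The SR2 presents 20 trials at target-to-masker ratios (TMRs) descending
#' from +10 dB to -8 dB in 2-dB steps, two trials at each of the 10 levels.
#'
#' @return Numeric vector of 20 TMR levels in presentation order (dB).
#' @examples
#' tmr_schedule()
#' @export
tmr_schedule <- function() {
  rep(seq(10, -8, by = -2), each = 2L)
}

#' Construct a single progressive-track trial block
#'
#' A trial block is one 20-trial run of the SR2 in one spatial condition.
#' Each trial is scored correct only when both the reported color and number
#' match the target sentence (closed-set CRM response).
#'
#' @param correct Logical vector of length 20: trial-by-trial correctness in
#'   presentation order.
#' @param condition `"colocated"` or `"separated"`.
#' @param schedule TMR levels (dB) in presentation order; defaults to the
#'   fixed SR2 schedule. Must contain exactly two trials at each of the 10
#'   levels 10, 8, ..., -8 dB.
#' @return A tibble with columns `trial`, `condition`, `tmr`, `correct`.
#' @examples
#' blk <- trial_block(rep(c(TRUE, FALSE), each = 10))
#' estimate_threshold(blk)
#' @export
trial_block <- function(correct, condition = c("colocated", "separated"),
                        schedule = tmr_schedule()) {
  condition <- match.arg(condition)
  if (length(correct) != 20L || anyNA(correct) || !is.logical(correct)) {
    stop("`correct` must be a logical vector of exactly 20 trials with no NA.",
         call. = FALSE)
  }
  levels <- seq(10, -8, by = -2)
  counts <- vapply(levels, function(l) sum(schedule == l), integer(1))
  if (length(schedule) != 20L || !all(counts == 2L) ||
      !all(schedule %in% levels)) {
    stop("`schedule` must contain exactly two trials at each TMR level 10, 8, ..., -8 dB.",
         call. = FALSE)
  }
  tibble::tibble(
    trial = seq_len(20L),
    condition = condition,
    tmr = as.numeric(schedule),
    correct = correct
  )
}

#' Estimate the TMR threshold from one progressive track
#'
#' The SR2 scoring rule: the threshold in dB TMR is 10 minus the number of
#' correct responses out of 20. A listener who answers every trial correctly
#' scores -10 dB; one who misses every trial scores +10 dB; half correct
#' scores 0 dB. The estimate depends only on the count of correct responses,
#' never their order, and cannot fall outside [-10, +10].
#'
#' @param block A trial block from [trial_block()] (or any data frame with a
#'   logical `correct` column of length 20), or a bare logical vector of 20
#'   correctness flags.
#' @return Integer threshold estimate in dB TMR.
#' @examples
#' estimate_threshold(trial_block(rep(TRUE, 20)))   # -10
#' estimate_threshold(rep(FALSE, 20))               # +10
#' @export
estimate_threshold <- function(block) {
  correct <- if (is.data.frame(block)) block$correct else block
  if (is.null(correct) || length(correct) != 20L || anyNA(correct)) {
    stop("A progressive track must contain exactly 20 scored trials.",
         call. = FALSE)
  }
  10L - sum(as.logical(correct))
}

#' Spatial release from masking
#'
#' SRM is the threshold difference between the colocated and spatially
#' separated conditions: a positive value means the listener benefits from
#' spatial separation of the maskers.
#'
#' @param colocated,separated Thresholds in dB TMR, each within [-10, 10].
#'   Vectorized.
#' @return `colocated - separated`, in dB.
#' @examples
#' compute_srm(2.34, -3.29)  # 5.63
#' @export
compute_srm <- function(colocated, separated) {
  check_tmr_range(colocated, "colocated")
  check_tmr_range(separated, "separated")
  colocated - separated
}

#' Average two test runs
#'
#' @param run1,run2 Thresholds (dB), vectorized.
#' @return Arithmetic mean of the two runs.
#' @examples
#' average_runs(2.34, 1.57)  # 1.955
#' @export
average_runs <- function(run1, run2) {
  (run1 + run2) / 2
}

check_tmr_range <- function(x, what) {
  bad <- which(is.finite(x) & (x < -10 | x > 10))
  if (length(bad)) {
    stop(sprintf("`%s` threshold outside the attainable range [-10, 10] at position %d (value %g).",
                 what, bad[1], x[bad[1]]), call. = FALSE)
  }
  invisible(x)
}

#' Score a trial-level response table into thresholds
#'
#' Collapses a long table of individual SR2 trials (one row per trial) into
#' one threshold per participant, condition, and run, then derives run
#' averages and SRM, yielding a cohort-table fragment that can be joined to
#' demographics.
#'
#' @param trials A data frame with columns `id`, `condition`
#'   (colocated/separated), `run` (1 or 2), `correct` (logical or 0/1), and
#'   optionally `trial` and `tmr`.
#' @return A tibble with one row per participant: `colocated_1`,
#'   `colocated_2`, `separated_1`, `separated_2` plus derived `colocated_avg`,
#'   `separated_avg`, `srm_1`, `srm_2`, `srm_avg`.
#' @examples
#' cfg <- sim_config(n = 3, seed = 1)
#' sim <- simulate_cohort(cfg, trials = TRUE)
#' score_trials(attr(sim, "trials"))
#' @export
score_trials <- function(trials) {
  required <- c("id", "condition", "run", "correct")
  missing_cols <- setdiff(required, names(trials))
  if (length(missing_cols)) {
    stop("Trial table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_cond <- setdiff(unique(trials$condition), c("colocated", "separated"))
  if (length(bad_cond)) {
    stop("Unknown condition(s) in trial table: ",
         paste(bad_cond, collapse = ", "), call. = FALSE)
  }
  scored <- trials |>
    dplyr::mutate(correct = as.logical(.data$correct)) |>
    dplyr::group_by(.data$id, .data$condition, .data$run) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      threshold = 10 - sum(.data$correct),
      .groups = "drop"
    )
  short <- dplyr::filter(scored, .data$n_trials != 20L)
  if (nrow(short)) {
    stop(sprintf("Track for id '%s', %s run %s has %d trials; exactly 20 are required.",
                 short$id[1], short$condition[1], short$run[1], short$n_trials[1]),
         call. = FALSE)
  }
  wide <- scored |>
    dplyr::select(-"n_trials") |>
    tidyr::pivot_wider(names_from = c("condition", "run"),
                       values_from = "threshold", names_sep = "_")
  derive_cohort(wide)
}
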