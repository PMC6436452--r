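#' Ordinary least-squares fit with inference
#'
#' Fits `response ~ 1 + predictors` by ordinary least squares and returns
#' the pieces the normative pipeline needs: coefficient estimates with
#' standard errors and two-sided t-test p-values (df = n - p - 1), adjusted
#' R-squared, and residuals.
#'
#' @param data A data frame of predictor columns (no intercept column; one
#'   is always added).
#' @param response Numeric response vector, `length(response) == nrow(data)`.
#' @return A list with `coefficients` (tibble: `term`, `estimate`,
#'   `std_error`, `p_value`), `adj_r2`, `r2`, `sigma`, `residuals`,
#'   `fitted`, `n`, and the underlying `lm` fit.
#' @examples
#' d <- data.frame(age = c(20, 30, 40, 50, 60, 70))
#' ols_fit(d, 2 + 0.05 * d$age)
#' @export
ols_fit <- function(data, response) {
  data <- as.data.frame(data)
  n <- nrow(data)
  p <- ncol(data)
  if (length(response) != n) {
    stop("`response` must have one value per row of `data`.", call. = FALSE)
  }
  if (n < p + 2L) {
    stop(sprintf("Need at least %d rows to fit %d predictor(s) plus an intercept; got %d.",
                 p + 2L, p, n), call. = FALSE)
  }
  x <- if (p > 0L) stats::model.matrix(~ ., data = data) else
    matrix(1, nrow = n, dimnames = list(NULL, "(Intercept)"))
  if (qr(x)$rank < ncol(x)) {
    stop("Design matrix is rank deficient; drop collinear predictors.",
         call. = FALSE)
  }
  df <- data.frame(.response = response, data, check.names = FALSE)
  fit <- if (p > 0L) stats::lm(.response ~ ., data = df) else
    stats::lm(.response ~ 1, data = df)
  sm <- suppressWarnings(summary(fit))
  coefs <- tibble::tibble(
    term = rownames(sm$coefficients),
    estimate = unname(sm$coefficients[, "Estimate"]),
    std_error = unname(sm$coefficients[, "Std. Error"]),
    p_value = unname(sm$coefficients[, "Pr(>|t|)"])
  )
  list(coefficients = coefs, adj_r2 = sm$adj.r.squared, r2 = sm$r.squared,
       sigma = sm$sigma, residuals = unname(stats::residuals(fit)),
       fitted = unname(stats::fitted(fit)), n = n, fit = fit)
}

#' Fit one normative regression function
#'
#' Fits the normative model for one outcome (a condition-by-run threshold or
#' SRM) on age and bilateral standard PTA, with backward elimination of
#' non-significant terms: the age-by-PTA interaction is tested first and
#' dropped when non-significant, then main effects are removed one at a time
#' (largest p-value first, refitting after each removal) until every
#' surviving term has p below `alpha`. The model error of the final fit is
#' the root-mean-square (or mean-absolute) residual and becomes the SD
#' denominator of the Z-score transform.
#'
#' A non-finite p-value (e.g. from a perfect, zero-residual fit where the
#' term's estimate is numerically zero) is treated as non-significant.
#'
#' @param data A cohort table, or any data frame with `age`, `pta_st` (or
#'   `pta`) and the outcome column.
#' @param outcome Name of the outcome column, e.g. `"srm_avg"` or
#'   `"separated_1"`.
#' @param alpha Significance level for term retention (default .05).
#' @param error_method `"rmse"` (default) or `"mae"`.
#' @param condition,run Labels stored on the model; inferred from `outcome`
#'   when it follows the `<condition>_<run>` naming.
#' @return An [normative_model()] object (`sr2_model`) with the final `lm`
#'   fit attached as attribute `fit`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 82, seed = 42))
#' fit_normative_model(cohort, "separated_avg")
#' @export
fit_normative_model <- function(data, outcome, alpha = 0.05,
                                error_method = c("rmse", "mae"),
                                condition = NULL, run = NULL) {
  error_method <- match.arg(error_method)
  pta_col <- if ("pta_st" %in% names(data)) "pta_st" else "pta"
  for (col in c("age", pta_col, outcome)) {
    if (!col %in% names(data)) {
      stop("Column '", col, "' is required to fit a normative model.",
           call. = FALSE)
    }
  }
  if (is.null(condition) || is.null(run)) {
    parts <- strsplit(outcome, "_", fixed = TRUE)[[1]]
    if (length(parts) == 2L && parts[1] %in% c("colocated", "separated", "srm") &&
        parts[2] %in% c("1", "2", "avg", "average")) {
      condition <- condition %||% parts[1]
      run <- run %||% parts[2]
    } else {
      condition <- condition %||% "srm"
      run <- run %||% "avg"
    }
  }
  d <- data.frame(age = as.numeric(data$age), pta = as.numeric(data[[pta_col]]))
  y <- as.numeric(data[[outcome]])
  keep <- stats::complete.cases(d) & is.finite(y)
  d <- d[keep, , drop = FALSE]
  y <- y[keep]

  ns <- function(p) !is.finite(p) || p >= alpha
  # Full model with interaction; drop the interaction first when NS.
  d_full <- d
  d_full$age_x_pta <- d$age * d$pta
  full <- ols_fit(d_full, y)
  p_int <- full$coefficients$p_value[full$coefficients$term == "age_x_pta"]
  current_terms <- if (ns(p_int)) c("age", "pta") else c("age", "pta", "age_x_pta")
  res <- if (ns(p_int)) ols_fit(d, y) else full
  # Backward elimination of main effects (the interaction, when retained,
  # keeps its parents per model hierarchy).
  if (!"age_x_pta" %in% current_terms) {
    repeat {
      mains <- res$coefficients[res$coefficients$term != "(Intercept)", ]
      drop_idx <- which(vapply(mains$p_value, ns, logical(1)))
      if (!length(drop_idx) || nrow(mains) == 0L) break
      worst <- mains$term[drop_idx[which.max(
        replace(mains$p_value[drop_idx], !is.finite(mains$p_value[drop_idx]), Inf))]]
      current_terms <- setdiff(current_terms, worst)
      res <- ols_fit(d[, current_terms, drop = FALSE], y)
    }
  }
  if (!length(current_terms)) {
    warning(sprintf("No predictor reached significance for '%s'; returning an intercept-only model.",
                    outcome), call. = FALSE)
  }
  err <- switch(error_method,
                rmse = sqrt(mean(res$residuals^2)),
                mae = mean(abs(res$residuals)))
  est <- function(term) {
    i <- match(term, res$coefficients$term)
    if (is.na(i)) NA_real_ else res$coefficients$estimate[i]
  }
  pv <- stats::setNames(res$coefficients$p_value, res$coefficients$term)
  model <- normative_model(condition, run,
                           constant = est("(Intercept)"),
                           beta_age = est("age"), beta_pta = est("pta"),
                           model_error = err, adj_r2 = res$adj_r2,
                           n = res$n, p_values = pv,
                           error_method = error_method)
  model$interaction <- if ("age_x_pta" %in% current_terms) est("age_x_pta") else NA_real_
  attr(model, "fit") <- res
  model
}

#' Fit the full set of nine normative models
#'
#' One model per condition (colocated, separated, SRM) and run label
#' (1, 2, average), mirroring the published analysis.
#'
#' @inheritParams fit_normative_model
#' @param cohort A cohort table with derived columns present.
#' @return An `sr2_modelset` of nine `sr2_model` objects.
#' @export
fit_normative_models <- function(cohort, alpha = 0.05,
                                 error_method = c("rmse", "mae")) {
  error_method <- match.arg(error_method)
  grid <- tidyr::expand_grid(condition = c("colocated", "separated", "srm"),
                             run = c("1", "2", "avg"))
  models <- purrr::pmap(grid, function(condition, run) {
    fit_normative_model(cohort, paste(condition, run, sep = "_"),
                        alpha = alpha, error_method = error_method,
                        condition = condition, run = run)
  })
  names(models) <- measure_label(grid$condition, grid$run)
  new_modelset(models, metadata = list(n = nrow(cohort), alpha = alpha,
                                       error_method = error_method))
}

#' Model error of a fitted normative function on a cohort
#'
#' The average magnitude of (observed - predicted) across participants:
#' root-mean-square by default, mean-absolute on request.
#'
#' @param model An `sr2_model`.
#' @param data Cohort (or any data frame with `age`, `pta_st`/`pta` and the
#'   outcome column).
#' @param outcome Outcome column name; defaults to the model's
#'   `<condition>_<run>` measure.
#' @param method `"rmse"` or `"mae"`.
#' @return Model error in dB.
#' @export
model_error <- function(model, data, outcome = NULL,
                        method = c("rmse", "mae")) {
  method <- match.arg(method)
  outcome <- outcome %||% measure_label(model$condition, model$run)
  if (!outcome %in% names(data)) {
    stop("Column '", outcome, "' not found in `data`.", call. = FALSE)
  }
  pta_col <- if ("pta_st" %in% names(data)) "pta_st" else "pta"
  pred <- predict_threshold(model,
                            age = if ("age" %in% model$predictors) data$age,
                            pta = if ("pta" %in% model$predictors) data[[pta_col]],
                            warn_extrapolation = FALSE)
  resid <- data[[outcome]] - pred
  switch(method, rmse = sqrt(mean(resid^2, na.rm = TRUE)),
         mae = mean(abs(resid), na.rm = TRUE))
}

#' Predict a threshold from a normative model
#'
#' Evaluates the linear normative function
#' `constant + age * beta_age + PTA * beta_pta` over the model's included
#' predictors only. Inputs outside the supported ranges (age 18-80 years,
#' PTA 0-45 dB HL) are computed but flagged as extrapolation with a warning.
#'
#' @param model An `sr2_model`.
#' @param age Age in years (vectorized); required iff the model includes age.
#' @param pta Bilateral standard PTA in dB HL; required iff included.
#' @param warn_extrapolation Warn when predicting outside the supported
#'   ranges (default `TRUE`).
#' @return Numeric vector of predicted thresholds (dB).
#' @examples
#' predict_threshold(sr2_norms()$separated_avg, age = 50, pta = 10)  # -4.327
#' @export
predict_threshold <- function(model, age = NULL, pta = NULL,
                              warn_extrapolation = TRUE) {
  needs_age <- "age" %in% model$predictors
  needs_pta <- "pta" %in% model$predictors
  if (needs_age && is.null(age)) {
    stop("This model includes age; supply `age`.", call. = FALSE)
  }
  if (needs_pta && is.null(pta)) {
    stop("This model includes PTA; supply `pta`.", call. = FALSE)
  }
  n <- max(1L, length(age), length(pta))
  pred <- rep(model$constant, n)
  if (needs_age) pred <- pred + as.numeric(age) * model$beta_age
  if (needs_pta) pred <- pred + as.numeric(pta) * model$beta_pta
  if (warn_extrapolation) {
    extra <- extrapolation_flags(model, age, pta)
    if (any(extra)) {
      warning(sprintf("%d prediction(s) fall outside the supported ranges (age 18-80, PTA 0-45 dB HL) and are extrapolations.",
                      sum(extra)), call. = FALSE)
    }
  }
  pred
}

extrapolation_flags <- function(model, age = NULL, pta = NULL) {
  n <- max(1L, length(age), length(pta))
  out <- rep(FALSE, n)
  if ("age" %in% model$predictors && !is.null(age)) {
    out <- out | (!is.na(age) & (age < 18 | age > 80))
  }
  if ("pta" %in% model$predictors && !is.null(pta)) {
    out <- out | (!is.na(pta) & (pta < 0 | pta > 45))
  }
  out
}

#' Z-score an observed threshold against a normative model
#'
#' `z = (observed - predicted) / model_error`, where the model error plays
#' the role of the SD of the normative distribution. Scores at or beyond
#' `k` SDs (default 2, two-sided) are flagged as abnormal for the given age
#' and hearing level.
#'
#' @param model An `sr2_model` with positive `model_error`.
#' @param observed Observed threshold(s) in dB.
#' @param age,pta Predictor values as required by the model (vectorized).
#' @param k Flagging criterion in SD units (default 2; the boundary is
#'   inclusive).
#' @return A tibble: `condition`, `run`, `observed`, `predicted`, `z`,
#'   `flagged`, `extrapolated`.
#' @examples
#' z_score(sr2_norms()$srm_avg, observed = 2.0, pta = 10)  # z ~ -2.98
#' @export
z_score <- function(model, observed, age = NULL, pta = NULL, k = 2) {
  if (!is.finite(model$model_error) || model$model_error <= 0) {
    stop("Model error must be strictly positive to compute Z-scores.",
         call. = FALSE)
  }
  predicted <- predict_threshold(model, age = age, pta = pta,
                                 warn_extrapolation = FALSE)
  z <- (observed - predicted) / model$model_error
  tibble::tibble(
    condition = model$condition, run = model$run,
    observed = as.numeric(observed), predicted = predicted, z = z,
    flagged = abs(z) >= k,
    extrapolated = extrapolation_flags(model, age, pta)
  )
}

#' Z-score every participant on every available measure
#'
#' @param cohort A cohort table with derived columns.
#' @param models An `sr2_modelset` (default: the published norms for all
#'   nine measures).
#' @param k Flagging criterion in SD units (default 2).
#' @return A long tibble with one row per participant and measure: `id`,
#'   `condition`, `run`, `observed`, `predicted`, `z`, `flagged`,
#'   `extrapolated`.
#' @export
z_report <- function(cohort, models = sr2_norms(), k = 2) {
  pta_col <- if ("pta_st" %in% names(cohort)) "pta_st" else "pta"
  purrr::map_dfr(unclass(models), function(m) {
    outcome <- measure_label(m$condition, m$run)
    if (!outcome %in% names(cohort)) return(NULL)
    dplyr::bind_cols(
      tibble::tibble(id = as.character(cohort$id)),
      z_score(m, observed = cohort[[outcome]],
              age = if ("age" %in% m$predictors) cohort$age,
              pta = if ("pta" %in% m$predictors) cohort[[pta_col]],
              k = k)
    )
  })
}

#' Flag participants abnormal on any measure
#'
#' A participant is flagged when any of the nine condition-by-run measures
#' yields a Z-score at or beyond `k` SDs from the value predicted for their
#' age and PTA.
#'
#' @inheritParams z_report
#' @return A tibble of flagged participants (`id`, `n_flagged`, `measures`,
#'   `worst_z`), with the full per-measure report attached as attribute
#'   `report`.
#' @export
flag_outliers <- function(cohort, models = sr2_norms(), k = 2) {
  expected <- measure_label(rep(c("colocated", "separated", "srm"), each = 3),
                            rep(c("1", "2", "avg"), 3))
  missing_models <- setdiff(expected, names(models))
  if (length(missing_models)) {
    stop("Missing normative model(s) for measure(s): ",
         paste(missing_models, collapse = ", "), call. = FALSE)
  }
  report <- z_report(cohort, models, k = k)
  flagged <- report |>
    dplyr::filter(.data$flagged) |>
    dplyr::group_by(.data$id) |>
    dplyr::summarise(
      n_flagged = dplyr::n(),
      measures = paste(measure_label(.data$condition, .data$run), collapse = ";"),
      worst_z = .data$z[which.max(abs(.data$z))][1],
      .groups = "drop"
    )
  attr(flagged, "report") <- report
  flagged
}

#' Correlation screen with Bonferroni criterion
#'
#' Pearson correlations of the run-averaged outcomes (colocated, separated,
#' SRM) with age and each hearing-loss measure present (bilateral SRT,
#' standard PTA, high-frequency PTA), plus the correlation of each
#' hearing-loss measure with age. The significance criterion is the family
#' alpha divided by the number of correlations considered (with the full
#' predictor set, .05/15 = .0033), reported alongside the exact critical
#' |r| it implies at the cohort's n.
#'
#' When `retest_delay` is present, its correlations with the run-1-minus-
#' run-2 difference scores are reported in attribute `retest_delay` (these
#' never enter the normative models).
#'
#' @param cohort A cohort table with derived columns.
#' @param alpha Family-wise alpha (default .05).
#' @return A tibble (`predictor`, `outcome`, `r`, `p`, `n`, `significant`)
#'   with attributes `criterion` (Bonferroni-corrected p criterion, rounded
#'   to 4 decimals), `n_correlations`, and `critical_r`.
#' @export
correlation_table <- function(cohort, alpha = 0.05) {
  outcomes <- c(colocated = "colocated_avg", separated = "separated_avg",
                srm = "srm_avg")
  outcomes <- outcomes[outcomes %in% names(cohort)]
  preds <- c(age = "age")
  if (all(c("srt_L", "srt_R") %in% names(cohort))) {
    cohort$srt <- (cohort$srt_L + cohort$srt_R) / 2
    preds <- c(preds, srt = "srt")
  }
  if ("pta_st" %in% names(cohort)) preds <- c(preds, pta_st = "pta_st")
  if ("pta_hf" %in% names(cohort)) preds <- c(preds, pta_hf = "pta_hf")
  pairs <- dplyr::bind_rows(
    tidyr::expand_grid(predictor = names(preds), outcome = names(outcomes)),
    tibble::tibble(predictor = setdiff(names(preds), "age"), outcome = "age")
  )
  cor_one <- function(xcol, ycol) {
    x <- cohort[[xcol]]
    y <- cohort[[ycol]]
    ok <- is.finite(x) & is.finite(y)
    n <- sum(ok)
    if (n < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(tibble::tibble(r = NA_real_, p = NA_real_, n = n))
    }
    ct <- stats::cor.test(x[ok], y[ok])
    tibble::tibble(r = unname(ct$estimate), p = ct$p.value, n = n)
  }
  lookup <- c(preds, outcomes)
  stats_tbl <- purrr::map2_dfr(pairs$predictor, pairs$outcome,
                               function(p, o) cor_one(lookup[[p]], lookup[[o]]))
  out <- dplyr::bind_cols(pairs, stats_tbl)
  n_cor <- nrow(out)
  criterion <- round(alpha / n_cor, 4)
  out$significant <- !is.na(out$p) & out$p < criterion
  n_med <- stats::median(out$n, na.rm = TRUE)
  tcrit <- stats::qt(1 - criterion / 2, df = n_med - 2)
  attr(out, "criterion") <- criterion
  attr(out, "n_correlations") <- n_cor
  attr(out, "critical_r") <- tcrit / sqrt(n_med - 2 + tcrit^2)
  if ("retest_delay" %in% names(cohort) &&
      any(is.finite(cohort$retest_delay))) {
    diffs <- tibble::tibble(
      colocated = cohort$colocated_1 - cohort$colocated_2,
      separated = cohort$separated_1 - cohort$separated_2,
      srm = cohort$srm_1 - cohort$srm_2
    )
    attr(out, "retest_delay") <- purrr::imap_dfr(diffs, function(d, nm) {
      ok <- is.finite(d) & is.finite(cohort$retest_delay)
      if (sum(ok) < 3 || stats::sd(d[ok]) == 0 ||
          stats::sd(cohort$retest_delay[ok]) == 0) {
        return(tibble::tibble(outcome_difference = nm, r = NA_real_,
                              p = NA_real_, n = sum(ok)))
      }
      ct <- stats::cor.test(cohort$retest_delay[ok], d[ok])
      tibble::tibble(outcome_difference = nm, r = unname(ct$estimate),
                     p = ct$p.value, n = sum(ok))
    })
  }
  out
}

#' Normative band around a predictive function
#'
#' Evaluates a normative model along a grid of one predictor (the other held
#' fixed) and returns the predicted line with a band of plus/minus
#' `k` model errors - the dashed 1-SD envelopes of the published normative
#' figures.
#'
#' @param model An `sr2_model`.
#' @param grid Numeric grid for the varying predictor. Defaults to the
#'   supported range of that predictor (ages 18-80 or PTA 0-45).
#' @param vary `"age"` or `"pta"`: which predictor the grid runs over.
#' @param fixed_age,fixed_pta Value of the non-varying predictor when the
#'   model includes it (defaults: age 50 years, PTA 10 dB HL, matching the
#'   published figures).
#' @param k Band half-width in model-error units (default 1).
#' @return A tibble of class `sr2_band` with columns named after `vary`
#'   plus `lower`, `center`, `upper`.
#' @examples
#' normative_band(sr2_norms()$srm_avg, vary = "pta")
#' @export
normative_band <- function(model, grid = NULL, vary = c("pta", "age"),
                           fixed_age = 50, fixed_pta = 10, k = 1) {
  vary <- match.arg(vary)
  if (is.null(grid)) {
    grid <- if (vary == "age") seq(18, 80) else seq(0, 45)
  }
  age <- if (vary == "age") grid else fixed_age
  pta <- if (vary == "pta") grid else fixed_pta
  center <- predict_threshold(model,
                              age = if ("age" %in% model$predictors) age,
                              pta = if ("pta" %in% model$predictors) pta,
                              warn_extrapolation = FALSE)
  center <- rep_len(center, length(grid))
  out <- tibble::tibble(!!vary := as.numeric(grid),
                        lower = center - k * model$model_error,
                        center = center,
                        upper = center + k * model$model_error)
  structure(out, class = c("sr2_band", class(out)),
            model = model, vary = vary, k = k,
            fixed = if (vary == "age") c(pta = fixed_pta) else c(age = fixed_age))
}

#' Draw outcomes directly from a normative model
#'
#' Samples `predicted + Normal(0, noise_sd)` for each row of `data` - the
#' regression-level generative process used in parameter-recovery
#' simulations (no progressive-track layer, hence no -10 dB floor).
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param model An `sr2_model` acting as generative truth.
#' @param data Data frame with `age` and/or `pta_st`/`pta` as the model
#'   requires.
#' @param noise_sd Residual SD (dB); defaults to the model's `model_error`.
#' @return Numeric vector of simulated outcomes.
#' @export
draw_normative_outcome <- function(model, data, noise_sd = model$model_error) {
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be a nonnegative number.", call. = FALSE)
  }
  pta_col <- if ("pta_st" %in% names(data)) "pta_st" else "pta"
  pred <- predict_threshold(model,
                            age = if ("age" %in% model$predictors) data$age,
                            pta = if ("pta" %in% model$predictors) data[[pta_col]],
                            warn_extrapolation = FALSE)
  rep_len(pred, nrow(data)) + stats::rnorm(nrow(data), 0, noise_sd)
}
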