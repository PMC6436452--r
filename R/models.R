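#' Construct a normative model
#'
#' A normative model predicts a TMR threshold (or SRM) from age and/or
#' bilateral standard PTA through the linear normative function
#' `predicted = constant + age * beta_age + PTA * beta_pta`, and carries the
#' model error (dB) used as the standard deviation in the Z-score transform.
#'
#' @param condition `"colocated"`, `"separated"` or `"srm"`.
#' @param run Run label: `"1"`, `"2"` or `"avg"`.
#' @param constant Intercept (dB).
#' @param beta_age Age coefficient (dB/year), or `NA` when age is excluded.
#' @param beta_pta PTA coefficient (dB per dB HL), or `NA` when excluded.
#' @param model_error Residual scale (dB); must be positive to Z-score.
#' @param adj_r2 Adjusted R-squared of the fit (optional).
#' @param n Number of participants behind the fit (optional).
#' @param p_values Named numeric vector of per-coefficient p-values
#'   (optional).
#' @param error_method `"rmse"` or `"mae"` - how `model_error` was computed.
#' @return An object of class `sr2_model`.
#' @examples
#' m <- normative_model("srm", "avg", constant = 9.166,
#'                      beta_pta = -0.171, model_error = 1.830)
#' predict_threshold(m, pta = 10)
#' @export
normative_model <- function(condition = c("colocated", "separated", "srm"),
                            run = c("1", "2", "avg"),
                            constant,
                            beta_age = NA_real_,
                            beta_pta = NA_real_,
                            model_error = NA_real_,
                            adj_r2 = NA_real_,
                            n = NA_integer_,
                            p_values = NULL,
                            error_method = "rmse") {
  condition <- match.arg(condition)
  run <- normalize_run(run)
  stopifnot(is.numeric(constant), length(constant) == 1L)
  if (!is.na(model_error) && model_error < 0) {
    stop("`model_error` must be nonnegative.", call. = FALSE)
  }
  predictors <- c("age", "pta")[c(!is.na(beta_age), !is.na(beta_pta))]
  structure(
    list(condition = condition, run = run, predictors = predictors,
         constant = as.numeric(constant), beta_age = as.numeric(beta_age),
         beta_pta = as.numeric(beta_pta),
         model_error = as.numeric(model_error),
         adj_r2 = as.numeric(adj_r2), n = as.integer(n),
         p_values = p_values, error_method = error_method),
    class = "sr2_model"
  )
}

normalize_run <- function(run) {
  run <- as.character(run)
  run <- match.arg(run, c("1", "2", "avg", "average"))
  if (run == "average") "avg" else run
}

measure_label <- function(condition, run) paste(condition, run, sep = "_")

#' @export
print.sr2_model <- function(x, ...) {
  terms <- c(sprintf("%.4g", x$constant),
             if (!is.na(x$beta_age)) sprintf("%+.4g * age", x$beta_age),
             if (!is.na(x$beta_pta)) sprintf("%+.4g * PTA", x$beta_pta))
  cat(sprintf("<SR2 normative model: %s, run %s>\n", x$condition, x$run))
  cat("  predicted =", paste(terms, collapse = " "), "\n")
  cat(sprintf("  model error %.3f dB (%s)", x$model_error, x$error_method))
  if (!is.na(x$adj_r2)) cat(sprintf(", adj. R2 %.3f", x$adj_r2))
  if (!is.na(x$n)) cat(sprintf(", n = %d", x$n))
  cat("\n")
  invisible(x)
}

#' Published SR2 normative coefficients
#'
#' The normative functions published for the SR2 test, fitted to 82 adults
#' aged 18-80 with bilateral standard PTAs of 0-45 dB HL: for each spatial
#' condition (colocated, separated) and for SRM, one model per run (1, 2)
#' and for the average of both runs. The colocated functions include only
#' age, the separated functions include age and PTA, and the SRM functions
#' include only PTA.
#'
#' @param run Optional run label (`"1"`, `"2"`, `"avg"`) to subset.
#' @param condition Optional condition to subset.
#' @return An `sr2_modelset`: a named list of [normative_model()] objects
#'   keyed `<condition>_<run>`.
#' @examples
#' sr2_norms()$srm_avg
#' predict_threshold(sr2_norms()$separated_avg, age = 50, pta = 10)
#' @export
sr2_norms <- function(run = NULL, condition = NULL) {
  tab <- tibble::tribble(
    ~condition, ~run, ~adj_r2, ~p, ~constant, ~beta_age, ~beta_pta, ~model_error,
    "colocated", "1",   0.071, 0.033,  0.957, 0.035, NA,     1.425,
    "colocated", "2",   0.050, 0.070,  0.141, 0.030, NA,     1.525,
    "colocated", "avg", 0.121, 0.005,  0.549, 0.033, NA,     1.045,
    "separated", "1",   0.280, 0.001, -8.207, 0.058, 0.174,  2.566,
    "separated", "2",   0.406, 0.001, -9.027, 0.047, 0.153,  1.894,
    "separated", "avg", 0.419, 0.001, -8.617, 0.053, 0.164,  1.864,
    "srm",       "1",   0.226, 0.001,  9.163, NA,    -0.188, 2.708,
    "srm",       "2",   0.241, 0.001,  9.168, NA,    -0.154, 2.189,
    "srm",       "avg", 0.377, 0.001,  9.166, NA,    -0.171, 1.830
  )
  if (!is.null(run)) tab <- tab[tab$run == normalize_run(run), ]
  if (!is.null(condition)) tab <- tab[tab$condition == condition, ]
  models <- purrr::pmap(tab, function(condition, run, adj_r2, p, constant,
                                      beta_age, beta_pta, model_error) {
    normative_model(condition, run, constant = constant, beta_age = beta_age,
                    beta_pta = beta_pta, model_error = model_error,
                    adj_r2 = adj_r2, n = 82L)
  })
  names(models) <- measure_label(tab$condition, tab$run)
  new_modelset(models, metadata = list(source = "published SR2 norms", n = 82L))
}

new_modelset <- function(models, metadata = list()) {
  structure(models, metadata = metadata, class = "sr2_modelset")
}

#' @export
print.sr2_modelset <- function(x, ...) {
  cat(sprintf("<SR2 normative model set: %d model(s)>\n", length(x)))
  print(tidy.sr2_modelset(x), n = length(x))
  invisible(x)
}

#' @export
`[.sr2_modelset` <- function(x, i) {
  new_modelset(NextMethod(), metadata = attr(x, "metadata"))
}

#' Serialize normative models to JSON
#'
#' Writes an `sr2_modelset` (or a single `sr2_model`) to a JSON model file
#' at full floating-point precision together with provenance metadata, so
#' that `read_models(write_models(m))` reproduces every coefficient
#' bit-identically.
#'
#' @param models An `sr2_modelset` or single `sr2_model`.
#' @param path Output path (`.json`).
#' @param metadata Optional named list merged into the file's metadata.
#' @return `path`, invisibly.
#' @export
write_models <- function(models, path, metadata = list()) {
  if (inherits(models, "sr2_model")) {
    models <- new_modelset(stats::setNames(list(models),
                                           measure_label(models$condition, models$run)))
  }
  if (!inherits(models, "sr2_modelset")) {
    stop("`models` must be an sr2_model or sr2_modelset.", call. = FALSE)
  }
  entries <- purrr::map(unclass(models), function(m) {
    m[c("condition", "run", "predictors", "constant", "beta_age", "beta_pta",
        "model_error", "adj_r2", "n", "p_values", "error_method")]
  })
  payload <- list(
    format = "sr2norm-models",
    version = 1L,
    metadata = utils::modifyList(
      list(created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
           package = as.character(utils::packageVersion("sr2norm"))),
      utils::modifyList(as.list(attr(models, "metadata") %||% list()), metadata)),
    models = entries
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' Read normative models from JSON
#'
#' @param path Path to a model file written by [write_models()].
#' @return An `sr2_modelset`.
#' @export
read_models <- function(path) {
  if (!file.exists(path)) stop("Model file not found: ", path, call. = FALSE)
  payload <- tryCatch(jsonlite::read_json(path),
                      error = function(e) {
                        stop("Malformed model file '", path, "': ",
                             conditionMessage(e), call. = FALSE)
                      })
  if (!identical(payload$format, "sr2norm-models") || is.null(payload$models)) {
    stop("Malformed model file '", path,
         "': not an sr2norm model file.", call. = FALSE)
  }
  num1 <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
  models <- purrr::map(payload$models, function(e) {
    pv <- if (length(e$p_values)) unlist(e$p_values) else NULL
    normative_model(e$condition, e$run, constant = num1(e$constant),
                    beta_age = num1(e$beta_age), beta_pta = num1(e$beta_pta),
                    model_error = num1(e$model_error),
                    adj_r2 = num1(e$adj_r2),
                    n = if (is.null(e$n)) NA_integer_ else as.integer(e$n),
                    p_values = pv,
                    error_method = e$error_method %||% "rmse")
  })
  names(models) <- names(payload$models)
  new_modelset(models, metadata = payload$metadata)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
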