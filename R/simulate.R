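#' Configuration for the synthetic listener cohort generator
#'
#' Defines the study conditions the simulator emulates: the cohort's
#' demographic and audiometric structure (age mean 46.74 y, SD 18.66, range
#' 18-80; bilateral standard PTA mean 12.48 dB HL, SD 8.89, range 0-45;
#' age-PTA Pearson correlation .51), latent thresholds drawn from the
#' published average-run normative functions plus individual deviations with
#' SD equal to each function's model error, a run-2 practice improvement
#' (0.7 dB colocated, 1.4 dB separated), and trial-by-trial responses from a
#' logistic psychometric function with a 1/32 guessing floor (4 colors x 8
#' numbers) run through the actual 20-trial progressive track.
#'
#' @param n Number of listeners (default 82, the study's sample size).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param age_mean,age_sd,age_range Truncated-normal age distribution
#'   (years). The underlying parameters are moment-matched so the
#'   *truncated* distribution hits `age_mean` / `age_sd`.
#' @param age_dist `"truncnorm"` (default) or `"uniform"` over `age_range`.
#' @param pta_mean,pta_sd,pta_range Marginal distribution of bilateral
#'   standard PTA (dB HL), moment-matched after truncation.
#' @param age_pta_cor Target Pearson correlation between age and PTA.
#' @param colocated_model,separated_model Generative [normative_model()]s
#'   (defaults: the published average-run functions).
#' @param dev_sd Named SDs (dB) of the persistent individual deviation from
#'   the normative prediction, per condition (defaults: each function's
#'   model error).
#' @param run_cor Persistence weight rho of the individual deviation across
#'   runs (each run's deviation is `rho * u + sqrt(1 - rho^2) * e_run`),
#'   default 0.8.
#' @param practice Named run-2 latent threshold shifts (dB; negative =
#'   improvement), default -0.7 colocated and -1.4 separated.
#' @param slope Psychometric slope (dB) of the logistic listener, default 2.
#' @param chance Guessing floor, default 1/32.
#' @param calibrate Place each listener's psychometric midpoint so the
#'   progressive track's expected score equals the latent threshold
#'   (default `TRUE`; see the methods vignette). `FALSE` puts the logistic
#'   midpoint at the latent threshold itself.
#' @param retest_mix Named counts (or weights) of retest-delay categories
#'   `same_day`, `day_to_week`, `week_to_month`, `month_to_year`,
#'   `over_year` (defaults: the study's 16/7/12/14/33 split). Delay has no
#'   generative effect on thresholds.
#' @return A validated list of class `sr2_sim_config`.
#' @examples
#' cfg <- sim_config(n = 20, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' @export
sim_config <- function(n = 82L, seed = NULL,
                       age_mean = 46.74, age_sd = 18.66,
                       age_range = c(18, 80),
                       age_dist = c("truncnorm", "uniform"),
                       pta_mean = 12.48, pta_sd = 8.89,
                       pta_range = c(0, 45),
                       age_pta_cor = 0.51,
                       colocated_model = sr2_norms()$colocated_avg,
                       separated_model = sr2_norms()$separated_avg,
                       dev_sd = c(colocated = 1.045, separated = 1.864),
                       run_cor = 0.8,
                       practice = c(colocated = -0.7, separated = -1.4),
                       slope = 2, chance = 1 / 32,
                       calibrate = TRUE,
                       retest_mix = c(same_day = 16, day_to_week = 7,
                                      week_to_month = 12, month_to_year = 14,
                                      over_year = 33)) {
  age_dist <- match.arg(age_dist)
  stopifnot(
    "n must be a positive integer" = is.numeric(n) && n >= 1,
    "age_sd must be nonnegative" = age_sd >= 0,
    "pta_sd must be nonnegative" = pta_sd >= 0,
    "age_range must be ordered" = diff(age_range) > 0,
    "pta_range must be ordered" = diff(pta_range) > 0,
    "run_cor must be in [0, 1]" = run_cor >= 0 && run_cor <= 1,
    "chance must be in (0, 1)" = chance > 0 && chance < 1,
    "slope must be positive" = slope > 0,
    "correlation must be in [-1, 1]" = abs(age_pta_cor) <= 1
  )
  dev_sd <- dev_sd[c("colocated", "separated")]
  practice <- practice[c("colocated", "separated")]
  if (anyNA(dev_sd) || any(dev_sd < 0)) {
    stop("`dev_sd` must supply nonnegative colocated and separated SDs.",
         call. = FALSE)
  }
  if (anyNA(practice)) {
    stop("`practice` must supply colocated and separated shifts.",
         call. = FALSE)
  }
  structure(
    list(n = as.integer(n), seed = seed,
         age_mean = age_mean, age_sd = age_sd, age_range = age_range,
         age_dist = age_dist,
         pta_mean = pta_mean, pta_sd = pta_sd, pta_range = pta_range,
         age_pta_cor = age_pta_cor,
         colocated_model = colocated_model, separated_model = separated_model,
         dev_sd = dev_sd, run_cor = run_cor, practice = practice,
         slope = slope, chance = chance, calibrate = calibrate,
         retest_mix = retest_mix),
    class = "sr2_sim_config"
  )
}

#' Read a generator configuration from YAML
#'
#' @param path Path to a YAML file whose keys are [sim_config()] arguments
#'   (generative models may be given as lists of coefficients with a
#'   `condition` field).
#' @return An `sr2_sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  # YAML 1.1 reads a bare key `n` as boolean FALSE; map it back
  names(raw)[names(raw) == "FALSE"] <- "n"
  for (key in c("colocated_model", "separated_model")) {
    if (!is.null(raw[[key]]) && is.list(raw[[key]])) {
      m <- raw[[key]]
      raw[[key]] <- normative_model(
        m$condition %||% sub("_model", "", key), m$run %||% "avg",
        constant = m$constant,
        beta_age = m$beta_age %||% NA_real_,
        beta_pta = m$beta_pta %||% NA_real_,
        model_error = m$model_error %||% NA_real_)
    }
  }
  for (key in c("dev_sd", "practice", "retest_mix", "age_range", "pta_range")) {
    if (!is.null(raw[[key]])) raw[[key]] <- unlist(raw[[key]])
  }
  do.call(sim_config, raw)
}

# --- truncated-normal machinery -------------------------------------------

tn_moments <- function(mu, sigma, a, b) {
  if (sigma <= 0) return(c(mean = mu, sd = 0))
  al <- (a - mu) / sigma
  be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  da <- stats::dnorm(al)
  db <- stats::dnorm(be)
  m <- mu + sigma * (da - db) / z
  v <- sigma^2 * (1 + (al * da - be * db) / z - ((da - db) / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Underlying (mu, sigma) whose [a, b]-truncated distribution has the target
# mean and SD.
tn_solve <- function(target_mean, target_sd, a, b) {
  if (target_sd == 0) return(c(mu = target_mean, sigma = 0))
  obj <- function(par) {
    mom <- tn_moments(par[1], exp(par[2]), a, b)
    (mom["mean"] - target_mean)^2 + (mom["sd"] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

qtn <- function(p, mu, sigma, a, b) {
  if (sigma == 0) return(rep(mu, length(p)))
  pa <- stats::pnorm(a, mu, sigma)
  pb <- stats::pnorm(b, mu, sigma)
  stats::qnorm(pa + p * (pb - pa), mu, sigma)
}

# Latent Gaussian-copula correlation that produces the target Pearson
# correlation after both marginal transforms, found by grid quadrature.
latent_rho_solve <- function(target_r, qx, qy) {
  if (target_r == 0) return(0)
  z <- seq(-5, 5, length.out = 141)
  w <- stats::dnorm(z)
  w <- w / sum(w)
  x <- qx(stats::pnorm(z))
  y <- qy(stats::pnorm(z))
  mx <- sum(w * x); my <- sum(w * y)
  sx <- sqrt(sum(w * (x - mx)^2)); sy <- sqrt(sum(w * (y - my)^2))
  if (sx == 0 || sy == 0) return(0)
  corr_at <- function(rho) {
    cond_m <- vapply(z, function(z1) {
      wz <- stats::dnorm((z - rho * z1) / sqrt(1 - rho^2))
      sum(wz * y) / sum(wz)
    }, numeric(1))
    (sum(w * x * cond_m) - mx * my) / (sx * sy)
  }
  sign(target_r) *
    stats::uniroot(function(r) corr_at(r) - abs(target_r),
                   lower = 0, upper = 0.995, tol = 1e-6)$root
}

sim_cache <- new.env(parent = emptyenv())

demographic_calibration <- function(config) {
  key <- paste(config$age_dist, config$age_mean, config$age_sd,
               paste(config$age_range, collapse = ","),
               config$pta_mean, config$pta_sd,
               paste(config$pta_range, collapse = ","),
               config$age_pta_cor, sep = "|")
  if (!is.null(sim_cache[[key]])) return(sim_cache[[key]])
  qage <- if (config$age_dist == "uniform") {
    function(p) stats::qunif(p, config$age_range[1], config$age_range[2])
  } else {
    par <- tn_solve(config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
    function(p) qtn(p, par["mu"], par["sigma"],
                    config$age_range[1], config$age_range[2])
  }
  ppar <- tn_solve(config$pta_mean, config$pta_sd,
                   config$pta_range[1], config$pta_range[2])
  qpta <- function(p) qtn(p, ppar["mu"], ppar["sigma"],
                          config$pta_range[1], config$pta_range[2])
  rho <- if (config$age_sd == 0 || config$pta_sd == 0) 0 else
    latent_rho_solve(config$age_pta_cor, qage, qpta)
  out <- list(qage = qage, qpta = qpta, rho = rho)
  sim_cache[[key]] <- out
  out
}

#' Sample a synthetic cohort's demographics and audiograms
#'
#' Draws ages and bilateral standard PTAs from the configured (truncated)
#' marginals through a Gaussian copula calibrated to the target age-PTA
#' correlation, synthesizes a flat-plus-sloping audiogram whose standard PTA
#' matches the sampled value, and samples gender, hearing-aid use, per-ear
#' SRTs and retest delays with the study's category frequencies.
#'
#' @param config An [sim_config()].
#' @return A tibble of participant records (one row per listener) with
#'   audiogram columns, `pta_st`, `pta_hf` and asymmetry recomputed.
#' @export
sample_demographics <- function(config) {
  stopifnot(inherits(config, "sr2_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  cal <- demographic_calibration(config)
  z1 <- stats::rnorm(n)
  z2 <- cal$rho * z1 + sqrt(1 - cal$rho^2) * stats::rnorm(n)
  age <- as.integer(pmin(pmax(round(cal$qage(stats::pnorm(z1))),
                              config$age_range[1]), config$age_range[2]))
  pta_target <- cal$qpta(stats::pnorm(z2))
  aud <- synth_audiogram(pta_target)
  srt_noise <- stats::rnorm(n, 0, 2)
  delay_cat <- sample(names(config$retest_mix), n, replace = TRUE,
                      prob = config$retest_mix / sum(config$retest_mix))
  delay_days <- vapply(delay_cat, function(cat) {
    switch(cat,
           same_day = 0L,
           day_to_week = sample(1:7, 1L),
           week_to_month = sample(8:30, 1L),
           month_to_year = sample(31:365, 1L),
           over_year = sample(366:1095, 1L))
  }, integer(1), USE.NAMES = FALSE)
  out <- tibble::tibble(
    id = sprintf("S%03d", seq_len(n)),
    age = age,
    gender = sample(c("M", "F"), n, replace = TRUE, prob = c(49, 33) / 82),
    hearing_aid = stats::runif(n) < 5 / 82,
    retest_delay = delay_days
  )
  out <- dplyr::bind_cols(out, aud)
  out$srt_L <- round(pta_target + srt_noise)
  out$srt_R <- out$srt_L
  derive_cohort(out)
}

#' Probability of a correct trial under the logistic listener model
#'
#' `chance + (1 - chance) * plogis((tmr - midpoint) / slope)`: strictly
#' increasing in TMR, approaching the guessing floor as TMR falls and 1 as
#' it rises.
#'
#' @param tmr Target-to-masker ratio(s), dB.
#' @param midpoint Location of the logistic midpoint (dB).
#' @param slope Psychometric slope (dB); must be positive.
#' @param chance Guessing floor (default 1/32 for the closed CRM set).
#' @return Probability/ies of a correct response.
#' @examples
#' psychometric_p(0, midpoint = 0, slope = 2)  # chance + (1 - chance) / 2
#' @export
psychometric_p <- function(tmr, midpoint, slope = 2, chance = 1 / 32) {
  if (!is.numeric(slope) || slope <= 0) {
    stop("`slope` must be positive.", call. = FALSE)
  }
  if (chance < 0 || chance >= 1) {
    stop("`chance` must be in [0, 1).", call. = FALSE)
  }
  chance + (1 - chance) * stats::plogis((tmr - midpoint) / slope)
}

# Expected track score 10 - 2 * sum(p) for a given psychometric midpoint.
expected_track_estimate <- function(midpoint, slope, chance) {
  levels <- seq(10, -8, by = -2)
  vapply(midpoint, function(m) {
    10 - 2 * sum(psychometric_p(levels, m, slope, chance))
  }, numeric(1))
}

# Psychometric midpoint at which the progressive track's expected score
# equals theta; vectorized bisection (E[score] is increasing in midpoint).
track_midpoint <- function(theta, slope, chance) {
  levels <- seq(10, -8, by = -2)
  target_sum <- ((10 - theta) / 2 - 10 * chance) / (1 - chance)
  lo <- rep(-80, length(theta))
  hi <- rep(80, length(theta))
  for (i in seq_len(80)) {
    mid <- (lo + hi) / 2
    s <- colSums(stats::plogis(outer(levels, mid, "-") / slope))
    high <- s > target_sum   # too many correct -> move midpoint up
    lo[high] <- mid[high]
    hi[!high] <- mid[!high]
  }
  mid <- (lo + hi) / 2
  # Thresholds outside the attainable expected-score range pin to the walls,
  # reproducing the floor at -10 dB.
  mid[target_sum >= 10] <- -80
  mid[target_sum <= 0] <- 80
  mid
}

#' Simulate one progressive track
#'
#' Draws 20 Bernoulli responses from the logistic listener model along the
#' fixed SR2 schedule and scores them with the progressive-track rule. With
#' `config$calibrate = TRUE` (the default) the psychometric midpoint is
#' positioned so the expected score equals `theta`; with `FALSE` the
#' midpoint is `theta` itself.
#'
#' Uses the current RNG state; seed beforehand for reproducibility.
#'
#' @param theta Latent threshold (dB) of the listener.
#' @param config An [sim_config()] (only `slope`, `chance`, `calibrate` are
#'   used).
#' @param condition Condition label stored on the block.
#' @return A list with `block` (a [trial_block()]) and `estimate` (dB).
#' @export
simulate_track <- function(theta, config = sim_config(),
                           condition = c("colocated", "separated")) {
  condition <- match.arg(condition)
  stopifnot(length(theta) == 1L, is.finite(theta))
  m <- if (isTRUE(config$calibrate)) {
    track_midpoint(theta, config$slope, config$chance)
  } else {
    theta
  }
  p <- psychometric_p(tmr_schedule(), m, config$slope, config$chance)
  correct <- stats::runif(20L) < p
  block <- trial_block(correct, condition)
  list(block = block, estimate = estimate_threshold(block))
}

# Vectorized track scores for a vector of latent thresholds (one track per
# listener); returns integer estimates. Draws n x 20 uniforms column-wise by
# trial so the stream is reproducible.
sim_track_estimates <- function(theta, config) {
  m <- if (isTRUE(config$calibrate)) {
    track_midpoint(theta, config$slope, config$chance)
  } else {
    theta
  }
  delta <- outer(m, tmr_schedule(), function(mm, tt) tt - mm)
  p <- psychometric_p(delta, midpoint = 0, slope = config$slope,
                      chance = config$chance)
  u <- matrix(stats::runif(length(theta) * 20L), ncol = 20L)
  correct <- u < p
  list(estimate = 10L - rowSums(correct), correct = correct)
}

#' Assign latent true thresholds to sampled listeners
#'
#' Each listener's baseline threshold in each condition is the generative
#' normative prediction for their age and PTA plus a persistent individual
#' deviation `u ~ Normal(0, dev_sd)`. Each run's latent threshold is
#' `prediction + rho * u + sqrt(1 - rho^2) * e_run` with fresh run noise
#' `e_run ~ Normal(0, dev_sd)`, plus the run-2 practice shift. Learning
#' affects the listener, not the scoring rule.
#'
#' @param records A demographics tibble from [sample_demographics()].
#' @param config An [sim_config()].
#' @return `records` with columns `theta_<condition>_<run>` appended.
#' @export
assign_latent_thresholds <- function(records, config) {
  n <- nrow(records)
  rho <- config$run_cor
  for (cond in c("colocated", "separated")) {
    model <- config[[paste0(cond, "_model")]]
    mu <- predict_threshold(model,
                            age = if ("age" %in% model$predictors) records$age,
                            pta = if ("pta" %in% model$predictors) records$pta_st,
                            warn_extrapolation = FALSE)
    mu <- rep_len(mu, n)
    sd_c <- config$dev_sd[[cond]]
    u <- stats::rnorm(n, 0, sd_c)
    for (run in c("1", "2")) {
      e <- stats::rnorm(n, 0, sd_c)
      shift <- if (run == "2") config$practice[[cond]] else 0
      records[[paste0("theta_", cond, "_", run)]] <-
        mu + rho * u + sqrt(1 - rho^2) * e + shift
    }
  }
  records
}

#' Simulate a full SR2 cohort
#'
#' Samples demographics, assigns latent thresholds, runs every listener
#' through the 20-trial progressive track in both conditions and both runs,
#' and assembles a validated cohort table with derived SRM and run averages.
#' Deterministic given `config$seed`.
#'
#' @param config An [sim_config()].
#' @param trials Also keep the trial-level response table (attribute
#'   `trials`)? Default `FALSE`.
#' @return A cohort tibble; latent thresholds are kept in attribute
#'   `latent`, the configuration in attribute `config`.
#' @examples
#' cohort <- simulate_cohort(sim_config(n = 10, seed = 7))
#' @export
simulate_cohort <- function(config = sim_config(), trials = FALSE) {
  stopifnot(inherits(config, "sr2_sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  records <- sample_demographics(strip_seed(config))
  records <- assign_latent_thresholds(records, config)
  trial_rows <- list()
  for (cond in c("colocated", "separated")) {
    for (run in c("1", "2")) {
      theta <- records[[paste0("theta_", cond, "_", run)]]
      sim <- sim_track_estimates(theta, config)
      records[[paste0(cond, "_", run)]] <- as.numeric(sim$estimate)
      if (trials) {
        trial_rows[[paste(cond, run)]] <- tibble::tibble(
          id = rep(records$id, each = 20L),
          condition = cond, run = as.integer(run),
          trial = rep(seq_len(20L), nrow(records)),
          tmr = rep(tmr_schedule(), nrow(records)),
          correct = as.vector(t(sim$correct))
        )
      }
    }
  }
  latent <- records[c("id", grep("^theta_", names(records), value = TRUE))]
  records <- records[setdiff(names(records),
                             grep("^theta_", names(records), value = TRUE))]
  cohort <- validate_cohort(derive_cohort(records), warn = FALSE)
  attr(cohort, "latent") <- latent
  attr(cohort, "config") <- config
  if (trials) attr(cohort, "trials") <- dplyr::bind_rows(trial_rows)
  cohort
}

strip_seed <- function(config) {
  config$seed <- NULL
  config
}
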