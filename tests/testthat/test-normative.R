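test_that("backward elimination recovers a noise-free generative truth exactly", {
  set.seed(51)
  d <- tibble::tibble(age = sample(18:80, 120, replace = TRUE),
                      pta_st = runif(120, 0, 45))
  d$separated_avg <- -8.617 + 0.053 * d$age + 0.164 * d$pta_st
  m <- fit_normative_model(d, "separated_avg")
  expect_equal(m$constant, -8.617, tolerance = 1e-8)
  expect_equal(m$beta_age, 0.053, tolerance = 1e-10)
  expect_equal(m$beta_pta, 0.164, tolerance = 1e-10)
  expect_equal(m$model_error, 0, tolerance = 1e-8)
  expect_identical(sort(m$predictors), c("age", "pta"))
})

test_that("elimination drops null terms and is deterministic", {
  set.seed(52)
  d <- tibble::tibble(age = sample(18:80, 800, replace = TRUE),
                      pta_st = runif(800, 0, 45))
  d$srm_avg <- 9.166 - 0.171 * d$pta_st + rnorm(800, 0, 1.830)
  m1 <- fit_normative_model(d, "srm_avg")
  m2 <- fit_normative_model(d, "srm_avg")
  expect_identical(m1$predictors, "pta")
  expect_true(is.na(m1$beta_age))
  expect_true(is.na(m1$interaction))
  expect_identical(unclass(m1)[names(unclass(m1)) != "p_values"],
                   unclass(m2)[names(unclass(m2)) != "p_values"])
  expect_identical(m1$p_values, m2$p_values)
  # an unrelated response falls back to an intercept-only model with warning
  d$noise <- rnorm(800)
  expect_warning(m0 <- fit_normative_model(d, "noise"), "intercept-only")
  expect_identical(m0$predictors, character(0))
  expect_equal(m0$constant, mean(d$noise), tolerance = 1e-10)
})

test_that("model error equals the RMSE (or MAE) of the residuals", {
  m <- normative_model("srm", "avg", constant = 5, model_error = 1)
  d <- tibble::tibble(age = c(30, 40), pta_st = c(5, 10),
                      srm_avg = c(6, 4))  # residuals +1, -1
  expect_equal(model_error(m, d, method = "rmse"), 1)
  expect_equal(model_error(m, d, method = "mae"), 1)
  d$srm_avg <- c(5, 5)
  expect_equal(model_error(m, d), 0)
  # RMSE is consistent for Normal noise
  set.seed(53)
  big <- tibble::tibble(age = sample(18:80, 20000, replace = TRUE),
                        pta_st = runif(20000, 0, 45))
  truth <- sr2_norms()$srm_avg
  big$srm_avg <- draw_normative_outcome(truth, big, noise_sd = 1.830)
  expect_equal(model_error(truth, big), 1.830, tolerance = 0.03)
})

test_that("predictions follow the linear normative function", {
  norms <- sr2_norms()
  expect_equal(predict_threshold(norms$srm_avg, pta = 0), 9.166)
  expect_equal(predict_threshold(norms$separated_avg, age = 50, pta = 10),
               -4.327, tolerance = 1e-9)
  # spatial release is predicted to vanish near 50 dB HL
  expect_warning(
    p50 <- predict_threshold(norms$srm_avg, pta = 50),
    "extrapolation")
  expect_equal(p50, 0.616, tolerance = 1e-9)
  expect_lt(abs(p50), 0.75)
  expect_error(predict_threshold(norms$separated_avg, age = 50), "PTA")
  expect_error(predict_threshold(norms$colocated_avg), "age")
  # vectorization over individuals
  expect_equal(predict_threshold(norms$colocated_avg, age = c(20, 40)),
               0.549 + c(20, 40) * 0.033)
})

test_that("z-scores are exact standardized residuals with inclusive flagging", {
  m <- sr2_norms()$separated_avg
  pred <- predict_threshold(m, age = 60, pta = 20, warn_extrapolation = FALSE)
  for (c_sd in c(-3, -2, -0.5, 0, 1, 2, 2.5)) {
    z <- z_score(m, observed = pred + c_sd * m$model_error, age = 60, pta = 20)
    expect_equal(z$z, c_sd, tolerance = 1e-12)
    expect_identical(z$flagged, abs(c_sd) >= 2)
  }
  zz <- z_score(sr2_norms()$srm_avg, observed = 2.0, pta = 10)
  expect_equal(zz$z, (2.0 - (9.166 - 0.171 * 10)) / 1.830)
  expect_equal(zz$z, -2.981, tolerance = 1e-3)
  expect_true(zz$flagged)
  bad <- normative_model("srm", "avg", constant = 1, model_error = 0)
  expect_error(z_score(bad, 1, pta = 0), "positive")
})

test_that("cohort-level flagging unions the nine measures", {
  # observed values equal to each model's prediction: no flags anywhere
  norms <- sr2_norms()
  d <- tibble::tibble(id = sprintf("P%02d", 1:6),
                      age = c(20, 30, 40, 50, 60, 70),
                      pta_st = c(0, 5, 10, 15, 20, 25))
  for (key in names(norms)) {
    m <- norms[[key]]
    d[[key]] <- predict_threshold(m,
                                  age = if ("age" %in% m$predictors) d$age,
                                  pta = if ("pta" %in% m$predictors) d$pta_st,
                                  warn_extrapolation = FALSE)
  }
  report <- z_report(d, norms)
  expect_identical(nrow(report), 54L)
  expect_true(all(abs(report$z) < 1e-12))
  expect_identical(nrow(flag_outliers(d, norms)), 0L)
  # push one participant's SRM 2.5 SDs out: exactly that id gets flagged
  d$srm_avg[3] <- d$srm_avg[3] + 2.5 * norms$srm_avg$model_error
  flags <- flag_outliers(d, norms)
  expect_identical(flags$id, "P03")
  expect_identical(flags$measures, "srm_avg")
  expect_error(flag_outliers(d, norms[1:3]), "Missing normative model")
})

test_that("flagged fractions under the generative model stay in the derivable band", {
  cohort <- simulate_cohort(sim_config(n = 2000, seed = 88))
  models <- fit_normative_models(cohort)
  flags <- flag_outliers(cohort, models)
  frac <- nrow(flags) / nrow(cohort)
  # between the single-measure two-sided rate and the Bonferroni bound over
  # nine correlated measures
  expect_gt(frac, 2 * pnorm(-2) * 0.7)
  expect_lt(frac, 9 * 2 * pnorm(-2))
})

test_that("the correlation screen applies the Bonferroni criterion", {
  cohort <- make_cohort(n = 82, seed = 61)
  ct <- correlation_table(cohort)
  expect_identical(attr(ct, "n_correlations"), 15L)
  expect_identical(attr(ct, "criterion"), 0.0033)
  # the exact critical |r| at this n (not the rounded published 0.333)
  tcrit <- qt(1 - 0.0033 / 2, df = 80)
  expect_equal(attr(ct, "critical_r"), tcrit / sqrt(80 + tcrit^2),
               tolerance = 1e-10)
  expect_true(attr(ct, "critical_r") > 0.30 && attr(ct, "critical_r") < 0.34)
  expect_identical(nrow(ct), 15L)
  expect_true(all(abs(ct$r) <= 1, na.rm = TRUE))
  # retest-delay difference-score correlations are reported but separate
  rd <- attr(ct, "retest_delay")
  expect_identical(rd$outcome_difference, c("colocated", "separated", "srm"))
  # simulated delays have no generative effect, so correlations are small
  expect_true(all(abs(rd$r) < 0.35))
})

test_that("correlations match truth on bivariate-normal data and degrade safely", {
  set.seed(62)
  n <- 10000
  age <- rnorm(n, 50, 10)
  y <- 0.5 * scale(age)[, 1] + sqrt(1 - 0.25) * rnorm(n)
  d <- tibble::tibble(id = as.character(1:n), age = age,
                      colocated_avg = y, separated_avg = rnorm(n),
                      srm_avg = rnorm(n))
  ct <- correlation_table(d)
  r_hat <- ct$r[ct$predictor == "age" & ct$outcome == "colocated"]
  expect_equal(r_hat, 0.5, tolerance = 0.02)
  expect_equal(cor(d$age, d$colocated_avg), r_hat, tolerance = 1e-12)
  # a constant column yields an undefined correlation, reported as NA
  d$pta_st <- 7
  ct2 <- correlation_table(d)
  expect_true(all(is.na(ct2$r[ct2$predictor == "pta_st"])))
})

test_that("normative bands are centered on the prediction with constant width", {
  m <- sr2_norms()$separated_avg
  band <- normative_band(m, grid = c(0, 20, 40), vary = "pta", fixed_age = 50)
  expect_equal(band$center, c(-5.967, -2.687, 0.593), tolerance = 1e-9)
  expect_equal(band$upper - band$center, rep(m$model_error, 3))
  expect_equal(band$center - band$lower, rep(m$model_error, 3))
  collapsed <- normative_band(m, grid = c(0, 20), vary = "pta", k = 0)
  expect_identical(collapsed$lower, collapsed$center)
  expect_identical(collapsed$upper, collapsed$center)
  # monotone in the direction of the published coefficient signs
  srm_band <- normative_band(sr2_norms()$srm_avg, vary = "pta")
  expect_identical(nrow(srm_band), 46L)
  expect_true(all(diff(srm_band$center) < 0))
  co_band <- normative_band(sr2_norms()$colocated_avg, vary = "age")
  expect_true(all(diff(co_band$center) > 0))
})

test_that("recovered coefficients are unbiased with nominal CI coverage", {
  set.seed(63)
  truth <- sr2_norms()$separated_avg
  reps <- 200
  est <- matrix(NA_real_, reps, 2)
  covered <- logical(reps)
  demo <- sample_demographics(sim_config(n = 82, seed = 64))
  for (r in seq_len(reps)) {
    y <- draw_normative_outcome(truth, demo)
    res <- ols_fit(data.frame(age = demo$age, pta = demo$pta_st), y)
    est[r, ] <- res$coefficients$estimate[2:3]
    ci <- res$coefficients$estimate[3] +
      c(-1, 1) * qt(0.975, 82 - 3) * res$coefficients$std_error[3]
    covered[r] <- ci[1] <= 0.164 && 0.164 <= ci[2]
  }
  mc_se <- apply(est, 2, sd) / sqrt(reps)
  expect_lt(abs(mean(est[, 1]) - 0.053), 2 * mc_se[1])
  expect_lt(abs(mean(est[, 2]) - 0.164), 2 * mc_se[2])
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("glance and tidy expose the coefficient-table layout", {
  models <- sr2_norms()
  tab <- tidy(models)
  expect_identical(nrow(tab), 9L)
  expect_identical(names(tab), c("condition", "run", "adj_r2", "constant",
                                 "beta_age", "beta_pta", "model_error", "n"))
  expect_true(all(is.na(tab$beta_pta[tab$condition == "colocated"])))
  expect_true(all(is.na(tab$beta_age[tab$condition == "srm"])))
  expect_true(all(!is.na(tab$beta_age[tab$condition == "separated"])))
  g <- glance(models$separated_avg)
  expect_identical(g$n_predictors, 2L)
})
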