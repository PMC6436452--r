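# Fixtures are generated in code; nothing is read from disk.

# Normal-equation OLS oracle, independent of the package's fitting path.
ols_oracle <- function(x, y) {
  xd <- cbind(`(Intercept)` = 1, as.matrix(x))
  drop(solve(t(xd) %*% xd, t(xd) %*% y))
}

# A small, fully in-bounds cohort for I/O and reporting tests.
make_cohort <- function(n = 12, seed = 101) {
  simulate_cohort(sim_config(n = n, seed = seed))
}

# Random audiogram table with all 16 per-ear columns.
make_audiogram <- function(n = 5, seed = 3) {
  set.seed(seed)
  cols <- sr2norm:::audiogram_cols()
  out <- tibble::as_tibble(
    matrix(round(runif(n * length(cols), -5, 60)), nrow = n,
           dimnames = list(NULL, cols)))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
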