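# Shared fixtures and independent oracles, built in code at test time.

# Dense grid-search oracle for the AP/AR extremum of a cubic in centred age.
grid_extremum <- function(intercept, linear, quadratic, cubic, center,
                          window, maximize = TRUE, step = 1e-5) {
  a <- seq(window[1] - center, window[2] - center, by = step)
  y <- intercept + linear * a + quadratic * a^2 + cubic * a^3
  i <- if (maximize) which.max(y) else which.min(y)
  list(age = a[i] + center, value = y[i])
}

# Closed-form OLS via the normal equations (independent of the package's
# residualisation route).
normal_equations_ols <- function(y, X) {
  XtX <- t(X) %*% X
  b <- solve(XtX, t(X) %*% y)
  res <- y - X %*% b
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  list(beta = as.numeric(b), se = unname(sqrt(diag(solve(XtX)) * sigma2)),
       df = df)
}

# Small cohort configuration used across tests.
quick_config <- function(n = 300, studies = 1, seed = 101, ...) {
  cohort_config(n_individuals = n, n_studies = studies, seed = seed,
                panel = default_snp_panel(6), ...)
}

# Deterministic noiseless Reed1 measurements for one or more subjects.
reed1_data <- function(params, t_months, noise_sd = 0, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(params)), function(i) {
    p <- params[i, ]
    y <- p$a + p$b * t_months + p$c * log(t_months) + p$d / t_months
    data.frame(id = sprintf("s%d", i), age_years = t_months / 12,
               height_cm = y + rnorm(length(t_months), 0, noise_sd))
  }))
}
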