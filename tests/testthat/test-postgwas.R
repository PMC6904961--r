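test_that("variance explained follows h2 = 2 f (1-f) beta^2 and its symmetry", {
  expect_equal(variance_explained(1, 0.5), 0.5)
  expect_equal(variance_explained(0, 0.3), 0)
  # published worked example: rs10938397, combined beta 0.06 at EAF 0.35
  h2 <- variance_explained(0.06, 0.35)
  expect_equal(h2, 0.0016, tolerance = 0.03)
  expect_lt(abs(h2 * 100 - 0.16), 0.005)  # ~0.2% as reported
  expect_equal(variance_explained(0.2, 0.1), variance_explained(0.2, 0.9))
  expect_error(variance_explained(0.1, 0), "frequency")
})

test_that("winner's-curse MLE shrinks near the threshold and not far from it", {
  # far from the threshold: negligible correction
  far <- winners_curse_mle(1.0, 0.02, 5e-8)
  expect_lt(abs(far$mle - 1.0) / 1.0, 0.001)

  # near the threshold: strict shrinkage, matching an independent grid oracle
  wc <- winners_curse_mle(0.11, 0.02, 1e-7)
  expect_lt(wc$mle, 0.11)
  grid <- seq(-0.2, 0.2, by = 1e-5)
  ll <- dnorm((0.11 - grid) / 0.02, log = TRUE) -
    log(pnorm(grid / 0.02 - wc$z_c) + pnorm(-grid / 0.02 - wc$z_c))
  expect_lt(abs(wc$mle - grid[which.max(ll)]), 1e-4)
  expect_equal(wc$compromise, (0.11 + wc$mle) / 2)

  # below the threshold the estimator is undefined
  expect_error(winners_curse_mle(0.05, 0.02, 1e-7), "not selected")
})

test_that("the conditional MLE reduces mean absolute bias under selection", {
  set.seed(2023)
  s <- 0.02
  alpha <- 1e-5
  z_c <- qnorm(alpha / 2, lower.tail = FALSE)
  true_b <- runif(4000, 0.02, 0.10)
  est <- rnorm(4000, true_b, s)
  sel <- which(abs(est / s) > z_c)
  sel <- sel[seq_len(min(length(sel), 250))]
  wc <- lapply(sel, function(i) winners_curse_mle(est[i], s, alpha))
  mle <- vapply(wc, `[[`, 0, "mle")
  comp <- vapply(wc, `[[`, 0, "compromise")
  # the curse inflates the naive estimate; the conditional MLE (and, more so,
  # the compromise estimator) reduce the magnitude of the mean bias
  bias_naive <- abs(mean(est[sel] - true_b[sel]))
  expect_lt(abs(mean(mle - true_b[sel])), bias_naive)
  expect_lt(abs(mean(comp - true_b[sel])), bias_naive)
})

test_that("Li-Ji effective tests match hand eigen-decompositions", {
  expect_equal(effective_tests(diag(6))$m_eff, 6)
  # one perfectly correlated pair among six traits: eigenvalues 2,1,1,1,1,0
  R <- diag(6)
  R[1, 2] <- R[2, 1] <- 1
  et <- effective_tests(R)
  expect_equal(et$m_eff, 5)
  expect_equal(sort(round(et$eigenvalues, 10)), c(0, 1, 1, 1, 1, 2))
  # the published correction: alpha 5e-8 over five independent phenotypes
  et5 <- effective_tests(R, alpha = 5e-8)
  expect_equal(et5$alpha_corrected, 1e-8)
  # all-unit correlations collapse to one test
  expect_equal(effective_tests(matrix(1, 4, 4))$m_eff, 1)
  expect_error(effective_tests(matrix(c(1, 0.5, 0.2, 1), 2, 2)), "symmetric")
  bad <- diag(2); bad[1, 1] <- 2
  expect_error(effective_tests(bad), "unit diagonal")
})

test_that("the summary-statistic GRS matches closed forms and eliminates outliers", {
  one <- grs_effect(1, 0.08, 0.03)
  expect_equal(one$alpha, 0.08)
  expect_equal(one$se, 0.03)

  g <- grs_effect(c(1, 1, 1), c(0.1, 0.2, 0.3), rep(0.1, 3))
  expect_equal(g$alpha, 0.2, tolerance = 1e-12)
  expect_equal(g$se, 0.1 / sqrt(3), tolerance = 1e-12)

  # an outlier drives initial heterogeneity and is removed first
  go <- grs_effect(c(1, 1, 1, 1), c(0.1, 0.2, 0.3, 5), rep(0.1, 4),
                   snps = c("a", "b", "c", "outlier"))
  expect_identical(go$removed[1], "outlier")
  expect_gte(go$p_het, 0.05)
  expect_equal(go$k, 3)

  # equal weights reduce the score to an IVW meta-analysis
  b <- c(0.05, 0.07, 0.04); s <- c(0.02, 0.03, 0.025)
  gw <- grs_effect(c(1, 1, 1), b, s)
  mw <- ivw_meta(b, s)
  expect_equal(gw$alpha, mw$beta, tolerance = 1e-12)
  expect_equal(gw$se, mw$se, tolerance = 1e-12)

  # h2_grs under HWE and SNP independence
  gh <- grs_effect(c(0.5, 0.2), c(0.1, 0.05), c(0.02, 0.02),
                   eafs = c(0.3, 0.4))
  expect_equal(gh$h2_grs,
               gh$alpha^2 * (0.5^2 * 2 * 0.3 * 0.7 + 0.2^2 * 2 * 0.4 * 0.6),
               tolerance = 1e-12)
  expect_error(grs_effect(numeric(0), numeric(0), numeric(0)), "empty")
})

test_that("conditional independence applies the 20% / nominal-significance rule", {
  expect_true(conditional_independence(0.10, 0.095, 0.01))
  expect_false(conditional_independence(0.10, 0.05, 0.001))
  expect_false(conditional_independence(0.10, 0.095, 0.20))
  expect_error(conditional_independence(0, 0.1, 0.01), "zero")
})

test_that("power calculations are calibrated, monotone, and invert correctly", {
  # null effect: power equals the significance level
  p0 <- power_analysis(n = 1000, maf = 0.3, alpha = 0.05, beta = 0)
  expect_equal(p0$power, 0.05, tolerance = 1e-10)

  # monotone in n at fixed effect
  pows <- vapply(c(500, 1000, 2000, 4000, 8000), function(n)
    power_analysis(n, maf = 0.22, r2 = 0.8, alpha = 5e-8, beta = 0.15)$power, 0)
  expect_true(all(diff(pows) > 0))

  # minimum detectable effect at the published design parameters
  md <- power_analysis(n = 6222, maf = 0.22, r2 = 0.8, alpha = 5e-8,
                       power = 0.8)
  expect_equal(md$beta, 0.152, tolerance = 0.005)
  # round trip: power at that effect is the requested power
  expect_equal(power_analysis(6222, 0.22, 0.8, 5e-8, beta = md$beta)$power,
               0.8, tolerance = 1e-6)

  # Monte-Carlo cross-check of the noncentral chi-square power
  set.seed(66)
  reps <- 1e5
  ncp <- md$ncp
  stat <- rchisq(reps, df = 1, ncp = ncp)
  emp <- mean(stat > qchisq(1 - 5e-8, 1))
  expect_equal(emp, 0.8, tolerance = 0.01)

  expect_error(power_analysis(10, 0.22, 0.8, 5e-8, power = 0.999999),
               "unattainable")
})
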