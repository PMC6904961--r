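make_poly_data <- function(n, stage = "infancy", noise = 0, re_sd = c(0, 0),
                           seed = 1) {
  set.seed(seed)
  ages <- if (stage == "infancy") c(0.06, 0.25, 0.5, 0.75, 1, 1.25, 1.45)
          else c(2, 3, 4, 5, 6, 7, 8, 10, 13)
  center <- if (stage == "infancy") 0.75 else 7.25
  id <- rep(sprintf("c%d", seq_len(n)), each = length(ages))
  age <- rep(ages, n)
  a <- age - center
  sex <- rep(rbinom(n, 1, 0.5), each = length(ages))
  u0 <- rep(rnorm(n, 0, re_sd[1]), each = length(ages))
  u1 <- rep(rnorm(n, 0, re_sd[2]), each = length(ages))
  beta <- if (stage == "infancy") c(2.86, 0.02, -0.35, 0.02, 0.03)
          else c(2.77, 0.037, 0.012, 0.0005, 0.01, -0.002, 0.0004)
  y <- beta[1] + beta[2] * a + beta[3] * a^2 + beta[4] * a^3 + beta[5] * sex +
    u0 + u1 * a + rnorm(length(a), 0, noise)
  if (stage == "childhood") y <- y + beta[6] * a * sex + beta[7] * a^2 * sex
  list(data = data.frame(id = id, age_years = age, sex = sex,
                         bmi_kgm2 = exp(y)),
       beta = beta, center = center)
}

test_that("noiseless data recover the infancy fixed effects exactly (OLS limit)", {
  sim <- make_poly_data(60, "infancy")
  fit <- fit_bmi_trajectory(sim$data, "infancy")
  expect_equal(unname(fit$fixef),
               sim$beta[c(1, 2, 3, 4, 5)], tolerance = 1e-6)
  expect_equal(fit$center_age, 0.75)
})

test_that("noiseless data recover the childhood fixed effects exactly", {
  sim <- make_poly_data(60, "childhood")
  fit <- fit_bmi_trajectory(sim$data, "childhood")
  expect_equal(unname(fit$fixef[c("(Intercept)", "a", "I(a^2)", "I(a^3)", "sex")]),
               sim$beta[1:5], tolerance = 1e-6)
  expect_equal(unname(fit$fixef[c("a:sex", "I(a^2):sex")]), sim$beta[6:7],
               tolerance = 1e-6)
})

test_that("fixed effects are recovered within 3 SEs on simulated children", {
  sim <- make_poly_data(500, "infancy", noise = 0.05, re_sd = c(0.08, 0.06),
                        seed = 42)
  fit <- fit_bmi_trajectory(sim$data, "infancy")
  se <- sqrt(diag(fit$vcov))
  expect_true(all(abs(fit$fixef - sim$beta) < 3 * se))
})

test_that("the ML log-likelihood is at least that of the generating parameters", {
  sim <- make_poly_data(120, "infancy", noise = 0.05, re_sd = c(0.08, 0.06),
                        seed = 7)
  fit <- fit_bmi_trajectory(sim$data, "infancy")
  # evaluate the marginal likelihood at the generating parameters
  d <- sim$data
  d <- d[d$age_years > 14 / 365.25 & d$age_years <= 1.5, ]
  a <- d$age_years - 0.75
  mu <- sim$beta[1] + sim$beta[2] * a + sim$beta[3] * a^2 + sim$beta[4] * a^3 +
    sim$beta[5] * d$sex
  r <- log(d$bmi_kgm2) - mu
  ll0 <- sum(vapply(split(seq_len(nrow(d)), d$id), function(ix) {
    Z <- cbind(1, a[ix])
    V <- Z %*% diag(c(0.08, 0.06)^2) %*% t(Z) + diag(0.05^2, length(ix))
    mvtnorm_ll <- -0.5 * (length(ix) * log(2 * pi) + determinant(V)$modulus +
                            t(r[ix]) %*% solve(V, r[ix]))
    as.numeric(mvtnorm_ll)
  }, 0))
  expect_gte(fit$logLik, ll0)
})

test_that("the fit is refused on too few subjects and degenerate input", {
  sim <- make_poly_data(10, "infancy")
  expect_error(fit_bmi_trajectory(sim$data, "infancy"), "fit refused")
})

test_that("individual curves reproduce the mixed-model prediction", {
  sim <- make_poly_data(80, "infancy", noise = 0.04, re_sd = c(0.08, 0.05),
                        seed = 3)
  fit <- fit_bmi_trajectory(sim$data, "infancy")
  curves <- individual_curves(fit)
  ages <- c(0.3, 0.75, 1.2)
  for (i in c(1, 40, 80)) {
    nd <- data.frame(id = curves$id[i], age_years = ages, sex = curves$sex[i])
    a <- ages - 0.75
    from_curve <- curves$intercept[i] + curves$linear[i] * a +
      curves$quadratic[i] * a^2 + curves$cubic[i] * a^3
    expect_equal(from_curve, predict(fit, nd, level = 1), tolerance = 1e-12)
  }
})

test_that("adiposity peak derivation matches hand-solved and grid oracles", {
  base <- data.frame(id = "x", sex = 0, intercept = 2.9, linear = 0,
                     quadratic = -0.4, cubic = 0)
  attr(base, "center_age") <- 0.75
  class(base) <- c("individual_curves", "data.frame")

  # symmetric quadratic: peak at the centring age
  ap <- derive_ap(base)
  expect_equal(ap$age_ap, 0.75)
  expect_equal(ap$bmi_ap, exp(2.9))
  expect_false(ap$ap_boundary)

  # cubic case against the dense grid oracle
  cv <- base; cv$linear <- 0.05; cv$quadratic <- -0.4; cv$cubic <- 0.02
  ap2 <- derive_ap(cv)
  gr <- grid_extremum(2.9, 0.05, -0.4, 0.02, 0.75, c(0.25, 1.25), TRUE)
  expect_lt(abs(ap2$age_ap - gr$age), 1e-4)
  expect_equal(ap2$age_ap, 0.813, tolerance = 1e-3)

  # strictly increasing curve pegs the boundary
  mono <- base; mono$linear <- 0.2; mono$quadratic <- 0; mono$cubic <- 0
  ap3 <- derive_ap(mono)
  expect_equal(ap3$age_ap, 1.25)
  expect_true(ap3$ap_boundary)

  bad <- base
  bad$linear <- NaN
  attr(bad, "center_age") <- 0.75
  expect_error(derive_ap(bad), "non-finite")
})

test_that("adiposity rebound derivation mirrors the peak on [2.5, 8.5]", {
  base <- data.frame(id = "x", sex = 1, intercept = 2.74, linear = 0,
                     quadratic = 0.012, cubic = 0)
  attr(base, "center_age") <- 7.25
  class(base) <- c("individual_curves", "data.frame")
  ar <- derive_ar(base)
  expect_equal(ar$age_ar, 7.25)
  expect_false(ar$ar_boundary)

  dec <- base; dec$linear <- -0.05; dec$quadratic <- 0
  ar2 <- derive_ar(dec)
  expect_equal(ar2$age_ar, 8.5)
  expect_true(ar2$ar_boundary)
})

test_that("AP/AR agree with the grid oracle on 1000 random curves", {
  set.seed(2718)
  n <- 1000
  curves <- data.frame(id = as.character(seq_len(n)), sex = 0,
                       intercept = rnorm(n, 2.9, 0.1),
                       linear = rnorm(n, 0, 0.1),
                       quadratic = rnorm(n, -0.35, 0.15),
                       cubic = rnorm(n, 0, 0.05))
  attr(curves, "center_age") <- 0.75
  class(curves) <- c("individual_curves", "data.frame")
  ap <- derive_ap(curves)
  worst <- 0
  for (i in seq_len(n)) {
    gr <- grid_extremum(curves$intercept[i], curves$linear[i],
                        curves$quadratic[i], curves$cubic[i], 0.75,
                        c(0.25, 1.25), TRUE)
    worst <- max(worst, abs(ap$age_ap[i] - gr$age))
  }
  expect_lt(worst, 1e-4)

  arc <- curves
  attr(arc, "center_age") <- 7.25
  arc$quadratic <- rnorm(n, 0.012, 0.01)
  arc$cubic <- rnorm(n, 0, 0.002)
  arc$linear <- rnorm(n, 0.03, 0.05)
  ar <- derive_ar(arc)
  worst <- 0
  for (i in seq_len(n)) {
    gr <- grid_extremum(arc$intercept[i], arc$linear[i], arc$quadratic[i],
                        arc$cubic[i], 7.25, c(2.5, 8.5), FALSE)
    worst <- max(worst, abs(ar$age_ar[i] - gr$age))
  }
  expect_lt(worst, 1e-4)
})

test_that("population mean Age-AP sits near the design value of 0.75 y", {
  cfg <- cohort_config(n_individuals = 1000, n_studies = 1, seed = 314,
                       panel = default_snp_panel(4))
  gt <- simulate_genotypes(cfg)
  st <- simulate_growth(cfg, gt)
  dt <- derive_growth_traits(st$measurements)
  expect_gt(mean(dt$age_ap, na.rm = TRUE), 0.6)
  expect_lt(mean(dt$age_ap, na.rm = TRUE), 0.9)
})
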