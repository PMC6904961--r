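test_that("trait preparation applies the log rule, z-scores, and is idempotent", {
  set.seed(11)
  x <- exp(rnorm(1e4, 0, 0.5))
  tv <- prepare_trait(x, "BMI-AP")
  expect_equal(mean(tv), 0, tolerance = 1e-10)
  expect_equal(sd(tv), 1, tolerance = 1e-10)
  expect_identical(attr(tv, "transform"), "log")
  # log reduces skewness
  skew <- function(v) mean((v - mean(v))^3) / sd(v)^3
  expect_lt(abs(skew(log(x))), abs(skew(x)))
  # ages are not logged
  ages <- rnorm(100, 5.5, 0.6)
  ta <- prepare_trait(ages, "Age-AR")
  expect_identical(attr(ta, "transform"), "none")
  expect_equal(mean(ta), 0, tolerance = 1e-10)
  # idempotence
  tv2 <- prepare_trait(tv, "bmi_ap")
  expect_equal(as.numeric(tv2), as.numeric(tv), tolerance = 1e-12)
  # errors
  expect_error(prepare_trait(rep(17, 10), "bmi_ap"), "zero variance")
  expect_error(prepare_trait(c(1, 2, -3), "pwv"), "non-positive")
})

test_that("the covariate rule adjusts AR traits for sex only", {
  expect_identical(trait_covariates("bmi_ar"), "sex")
  expect_identical(trait_covariates("age_ar"), "sex")
  expect_identical(trait_covariates("bmi_ap"), c("sex", "ga_weeks"))
  expect_identical(trait_covariates("phv"), c("sex", "ga_weeks"))
})

test_that("an exactly linear phenotype gives beta 0.5 with vanishing SE", {
  set.seed(5)
  dos <- rbinom(300, 2, 0.3)
  y <- 0.5 * dos
  tv <- structure(y, covariates = "sex", class = "trait_vector")
  r <- run_snp_association(tv, dos, data.frame(sex = rbinom(300, 1, 0.5)))
  expect_equal(r$beta, 0.5, tolerance = 1e-12)
  expect_lt(r$se, 1e-10)
})

test_that("association estimates agree with the normal-equations oracle to 1e-10", {
  set.seed(123)
  n <- 200
  dos <- rbinom(n, 2, 0.4)
  sex <- rbinom(n, 1, 0.5)
  ga <- sample(37:41, n, replace = TRUE)
  y <- 0.2 * dos + 0.1 * sex - 0.05 * ga + rnorm(n)
  tv <- structure(y, covariates = c("sex", "ga_weeks"),
                  class = "trait_vector")
  r <- run_snp_association(tv, dos, data.frame(sex = sex, ga_weeks = ga))
  oracle <- normal_equations_ols(y, cbind(1, sex, ga, dos))
  expect_equal(r$beta, oracle$beta[4], tolerance = 1e-10)
  expect_equal(r$se, oracle$se[4], tolerance = 1e-10)
  expect_equal(r$p, 2 * pt(-abs(oracle$beta[4] / oracle$se[4]), oracle$df),
               tolerance = 1e-10)
})

test_that("association is invariant to affine recoding of covariates", {
  set.seed(9)
  n <- 400
  dos <- rbinom(n, 2, 0.25)
  sex <- rbinom(n, 1, 0.5)
  ga <- sample(37:41, n, replace = TRUE)
  y <- rnorm(n) + 0.1 * dos
  tv <- structure(y, covariates = c("sex", "ga_weeks"), class = "trait_vector")
  r1 <- run_snp_association(tv, dos, data.frame(sex = sex, ga_weeks = ga))
  r2 <- run_snp_association(tv, dos, data.frame(sex = 2 * sex - 1,
                                                ga_weeks = (ga - 39) / 2))
  expect_equal(r1$beta, r2$beta, tolerance = 1e-10)
  expect_equal(r1$se, r2$se, tolerance = 1e-10)
})

test_that("monomorphic SNPs are flagged without an estimate", {
  tv <- structure(rnorm(50), covariates = "sex", class = "trait_vector")
  r <- run_snp_association(tv, rep(2, 50), data.frame(sex = rbinom(50, 1, 0.5)))
  expect_true(r$monomorphic)
  expect_true(is.na(r$beta))
})

test_that("type-I error is nominal across null SNPs", {
  set.seed(404)
  n <- 2000
  m <- 1000
  y <- rnorm(n)
  tv <- structure(y, covariates = "sex", class = "trait_vector")
  sexv <- rbinom(n, 1, 0.5)
  G <- matrix(rbinom(n * m, 2, 0.3), n, m,
              dimnames = list(NULL, sprintf("s%d", 1:m)))
  scan <- gwas_scan(tv, G, data.frame(sex = sexv))
  frac <- mean(scan$P < 0.05)
  expect_gte(frac, 0.035)
  expect_lte(frac, 0.065)
  # scan equals single-SNP route
  r1 <- run_snp_association(tv, G[, 17], data.frame(sex = sexv))
  expect_equal(scan$BETA[17], r1$beta, tolerance = 1e-12)
  expect_equal(scan$SE[17], r1$se, tolerance = 1e-12)
})

test_that("QC filtering applies every threshold and counts exclusions", {
  rec <- data.frame(SNP = sprintf("s%d", 1:6),
                    EAF = c(0.005, 0.3, 0.25, 0.4, 0.45, 0.2),
                    BETA = 0.1, SE = 0.02,
                    P = 0.5, N = 100,
                    INFO = c(0.9, 0.35, 0.95, 0.99, 0.8, 0.7),
                    HWE_P = c(0.5, 0.5, 1e-5, 0.2, 0.9, 0.3))
  out <- qc_filter(rec, qc_thresholds(), dialect = "impute")
  expect_identical(out$SNP, c("s4", "s5", "s6"))
  ex <- attr(out, "exclusions")
  expect_equal(unname(ex[c("maf", "info", "hwe")]), c(1, 1, 1))
  # vacuous thresholds keep everything
  loose <- qc_thresholds(min_maf = 1e-300, min_info = 1e-300,
                         min_r2 = 1e-300, min_hwe_p = 1e-300,
                         min_call_rate = 1e-300)
  expect_equal(nrow(qc_filter(rec, loose)), 6)
  # empty input, unknown dialect
  expect_equal(nrow(qc_filter(rec[0, ], qc_thresholds())), 0)
  expect_error(qc_filter(rec, qc_thresholds(), dialect = "beagle"), "dialect")
})

test_that("genomic control is calibrated, equivariant, and never shrinks", {
  # a calibrated null: median chi-square at exactly the reference point
  z <- sqrt(qchisq(seq(0.001, 0.999, length.out = 1001), 1))
  rec <- data.frame(BETA = z, SE = 1, P = 2 * pnorm(-z))
  gc1 <- genomic_control(rec)
  expect_equal(gc1$lambda, 1, tolerance = 1e-12)
  expect_equal(gc1$records$SE, rec$SE)
  # doubling all chi-squares doubles lambda; corrected median returns to 0.4549
  rec2 <- rec
  rec2$BETA <- rec$BETA * sqrt(2)
  gc2 <- genomic_control(rec2)
  expect_equal(gc2$lambda, 2, tolerance = 1e-12)
  chisq_corr <- (gc2$records$BETA / gc2$records$SE)^2
  expect_equal(median(chisq_corr), qchisq(0.5, 1), tolerance = 1e-9)
  # after correction with lambda > 1, every p is >= its uncorrected value
  expect_true(all(gc2$records$P >= 2 * pnorm(-abs(rec2$BETA / rec2$SE)) - 1e-15))
  # large null simulation: lambda within [0.97, 1.03]
  set.seed(31)
  zr <- rnorm(1e5)
  rec3 <- data.frame(BETA = zr, SE = 1, P = 2 * pnorm(-abs(zr)))
  gc3 <- genomic_control(rec3)
  expect_gt(gc3$lambda, 0.97)
  expect_lt(gc3$lambda, 1.03)
  # lambda < 1 leaves records untouched
  rec4 <- data.frame(BETA = zr / 2, SE = 1, P = 2 * pnorm(-abs(zr / 2)))
  gc4 <- genomic_control(rec4)
  expect_lt(gc4$lambda, 1)
  expect_identical(gc4$records$SE, rec4$SE)
})
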