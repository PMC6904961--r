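## ---------------------------------------------------------------------------
## Formula-level downstream statistics: variance explained, winner's-curse
## conditional-likelihood correction, Li-Ji effective number of tests,
## summary-statistic genetic risk score with downward elimination,
## conditional independence, and chi-square power via the noncentrality
## parameter.
## ---------------------------------------------------------------------------

#' Variance explained by a SNP
#'
#' `h2 = beta^2 * 2 f (1 - f)` for an effect `beta` in SD units of a unit-
#' variance trait and risk-allele frequency `f`; symmetric in `f` and
#' `1 - f`.
#'
#' @param beta Effect size (SD units per allele).
#' @param f Risk-allele frequency in (0, 1).
#' @return Fraction of trait variance explained.
#' @export
variance_explained <- function(beta, f) {
  if (any(f <= 0) || any(f >= 1)) stop("allele frequency must lie in (0, 1)")
  beta^2 * 2 * f * (1 - f)
}

#' Winner's-curse bias-reduced effect estimate
#'
#' Conditional maximum likelihood for an effect estimated in a scan that
#' only reports associations passing a two-sided significance threshold:
#' maximises `log phi((bhat - b)/s) - log[Phi(b/s - z_c) + Phi(-b/s - z_c)]`
#' over `b`, where `z_c` is the threshold z-value of the selection alpha.
#' The compromise estimator `(naive + mle)/2` is reported alongside.
#'
#' @param beta Naive (selected) estimate.
#' @param se Its standard error.
#' @param selection_alpha Two-sided selection threshold (e.g. `1e-5`).
#' @return List of class `winners_curse`: `naive`, `se`, `alpha`, `z_c`,
#'   `mle`, `compromise`.
#' @export
winners_curse_mle <- function(beta, se, selection_alpha) {
  stopifnot(se > 0, selection_alpha > 0, selection_alpha < 1)
  z_c <- stats::qnorm(selection_alpha / 2, lower.tail = FALSE)
  if (abs(beta / se) <= z_c) {
    stop(sprintf("estimate not selected at this cutoff (|z| = %.2f <= z_c = %.2f)",
                 abs(beta / se), z_c))
  }
  ll <- function(b) {
    stats::dnorm((beta - b) / se, log = TRUE) -
      log(stats::pnorm(b / se - z_c) + stats::pnorm(-b / se - z_c))
  }
  lim <- abs(beta) + 10 * se
  opt <- stats::optimize(ll, interval = c(-lim, lim), maximum = TRUE,
                         tol = 1e-9)
  structure(list(naive = beta, se = se, alpha = selection_alpha, z_c = z_c,
                 mle = opt$maximum, compromise = (beta + opt$maximum) / 2),
            class = "winners_curse")
}

#' @export
#' @method print winners_curse
print.winners_curse <- function(x, ...) {
  cat(sprintf("winner's-curse correction (alpha = %.3g, z_c = %.3f)\n",
              x$alpha, x$z_c))
  cat(sprintf("  naive %.4f (SE %.4f) -> MLE %.4f, compromise %.4f\n",
              x$naive, x$se, x$mle, x$compromise))
  invisible(x)
}

#' Effective number of independent tests (Li-Ji)
#'
#' From the eigenvalues `lambda_i` of the phenotype correlation matrix,
#' `m_eff = sum( I(lambda_i >= 1) + (lambda_i - floor(lambda_i)) )`; the
#' Bonferroni-corrected level is `alpha / m_eff`.  Tiny negative eigenvalues
#' (> -1e-10, numerical noise) are clipped at zero.
#'
#' @param corr_matrix Symmetric correlation matrix with unit diagonal.
#' @param alpha Nominal significance level.
#' @return List of class `effective_tests`: `eigenvalues`, `m_eff`, `alpha`,
#'   `alpha_corrected`.
#' @export
effective_tests <- function(corr_matrix, alpha = 5e-8) {
  R <- as.matrix(corr_matrix)
  if (nrow(R) != ncol(R) || max(abs(R - t(R))) > 1e-8) {
    stop("corr_matrix must be symmetric")
  }
  if (max(abs(diag(R) - 1)) > 1e-8) stop("corr_matrix must have unit diagonal")
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-6)) stop("corr_matrix is not positive semi-definite")
  ev <- pmax(ev, 0)
  ## guard floor() against eigenvalues a rounding error below an integer
  eps <- 1e-9
  m_eff <- sum((ev >= 1 - eps) + pmax(ev - floor(ev + eps), 0))
  structure(list(eigenvalues = ev, m_eff = m_eff, alpha = alpha,
                 alpha_corrected = alpha / m_eff),
            class = "effective_tests")
}

#' @export
#' @method print effective_tests
print.effective_tests <- function(x, ...) {
  cat(sprintf("Li-Ji effective tests: m_eff = %.3f of %d phenotypes\n",
              x$m_eff, length(x$eigenvalues)))
  cat(sprintf("  alpha %.3g -> corrected %.3g\n", x$alpha, x$alpha_corrected))
  invisible(x)
}

#' Summary-statistic genetic risk score effect
#'
#' gtx-style estimate of the effect of an externally weighted allele score
#' on a trait from per-SNP summary statistics:
#' `alpha = sum(w b / se^2) / sum(w^2 / se^2)`,
#' `se(alpha) = (sum w^2 / se^2)^(-1/2)`, with heterogeneity
#' `Q = sum(((b - alpha w)/se)^2)` on `k - 1` df.  When `p_het < 0.05` the
#' SNP with the largest `|b|` is dropped and the model refitted until the
#' score is homogeneous (downward elimination).  With effect-allele
#' frequencies supplied, the score's explained variance is
#' `h2_grs = alpha^2 * sum(w^2 * 2 f (1 - f))` (unit trait variance,
#' independent SNPs in Hardy-Weinberg proportions).
#'
#' @param weights External per-SNP weights (e.g. adult-BMI effect sizes).
#' @param betas,ses Local per-SNP estimates and standard errors.
#' @param eafs Optional effect-allele frequencies for `h2_grs`.
#' @param snps Optional SNP identifiers (for the removal report).
#' @param p_het_threshold Heterogeneity level driving elimination.
#' @return List of class `grs_result`: `alpha`, `se`, `p`, `Q`, `df`,
#'   `p_het`, `h2_grs`, `removed`, `k`.
#' @export
grs_effect <- function(weights, betas, ses, eafs = NULL, snps = NULL,
                       p_het_threshold = 0.05) {
  k <- length(weights)
  if (k == 0) stop("empty risk score")
  stopifnot(length(betas) == k, length(ses) == k, all(ses > 0))
  if (is.null(snps)) snps <- paste0("snp", seq_len(k))
  use <- seq_len(k)
  removed <- character(0)
  repeat {
    w <- weights[use]; b <- betas[use]; s <- ses[use]
    alpha <- sum(w * b / s^2) / sum(w^2 / s^2)
    se_a <- 1 / sqrt(sum(w^2 / s^2))
    Q <- sum(((b - alpha * w) / s)^2)
    dfQ <- length(use) - 1
    p_het <- if (dfQ > 0) stats::pchisq(Q, dfQ, lower.tail = FALSE) else NA_real_
    if (is.na(p_het) || p_het >= p_het_threshold) break
    drop <- use[which.max(abs(betas[use]))]
    removed <- c(removed, snps[drop])
    use <- setdiff(use, drop)
    if (!length(use)) stop("all SNPs eliminated; score irreducibly heterogeneous")
  }
  h2 <- if (!is.null(eafs)) {
    f <- eafs[use]
    alpha^2 * sum(weights[use]^2 * 2 * f * (1 - f))
  } else NA_real_
  structure(list(alpha = alpha, se = se_a,
                 p = 2 * stats::pnorm(-abs(alpha / se_a)),
                 Q = Q, df = dfQ, p_het = p_het, h2_grs = h2,
                 removed = removed, k = length(use)),
            class = "grs_result")
}

#' @export
#' @method print grs_result
print.grs_result <- function(x, ...) {
  cat(sprintf("GRS effect: alpha = %.4f (SE %.4f), p = %.3g; k = %d SNPs\n",
              x$alpha, x$se, x$p, x$k))
  cat(sprintf("  heterogeneity Q = %.2f on %d df (p = %.3g)\n",
              x$Q, x$df, x$p_het))
  if (length(x$removed)) {
    cat("  removed by downward elimination:", paste(x$removed, collapse = ", "), "\n")
  }
  if (is.finite(x$h2_grs)) cat(sprintf("  h2_grs = %.4f\n", x$h2_grs))
  invisible(x)
}

#' Conditional independence of two association signals
#'
#' Two signals are independent if, after adding the second SNP to the model,
#' the lead SNP's effect changes by at most 20% of its unconditional value
#' and stays nominally significant (p < 0.05).
#'
#' @param beta_model1 Lead-SNP effect in the unconditional model (non-zero).
#' @param beta_model2 Lead-SNP effect after conditioning.
#' @param p_lead_model2 Lead-SNP p-value after conditioning.
#' @param max_change Allowed relative effect change.
#' @param alpha Nominal significance level.
#' @return Logical.
#' @export
conditional_independence <- function(beta_model1, beta_model2, p_lead_model2,
                                     max_change = 0.20, alpha = 0.05) {
  if (beta_model1 == 0) stop("unconditional effect is zero; relative change undefined")
  abs(beta_model2 - beta_model1) / abs(beta_model1) <= max_change &&
    p_lead_model2 < alpha
}

#' GWAS power from the chi-square noncentrality parameter
#'
#' For an additive effect `b` (SD units) at allele frequency `f`, imputation
#' quality `r2` and sample size `n`, the association chi-square has
#' noncentrality `NCP = n * 2 f (1 - f) * b^2 * r2`; power is the upper tail
#' of the noncentral chi-square beyond the 1-df critical value at `alpha`.
#' With `power` supplied instead of `beta`, the minimum detectable effect is
#' found by bisection on (0, 5] SD (tolerance 1e-10).
#'
#' @param n Sample size.
#' @param maf Allele frequency in (0, 1).
#' @param r2 Imputation quality in (0, 1].
#' @param alpha Significance level.
#' @param beta Effect size in SD units (mode `power_at_effect`).
#' @param power Target power (mode `min_detectable_effect`).
#' @return List of class `gwas_power`: `n`, `maf`, `r2`, `alpha`, `beta`,
#'   `ncp`, `power`.
#' @export
power_analysis <- function(n, maf, r2 = 1, alpha = 5e-8, beta = NULL,
                           power = NULL) {
  stopifnot(n >= 1, maf > 0, maf < 1, r2 > 0, r2 <= 1, alpha > 0, alpha < 1)
  crit <- stats::qchisq(alpha, df = 1, lower.tail = FALSE)
  pow_at <- function(b) {
    ncp <- n * 2 * maf * (1 - maf) * b^2 * r2
    stats::pchisq(crit, df = 1, ncp = ncp, lower.tail = FALSE)
  }
  if (!is.null(beta)) {
    p <- pow_at(beta)
    out <- list(n = n, maf = maf, r2 = r2, alpha = alpha, beta = beta,
                ncp = n * 2 * maf * (1 - maf) * beta^2 * r2, power = p)
  } else {
    if (is.null(power)) stop("supply either beta or power")
    stopifnot(power > 0, power < 1)
    if (pow_at(5) < power) stop("requested power unattainable for effects <= 5 SD")
    lo <- 0; hi <- 5
    while (hi - lo > 1e-10) {
      mid <- (lo + hi) / 2
      if (pow_at(mid) < power) lo <- mid else hi <- mid
    }
    b <- (lo + hi) / 2
    out <- list(n = n, maf = maf, r2 = r2, alpha = alpha, beta = b,
                ncp = n * 2 * maf * (1 - maf) * b^2 * r2, power = pow_at(b))
  }
  class(out) <- "gwas_power"
  out
}

#' @export
#' @method print gwas_power
print.gwas_power <- function(x, ...) {
  cat(sprintf(
    "GWAS power: n = %d, f = %.3g, r2 = %.2f, alpha = %.3g\n  beta = %.4f SD -> NCP = %.2f, power = %.3f\n",
    x$n, x$maf, x$r2, x$alpha, x$beta, x$ncp, x$power))
  invisible(x)
}
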