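## ---------------------------------------------------------------------------
## Per-study GWAS: trait transformation and z-scoring, additive OLS
## association with trait-specific covariates, QC filtering, genomic control.
## ---------------------------------------------------------------------------

#' Prepare a derived trait for association testing
#'
#' Applies the trait transformation rule — natural log for every trait except
#' the two ages (`age_ap`, `age_ar`), to reduce skewness — then converts to
#' z-scores within the study.  Missing values propagate.  Idempotent: a
#' vector that has already been prepared is only re-standardised.
#'
#' @param values Numeric trait values (natural scale).
#' @param trait Trait name (any spelling of the six canonical traits).
#' @return Numeric vector of z-scores with class `trait_vector` and
#'   attributes `trait`, `transform` and `covariates`.
#' @export
prepare_trait <- function(values, trait) {
  trait <- normalize_trait(trait)
  x <- as.numeric(values)
  transform <- if (trait %in% .LOG_TRAITS) "log" else "none"
  if (!inherits(values, "trait_vector") && transform == "log") {
    bad <- which(!is.na(x) & x <= 0)
    if (length(bad)) {
      stop("non-positive ", trait, " value under log transform at position(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    x <- log(x)
  }
  ok <- !is.na(x)
  if (sum(ok) < 2 || stats::sd(x[ok]) == 0) {
    stop("trait '", trait, "' has zero variance; cannot z-score")
  }
  z <- x
  z[ok] <- (x[ok] - mean(x[ok])) / stats::sd(x[ok])
  structure(z, trait = trait, transform = transform,
            covariates = trait_covariates(trait), class = "trait_vector")
}

#' Covariate rule per trait
#'
#' All traits are adjusted for gestational age and sex, except `bmi_ar` and
#' `age_ar`, which are adjusted for sex only (gestational effects do not
#' reach the rebound).
#'
#' @param trait Trait name.
#' @return Character vector of covariate column names.
#' @export
trait_covariates <- function(trait) {
  trait <- normalize_trait(trait)
  if (trait %in% c("bmi_ar", "age_ar")) "sex" else c("sex", "ga_weeks")
}

## Exact OLS of y on each column of G with shared covariates X (including
## intercept), via Frisch-Waugh residualisation.  Returns beta, se, p (t
## distribution with exact residual df), n.
.ols_assoc <- function(y, G, X) {
  ok <- stats::complete.cases(y, X)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  G <- G[ok, , drop = FALSE]
  n <- length(y)
  p <- ncol(X)
  if (n < p + 2) stop("too few complete cases for association testing")
  qx <- qr(X)
  ry <- stats::resid(stats::lm.fit(X, y))
  rG <- G - X %*% qr.coef(qx, G)
  gg <- colSums(rG^2)
  gy <- as.numeric(crossprod(rG, ry))
  beta <- ifelse(gg > 0, gy / gg, NA_real_)
  df <- n - p - 1
  rss <- sum(ry^2) - ifelse(is.na(beta), 0, beta^2 * gg)
  se <- sqrt(pmax(rss, 0) / df / gg)
  tval <- beta / se
  data.frame(beta = beta, se = se,
             p = 2 * stats::pt(-abs(tval), df = df),
             n = n, df = df)
}

#' Single-SNP additive association
#'
#' Ordinary least squares of a prepared trait on an additive dosage with the
#' trait's covariate set (selected by [trait_covariates()] when `covariates`
#' contains both `sex` and `ga_weeks`).  Two-sided p-value from the t
#' statistic with exact residual degrees of freedom.
#'
#' @param trait A [prepare_trait()] vector (or plain z-scores plus `trait=`).
#' @param dosage Additive dosages in `[0, 2]`.
#' @param covariates data.frame with `sex` and (where applicable) `ga_weeks`,
#'   plus any extra adjustment columns.
#' @param snp Optional SNP identifier copied to the output.
#' @return One-row data.frame: `snp`, `eaf`, `beta`, `se`, `p`, `n`, and
#'   `monomorphic` flag (no estimate when `TRUE`).
#' @export
run_snp_association <- function(trait, dosage, covariates, snp = NA_character_) {
  cov_use <- attr(trait, "covariates")
  cv <- as.data.frame(covariates)
  if (!is.null(cov_use)) {
    missing_cov <- setdiff(cov_use, names(cv))
    if (length(missing_cov)) {
      stop("covariates lack column(s): ", paste(missing_cov, collapse = ", "))
    }
    extra <- setdiff(names(cv), c("sex", "ga_weeks"))
    cv <- cv[, c(cov_use, extra), drop = FALSE]
  }
  ok <- stats::complete.cases(trait, dosage, cv)
  eaf <- mean(dosage[ok]) / 2
  if (stats::var(dosage[ok]) == 0) {
    return(data.frame(snp = snp, eaf = eaf, beta = NA_real_, se = NA_real_,
                      p = NA_real_, n = sum(ok), monomorphic = TRUE,
                      stringsAsFactors = FALSE))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(cv))
  res <- .ols_assoc(as.numeric(trait), matrix(dosage, ncol = 1), X)
  data.frame(snp = snp, eaf = eaf, beta = res$beta, se = res$se, p = res$p,
             n = res$n, monomorphic = FALSE, stringsAsFactors = FALSE)
}

#' Genome-wide association scan for one trait in one study
#'
#' Vectorised OLS association of a prepared trait against every SNP of a
#' dosage matrix (exact least squares via residualisation on the covariates).
#' Produces the per-study summary-statistic table with effect-allele
#' frequency, Hardy-Weinberg goodness-of-fit p-value (on rounded hard calls)
#' and the panel's imputation info score.
#'
#' @param trait A [prepare_trait()] vector, one value per subject.
#' @param genotypes Dosage matrix (subjects x SNPs), e.g. a
#'   `genotype_matrix`.
#' @param covariates data.frame with `sex`, `ga_weeks` for the same subjects.
#' @param study Study label stored in the table.
#' @param stage Stage label (1 or 2).
#' @return data.frame with canonical columns `SNP, CHR, POS, EA, OA, EAF,
#'   BETA, SE, P, N, INFO, HWE_P` plus `study` and `stage`.
#' @export
gwas_scan <- function(trait, genotypes, covariates, study = "S1", stage = 1L) {
  panel <- attr(genotypes, "panel")
  G <- unclass(genotypes)
  attr(G, "panel") <- NULL
  attr(G, "info") <- NULL
  cov_use <- attr(trait, "covariates")
  cv <- as.data.frame(covariates)
  if (!is.null(cov_use)) cv <- cv[, cov_use, drop = FALSE]
  ok <- stats::complete.cases(as.numeric(trait), cv)
  res <- .ols_assoc(as.numeric(trait)[ok],
                    G[ok, , drop = FALSE],
                    cbind(1, as.matrix(cv)[ok, , drop = FALSE]))
  eaf <- colMeans(G[ok, , drop = FALSE]) / 2
  hwe <- apply(G[ok, , drop = FALSE], 2, hwe_gof_p)
  data.frame(
    SNP = colnames(G),
    CHR = if (is.null(panel)) NA_character_ else panel$chrom,
    POS = if (is.null(panel)) NA_integer_ else panel$pos,
    EA = if (is.null(panel)) NA_character_ else panel$ea,
    OA = if (is.null(panel)) NA_character_ else panel$oa,
    EAF = eaf, BETA = res$beta, SE = res$se, P = res$p, N = res$n,
    INFO = if (is.null(panel)) 1 else panel$info,
    HWE_P = hwe, study = study, stage = as.integer(stage),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Hardy-Weinberg goodness-of-fit p-value
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of hard-call
#' genotype counts (dosages rounded to 0/1/2) against Hardy-Weinberg
#' expectations at the sample allele frequency.
#'
#' @param dosage Dosage vector.
#' @return Two-sided p-value (1 for monomorphic SNPs).
#' @export
hwe_gof_p <- function(dosage) {
  g <- round(dosage[!is.na(dosage)])
  n <- length(g)
  obs <- c(sum(g == 0), sum(g == 1), sum(g == 2))
  p <- (obs[2] + 2 * obs[3]) / (2 * n)
  if (p <= 0 || p >= 1) return(1)
  expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((obs - expd)^2 / expd)
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' Quality-control thresholds
#'
#' Defaults follow the standard imputed-GWAS practice: exclude SNPs with
#' MAF < 1%, imputation info < 0.4 (IMPUTE dialect) or r^2 < 0.3 (MACH
#' dialect), Hardy-Weinberg P < 1e-4, and call rate < 95%.
#'
#' @param min_maf,min_info,min_r2,min_hwe_p,min_call_rate Thresholds, each
#'   in (0, 1).
#' @return Named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_maf = 0.01, min_info = 0.4, min_r2 = 0.3,
                          min_hwe_p = 1e-4, min_call_rate = 0.95) {
  th <- list(min_maf = min_maf, min_info = min_info, min_r2 = min_r2,
             min_hwe_p = min_hwe_p, min_call_rate = min_call_rate)
  num <- unlist(th)
  if (any(num <= 0) || any(num >= 1)) {
    stop("all QC thresholds must lie strictly inside (0, 1)")
  }
  structure(th, class = "qc_thresholds")
}

#' Filter summary statistics on quality-control criteria
#'
#' A record survives iff it passes every applicable threshold: minor allele
#' frequency (from `EAF`), imputation quality (`INFO` against the dialect's
#' cutoff), Hardy-Weinberg (`HWE_P`) and, when a `CALL_RATE` column is
#' present, call rate.  Exclusion counts per criterion are attached as the
#' `exclusions` attribute.
#'
#' @param records Summary-statistic data.frame ([gwas_scan()] dialect).
#' @param thresholds A [qc_thresholds()] object.
#' @param dialect `"impute"` (info score) or `"mach"` (r^2).
#' @return Filtered records with an `exclusions` attribute.
#' @export
qc_filter <- function(records, thresholds = qc_thresholds(),
                      dialect = c("impute", "mach")) {
  if (is.character(dialect) && !all(dialect %in% c("impute", "mach"))) {
    stop("unknown imputation dialect '", dialect[1], "'")
  }
  dialect <- match.arg(dialect)
  if (!nrow(records)) {
    attr(records, "exclusions") <- c(maf = 0L, info = 0L, hwe = 0L, call_rate = 0L)
    return(records)
  }
  maf <- pmin(records$EAF, 1 - records$EAF)
  info_cut <- if (dialect == "impute") thresholds$min_info else thresholds$min_r2
  pass_maf <- maf >= thresholds$min_maf
  pass_info <- if ("INFO" %in% names(records)) records$INFO >= info_cut else TRUE
  pass_hwe <- if ("HWE_P" %in% names(records)) records$HWE_P >= thresholds$min_hwe_p else TRUE
  pass_cr <- if ("CALL_RATE" %in% names(records)) records$CALL_RATE >= thresholds$min_call_rate else TRUE
  keep <- pass_maf & pass_info & pass_hwe & pass_cr
  out <- records[keep, , drop = FALSE]
  attr(out, "exclusions") <- c(maf = sum(!pass_maf), info = sum(!pass_info & pass_maf),
                               hwe = sum(!pass_hwe & pass_maf & pass_info),
                               call_rate = sum(!pass_cr & pass_maf & pass_info & pass_hwe))
  out
}

#' Genomic control
#'
#' Computes the inflation factor `lambda` as the median association
#' chi-square `(BETA/SE)^2` divided by the 1-df chi-square median
#' (0.4549364).  When `lambda > 1` the standard errors are multiplied by
#' `sqrt(lambda)` and p-values recomputed (normal approximation); statistics
#' are never shrunk when `lambda <= 1`.
#'
#' @param records Summary-statistic data.frame with `BETA` and `SE`.
#' @return List with `records` (adjusted) and `lambda`.
#' @export
genomic_control <- function(records) {
  est <- is.finite(records$BETA) & is.finite(records$SE) & records$SE > 0
  if (sum(est) < 100) {
    warning("genomic control on fewer than 100 records; lambda is unstable")
  }
  chisq <- (records$BETA[est] / records$SE[est])^2
  lambda <- stats::median(chisq) / .CHISQ1_MEDIAN
  if (is.finite(lambda) && lambda > 1) {
    records$SE[est] <- records$SE[est] * sqrt(lambda)
    records$P[est] <- 2 * stats::pnorm(-abs(records$BETA[est] / records$SE[est]))
  }
  records$lambda_gc <- lambda
  list(records = records, lambda = lambda)
}
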