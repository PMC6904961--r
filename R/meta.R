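## ---------------------------------------------------------------------------
## Inverse-variance fixed-effects meta-analysis with double genomic control,
## follow-up selection, significance tiers, and Efron local false discovery
## rate on stage-1 z-values.
## ---------------------------------------------------------------------------

#' Inverse-variance fixed-effects meta-analysis
#'
#' Combines estimates as `beta = sum(b_i/se_i^2) / sum(1/se_i^2)` with
#' `se = (sum 1/se_i^2)^(-1/2)`; two-sided p from the normal approximation.
#' Cochran's heterogeneity statistic `Q = sum(((b_i - beta)/se_i)^2)` is
#' referred to a chi-square on `k - 1` df and summarised as
#' `I^2 = max(0, (Q - (k-1))/Q) * 100`.
#'
#' @param beta Per-study estimates.
#' @param se Per-study standard errors (all > 0).
#' @return One-row data.frame: `beta`, `se`, `p`, `k`, `Q`, `q_p`, `i2`.
#' @export
ivw_meta <- function(beta, se) {
  k <- length(beta)
  if (k == 0) stop("no estimates to meta-analyse")
  if (length(se) != k) stop("beta and se lengths differ")
  if (any(!is.finite(se)) || any(se <= 0)) stop("standard errors must be positive")
  w <- 1 / se^2
  b <- sum(w * beta) / sum(w)
  s <- 1 / sqrt(sum(w))
  Q <- sum(((beta - b) / se)^2)
  i2 <- if (k > 1 && Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  data.frame(beta = b, se = s, p = 2 * stats::pnorm(-abs(b / s)), k = k,
             Q = Q, q_p = if (k > 1) stats::pchisq(Q, k - 1, lower.tail = FALSE) else NA_real_,
             i2 = i2)
}

#' Random-effects (DerSimonian-Laird) meta-analysis
#'
#' Provided as a sensitivity option; the fixed-effects combination is the
#' default throughout the pipeline.
#'
#' @inheritParams ivw_meta
#' @return One-row data.frame as [ivw_meta()] plus `tau2`.
#' @export
dl_meta <- function(beta, se) {
  fe <- ivw_meta(beta, se)
  k <- fe$k
  w <- 1 / se^2
  tau2 <- max(0, (fe$Q - (k - 1)) / (sum(w) - sum(w^2) / sum(w)))
  wr <- 1 / (se^2 + tau2)
  b <- sum(wr * beta) / sum(wr)
  s <- 1 / sqrt(sum(wr))
  cbind(data.frame(beta = b, se = s, p = 2 * stats::pnorm(-abs(b / s)),
                   k = k, Q = fe$Q, q_p = fe$q_p, i2 = fe$i2), tau2 = tau2)
}

#' Meta-analyse per-study summary statistics SNP by SNP
#'
#' Aligns studies on `SNP` and applies [ivw_meta()] per SNP.  Monomorphic or
#' missing per-study records are dropped SNP-wise.
#'
#' @param study_stats List of per-study summary-statistic data.frames
#'   ([gwas_scan()] dialect).
#' @param stage Stage label stored in the result.
#' @return data.frame: `SNP`, `BETA`, `SE`, `P`, `K`, `Q`, `Q_P`, `I2`,
#'   `stage`, plus `EAF`/`N` (weighted mean and total) and panel columns from
#'   the first study carrying them.
#' @export
meta_analyze <- function(study_stats, stage = "stage1") {
  stopifnot(length(study_stats) >= 1)
  all_stats <- do.call(rbind, lapply(study_stats, function(d) {
    d[is.finite(d$BETA) & is.finite(d$SE) & d$SE > 0,
      intersect(c("SNP", "BETA", "SE", "EAF", "N"), names(d)), drop = FALSE]
  }))
  ## vectorised IVW across the per-SNP groups
  g <- factor(all_stats$SNP, levels = unique(all_stats$SNP))
  w <- 1 / all_stats$SE^2
  sw <- tapply(w, g, sum)
  b <- tapply(w * all_stats$BETA, g, sum) / sw
  k <- as.integer(table(g))
  Q <- tapply((all_stats$BETA - b[g])^2 * w, g, sum)
  s <- 1 / sqrt(sw)
  i2 <- ifelse(k > 1 & Q > 0, pmax(0, (Q - (k - 1)) / Q) * 100, 0)
  out <- data.frame(
    SNP = levels(g), BETA = as.numeric(b), SE = as.numeric(s),
    P = 2 * stats::pnorm(-abs(b / s)), K = k, Q = as.numeric(Q),
    Q_P = ifelse(k > 1, stats::pchisq(Q, pmax(k - 1, 1), lower.tail = FALSE),
                 NA_real_),
    I2 = as.numeric(i2),
    EAF = if ("EAF" %in% names(all_stats) && "N" %in% names(all_stats)) {
      as.numeric(tapply(all_stats$EAF * all_stats$N, g, sum) /
                   tapply(all_stats$N, g, sum))
    } else NA_real_,
    N = if ("N" %in% names(all_stats)) as.integer(tapply(all_stats$N, g, sum))
        else NA_integer_,
    stringsAsFactors = FALSE, row.names = NULL)
  first <- study_stats[[1]]
  keep <- intersect(c("SNP", "CHR", "POS", "EA", "OA"), names(first))
  if (length(keep) > 1) {
    out <- merge(unique(first[, keep, drop = FALSE]), out, by = "SNP",
                 all.y = TRUE, sort = FALSE)
  }
  out$stage <- stage
  rownames(out) <- NULL
  out[order(match(out$SNP, first$SNP)), , drop = FALSE]
}

#' Stage-1 meta-analysis with double genomic control
#'
#' Applies genomic control within each study (first correction), combines
#' studies by inverse-variance fixed effects, then applies genomic control
#' again to the meta-level chi-square distribution (second correction).
#'
#' @param study_stats List of per-study stage-1 summary statistics.
#' @param gc_studies Apply the per-study correction (set `FALSE` if the
#'   inputs are already genomic-control adjusted).
#' @return List: `records` (meta table, `lambda_gc` column = meta lambda),
#'   `lambda_meta`, `lambda_studies`.
#' @export
double_gc_meta <- function(study_stats, gc_studies = TRUE) {
  lambdas <- rep(NA_real_, length(study_stats))
  if (gc_studies) {
    for (i in seq_along(study_stats)) {
      gc <- genomic_control(study_stats[[i]])
      study_stats[[i]] <- gc$records
      lambdas[i] <- gc$lambda
    }
  }
  meta <- meta_analyze(study_stats, stage = "stage1")
  gc2 <- genomic_control(meta)
  list(records = gc2$records, lambda_meta = gc2$lambda,
       lambda_studies = lambdas)
}

#' Follow-up selection configuration
#'
#' Thresholds of the two-stage design: strict stage-1 significance
#' (`p_strict = 1e-7`), the relaxed candidate-gene threshold
#' (`p_candidate = 1e-5`) for SNPs in/near genes with established links to
#' adiposity or metabolic phenotypes, an explicit override allowlist for
#' SNPs carried forward on prior evidence, and the combined-stage tiers
#' (genome-wide `5e-8`, suggestive `5e-6`).
#'
#' @param p_strict,p_candidate Stage-1 selection thresholds
#'   (`p_strict < p_candidate`).
#' @param candidate_snps SNP ids flagged as in/near candidate genes.
#' @param override_snps SNP ids always selected.
#' @param genome_wide,suggestive Combined-stage significance tiers.
#' @return List of class `selection_config`.
#' @export
selection_config <- function(p_strict = 1e-7, p_candidate = 1e-5,
                             candidate_snps = character(),
                             override_snps = character(),
                             genome_wide = 5e-8, suggestive = 5e-6) {
  if (!(p_strict < p_candidate)) stop("p_strict must be < p_candidate")
  structure(list(p_strict = p_strict, p_candidate = p_candidate,
                 candidate_snps = candidate_snps,
                 override_snps = override_snps,
                 genome_wide = genome_wide, suggestive = suggestive),
            class = "selection_config")
}

#' Select SNPs for stage-2 follow-up
#'
#' A SNP is selected iff its stage-1 p-value is below `p_strict`, or below
#' `p_candidate` while flagged as in/near a candidate gene, or it is on the
#' override allowlist.  The reason for selection is recorded.
#'
#' @param records Stage-1 meta-analysis records (`SNP`, `P`).
#' @param config A [selection_config()].
#' @return The selected subset with a `reason` column
#'   (`strict`/`candidate`/`override`).
#' @export
select_for_followup <- function(records, config = selection_config()) {
  if (!nrow(records)) {
    out <- records
    out$reason <- character(0)
    return(out)
  }
  strict <- records$P < config$p_strict
  cand <- records$P < config$p_candidate & records$SNP %in% config$candidate_snps
  over <- records$SNP %in% config$override_snps
  keep <- strict | cand | over
  out <- records[keep, , drop = FALSE]
  out$reason <- ifelse(strict[keep], "strict",
                       ifelse(cand[keep], "candidate", "override"))
  rownames(out) <- NULL
  out
}

#' Classify combined-stage significance
#'
#' Tiers by strict inequality: `genome-wide` below `5e-8`, `suggestive`
#' below `5e-6`, otherwise `none`.
#'
#' @param records Combined-stage meta records (`SNP`, `P`).
#' @param config A [selection_config()].
#' @return `records` with a `tier` factor column; tier counts in the
#'   `tier_counts` attribute.
#' @export
classify_significance <- function(records, config = selection_config()) {
  tier <- ifelse(records$P < config$genome_wide, "genome-wide",
                 ifelse(records$P < config$suggestive, "suggestive", "none"))
  records$tier <- factor(tier, levels = c("genome-wide", "suggestive", "none"))
  attr(records, "tier_counts") <- table(records$tier)
  records
}

#' Efron local false discovery rate
#'
#' Two-groups model `fdr(z) = pi0 f0(z) / f(z)` with the theoretical null
#' `f0 = N(0, 1)`.  The marginal density `f` is estimated by Poisson
#' regression of histogram counts on a natural-spline basis of the bin
#' midpoints (Lindsey's method); `pi0` by central matching — the median of
#' `f(z)/phi(z)` over the central window — capped at 1.
#'
#' @param z z-values; alternatively supply two-sided p-values via `p`
#'   (converted to `|z|` with alternating signs for a symmetric histogram).
#' @param p Two-sided p-values (used when `z` is `NULL`).
#' @param bins Number of histogram bins.
#' @param df Spline degrees of freedom.
#' @param central_window Half-width of the `pi0` matching window.
#' @return List of class `local_fdr`: `fdr` (per input value, in `[0, 1]`),
#'   `pi0`, `z`, and the binned density estimate.
#' @export
local_fdr <- function(z = NULL, p = NULL, bins = 120, df = 7,
                      central_window = 1) {
  if (is.null(z)) {
    if (is.null(p)) stop("supply z-values or p-values")
    zq <- stats::qnorm(pmax(p, 1e-300) / 2, lower.tail = FALSE)
    z <- zq * rep_len(c(-1, 1), length(zq))
  }
  z <- z[is.finite(z)]
  if (length(z) < 1000) {
    stop("local fdr needs at least 1000 values for stable density estimation")
  }
  L <- max(abs(z)) * (1 + 1e-8)
  breaks <- seq(-L, L, length.out = bins + 1)
  mid <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  width <- diff(breaks)[1]
  counts <- tabulate(findInterval(z, breaks, rightmost.closed = TRUE), bins)
  basis <- splines::ns(mid, df = df)
  fit <- stats::glm(counts ~ basis, family = stats::poisson())
  fhat_bin <- pmax(stats::fitted(fit), 1e-12) / (length(z) * width)
  central <- abs(mid) < central_window
  pi0 <- min(1, stats::median(fhat_bin[central] / stats::dnorm(mid[central])))
  basis_z <- splines::ns(z, knots = attr(basis, "knots"),
                         Boundary.knots = attr(basis, "Boundary.knots"))
  eta <- as.numeric(cbind(1, basis_z) %*% stats::coef(fit))
  fz <- pmax(exp(eta), 1e-300) / (length(z) * width)
  fdr <- pmin(1, pi0 * stats::dnorm(z) / fz)
  structure(list(fdr = fdr, pi0 = pi0, z = z,
                 density = data.frame(mid = mid, f = fhat_bin)),
            class = "local_fdr")
}

#' @export
#' @method print local_fdr
print.local_fdr <- function(x, ...) {
  cat(sprintf("local fdr on %d z-values: pi0 = %.3f, median fdr = %.3f\n",
              length(x$z), x$pi0, stats::median(x$fdr)))
  invisible(x)
}
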