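## ---------------------------------------------------------------------------
## Synthetic multi-study cohorts: term-born singletons with irregular visit
## schedules from birth to 13 years, log-BMI trajectories generated from the
## infancy and childhood polynomial mixed models, Reed first-order height
## curves 0-24 months, Hardy-Weinberg genotypes, and SNP effects injected on
## the latent derived traits so every downstream stage has known ground truth.
## ---------------------------------------------------------------------------

#' Construct a SNP panel
#'
#' A panel of independent (no LD) biallelic SNPs used by the genotype
#' simulator. `info` is a per-SNP imputation-quality score in (0, 1]; SNPs
#' with `info < 1` get fractional dosages emulating imputation noise.
#'
#' @param id SNP identifiers.
#' @param chrom Chromosome labels.
#' @param pos 1-based positions.
#' @param ea,oa Effect and other allele (single bases).
#' @param maf Minor (= effect) allele frequencies, each in (0, 1).
#' @param info Imputation info scores in (0, 1]; default 1 (hard calls).
#' @return A `data.frame` with class `snp_panel`.
#' @export
snp_panel <- function(id, chrom, pos, ea, oa, maf, info = 1) {
  panel <- data.frame(id = as.character(id), chrom = as.character(chrom),
                      pos = as.integer(pos), ea = as.character(ea),
                      oa = as.character(oa), maf = as.numeric(maf),
                      info = rep_len(as.numeric(info), length(id)),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(panel$id)) stop("duplicated SNP ids in panel")
  if (any(!is.finite(panel$maf)) || any(panel$maf <= 0) || any(panel$maf >= 1)) {
    stop("MAF must lie strictly inside (0, 1)")
  }
  if (any(panel$info <= 0) || any(panel$info > 1)) {
    stop("info scores must lie in (0, 1]")
  }
  class(panel) <- c("snp_panel", "data.frame")
  panel
}

#' Default SNP panel
#'
#' Twenty independent SNPs with minor allele frequencies spread over
#' 0.05-0.50, one per pseudo-chromosome position.
#'
#' @param n_snps Number of SNPs.
#' @return A [snp_panel()].
#' @export
default_snp_panel <- function(n_snps = 20) {
  maf <- round(seq(0.05, 0.50, length.out = n_snps), 3)
  snp_panel(id = sprintf("snp_%02d", seq_len(n_snps)),
            chrom = as.character(rep_len(1:22, n_snps)),
            pos = 1e6L + seq_len(n_snps) * 1000L,
            ea = rep_len(c("A", "G", "C", "T"), n_snps),
            oa = rep_len(c("G", "A", "T", "C"), n_snps),
            maf = maf)
}

## Generative population parameters.  Fixed effects are on the log-BMI scale
## with age centred (0.75 y infancy, 7.25 y childhood); they put the average
## adiposity peak at 0.75 y / 17.5 kg/m^2 and the average adiposity rebound
## near 5.5 y / 15.5 kg/m^2.  Reed height parameters (cm vs months) give a
## newborn length near 50 cm, 24-month height near 84 cm and a peak height
## velocity of ~6.4 cm/month shortly after birth.
default_population <- function() {
  list(
    infancy = list(
      beta = c(b0 = log(17.5), b1 = 0, b2 = -0.35, b3 = 0.02, b4 = 0.03),
      re_sd = c(u0 = 0.08, u1 = 0.06), re_cor = 0.2,
      ga_beta = 0.010),
    childhood = list(
      beta = c(b0 = 2.772, b1 = 0.0374, b2 = 0.012, b3 = 0.0005,
               b4 = 0.010, b5 = -0.002, b6 = 0.0004),
      re_sd = c(u0 = 0.10, u1 = 0.012), re_cor = -0.2,
      ga_beta = 0),
    reed_height = list(
      a = 53, b = 0.58, c = 5.3, d = 1.2,
      a_sd = 2.0, b_sd = 0.3, a_sex = 1.0, b_sex = 0.02, ga_beta = 0.6),
    infancy_break = 1.5,    # years; boundary between the two log-BMI models
    height_growth_cm_y = 6.5  # linear height growth beyond 24 months
  )
}

#' Cohort simulation configuration
#'
#' Parameters of the synthetic multi-study design: per-study sample size,
#' visit schedule with per-visit dropout, term-born gestational-age
#' distribution (37-41 completed weeks), sex ratio, SNP panel, causal SNP
#' effects on the latent derived traits (in SD units of the trait as analysed,
#' i.e. after any log transform), between-study heterogeneity of those
#' effects, and measurement noise.
#'
#' @param n_individuals Subjects per study.
#' @param n_studies Number of independent studies.
#' @param visit_schedule Target visit ages in years.
#' @param visit_dropout Per-visit dropout probability, scalar or one value per
#'   visit, each in `[0, 1)` (1 is allowed to force-drop a visit).
#' @param ga_probs Named probabilities over gestational weeks 37-41.
#' @param sex_ratio Fraction of males (sex coded 0 = female, 1 = male).
#' @param panel A [snp_panel()].
#' @param causal_effects `data.frame` with columns `snp`, `trait`, `beta`
#'   (SD units of the analysed trait per effect allele), or `NULL`.
#' @param between_study_sd SD of the study-level random shift added to each
#'   causal effect.
#' @param sigma_logbmi Residual SD on log-BMI observations.
#' @param sigma_height Measurement SD on height (cm).
#' @param age_jitter Multiplicative visit-age jitter half-width (uniform).
#' @param population Named list overriding entries of the generative
#'   population parameters (see the methods vignette).
#' @param seed Base RNG seed.
#' @return A list with class `cohort_config`.
#' @export
cohort_config <- function(n_individuals = 1000,
                          n_studies = 4,
                          visit_schedule = c(0, 0.04, 0.25, 0.5, 0.75, 1, 1.5,
                                             2, 3, 4, 5, 6, 7, 8, 10, 13),
                          visit_dropout = 0.15,
                          ga_probs = c(`37` = 0.08, `38` = 0.18, `39` = 0.30,
                                       `40` = 0.30, `41` = 0.14),
                          sex_ratio = 0.51,
                          panel = default_snp_panel(),
                          causal_effects = NULL,
                          between_study_sd = 0,
                          sigma_logbmi = 0.05,
                          sigma_height = 0.5,
                          age_jitter = 0.04,
                          population = list(),
                          seed = 20190904) {
  stopifnot(n_individuals >= 1, n_studies >= 0)
  dropout <- rep_len(visit_dropout, length(visit_schedule))
  if (any(dropout < 0) || any(dropout > 1)) {
    stop("visit dropout probabilities must lie in [0, 1]")
  }
  if (abs(sum(ga_probs) - 1) > 1e-8) stop("ga_probs must sum to 1")
  if (!identical(names(ga_probs), as.character(37:41))) {
    stop("ga_probs must be named over weeks 37..41 (term-born design)")
  }
  if (!inherits(panel, "snp_panel")) panel <- do.call(snp_panel, as.list(panel))
  if (!is.null(causal_effects)) {
    causal_effects <- as.data.frame(causal_effects)
    stopifnot(all(c("snp", "trait", "beta") %in% names(causal_effects)))
    causal_effects$trait <- vapply(causal_effects$trait, normalize_trait, "")
    if (!all(causal_effects$snp %in% panel$id)) {
      stop("causal_effects refer to SNPs absent from the panel")
    }
    if (any(!is.finite(causal_effects$beta))) stop("effect sizes must be finite")
  }
  pop <- utils::modifyList(default_population(), population)
  cfg <- list(n_individuals = n_individuals, n_studies = n_studies,
              visit_schedule = visit_schedule, visit_dropout = dropout,
              ga_probs = ga_probs, sex_ratio = sex_ratio, panel = panel,
              causal_effects = causal_effects,
              between_study_sd = between_study_sd,
              sigma_logbmi = sigma_logbmi, sigma_height = sigma_height,
              age_jitter = age_jitter, population = pop, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

#' @export
#' @method print cohort_config
print.cohort_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  %d stud%s x %d subjects, %d visits (dropout %s)\n",
              x$n_studies, if (x$n_studies == 1) "y" else "ies",
              x$n_individuals, length(x$visit_schedule),
              paste(unique(x$visit_dropout), collapse = "/")))
  cat(sprintf("  panel: %d SNPs; causal effects: %d; between-study SD %.3g\n",
              nrow(x$panel),
              if (is.null(x$causal_effects)) 0L else nrow(x$causal_effects),
              x$between_study_sd))
  invisible(x)
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Dosages are drawn per subject as Binomial(2, MAF), independently across
#' SNPs, so hard-call genotype counts are Hardy-Weinberg consistent by
#' construction. SNPs with `info < 1` receive zero-mean dosage noise of
#' variance `(1 - info) * 2 maf (1 - maf)` (clamped to `[0, 2]`), emulating
#' imputed dosages.
#'
#' @param config A [cohort_config()].
#' @param n Number of subjects (default `config$n_individuals`).
#' @param seed RNG seed (default `config$seed`).
#' @param ids Subject identifiers (default `ind_1..n`).
#' @return A dosage matrix (subjects x SNPs) with class `genotype_matrix` and
#'   attributes `panel` and `info`.
#' @export
simulate_genotypes <- function(config, n = config$n_individuals,
                               seed = config$seed, ids = NULL) {
  panel <- config$panel
  with_seed(seed, {
    m <- nrow(panel)
    dos <- vapply(seq_len(m), function(j) stats::rbinom(n, 2L, panel$maf[j]),
                  numeric(n))
    dos <- matrix(dos, nrow = n, ncol = m)
    soft <- which(panel$info < 1)
    for (j in soft) {
      v <- (1 - panel$info[j]) * 2 * panel$maf[j] * (1 - panel$maf[j])
      dos[, j] <- pmin(2, pmax(0, dos[, j] + stats::rnorm(n, 0, sqrt(v))))
    }
    dimnames(dos) <- list(if (is.null(ids)) sprintf("ind_%d", seq_len(n)) else ids,
                          panel$id)
    structure(dos, panel = panel, info = panel$info,
              class = c("genotype_matrix", "matrix", "array"))
  })
}

## -- latent curves ----------------------------------------------------------

## Per-subject infancy/childhood curve coefficients in centred age, as rows of
## a data.frame: intercept, linear, quadratic, cubic.
.stage_coef <- function(pop_stage, sex, ga, u0, u1, childhood = FALSE) {
  b <- pop_stage$beta
  if (childhood) {
    data.frame(intercept = b["b0"] + b["b4"] * sex + pop_stage$ga_beta * (ga - 39) + u0,
               linear = b["b1"] + b["b5"] * sex + u1,
               quadratic = b["b2"] + b["b6"] * sex,
               cubic = rep_len(b["b3"], length(sex)))
  } else {
    data.frame(intercept = b["b0"] + b["b4"] * sex + pop_stage$ga_beta * (ga - 39) + u0,
               linear = b["b1"] + u1,
               quadratic = rep_len(b["b2"], length(sex)),
               cubic = rep_len(b["b3"], length(sex)))
  }
}

.eval_curve <- function(coef, age_centered) {
  coef$intercept + coef$linear * age_centered + coef$quadratic * age_centered^2 +
    coef$cubic * age_centered^3
}

## Latent height (cm) at age t months from the Reed curve, extended linearly
## beyond 24 months.
.latent_height <- function(reed, t_months, pop) {
  k <- max(length(t_months), length(reed$a))
  t <- rep_len(pmax(t_months, 0.25), k)
  a <- rep_len(reed$a, k)
  b <- rep_len(reed$b, k)
  h24 <- a + b * 24 + reed$c_shared * log(24) + reed$d_shared / 24
  ifelse(t <= 24,
         a + b * t + reed$c_shared * log(t) + reed$d_shared / t,
         h24 + pop$height_growth_cm_y * (t - 24) / 12)
}

## Latent log-BMI at age t months (uses infancy curve up to the model break).
.latent_logbmi <- function(inf_coef, chi_coef, t_months, pop) {
  yrs <- rep_len(t_months / 12, max(length(t_months), nrow(inf_coef)))
  ifelse(yrs <= pop$infancy_break,
         .eval_curve(inf_coef, yrs - 0.75),
         .eval_curve(chi_coef, yrs - 7.25))
}

## Latent derived traits on the analysis scale (log for phv/pwv/bmi_ap/bmi_ar,
## natural for the two ages).  `state` carries the per-subject random effects
## and Reed parameters.
.latent_traits <- function(state, pop) {
  inf_coef <- .stage_coef(pop$infancy, state$sex, state$ga_weeks,
                          state$u0_inf, state$u1_inf)
  chi_coef <- .stage_coef(pop$childhood, state$sex, state$ga_weeks,
                          state$u0_chi, state$u1_chi, childhood = TRUE)
  ap <- curve_extremum(inf_coef$intercept, inf_coef$linear, inf_coef$quadratic,
                       inf_coef$cubic, center = 0.75, window = c(0.25, 1.25),
                       maximize = TRUE)
  ar <- curve_extremum(chi_coef$intercept, chi_coef$linear, chi_coef$quadratic,
                       chi_coef$cubic, center = 7.25, window = c(2.5, 8.5),
                       maximize = FALSE)
  reed <- list(a = state$reed_a, b = state$reed_b,
               c_shared = pop$reed_height$c, d_shared = pop$reed_height$d)
  phv <- reed1_peak_velocity(state$reed_b, pop$reed_height$c, pop$reed_height$d,
                             window = c(0.25, 24))
  ## peak weight velocity from the latent weight curve w(t) = BMI * (h/100)^2,
  ## by central differences on a fine monthly grid
  grid <- seq(0.25, 24, by = 0.05)
  n <- length(state$sex)
  H <- vapply(grid, function(t) .latent_height(reed, t, pop), numeric(n))
  B <- vapply(grid, function(t) exp(.latent_logbmi(inf_coef, chi_coef, t, pop)),
              numeric(n))
  W <- B * (H / 100)^2
  K <- length(grid)
  V <- (W[, 3:K, drop = FALSE] - W[, 1:(K - 2), drop = FALSE]) / (2 * 0.05)
  pwv <- apply(V, 1, max)
  data.frame(id = state$id,
             phv = log(phv$velocity), pwv = log(pwv),
             age_ap = ap$age, bmi_ap = ap$value,  # log scale (curve is log-BMI)
             age_ar = ar$age, bmi_ar = ar$value,
             ap_boundary = ap$boundary, ar_boundary = ar$boundary)
}

## Injection: shift the relevant per-subject parameter so the latent trait on
## the analysis scale moves by exactly `delta` (per subject), except the two
## age traits, where the stationary point is moved to the shifted age by a
## closed-form change of the random slope (clamped to the search window).
.apply_injection <- function(state, pop, trait, delta) {
  eps <- 1e-3
  if (trait %in% c("bmi_ap", "pwv")) {
    state$u0_inf <- state$u0_inf + delta
  } else if (trait == "bmi_ar") {
    state$u0_chi <- state$u0_chi + delta
  } else if (trait == "phv") {
    lat <- reed1_peak_velocity(state$reed_b, pop$reed_height$c,
                               pop$reed_height$d, window = c(0.25, 24))$velocity
    state$reed_b <- state$reed_b + (exp(log(lat) + delta) - lat)
  } else if (trait == "age_ap") {
    ## move the stationary point of the infancy curve to the shifted age:
    ## the random slope enters the derivative additively, so the required new
    ## slope has a closed form
    cur <- .latent_traits(state, pop)
    target <- pmin(pmax(cur$age_ap + delta, 0.25 + eps), 1.25 - eps)
    a_t <- target - 0.75
    b <- pop$infancy$beta
    state$u1_inf <- as.numeric(-(b["b1"] + 2 * b["b2"] * a_t + 3 * b["b3"] * a_t^2))
  } else if (trait == "age_ar") {
    cur <- .latent_traits(state, pop)
    target <- pmin(pmax(cur$age_ar + delta, 2.5 + eps), 8.5 - eps)
    a_t <- target - 7.25
    b <- pop$childhood$beta
    quad <- b["b2"] + b["b6"] * state$sex
    state$u1_chi <- as.numeric(-(b["b1"] + b["b5"] * state$sex +
                                   2 * quad * a_t + 3 * b["b3"] * a_t^2))
  } else {
    stop("cannot inject effects on trait '", trait, "'")
  }
  state
}

#' Simulate growth records for one study
#'
#' Generates subject records and longitudinal measurements for one study from
#' the configured population: log-BMI observations follow the infancy and
#' childhood polynomial mixed models (subject random intercept and slope),
#' heights follow subject-specific Reed curves over 0-24 months (linear
#' extension afterwards), and weight is derived as `BMI * (height/100)^2` so
#' every record is internally consistent.  Causal SNP effects are injected on
#' the latent derived traits, in SD units of the trait as analysed, before
#' measurements are realised.
#'
#' @param config A [cohort_config()].
#' @param genotypes A `genotype_matrix` covering the study subjects.
#' @param study Study label.
#' @param effect_shift Optional named numeric: study-level shift added to each
#'   causal effect (names = SNP ids). Drawn by [simulate_multi_study()].
#' @param seed RNG seed (default `config$seed`).
#' @return A list with `subjects`, `measurements` and a `truth` sidecar
#'   (latent traits on the analysis scale, per-study realised effects, and the
#'   baseline SDs used to convert SD-unit effects).
#' @export
simulate_growth <- function(config, genotypes, study = "S1",
                            effect_shift = NULL, seed = config$seed) {
  pop <- config$population
  n <- nrow(genotypes)
  ids <- rownames(genotypes)
  with_seed(seed, {
    sex <- stats::rbinom(n, 1, config$sex_ratio)
    ga <- as.integer(sample(37:41, n, replace = TRUE, prob = config$ga_probs))

    re <- function(sd2, rho) {
      ## closed-form Cholesky of the 2x2 covariance; robust to zero variances
      z <- matrix(stats::rnorm(2 * n), n, 2)
      cbind(sd2[1] * z[, 1],
            sd2[2] * (rho * z[, 1] + sqrt(1 - rho^2) * z[, 2]))
    }
    re_inf <- re(pop$infancy$re_sd, pop$infancy$re_cor)
    re_chi <- re(pop$childhood$re_sd, pop$childhood$re_cor)

    state <- data.frame(
      id = ids, sex = sex, ga_weeks = ga,
      u0_inf = re_inf[, 1], u1_inf = re_inf[, 2],
      u0_chi = re_chi[, 1], u1_chi = re_chi[, 2],
      reed_a = pop$reed_height$a + pop$reed_height$a_sex * sex +
        pop$reed_height$ga_beta * (ga - 39) +
        stats::rnorm(n, 0, pop$reed_height$a_sd),
      reed_b = pop$reed_height$b + pop$reed_height$b_sex * sex +
        stats::rnorm(n, 0, pop$reed_height$b_sd),
      stringsAsFactors = FALSE)

    ## baseline latent traits, SDs on the analysis scale, then injection
    base <- .latent_traits(state, pop)
    sd0 <- vapply(.TRAITS, function(tr) stats::sd(base[[tr]]), 0)
    effects <- NULL
    if (!is.null(config$causal_effects) && nrow(config$causal_effects) > 0) {
      ce <- config$causal_effects
      shift <- if (is.null(effect_shift)) stats::setNames(rep(0, nrow(ce)), ce$snp) else effect_shift
      ce$beta_study <- ce$beta + as.numeric(shift[ce$snp])
      ## accumulate per-trait deltas (analysis scale) and apply once per trait
      for (tr in unique(ce$trait)) {
        if (sd0[tr] == 0) {
          stop("cannot inject on trait '", tr, "': latent trait has zero variance")
        }
        rows <- ce[ce$trait == tr, , drop = FALSE]
        delta <- rep(0, n)
        for (r in seq_len(nrow(rows))) {
          delta <- delta + genotypes[, rows$snp[r]] * rows$beta_study[r] * sd0[tr]
        }
        state <- .apply_injection(state, pop, tr, delta)
      }
      effects <- ce
    }
    latent <- .latent_traits(state, pop)

    ## realise visits
    sched <- config$visit_schedule
    nv <- length(sched)
    keep <- matrix(stats::runif(n * nv) >= rep(config$visit_dropout, each = n), n, nv)
    jit <- matrix(stats::runif(n * nv, 1 - config$age_jitter, 1 + config$age_jitter), n, nv)
    ages <- sweep(jit, 2, sched, `*`)
    ages[, sched == 0] <- 0
    ages <- pmin(pmax(ages, 0), 13)

    inf_coef <- .stage_coef(pop$infancy, state$sex, state$ga_weeks,
                            state$u0_inf, state$u1_inf)
    chi_coef <- .stage_coef(pop$childhood, state$sex, state$ga_weeks,
                            state$u0_chi, state$u1_chi, childhood = TRUE)
    reed <- list(a = state$reed_a, b = state$reed_b,
                 c_shared = pop$reed_height$c, d_shared = pop$reed_height$d)

    rows <- which(keep, arr.ind = TRUE)
    subj <- rows[, 1]
    age_y <- ages[rows]
    t_mo <- age_y * 12
    sub_inf <- inf_coef[subj, , drop = FALSE]
    sub_chi <- chi_coef[subj, , drop = FALSE]
    sub_reed <- list(a = reed$a[subj], b = reed$b[subj],
                     c_shared = reed$c_shared, d_shared = reed$d_shared)
    logbmi <- .latent_logbmi(sub_inf, sub_chi, t_mo, pop) +
      stats::rnorm(length(subj), 0, config$sigma_logbmi)
    height <- .latent_height(sub_reed, t_mo, pop) +
      stats::rnorm(length(subj), 0, config$sigma_height)
    bmi <- exp(logbmi)
    meas <- data.frame(study = study, id = ids[subj], sex = sex[subj],
                       ga_weeks = ga[subj], age_years = age_y,
                       weight_kg = bmi * (height / 100)^2,
                       height_cm = height, bmi_kgm2 = bmi,
                       stringsAsFactors = FALSE)
    meas <- meas[order(match(meas$id, ids), meas$age_years), ]
    rownames(meas) <- NULL

    subjects <- data.frame(id = ids, study = study, sex = sex, ga_weeks = ga,
                           stringsAsFactors = FALSE)
    list(subjects = subjects, measurements = meas,
         truth = list(study = study, latent = latent, trait_sd0 = sd0,
                      effects = effects, state = state))
  })
}

#' Simulate a multi-study design
#'
#' Generates `n_studies` independent cohorts.  Causal effects are perturbed
#' per study by a Normal(0, `between_study_sd`) shift, so Cochran's Q behaves
#' as a chi-square under homogeneity (`between_study_sd = 0`) and inflates
#' under heterogeneity.
#'
#' @param config A [cohort_config()].
#' @param seed RNG seed (default `config$seed`).
#' @return A list of studies (each with `subjects`, `measurements`,
#'   `genotypes`, `truth`) with class `multi_cohort`.
#' @export
simulate_multi_study <- function(config, seed = config$seed) {
  if (config$n_studies < 1) stop("n_studies must be >= 1")
  ce <- config$causal_effects
  shifts <- with_seed(child_seed(seed, 0), {
    if (is.null(ce) || config$between_study_sd == 0) NULL
    else matrix(stats::rnorm(config$n_studies * nrow(ce), 0, config$between_study_sd),
                config$n_studies, nrow(ce), dimnames = list(NULL, ce$snp))
  })
  studies <- lapply(seq_len(config$n_studies), function(s) {
    label <- sprintf("S%d", s)
    gt <- simulate_genotypes(config, seed = child_seed(seed, 2 * s),
                             ids = sprintf("%s_ind_%d", label, seq_len(config$n_individuals)))
    sh <- if (is.null(shifts)) NULL else stats::setNames(shifts[s, ], colnames(shifts))
    st <- simulate_growth(config, gt, study = label, effect_shift = sh,
                          seed = child_seed(seed, 2 * s + 1))
    st$genotypes <- gt
    st
  })
  names(studies) <- vapply(studies, function(s) s$truth$study, "")
  structure(studies, class = c("multi_cohort", "list"))
}
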