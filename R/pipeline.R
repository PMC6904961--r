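## ---------------------------------------------------------------------------
## End-to-end pipeline: simulate -> fit growth -> derive traits -> per-study
## GWAS + QC + genomic control -> meta-analysis with double genomic control
## -> follow-up selection and significance tiers.  Every stage writes its
## artifact with provenance headers; a resolved configuration copy is stored
## next to the outputs.
## ---------------------------------------------------------------------------

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param qc A [qc_thresholds()].
#' @param selection A [selection_config()].
#' @param traits Traits to scan (default all six).
#' @param dialect Imputation dialect for [qc_filter()].
#' @param out_dir Output directory.
#' @param seed Overrides `cohort$seed` when given.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), qc = qc_thresholds(),
                            selection = selection_config(),
                            traits = growth_traits(), dialect = "impute",
                            out_dir = tempfile("growthgwas_run_"),
                            seed = NULL) {
  if (!is.null(seed)) cohort$seed <- as.integer(seed)
  traits <- vapply(traits, normalize_trait, "")
  structure(list(cohort = cohort, qc = qc, selection = selection,
                 traits = unname(traits), dialect = dialect,
                 out_dir = out_dir),
            class = "pipeline_config")
}

.stage_log <- function(fmt, ..., t0 = NULL) {
  msg <- sprintf(fmt, ...)
  if (!is.null(t0)) {
    msg <- sprintf("%s [%.1f s]", msg, as.numeric(proc.time()[3]) - t0)
  }
  message("[growthgwas] ", msg)
}

#' Run the full synthetic-cohort GWAS pipeline
#'
#' Simulates the configured multi-study design, derives the six early-growth
#' traits per study, runs the per-SNP association scans with QC filtering,
#' applies double genomic control in the stage-1 meta-analysis, and applies
#' the follow-up selection and significance-tier rules.  All artifacts
#' (phenotypes, genotypes as VCF and dosage TSV, derived traits, per-study
#' and meta summary statistics, selection report, ground-truth sidecar,
#' resolved configuration) are written under `config$out_dir`.
#' Deterministic given the seed.
#'
#' @param config A [pipeline_config()].
#' @return Invisible list: `traits` (per-study derived traits), `study_stats`
#'   and `meta` per trait, `selection`, `lambda`, `paths`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (config$cohort$n_studies < 1) stop("n_studies must be >= 1")
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- as.numeric(proc.time()[3])

  resolved <- list(
    seed = config$cohort$seed,
    n_studies = config$cohort$n_studies,
    n_individuals = config$cohort$n_individuals,
    traits = config$traits, dialect = config$dialect,
    qc = unclass(config$qc),
    selection = lapply(unclass(config$selection), as.vector),
    visit_schedule = config$cohort$visit_schedule,
    between_study_sd = config$cohort$between_study_sd)
  yaml::write_yaml(resolved, file.path(out_dir, "config_resolved.yaml"))

  .stage_log("simulating %d studies x %d subjects (seed %d)",
             config$cohort$n_studies, config$cohort$n_individuals,
             config$cohort$seed)
  studies <- simulate_multi_study(config$cohort)
  .stage_log("simulation done", t0 = t0)

  trait_tables <- list()
  for (st in names(studies)) {
    s <- studies[[st]]
    write_phenotypes(s$measurements, file.path(out_dir, sprintf("phenotypes_%s.tsv", st)))
    write_vcf(s$genotypes, file.path(out_dir, sprintf("genotypes_%s.vcf", st)))
    write_dosage_tsv(s$genotypes, file.path(out_dir, sprintf("dosages_%s.tsv", st)))
    dt <- derive_growth_traits(s$measurements)
    utils::write.table(dt, file.path(out_dir, sprintf("derived_traits_%s.tsv", st)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    trait_tables[[st]] <- dt
    .stage_log("derived traits for %s (%d children)", st, nrow(dt), t0 = t0)
  }
  truth <- lapply(studies, function(s) {
    list(study = s$truth$study, trait_sd0 = as.list(s$truth$trait_sd0),
         effects = s$truth$effects)
  })
  jsonlite::write_json(truth, file.path(out_dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")

  results <- list()
  lambda_log <- list()
  for (tr in config$traits) {
    study_stats <- list()
    for (st in names(studies)) {
      dt <- trait_tables[[st]]
      gt <- studies[[st]]$genotypes
      ix <- match(rownames(gt), dt$id)
      tv <- prepare_trait(dt[[tr]][ix], tr)
      cov <- dt[ix, c("sex", "ga_weeks")]
      stats_st <- gwas_scan(tv, gt, cov, study = st, stage = 1L)
      stats_st <- qc_filter(stats_st, config$qc, dialect = config$dialect)
      write_summary_stats(
        stats_st, file.path(out_dir, sprintf("sumstats_%s_%s.tsv", tr, st)),
        provenance = list(stage = 1, study = st, trait = tr,
                          seed = config$cohort$seed,
                          date = format(Sys.Date())))
      study_stats[[st]] <- stats_st
    }
    meta <- double_gc_meta(study_stats, gc_studies = TRUE)
    rec <- classify_significance(meta$records, config$selection)
    write_summary_stats(
      stats::setNames(rec, sub("^Q_P$", "HetP", names(rec))),
      file.path(out_dir, sprintf("meta_%s.tsv", tr)),
      provenance = list(stage = "stage1-meta", trait = tr,
                        lambda = sprintf("%.6f", meta$lambda_meta),
                        seed = config$cohort$seed))
    results[[tr]] <- list(study_stats = study_stats, meta = rec)
    lambda_log[[tr]] <- list(studies = meta$lambda_studies,
                             meta = meta$lambda_meta)
    .stage_log("GWAS + meta for %s: lambda_meta %.3f", tr, meta$lambda_meta,
               t0 = t0)
  }

  sel <- do.call(rbind, lapply(config$traits, function(tr) {
    s <- select_for_followup(results[[tr]]$meta, config$selection)
    if (nrow(s)) cbind(trait = tr, s[, c("SNP", "BETA", "SE", "P", "reason")])
    else NULL
  }))
  if (!is.null(sel)) {
    utils::write.table(sel, file.path(out_dir, "selection_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  .stage_log("pipeline complete", t0 = t0)
  invisible(list(traits = trait_tables,
                 results = results, selection = sel, lambda = lambda_log,
                 truth = truth, out_dir = out_dir))
}
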