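## ---------------------------------------------------------------------------
## File formats: phenotype TSV, genotype VCF v4.2 / dosage TSV, summary-
## statistic TSV with provenance headers and METAL-style column aliases.
## All floating point is serialised at 15 significant digits so round trips
## are stable to 12 significant digits.
## ---------------------------------------------------------------------------

.PHENO_COLS <- c("study", "id", "sex", "ga_weeks", "age_years", "weight_kg",
                 "height_cm")
.SUMSTAT_COLS <- c("SNP", "CHR", "POS", "EA", "OA", "EAF", "BETA", "SE", "P",
                   "N", "INFO", "HWE_P")
.METAL_ALIASES <- c(MarkerName = "SNP", Effect = "BETA", StdErr = "SE",
                    `P-value` = "P", `P.value` = "P", Freq1 = "EAF",
                    Allele1 = "EA", Allele2 = "OA", Weight = "N")

.fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.15g", x))
}

#' Write a phenotype table
#'
#' @param data data.frame with the canonical columns `study, id, sex,
#'   ga_weeks, age_years, weight_kg, height_cm`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(data, path) {
  miss <- setdiff(.PHENO_COLS, names(data))
  if (length(miss)) stop("missing column: ", paste(miss, collapse = ", "))
  out <- data[, .PHENO_COLS]
  for (cn in c("age_years", "weight_kg", "height_cm")) out[[cn]] <- .fmt_num(out[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype table
#'
#' Malformed rows (non-positive weight or height, negative or missing age)
#' are dropped with a message naming their line numbers; valid rows are
#' returned with BMI recomputed.
#'
#' @param path TSV path written by [write_phenotypes()] (or compatible).
#' @return data.frame with the canonical columns plus `bmi_kgm2`.
#' @export
read_phenotypes <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, comment.char = "#")
  miss <- setdiff(.PHENO_COLS, names(d))
  if (length(miss)) stop("phenotype file lacks column: ", paste(miss, collapse = ", "))
  bad <- !is.finite(d$age_years) | d$age_years < 0 |
    !is.finite(d$weight_kg) | d$weight_kg <= 0 |
    !is.finite(d$height_cm) | d$height_cm <= 0 |
    !d$sex %in% c(0, 1)
  if (any(bad)) {
    message("dropping ", sum(bad), " malformed row(s) at line(s): ",
            paste(utils::head(which(bad) + 1L, 10), collapse = ", "))
    d <- d[!bad, , drop = FALSE]
  }
  d$id <- as.character(d$id)
  d$bmi_kgm2 <- d$weight_kg / (d$height_cm / 100)^2
  rownames(d) <- NULL
  d
}

#' Write genotypes as a dosage TSV
#'
#' Long header columns `SNP CHR POS EA OA INFO` followed by one dosage
#' column per subject.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dosage_tsv <- function(genotypes, path) {
  panel <- attr(genotypes, "panel")
  if (is.null(panel)) stop("genotypes carry no panel attribute")
  dos <- t(unclass(genotypes))
  out <- data.frame(SNP = panel$id, CHR = panel$chrom, POS = panel$pos,
                    EA = panel$ea, OA = panel$oa, INFO = .fmt_num(panel$info),
                    stringsAsFactors = FALSE)
  dosc <- as.data.frame(matrix(.fmt_num(dos), nrow = nrow(dos)))
  names(dosc) <- rownames(genotypes)
  utils::write.table(cbind(out, dosc), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write genotypes as VCF v4.2
#'
#' One biallelic record per SNP with `GT:DS` FORMAT: the hard call (rounded
#' dosage) and the dosage itself. Positions are 1-based.
#'
#' @param genotypes A `genotype_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(genotypes, path) {
  panel <- attr(genotypes, "panel")
  if (is.null(panel)) stop("genotypes carry no panel attribute")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=growthgwas",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Estimated alternate allele dosage">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(genotypes)), collapse = "\t")), con)
  dos <- unclass(genotypes)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(panel))) {
    hard <- pmin(pmax(round(dos[, j]), 0), 2)
    cells <- paste0(gt_codes[hard + 1], ":", .fmt_num(dos[, j]))
    ## REF = other allele, ALT = effect allele, so dosage counts effect alleles
    writeLines(paste(c(panel$chrom[j], panel$pos[j], panel$id[j], panel$oa[j],
                       panel$ea[j], ".", "PASS", ".", "GT:DS", cells),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from VCF or dosage TSV
#'
#' VCF records are converted to effect-allele dosages (`DS` preferred, `GT`
#' hard calls otherwise); multi-allelic sites are skipped with a warning.
#' The dosage TSV dialect is the one written by [write_dosage_tsv()].
#'
#' @param path Input path.
#' @param format `"vcf"` or `"dosage"`.
#' @return A `genotype_matrix` (subjects x SNPs, panel attribute attached;
#'   MAF recomputed from the dosages, floored away from 0 for panel
#'   validity).
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "dosage") {
    d <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
    meta <- d[, c("SNP", "CHR", "POS", "EA", "OA", "INFO")]
    dos <- t(as.matrix(d[, setdiff(names(d), names(meta)), drop = FALSE]))
    colnames(dos) <- meta$SNP
  } else {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    multi <- grepl(",", fix$ALT, fixed = TRUE)
    if (any(multi)) {
      warning("skipping ", sum(multi), " multi-allelic site(s)")
    }
    keep <- which(!multi)
    ds <- tryCatch(vcfR::extract.gt(v, element = "DS", as.numeric = TRUE),
                   error = function(e) NULL)
    gt <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                   error = function(e) NULL)
    if (is.null(ds) && is.null(gt)) stop("VCF carries neither DS nor GT")
    gt_dos <- if (!is.null(gt)) {
      matrix(vapply(gsub("\\|", "/", gt), function(x) {
        if (is.na(x) || x == "./.") NA_real_
        else sum(as.numeric(strsplit(x, "/", fixed = TRUE)[[1]]))
      }, 0), nrow = nrow(gt), dimnames = dimnames(gt))
    }
    dos_full <- if (!is.null(ds)) {
      if (!is.null(gt_dos)) ifelse(is.na(ds), gt_dos, ds) else ds
    } else gt_dos
    dos <- t(dos_full[keep, , drop = FALSE])
    colnames(dos) <- fix$ID[keep]
    meta <- data.frame(SNP = fix$ID[keep], CHR = fix$CHROM[keep],
                       POS = as.integer(fix$POS[keep]),
                       EA = fix$ALT[keep], OA = fix$REF[keep], INFO = 1,
                       stringsAsFactors = FALSE)
  }
  eaf <- colMeans(dos, na.rm = TRUE) / 2
  panel <- snp_panel(id = meta$SNP, chrom = meta$CHR, pos = meta$POS,
                     ea = meta$EA, oa = meta$OA,
                     maf = pmin(pmax(pmin(eaf, 1 - eaf), 1e-6), 1 - 1e-6),
                     info = as.numeric(meta$INFO))
  structure(dos, panel = panel, info = panel$info,
            class = c("genotype_matrix", "matrix", "array"))
}

#' Write a summary-statistic table
#'
#' Canonical column order with `# key=value` provenance header lines
#' (stage, study, trait, lambda, seed, date ...).
#'
#' @param records Summary-statistic data.frame.
#' @param path Output path.
#' @param provenance Named list/vector written as `# key=value` lines.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(records, path, provenance = list()) {
  cols <- intersect(c(.SUMSTAT_COLS, setdiff(names(records), .SUMSTAT_COLS)),
                    names(records))
  out <- records[, cols, drop = FALSE]
  for (cn in names(out)) if (is.numeric(out[[cn]])) out[[cn]] <- .fmt_num(out[[cn]])
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(provenance)) {
    writeLines(sprintf("# %s=%s", k, as.character(provenance[[k]])), con)
  }
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a summary-statistic table
#'
#' Accepts the canonical dialect and METAL-style aliases (`MarkerName`,
#' `Effect`, `StdErr`, `P-value`, `Freq1`, ...); provenance header lines are
#' returned in the `provenance` attribute.
#'
#' @param path Input path.
#' @return data.frame with canonical column names.
#' @export
read_summary_stats <- function(path) {
  lines <- readLines(path)
  prov_lines <- grep("^#\\s*\\S+=", lines, value = TRUE)
  prov <- list()
  for (ln in prov_lines) {
    kv <- sub("^#\\s*", "", ln)
    eq <- regexpr("=", kv, fixed = TRUE)
    prov[[substr(kv, 1, eq - 1)]] <- substr(kv, eq + 1, nchar(kv))
  }
  d <- utils::read.table(text = lines[!startsWith(lines, "#")], header = TRUE,
                         sep = "\t", stringsAsFactors = FALSE,
                         check.names = FALSE)
  hits <- names(d) %in% names(.METAL_ALIASES)
  names(d)[hits] <- .METAL_ALIASES[names(d)[hits]]
  attr(d, "provenance") <- prov
  d
}

#' Published index SNPs of the early-growth GWAS
#'
#' The eight index SNPs of the published two-stage GWAS meta-analysis of
#' early growth traits, with their printed stage-1, stage-2 and combined
#' effect sizes (SD units), standard errors and p-values, effect-allele
#' frequencies, candidate-gene flags and the follow-up override flag.  Used
#' as the worked example for the selection, classification and combination
#' operations.
#'
#' @return data.frame, one row per SNP.
#' @export
growth_gwas_snps <- function() {
  path <- system.file("extdata", "published_growth_gwas_snps.tsv",
                      package = "growthgwas", mustWork = TRUE)
  d <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE)
  d$candidate <- d$candidate == 1
  d$override <- d$override == 1
  d
}
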