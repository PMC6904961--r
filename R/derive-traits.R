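## ---------------------------------------------------------------------------
## End-to-end derivation of the six early-growth traits for one study.
## ---------------------------------------------------------------------------

#' Derive the six early-growth traits
#'
#' Runs the full trait-derivation chain on one study's longitudinal records:
#' fits the infancy and childhood log-BMI mixed models, derives the adiposity
#' peak and rebound from the individual curves, fits sex-stratified Reed1
#' models to height and weight over 0-24 months, and derives peak height and
#' weight velocity.  Children that fail a stage's minimum-measurement rule
#' get `NA` for that stage's traits.
#'
#' @param measurements data.frame with `id`, `sex`, `ga_weeks`, `age_years`,
#'   `weight_kg`, `height_cm` (and optionally `study`, `bmi_kgm2`).
#' @param ga_range Term-born inclusion window in completed weeks.
#' @param windows List with `ap`, `ar` (years) and `velocity` (months)
#'   search windows.
#' @param min_measurements Minimum per-window measurements per child.
#' @return data.frame of class `derived_traits`: one row per child with the
#'   six traits, boundary flags and per-trait missingness, plus attribute
#'   `fits` holding the four fitted models.
#' @export
derive_growth_traits <- function(measurements,
                                 ga_range = c(37, 41),
                                 windows = list(ap = c(0.25, 1.25),
                                                ar = c(2.5, 8.5),
                                                velocity = c(0.25, 24)),
                                 min_measurements = 3) {
  m <- as.data.frame(measurements)
  need <- c("id", "sex", "ga_weeks", "age_years", "weight_kg", "height_cm")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (!"bmi_kgm2" %in% names(m)) {
    m$bmi_kgm2 <- m$weight_kg / (m$height_cm / 100)^2
  }
  m <- m[m$ga_weeks >= ga_range[1] & m$ga_weeks <= ga_range[2], ]
  if (!nrow(m)) stop("no term-born children in the input")

  subjects <- unique(m[, c("id", "sex", "ga_weeks",
                           intersect("study", names(m)))])
  subjects$id <- as.character(subjects$id)

  inf_fit <- fit_bmi_trajectory(m, "infancy", min_measurements = min_measurements)
  chi_fit <- fit_bmi_trajectory(m, "childhood", min_measurements = min_measurements)
  ap <- derive_ap(individual_curves(inf_fit), window = windows$ap)
  ar <- derive_ar(individual_curves(chi_fit), window = windows$ar)

  pv_one <- function(measure) {
    parts <- lapply(sort(unique(m$sex)), function(s) {
      fit <- fit_reed1(m, measure = measure, sex_stratum = s,
                       min_measurements = min_measurements,
                       window_months = c(0, windows$velocity[2]))
      derive_peak_velocity(fit, window_months = windows$velocity)
    })
    do.call(rbind, parts)
  }
  phv <- pv_one("height_cm")
  pwv <- pv_one("weight_kg")

  out <- subjects
  out <- merge(out, stats::setNames(phv[, c("id", "pv", "pv_boundary")],
                                    c("id", "phv", "phv_boundary")),
               by = "id", all.x = TRUE)
  out <- merge(out, stats::setNames(pwv[, c("id", "pv", "pv_boundary")],
                                    c("id", "pwv", "pwv_boundary")),
               by = "id", all.x = TRUE)
  out <- merge(out, ap, by = "id", all.x = TRUE)
  out <- merge(out, ar, by = "id", all.x = TRUE)
  rownames(out) <- NULL
  attr(out, "fits") <- list(infancy = inf_fit, childhood = chi_fit)
  class(out) <- c("derived_traits", "data.frame")
  out
}
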