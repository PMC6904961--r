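## ---------------------------------------------------------------------------
## Infancy and childhood log-BMI mixed models and derivation of the adiposity
## peak (AP) and adiposity rebound (AR) from individual fitted curves.
##
## Infancy (2 weeks - 18 months, age centred at 0.75 y):
##   log(BMI) = b0 + b1 a + b2 a^2 + b3 a^3 + b4 sex + u0 + u1 a + eps
## Childhood (18 months - 13 years, age centred at 7.25 y) adds
##   b5 a:sex + b6 a^2:sex.
## Random intercept + random linear slope per child; ML estimation;
## empirical-Bayes prediction of (u0, u1).
## ---------------------------------------------------------------------------

.STAGE_DEFAULTS <- list(
  infancy = list(center_age = 0.75, window = c(14 / 365.25, 1.5)),
  childhood = list(center_age = 7.25, window = c(1.5, 13))
)

#' Fit a log-BMI trajectory mixed model
#'
#' Fits the stage-specific polynomial linear mixed model of log BMI on
#' centred age with a per-child random intercept and random linear age slope,
#' by maximum likelihood.  The infancy model uses ages in (2 weeks, 18
#' months] centred at 0.75 years; the childhood model uses ages in (18
#' months, 13 years] centred at 7.25 years and adds age-by-sex and
#' age-squared-by-sex interactions.
#'
#' @param data A data.frame with columns `id`, `age_years`, `sex` (0 =
#'   female, 1 = male) and either `bmi_kgm2` or both `weight_kg` and
#'   `height_cm`.
#' @param stage `"infancy"` or `"childhood"`.
#' @param center_age Centring age in years (stage default if `NULL`).
#' @param min_measurements Minimum in-window measurements per retained child.
#' @param min_subjects Fit is refused below this number of children.
#' @return An object of class `bmi_growth_fit`.
#' @seealso [individual_curves()], [derive_ap()], [derive_ar()]
#' @export
fit_bmi_trajectory <- function(data, stage = c("infancy", "childhood"),
                               center_age = NULL, min_measurements = 3,
                               min_subjects = 20) {
  stage <- match.arg(stage)
  def <- .STAGE_DEFAULTS[[stage]]
  if (is.null(center_age)) center_age <- def$center_age
  data <- as.data.frame(data)
  if (!"bmi_kgm2" %in% names(data)) {
    if (!all(c("weight_kg", "height_cm") %in% names(data))) {
      stop("data must contain 'bmi_kgm2' or both 'weight_kg' and 'height_cm'")
    }
    data$bmi_kgm2 <- data$weight_kg / (data$height_cm / 100)^2
  }
  need <- c("id", "age_years", "sex", "bmi_kgm2")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))

  d <- data[data$age_years > def$window[1] & data$age_years <= def$window[2] &
              is.finite(data$bmi_kgm2) & data$bmi_kgm2 > 0, need]
  cnt <- table(d$id)
  keep <- names(cnt)[cnt >= min_measurements]
  d <- d[d$id %in% keep, ]
  if (length(keep) < min_subjects) {
    stop(sprintf(
      "fit refused: %d children with >= %d measurements in the %s window (need >= %d)",
      length(keep), min_measurements, stage, min_subjects))
  }
  d$a <- d$age_years - center_age
  d$y <- log(d$bmi_kgm2)

  form <- if (stage == "infancy") {
    y ~ a + I(a^2) + I(a^3) + sex + (a | id)
  } else {
    y ~ a + I(a^2) + I(a^3) + sex + a:sex + I(a^2):sex + (a | id)
  }
  fit <- suppressWarnings(
    lme4::lmer(form, data = d, REML = FALSE,
               control = lme4::lmerControl(check.conv.singular = "ignore")))

  re <- lme4::ranef(fit)$id
  ranef_df <- data.frame(id = rownames(re), u0 = re[["(Intercept)"]],
                         u1 = re[["a"]], stringsAsFactors = FALSE)
  vc <- lme4::VarCorr(fit)$id
  out <- list(stage = stage, center_age = center_age,
              fixef = lme4::fixef(fit),
              vcov = as.matrix(stats::vcov(fit)),
              ranef = ranef_df,
              re_cov = matrix(vc[1:2, 1:2], 2, 2,
                              dimnames = list(c("u0", "u1"), c("u0", "u1"))),
              sigma = stats::sigma(fit),
              logLik = as.numeric(stats::logLik(fit)),
              n_obs = nrow(d), n_subjects = length(keep),
              window = def$window, model = fit)
  class(out) <- "bmi_growth_fit"
  out
}

#' @export
#' @method print bmi_growth_fit
print.bmi_growth_fit <- function(x, ...) {
  cat(sprintf("log-BMI %s trajectory model (ML)\n", x$stage))
  cat(sprintf("  %d children, %d observations; age centred at %.2f y\n",
              x$n_subjects, x$n_obs, x$center_age))
  cat("  fixed effects:\n")
  print(round(x$fixef, 5))
  cat(sprintf("  residual SD %.4f; logLik %.2f\n", x$sigma, x$logLik))
  invisible(x)
}

#' @export
#' @method summary bmi_growth_fit
summary.bmi_growth_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$fixef, `Std. Error` = se,
               `z value` = object$fixef / se)
  out <- list(stage = object$stage, coefficients = tab,
              re_cov = object$re_cov, sigma = object$sigma,
              logLik = object$logLik, n_subjects = object$n_subjects,
              n_obs = object$n_obs)
  class(out) <- "summary.bmi_growth_fit"
  out
}

#' @export
#' @method print summary.bmi_growth_fit
print.summary.bmi_growth_fit <- function(x, ...) {
  cat(sprintf("log-BMI %s trajectory model: %d children, %d observations\n",
              x$stage, x$n_subjects, x$n_obs))
  stats::printCoefmat(x$coefficients, digits = 4)
  cat("random-effect covariance (u0, u1):\n")
  print(signif(x$re_cov, 4))
  cat(sprintf("residual SD %.4f, logLik %.2f\n", x$sigma, x$logLik))
  invisible(x)
}

#' @export
coef.bmi_growth_fit <- function(object, ...) object$fixef

#' @export
logLik.bmi_growth_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$fixef) + 4, class = "logLik")
}

#' Predict log-BMI from a fitted trajectory model
#'
#' @param object A `bmi_growth_fit`.
#' @param newdata data.frame with `age_years`, `sex`, and (for `level = 1`)
#'   `id`.
#' @param level 0 for population-level prediction, 1 to include the child's
#'   empirical-Bayes random effects (unknown ids get 0).
#' @param ... Unused.
#' @return Predicted log-BMI values.
#' @export
predict.bmi_growth_fit <- function(object, newdata, level = 1, ...) {
  a <- newdata$age_years - object$center_age
  sex <- newdata$sex
  b <- object$fixef
  y <- b[["(Intercept)"]] + b[["a"]] * a + b[["I(a^2)"]] * a^2 +
    b[["I(a^3)"]] * a^3 + b[["sex"]] * sex
  if (object$stage == "childhood") {
    y <- y + b[["a:sex"]] * a * sex + b[["I(a^2):sex"]] * a^2 * sex
  }
  if (level >= 1) {
    if (is.null(newdata$id)) stop("level-1 prediction needs an 'id' column")
    idx <- match(as.character(newdata$id), object$ranef$id)
    u0 <- ifelse(is.na(idx), 0, object$ranef$u0[idx])
    u1 <- ifelse(is.na(idx), 0, object$ranef$u1[idx])
    y <- y + u0 + u1 * a
  }
  as.numeric(y)
}

#' Per-child fitted curve coefficients
#'
#' Collapses the fixed effects and the child's empirical-Bayes random effects
#' into one cubic polynomial in centred age per child: intercept
#' `b0 + b4 sex + u0`, linear `b1 [+ b5 sex] + u1`, quadratic
#' `b2 [+ b6 sex]`, cubic `b3`.
#'
#' @param fit A [fit_bmi_trajectory()] object.
#' @return data.frame of class `individual_curves` with columns `id`, `sex`,
#'   `intercept`, `linear`, `quadratic`, `cubic` and attribute `center_age`.
#' @export
individual_curves <- function(fit) {
  stopifnot(inherits(fit, "bmi_growth_fit"))
  d <- fit$model@frame
  sex <- d$sex[match(fit$ranef$id, as.character(d$id))]
  b <- fit$fixef
  b5 <- if ("a:sex" %in% names(b)) b[["a:sex"]] else 0
  b6 <- if ("I(a^2):sex" %in% names(b)) b[["I(a^2):sex"]] else 0
  out <- data.frame(
    id = fit$ranef$id, sex = sex,
    intercept = b[["(Intercept)"]] + b[["sex"]] * sex + fit$ranef$u0,
    linear = b[["a"]] + b5 * sex + fit$ranef$u1,
    quadratic = b[["I(a^2)"]] + b6 * sex,
    cubic = b[["I(a^3)"]],
    stringsAsFactors = FALSE)
  attr(out, "center_age") <- fit$center_age
  attr(out, "stage") <- fit$stage
  class(out) <- c("individual_curves", "data.frame")
  out
}

#' Extremum of a cubic log-BMI curve inside an age window
#'
#' Candidates are the real roots of the derivative
#' `linear + 2 quadratic a + 3 cubic a^2` (centred age) that fall inside the
#' window, plus the two window endpoints; the extremum is the candidate with
#' the largest (or smallest) predicted value, ties broken by earliest age.
#' Vectorised over curves.
#'
#' @param intercept,linear,quadratic,cubic Curve coefficients in centred age.
#' @param center Centring age (years).
#' @param window Age window (years, uncentred).
#' @param maximize `TRUE` for a maximum (adiposity peak), `FALSE` for a
#'   minimum (adiposity rebound).
#' @return data.frame with `age` (years), `value` (curve scale, i.e. log
#'   BMI), and `boundary` (`TRUE` when the extremum sits on a window edge).
#' @export
curve_extremum <- function(intercept, linear, quadratic, cubic, center,
                           window, maximize = TRUE) {
  k <- max(length(intercept), length(linear), length(quadratic), length(cubic))
  intercept <- rep_len(intercept, k); linear <- rep_len(linear, k)
  quadratic <- rep_len(quadratic, k); cubic <- rep_len(cubic, k)
  if (any(!is.finite(c(intercept, linear, quadratic, cubic)))) {
    stop("non-finite curve coefficients")
  }
  lo <- window[1] - center
  hi <- window[2] - center

  ## roots of 3 c a^2 + 2 q a + l = 0, vectorised; NA when absent.  The
  ## numerically stable form avoids cancellation when the cubic term is tiny.
  r1 <- r2 <- rep(NA_real_, k)
  cub <- abs(cubic) > 1e-12
  qd <- !cub & abs(quadratic) > 1e-12
  r1[qd] <- -linear[qd] / (2 * quadratic[qd])
  A <- 3 * cubic
  B <- 2 * quadratic
  disc <- B^2 - 4 * A * linear
  ok <- cub & disc >= 0
  sq <- sqrt(pmax(disc, 0))
  qq <- -(B + sign(B + (B == 0)) * sq) / 2
  r1[ok] <- (qq / A)[ok]
  r2[ok] <- ifelse(qq == 0, -B / (2 * A), linear / qq)[ok]

  cand_age <- cbind(lo, r1, r2, hi)
  cand_age[, 2][!is.na(r1) & (r1 <= lo | r1 >= hi)] <- NA
  cand_age[, 3][!is.na(r2) & (r2 <= lo | r2 >= hi)] <- NA
  cand_val <- matrix(NA_real_, k, 4)
  for (j in 1:4) {
    idx <- which(!is.na(cand_age[, j]))
    a <- cand_age[idx, j]
    cand_val[idx, j] <- intercept[idx] + linear[idx] * a +
      quadratic[idx] * a^2 + cubic[idx] * a^3
  }
  obj <- if (maximize) cand_val else -cand_val
  age <- value <- numeric(k)
  boundary <- logical(k)
  ## order candidates by age so which.max returns the earliest tie
  ord <- t(apply(cand_age, 1, order))
  for (i in seq_len(k)) {
    o <- ord[i, ]
    oi <- obj[i, o]
    best <- o[which.max(oi)]             # NAs never win which.max
    age[i] <- cand_age[i, best]
    value[i] <- cand_val[i, best]
    boundary[i] <- best %in% c(1, 4) || age[i] <= lo || age[i] >= hi
  }
  data.frame(age = age + center, value = value, boundary = boundary)
}

#' Derive the adiposity peak
#'
#' Locates the maximum of each child's fitted infancy log-BMI curve between
#' 0.25 and 1.25 years. `bmi_ap` back-transforms the log-scale prediction
#' with `exp()`.
#'
#' @param curves An [individual_curves()] data.frame from the infancy fit.
#' @param window AP search window in years.
#' @return data.frame with `id`, `age_ap`, `bmi_ap`, `ap_boundary`.
#' @export
derive_ap <- function(curves, window = c(0.25, 1.25)) {
  center <- attr(curves, "center_age")
  if (is.null(center)) stop("curves must carry a 'center_age' attribute")
  ext <- curve_extremum(curves$intercept, curves$linear, curves$quadratic,
                        curves$cubic, center = center, window = window,
                        maximize = TRUE)
  data.frame(id = curves$id, age_ap = ext$age, bmi_ap = exp(ext$value),
             ap_boundary = ext$boundary, stringsAsFactors = FALSE)
}

#' Derive the adiposity rebound
#'
#' Locates the minimum of each child's fitted childhood log-BMI curve between
#' 2.5 and 8.5 years.
#'
#' @param curves An [individual_curves()] data.frame from the childhood fit.
#' @param window AR search window in years.
#' @return data.frame with `id`, `age_ar`, `bmi_ar`, `ar_boundary`.
#' @export
derive_ar <- function(curves, window = c(2.5, 8.5)) {
  center <- attr(curves, "center_age")
  if (is.null(center)) stop("curves must carry a 'center_age' attribute")
  ext <- curve_extremum(curves$intercept, curves$linear, curves$quadratic,
                        curves$cubic, center = center, window = window,
                        maximize = FALSE)
  data.frame(id = curves$id, age_ar = ext$age, bmi_ar = exp(ext$value),
             ar_boundary = ext$boundary, stringsAsFactors = FALSE)
}
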