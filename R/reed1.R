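## ---------------------------------------------------------------------------
## Reed first-order growth model for infant height/weight, 0-24 months:
##   y(t) = a + b t + c ln(t) + d / t,   t in months (floored at 0.25)
## Fitted in two stages: shared (c, d) per sex stratum by pooled least squares
## with per-subject (a, b) profiled out (Frisch-Waugh), then per-subject
## (a, b) by least squares given (c, d).  The model is linear in all four
## parameters on the basis {1, t, ln t, 1/t}, so the noiseless fit is exact.
## ---------------------------------------------------------------------------

#' Fit the Reed1 infant growth model
#'
#' Fits `y(t) = a + b t + c ln(t) + d/t` (t in months) to height or weight
#' measurements from birth to 24 months, with `(c, d)` shared across the
#' subjects supplied (one sex stratum in the standard workflow) and `(a, b)`
#' subject specific.  Ages are floored at 0.25 months to avoid the `ln t`,
#' `1/t` singularity at birth.  Subjects with fewer than `min_measurements`
#' usable timepoints are flagged missing, not fitted.
#'
#' @param data data.frame with columns `id`, `age_years` and the measure
#'   column; an optional `sex` column is used when `sex_stratum` is given.
#' @param measure `"height_cm"` or `"weight_kg"`.
#' @param sex_stratum Optional 0/1; fit only that sex stratum.
#' @param min_measurements Minimum usable timepoints per subject.
#' @param window_months Age window in months.
#' @param t_floor Lower floor on age in months.
#' @return Object of class `reed1_fit` with shared `c`, `d`, per-subject
#'   `(a, b)` and residual summaries.
#' @export
fit_reed1 <- function(data, measure = c("height_cm", "weight_kg"),
                      sex_stratum = NULL, min_measurements = 3,
                      window_months = c(0, 24), t_floor = 0.25) {
  measure <- match.arg(measure)
  data <- as.data.frame(data)
  if (!measure %in% names(data)) stop("data lacks column '", measure, "'")
  if (!is.null(sex_stratum)) {
    if (!"sex" %in% names(data)) stop("sex_stratum given but data has no 'sex' column")
    data <- data[data$sex == sex_stratum, ]
  }
  t <- pmax(data$age_years * 12, t_floor)
  ok <- t >= max(window_months[1], t_floor) & t <= window_months[2] &
    is.finite(data[[measure]])
  d <- data.frame(id = as.character(data$id)[ok], t = t[ok],
                  y = data[[measure]][ok], stringsAsFactors = FALSE)
  ## distinct timepoints per subject (duplicated ages cannot identify a+bt)
  cnt <- tapply(d$t, d$id, function(x) length(unique(x)))
  usable <- names(cnt)[cnt >= min_measurements]
  missing_ids <- unique(c(setdiff(unique(as.character(data$id)), usable)))
  d <- d[d$id %in% usable, ]
  if (length(usable) < 1) stop("no subject has enough usable timepoints")

  ## stage 1: shared (c, d) after projecting out per-subject {1, t}
  sp <- split(seq_len(nrow(d)), d$id)
  Z <- cbind(lnt = log(d$t), invt = 1 / d$t)
  ry <- d$y
  rZ <- Z
  for (ix in sp) {
    X <- cbind(1, d$t[ix])
    qx <- qr(X)
    ry[ix] <- ry[ix] - X %*% qr.coef(qx, d$y[ix])
    rZ[ix, ] <- Z[ix, , drop = FALSE] - X %*% qr.coef(qx, Z[ix, , drop = FALSE])
  }
  cd <- qr.coef(qr(rZ), ry)
  cd[is.na(cd)] <- 0    # degenerate design (e.g. single shared timepoint set)

  ## stage 2: per-subject (a, b) given (c, d)
  y_adj <- d$y - cd[1] * log(d$t) - cd[2] / d$t
  ab <- t(vapply(sp, function(ix) {
    fit <- stats::lm.fit(cbind(1, d$t[ix]), y_adj[ix])
    r <- d$y[ix] - (fit$coefficients[1] + fit$coefficients[2] * d$t[ix] +
                      cd[1] * log(d$t[ix]) + cd[2] / d$t[ix])
    c(fit$coefficients, sd = if (length(ix) > 2) stats::sd(r) else NA_real_,
      n = length(ix))
  }, numeric(4)))
  subjects <- data.frame(id = names(sp), a = ab[, 1], b = ab[, 2],
                         resid_sd = ab[, 3], n = as.integer(ab[, 4]),
                         stringsAsFactors = FALSE, row.names = NULL)
  resid <- d$y - predict_reed1_core(subjects, cd, d$id, d$t)
  out <- list(measure = measure, sex_stratum = sex_stratum,
              c = unname(cd[1]), d = unname(cd[2]), subjects = subjects,
              missing = missing_ids, sigma = stats::sd(resid),
              n_obs = nrow(d), t_floor = t_floor,
              window_months = window_months,
              data = d, residuals = resid)
  class(out) <- "reed1_fit"
  out
}

predict_reed1_core <- function(subjects, cd, id, t) {
  ix <- match(as.character(id), subjects$id)
  subjects$a[ix] + subjects$b[ix] * t + cd[1] * log(t) + cd[2] / t
}

#' @export
#' @method print reed1_fit
print.reed1_fit <- function(x, ...) {
  cat(sprintf("Reed1 growth model for %s (%d subjects, %d observations)\n",
              x$measure, nrow(x$subjects), x$n_obs))
  cat(sprintf("  shared c = %.4f, d = %.4f; residual SD %.4f\n",
              x$c, x$d, x$sigma))
  if (length(x$missing)) {
    cat(sprintf("  %d subject(s) flagged missing (insufficient timepoints)\n",
                length(x$missing)))
  }
  invisible(x)
}

#' @export
coef.reed1_fit <- function(object, ...) {
  cbind(a = object$subjects$a, b = object$subjects$b,
        c = object$c, d = object$d)
}

#' Predict from a Reed1 fit
#'
#' @param object A `reed1_fit`.
#' @param newdata data.frame with `id` and `age_months` (or `age_years`).
#' @param ... Unused.
#' @return Predicted measurements; `NA` for unknown subjects.
#' @export
predict.reed1_fit <- function(object, newdata, ...) {
  t <- if ("age_months" %in% names(newdata)) newdata$age_months else newdata$age_years * 12
  t <- pmax(t, object$t_floor)
  predict_reed1_core(object$subjects, c(object$c, object$d), newdata$id, t)
}

#' @export
fitted.reed1_fit <- function(object, ...) {
  object$data$y - object$residuals
}

#' @export
residuals.reed1_fit <- function(object, ...) object$residuals

#' Peak velocity of a Reed1 curve
#'
#' The growth velocity is `v(t) = b + c/t - d/t^2`; its stationary point
#' `t* = 2 d / c` (from `v'(t) = -c/t^2 + 2 d/t^3 = 0`) is a candidate when
#' it lies inside the window and is a maximum (`d > 0`); the window endpoints
#' complete the candidate set.  With `c = d = 0` the velocity is the constant
#' `b` (no boundary flag).  Vectorised over `b`.
#'
#' @param b Per-subject linear coefficients (cm/month or kg/month).
#' @param c,d Shared Reed1 coefficients.
#' @param window Search window in months.
#' @return data.frame with `velocity`, `age_months`, `boundary`.
#' @export
reed1_peak_velocity <- function(b, c, d, window = c(0.25, 24)) {
  if (window[1] <= 0) stop("velocity window must start above 0 months")
  v <- function(t) b + c / t - d / t^2
  if (c == 0 && d == 0) {
    return(data.frame(velocity = b, age_months = window[1],
                      boundary = FALSE))
  }
  cand_t <- c(window[1], window[2])
  if (c != 0 && d > 0) {
    tstar <- 2 * d / c
    if (tstar > window[1] && tstar < window[2]) cand_t <- c(cand_t, tstar)
  }
  V <- vapply(cand_t, v, numeric(length(b)))
  V <- matrix(V, nrow = length(b))
  best <- max.col(V, ties.method = "first")
  data.frame(velocity = V[cbind(seq_along(b), best)],
             age_months = cand_t[best],
             boundary = best <= 2)
}

#' Peak velocity traits from a fitted Reed1 model
#'
#' Applies [reed1_peak_velocity()] to every subject of a [fit_reed1()] object
#' (peak height velocity in cm/month for height fits, peak weight velocity in
#' kg/month for weight fits).
#'
#' @param fit A `reed1_fit`.
#' @param window_months Search window in months.
#' @return data.frame with `id`, `pv`, `age_at_pv`, `pv_boundary`.
#' @export
derive_peak_velocity <- function(fit, window_months = c(0.25, 24)) {
  stopifnot(inherits(fit, "reed1_fit"))
  pv <- reed1_peak_velocity(fit$subjects$b, fit$c, fit$d, window = window_months)
  data.frame(id = fit$subjects$id, pv = pv$velocity,
             age_at_pv = pv$age_months, pv_boundary = pv$boundary,
             stringsAsFactors = FALSE)
}
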