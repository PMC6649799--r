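#' Age- and BMI-adjusted residual standardization (OPERA adjustment)
#'
#' Expresses a risk measure on a scale comparable across measures: the
#' residual after regressing the measure on age and log(BMI) *among
#' controls only* (ordinary least squares), divided by the control-group
#' residual standard deviation. Residuals for cases are computed from the
#' control-fitted model, so among controls the adjusted values have mean 0
#' and SD 1 by construction, and the case mean is the standardized
#' case-control separation.
#'
#' @param measure numeric vector, one value per woman.
#' @param age numeric vector of ages in years.
#' @param bmi numeric vector of BMI in kg/m^2 (entered as log BMI).
#' @param status case indicator: logical, 0/1, or factor/character with
#'   `"case"`/`"control"` levels.
#' @return numeric vector of adjusted values in control-residual SD units
#'   (`NA` where any input is missing).
#' @export
opera_adjust <- function(measure, age, bmi, status) {
  status <- .as_case_indicator(status)
  n <- length(measure)
  stopifnot(length(age) == n, length(bmi) == n, length(status) == n)
  ok <- complete.cases(measure, age, bmi, status)
  if (any(!ok)) message(sum(!ok), " rows with missing values dropped from adjustment")
  ctrl <- ok & status == 0
  if (sum(ctrl) < 10) stop("need at least 10 complete control rows for adjustment")
  dat <- data.frame(m = measure, age = age, logbmi = log(bmi))
  fit <- lm(m ~ age + logbmi, data = dat[ctrl, , drop = FALSE])
  if (any(is.na(coef(fit)))) stop("singular adjustment design (constant age or BMI)")
  resid_all <- rep(NA_real_, n)
  resid_all[ok] <- dat$m[ok] - predict(fit, newdata = dat[ok, , drop = FALSE])
  s <- sd(resid_all[ctrl])
  if (!is.finite(s) || s == 0) stop("control residual SD is zero; measure is fully explained by age and BMI")
  resid_all / s
}

.as_case_indicator <- function(status) {
  if (is.logical(status)) return(as.integer(status))
  if (is.numeric(status)) {
    stopifnot(all(status %in% c(0, 1, NA)))
    return(as.integer(status))
  }
  s <- tolower(as.character(status))
  stopifnot(all(s %in% c("case", "control", NA)))
  as.integer(s == "case")
}

#' Odds ratio per adjusted standard deviation
#'
#' Maximum-likelihood logistic regression of case status on an adjusted
#' measure plus age and log(BMI) (and optionally further co-measures, for
#' joint models). Returns the OR per unit (i.e. per adjusted SD when the
#' measure comes from [opera_adjust]) with the 95% Wald interval and Wald
#' p-value for the primary measure; the full coefficient table for all
#' measures is attached as `$table`.
#'
#' @param adjusted numeric vector (primary measure, adjusted-SD units).
#' @param status case indicator (see [opera_adjust]).
#' @param age,bmi covariates (BMI entered as log BMI).
#' @param extra_measures optional named data frame / list of co-measures to
#'   include in the same model.
#' @return An `or_result`: list with `or_per_sd`, `ci_low`, `ci_high`,
#'   `p_value`, `log_or`, `se`, `n_cases`, `n_controls` and `table`.
#' @export
adjusted_or <- function(adjusted, status, age, bmi, extra_measures = NULL) {
  status <- .as_case_indicator(status)
  dat <- data.frame(y = status, measure = adjusted, age = age, logbmi = log(bmi))
  measure_names <- "measure"
  if (!is.null(extra_measures)) {
    extra_measures <- as.data.frame(extra_measures)
    stopifnot(!is.null(names(extra_measures)), nrow(extra_measures) == nrow(dat))
    dat <- cbind(dat, extra_measures)
    measure_names <- c(measure_names, names(extra_measures))
  }
  dat <- dat[complete.cases(dat), , drop = FALSE]
  if (!all(c(0, 1) %in% dat$y)) stop("both cases and controls are required")
  form <- stats::reformulate(c(measure_names, "age", "logbmi"), response = "y")
  fit <- suppressWarnings(glm(form, family = binomial(), data = dat))
  cf <- coef(fit)
  if (!fit$converged || any(abs(cf[measure_names]) > 15))
    stop("logistic fit did not converge (possible separation); ",
         "consider the Bayesian lasso fit instead")
  se <- sqrt(diag(vcov(fit)))
  z95 <- 1.959964
  tab <- data.frame(
    measure = measure_names,
    or = exp(cf[measure_names]),
    ci_low = exp(cf[measure_names] - z95 * se[measure_names]),
    ci_high = exp(cf[measure_names] + z95 * se[measure_names]),
    p_value = 2 * pnorm(-abs(cf[measure_names] / se[measure_names])),
    row.names = NULL)
  structure(list(
    or_per_sd = tab$or[1], ci_low = tab$ci_low[1], ci_high = tab$ci_high[1],
    p_value = tab$p_value[1], log_or = log(tab$or[1]), se = se[["measure"]],
    n_cases = sum(dat$y == 1), n_controls = sum(dat$y == 0), table = tab),
    class = "or_result")
}

#' @export
print.or_result <- function(x, ...) {
  cat(sprintf("OR per adjusted SD: %.2f (95%% CI %.2f to %.2f), P = %.3g [%d cases / %d controls]\n",
              x$or_per_sd, x$ci_low, x$ci_high, x$p_value, x$n_cases, x$n_controls))
  if (nrow(x$table) > 1) { cat("Joint model:\n"); print(x$table, digits = 3) }
  invisible(x)
}

#' Interquartile risk ratio from an OR per SD
#'
#' For a continuous normally distributed risk factor and a relatively rare
#' disease, the risk ratio between the top and bottom quartiles of the
#' factor has the closed form
#' `IQRR = Phi(log(OR) - b) / Phi(a - log(OR))` with `a = Phi^-1(0.25)`,
#' `b = Phi^-1(0.75) = -a`, and `Phi` the standard normal CDF.
#'
#' @param or_per_sd odds ratio per adjusted SD (> 0); vectorized.
#' @return the interquartile risk ratio (fold difference).
#' @examples
#' iqrr(1)     # 1: no gradient
#' iqrr(1.76)  # about 4.2-fold
#' @export
iqrr <- function(or_per_sd) {
  stopifnot(all(or_per_sd > 0))
  b <- qnorm(0.75)
  lo <- log(or_per_sd)
  pnorm(lo - b) / pnorm(-b - lo)
}

#' AUC implied by a log OR per SD under the normal model
#'
#' When case and control distributions of a measure are normal with equal
#' variance, the standardized mean difference equals the log OR per SD and
#' the area under the ROC curve is `Phi(log_or / sqrt(2))` - approximately
#' linear in the log OR over the AUC range 0.5-0.7.
#'
#' @param log_or log odds ratio per SD; vectorized.
#' @return implied AUC in (0, 1).
#' @export
auc_from_log_or <- function(log_or) pnorm(log_or / sqrt(2))

#' OR per SD implied by a standardized case-control mean difference
#'
#' Under the equal-variance normal model the log OR per SD equals the
#' difference in means between cases and controls in SD units, so the OR is
#' simply `exp(delta)`.
#'
#' @param delta standardized mean difference; vectorized.
#' @return implied OR per SD.
#' @export
or_from_mean_difference <- function(delta) exp(delta)

#' Empirical (Mann-Whitney) AUC with 95% CI
#'
#' The probability that a randomly chosen case outscores a randomly chosen
#' control, ties counted one half; computed from midranks. The confidence
#' interval uses the Hanley-McNeil asymptotic variance.
#'
#' @param scores numeric vector of risk scores.
#' @param status case indicator (see [opera_adjust]).
#' @return list with `auc`, `ci_low`, `ci_high`, `n_cases`, `n_controls`.
#' @export
empirical_auc <- function(scores, status) {
  status <- .as_case_indicator(status)
  ok <- complete.cases(scores, status)
  scores <- scores[ok]; status <- status[ok]
  n1 <- as.numeric(sum(status == 1)); n0 <- as.numeric(sum(status == 0))
  if (n1 == 0 || n0 == 0) stop("both cases and controls are required")
  r <- rank(scores)                     # midranks handle ties as 1/2
  auc <- (sum(r[status == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) + (n0 - 1) * (q2 - auc^2)) /
    (n1 * n0)
  hw <- 1.959964 * sqrt(max(v, 0))
  list(auc = auc, ci_low = max(0, auc - hw), ci_high = min(1, auc + hw),
       n_cases = as.integer(n1), n_controls = as.integer(n0))
}

#' Variance-stabilizing transforms for conventional density measures
#'
#' Conventional mammographic density enters the models after Box-Cox-style
#' power transforms: the fourth root of absolute dense area (cm^2) and the
#' cube root of percent density. Downstream these are adjusted like any
#' other measure via [opera_adjust].
#'
#' @param absolute_density absolute dense area in cm^2 (>= 0).
#' @param percent_density percent density in `[0, 100]`.
#' @return list with `absolute` (fourth root) and `percent` (cube root).
#' @export
transform_density <- function(absolute_density, percent_density) {
  if (any(absolute_density < 0, na.rm = TRUE)) stop("absolute density must be >= 0")
  if (any(percent_density < 0 | percent_density > 100, na.rm = TRUE))
    stop("percent density must lie in [0, 100]")
  list(absolute = absolute_density^(1 / 4), percent = percent_density^(1 / 3))
}
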