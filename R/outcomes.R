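#' Per-group outcome rates
#'
#' Exact integer counts with the percentage rounded to `digits` decimals.
#'
#' @param outcomes 0/1 vector.
#' @param groups group labels aligned with `outcomes`.
#' @param digits decimals for the percentage (default 1).
#' @return data.frame: `group`, `n`, `events`, `rate_percent`; empty groups
#'   carry NA rates.
#' @export
group_rates <- function(outcomes, groups, digits = 1) {
  stopifnot(length(outcomes) == length(groups),
            all(outcomes %in% c(0, 1)))
  groups <- factor(groups)
  n <- as.integer(table(groups))
  k <- as.integer(tapply(outcomes, groups, sum, default = 0L))
  data.frame(group = levels(groups), n = n, events = k,
             rate_percent = ifelse(n > 0, round(100 * k / n, digits),
                                   NA_real_),
             stringsAsFactors = FALSE)
}

#' Firth-adjusted reproductive-outcome model over community types
#'
#' Fits a Firth-penalized logistic regression of a binary outcome on
#' community-type dummies (against the given reference type) plus
#' covariates, and reports per-type rates, odds ratios with
#' profile-penalized 95% confidence intervals, and penalized
#' likelihood-ratio p-values.
#'
#' @param assignments character vector of type labels per sample.
#' @param outcomes 0/1 outcome vector aligned with `assignments`.
#' @param covariate_data data.frame of covariates aligned with samples
#'   (default columns: age, bmi, embryos_transferred).
#' @param covariates covariate column names to adjust for.
#' @param reference reference type label (must be present).
#' @param level confidence level (default 0.95).
#' @return list: `rates` (per-type [group_rates()]), `model` (data.frame of
#'   contrasts: `type`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`),
#'   `fit`, `reference`, `covariates`.
#' @export
vagitype_outcome_model <- function(assignments, outcomes,
                                   covariate_data = NULL,
                                   covariates = c("age", "bmi",
                                                  "embryos_transferred"),
                                   reference, level = 0.95) {
  types <- factor(assignments)
  if (!reference %in% levels(types)) {
    stop2("reference type not present: ", reference)
  }
  types <- stats::relevel(types, ref = reference)
  dat <- data.frame(.y = outcomes, .type = types)
  if (!is.null(covariate_data) && length(covariates)) {
    miss <- setdiff(covariates, colnames(covariate_data))
    if (length(miss)) stop2("missing covariate(s): ",
                            paste(miss, collapse = ", "))
    dat <- cbind(dat, covariate_data[, covariates, drop = FALSE])
  } else {
    covariates <- character(0)
  }
  x <- stats::model.matrix(
    stats::as.formula(paste(".y ~ .type",
                            if (length(covariates))
                              paste("+", paste(covariates, collapse = " + "))
                            else "")), dat)
  fit <- firth_logistic(dat$.y, x)
  type_terms <- colnames(x)[startsWith(colnames(x), ".type")]
  ci <- profile_penalized_ci(fit, level = level, parameters = type_terms)
  model <- data.frame(type = sub("^\\.type", "", ci$term),
                      odds_ratio = exp(ci$estimate),
                      ci_low = exp(ci$ci_low), ci_high = exp(ci$ci_high),
                      p_value = ci$p_value, boundary = ci$boundary,
                      stringsAsFactors = FALSE)
  list(rates = group_rates(outcomes, assignments), model = model,
       fit = fit, reference = reference, covariates = covariates)
}
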