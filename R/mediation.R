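# coefficient lookup mapping aliased (NA) terms to zero
coef0 <- function(fit, term) {
  v <- stats::coef(fit)[[term]]
  if (is.na(v)) 0 else v
}

mediation_point <- function(dat, treatment, mediator, outcome, covariates,
                            mediator_scale) {
  fm <- stats::as.formula(paste(
    mediator, "~", paste(c(treatment, covariates), collapse = " + ")))
  # the mediator precedes the treatment so that a degenerate (noiseless)
  # chain, where the two are collinear, resolves to full mediation
  fy <- stats::as.formula(paste(
    outcome, "~", paste(c(mediator, treatment, covariates),
                        collapse = " + ")))
  t_obs <- dat[[treatment]]
  binary_t <- all(t_obs %in% c(0, 1))
  if (binary_t) {
    t0 <- 0; t1 <- 1
  } else {
    t0 <- mean(t_obs) - stats::sd(t_obs)
    t1 <- mean(t_obs) + stats::sd(t_obs)
  }
  delta <- t1 - t0
  my <- stats::lm(fy, data = dat)
  firth_flag <- FALSE
  if (mediator_scale == "binary") {
    mm <- suppressWarnings(stats::glm(fm, data = dat,
                                      family = stats::binomial()))
    if (!mm$converged || any(abs(stats::coef(mm)) > 15)) {
      # near-separation: refit the mediator model with Firth's penalty
      firth_flag <- TRUE
      xm <- stats::model.matrix(fm, dat)
      fr <- firth_logistic(dat[[mediator]], xm)
      mm$coefficients[] <- fr$coefficients[colnames(xm)]
    }
    d1 <- d0 <- dat
    d1[[treatment]] <- t1
    d0[[treatment]] <- t0
    p1 <- stats::predict(mm, newdata = d1, type = "response")
    p0 <- stats::predict(mm, newdata = d0, type = "response")
    b <- coef0(my, mediator)
    acme <- b * mean(p1 - p0) / delta
  } else {
    mm <- stats::lm(fm, data = dat)
    a <- coef0(mm, treatment)
    b <- coef0(my, mediator)
    acme <- a * b
  }
  ade <- coef0(my, treatment)
  te <- acme + ade
  c(acme = acme, ade = ade, total_effect = te,
    prop_mediated = if (abs(te) > .Machine$double.eps) acme / te else NA,
    firth_fallback = as.numeric(firth_flag))
}

#' Counterfactual mediation analysis for one triple
#'
#' Fits a mediator model (linear, or logistic for a binary mediator, with a
#' Firth-penalized fallback under separation) and a linear outcome model,
#' and computes the average causal mediation effect (ACME), average direct
#' effect (ADE) and total effect by the counterfactual contrast at
#' treatment mean +/- 1 sd (or 0/1 for a binary treatment), averaged over
#' arms and expressed per unit of treatment -- so for linear-linear fits the
#' ACME equals the product of coefficients exactly. Inference is by
#' nonparametric bootstrap (row resampling): percentile confidence
#' intervals and two-sided p = 2 min(frac <= 0, frac >= 0).
#'
#' @param data data.frame of complete cases.
#' @param treatment,mediator,outcome column names.
#' @param covariates additional adjustment columns.
#' @param mediator_scale `"continuous"` (linear model) or `"binary"`
#'   (logistic).
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param conf_level confidence level (default 0.95).
#' @return object of class `mediation_triple` with point estimates, CIs,
#'   p-values and the data/fit context needed by
#'   [mediation_sensitivity()].
#' @export
mediate <- function(data, treatment, mediator, outcome,
                    covariates = character(0),
                    mediator_scale = c("continuous", "binary"),
                    n_boot = 1000, seed = 1L, conf_level = 0.95) {
  mediator_scale <- match.arg(mediator_scale)
  cols <- c(treatment, mediator, outcome, covariates)
  miss <- setdiff(cols, colnames(data))
  if (length(miss)) stop2("missing column(s): ", paste(miss, collapse = ", "))
  dat <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
              drop = FALSE]
  if (length(unique(dat[[mediator]])) < 2) stop2("mediator is constant")
  pt <- mediation_point(dat, treatment, mediator, outcome, covariates,
                        mediator_scale)
  boot <- with_seed(split_seed(seed, "mediate_boot"), {
    if (mediator_scale == "continuous") {
      # linear-linear point estimates reduce to products/sums of OLS
      # coefficients, so the bootstrap can run on prebuilt model matrices
      fm <- stats::as.formula(paste(
        "~", paste(c(treatment, covariates), collapse = " + ")))
      xm <- stats::model.matrix(fm, dat)
      mv <- dat[[mediator]]
      yv <- dat[[outcome]]
      # outcome design with the mediator in second place, matching the
      # aliasing convention of the point estimator
      xy <- cbind(xm[, 1, drop = FALSE], .m = mv,
                  xm[, -1, drop = FALSE])
      jt <- match(treatment, colnames(xm))
      jt_y <- jt + 1L
      t(vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(dat), replace = TRUE)
        a <- stats::.lm.fit(xm[idx, , drop = FALSE], mv[idx])$coefficients[jt]
        cy <- stats::.lm.fit(xy[idx, , drop = FALSE], yv[idx])$coefficients
        cy[is.na(cy)] <- 0
        if (is.na(a)) a <- 0
        acme <- a * cy[2L]
        ade <- cy[jt_y]
        te <- acme + ade
        c(acme = acme, ade = ade, total_effect = te,
          prop_mediated = if (abs(te) > .Machine$double.eps) acme / te
          else NA_real_, firth_fallback = 0)
      }, numeric(5)))
    } else {
      t(vapply(seq_len(n_boot), function(b) {
        idx <- sample.int(nrow(dat), replace = TRUE)
        tryCatch(mediation_point(dat[idx, , drop = FALSE], treatment,
                                 mediator, outcome, covariates,
                                 mediator_scale),
                 error = function(e) rep(NA_real_, 5))
      }, numeric(5)))
    }
  })
  alpha <- (1 - conf_level) / 2
  ci <- function(v) stats::quantile(v, c(alpha, 1 - alpha), na.rm = TRUE,
                                    names = FALSE)
  pval <- function(v) {
    v <- v[!is.na(v)]
    max(2 * min(mean(v <= 0), mean(v >= 0)), 1 / length(v))
  }
  structure(list(
    treatment = treatment, mediator = mediator, outcome = outcome,
    covariates = covariates, mediator_scale = mediator_scale,
    acme = unname(pt["acme"]), ade = unname(pt["ade"]),
    total_effect = unname(pt["total_effect"]),
    prop_mediated = unname(pt["prop_mediated"]),
    acme_ci = ci(boot[, "acme"]), ade_ci = ci(boot[, "ade"]),
    te_ci = ci(boot[, "total_effect"]),
    acme_p = pval(boot[, "acme"]), te_p = pval(boot[, "total_effect"]),
    firth_fallback = pt["firth_fallback"] > 0,
    n_boot = n_boot, data = dat), class = "mediation_triple")
}

#' @export
print.mediation_triple <- function(x, ...) {
  cat(sprintf(
    "mediation: %s -> %s -> %s\n  ACME %.4f [%.4f, %.4f] p=%.4g\n  ADE %.4f  TE %.4f p=%.4g  prop. mediated %.3f\n",
    x$treatment, x$mediator, x$outcome, x$acme, x$acme_ci[1], x$acme_ci[2],
    x$acme_p, x$ade, x$total_effect, x$te_p, x$prop_mediated))
  invisible(x)
}

#' Sensitivity analysis for unmeasured mediator-outcome confounding
#'
#' For a linear-linear triple, recomputes the ACME under a hypothesized
#' correlation rho between the mediator-model and outcome-model errors
#' across a grid, and reports the grid-interpolated rho at which the ACME
#' crosses zero. If the ACME never crosses zero on the grid, the boundary
#' value is returned with a flag.
#'
#' @param triple a [mediate()] result with a continuous mediator.
#' @param rho_grid grid of rho values (default seq(-0.8, 0.8, 0.1)).
#' @return list: `sensitivity_rho`, `acme_by_rho` (data.frame), `boundary`
#'   flag.
#' @export
mediation_sensitivity <- function(triple, rho_grid = seq(-0.8, 0.8, 0.1)) {
  stopifnot(inherits(triple, "mediation_triple"))
  if (triple$mediator_scale != "continuous") {
    stop2("sensitivity analysis requires a linear mediator model")
  }
  dat <- triple$data
  rhs <- paste(c(triple$treatment, triple$covariates), collapse = " + ")
  rm_ <- stats::resid(stats::lm(
    stats::as.formula(paste(triple$mediator, "~", rhs)), data = dat))
  ry_ <- stats::resid(stats::lm(
    stats::as.formula(paste(triple$outcome, "~", rhs)), data = dat))
  a <- stats::coef(stats::lm(stats::as.formula(
    paste(triple$mediator, "~", rhs)), data = dat))[[triple$treatment]]
  s1 <- stats::sd(rm_); s2 <- stats::sd(ry_)
  r12 <- stats::cor(rm_, ry_)
  acme_rho <- a * (s2 / s1) *
    (r12 - rho_grid * sqrt((1 - r12^2) / (1 - rho_grid^2)))
  df <- data.frame(rho = rho_grid, acme = acme_rho)
  s <- sign(acme_rho)
  cross <- which(s[-1] * s[-length(s)] <= 0 &
                   !(s[-1] == 0 & s[-length(s)] == 0))
  if (abs(triple$acme) < 1e-12) {
    return(list(sensitivity_rho = 0, acme_by_rho = df, boundary = FALSE))
  }
  if (length(cross) == 0) {
    rho_star <- rho_grid[if (sign(triple$acme) > 0) length(rho_grid) else 1]
    return(list(sensitivity_rho = rho_star, acme_by_rho = df,
                boundary = TRUE))
  }
  i <- cross[1]
  # linear interpolation of the zero crossing between grid points
  rho_star <- rho_grid[i] + (0 - acme_rho[i]) *
    (rho_grid[i + 1] - rho_grid[i]) / (acme_rho[i + 1] - acme_rho[i])
  list(sensitivity_rho = rho_star, acme_by_rho = df, boundary = FALSE)
}

#' Screen (treatment, mediator, taxon) triples
#'
#' Runs [mediate()] for every mediator-taxon pair, applies BH-FDR
#' separately to the ACME and total-effect p-value families across all
#' triples, computes each linear-linear triple's sensitivity rho, and
#' returns the triples passing ACME FDR, total-effect FDR and
#' sensitivity-rho thresholds.
#'
#' @param data data.frame holding treatment, mediators and covariates.
#' @param treatment treatment column name.
#' @param mediators candidate mediator columns (continuous/ordinal).
#' @param outcomes matrix of per-taxon outcomes (samples x taxa, e.g. log2
#'   relative abundances) aligned with `data` rows.
#' @param covariates adjustment columns.
#' @param acme_fdr_max,te_fdr_max,rho_min screen thresholds (defaults 0.05,
#'   0.05, 0).
#' @param n_boot,seed bootstrap controls.
#' @return data.frame of all triples with estimates, FDRs, sensitivity rho
#'   and a `selected` flag.
#' @export
screen_mediations <- function(data, treatment, mediators, outcomes,
                              covariates = character(0),
                              acme_fdr_max = 0.05, te_fdr_max = 0.05,
                              rho_min = 0, n_boot = 1000, seed = 1L) {
  if (length(mediators) == 0 || ncol(outcomes) == 0) {
    stop2("empty candidate mediator or taxon list")
  }
  rows <- list()
  for (m in mediators) {
    for (tx in colnames(outcomes)) {
      dat <- data
      dat$.taxon_outcome <- outcomes[, tx]
      tr <- mediate(dat, treatment, m, ".taxon_outcome", covariates,
                    mediator_scale = "continuous", n_boot = n_boot,
                    seed = split_seed(seed, paste(m, tx)))
      sens <- mediation_sensitivity(tr)
      rows[[paste(m, tx)]] <- data.frame(
        treatment = treatment, mediator = m, taxon = tx,
        acme = tr$acme, ade = tr$ade, total_effect = tr$total_effect,
        prop_mediated = tr$prop_mediated, acme_p = tr$acme_p,
        te_p = tr$te_p, sensitivity_rho = sens$sensitivity_rho,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$acme_fdr <- bh(out$acme_p)
  out$te_fdr <- bh(out$te_p)
  out$selected <- out$acme_fdr < acme_fdr_max & out$te_fdr < te_fdr_max &
    out$sensitivity_rho > rho_min
  out
}
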