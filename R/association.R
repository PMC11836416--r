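discretize_quartiles <- function(x) {
  br <- unique(stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), na.rm = TRUE))
  if (length(br) < 2) return(factor(rep("q1", length(x))))
  cut(x, breaks = br, include.lowest = TRUE)
}

#' Pairwise Cramer's V between metadata variables
#'
#' Continuous variables are discretized into quartile bins; each pair then
#' yields V = sqrt(chi-squared / (n (min(r, c) - 1))) from the contingency
#' table, with BH-adjusted chi-squared p-values. Pairs with V above
#' `v_threshold` and adjusted p below `p_threshold` are flagged collinear.
#'
#' @param metadata data.frame of variables (a `sample_id` column is
#'   ignored).
#' @param variables optional subset of columns.
#' @param v_threshold collinearity V cut (default 0.3).
#' @param p_threshold adjusted-p cut (default 0.05).
#' @return list with `v` (symmetric matrix), `p_adjusted` (symmetric
#'   matrix), `collinear` (logical matrix), `undefined` (variables with a
#'   single observed level).
#' @export
cramers_v_matrix <- function(metadata, variables = NULL, v_threshold = 0.3,
                             p_threshold = 0.05) {
  if (is.null(variables)) {
    variables <- setdiff(colnames(metadata), "sample_id")
  }
  if (length(variables) < 2) stop2("need at least 2 variables")
  binned <- lapply(metadata[variables], function(x) {
    if (is.numeric(x) && length(unique(x)) > 8) discretize_quartiles(x)
    else factor(x)
  })
  undefined <- names(binned)[vapply(binned, nlevels, 1L) < 2]
  k <- length(variables)
  v <- p <- matrix(NA_real_, k, k, dimnames = list(variables, variables))
  diag(v) <- 1; diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in seq(i + 1, k)) {
      a <- binned[[i]]; b <- binned[[j]]
      if (nlevels(droplevels(a)) < 2 || nlevels(droplevels(b)) < 2) next
      tab <- table(droplevels(a), droplevels(b))
      chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      n <- sum(tab)
      vij <- sqrt(unname(chi$statistic) / (n * (min(dim(tab)) - 1)))
      v[i, j] <- v[j, i] <- vij
      p[i, j] <- p[j, i] <- chi$p.value
    }
  }
  padj <- p
  ut <- upper.tri(p)
  padj[ut] <- bh(p[ut])
  padj[lower.tri(padj)] <- t(padj)[lower.tri(padj)]
  collinear <- !is.na(v) & v > v_threshold & !is.na(padj) &
    padj < p_threshold
  diag(collinear) <- FALSE
  list(v = v, p_adjusted = padj, collinear = collinear,
       undefined = undefined)
}

#' Pick one representative variable per phenotype category
#'
#' Greedy, deterministic selection: categories are visited in alphabetical
#' order; within each, candidates are ranked by decreasing effect size (ties
#' broken by variable name) and the best candidate not collinear with any
#' already-picked variable from another category is chosen.
#'
#' @param effect_table data.frame with columns `variable`, `category`,
#'   `effect` (e.g. absolute Spearman rho with Shannon diversity).
#' @param collinear logical matrix from [cramers_v_matrix()].
#' @return data.frame of picks (`category`, `variable`, `effect`); omitted
#'   categories are reported in the `omitted` attribute.
#' @export
select_representatives <- function(effect_table, collinear) {
  stopifnot(all(c("variable", "category", "effect") %in%
                  colnames(effect_table)))
  cats <- sort(unique(effect_table$category))
  picked <- character(0)
  omitted <- character(0)
  rows <- list()
  for (cat in cats) {
    cand <- effect_table[effect_table$category == cat, , drop = FALSE]
    cand <- cand[order(-cand$effect, cand$variable), , drop = FALSE]
    chosen <- NULL
    for (i in seq_len(nrow(cand))) {
      v <- cand$variable[i]
      clash <- v %in% rownames(collinear) && length(picked) &&
        any(collinear[v, intersect(picked, colnames(collinear))])
      if (!clash) { chosen <- cand[i, , drop = FALSE]; break }
    }
    if (is.null(chosen)) {
      omitted <- c(omitted, cat)
    } else {
      picked <- c(picked, chosen$variable)
      rows[[cat]] <- chosen[, c("category", "variable", "effect")]
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "omitted") <- omitted
  out
}

#' Log2 total-sum-scaled abundances
#'
#' The outcome transform shared by the per-taxon association and mediation
#' stages: log2(relative abundance + pseudocount), with a per-taxon
#' pseudocount of half the taxon's minimum nonzero relative abundance.
#'
#' @param rel relative-abundance matrix (samples x taxa), see
#'   [to_relative()].
#' @return matrix of the same shape.
#' @export
log2_tss <- function(rel) {
  apply(rel, 2, function(col) {
    nz <- col[col > 0]
    pc <- if (length(nz)) min(nz) / 2 else 0.5
    log2(col + pc)
  })
}

#' Covariate-adjusted per-taxon association (MaAsLin-style)
#'
#' For each taxon passing prevalence/abundance gates, fits an
#' ordinary-least-squares model of log2(relative abundance + pseudocount)
#' on the tested variable plus covariates. Nominal variables are contrasted
#' against their declared (or most frequent) reference level; BH-FDR is
#' applied across all (taxon, level) tests of the variable.
#'
#' @param table a [feature_table()].
#' @param metadata data.frame indexed by sample id (with optional
#'   `variable_types` attribute declaring scales and reference levels).
#' @param variable name of the tested variable.
#' @param covariates covariate names (should come from other phenotype
#'   categories than the tested variable).
#' @param min_prevalence taxon presence gate (default 0.1).
#' @param min_abundance mean relative-abundance gate (default 1e-4).
#' @return data.frame: `taxon`, `variable`, `level`, `coefficient`,
#'   `std_error`, `p_value`, `fdr`, `direction`.
#' @export
taxon_association <- function(table, metadata, variable,
                              covariates = character(0),
                              min_prevalence = 0.1, min_abundance = 1e-4) {
  stopifnot(inherits(table, "feature_table"))
  md <- metadata[sample_ids(table), , drop = FALSE]
  rel <- to_relative(table)
  keep <- colMeans(rel > 0) >= min_prevalence &
    colMeans(rel) >= min_abundance
  if (!any(keep)) stop2("no taxa pass the prevalence/abundance gates")
  y_all <- log2_tss(rel[, keep, drop = FALSE])

  types <- attr(metadata, "variable_types")
  x <- md[[variable]]
  if (is.null(x)) stop2("variable not in metadata: ", variable)
  is_nominal <- is.character(x) || is.factor(x)
  if (is_nominal) {
    x <- factor(x)
    ref <- NULL
    if (!is.null(types) && variable %in% types$variable) {
      ref <- types$reference[types$variable == variable]
    }
    if (is.null(ref) || is.na(ref) || !(ref %in% levels(x))) {
      ref <- names(sort(base::table(x), decreasing = TRUE))[1]
    }
    x <- stats::relevel(x, ref = ref)
  }
  dat0 <- data.frame(.x = x, md[, setdiff(covariates, variable),
                                drop = FALSE])
  dat0[] <- lapply(dat0, function(v) if (is.character(v)) factor(v) else v)

  rows <- list()
  for (tx in colnames(y_all)) {
    dat <- dat0
    dat$.y <- y_all[, tx]
    fit <- stats::lm(.y ~ ., data = dat)
    sm <- summary(fit)$coefficients
    xr <- rownames(sm)[startsWith(rownames(sm), ".x")]
    for (term in xr) {
      lvl <- if (is_nominal) sub("^\\.x", "", term) else "linear"
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, variable = variable, level = lvl,
        coefficient = sm[term, "Estimate"],
        std_error = sm[term, "Std. Error"],
        p_value = sm[term, "Pr(>|t|)"], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- bh(out$p_value)
  out$direction <- sign(out$coefficient)
  out$significant <- out$fdr < 0.05
  out
}

#' Rank taxa by association coefficient
#'
#' Taxa ordered by the absolute coefficient of their most significant
#' contrast; ties broken lexicographically by taxon id.
#'
#' @param results a [taxon_association()] result (one variable).
#' @param n number of taxa to return (default 16).
#' @return character vector of taxon ids, strongest first; if fewer than `n`
#'   are available a `short` attribute is set.
#' @export
rank_taxa_by_coefficient <- function(results, n = 16) {
  stopifnot(length(unique(results$variable)) <= 1)
  best <- do.call(rbind, lapply(split(results, results$taxon), function(d) {
    d[which.min(d$p_value), , drop = FALSE]
  }))
  best <- best[order(-abs(best$coefficient), best$taxon), , drop = FALSE]
  out <- utils::head(best$taxon, n)
  if (length(out) < n) attr(out, "short") <- TRUE
  out
}

#' Union of taxa significantly associated with any screened variable
#'
#' The key-taxon panel: taxa showing at least one FDR-significant
#' association across the screened variables.
#'
#' @param association_results list of [taxon_association()] results.
#' @param fdr_max significance cut (default 0.05).
#' @return sorted character vector of taxon ids.
#' @export
key_taxa <- function(association_results, fdr_max = 0.05) {
  all <- do.call(rbind, association_results)
  sort(unique(all$taxon[!is.na(all$fdr) & all$fdr < fdr_max]))
}
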