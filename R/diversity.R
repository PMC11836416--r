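#' Alpha diversity indices
#'
#' Shannon entropy (natural log), Gini-Simpson index, observed richness, and
#' the classic Chao1 estimator S + F1^2 / (2 F2), replaced by the
#' bias-corrected S + F1 (F1 - 1) / (2 (F2 + 1)) when no doubletons are
#' present.
#'
#' @param table a [feature_table()]; a rarefied table is recommended so
#'   richness estimates are comparable across samples.
#' @return data.frame with one row per sample: `shannon`, `simpson`,
#'   `chao1`, `observed_richness`.
#' @export
alpha_diversity <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$counts
  if (any(rowSums(x) == 0)) {
    stop2("zero-total sample(s): ",
          paste(sample_ids(table)[rowSums(x) == 0], collapse = ", "))
  }
  shannon <- vegan::diversity(x, index = "shannon")
  simpson <- vegan::diversity(x, index = "simpson")
  s_obs <- rowSums(x > 0)
  f1 <- rowSums(x == 1)
  f2 <- rowSums(x == 2)
  chao1 <- ifelse(f2 > 0, s_obs + f1^2 / (2 * f2),
                  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1)))
  data.frame(sample_id = sample_ids(table),
             shannon = unname(shannon), simpson = unname(simpson),
             chao1 = unname(chao1), observed_richness = unname(s_obs),
             stringsAsFactors = FALSE)
}

#' Beta-diversity distance matrix
#'
#' Bray-Curtis on counts, Jaccard on presence/absence, and weighted
#' (normalized) or unweighted UniFrac given a phylogenetic tree covering all
#' taxa. Unrooted trees are midpoint-rooted for determinism.
#'
#' @param table a [feature_table()].
#' @param metric one of `"bray_curtis"`, `"jaccard"`, `"unifrac_weighted"`,
#'   `"unifrac_unweighted"`.
#' @param tree ape `phylo`, required for the UniFrac metrics.
#' @return a `dist` object with a `metric_name` attribute.
#' @export
beta_diversity <- function(table, metric = c("bray_curtis", "jaccard",
                                             "unifrac_weighted",
                                             "unifrac_unweighted"),
                           tree = NULL) {
  stopifnot(inherits(table, "feature_table"))
  metric <- match.arg(metric)
  x <- table$counts
  d <- switch(metric,
    bray_curtis = vegan::vegdist(x, method = "bray"),
    jaccard = vegan::vegdist(x, method = "jaccard", binary = TRUE),
    {
      if (is.null(tree)) stop2("UniFrac metrics require a tree")
      miss <- setdiff(taxon_ids(table), tree$tip.label)
      if (length(miss)) stop2("taxa missing from tree: ",
                              paste(utils::head(miss, 5), collapse = ", "))
      if (!requireNamespace("phyloseq", quietly = TRUE)) {
        stop2("package 'phyloseq' is required for UniFrac")
      }
      tree <- ape::drop.tip(tree, setdiff(tree$tip.label, taxon_ids(table)))
      if (!ape::is.rooted(tree)) tree <- phangorn::midpoint(tree)
      ps <- phyloseq::phyloseq(
        phyloseq::otu_table(x, taxa_are_rows = FALSE),
        phyloseq::phy_tree(tree))
      phyloseq::UniFrac(ps, weighted = metric == "unifrac_weighted",
                        normalized = TRUE)
    })
  attr(d, "metric_name") <- metric
  d
}

#' Principal coordinates analysis
#'
#' Gower double-centering of the squared distances followed by
#' eigendecomposition. Axes are ordered by eigenvalue; negative eigenvalues
#' are dropped and flagged.
#'
#' @param dm a `dist` object or square symmetric matrix.
#' @param n_axes number of coordinate axes requested.
#' @return list with `coordinates` (samples x axes), `eigenvalues` (all,
#'   decreasing), `negative_eigenvalues` flag, and `axes_returned`.
#' @export
pcoa <- function(dm, n_axes = 2) {
  m <- as.matrix(dm)
  n <- nrow(m)
  a <- -0.5 * m^2
  ctr <- diag(n) - matrix(1 / n, n, n)
  g <- ctr %*% a %*% ctr
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  pos <- e$values > max(e$values, 0) * 1e-10
  n_pos <- sum(pos)
  k <- min(n_axes, n_pos)
  coords <- if (k > 0) {
    sweep(e$vectors[, seq_len(k), drop = FALSE], 2,
          sqrt(e$values[seq_len(k)]), `*`)
  } else {
    matrix(0, n, 0)
  }
  rownames(coords) <- rownames(m)
  list(coordinates = coords, eigenvalues = e$values,
       negative_eigenvalues = any(e$values < -max(abs(e$values)) * 1e-8),
       axes_returned = k, truncated = k < n_axes)
}

#' Associate alpha diversity with metadata variables
#'
#' For every variable: Spearman rank correlation (average-rank ties) of
#' Shannon diversity with continuous/ordinal/binary variables, and an
#' ordinary-least-squares model `shannon ~ variable + covariates` for all
#' variables (nominal variables dummy-coded). BH-FDR is applied across
#' variables separately for the two families; FDR < 0.05 flags significance.
#'
#' @param alpha result of [alpha_diversity()].
#' @param metadata data.frame with a `variable_types` attribute (see
#'   [generate_cohort()]) or plain columns.
#' @param variables variables to test (default: all typed variables).
#' @param covariates variable names adjusted for in the linear models.
#' @return data.frame per variable: `spearman_rho`, `spearman_p`,
#'   `spearman_fdr`, `lm_coef`, `lm_p`, `lm_fdr`, `estimable`.
#' @export
alpha_association <- function(alpha, metadata, variables = NULL,
                              covariates = character(0)) {
  types <- attr(metadata, "variable_types")
  if (is.null(variables)) {
    variables <- if (!is.null(types)) types$variable else
      setdiff(colnames(metadata), "sample_id")
  }
  md <- metadata[alpha$sample_id, , drop = FALSE]
  y <- alpha$shannon
  scale_of <- function(v) {
    if (!is.null(types) && v %in% types$variable) {
      types$scale[types$variable == v]
    } else if (is.numeric(md[[v]])) "continuous" else "nominal"
  }
  rows <- lapply(variables, function(v) {
    x <- md[[v]]
    if (is.null(x)) stop2("variable not in metadata: ", v)
    est <- length(unique(x[!is.na(x)])) > 1
    rho <- p_s <- NA_real_
    if (est && scale_of(v) != "nominal" && is.numeric(x)) {
      ct <- suppressWarnings(
        stats::cor.test(x, y, method = "spearman", exact = FALSE))
      rho <- unname(ct$estimate); p_s <- ct$p.value
    }
    coef_lm <- p_lm <- NA_real_
    if (est) {
      covs <- setdiff(covariates, v)
      dat <- data.frame(.y = y, .x = if (scale_of(v) == "nominal")
        factor(x) else x, md[, covs, drop = FALSE])
      fit <- stats::lm(.y ~ ., data = dat)
      sm <- summary(fit)$coefficients
      xr <- grep("^\\.x", rownames(sm))
      if (length(xr)) {
        i <- xr[which.max(abs(sm[xr, "t value"]))]
        coef_lm <- sm[i, "Estimate"]; p_lm <- sm[i, "Pr(>|t|)"]
      }
    }
    data.frame(variable = v, spearman_rho = rho, spearman_p = p_s,
               lm_coef = coef_lm, lm_p = p_lm, estimable = est,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$spearman_fdr <- bh(out$spearman_p)
  out$lm_fdr <- bh(out$lm_p)
  out$significant <- !is.na(out$lm_fdr) & out$lm_fdr < 0.05
  out
}

#' Permutation-based beta-diversity test
#'
#' One variable against a distance matrix by one of ADONIS (PERMANOVA
#' pseudo-F and R-squared), ANOSIM (rank statistic R), MRPP (chance-corrected
#' A) or db-RDA (pseudo-F of the constrained ordination); p-values from
#' `n_perm` permutations as (exceedances + 1) / (n_perm + 1).
#'
#' @param dm `dist` object (see [beta_diversity()]).
#' @param metadata data.frame indexed by the samples of `dm`.
#' @param variable column name to test; ANOSIM/MRPP require a categorical
#'   variable with every level represented at least twice.
#' @param method one of `"ADONIS"`, `"ANOSIM"`, `"MRPP"`, `"dbRDA"`.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed for the permutation stream.
#' @return one-row data.frame: `variable`, `method`, `metric`, `statistic`,
#'   `p_value`, `n_permutations`.
#' @export
permutation_beta_test <- function(dm, metadata, variable,
                                  method = c("ADONIS", "ANOSIM", "MRPP",
                                             "dbRDA"),
                                  n_perm = 1000, seed = 1L) {
  method <- match.arg(method)
  ids <- attr(dm, "Labels") %||% rownames(as.matrix(dm))
  md <- metadata[ids, , drop = FALSE]
  x <- md[[variable]]
  if (is.null(x)) stop2("variable not in metadata: ", variable)
  if (is.character(x)) x <- factor(x)
  if (is.factor(x) && any(table(x) < 2) && method %in% c("ANOSIM", "MRPP")) {
    stop2("ANOSIM/MRPP require every level to have at least 2 samples")
  }
  if (!is.factor(x) && method %in% c("ANOSIM", "MRPP")) {
    stop2(method, " requires a categorical variable")
  }
  res <- with_seed(split_seed(seed, paste0("betatest_", method)), {
    switch(method,
      ADONIS = {
        fit <- vegan::adonis2(dm ~ x, data = data.frame(x = x),
                              permutations = n_perm)
        c(stat = fit$R2[1], p = fit$`Pr(>F)`[1])
      },
      ANOSIM = {
        fit <- vegan::anosim(dm, x, permutations = n_perm)
        c(stat = fit$statistic, p = fit$signif)
      },
      MRPP = {
        fit <- vegan::mrpp(dm, x, permutations = n_perm)
        c(stat = fit$A, p = fit$Pvalue)
      },
      dbRDA = {
        dat <- data.frame(x = x)
        fit <- vegan::dbrda(dm ~ x, data = dat)
        an <- stats::anova(fit, permutations = n_perm)
        c(stat = an$F[1], p = an$`Pr(>F)`[1])
      })
  })
  data.frame(variable = variable, method = method,
             metric = attr(dm, "metric_name") %||% NA_character_,
             statistic = unname(res["stat"]), p_value = unname(res["p"]),
             n_permutations = n_perm, stringsAsFactors = FALSE)
}

#' Per-category variance partitioning by sequential PERMANOVA
#'
#' Runs a sequential (terms) ADONIS of the distance matrix on each
#' category's variable set and returns the summed model R-squared per
#' category. Aliased terms are dropped with a flag.
#'
#' @param dm `dist` object.
#' @param metadata data.frame indexed by the samples of `dm`.
#' @param variables_by_category named list: category -> variable names.
#' @param n_perm permutations for the embedded tests.
#' @param seed integer seed.
#' @return data.frame: `category`, `r_squared`, `n_variables`, `aliased`.
#' @export
multivariable_variance_partition <- function(dm, metadata,
                                             variables_by_category,
                                             n_perm = 199, seed = 1L) {
  ids <- attr(dm, "Labels") %||% rownames(as.matrix(dm))
  md <- metadata[ids, , drop = FALSE]
  rows <- lapply(names(variables_by_category), function(cat) {
    vars <- variables_by_category[[cat]]
    dat <- md[, vars, drop = FALSE]
    dat[] <- lapply(dat, function(v) if (is.character(v)) factor(v) else v)
    aliased <- FALSE
    # drop aliased (constant or duplicated) terms
    keep <- vapply(vars, function(v) length(unique(dat[[v]])) > 1, logical(1))
    if (!all(keep)) aliased <- TRUE
    vars <- vars[keep]
    if (!length(vars)) {
      return(data.frame(category = cat, r_squared = NA_real_,
                        n_variables = 0L, aliased = TRUE))
    }
    fml <- stats::as.formula(paste("dm ~", paste(vars, collapse = " + ")))
    fit <- with_seed(split_seed(seed, paste0("varpart_", cat)), {
      vegan::adonis2(fml, data = dat, permutations = n_perm, by = "terms")
    })
    terms_r2 <- fit$R2[seq_len(nrow(fit) - 2)]
    if (anyNA(terms_r2)) aliased <- TRUE
    data.frame(category = cat, r_squared = sum(terms_r2, na.rm = TRUE),
               n_variables = length(vars), aliased = aliased,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Screen variables supported across beta-diversity tests
#'
#' A variable is selected when it is significant (FDR below `fdr_max`,
#' adjusted within each method-metric family) in at least `min_methods`
#' of the four methods -- each method's call requiring significance in at
#' least `min_metrics` of the distance metrics -- and its ADONIS R-squared
#' exceeds `min_r2`.
#'
#' @param results data.frame of stacked [permutation_beta_test()] rows over
#'   variables, methods and metrics.
#' @param fdr_max FDR threshold (default 0.1).
#' @param min_methods minimum supporting methods (default 3).
#' @param min_metrics minimum supporting metrics per method (default 3).
#' @param min_r2 minimum ADONIS R-squared (default 0.001).
#' @return character vector of selected variable names.
#' @export
screen_beta_variables <- function(results, fdr_max = 0.1, min_methods = 3,
                                  min_metrics = 3, min_r2 = 0.001) {
  results$fdr <- stats::ave(results$p_value,
                            interaction(results$method, results$metric),
                            FUN = bh)
  sig <- results[!is.na(results$fdr) & results$fdr < fdr_max, , drop = FALSE]
  sel <- vapply(unique(results$variable), function(v) {
    sv <- sig[sig$variable == v, , drop = FALSE]
    n_by_method <- table(sv$method[!duplicated(paste(sv$method, sv$metric))])
    supported <- sum(n_by_method >= min_metrics)
    r2 <- results$statistic[results$variable == v &
                              results$method == "ADONIS"]
    supported >= min_methods && length(r2) > 0 &&
      max(r2, na.rm = TRUE) > min_r2
  }, logical(1))
  names(sel)[sel]
}
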