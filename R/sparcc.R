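sparcc_once <- function(logf, n_excl_rounds, excl_threshold) {
  d <- ncol(logf)
  v <- stats::cov(logf)
  tmat <- outer(diag(v), diag(v), `+`) - 2 * v  # var(log(x_i/x_j))
  m <- matrix(1, d, d)
  diag(m) <- d - 1
  t_row <- rowSums(tmat)
  excluded <- matrix(FALSE, d, d)
  basis_cor <- function() {
    w <- solve(m, t_row)
    w <- pmax(w, 1e-12)
    r <- (outer(w, w, `+`) - tmat) / (2 * sqrt(outer(w, w)))
    diag(r) <- 1
    pmax(pmin(r, 1), -1)
  }
  rho <- basis_cor()
  for (iter in seq_len(n_excl_rounds)) {
    cand <- abs(rho)
    cand[excluded | lower.tri(cand, diag = TRUE)] <- 0
    mx <- which.max(cand)
    if (cand[mx] <= excl_threshold) break
    i <- (mx - 1) %% d + 1
    j <- (mx - 1) %/% d + 1
    excluded[i, j] <- excluded[j, i] <- TRUE
    m[i, i] <- m[i, i] - 1
    m[j, j] <- m[j, j] - 1
    m[i, j] <- m[j, i] <- 0
    t_row[i] <- t_row[i] - tmat[i, j]
    t_row[j] <- t_row[j] - tmat[i, j]
    rho <- basis_cor()
  }
  rho
}

#' SparCC compositional correlation estimation
#'
#' Estimates correlations among basis (absolute) abundances from
#' compositional count data: per Dirichlet resampling draw (uniform prior,
#' counts + 1), the log-ratio variance matrix t_ij = var(log(x_i/x_j)) is
#' formed and the basis-variance linear system solved, iteratively excluding
#' the strongest correlated pair above `excl_threshold` for up to
#' `n_excl_rounds` rounds; the element-wise median over `n_inner` draws is
#' returned, clipped to [-1, 1].
#'
#' @param table a [feature_table()] with at least 4 taxa.
#' @param n_excl_rounds maximum strong-pair exclusion rounds (default 10).
#' @param excl_threshold absolute-correlation exclusion threshold
#'   (default 0.1).
#' @param n_inner Dirichlet resampling draws (default 50).
#' @param seed integer seed.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
sparcc <- function(table, n_excl_rounds = 10, excl_threshold = 0.1,
                   n_inner = 50, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  x <- table$counts
  if (ncol(x) < 4) stop2("SparCC needs at least 4 taxa")
  if (any(colSums(x) == 0)) stop2("taxa with all-zero counts present")
  d <- ncol(x)
  draws <- with_seed(split_seed(seed, "sparcc"), {
    lapply(seq_len(n_inner), function(b) {
      g <- matrix(stats::rgamma(length(x), shape = x + 1, rate = 1),
                  nrow(x), d)
      sparcc_once(log(g / rowSums(g)), n_excl_rounds, excl_threshold)
    })
  })
  rho <- apply(simplify2array(draws), c(1, 2), stats::median)
  dimnames(rho) <- list(colnames(x), colnames(x))
  diag(rho) <- 1
  pmax(pmin(rho, 1), -1)
}

#' Permutation p-values for SparCC correlations
#'
#' Null tables are built by independently permuting each taxon's counts
#' across samples; the two-sided pseudo p-value is
#' (# of null |rho| >= observed |rho| + 1) / (n_boot + 1), element-wise.
#'
#' @param table the [feature_table()] used for [sparcc()].
#' @param correlation observed SparCC correlation matrix.
#' @param n_boot number of null tables (default 1000).
#' @param n_inner Dirichlet draws per null SparCC fit (default 10; the null
#'   statistic needs less smoothing than the point estimate).
#' @param seed integer seed.
#' @inheritParams sparcc
#' @return symmetric p-value matrix with 1 on the diagonal.
#' @export
sparcc_pvalues <- function(table, correlation, n_boot = 1000,
                           n_excl_rounds = 10, excl_threshold = 0.1,
                           n_inner = 10, seed = 1L) {
  stopifnot(inherits(table, "feature_table"), n_boot >= 1)
  x <- table$counts
  obs <- abs(correlation)
  exceed <- matrix(0, ncol(x), ncol(x))
  with_seed(split_seed(seed, "sparcc_boot"), {
    for (b in seq_len(n_boot)) {
      xp <- apply(x, 2, sample)
      rownames(xp) <- rownames(x)
      rho_null <- sparcc(feature_table(xp), n_excl_rounds, excl_threshold,
                         n_inner, seed = sample.int(2^31 - 2, 1))
      exceed <- exceed + (abs(rho_null) >= obs)
    }
  })
  p <- (exceed + 1) / (n_boot + 1)
  diag(p) <- 1
  dimnames(p) <- dimnames(correlation)
  p
}

#' Bundle SparCC estimates and p-values
#'
#' @param correlation SparCC correlation matrix.
#' @param p_value matching p-value matrix.
#' @param params list of estimation parameters (recorded verbatim).
#' @return object of class `sparcc_result`.
#' @export
sparcc_result <- function(correlation, p_value, params = list()) {
  stopifnot(all(dim(correlation) == dim(p_value)))
  structure(list(taxa = colnames(correlation), correlation = correlation,
                 p_value = p_value, params = params),
            class = "sparcc_result")
}
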