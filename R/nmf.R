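nmf_mu <- function(x, k, seed, max_iter = 2000, tol = 1e-6) {
  n <- nrow(x); m <- ncol(x)
  eps <- .Machine$double.eps
  set.seed(seed)
  w <- matrix(stats::runif(n * k, 0.1, 1), n, k)
  h <- matrix(stats::runif(k * m, 0.1, 1), k, m)
  obj <- numeric(0)
  prev <- Inf
  for (it in seq_len(max_iter)) {
    h <- h * (crossprod(w, x) / (crossprod(w) %*% h + eps))
    w <- w * (x %*% t(h)) / (w %*% tcrossprod(h) + eps)
    if (it %% 10 == 0 || it == max_iter) {
      cur <- sum((x - w %*% h)^2)
      obj <- c(obj, cur)
      if (is.finite(prev) && prev > 0 &&
          (prev - cur) / max(prev, eps) < tol) break
      prev <- cur
    }
  }
  list(w = w, h = h, objective = sum((x - w %*% h)^2),
       objective_trace = obj)
}

#' Non-negative matrix factorization (Frobenius, multiplicative updates)
#'
#' Factorizes a non-negative samples-by-taxa matrix as X ~ W H with W
#' (samples x k, "coefficients") and H (k x taxa, "basis") from random
#' non-negative initializations, keeping the best of `n_restarts` runs. The
#' Frobenius objective is non-increasing across multiplicative updates;
#' convergence is declared when the relative objective change drops below
#' 1e-6 (or after 2000 iterations).
#'
#' @param x non-negative matrix (samples x taxa).
#' @param k factorization rank (>= 2).
#' @param seed integer seed; restart r uses a seed split from it.
#' @param n_restarts random restarts (default 30).
#' @param max_iter iteration cap per run.
#' @return list: `basis` (k x taxa), `coefficients` (samples x k),
#'   `objective`, `objective_trace` (recorded every 10 iterations).
#' @export
nmf_fit <- function(x, k, seed = 1L, n_restarts = 30, max_iter = 2000) {
  x <- as.matrix(x)
  if (any(x < 0)) stop2("NMF requires a non-negative matrix")
  if (k < 2 || k > min(dim(x))) stop2("k must lie in [2, min(dim(x))]")
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- nmf_mu(x, k, seed = split_seed(seed, paste0("nmf_restart_", r)),
                  max_iter = max_iter)
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  basis <- best$h
  rownames(basis) <- paste0("type_", seq_len(k))
  colnames(basis) <- colnames(x)
  coefs <- best$w
  rownames(coefs) <- rownames(x)
  colnames(coefs) <- rownames(basis)
  list(basis = basis, coefficients = coefs, objective = best$objective,
       objective_trace = best$objective_trace)
}

# dominant type per sample: W columns weighted by the L1 mass of the
# corresponding basis rows, removing the W/H scale ambiguity
dominant_type <- function(w, h) {
  max.col(w * rep(rowSums(h), each = nrow(w)), ties.method = "first")
}

nmf_consensus <- function(x, k, seed, n_restarts, max_iter) {
  n <- nrow(x)
  cons <- matrix(0, n, n)
  best_obj <- Inf
  for (r in seq_len(n_restarts)) {
    fit <- nmf_mu(x, k, seed = split_seed(seed, paste0("cons", k, "_", r)),
                  max_iter = max_iter)
    cl <- dominant_type(fit$w, fit$h)
    cons <- cons + outer(cl, cl, `==`)
    best_obj <- min(best_obj, fit$objective)
  }
  list(consensus = cons / n_restarts, objective = best_obj)
}

cophenetic_cor <- function(cons) {
  d <- stats::as.dist(1 - cons)
  if (stats::sd(d) == 0) return(1)
  hc <- stats::hclust(d, method = "average")
  stats::cor(d, stats::cophenetic(hc))
}

#' Select the NMF rank by consensus cophenetic correlation
#'
#' For each rank in `k_min:k_max`, builds a consensus matrix over random
#' restarts (samples co-clustered by their dominant, basis-mass-weighted
#' coefficient) and computes its cophenetic correlation. The chosen rank is
#' the largest k before the first cophenetic drop exceeding
#' `drop_threshold`. When every rank in the range is consensus-stable (no
#' drop ever exceeds the threshold, as happens when well-separated
#' communities admit stable nested coarsenings), the cophenetic criterion
#' carries no information and the choice falls back to the
#' reconstruction-error criterion: the rank with the largest relative
#' Frobenius improvement over rank k - 1, i.e. the last rank that adds a
#' dominant structural component. If the correlations never reach
#' `min_cophenetic` the choice is flagged low-confidence.
#'
#' @param x non-negative matrix (samples x taxa).
#' @param k_min,k_max rank range (defaults 2 and 20).
#' @param seed integer seed.
#' @param n_restarts consensus runs per rank (default 20).
#' @param max_iter iteration cap per run (default 300; consensus runs need
#'   stability, not convergence to machine precision).
#' @param drop_threshold cophenetic drop declaring instability
#'   (default 0.05).
#' @param min_cophenetic confidence floor (default 0.9).
#' @return list: `k` (chosen), `diagnostics` (data.frame: k, cophenetic,
#'   objective, rel_improvement), `low_confidence` flag, `criterion` used.
#' @export
select_rank <- function(x, k_min = 2, k_max = 20, seed = 1L,
                        n_restarts = 20, max_iter = 300,
                        drop_threshold = 0.05, min_cophenetic = 0.9) {
  x <- as.matrix(x)
  k_max <- min(k_max, min(dim(x)))
  ks <- seq(k_min, k_max)
  runs <- lapply(ks, function(k) {
    nmf_consensus(x, k, seed, n_restarts, max_iter)
  })
  coph <- vapply(runs, function(r) cophenetic_cor(r$consensus), numeric(1))
  obj <- vapply(runs, function(r) r$objective, numeric(1))
  # objective one rank below the range anchors the first improvement ratio
  obj_prev <- nmf_mu(x, max(k_min - 1, 1),
                     seed = split_seed(seed, "cons_anchor"),
                     max_iter = max_iter)$objective
  imp <- (c(obj_prev, obj[-length(obj)]) - obj) /
    c(obj_prev, obj[-length(obj)])
  diagnostics <- data.frame(k = ks, cophenetic = coph, objective = obj,
                            rel_improvement = imp)
  if (length(ks) == 1L) {
    return(list(k = ks, diagnostics = diagnostics,
                low_confidence = coph[1] < min_cophenetic,
                criterion = "forced"))
  }
  drops <- coph[-length(coph)] - coph[-1]
  first_drop <- which(drops > drop_threshold)
  if (length(first_drop)) {
    k_chosen <- ks[first_drop[1]]
    criterion <- "cophenetic_drop"
  } else {
    k_chosen <- ks[which.max(imp)]
    criterion <- "objective_improvement"
  }
  list(k = k_chosen, diagnostics = diagnostics,
       low_confidence = max(coph) < min_cophenetic,
       criterion = criterion)
}
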