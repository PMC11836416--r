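# Small deterministic fixtures shared across the suite.

make_table <- function(counts, samples = NULL, taxa = NULL) {
  m <- as.matrix(counts)
  rownames(m) <- samples %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- taxa %||% paste0("t", seq_len(ncol(m)))
  feature_table(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_table <- function(n, d, seed, lambda = 30) {
  set.seed(seed)
  m <- matrix(rpois(n * d, lambda), n, d)
  m[1, ] <- m[1, ] + 1  # avoid empty rows
  make_table(m)
}

# counts whose basis abundances are lognormal with a planted correlation
# between the first two taxa
lognormal_counts <- function(n, d, rho12, seed, depth = 50000) {
  set.seed(seed)
  sigma <- diag(d)
  sigma[1, 2] <- sigma[2, 1] <- rho12
  lab <- matrix(rnorm(n * d), n, d) %*% chol(sigma) +
    matrix(rep(rnorm(d, 5, 1), each = n), n, d)
  fr <- exp(lab) / rowSums(exp(lab))
  m <- t(apply(fr, 1, function(p) rmultinom(1, depth, p)))
  make_table(m)
}

# brute-force PERMANOVA R^2 from the pairwise-distance identity
adonis_r2_bruteforce <- function(dm, groups) {
  d <- as.matrix(dm)
  n <- nrow(d)
  ss <- function(idx) {
    if (length(idx) < 2) return(0)
    sum(d[idx, idx][upper.tri(d[idx, idx])]^2) / length(idx)
  }
  ss_total <- sum(d[upper.tri(d)]^2) / n
  ss_within <- sum(vapply(split(seq_len(n), groups), ss, numeric(1)))
  (ss_total - ss_within) / ss_total
}
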