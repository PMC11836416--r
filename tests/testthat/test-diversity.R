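test_that("alpha indices match direct formula evaluation", {
  ft <- make_table(rbind(c(5, 5, 5, 5),   # 4 even taxa
                         c(7, 0, 0, 0),   # single taxon
                         c(2, 1, 1, 0)))  # mixed
  a <- alpha_diversity(ft)
  expect_equal(a$shannon[1], log(4), tolerance = 1e-12)
  expect_equal(a$simpson[1], 0.75, tolerance = 1e-12)
  expect_equal(a$shannon[2], 0)
  expect_equal(a$simpson[2], 0)
  expect_equal(a$observed_richness[2], 1)
  expect_equal(a$chao1[2], 1)
  expect_equal(a$shannon[3], -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)),
               tolerance = 1e-12)
})

test_that("Chao1 uses the classic form with the doubleton guard", {
  # F1 = 2, F2 = 1 -> S + F1^2/(2 F2) = 4 + 2 = 6
  a1 <- alpha_diversity(make_table(matrix(c(1, 1, 2, 3), 1)))
  expect_equal(a1$chao1, 6)
  # F2 = 0 -> S + F1(F1-1)/(2(F2+1)) = 3 + 1 = 4
  a2 <- alpha_diversity(make_table(matrix(c(1, 1, 3), 1)))
  expect_equal(a2$chao1, 4)
  expect_true(all(a1$chao1 >= a1$observed_richness))
})

test_that("Bray-Curtis and Jaccard match their definitions", {
  ft <- make_table(rbind(c(6, 2, 0), c(2, 2, 0), c(0, 0, 5)))
  bc <- as.matrix(beta_diversity(ft, "bray_curtis"))
  expect_equal(bc["s1", "s2"], 1 / 3, tolerance = 1e-12)
  expect_equal(bc["s1", "s3"], 1)   # disjoint taxa
  jc <- as.matrix(beta_diversity(ft, "jaccard"))
  expect_equal(jc["s1", "s3"], 1)
  expect_equal(jc["s1", "s2"], 0)   # same presence pattern
  # identical samples at distance zero
  ft2 <- make_table(rbind(c(3, 1), c(3, 1)))
  expect_equal(as.matrix(beta_diversity(ft2, "bray_curtis"))[1, 2], 0)
})

test_that("UniFrac distances respect the tree", {
  skip_if_not_installed("phyloseq")
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  ft <- make_table(rbind(c(5, 5, 0, 0), c(0, 0, 5, 5), c(5, 5, 0, 0)),
                   taxa = c("a", "b", "c", "d"))
  for (metric in c("unifrac_unweighted", "unifrac_weighted")) {
    d <- as.matrix(beta_diversity(ft, metric, tree = tree))
    expect_equal(d["s1", "s3"], 0, tolerance = 1e-12)
    expect_equal(d["s1", "s2"], 1, tolerance = 1e-12) # fully unshared clades
  }
  expect_error(beta_diversity(ft, "unifrac_weighted"), "tree")
  bad_tree <- ape::read.tree(text = "((a:1,b:1):1,c:1);")
  expect_error(beta_diversity(ft, "unifrac_weighted", tree = bad_tree),
               "missing")
})

test_that("distances satisfy metric axioms on random tables", {
  ft <- random_table(15, 10, seed = 2)
  for (metric in c("bray_curtis", "jaccard")) {
    d <- as.matrix(beta_diversity(ft, metric))
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0 & d <= 1 + 1e-12))
  }
  # triangle inequality for Jaccard
  d <- as.matrix(beta_diversity(ft, "jaccard"))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
  }
})

test_that("PCoA embeds simple geometries", {
  # two samples at distance d -> points at +/- d/2 on one axis
  m <- matrix(c(0, 4, 4, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  p <- pcoa(m, n_axes = 2)
  expect_equal(p$axes_returned, 1)
  expect_true(p$truncated)
  expect_equal(unname(sort(p$coordinates[, 1])), c(-2, 2),
               tolerance = 1e-9)
  # all-zero distances -> all coordinates zero
  z <- pcoa(matrix(0, 3, 3), n_axes = 2)
  expect_equal(z$axes_returned, 0)
  # collinear points are recovered up to sign and shift
  x <- c(0, 1, 3, 7)
  dm <- as.matrix(dist(x))
  p2 <- pcoa(dm, n_axes = 1)
  expect_equal(abs(cor(p2$coordinates[, 1], x)), 1, tolerance = 1e-9)
})

test_that("permutation beta tests recover planted structure and stay calibrated", {
  # two tight, well-separated clusters
  set.seed(7)
  m <- rbind(matrix(rpois(10 * 6, 5), 10),
             matrix(rpois(10 * 6, 5) + 200, 10))
  ft <- make_table(m)
  md <- data.frame(g = rep(c("lo", "hi"), each = 10),
                   row.names = rownames(ft$counts))
  dm <- beta_diversity(ft, "bray_curtis")
  an <- permutation_beta_test(dm, md, "g", "ANOSIM", n_perm = 99, seed = 1)
  expect_equal(an$statistic, 1, tolerance = 1e-9)
  ad <- permutation_beta_test(dm, md, "g", "ADONIS", n_perm = 99, seed = 1)
  expect_equal(ad$p_value, 1 / 100)
  expect_gte(ad$p_value, 1 / (ad$n_permutations + 1))
  mr <- permutation_beta_test(dm, md, "g", "MRPP", n_perm = 99, seed = 1)
  expect_lte(mr$statistic, 1)
  db <- permutation_beta_test(dm, md, "g", "dbRDA", n_perm = 99, seed = 1)
  expect_lt(db$p_value, 0.05)
  # determinism under a fixed seed
  ad2 <- permutation_beta_test(dm, md, "g", "ADONIS", n_perm = 99, seed = 1)
  expect_identical(ad, ad2)
  # errors on degenerate designs
  md$single <- c("x", rep("y", 19))
  expect_error(permutation_beta_test(dm, md, "single", "ANOSIM"), "2 samples")
})

test_that("ADONIS R-squared matches the brute-force decomposition", {
  for (seed in c(1, 2)) {
    ft <- random_table(6, 5, seed = seed)
    dm <- beta_diversity(ft, "bray_curtis")
    g <- rep(c("a", "b"), each = 3)
    md <- data.frame(g = g, row.names = rownames(ft$counts))
    got <- permutation_beta_test(dm, md, "g", "ADONIS", n_perm = 99,
                                 seed = 3)$statistic
    expect_equal(got, adonis_r2_bruteforce(dm, g), tolerance = 1e-10)
    expect_true(got >= 0 && got <= 1)
  }
})

test_that("alpha associations detect planted and reject null effects", {
  coh <- generate_cohort(synthetic_spec(n_samples = 400, seed = 17))
  alpha <- alpha_diversity(coh$table)
  md <- coh$metadata
  res <- alpha_association(alpha, md, variables = c("age", "bmi"),
                           covariates = "bmi")
  age_row <- res[res$variable == "age", ]
  expect_gt(age_row$spearman_rho, 0.3)
  expect_gt(age_row$lm_coef, 0)
  expect_lt(age_row$lm_fdr, 0.05)
  # perfectly monotone variable
  md$mono <- rank(alpha$shannon)
  res2 <- alpha_association(alpha, md, variables = "mono")
  expect_equal(res2$spearman_rho, 1, tolerance = 1e-12)
  # constant variable flagged non-estimable
  md$const <- 1
  res3 <- alpha_association(alpha, md, variables = c("age", "const"))
  expect_false(res3$estimable[res3$variable == "const"])
  expect_true(is.na(res3$spearman_fdr[res3$variable == "const"]))
})

test_that("null alpha-association p-values are approximately uniform", {
  coh <- generate_cohort(synthetic_spec(n_samples = 100, seed = 23))
  alpha <- alpha_diversity(coh$table)
  md <- coh$metadata
  set.seed(99)
  nullvars <- paste0("null_", 1:200)
  for (v in nullvars) md[[v]] <- rnorm(nrow(md))
  res <- alpha_association(alpha, md, variables = nullvars)
  ks <- suppressWarnings(ks.test(res$spearman_p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("variance partition is consistent and handles aliasing", {
  coh <- generate_cohort(synthetic_spec(n_samples = 80, seed = 29))
  dm <- beta_diversity(coh$table, "bray_curtis")
  md <- coh$metadata
  uni <- permutation_beta_test(dm, md, "residence", "ADONIS", n_perm = 49,
                               seed = 1)
  vp <- multivariable_variance_partition(dm, md,
                                         list(social = "residence"),
                                         n_perm = 49, seed = 1)
  expect_equal(vp$r_squared, uni$statistic, tolerance = 1e-10)
  # duplicated variable contributes (almost) nothing extra
  md$residence2 <- md$residence
  vp2 <- multivariable_variance_partition(
    dm, md, list(social = c("residence", "residence2")),
    n_perm = 49, seed = 1)
  expect_equal(vp2$r_squared, uni$statistic, tolerance = 1e-6)
})

test_that("beta-variable screening applies the support and effect-size gates", {
  grid <- expand.grid(metric = c("bray_curtis", "jaccard",
                                 "unifrac_weighted", "unifrac_unweighted"),
                      method = c("ADONIS", "ANOSIM", "MRPP", "dbRDA"),
                      stringsAsFactors = FALSE)
  mk <- function(variable, p, r2) {
    data.frame(variable = variable, method = grid$method,
               metric = grid$metric,
               statistic = ifelse(grid$method == "ADONIS", r2, 0.5),
               p_value = p, n_permutations = 999)
  }
  res <- rbind(
    mk("strong", 0.001, 0.05),
    mk("weak_r2", 0.001, 0.0009),
    {
      r <- mk("two_methods", 0.9, 0.05)
      r$p_value[r$method %in% c("ADONIS", "ANOSIM")] <- 0.001
      r
    },
    mk("null", 0.8, 0.0005))
  sel <- screen_beta_variables(res)
  expect_true("strong" %in% sel)
  expect_false("weak_r2" %in% sel)
  expect_false("two_methods" %in% sel)
  expect_false("null" %in% sel)
})
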