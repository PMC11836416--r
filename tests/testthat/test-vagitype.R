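test_that("Yue-Clayton theta matches its closed form and bounds", {
  expect_equal(yue_clayton_theta(c(0.2, 0.5, 0.3), c(0.2, 0.5, 0.3)), 1)
  expect_equal(yue_clayton_theta(c(1, 0, 0), c(0, 0.4, 0.6)), 0)
  expect_equal(yue_clayton_theta(c(0.5, 0.5, 0), c(0.5, 0, 0.5)), 1 / 3,
               tolerance = 1e-12)
  # symmetry and bounds on random proportion pairs
  set.seed(31)
  for (i in 1:25) {
    a <- runif(6); b <- runif(6)
    th <- yue_clayton_theta(a, b)
    expect_equal(th, yue_clayton_theta(b, a), tolerance = 1e-12)
    expect_true(th >= 0 && th <= 1)
    if (i == 1) expect_lt(yue_clayton_theta(a, b + 0.5), 1)
  }
  # theta = 1 iff the renormalized vectors coincide
  expect_equal(yue_clayton_theta(c(1, 1), c(2, 2)), 1)
  expect_lt(yue_clayton_theta(c(1, 1), c(2, 1)), 1)
  expect_error(yue_clayton_theta(c(0, 0), c(0, 0)), "empty")
  expect_error(yue_clayton_theta(c(1, 0), c(1, 0, 0)), "axis")
})

test_that("NMF factorizes exactly-low-rank matrices with monotone objective", {
  set.seed(5)
  w <- matrix(runif(30 * 2), 30, 2)
  h <- matrix(runif(2 * 10), 2, 10)
  x <- w %*% h
  dimnames(x) <- list(paste0("s", 1:30), paste0("t", 1:10))
  fit <- nmf_fit(x, k = 2, seed = 1, n_restarts = 5)
  rel_err <- sqrt(fit$objective) / sqrt(sum(x^2))
  expect_lt(rel_err, 1e-3)
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  expect_true(all(fit$basis >= 0) && all(fit$coefficients >= 0))
  expect_error(nmf_fit(x, k = 50, seed = 1), "k must")
  expect_error(nmf_fit(-x, k = 2, seed = 1), "non-negative")
})

test_that("NMF separates planted community types", {
  spec <- synthetic_spec(
    n_samples = 240,
    type_profiles = default_type_profiles(default_taxon_panel())[1:3],
    type_proportions = c(0.4, 0.35, 0.25), seed = 61)
  coh <- generate_cohort(spec)
  rel <- to_relative(coh$table)
  fit <- nmf_fit(rel, k = 3, seed = 2, n_restarts = 10)
  cl <- max.col(fit$coefficients)
  ari <- mclust::adjustedRandIndex(cl, coh$true_labels)
  expect_gt(ari, 0.9)
})

test_that("rank selection finds planted k and degrades gracefully on noise", {
  picks <- sapply(1:4, function(r) {
    spec <- synthetic_spec(
      n_samples = 120,
      type_profiles = default_type_profiles(default_taxon_panel())[1:3],
      type_proportions = c(0.4, 0.35, 0.25), seed = 700 + r)
    rel <- to_relative(generate_cohort(spec)$table)
    select_rank(rel, k_min = 2, k_max = 5, seed = r, n_restarts = 8)$k
  })
  expect_gte(sum(picks == 3), 3)
  # pure noise: returns diagnostics without crashing
  set.seed(9)
  noise <- matrix(runif(40 * 12), 40, 12,
                  dimnames = list(paste0("s", 1:40), paste0("t", 1:12)))
  rk <- select_rank(noise, k_min = 2, k_max = 4, seed = 1, n_restarts = 5)
  expect_true(rk$k %in% 2:4)
  expect_equal(nrow(rk$diagnostics), 3)
  # degenerate range
  rk2 <- select_rank(noise, k_min = 3, k_max = 3, seed = 1, n_restarts = 5)
  expect_equal(rk2$k, 3)
})

test_that("vagitype definition yields dominant-taxon centroids and labels", {
  spec <- synthetic_spec(
    n_samples = 200,
    type_profiles = default_type_profiles(default_taxon_panel())[1:2],
    type_proportions = c(0.55, 0.45), seed = 71)
  coh <- generate_cohort(spec)
  rel <- to_relative(coh$table)
  model <- define_vagitypes(rel, k = 2, seed = 3, n_restarts = 10)
  expect_setequal(model$type_labels,
                  c("Lactobacillus_crispatus-dominated",
                    "Lactobacillus_iners-dominated"))
  # centroids dominated by the namesake taxon
  for (lbl in model$type_labels) {
    dom <- sub("-dominated$", "", lbl)
    expect_equal(names(which.max(model$centroids[lbl, ])), dom)
  }
  # recovered type frequencies close to planted proportions
  freq <- table(model$assignments) / length(model$assignments)
  planted <- c("Lactobacillus_crispatus-dominated" = 0.55,
               "Lactobacillus_iners-dominated" = 0.45)
  expect_true(all(abs(freq[names(planted)] - planted) < 0.06))
})

test_that("centroid assignment is exact on centroids and accurate on held-out data", {
  spec <- synthetic_spec(
    n_samples = 300,
    type_profiles = default_type_profiles(default_taxon_panel())[1:3],
    type_proportions = c(0.4, 0.35, 0.25), seed = 81)
  coh <- generate_cohort(spec)
  rel <- to_relative(coh$table)
  train <- rel[1:200, ]
  test <- rel[201:300, ]
  model <- define_vagitypes(train, k = 3, seed = 4, n_restarts = 10)
  # a sample equal to a centroid maps to it with theta 1
  asg_c <- assign_by_centroid(model$centroids, model)
  expect_equal(asg_c$assigned_type, rownames(model$centroids))
  expect_equal(asg_c$theta, rep(1, 3), tolerance = 1e-12)
  # held-out accuracy over planted truth
  asg <- assign_by_centroid(test, model)
  truth <- coh$true_labels[201:300]
  map <- c("L_crispatus" = "Lactobacillus_crispatus-dominated",
           "L_iners" = "Lactobacillus_iners-dominated",
           "G_vaginalis" = "Gardnerella_vaginalis-dominated")
  expect_gt(mean(asg$assigned_type == map[truth]), 0.9)
  # training reclassification consistency
  self <- assign_by_centroid(train, model)
  expect_gt(mean(self$assigned_type == model$assignments), 0.9)
})

test_that("assignment handles ties, missing taxa and zero-mass samples", {
  centroids <- rbind(c(0.7, 0.3, 0), c(0.7, 0.3, 0), c(0, 0.2, 0.8))
  colnames(centroids) <- c("ta", "tb", "tc")
  rownames(centroids) <- c("dup1", "dup2", "other")
  model <- structure(list(k = 3, key_taxa = colnames(centroids),
                          centroids = centroids,
                          type_labels = rownames(centroids)),
                     class = "vagitype_model")
  asg <- assign_by_centroid(c(ta = 0.7, tb = 0.3, tc = 0), model)
  expect_equal(asg$assigned_type, "dup1")  # first-centroid tie-break
  expect_true(asg$tie_flag)
  # extra taxa ignored, missing taxa zero-filled
  asg2 <- assign_by_centroid(c(tc = 0.5, zz = 0.5), model)
  expect_equal(asg2$assigned_type, "other")
  asg3 <- assign_by_centroid(c(ta = 0, zz = 1), model)
  expect_true(asg3$unclassifiable)
  expect_error(assign_by_centroid(c(zz = 1), model), "no key taxa")
})

test_that("models round-trip losslessly through JSON", {
  spec <- synthetic_spec(n_samples = 120, seed = 91)
  coh <- generate_cohort(spec)
  rel <- to_relative(coh$table)
  model <- define_vagitypes(rel, k = 4, seed = 5, n_restarts = 8)
  path <- withr::local_tempfile(fileext = ".json")
  write_vagitype_model(model, path)
  back <- read_vagitype_model(path)
  expect_equal(back$centroids, model$centroids, tolerance = 1e-12)
  a1 <- assign_by_centroid(rel, model)
  a2 <- assign_by_centroid(rel, back)
  expect_identical(a1$assigned_type, a2$assigned_type)
  expect_equal(a1$theta, a2$theta, tolerance = 1e-12)
})
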