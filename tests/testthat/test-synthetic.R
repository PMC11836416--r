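test_that("identical specs reproduce identical cohorts", {
  spec <- synthetic_spec(n_samples = 40, seed = 5)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$table$counts, b$table$counts)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$true_labels, b$true_labels)
  expect_identical(ape::write.tree(a$tree), ape::write.tree(b$tree))
})

test_that("degenerate type proportions give a single type", {
  spec <- synthetic_spec(n_samples = 30,
                         type_proportions = c(1, 0, 0, 0, 0), seed = 2)
  coh <- generate_cohort(spec)
  expect_true(all(coh$true_labels == names(spec$type_profiles)[1]))
})

test_that("empirical type frequencies match the sampling law", {
  props <- c(0.5, 0.3, 0.2)
  spec <- synthetic_spec(
    n_samples = 600,
    type_profiles = default_type_profiles(default_taxon_panel())[1:3],
    type_proportions = props, seed = 11)
  coh <- generate_cohort(spec)
  freq <- table(factor(coh$true_labels,
                       levels = names(spec$type_profiles))) / 600
  se <- sqrt(props * (1 - props) / 600)
  expect_true(all(abs(as.numeric(freq) - props) <= 3 * se))
})

test_that("counts are integer with rows matching drawn depths", {
  coh <- generate_cohort(synthetic_spec(n_samples = 50, seed = 3))
  cts <- coh$table$counts
  expect_true(all(cts >= 0 & cts == round(cts)))
  depths <- rowSums(cts)
  expect_true(all(depths >= 48000 & depths <= 100000))
  expect_true(abs(median(depths) - 79047) < 8000)
})

test_that("dominance lowers Shannon diversity relative to even profiles", {
  panel <- c("Lactobacillus_crispatus", "Lactobacillus_iners",
             "Gardnerella_vaginalis", "Ureaplasma_parvum",
             paste0("taxon_", 5:20))
  dom <- setNames(c(50, rep(1, 19)), panel)
  even <- setNames(rep(5, 20), panel)
  for (seed in 1:3) {
    mk <- function(profile) {
      spec <- synthetic_spec(
        n_samples = 50, taxon_panel = panel,
        type_profiles = list(only = profile), type_proportions = 1,
        metadata_effects = list(age_shannon = 0, base_mix = 0,
                                bmi_gardnerella = 0, nugent_noise = 1),
        mediation_path = list(mediator = "parity", taxon = panel[1],
                              a = 0, b = 0, c_prime = 0,
                              mediator_noise = 1, mediator_base = 2),
        seed = seed)
      mean(alpha_diversity(generate_cohort(spec)$table)$shannon)
    }
    expect_lt(mk(dom), mk(even))
  }
})

test_that("metadata carries typed variables and a composition-linked Nugent score", {
  coh <- generate_cohort(synthetic_spec(n_samples = 300, seed = 9))
  types <- attr(coh$metadata, "variable_types")
  expect_true(all(c("age", "bmi", "parity", "nugent", "delivery_mode") %in%
                    types$variable))
  expect_true(all(coh$metadata$nugent >= 0 & coh$metadata$nugent <= 10))
  lacto <- rowSums(coh$table$counts[, grep("^Lactobacillus",
                                           colnames(coh$table$counts))]) /
    rowSums(coh$table$counts)
  expect_gt(cor(1 - lacto, coh$metadata$nugent, method = "spearman"), 0.5)
  expect_true(abs(mean(coh$metadata$age) - 33.9) < 2)
})

test_that("invalid specs are rejected", {
  expect_error(synthetic_spec(n_samples = 0), "positive")
  expect_error(synthetic_spec(taxon_panel = character(0)), "empty")
  expect_error(synthetic_spec(type_proportions = c(0.6, 0.3, 0.05, 0.04, 0)),
               "sum to 1")
})

test_that("outcome generation respects the logit law and outcome nesting", {
  # null model: all coefficients and intercept zero -> 50% live birth
  spec0 <- synthetic_spec(
    n_samples = 1000,
    outcome_model = list(intercept_lb = 0, intercept_cp = 0,
                         type_coef = c(0, 0, 0, 0, 0), age = 0, bmi = 0,
                         embryos = 0), seed = 21)
  coh <- generate_cohort(spec0)
  out <- generate_outcomes(coh$true_labels, coh$metadata, spec0)
  se <- sqrt(0.25 / 1000)
  expect_lt(abs(mean(out$live_birth) - 0.5), 3 * se)
  expect_true(all(out$clinical_pregnancy >= out$live_birth))

  # a very large negative type coefficient suppresses the outcome
  spec_neg <- synthetic_spec(
    n_samples = 400,
    outcome_model = list(intercept_lb = 0, intercept_cp = 0,
                         type_coef = stats::setNames(
                           c(-30, 0, 0, 0, 0),
                           names(default_type_profiles(default_taxon_panel()))),
                         age = 0, bmi = 0, embryos = 0), seed = 22)
  coh2 <- generate_cohort(spec_neg)
  out2 <- generate_outcomes(coh2$true_labels, coh2$metadata, spec_neg)
  sel <- coh2$true_labels == "L_crispatus"
  expect_equal(mean(out2$live_birth[sel]), 0)

  expect_error(generate_outcomes(coh$true_labels,
                                 coh$metadata[, c("age", "bmi")], spec0),
               "embryos_transferred")
})

test_that("planted odds ratios are recovered in large samples", {
  # two types, planted log-OR 1.286 (OR ~ 3.62), covariate effects off
  panel <- default_taxon_panel()
  spec <- synthetic_spec(
    n_samples = 4000,
    type_profiles = default_type_profiles(panel)[1:2],
    type_proportions = c(0.5, 0.5),
    outcome_model = list(intercept_lb = -0.6, intercept_cp = 0,
                         type_coef = c(L_crispatus = 1.286, L_iners = 0),
                         age = 0, bmi = 0, embryos = 0),
    seed = 31)
  coh <- generate_cohort(spec)
  out <- generate_outcomes(coh$true_labels, coh$metadata, spec)
  tab <- table(coh$true_labels, out$live_birth)
  or <- (tab["L_crispatus", "1"] / tab["L_crispatus", "0"]) /
    (tab["L_iners", "1"] / tab["L_iners", "0"])
  expect_lt(abs(or - exp(1.286)) / exp(1.286), 0.25)
})

test_that("cohorts serialize to plain-text artifacts", {
  dir <- withr::local_tempdir()
  spec <- synthetic_spec(n_samples = 20, seed = 4)
  coh <- generate_cohort(spec)
  write_cohort(coh, dir, spec = spec)
  expect_true(all(file.exists(file.path(
    dir, c("counts.tsv", "metadata.tsv", "metadata_types.tsv", "tree.nwk",
           "true_labels.tsv", "spec.json")))))
  back <- read_feature_table(file.path(dir, "counts.tsv"))
  expect_equal(back$counts, coh$table$counts)
  tr <- ape::read.tree(file.path(dir, "tree.nwk"))
  expect_setequal(tr$tip.label, spec$taxon_panel)
})
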