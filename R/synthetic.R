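#' Default taxon panel for synthetic cohorts
#'
#' Thirty species/genus-level taxa spanning the communities typically seen in
#' vaginal microbiome cohorts: the four near-ubiquitous core species
#' (*L. crispatus*, *L. iners*, *G. vaginalis*, *U. parvum*), additional
#' lactobacilli, and the anaerobes associated with bacterial vaginosis.
#'
#' @return character vector of taxon names.
#' @export
default_taxon_panel <- function() {
  c("Lactobacillus_crispatus", "Lactobacillus_iners",
    "Gardnerella_vaginalis", "Ureaplasma_parvum",
    "Lactobacillus_jensenii", "Lactobacillus_gasseri",
    "Fannyhessea_vaginae", "Prevotella_timonensis", "Prevotella_bivia",
    "Prevotella_amnii", "Sneathia_amnii", "Dialister_micraerophilus",
    "Megasphaera_genomosp", "Mobiluncus_curtisii", "Atopobium_deltae",
    "Mycoplasma_hominis", "Aerococcus_christensenii",
    "Streptococcus_anginosus", "Anaerococcus_tetradius",
    "Peptoniphilus_harei", "Finegoldia_magna", "Veillonella_montpellierensis",
    "Parvimonas_micra", "Porphyromonas_asaccharolytica",
    "Corynebacterium_amycolatum", "Enterococcus_faecalis",
    "Escherichia_coli", "Bifidobacterium_breve", "Staphylococcus_epidermidis",
    "Bacteroides_fragilis")
}

#' Default community-type Dirichlet profiles
#'
#' Five community types over the default panel: *L. crispatus*-,
#' *L. iners*-, *G. vaginalis*- and *U. parvum*-dominated communities plus a
#' diverse anaerobe-rich (BV-like) type. Concentrations keep the four core
#' species near-ubiquitous in every type.
#'
#' @param panel taxon panel (see [default_taxon_panel()]).
#' @return named list of concentration vectors.
#' @export
default_type_profiles <- function(panel) {
  base <- stats::setNames(rep(0.05, length(panel)), panel)
  # the four core species are near-ubiquitous in every community type
  base[c("Lactobacillus_crispatus", "Lactobacillus_iners",
         "Gardnerella_vaginalis", "Ureaplasma_parvum")] <- 0.8
  # the mediation target keeps a moderate concentration in every type so its
  # log abundance is informative across the whole cohort
  base["Mycoplasma_hominis"] <- 2
  mk <- function(dom, conc = 30, extra = NULL) {
    a <- base
    a[dom] <- conc
    if (!is.null(extra)) a[names(extra)] <- extra
    a
  }
  list(
    "L_crispatus" = mk("Lactobacillus_crispatus",
                       extra = c(Lactobacillus_iners = 1.5)),
    "L_iners" = mk("Lactobacillus_iners",
                   extra = c(Lactobacillus_crispatus = 1)),
    "G_vaginalis" = mk("Gardnerella_vaginalis",
                       extra = c(Fannyhessea_vaginae = 2,
                                 Prevotella_timonensis = 2,
                                 Lactobacillus_iners = 1)),
    "U_parvum" = mk("Ureaplasma_parvum",
                    extra = c(Lactobacillus_iners = 2)),
    "diverse_BV" = {
      a <- base
      a[c("Gardnerella_vaginalis", "Fannyhessea_vaginae",
          "Prevotella_timonensis", "Prevotella_bivia", "Sneathia_amnii",
          "Dialister_micraerophilus", "Megasphaera_genomosp",
          "Atopobium_deltae")] <- 4
      a["Lactobacillus_iners"] <- 2
      a
    }
  )
}

#' Specify a synthetic vaginal-microbiome cohort
#'
#' Defines the generative model for a seeded synthetic cohort: samples are
#' drawn from a small number of Dirichlet-multinomial community types, read
#' depths follow a truncated lognormal law (median about 79,000 reads, all
#' samples above 48,000), and the metadata carry planted, documented effects:
#' an age-diversity association, a BMI tilt on *G. vaginalis*, an
#' age -> parity -> taxon mediation chain (coefficients on the age z-scale),
#' a Nugent score tied to *Lactobacillus* depletion, and community-type
#' effects on IVF outcomes.
#'
#' @param n_samples number of samples.
#' @param taxon_panel ordered taxon names (>= 20, must contain the four core
#'   species).
#' @param type_profiles named list of Dirichlet concentration vectors over
#'   the panel, one per community type.
#' @param type_proportions probability vector over types (sums to 1).
#' @param depth_law list with `meanlog`, `sdlog`, `min`, `max` for the
#'   truncated lognormal read-depth distribution.
#' @param metadata_effects list of planted-effect coefficients
#'   (`age_shannon`, `base_mix`, `bmi_gardnerella`, `nugent_noise`).
#' @param mediation_path list with `mediator`, `taxon`, `a`, `b`, `c_prime`,
#'   `mediator_noise`, `mediator_base` for the planted mediation chain.
#' @param outcome_model list of logit coefficients: `intercept_lb`,
#'   `intercept_cp`, `type_coef` (named per type), `age`, `bmi`, `embryos`.
#' @param seed root seed; all stage randomness is split from it.
#' @return an object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 500,
                           taxon_panel = default_taxon_panel(),
                           type_profiles = default_type_profiles(taxon_panel),
                           type_proportions = c(0.30, 0.33, 0.15, 0.08, 0.14),
                           depth_law = list(meanlog = log(79047),
                                            sdlog = 0.10,
                                            min = 48000, max = 100000),
                           metadata_effects = list(age_shannon = 0.8,
                                                   base_mix = 0,
                                                   bmi_gardnerella = 0.5,
                                                   nugent_noise = 1),
                           mediation_path = list(mediator = "parity",
                                                 taxon = "Mycoplasma_hominis",
                                                 a = 0.5, b = 0.4,
                                                 c_prime = 0.1,
                                                 mediator_noise = 1,
                                                 mediator_base = 2),
                           outcome_model = list(
                             intercept_lb = -0.2, intercept_cp = 0.3,
                             type_coef = c("L_crispatus" = 0.4,
                                           "L_iners" = 0.5,
                                           "G_vaginalis" = -0.6,
                                           "U_parvum" = 0,
                                           "diverse_BV" = -0.9),
                             age = -0.3, bmi = -0.1, embryos = 0.3),
                           seed = 1L) {
  if (!is.numeric(n_samples) || n_samples < 1) stop2("n_samples must be positive")
  if (length(taxon_panel) == 0L) stop2("taxon_panel must not be empty")
  core <- c("Lactobacillus_crispatus", "Lactobacillus_iners",
            "Gardnerella_vaginalis", "Ureaplasma_parvum")
  if (length(taxon_panel) >= 20 && !all(core %in% taxon_panel)) {
    stop2("taxon_panel must include the four core species")
  }
  if (abs(sum(type_proportions) - 1) > 1e-12) {
    stop2("type_proportions must sum to 1")
  }
  if (length(type_profiles) != length(type_proportions)) {
    stop2("one profile per type is required")
  }
  for (pr in type_profiles) {
    if (length(pr) != length(taxon_panel) || any(pr <= 0)) {
      stop2("each type profile must be a strictly positive vector over the panel")
    }
  }
  if (is.null(names(type_profiles))) {
    names(type_profiles) <- paste0("type_", seq_along(type_profiles))
  }
  structure(list(n_samples = as.integer(n_samples),
                 taxon_panel = taxon_panel,
                 type_profiles = type_profiles,
                 type_proportions = type_proportions,
                 depth_law = depth_law,
                 metadata_effects = metadata_effects,
                 mediation_path = mediation_path,
                 outcome_model = outcome_model,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

rtrunc_lognorm <- function(n, meanlog, sdlog, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    out <- c(out, x[x >= lo & x <= hi])
  }
  round(out[seq_len(n)])
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic cohort
#'
#' Draws, for each sample, a community type, a Dirichlet composition from
#' that type's profile (tilted by the planted age-diversity, BMI and
#' mediation effects), and multinomial counts at a truncated-lognormal read
#' depth; produces typed metadata (age, BMI, parity, delivery mode,
#' contraception, douching and sexual frequency, residence, sampling month,
#' Nugent score, hemoglobin, embryos transferred) and a random rooted binary
#' tree over the panel.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `table` ([feature_table()]), `metadata` (data.frame with
#'   a `variable_types` attribute), `tree` (ape `phylo`), and `true_labels`
#'   (named character vector of community types per sample).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_samples
  panel <- spec$taxon_panel
  k <- length(spec$type_profiles)
  ids <- sprintf("S%04d", seq_len(n))

  labels <- with_seed(split_seed(spec$seed, "labels"), {
    sample(names(spec$type_profiles), n, replace = TRUE,
           prob = spec$type_proportions)
  })

  md <- with_seed(split_seed(spec$seed, "metadata"), {
    age <- rtrunc_norm(n, 33.9, 6.3, 19, 64)
    bmi <- rtrunc_norm(n, 24.0, 3.7, 15, 42)
    z_age <- (age - mean(age)) / stats::sd(age)
    mp <- spec$mediation_path
    parity_lat <- mp$mediator_base + mp$a * z_age +
      stats::rnorm(n, 0, mp$mediator_noise)
    parity <- pmax(0L, as.integer(round(parity_lat)))
    data.frame(
      sample_id = ids,
      age = age, bmi = bmi, parity = parity,
      delivery_mode = sample(c("vaginal", "cesarean", "nulliparous"),
                             n, TRUE, prob = c(0.5, 0.3, 0.2)),
      contraception = sample(c("none", "condom", "IUD", "oral"),
                             n, TRUE, prob = c(0.4, 0.3, 0.2, 0.1)),
      douching_frequency = sample(0:3, n, TRUE,
                                  prob = c(0.55, 0.25, 0.12, 0.08)),
      sexual_frequency = sample(0:4, n, TRUE,
                                prob = c(0.15, 0.3, 0.3, 0.15, 0.1)),
      residence = sample(c("urban", "rural"), n, TRUE, prob = c(0.7, 0.3)),
      sampling_month = sample(1:12, n, TRUE),
      vvc = sample(0:1, n, TRUE, prob = c(0.85, 0.15)),
      hemoglobin = stats::rnorm(n, 130, 12),
      embryos_transferred = sample(1:2, n, TRUE, prob = c(0.45, 0.55)),
      stringsAsFactors = FALSE)
  })
  rownames(md) <- ids
  z_age <- (md$age - mean(md$age)) / stats::sd(md$age)
  z_bmi <- (md$bmi - mean(md$bmi)) / stats::sd(md$bmi)

  comp <- with_seed(split_seed(spec$seed, "composition"), {
    eff <- spec$metadata_effects
    mp <- spec$mediation_path
    m_ctr <- md[[mp$mediator]] - mean(md[[mp$mediator]])
    t(vapply(seq_len(n), function(i) {
      # planted age-diversity association: a concentration exponent < 1
      # flattens the profile (higher Shannon) for older women while keeping
      # rare taxa rare
      tilt <- exp(-0.35 * eff$age_shannon * z_age[i])
      p <- rdirichlet1(spec$type_profiles[[labels[i]]]^tilt)
      if (eff$base_mix > 0) {
        p <- (1 - eff$base_mix) * p + eff$base_mix / length(panel)
      }
      # planted BMI effect on G. vaginalis (log2 fold per BMI sd)
      gv <- match("Gardnerella_vaginalis", panel)
      if (!is.na(gv)) {
        p[gv] <- p[gv] * 2^(eff$bmi_gardnerella * z_bmi[i])
      }
      p <- p / sum(p)
      # planted mediation chain: mediator and direct age effects applied
      # exactly on the target's log2 relative abundance (the remaining taxa
      # are rescaled so the composition stays normalized)
      tt <- match(mp$taxon, panel)
      if (!is.na(tt)) {
        p_new <- min(p[tt] * 2^(mp$b * m_ctr[i] + mp$c_prime * z_age[i]),
                     0.9)
        p[-tt] <- p[-tt] * (1 - p_new) / (1 - p[tt])
        p[tt] <- p_new
      }
      p
    }, numeric(length(panel))))
  })
  colnames(comp) <- panel

  counts <- with_seed(split_seed(spec$seed, "counts"), {
    depths <- rtrunc_lognorm(n, spec$depth_law$meanlog, spec$depth_law$sdlog,
                             spec$depth_law$min, spec$depth_law$max)
    m <- t(vapply(seq_len(n), function(i) {
      as.numeric(stats::rmultinom(1, depths[i], comp[i, ]))
    }, numeric(length(panel))))
    dimnames(m) <- list(ids, panel)
    m
  })

  # Nugent score: monotone in Lactobacillus depletion plus discrete noise
  lacto <- rowSums(counts[, grep("^Lactobacillus", panel), drop = FALSE]) /
    rowSums(counts)
  md$nugent <- with_seed(split_seed(spec$seed, "nugent"), {
    noise <- sample(-1:1, n, TRUE)
    pmin(10L, pmax(0L, as.integer(round(10 * (1 - lacto))) + noise))
  })
  md$nugent_class <- cut(md$nugent, c(-1, 3, 6, 10),
                         labels = c("normal", "intermediate", "BV"))
  md$nugent_class <- as.character(md$nugent_class)

  tree <- with_seed(split_seed(spec$seed, "tree"), {
    tr <- ape::rtree(length(panel))
    tr$tip.label <- sample(panel)
    tr
  })

  types <- data.frame(
    variable = c("age", "bmi", "parity", "delivery_mode", "contraception",
                 "douching_frequency", "sexual_frequency", "residence",
                 "sampling_month", "vvc", "hemoglobin",
                 "embryos_transferred", "nugent", "nugent_class"),
    scale = c("continuous", "continuous", "ordinal", "nominal", "nominal",
              "ordinal", "ordinal", "nominal", "nominal", "binary",
              "continuous", "ordinal", "ordinal", "nominal"),
    category = c("anthropometrics", "anthropometrics", "OB-GYN", "OB-GYN",
                 "OB-GYN", "lifestyle", "lifestyle", "social", "environment",
                 "vaginal dysbiosis", "laboratory", "OB-GYN",
                 "vaginal dysbiosis", "vaginal dysbiosis"),
    reference = c(NA, NA, NA, "vaginal", "none", NA, NA, "urban", NA, "0",
                  NA, NA, NA, "normal"),
    stringsAsFactors = FALSE)
  attr(md, "variable_types") <- types

  names(labels) <- ids
  list(table = feature_table(counts), metadata = md, tree = tree,
       true_labels = labels)
}

#' Generate IVF outcomes for a synthetic cohort
#'
#' Live birth is drawn from a Bernoulli model on the logit scale (community
#' type plus age, BMI and embryos-transferred effects, age/BMI standardized);
#' clinical pregnancy is forced to 1 whenever live birth occurred and drawn
#' from its own model otherwise, so live birth always implies clinical
#' pregnancy while the marginal live-birth rate matches its linear predictor
#' exactly.
#'
#' @param labels named character vector of community types per sample.
#' @param metadata cohort metadata containing `age`, `bmi`,
#'   `embryos_transferred`.
#' @param spec a [synthetic_spec()] providing `outcome_model` and the seed.
#' @return data.frame with `sample_id`, `clinical_pregnancy`, `live_birth`.
#' @export
generate_outcomes <- function(labels, metadata, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  om <- spec$outcome_model
  need <- c("age", "bmi", "embryos_transferred")
  miss <- setdiff(need, colnames(metadata))
  if (length(miss)) stop2("missing covariate column(s): ",
                          paste(miss, collapse = ", "))
  if (!all(names(labels) %in% rownames(metadata))) {
    stop2("every labelled sample needs metadata")
  }
  md <- metadata[names(labels), , drop = FALSE]
  z_age <- as.numeric(scale(md$age))
  z_bmi <- as.numeric(scale(md$bmi))
  if (any(is.na(z_age))) z_age <- rep(0, nrow(md))
  if (any(is.na(z_bmi))) z_bmi <- rep(0, nrow(md))
  tc <- om$type_coef[labels]
  tc[is.na(tc)] <- 0
  covs <- om$age * z_age + om$bmi * z_bmi +
    om$embryos * (md$embryos_transferred - mean(md$embryos_transferred))
  lp_lb <- om$intercept_lb + tc + covs
  lp_cp <- om$intercept_cp + tc + covs
  with_seed(split_seed(spec$seed, "outcomes"), {
    lb <- stats::rbinom(length(lp_lb), 1, stats::plogis(lp_lb))
    cp <- ifelse(lb == 1, 1L, stats::rbinom(length(lp_cp), 1,
                                            stats::plogis(lp_cp)))
    data.frame(sample_id = names(labels), clinical_pregnancy = cp,
               live_birth = lb, stringsAsFactors = FALSE)
  })
}

#' Write a synthetic cohort to disk
#'
#' Counts as a tab-separated samples-by-taxa matrix, metadata as TSV with a
#' sidecar variable-typing file, the tree as Newick, and the spec as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param spec optional [synthetic_spec()] to serialize alongside.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, spec = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(cohort$table, file.path(dir, "counts.tsv"))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(attr(cohort$metadata, "variable_types"),
                     file.path(dir, "metadata_types.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  ape::write.tree(cohort$tree, file.path(dir, "tree.nwk"))
  utils::write.table(
    data.frame(sample_id = names(cohort$true_labels),
               type = unname(cohort$true_labels)),
    file.path(dir, "true_labels.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), file.path(dir, "spec.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}
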