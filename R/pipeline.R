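#' Default pipeline configuration
#'
#' One structured configuration governs all stages; values supplied in
#' `...` override the defaults. Paths may be NULL when the run starts from
#' a simulated cohort.
#'
#' @param ... overrides (same names as the defaults).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    counts_path = NULL, metadata_path = NULL, tree_path = NULL,
    output_dir = "vagitools_run",
    simulate = TRUE, n_samples = 300,
    filter_min_total = 50, filter_min_prevalence = 0.01,
    rarefaction_depth = 10000,
    beta_metrics = c("bray_curtis", "jaccard"),
    beta_methods = c("ADONIS", "ANOSIM", "MRPP", "dbRDA"),
    n_perm = 199,
    sparcc_n_inner = 20, sparcc_n_boot = 100,
    network_p_max = 0.01, network_min_abs_cor = 0.1,
    nmf_k = NULL, nmf_k_min = 2, nmf_k_max = 8, nmf_restarts = 10,
    mediation_n_boot = 200,
    outcome_reference = NULL,
    fdr_max = 0.05,
    seed = 1L)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop2("unknown config field(s): ",
                             paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order -- simulate (or load), filter, rarefy,
#' diversity, beta tests, per-taxon association, SparCC network, Vagitype
#' fitting and assignment, mediation screen, outcome models -- writing each
#' stage's TSV/JSON outputs plus a machine-readable run manifest into the
#' configured output directory. Every stage is also callable on its own
#' through the exported functions; this wrapper only sequences them.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list of in-memory stage results; artifacts are under
#'   `config$output_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!config$simulate &&
      (is.null(config$counts_path) || is.null(config$metadata_path))) {
    stop2("counts_path and metadata_path are required when simulate = FALSE")
  }
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)
  log_stage <- function(s) message("[vagitools] stage: ", s)

  log_stage("input")
  if (config$simulate) {
    spec <- synthetic_spec(n_samples = config$n_samples, seed = config$seed)
    cohort <- generate_cohort(spec)
    write_cohort(cohort, out("cohort"), spec = spec)
  } else {
    cohort <- list(
      table = read_feature_table(config$counts_path),
      metadata = utils::read.delim(config$metadata_path,
                                   row.names = 1, stringsAsFactors = FALSE),
      tree = if (!is.null(config$tree_path))
        ape::read.tree(config$tree_path) else NULL,
      true_labels = NULL)
  }
  if (any(grepl("^unifrac", config$beta_metrics)) && is.null(cohort$tree)) {
    stop2("UniFrac metric requested but no tree available (tree_path)")
  }

  log_stage("filter")
  filt <- filter_features(cohort$table, config$filter_min_total,
                          config$filter_min_prevalence)
  rar <- rarefy(filt, depth = min(config$rarefaction_depth,
                                  min(rowSums(filt$counts))),
                seed = config$seed)

  log_stage("diversity")
  alpha <- alpha_diversity(rar$table)
  utils::write.table(alpha, out("alpha_diversity.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  md <- cohort$metadata[alpha$sample_id, , drop = FALSE]
  attr(md, "variable_types") <- attr(cohort$metadata, "variable_types")
  aassoc <- alpha_association(alpha, md, covariates = c("age", "bmi"))
  utils::write.table(aassoc, out("alpha_association.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  log_stage("betatest")
  beta_rows <- list()
  dms <- list()
  for (metric in config$beta_metrics) {
    dm <- beta_diversity(rar$table, metric, tree = cohort$tree)
    dms[[metric]] <- dm
    for (method in config$beta_methods) {
      beta_rows[[paste(metric, method)]] <- permutation_beta_test(
        dm, md, "nugent_class", method = method, n_perm = config$n_perm,
        seed = config$seed)
    }
  }
  beta_res <- do.call(rbind, beta_rows)
  utils::write.table(beta_res, out("beta_tests.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  log_stage("associate")
  assoc <- taxon_association(rar$table, md, "nugent_class",
                             covariates = c("age", "bmi"))
  utils::write.table(assoc, out("taxon_association.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  panel <- key_taxa(list(assoc), fdr_max = config$fdr_max)
  if (length(panel) < 4) {
    panel <- utils::head(order(-colMeans(to_relative(filt))), 8)
    panel <- colnames(filt$counts)[panel]
  }

  log_stage("network")
  rho <- sparcc(filt, n_inner = config$sparcc_n_inner, seed = config$seed)
  pv <- sparcc_pvalues(filt, rho, n_boot = config$sparcc_n_boot,
                       n_inner = 5, seed = config$seed)
  net <- build_network(sparcc_result(rho, pv), colMeans(to_relative(filt)),
                       p_max = config$network_p_max,
                       min_abs_cor = config$network_min_abs_cor)
  write_network(net, out("network_edges.tsv"), out("network_nodes.tsv"))

  log_stage("vagitype")
  rel <- to_relative(filt)
  k <- config$nmf_k
  if (is.null(k)) {
    rk <- select_rank(rel[, panel, drop = FALSE], config$nmf_k_min,
                      min(config$nmf_k_max, length(panel)),
                      seed = config$seed, n_restarts = config$nmf_restarts)
    k <- rk$k
    utils::write.table(rk$diagnostics, out("vagitype_rank.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  model <- define_vagitypes(rel, k, key_taxa = panel, seed = config$seed,
                            n_restarts = config$nmf_restarts)
  write_vagitype_model(model, out("vagitype_model.json"))
  assign <- assign_by_centroid(rel, model)
  utils::write.table(assign, out("vagitype_assignments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  log_stage("mediate")
  med_data <- cohort$metadata
  med_data$age_z <- as.numeric(scale(med_data$age))
  outc <- log2_tss(to_relative(filt))
  med <- screen_mediations(med_data, "age_z", "parity",
                           outc[, utils::head(panel, 3), drop = FALSE],
                           n_boot = config$mediation_n_boot,
                           seed = config$seed)
  utils::write.table(med, out("mediation.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)

  log_stage("outcomes")
  outcome_res <- NULL
  if (config$simulate) {
    spec <- synthetic_spec(n_samples = config$n_samples, seed = config$seed)
    ivf <- generate_outcomes(cohort$true_labels, cohort$metadata, spec)
    asg <- assign$assigned_type
    names(asg) <- assign$sample
    ok <- !is.na(asg[ivf$sample_id])
    ref <- config$outcome_reference %||%
      names(sort(table(asg[ivf$sample_id][ok])))[1]
    outcome_res <- vagitype_outcome_model(
      asg[ivf$sample_id][ok], ivf$live_birth[ok],
      cohort$metadata[ivf$sample_id[ok], ], reference = ref)
    utils::write.table(outcome_res$rates, out("outcome_rates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(outcome_res$model, out("outcome_model.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    package = "vagitools",
    version = as.character(utils::packageVersion("vagitools")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), tz = "UTC"),
    seed = config$seed,
    config = unclass(config),
    n_samples = nrow(cohort$table$counts),
    n_taxa_filtered = ncol(filt$counts),
    discarded_by_rarefaction = rar$discarded_samples,
    key_taxa = panel,
    chosen_k = k)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(list(cohort = cohort, filtered = filt, rarefied = rar,
                 alpha = alpha, beta = beta_res, association = assoc,
                 network = net, vagitype_model = model,
                 assignments = assign, mediation = med,
                 outcomes = outcome_res, manifest = manifest))
}
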