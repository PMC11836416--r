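#' Construct a feature table
#'
#' A feature table holds a non-negative integer count matrix with samples as
#' rows and taxa as columns, plus an optional taxonomy map. It is the
#' universal input of the pipeline.
#'
#' @param counts numeric matrix (samples x taxa) of non-negative counts with
#'   unique row and column names.
#' @param taxonomy optional data.frame of ranked labels, one row per taxon
#'   (rownames are taxon ids).
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop2("counts must have sample rownames and taxon colnames")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop2("sample and taxon ids must be unique")
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop2("counts must be finite and non-negative")
  }
  if (any(counts != round(counts))) {
    stop2("counts must be integers")
  }
  storage.mode(counts) <- "double"
  if (!is.null(taxonomy)) {
    taxonomy <- as.data.frame(taxonomy)
    if (!all(colnames(counts) %in% rownames(taxonomy))) {
      stop2("taxonomy must cover every taxon in the table")
    }
    taxonomy <- taxonomy[colnames(counts), , drop = FALSE]
  }
  structure(list(counts = counts, taxonomy = taxonomy),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("feature_table: %d samples x %d taxa, total reads %s\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$counts)

sample_ids <- function(table) rownames(table$counts)
taxon_ids <- function(table) colnames(table$counts)

#' Filter taxa by total count and prevalence
#'
#' Retains exactly the taxa whose total count across samples is at least
#' `min_total` and whose prevalence (fraction of samples with a nonzero
#' count) is at least `min_prevalence`; by default taxa with an absolute
#' count sum below 50 or prevalence below 1% are excluded. Both criteria are
#' evaluated on the original table simultaneously; the sample axis is never
#' changed.
#'
#' @param table a [feature_table()].
#' @param min_total minimum total count (inclusive).
#' @param min_prevalence minimum presence fraction (inclusive).
#' @return a filtered `feature_table`.
#' @export
filter_features <- function(table, min_total = 50, min_prevalence = 0.01) {
  stopifnot(inherits(table, "feature_table"))
  totals <- colSums(table$counts)
  prev <- colMeans(table$counts > 0)
  keep <- totals >= min_total & prev >= min_prevalence
  if (!any(keep)) {
    stop2("no features retained: every taxon fails the count/prevalence filter")
  }
  feature_table(table$counts[, keep, drop = FALSE],
                taxonomy = if (is.null(table$taxonomy)) NULL else
                  table$taxonomy[keep, , drop = FALSE])
}

#' Rarefy a feature table to even depth
#'
#' Subsamples each sample's counts uniformly without replacement
#' (multivariate hypergeometric) to `depth` reads. Samples whose total is
#' below `depth` are dropped and reported.
#'
#' @param table a [feature_table()].
#' @param depth target depth (default 10,000 reads).
#' @param seed integer seed controlling the subsampling.
#' @return list with `table` (rarefied `feature_table`) and
#'   `discarded_samples` (character vector of dropped sample ids).
#' @export
rarefy <- function(table, depth = 10000, seed) {
  stopifnot(inherits(table, "feature_table"), depth > 0)
  totals <- rowSums(table$counts)
  discard <- sample_ids(table)[totals < depth]
  keep <- table$counts[totals >= depth, , drop = FALSE]
  if (nrow(keep) == 0L) {
    stop2("all samples fall below the rarefaction depth")
  }
  rare <- with_seed(split_seed(seed, "rarefy"), {
    # rrarefy warns when a table has no low counts (suspecting normalized
    # data); integer counts are already enforced by feature_table()
    suppressWarnings(vegan::rrarefy(keep, depth))
  })
  list(table = feature_table(rare, taxonomy = table$taxonomy),
       discarded_samples = discard)
}

#' Convert counts to relative abundance
#'
#' Total-sum scaling: each sample's counts divided by its library size.
#'
#' @param table a [feature_table()].
#' @return numeric matrix (samples x taxa) whose rows sum to 1.
#' @export
to_relative <- function(table) {
  stopifnot(inherits(table, "feature_table"))
  totals <- rowSums(table$counts)
  if (any(totals == 0)) {
    stop2("zero-total sample(s): ",
          paste(sample_ids(table)[totals == 0], collapse = ", "))
  }
  table$counts / totals
}

#' Identify the core microbiome
#'
#' Taxa present (count > 0) in strictly more than `prevalence_threshold` of
#' the samples, with per-taxon prevalence, median relative abundance and
#' share of total reads, plus the summed median relative abundance of the
#' core set.
#'
#' @param table a [feature_table()].
#' @param prevalence_threshold strict prevalence cut (default 0.9,
#'   i.e. "more than 90% of individuals").
#' @return list with `core` (data.frame: taxon, prevalence,
#'   median_rel_abundance, total_read_share) and `core_median_share`
#'   (sum of the core taxa's median relative abundances).
#' @export
core_taxa <- function(table, prevalence_threshold = 0.9) {
  stopifnot(inherits(table, "feature_table"))
  rel <- to_relative(table)
  prev <- colMeans(table$counts > 0)
  med <- apply(rel, 2, stats::median)
  share <- colSums(table$counts) / sum(table$counts)
  keep <- prev > prevalence_threshold
  core <- data.frame(taxon = taxon_ids(table)[keep],
                     prevalence = unname(prev[keep]),
                     median_rel_abundance = unname(med[keep]),
                     total_read_share = unname(share[keep]),
                     stringsAsFactors = FALSE)
  core <- core[order(-core$median_rel_abundance), , drop = FALSE]
  rownames(core) <- NULL
  list(core = core, core_median_share = sum(core$median_rel_abundance))
}

#' Read a tab-separated count matrix as a feature table
#'
#' @param path TSV file; first column holds ids, remaining columns counts.
#' @param samples_as_rows if `TRUE` (default) rows are samples; otherwise
#'   the matrix is transposed on read.
#' @param taxonomy_path optional TSV (taxon_id + rank columns).
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, samples_as_rows = TRUE,
                               taxonomy_path = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  if (!samples_as_rows) m <- t(m)
  tax <- NULL
  if (!is.null(taxonomy_path)) {
    td <- utils::read.delim(taxonomy_path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    tax <- td[, -1, drop = FALSE]
    rownames(tax) <- td[[1]]
  }
  feature_table(m, taxonomy = tax)
}

#' Write a feature table as TSV
#'
#' @param table a [feature_table()].
#' @param path output file; samples are rows, first column `sample_id`.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(sample_id = sample_ids(table),
                   table$counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
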