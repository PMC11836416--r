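#' Yue and Clayton theta community similarity
#'
#' theta = sum(a b) / (sum(a^2) + sum(b^2) - sum(a b)) on relative
#' abundances over a shared taxon axis; 1 for identical communities, 0 for
#' completely disjoint ones. Inputs are renormalized internally.
#'
#' @param a,b non-negative vectors on the same taxon axis, each with
#'   positive total.
#' @return theta in [0, 1].
#' @export
yue_clayton_theta <- function(a, b) {
  if (length(a) != length(b)) stop2("a and b must share a taxon axis")
  if (any(a < 0) || any(b < 0)) stop2("proportions must be non-negative")
  sa <- sum(a); sb <- sum(b)
  if (sa == 0 && sb == 0) stop2("both communities are empty")
  if (sa == 0 || sb == 0) return(0)
  a <- a / sa; b <- b / sb
  ab <- sum(a * b)
  ab / (sum(a^2) + sum(b^2) - ab)
}

#' Define community types ("Vagitypes") by NMF
#'
#' Fits NMF of the key-taxon relative abundances at rank `k`, assigns each
#' sample to its dominant-coefficient type, derives per-type marker taxa
#' from the basis loadings, builds reference centroids as the per-type mean
#' key-taxon relative abundance, and names each type after its centroid's
#' dominant taxon. Empty types (no assigned samples) are dropped with a
#' flag.
#'
#' @param rel relative-abundance matrix (samples x taxa) restricted to (or
#'   containing) the key-taxon panel.
#' @param k number of types.
#' @param key_taxa ordered panel of key taxa (default: all columns of
#'   `rel`).
#' @param seed integer seed for the NMF restarts.
#' @param n_restarts NMF restarts (default 30).
#' @param n_markers marker taxa listed per type (default 5).
#' @return object of class `vagitype_model`: `k`, `key_taxa`, `basis`,
#'   `coefficients`, `centroids`, `marker_taxa`, `type_labels`,
#'   `assignments` (named vector of type labels), `dropped_types`.
#' @export
define_vagitypes <- function(rel, k, key_taxa = colnames(rel), seed = 1L,
                             n_restarts = 30, n_markers = 5) {
  miss <- setdiff(key_taxa, colnames(rel))
  if (length(miss)) stop2("key taxa absent from table: ",
                          paste(utils::head(miss, 5), collapse = ", "))
  x <- rel[, key_taxa, drop = FALSE]
  fit <- nmf_fit(x, k, seed = seed, n_restarts = n_restarts)
  cl <- dominant_type(fit$coefficients, fit$basis)
  present <- sort(unique(cl))
  dropped <- setdiff(seq_len(k), present)
  centroids <- t(vapply(present, function(t) {
    colMeans(x[cl == t, , drop = FALSE])
  }, numeric(ncol(x))))
  dominant <- key_taxa[max.col(centroids, ties.method = "first")]
  labels <- make.unique(paste0(dominant, "-dominated"), sep = "_")
  rownames(centroids) <- labels
  markers <- lapply(present, function(t) {
    key_taxa[order(-fit$basis[t, ])][seq_len(min(n_markers, ncol(x)))]
  })
  names(markers) <- labels
  assignments <- labels[match(cl, present)]
  names(assignments) <- rownames(rel)
  structure(list(k = length(present), key_taxa = key_taxa,
                 basis = fit$basis[present, , drop = FALSE],
                 coefficients = fit$coefficients,
                 centroids = centroids, marker_taxa = markers,
                 type_labels = labels, assignments = assignments,
                 dropped_types = dropped, objective = fit$objective),
            class = "vagitype_model")
}

#' @export
print.vagitype_model <- function(x, ...) {
  cat(sprintf("vagitype_model: %d types over %d key taxa\n",
              x$k, length(x$key_taxa)))
  cat(paste0("  ", x$type_labels, collapse = "\n"), "\n")
  invisible(x)
}

#' Assign samples to Vagitypes by nearest theta centroid
#'
#' Each sample's relative abundances are projected onto the model's
#' key-taxon panel (missing taxa contribute 0; extra taxa are ignored),
#' Yue-Clayton theta is computed against every centroid, and the sample is
#' assigned to the most similar type. Exact ties are broken by centroid
#' order and flagged; samples with zero mass on the panel are
#' "unclassifiable".
#'
#' @param rel matrix (samples x taxa) or a single named vector of relative
#'   abundances.
#' @param model a `vagitype_model`.
#' @return data.frame: `sample`, `assigned_type`, `theta`, `tie_flag`,
#'   `unclassifiable`, plus a `theta_all` matrix attribute (samples x
#'   types).
#' @export
assign_by_centroid <- function(rel, model) {
  stopifnot(inherits(model, "vagitype_model"))
  if (is.null(dim(rel))) {
    rel <- matrix(rel, nrow = 1, dimnames = list("sample_1", names(rel)))
  }
  key <- model$key_taxa
  proj <- matrix(0, nrow(rel), length(key),
                 dimnames = list(rownames(rel), key))
  shared <- intersect(colnames(rel), key)
  if (length(shared) == 0) stop2("no key taxa present in the input")
  proj[, shared] <- rel[, shared, drop = FALSE]
  k <- nrow(model$centroids)
  theta_all <- matrix(NA_real_, nrow(rel), k,
                      dimnames = list(rownames(rel),
                                      rownames(model$centroids)))
  out <- data.frame(sample = rownames(rel),
                    assigned_type = NA_character_, theta = NA_real_,
                    tie_flag = FALSE, unclassifiable = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(proj))) {
    v <- proj[i, ]
    if (sum(v) == 0) {
      out$unclassifiable[i] <- TRUE
      next
    }
    th <- vapply(seq_len(k), function(j) {
      yue_clayton_theta(v, model$centroids[j, ])
    }, numeric(1))
    theta_all[i, ] <- th
    best <- which(th == max(th))
    out$assigned_type[i] <- rownames(model$centroids)[best[1]]
    out$theta[i] <- th[best[1]]
    out$tie_flag[i] <- length(best) > 1
  }
  attr(out, "theta_all") <- theta_all
  out
}

#' Serialize a Vagitype model to JSON
#'
#' @param model a `vagitype_model`.
#' @param path output JSON file.
#' @export
write_vagitype_model <- function(model, path) {
  stopifnot(inherits(model, "vagitype_model"))
  centroids <- lapply(seq_len(nrow(model$centroids)), function(i) {
    as.list(model$centroids[i, ])
  })
  names(centroids) <- rownames(model$centroids)
  obj <- list(k = model$k, key_taxa = model$key_taxa,
              type_labels = model$type_labels,
              centroids = centroids,
              marker_taxa = model$marker_taxa)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a Vagitype model written by [write_vagitype_model()]
#'
#' The deserialized model carries everything needed for
#' [assign_by_centroid()]; NMF factors are not persisted.
#'
#' @param path JSON file.
#' @return a `vagitype_model`.
#' @export
read_vagitype_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  centroids <- do.call(rbind, lapply(obj$centroids, function(r) {
    unlist(r)[obj$key_taxa]
  }))
  rownames(centroids) <- obj$type_labels
  colnames(centroids) <- obj$key_taxa
  structure(list(k = obj$k, key_taxa = obj$key_taxa,
                 basis = NULL, coefficients = NULL,
                 centroids = centroids,
                 marker_taxa = obj$marker_taxa,
                 type_labels = obj$type_labels,
                 assignments = NULL, dropped_types = integer(0)),
            class = "vagitype_model")
}
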