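#' Build a microbial co-occurrence network from SparCC results
#'
#' Keeps edges with p-value strictly below `p_max` and absolute correlation
#' strictly above `min_abs_cor`; detects modules by greedy modularity
#' maximization on the unweighted, sign-agnostic graph; computes degree,
#' closeness (within connected components, component-size normalized),
#' betweenness, the within-module degree z-score Zi, the participation
#' coefficient Pi, and topological roles using the 2.5 (Zi) and 0.62 (Pi)
#' thresholds.
#'
#' @param sparcc a [sparcc_result()].
#' @param abundances optional named vector of mean relative abundances.
#' @param p_max edge p-value cut (default 0.01, strict).
#' @param min_abs_cor absolute-correlation cut (default 0.1, strict).
#' @return object of class `microbial_network`: `graph` (igraph), `edges`
#'   (data.frame), `nodes` (data.frame with module, centralities, Zi, Pi,
#'   role), `empty` flag.
#' @export
build_network <- function(sparcc, abundances = NULL, p_max = 0.01,
                          min_abs_cor = 0.1) {
  stopifnot(inherits(sparcc, "sparcc_result"))
  taxa <- sparcc$taxa
  rho <- sparcc$correlation
  pm <- sparcc$p_value
  idx <- which(upper.tri(rho) & pm < p_max & abs(rho) > min_abs_cor,
               arr.ind = TRUE)
  edges <- data.frame(
    taxon_i = taxa[idx[, 1]], taxon_j = taxa[idx[, 2]],
    correlation = rho[idx], p_value = pm[idx],
    sign = ifelse(rho[idx] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("taxon_i", "taxon_j")], directed = FALSE,
    vertices = data.frame(name = taxa))
  empty <- nrow(edges) == 0L

  membership <- if (empty) {
    stats::setNames(seq_along(taxa), taxa)
  } else {
    igraph::membership(igraph::cluster_fast_greedy(g))
  }
  membership <- membership[taxa]

  deg <- igraph::degree(g)[taxa]
  btw <- igraph::betweenness(g)[taxa]
  comp <- igraph::components(g)$membership[taxa]
  clo <- vapply(taxa, function(v) {
    members <- taxa[comp == comp[v]]
    if (length(members) < 2) return(0)
    dmat <- igraph::distances(g, v = v, to = members)
    s <- sum(dmat[is.finite(dmat) & dmat > 0])
    if (s == 0) 0 else (length(members) - 1) / s *
      (length(members) - 1) / (length(taxa) - 1)
  }, numeric(1))

  zipi <- node_zi_pi(g, membership)
  nodes <- data.frame(
    taxon = taxa,
    abundance = if (is.null(abundances)) NA_real_ else
      unname(abundances[taxa]),
    module = as.integer(membership),
    degree = unname(deg), closeness = unname(clo),
    betweenness = unname(btw),
    zi = zipi$zi, pi = zipi$pi,
    stringsAsFactors = FALSE)
  nodes$role <- classify_roles(nodes$zi, nodes$pi)
  structure(list(graph = g, edges = edges, nodes = nodes, empty = empty,
                 params = list(p_max = p_max, min_abs_cor = min_abs_cor)),
            class = "microbial_network")
}

node_zi_pi <- function(g, membership) {
  taxa <- names(membership)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)[taxa, taxa,
                                                        drop = FALSE]
  k <- rowSums(adj)
  mods <- sort(unique(membership))
  # within-module degree per node and per-module degree split
  k_by_mod <- sapply(mods, function(m) {
    rowSums(adj[, membership == m, drop = FALSE])
  })
  if (is.null(dim(k_by_mod))) k_by_mod <- matrix(k_by_mod, ncol = length(mods))
  k_within <- k_by_mod[cbind(seq_along(taxa), match(membership, mods))]
  zi <- numeric(length(taxa))
  for (m in mods) {
    members <- membership == m
    mu <- mean(k_within[members])
    sdv <- stats::sd(k_within[members])
    zi[members] <- if (is.na(sdv) || sdv == 0) 0 else
      (k_within[members] - mu) / sdv
  }
  pi <- ifelse(k > 0, 1 - rowSums((k_by_mod / pmax(k, 1))^2), 0)
  list(zi = zi, pi = unname(pi))
}

#' Classify node topological roles from Zi and Pi
#'
#' Peripheral (Zi <= 2.5, Pi <= 0.62), connector (Zi <= 2.5, Pi > 0.62),
#' module hub (Zi > 2.5, Pi <= 0.62), network hub (Zi > 2.5, Pi > 0.62).
#'
#' @param zi within-module degree z-scores.
#' @param pi participation coefficients.
#' @param zi_threshold default 2.5.
#' @param pi_threshold default 0.62.
#' @return character vector of roles.
#' @export
classify_roles <- function(zi, pi, zi_threshold = 2.5, pi_threshold = 0.62) {
  ifelse(zi > zi_threshold,
         ifelse(pi > pi_threshold, "network hub", "module hub"),
         ifelse(pi > pi_threshold, "connector", "peripheral"))
}

#' Recompute role labels for an existing network
#'
#' @param network a `microbial_network`.
#' @inheritParams classify_roles
#' @return the network with updated `nodes$role`.
#' @export
node_roles <- function(network, zi_threshold = 2.5, pi_threshold = 0.62) {
  stopifnot(inherits(network, "microbial_network"))
  network$nodes$role <- classify_roles(network$nodes$zi, network$nodes$pi,
                                       zi_threshold, pi_threshold)
  network
}

#' Summarize a microbial network
#'
#' @param network a `microbial_network`.
#' @return list: `n_nodes`, `n_edges`, `mean_degree` (2 E / N),
#'   `positive_edge_fraction` (NA when edgeless), `hubs` (module and network
#'   hubs), `modularity` (greedy partition on the filtered graph).
#' @export
network_summary <- function(network) {
  stopifnot(inherits(network, "microbial_network"))
  n <- nrow(network$nodes)
  e <- nrow(network$edges)
  list(n_nodes = n, n_edges = e,
       mean_degree = if (n > 0) 2 * e / n else 0,
       positive_edge_fraction = if (e > 0)
         mean(network$edges$correlation > 0) else NA_real_,
       hubs = network$nodes$taxon[network$nodes$role %in%
                                    c("module hub", "network hub")],
       modularity = if (e > 0)
         igraph::modularity(network$graph,
                            network$nodes$module) else NA_real_)
}

#' Write a network as edge-list and node-table TSVs
#'
#' @param network a `microbial_network`.
#' @param edge_path,node_path output files.
#' @export
write_network <- function(network, edge_path, node_path) {
  utils::write.table(network$edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(network$nodes, node_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Read a network written by [write_network()]
#'
#' @param edge_path,node_path TSV files.
#' @return a `microbial_network` (graph rebuilt from the edge list).
#' @export
read_network <- function(edge_path, node_path) {
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE)
  nodes <- utils::read.delim(node_path, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("taxon_i", "taxon_j")], directed = FALSE,
    vertices = data.frame(name = nodes$taxon))
  structure(list(graph = g, edges = edges, nodes = nodes,
                 empty = nrow(edges) == 0L, params = list()),
            class = "microbial_network")
}
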