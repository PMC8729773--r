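# Topological indices of co-occurrence networks (NetworkAnalyzer-style
# definitions) and hub/keystone classification.

.as_graph <- function(network) {
  if (inherits(network, "coocc_network")) network$graph else network
}

#' Network density
#'
#' `2E / (N(N-1))`: the fraction of possible edges that are present;
#' zero for graphs with fewer than two nodes.
#'
#' @param network a `coocc_network` or igraph object.
#' @return density in `[0, 1]`.
#' @export
net_density <- function(network) {
  g <- .as_graph(network)
  n <- igraph::vcount(g)
  if (n < 2) return(0)
  2 * igraph::ecount(g) / (n * (n - 1))
}

#' Average number of neighbors
#'
#' Mean node degree, `2E / N`.
#'
#' @param network a `coocc_network` or igraph object.
#' @return mean degree (0 for an empty vertex set).
#' @export
avg_neighbors <- function(network) {
  g <- .as_graph(network)
  n <- igraph::vcount(g)
  if (n == 0) return(0)
  2 * igraph::ecount(g) / n
}

#' Degree mean and standard deviation
#'
#' @param network a `coocc_network` or igraph object.
#' @return list with `mean` and `sd` (sample sd; 0 for regular graphs).
#' @export
degree_stats <- function(network) {
  g <- .as_graph(network)
  k <- igraph::degree(g)
  list(mean = mean(k), sd = if (length(k) > 1) stats::sd(k) else 0)
}

#' Freeman degree centralization
#'
#' `sum(k_max - k_i) / ((N-1)(N-2))`: 1 for a star, 0 for any regular
#' graph; zero for graphs with fewer than three nodes.
#'
#' @param network a `coocc_network` or igraph object.
#' @return centralization in `[0, 1]`.
#' @export
centralization <- function(network) {
  g <- .as_graph(network)
  n <- igraph::vcount(g)
  if (n < 3) return(0)
  k <- igraph::degree(g)
  sum(max(k) - k) / ((n - 1) * (n - 2))
}

#' Network heterogeneity
#'
#' Coefficient of variation of the degree distribution,
#' `sqrt(var(k)) / mean(k)` with the population variance; 0 for regular
#' graphs.
#'
#' @param network a `coocc_network` or igraph object.
#' @return non-negative heterogeneity.
#' @export
heterogeneity <- function(network) {
  g <- .as_graph(network)
  k <- igraph::degree(g)
  if (!length(k) || mean(k) == 0) return(0)
  sqrt(mean(k^2) - mean(k)^2) / mean(k)
}

#' Average clustering coefficient and characteristic path length
#'
#' Average local clustering over all nodes (nodes of degree < 2
#' contribute 0) and the mean shortest-path length over connected node
#' pairs only (so disconnected components do not produce infinities).
#' A transitivity (global clustering) variant is available via
#' `clustering = "global"`.
#'
#' @param network a `coocc_network` or igraph object.
#' @param clustering `"local_average"` (default) or `"global"`.
#' @return list with `clustering_coefficient` and `avg_path_length`.
#' @export
clustering_and_path <- function(network,
                                clustering = c("local_average", "global")) {
  clustering <- match.arg(clustering)
  g <- .as_graph(network)
  cc <- if (igraph::vcount(g) == 0) {
    0
  } else if (clustering == "local_average") {
    mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
  } else {
    tg <- igraph::transitivity(g, type = "global")
    if (is.nan(tg)) 0 else tg
  }
  apl <- if (igraph::ecount(g) == 0) NA_real_ else
    igraph::mean_distance(g, unconnected = TRUE)
  list(clustering_coefficient = cc, avg_path_length = apl)
}

#' Percentage of positive edges
#'
#' `100 * n_positive / n_edges`, rounded to the nearest integer (half
#' away from zero). Requires a `sign` edge attribute.
#'
#' @param network a `coocc_network` or igraph object with edge signs.
#' @return integer percent (NA for an edgeless graph).
#' @export
positive_edge_fraction <- function(network) {
  g <- .as_graph(network)
  if (igraph::ecount(g) == 0) return(NA_real_)
  s <- igraph::E(g)$sign
  if (is.null(s)) stop("network has no 'sign' edge attribute")
  round_half_away(100 * sum(s > 0) / igraph::ecount(g))
}

#' Full topology summary
#'
#' All topological indices of a network in one record: node/edge
#' counts, positive/negative split, degree statistics, clustering,
#' centralization, path length, average neighbors, density and
#' heterogeneity.
#'
#' @param network a `coocc_network` or igraph object.
#' @param clustering passed to [clustering_and_path()].
#' @return data.frame with one row.
#' @export
topology_summary <- function(network, clustering = "local_average") {
  g <- .as_graph(network)
  ds <- degree_stats(g)
  cp <- clustering_and_path(g, clustering)
  s <- igraph::E(g)$sign
  n_pos <- if (is.null(s)) NA_integer_ else sum(s > 0)
  n_neg <- if (is.null(s)) NA_integer_ else sum(s < 0)
  data.frame(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    n_positive = n_pos,
    n_negative = n_neg,
    positive_pct = if (is.null(s)) NA_real_ else positive_edge_fraction(g),
    degree_mean = ds$mean,
    degree_sd = ds$sd,
    clustering_coefficient = cp$clustering_coefficient,
    centralization = centralization(g),
    avg_path_length = cp$avg_path_length,
    avg_neighbors = avg_neighbors(g),
    density = net_density(g),
    heterogeneity = heterogeneity(g)
  )
}

#' Topology comparison table across networks
#'
#' Stacks [topology_summary()] rows for several networks and adds
#' percent-change columns relative to a reference network. Percent
#' changes are computed from the unrounded index values and only then
#' rounded to the nearest integer.
#'
#' @param networks named list of `coocc_network`/igraph objects.
#' @param reference name of the reference network (default: first).
#' @return data.frame, one row per network, with `*_pct_change` columns.
#' @export
topology_table <- function(networks, reference = names(networks)[1]) {
  stopifnot(reference %in% names(networks))
  tab <- do.call(rbind, lapply(networks, topology_summary))
  tab <- cbind(network = names(networks), tab)
  rownames(tab) <- NULL
  idx_cols <- c("clustering_coefficient", "centralization",
                "avg_path_length", "avg_neighbors", "density",
                "heterogeneity")
  ref <- tab[tab$network == reference, ]
  for (col in idx_cols) {
    tab[[paste0(col, "_pct_change")]] <-
      round_half_away(100 * (tab[[col]] - ref[[col]]) / ref[[col]])
  }
  tab
}

#' Classify hub and keystone nodes
#'
#' Hubs are nodes whose degree lies strictly above the
#' `hub_quantile`-quantile of the degree distribution (default: top
#' quartile, "degree of connection > 75%"); keystones are hubs whose
#' betweenness centrality (Brandes algorithm, unweighted) also lies
#' strictly above the `keystone_quantile`-quantile of the betweenness
#' distribution. In a regular graph no node exceeds the quantile
#' strictly, so there are no hubs.
#'
#' @param network a `coocc_network` or igraph object.
#' @param hub_quantile degree quantile for hubs (default 0.75).
#' @param keystone_quantile betweenness quantile for keystones
#'   (default 0.75).
#' @return list with `hubs`, `keystones` (character id vectors),
#'   `nodes` (per-node degree and betweenness table) and
#'   `keystone_taxonomy` (shares of taxonomy labels among keystones, or
#'   NULL when no taxonomy is attached).
#' @export
classify_hubs_keystones <- function(network, hub_quantile = 0.75,
                                    keystone_quantile = 0.75) {
  g <- .as_graph(network)
  if (igraph::vcount(g) == 0) {
    return(list(hubs = character(0), keystones = character(0),
                nodes = data.frame(), keystone_taxonomy = NULL))
  }
  k <- igraph::degree(g)
  btw <- igraph::betweenness(g, weights = NA)
  ids <- igraph::V(g)$name %||% as.character(seq_along(k))
  hub_thr <- stats::quantile(k, hub_quantile, names = FALSE)
  key_thr <- stats::quantile(btw, keystone_quantile, names = FALSE)
  hubs <- ids[k > hub_thr]
  keystones <- ids[k > hub_thr & btw > key_thr]
  nodes <- data.frame(node = ids, degree = unname(k),
                      betweenness = unname(btw),
                      is_hub = ids %in% hubs,
                      is_keystone = ids %in% keystones,
                      stringsAsFactors = FALSE)
  tax <- igraph::V(g)$taxonomy
  keystone_taxonomy <- NULL
  if (!is.null(tax) && length(keystones) && !all(is.na(tax))) {
    tk <- tax[match(keystones, ids)]
    keystone_taxonomy <- 100 * table(tk) / length(tk)
  }
  list(hubs = hubs, keystones = keystones, nodes = nodes,
       keystone_taxonomy = keystone_taxonomy)
}
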