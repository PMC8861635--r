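#' Build the contact-site network
#'
#' Contact sites (beads participating in at least one contact) become nodes
#' and contacts become edges; beads without contacts are discarded. The only
#' three-contact arrangement that closes a triangle in this graph is the
#' *trefoil*: two concerted-series contacts enveloped by a concerted-parallel
#' contact, the configuration produced when two extruded loops meet at a
#' shared anchor.
#'
#' @param contacts a [ct_contacts].
#' @return an [igraph][igraph::graph] object; vertex names are 0-based bead
#'   indices.
#' @export
build_graph <- function(contacts) {
  stopifnot(inherits(contacts, "ct_contacts"))
  if (n_contacts(contacts) == 0L)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  edges <- rbind(as.character(contacts$i), as.character(contacts$j))
  igraph::graph_from_edgelist(t(edges), directed = FALSE)
}

#' Local clustering coefficient of one contact site
#'
#' `C_n = e_n / K_n` where `k_n` is the node degree,
#' `K_n = k_n (k_n - 1) / 2` the number of possible edges among its
#' neighbors, and `e_n` the number that exist. Nodes with fewer than two
#' neighbors have `K_n = 0` and are assigned `C_n = 0`.
#'
#' @param g graph from [build_graph()].
#' @param node bead index (0-based, as integer or character).
#' @export
local_clustering <- function(g, node) {
  node <- as.character(node)
  if (!node %in% igraph::V(g)$name) stop("unknown node: ", node)
  val <- igraph::transitivity(g, type = "localundirected", vids = node,
                              isolates = "zero")
  unname(val)
}

#' Average clustering coefficient of the contact network
#'
#' Unweighted mean of the local clustering coefficient over all nodes;
#' degree-<2 nodes contribute 0 (Watts-Strogatz convention). Nonzero values
#' arise only from trefoil configurations.
#'
#' @param g graph from [build_graph()].
#' @export
average_clustering <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  mean(igraph::transitivity(g, type = "localundirected", isolates = "zero"))
}

#' Count trefoil configurations (triangles) in the contact network
#' @param g graph from [build_graph()].
#' @export
count_trefoils <- function(g) {
  if (igraph::vcount(g) == 0L) return(0L)
  as.integer(sum(igraph::count_triangles(g)) / 3L)
}

#' Network connectivity (mean degree)
#'
#' Defined here as `2 |edges| / |nodes|`; reported as such since no other
#' formal definition is attached to the term in this context.
#'
#' @param g graph from [build_graph()].
#' @export
connectivity <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  2 * igraph::ecount(g) / igraph::vcount(g)
}

#' Classify cells into high/low clustering states
#'
#' @param per_cell_means numeric vector of per-cell average clustering
#'   coefficients.
#' @param threshold split point (default 0.02, the empirical boundary
#'   separating the two cell subpopulations); the comparison is inclusive,
#'   so a mean exactly at the threshold is labeled `"high"`.
#' @return character vector of `"high"` / `"low"` labels.
#' @export
classify_clustering_state <- function(per_cell_means, threshold = 0.02) {
  if (any(!is.finite(per_cell_means))) stop("values must be finite")
  ifelse(per_cell_means >= threshold, "high", "low")
}

#' Write the contact network as an edge-list TSV (1-based bead indices)
#' @param g graph from [build_graph()].
#' @param path output file.
#' @export
write_graph_tsv <- function(g, path) {
  el <- igraph::as_edgelist(g)
  df <- data.frame(from = as.integer(el[, 1L]) + 1L,
                   to = as.integer(el[, 2L]) + 1L)
  write_tsv_plain(df, path)
}

#' Summarize the contact network as a report list
#'
#' @param g graph from [build_graph()].
#' @return list with per-node clustering, average clustering, trefoil count
#'   and connectivity, suitable for JSON export.
#' @export
network_report <- function(g) {
  if (igraph::vcount(g) == 0L) stop("empty graph")
  per_node <- igraph::transitivity(g, type = "localundirected",
                                   isolates = "zero")
  names(per_node) <- igraph::V(g)$name
  list(per_node = as.list(per_node),
       average = mean(per_node),
       trefoils = count_trefoils(g),
       connectivity = connectivity(g))
}
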