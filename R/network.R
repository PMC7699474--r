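#' Largest-connected-component summary of an interaction network
#'
#' Extracts the maximum-cardinality connected component (ties broken by the
#' lexicographically smallest member), its mean degree (2E/V over the
#' induced subgraph) and its hubs (nodes whose within-component degree
#' reaches `hub_degree`).
#'
#' @param graph An undirected simple [igraph::igraph] with named vertices.
#' @param hub_degree Degree threshold for hub status (default 10).
#' @return List with `component` (sorted member names), `size`,
#'   `mean_degree`, `n_edges`, `hubs`, `hub_count`.
#' @export
largest_component_summary <- function(graph, hub_degree = 10) {
  assert_that(igraph::vcount(graph) > 0, "empty graph")
  comp <- igraph::components(graph)
  best_size <- max(comp$csize)
  cand <- which(comp$csize == best_size)
  members <- lapply(cand, function(ci)
    sort(names(comp$membership)[comp$membership == ci]))
  firsts <- vapply(members, `[[`, "", 1)
  nodes <- members[[which(firsts == min(firsts))[1]]]
  sub <- igraph::induced_subgraph(graph, nodes)
  e <- igraph::ecount(sub)
  deg <- igraph::degree(sub)
  hubs <- sort(names(deg)[deg >= hub_degree])
  list(component = nodes,
       size = length(nodes),
       n_edges = as.integer(e),
       mean_degree = 2 * e / length(nodes),
       hubs = hubs,
       hub_count = length(hubs))
}

#' Fraction of a gene list captured by its largest induced component
#'
#' Induces the subgraph of `graph` on the gene list and reports the share
#' of the full list (including members absent from the graph) inside the
#' largest connected component. Components need at least two nodes to
#' count: an isolated gene interacts with nothing, so an edgeless induced
#' subgraph retains 0%.
#'
#' @param genes Non-empty character vector of gene ids.
#' @param graph An undirected [igraph::igraph].
#' @return List with `n_list`, `n_in_graph`, `component_size`, `fraction`
#'   (exact) and `percent` (rounded to the nearest integer for display).
#' @export
component_retention <- function(genes, graph) {
  assert_that(length(genes) > 0, "empty gene list")
  present <- intersect(genes, igraph::V(graph)$name)
  if (length(present) == 0) {
    message("no list gene is present in the graph; retention is 0")
    size <- 0L
  } else {
    sub <- igraph::induced_subgraph(graph, present)
    comp <- igraph::components(sub)
    size <- max(comp$csize)
    if (size < 2) size <- 0L  # isolated nodes are not a connected component
  }
  fraction <- size / length(genes)
  list(n_list = length(genes),
       n_in_graph = length(present),
       component_size = as.integer(size),
       fraction = fraction,
       percent = round(100 * fraction))
}

#' Subset a gene list to the interactants of a hub
#'
#' Returns the members of `genes` adjacent to `hub` in the graph, intended
#' to feed [stratum_distribution()] or [bivalent_enrichment_test()] for
#' hub-interactant analyses (e.g. the ploidy-responsive interactants of a
#' master regulator).
#'
#' @param genes Character vector of gene ids.
#' @param graph An undirected [igraph::igraph].
#' @param hub A single gene id present in the graph.
#' @return Character vector, the sublist of `genes` adjacent to `hub`.
#' @export
neighbor_subset <- function(genes, graph, hub) {
  assert_that(length(hub) == 1 && hub %in% igraph::V(graph)$name,
              "hub '%s' is not present in the graph", hub)
  nbrs <- igraph::as_ids(igraph::neighbors(graph, hub))
  genes[genes %in% nbrs]
}
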