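#' Build a molecular-interaction graph from a typed edge list
#'
#' Undirected graph over protein/gene ids. Self-loops are dropped and
#' duplicate rows collapse to one edge per unordered pair and interaction
#' type; edge attributes (`type`, `evidence`) are retained from the first
#' occurrence. Queries are invariant to edge-list row order and
#' duplication.
#'
#' @param edges data.frame with columns `node_a`, `node_b` and optionally
#'   `type` (one of protein-protein, protein-DNA, protein-RNA, genetic) and
#'   `evidence`.
#' @return an object of class `interaction_graph` wrapping an
#'   [igraph::graph_from_data_frame()] graph.
#' @export
build_graph <- function(edges) {
  if (!is.data.frame(edges) || !all(c("node_a", "node_b") %in% names(edges)))
    stop("edge list must have columns `node_a` and `node_b`")
  if (any(!nzchar(edges$node_a) | !nzchar(edges$node_b)) ||
      anyNA(edges$node_a) || anyNA(edges$node_b))
    stop("malformed edge row: empty node id")
  if (!"type" %in% names(edges))
    edges$type <- rep("protein-protein", nrow(edges))
  if (!"evidence" %in% names(edges))
    edges$evidence <- rep(NA_character_, nrow(edges))
  edges <- edges[edges$node_a != edges$node_b, , drop = FALSE]
  if (nrow(edges)) {
    a <- pmin(edges$node_a, edges$node_b)
    b <- pmax(edges$node_a, edges$node_b)
    keep <- !duplicated(paste(a, b, edges$type, sep = "\r"))
    edges <- data.frame(node_a = a[keep], node_b = b[keep],
                        type = edges$type[keep],
                        evidence = edges$evidence[keep],
                        stringsAsFactors = FALSE)
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  structure(list(graph = g), class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("interaction_graph: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

# internal: optionally restrict a graph to edges of given type(s)
filter_type <- function(g, type) {
  if (is.null(type)) return(g$graph)
  igraph::subgraph_from_edges(g$graph,
                              which(igraph::E(g$graph)$type %in% type),
                              delete.vertices = FALSE)
}

#' Nodes of an interaction graph
#' @param g an `interaction_graph`.
#' @return sorted character vector of node ids.
#' @export
graph_nodes <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  sort(igraph::V(g$graph)$name)
}

#' Common interactants of a protein pair
#'
#' The nodes adjacent to both `a` and `b`, excluding `a` and `b`
#' themselves — the "via how many common interactants are these two
#' connected" query. Symmetric in (a, b).
#'
#' @param g an `interaction_graph`.
#' @param a,b node ids present in the graph.
#' @param type optional interaction type(s) to restrict to (default: all
#'   types are mixed, as the source queries do).
#' @return sorted character vector of shared neighbor ids.
#' @export
common_interactants <- function(g, a, b, type = NULL) {
  stopifnot(inherits(g, "interaction_graph"))
  gr <- filter_type(g, type)
  missing <- setdiff(c(a, b), igraph::V(gr)$name)
  if (length(missing))
    stop("unknown node(s): ", paste(missing, collapse = ", "))
  na <- igraph::neighbors(gr, a)$name
  nb <- igraph::neighbors(gr, b)$name
  sort(setdiff(intersect(na, nb), c(a, b)))
}

#' High-degree nodes ("hubs")
#'
#' Nodes whose degree is unusually high. Default rule: degree strictly
#' exceeding the mean degree plus one population SD over all nodes (so a
#' regular graph has no hubs); an overridable convention, since the source
#' names its hubs without stating a rule. An explicit `min_degree` is an
#' inclusive cut-off.
#'
#' @param g an `interaction_graph`.
#' @param min_degree explicit degree threshold (inclusive); overrides the
#'   default rule.
#' @param type optional interaction type filter.
#' @return sorted character vector of hub node ids (possibly empty).
#' @export
hubs <- function(g, min_degree = NULL, type = NULL) {
  stopifnot(inherits(g, "interaction_graph"))
  gr <- filter_type(g, type)
  if (!igraph::vcount(gr)) stop("empty graph")
  deg <- igraph::degree(gr)
  keep <- if (is.null(min_degree))
    deg > mean(deg) + sqrt(mean((deg - mean(deg))^2))
  else deg >= min_degree
  sort(names(deg)[keep])
}

#' Export a graph as plain node/edge tables
#'
#' @param g an `interaction_graph`.
#' @return list with `nodes` (data.frame: id, degree) and `edges`
#'   (data.frame: node_a, node_b, type, evidence), suitable for TSV export
#'   or external viewers.
#' @export
graph_tables <- function(g) {
  stopifnot(inherits(g, "interaction_graph"))
  ed <- igraph::as_data_frame(g$graph, what = "edges")
  names(ed)[1:2] <- c("node_a", "node_b")
  deg <- igraph::degree(g$graph)
  list(nodes = data.frame(id = names(deg), degree = unname(deg),
                          stringsAsFactors = FALSE),
       edges = ed)
}
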