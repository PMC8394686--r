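#' Directed causal graph over channels
#'
#' @param nodes character vector of node labels (unique).
#' @param edges data.frame with columns `source`, `target` and optionally
#'   `weight`; ordered pairs, self-loops forbidden, endpoints drawn from
#'   `nodes`. Duplicate ordered pairs are rejected.
#' @return object of class `causal_graph` with fields `nodes` and `edges`.
#' @export
causal_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node labels must be unique")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(source = character(0), target = character(0),
                        weight = numeric(0))
  } else {
    edges <- as.data.frame(edges)
    stopifnot(all(c("source", "target") %in% names(edges)))
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    if (!"weight" %in% names(edges)) edges$weight <- NA_real_
    edges <- edges[, c("source", "target", "weight")]
    bad <- setdiff(c(edges$source, edges$target), nodes)
    if (length(bad))
      stop("edge endpoint(s) not among nodes: ", paste(bad, collapse = ", "))
    if (any(edges$source == edges$target))
      stop("self-loops are not allowed")
    if (anyDuplicated(edges[, c("source", "target")]))
      stop("duplicate edges are not allowed")
    rownames(edges) <- NULL
  }
  structure(list(nodes = nodes, edges = edges), class = "causal_graph")
}

#' @export
print.causal_graph <- function(x, ...) {
  cat("<causal_graph> ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  if (nrow(x$edges))
    cat(" ", paste(x$edges$source, "->", x$edges$target, collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Convert a causal graph to an igraph object
#' @param graph a [causal_graph()]
#' @return a directed `igraph` graph with the same vertices and edges.
#' @export
as_igraph <- function(graph) {
  stopifnot(inherits(graph, "causal_graph"))
  igraph::graph_from_data_frame(graph$edges, directed = TRUE,
                                vertices = data.frame(name = graph$nodes))
}

#' Out-degree of nodes
#'
#' Number of directed edges leaving each node; the importance criterion used
#' throughout the package.
#'
#' @param graph a [causal_graph()]
#' @param node optional single node label; if omitted, a named vector over
#'   all nodes is returned.
#' @return integer (vector).
#' @export
out_degree <- function(graph, node = NULL) {
  deg <- igraph::degree(as_igraph(graph), mode = "out")
  storage.mode(deg) <- "integer"
  if (is.null(node)) return(deg)
  node <- as.character(node)
  if (!node %in% graph$nodes) stop("unknown node: ", node)
  unname(deg[node])
}

#' In-degree of nodes (for reporting)
#' @inheritParams out_degree
#' @return integer (vector).
#' @export
in_degree <- function(graph, node = NULL) {
  deg <- igraph::degree(as_igraph(graph), mode = "in")
  storage.mode(deg) <- "integer"
  if (is.null(node)) return(deg)
  node <- as.character(node)
  if (!node %in% graph$nodes) stop("unknown node: ", node)
  unname(deg[node])
}

#' Important nodes by maximal out-degree
#'
#' All nodes attaining the maximum out-degree. A graph without edges has no
#' important node (an "important" node must point somewhere).
#'
#' @param graph a nonempty [causal_graph()]
#' @return character vector (possibly empty).
#' @export
important_nodes <- function(graph) {
  stopifnot(inherits(graph, "causal_graph"))
  if (length(graph$nodes) == 0) stop("graph has no nodes")
  if (nrow(graph$edges) == 0) return(character(0))
  deg <- out_degree(graph)
  names(deg)[deg == max(deg) & deg > 0]
}

#' Reciprocal (feedback) pairs
#'
#' All unordered pairs {u, v} with both u -> v and v -> u present: the
#' 2-cycle "feedback" signature that, after hub removal, is read as evidence
#' of an unobserved common driver.
#'
#' @param graph a [causal_graph()]
#' @return character matrix with 2 columns, one row per pair, each row
#'   sorted; zero rows when the graph has no 2-cycle.
#' @export
two_cycles <- function(graph) {
  g <- as_igraph(graph)
  out <- matrix(character(0), ncol = 2,
                dimnames = list(NULL, c("node1", "node2")))
  if (igraph::ecount(g) == 0) return(out)
  mut <- igraph::which_mutual(g)
  if (!any(mut)) return(out)
  ends <- igraph::as_edgelist(g)[mut, , drop = FALSE]
  pairs <- unique(t(apply(ends, 1, sort)))
  colnames(pairs) <- c("node1", "node2")
  pairs
}
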