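#' Load a protein/RNA interaction network from an edge list
#'
#' Two-column TSV (or data frame) of interacting molecule names. A collapse
#' map merges the members of a stable complex into a single node (e.g.
#' Lsm1...Lsm7 into "Lsm1-7") before deduplication; edges internal to a
#' complex disappear, edges to outside partners are unioned. Undirected,
#' unweighted.
#'
#' @param edges Path to a TSV file (no header, two columns) or a two-column
#'   data frame.
#' @param collapse Optional named character vector mapping member -> complex
#'   node name, or a two-column data frame (member, complex).
#' @return A `connectivity_graph` wrapping an igraph object.
#' @export
load_edge_list <- function(edges, collapse = NULL) {
  if (is.character(edges) && length(edges) == 1L) {
    if (file.size(edges) == 0) {
      df <- data.frame(from = character(0), to = character(0))
    } else {
      df <- utils::read.table(edges, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE,
                              col.names = c("from", "to"))
    }
  } else {
    df <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (nrow(df)) names(df)[1:2] <- c("from", "to")
    else df <- data.frame(from = character(0), to = character(0))
  }
  df$from <- trimws(as.character(df$from))
  df$to <- trimws(as.character(df$to))
  self <- which(df$from == df$to)
  if (length(self)) {
    stop("self-loop in edge list at row(s): ", paste(self, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(collapse)) {
    if (is.data.frame(collapse)) {
      collapse <- stats::setNames(as.character(collapse[[2]]),
                                  as.character(collapse[[1]]))
    }
    map <- function(x) ifelse(x %in% names(collapse), collapse[x], x)
    df$from <- unname(map(df$from))
    df$to <- unname(map(df$to))
    # collapse-induced self-loops are internal complex edges: drop them
    df <- df[df$from != df$to, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  structure(list(graph = g), class = "connectivity_graph")
}

#' @export
print.connectivity_graph <- function(x, ...) {
  cat(sprintf("connectivity graph: %d nodes, %d edges\n",
              igraph::vcount(x$graph), igraph::ecount(x$graph)))
  invisible(x)
}

#' Valency: number of distinct interaction partners
#'
#' @param graph A `connectivity_graph`.
#' @param node Node name.
#' @return Integer degree.
#' @export
valency <- function(graph, node) {
  stopifnot(inherits(graph, "connectivity_graph"))
  if (!node %in% igraph::V(graph$graph)$name) {
    stop("unknown node: ", node, call. = FALSE)
  }
  unname(igraph::degree(graph$graph, v = node))
}

#' Eigenvector centrality by power iteration
#'
#' Dominant eigenvector of the adjacency matrix, computed by power
#' iteration on A + cI (a small spectral shift, c = 0.05 x max degree,
#' which leaves the eigenvectors unchanged while guaranteeing convergence
#' on bipartite components). Scores are nonnegative and L2-normalized over
#' the component on which they are computed.
#'
#' For disconnected graphs the component containing `component_of` (default:
#' the largest component, or the one containing a node named "RNA" if
#' present) is scored; all other nodes get 0.
#'
#' @param graph A `connectivity_graph`.
#' @param component_of Optional node name selecting the component to score.
#' @param tol Convergence tolerance on the L2 change per iteration.
#' @param max_iter Iteration cap.
#' @return Named numeric vector of centrality scores, one per node.
#' @export
eigenvector_centrality <- function(graph, component_of = NULL, tol = 1e-12,
                                   max_iter = 1e5) {
  stopifnot(inherits(graph, "connectivity_graph"))
  g <- graph$graph
  nodes <- igraph::V(g)$name
  if (length(nodes) == 0L) stop("graph is empty", call. = FALSE)
  comp <- igraph::components(g)
  target <- if (!is.null(component_of)) {
    if (!component_of %in% nodes) stop("unknown node: ", component_of,
                                       call. = FALSE)
    comp$membership[component_of]
  } else if ("RNA" %in% nodes) {
    comp$membership["RNA"]
  } else {
    which.max(comp$csize)
  }
  sel <- names(comp$membership)[comp$membership == target]
  scores <- stats::setNames(numeric(length(nodes)), nodes)
  A <- igraph::as_adjacency_matrix(igraph::induced_subgraph(g, sel),
                                   sparse = FALSE)
  m <- nrow(A)
  if (m == 1L) {
    scores[sel] <- 1
    return(scores)
  }
  shift <- 0.05 * max(rowSums(A))
  M <- A + diag(shift, m)
  v <- rep(1 / sqrt(m), m)
  for (i in seq_len(max_iter)) {
    w <- M %*% v
    w <- as.numeric(w) / sqrt(sum(w^2))
    if (sqrt(sum((w - v)^2)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  v <- abs(v) / sqrt(sum(v^2))
  scores[rownames(A)] <- v
  scores
}

#' Valency and centrality table for a network
#'
#' @param graph A `connectivity_graph`.
#' @return Data frame with `node`, `valency`, `centrality`, sorted by
#'   decreasing centrality.
#' @export
network_summary <- function(graph) {
  stopifnot(inherits(graph, "connectivity_graph"))
  nodes <- igraph::V(graph$graph)$name
  cen <- eigenvector_centrality(graph)
  out <- data.frame(node = nodes,
                    valency = unname(igraph::degree(graph$graph)),
                    centrality = unname(cen[nodes]))
  out[order(-out$centrality), ]
}
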