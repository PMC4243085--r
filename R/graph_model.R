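#' Construct a probability graph
#'
#' A probability graph (uncertain network) is a simple graph in which every
#' edge carries an existence probability in (0, 1]. It is the standard model
#' for confidence-scored biological interaction data: nodes are molecules
#' (proteins, genes), edges are putative interactions, and the probability
#' encodes the confidence that the interaction is real.
#'
#' @param edges a data.frame (or matrix) with three columns: source node
#'   label, target node label, and edge probability. Labels are coerced to
#'   character; probabilities must lie in (0, 1].
#' @param nodes optional character vector of node labels fixing the node
#'   order; defaults to first-appearance order in `edges`. Isolated nodes may
#'   be declared here.
#' @param directed logical; if `TRUE` edges are ordered pairs. Default
#'   `FALSE`.
#' @return an object of class `probability_graph` with elements `nodes`
#'   (character vector), `edges` (data.frame with columns `from`, `to`, `p`)
#'   and `directed`.
#' @examples
#' g <- probability_graph(data.frame(
#'   from = c("a", "b", "a"), to = c("b", "c", "c"),
#'   p = c(0.92, 0.97, 1.0)))
#' g
#' @export
probability_graph <- function(edges, nodes = NULL, directed = FALSE) {
  if (is.matrix(edges)) edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(), p = numeric(),
                        stringsAsFactors = FALSE)
  } else {
    if (ncol(edges) < 3L)
      stop("`edges` must have three columns: from, to, probability")
    edges <- data.frame(from = as.character(edges[[1L]]),
                        to = as.character(edges[[2L]]),
                        p = as.numeric(edges[[3L]]),
                        stringsAsFactors = FALSE)
  }
  if (is.null(nodes)) {
    nodes <- unique(c(rbind(edges$from, edges$to)))
  } else {
    nodes <- as.character(nodes)
    extra <- setdiff(unique(c(edges$from, edges$to)), nodes)
    if (length(extra))
      stop("edge endpoints not in declared nodes: ", paste(extra, collapse = ", "))
  }
  g <- structure(list(nodes = nodes, edges = edges, directed = isTRUE(directed)),
                 class = "probability_graph")
  validate_probability_graph(g)
  g
}

validate_probability_graph <- function(g) {
  if (length(g$nodes) < 1L) stop("a probability graph needs at least one node")
  if (anyDuplicated(g$nodes)) stop("duplicate node labels")
  e <- g$edges
  if (nrow(e)) {
    if (any(!is.finite(e$p)))
      stop("non-numeric or non-finite edge probability")
    bad <- which(e$p <= 0 | e$p > 1)
    if (length(bad))
      stop(sprintf("edge probability must lie in (0,1]; offending edge %s-%s (p=%g)",
                   e$from[bad[1L]], e$to[bad[1L]], e$p[bad[1L]]))
    loops <- which(e$from == e$to)
    if (length(loops))
      stop(sprintf("self-loop on node '%s' is not allowed", e$from[loops[1L]]))
    key <- if (g$directed) paste(e$from, e$to, sep = "\r") else
      paste(pmin(e$from, e$to), pmax(e$from, e$to), sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1L]
      rows <- which(key == d)
      msg <- if (length(unique(e$p[rows])) > 1L) "conflicting probabilities" else
        "duplicate edge"
      stop(sprintf("%s for edge %s-%s", msg, e$from[rows[1L]], e$to[rows[1L]]))
    }
  }
  invisible(g)
}

#' @export
print.probability_graph <- function(x, ...) {
  cat(sprintf("Probability graph: %d nodes, %d edges%s\n",
              length(x$nodes), nrow(x$edges),
              if (x$directed) " (directed)" else ""))
  if (nrow(x$edges)) {
    n <- min(nrow(x$edges), 10L)
    for (i in seq_len(n))
      cat(sprintf("  %s %s %s  p=%g\n", x$edges$from[i],
                  if (x$directed) "->" else "--", x$edges$to[i], x$edges$p[i]))
    if (nrow(x$edges) > n) cat(sprintf("  ... %d more edges\n", nrow(x$edges) - n))
  }
  invisible(x)
}

#' Number of nodes of a probability graph
#' @param g a `probability_graph`
#' @return integer node count
#' @export
n_nodes <- function(g) length(g$nodes)

#' Number of edges of a probability graph
#' @param g a `probability_graph`
#' @return integer edge count
#' @export
n_edges <- function(g) nrow(g$edges)

#' Read a probability network from an edge-list file
#'
#' Parses the canonical plain-text exchange format: one edge per line,
#' whitespace- or tab-separated fields `source target probability`, `#`
#' comment lines skipped. A header line is detected (and skipped) when its
#' third field does not parse as a number. This matches common exports of
#' confidence-weighted interaction networks.
#'
#' @param path path to the edge-list file.
#' @param directed logical; read edges as ordered pairs.
#' @return a [probability_graph].
#' @export
read_edge_list <- function(path, directed = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  from <- character(); to <- character(); p <- numeric()
  first_data <- TRUE
  for (i in keep) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (length(f) != 3L)
      stop(sprintf("line %d: expected 3 fields, got %d", i, length(f)))
    pv <- suppressWarnings(as.numeric(f[3L]))
    if (is.na(pv)) {
      if (first_data) { first_data <- FALSE; next }  # header line
      stop(sprintf("line %d: probability '%s' is not a number", i, f[3L]))
    }
    first_data <- FALSE
    if (pv <= 0 || pv > 1)
      stop(sprintf("line %d: probability %g outside (0,1]", i, pv))
    if (f[1L] == f[2L])
      stop(sprintf("line %d: self-loop on node '%s'", i, f[1L]))
    from <- c(from, f[1L]); to <- c(to, f[2L]); p <- c(p, pv)
  }
  probability_graph(data.frame(from = from, to = to, p = p,
                               stringsAsFactors = FALSE),
                    directed = directed)
}

#' Write a probability graph as an edge list
#'
#' Writes the same dialect [read_edge_list] reads. Probabilities are printed
#' with enough digits (`%.17g`) that reading the file back reproduces them
#' exactly.
#'
#' @param g a `probability_graph`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  lines <- sprintf("%s\t%s\t%.17g", g$edges$from, g$edges$to, g$edges$p)
  writeLines(lines, path)
  invisible(path)
}

#' Induced subgraph on a node subset
#'
#' Keeps the given nodes and every host edge whose endpoints both lie in the
#' subset, probabilities unchanged (induced-subgraph semantics, the standard
#' motif convention).
#'
#' @param g a `probability_graph`.
#' @param nodes character vector of node labels, a subset of `g$nodes`.
#' @return a `probability_graph` on `nodes` (in host node order).
#' @export
induced_subgraph <- function(g, nodes) {
  nodes <- as.character(nodes)
  unknown <- setdiff(nodes, g$nodes)
  if (length(unknown))
    stop("unknown node label(s): ", paste(unknown, collapse = ", "))
  nodes <- g$nodes[g$nodes %in% nodes]  # host order
  keep <- g$edges$from %in% nodes & g$edges$to %in% nodes
  probability_graph(g$edges[keep, , drop = FALSE], nodes = nodes,
                    directed = g$directed)
}

#' Probability adjacency matrix
#'
#' The probability adjacency matrix identifies a probability graph up to node
#' order: entry (i, j) is the probability of edge (i, j), 0 when absent, with
#' a zero diagonal. Symmetric for undirected graphs.
#'
#' @param g a `probability_graph`.
#' @param node_order permutation of `g$nodes` giving the row/column order;
#'   defaults to the graph's node order.
#' @return a numeric k x k matrix with `node_order` as dimnames.
#' @export
probability_adjacency <- function(g, node_order = g$nodes) {
  node_order <- as.character(node_order)
  if (length(node_order) != length(g$nodes) ||
      !setequal(node_order, g$nodes) || anyDuplicated(node_order))
    stop("`node_order` must be a permutation of the graph's nodes")
  k <- length(node_order)
  A <- matrix(0, k, k, dimnames = list(node_order, node_order))
  if (nrow(g$edges)) {
    i <- match(g$edges$from, node_order)
    j <- match(g$edges$to, node_order)
    A[cbind(i, j)] <- g$edges$p
    if (!g$directed) A[cbind(j, i)] <- g$edges$p
  }
  A
}

# Build a probability_graph back from an adjacency matrix (dimnames = labels).
graph_from_adjacency <- function(A, directed = FALSE) {
  labs <- rownames(A)
  if (is.null(labs)) labs <- as.character(seq_len(nrow(A)))
  if (directed) {
    idx <- which(A != 0, arr.ind = TRUE)
  } else {
    idx <- which(upper.tri(A) & A != 0, arr.ind = TRUE)
  }
  edges <- data.frame(from = labs[idx[, 1L]], to = labs[idx[, 2L]],
                      p = A[idx], stringsAsFactors = FALSE)
  probability_graph(edges, nodes = labs, directed = directed)
}

# Adjacency-list representation (list of integer neighbour vectors, by node
# index). Undirected view regardless of directed_flag (weak connectivity).
adjacency_list <- function(g) {
  k <- length(g$nodes)
  adj <- vector("list", k)
  for (v in seq_len(k)) adj[[v]] <- integer()
  if (nrow(g$edges)) {
    i <- match(g$edges$from, g$nodes)
    j <- match(g$edges$to, g$nodes)
    for (e in seq_along(i)) {
      adj[[i[e]]] <- c(adj[[i[e]]], j[e])
      adj[[j[e]]] <- c(adj[[j[e]]], i[e])
    }
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  adj
}

#' Is a probability graph connected?
#'
#' Connectivity of the underlying undirected graph (weak connectivity for
#' directed input).
#'
#' @param g a `probability_graph`.
#' @return logical.
#' @export
is_connected <- function(g) {
  k <- length(g$nodes)
  if (k == 1L) return(TRUE)
  adj <- adjacency_list(g)
  seen <- logical(k)
  stack <- 1L
  seen[1L] <- TRUE
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; stack <- c(stack, w) }
  }
  all(seen)
}
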