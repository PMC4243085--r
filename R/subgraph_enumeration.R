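#' Enumerate connected k-node induced subgraphs (ESU)
#'
#' Exact enumeration of every k-node subset of the host network that induces
#' a connected subgraph, each exactly once, using the ESU algorithm
#' (the FANMOD enumeration scheme): each node v starts an extension
#' restricted to neighbours with index greater than v, so every connected
#' subset is generated from its minimum-index node only. The order of the
#' output is deterministic given the host node order. For directed hosts
#' connectivity is taken on the underlying undirected graph.
#'
#' @param g a [probability_graph].
#' @param k subgraph scale (number of nodes), k >= 2.
#' @param max_instances safety cap; enumeration aborts with an error when
#'   more than this many subsets are produced. Default `Inf`.
#' @return list of character vectors, each the node labels (in host order)
#'   of one connected k-subgraph. Empty list when k > number of nodes.
#' @export
enumerate_connected_subgraphs <- function(g, k, max_instances = Inf) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop("k must be an integer >= 2")
  nv <- length(g$nodes)
  if (k > nv) return(list())
  adj <- adjacency_list(g)
  out <- vector("list", 256L)
  cnt <- 0L

  emit <- function(sub) {
    cnt <<- cnt + 1L
    if (cnt > max_instances)
      stop(sprintf("more than %g connected %d-subgraphs; raise `max_instances`",
                   max_instances, k))
    if (cnt > length(out)) length(out) <<- 2L * cnt  # grow geometrically
    out[[cnt]] <<- sub
  }

  # ESU recursion: `sub` current subset, `ext` extension candidates (all with
  # index > root and not adjacent to earlier-subset nodes), `root` the start.
  extend <- function(sub, ext, root) {
    if (length(sub) == k) { emit(sub); return(invisible()) }
    while (length(ext)) {
      w <- ext[1L]
      ext <- ext[-1L]
      # exclusive neighbourhood of w: neighbours > root, not in sub and not
      # already reachable from sub (i.e. not neighbours of sub)
      nb_sub <- unique(unlist(adj[sub]))
      excl <- setdiff(adj[[w]][adj[[w]] > root], c(sub, nb_sub))
      extend(c(sub, w), c(ext, excl), root)
    }
    invisible()
  }

  for (v in seq_len(nv)) {
    ext0 <- adj[[v]][adj[[v]] > v]
    extend(v, ext0, v)
  }
  lapply(out[seq_len(cnt)], function(idx) g$nodes[sort(idx)])
}

#' Does a connected subgraph contain a cycle?
#'
#' A connected graph on k nodes is a tree iff it has exactly k - 1 edges;
#' with k or more edges it contains at least one cycle ("non-tree").
#' Biologically characterized motifs are predominantly non-tree, so only
#' these are mined.
#'
#' @param x a [probability_graph] or a `subgraph_instance` (as produced by
#'   [collect_candidates]).
#' @return logical.
#' @export
is_nontree <- function(x) {
  g <- if (inherits(x, "probability_graph")) x else x$pattern
  nrow(g$edges) >= length(g$nodes)
}

#' Collect the candidate subgraph set
#'
#' Runs the connected-subgraph enumeration and keeps the non-tree instances:
#' the candidate set from which frequent probability patterns are mined.
#' Each instance records its host node labels and the induced probability
#' subgraph.
#'
#' @param g host [probability_graph].
#' @param k subgraph scale; must be >= 3 (the smallest non-tree subgraph is
#'   a triangle).
#' @param max_instances passed to [enumerate_connected_subgraphs].
#' @return an object of class `candidate_set`: list with `k` and
#'   `instances`, a list of `subgraph_instance` objects (fields
#'   `host_node_ids`, `pattern`).
#' @export
collect_candidates <- function(g, k, max_instances = Inf) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L)
    stop("k must be >= 3: the smallest non-tree subgraph is a triangle")
  subsets <- enumerate_connected_subgraphs(g, k, max_instances = max_instances)
  instances <- list()
  for (s in subsets) {
    pat <- induced_subgraph(g, s)
    if (is_nontree(pat))
      instances[[length(instances) + 1L]] <-
        structure(list(host_node_ids = s, pattern = pat),
                  class = "subgraph_instance")
  }
  structure(list(k = k, instances = instances), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("Candidate set: %d non-tree connected subgraphs of scale k=%d\n",
              length(x$instances), x$k))
  invisible(x)
}
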