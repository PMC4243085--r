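#' The four-node benchmark probability graph
#'
#' A small uncertain network used throughout the package's tests and
#' documentation: four nodes v1..v4 with edges (v1,v2) = 0.92,
#' (v2,v3) = 0.97, (v2,v4) = 0.94, (v3,v4) = 0.1, (v1,v4) = 1.0. It is
#' connected, non-tree (5 edges on 4 nodes) and asymmetric enough that all
#' four node voltage sequences differ, which makes it a convenient reference
#' case for the circuit machinery.
#'
#' @return a [probability_graph] on v1..v4.
#' @examples
#' node_voltage_sequence(example4_graph(), "v4")
#' @export
example4_graph <- function() {
  probability_graph(data.frame(
    from = c("v1", "v2", "v2", "v3", "v1"),
    to   = c("v2", "v3", "v4", "v4", "v4"),
    p    = c(0.92, 0.97, 0.94, 0.10, 1.00),
    stringsAsFactors = FALSE))
}

#' Generate a random uncertain network, optionally with planted patterns
#'
#' Emulates a sparse uncertain interaction network: a uniform random simple
#' graph on `n_nodes` nodes with `n_edges` edges in total, edge
#' probabilities drawn from `prob_law`. When a `pattern` is supplied,
#' `copies` disjoint node sets are reserved and each receives an exact copy
#' of the pattern's topology with every edge probability independently
#' perturbed by a uniform jitter in [-jitter, +jitter] and clipped to
#' [0.01, 1]; background edges are drawn only outside the planted node sets,
#' so each planted copy remains an exact induced occurrence. The planted
#' node sets are returned as ground truth.
#'
#' @param n_nodes number of nodes (labelled n1..nN).
#' @param n_edges total number of edges, planted edges included.
#' @param prob_law probability distribution of background edges:
#'   `"uniform"` on `(law_par[1], law_par[2]]` or `"beta"` with shape
#'   parameters `law_par`, truncated to (0.01, 1].
#' @param law_par numeric parameters of `prob_law` (default `c(0.5, 1)` for
#'   uniform — confidence-scored interactions are typically reported above
#'   0.5).
#' @param pattern optional [probability_graph] to plant.
#' @param copies number of disjoint planted copies.
#' @param jitter maximum absolute per-edge probability perturbation of
#'   planted copies.
#' @param seed integer seed; the generator is fully deterministic given it.
#' @return list with `graph` (a [probability_graph]) and `planted` (list of
#'   character vectors, the node sets of the planted copies; empty when
#'   nothing is planted).
#' @export
random_probability_network <- function(n_nodes, n_edges,
                                       prob_law = c("uniform", "beta"),
                                       law_par = c(0.5, 1),
                                       pattern = NULL, copies = 0L,
                                       jitter = 0.01, seed = 1L) {
  prob_law <- match.arg(prob_law)
  n_nodes <- as.integer(n_nodes)
  n_edges <- as.integer(n_edges)
  copies <- as.integer(copies)
  if (n_edges > n_nodes * (n_nodes - 1L) / 2L)
    stop("n_edges exceeds the number of node pairs")
  if (copies > 0L && is.null(pattern)) stop("`pattern` required when copies > 0")
  kp <- if (is.null(pattern)) 0L else length(pattern$nodes)
  if (copies * kp > n_nodes)
    stop("not enough nodes for the requested disjoint planted copies")
  pe <- if (is.null(pattern)) 0L else nrow(pattern$edges)
  n_background <- n_edges - copies * pe
  if (n_background < 0L)
    stop("n_edges is smaller than the number of planted edges")

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))

  labels <- sprintf("n%d", seq_len(n_nodes))
  planted_sets <- list()
  from <- character(); to <- character(); p <- numeric()
  planted_idx <- integer()
  if (copies > 0L) {
    chosen <- sample.int(n_nodes, copies * kp)
    for (c_i in seq_len(copies)) {
      set <- sort(chosen[((c_i - 1L) * kp + 1L):(c_i * kp)])
      planted_sets[[c_i]] <- labels[set]
      # map pattern node j -> host node set[j]
      for (e in seq_len(pe)) {
        i1 <- set[match(pattern$edges$from[e], pattern$nodes)]
        i2 <- set[match(pattern$edges$to[e], pattern$nodes)]
        pv <- pattern$edges$p[e] + stats::runif(1L, -jitter, jitter)
        pv <- min(max(pv, 0.01), 1)
        from <- c(from, labels[i1]); to <- c(to, labels[i2]); p <- c(p, pv)
      }
    }
    planted_idx <- chosen
  }

  # background edges: pairs with at least one endpoint outside planted sets
  if (n_background > 0L) {
    all_pairs <- utils::combn(n_nodes, 2L)
    in_plant <- logical(n_nodes); in_plant[planted_idx] <- TRUE
    # exclude pairs internal to any single planted copy (any intra-plant pair
    # is excluded entirely: keeps every planted induced subgraph exact)
    ok <- !(in_plant[all_pairs[1L, ]] & in_plant[all_pairs[2L, ]])
    pool <- which(ok)
    if (length(pool) < n_background)
      stop("not enough non-planted node pairs for the requested background edges")
    pick <- sample(pool, n_background)
    pv <- draw_probabilities(n_background, prob_law, law_par)
    from <- c(from, labels[all_pairs[1L, pick]])
    to <- c(to, labels[all_pairs[2L, pick]])
    p <- c(p, pv)
  }

  g <- probability_graph(data.frame(from = from, to = to, p = p,
                                    stringsAsFactors = FALSE),
                         nodes = labels)
  list(graph = g, planted = planted_sets)
}

draw_probabilities <- function(n, law, par) {
  p <- switch(law,
    uniform = stats::runif(n, par[1L], par[2L]),
    beta = stats::rbeta(n, par[1L], par[2L]))
  pmin(pmax(p, 0.01), 1)
}
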