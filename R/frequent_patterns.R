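#' Mining configuration
#'
#' Bundles every knob of the frequent-pattern miner. The default mismatch
#' thresholds are epsilon = theta = ln(k(k-1)), the heuristic upper limit
#' under which cluster counts and contents are satisfactory on regulatory
#' networks; lowering either threshold splits clusters (cluster count is
#' non-increasing in both).
#'
#' @param k subgraph scale (>= 3).
#' @param epsilon,theta,alpha,augment see [iso_thresholds].
#' @param min_sup minimum support: a pattern is frequent when at least this
#'   many candidate subgraphs fall in its cluster. Default 1.
#' @param seed integer seed recorded in reports (the miner itself is
#'   deterministic; the seed matters for generated inputs).
#' @param directed treat the network as directed.
#' @param merge_rule how a cluster representative absorbs a merged cluster:
#'   `"weighted_mean"` (support-weighted mean of aligned probability
#'   adjacencies, the default) or `"first"` (keep the first member's
#'   adjacency unchanged).
#' @param max_permutation_k cap for the mapping-enumeration stage.
#' @return object of class `mining_config`.
#' @export
mining_config <- function(k, epsilon = default_threshold(k),
                          theta = default_threshold(k), alpha = NULL,
                          augment = TRUE, min_sup = 1L, seed = NULL,
                          directed = FALSE,
                          merge_rule = c("weighted_mean", "first"),
                          max_permutation_k = 8L) {
  k <- as.integer(k)
  if (is.na(k) || k < 3L) stop("k must be >= 3")
  min_sup <- as.integer(min_sup)
  if (is.na(min_sup) || min_sup < 1L) stop("min_sup must be >= 1")
  structure(list(k = k, epsilon = epsilon, theta = theta, alpha = alpha,
                 augment = isTRUE(augment), min_sup = min_sup, seed = seed,
                 directed = isTRUE(directed),
                 merge_rule = match.arg(merge_rule),
                 max_permutation_k = as.integer(max_permutation_k)),
            class = "mining_config")
}

config_thresholds <- function(config) {
  iso_thresholds(config$epsilon, config$theta, alpha = config$alpha,
                 augment = config$augment,
                 max_permutation_k = config$max_permutation_k)
}

new_cluster <- function(instance) {
  structure(list(representative = instance$pattern,
                 members = list(instance),
                 support = 1L),
            class = "upm_cluster")
}

#' Merge two pattern clusters
#'
#' The merged representative is the support-weighted mean of the two
#' representatives' probability adjacencies after aligning cluster `b` onto
#' cluster `a` with the given node mapping; members are concatenated and
#' supports added. Because both representatives have entries in (0,1] on
#' their common support pattern, the weighted mean stays in (0,1] wherever
#' either graph has an edge.
#'
#' @param a,b `upm_cluster` objects with k-node representatives.
#' @param mapping bijection: node i of `a`'s representative corresponds to
#'   node `mapping[i]` of `b`'s (as returned by [iso_test]).
#' @param rule `"weighted_mean"` or `"first"` (keep `a`'s representative).
#' @return merged `upm_cluster`.
#' @export
merge_clusters <- function(a, b, mapping, rule = "weighted_mean") {
  A <- probability_adjacency(a$representative)
  rep_g <- if (identical(rule, "first")) {
    a$representative
  } else {
    B <- probability_adjacency(b$representative)[mapping, mapping, drop = FALSE]
    M <- (a$support * A + b$support * B) / (a$support + b$support)
    dimnames(M) <- dimnames(A)
    graph_from_adjacency(M, directed = a$representative$directed)
  }
  structure(list(representative = rep_g,
                 members = c(a$members, b$members),
                 support = a$support + b$support),
            class = "upm_cluster")
}

#' Two-step hierarchical clustering of candidate subgraphs
#'
#' Groups the candidate set into probability-isomorphism clusters without
#' ever materializing an n x n distance matrix.
#'
#' Phase 1 (stride pairing): with L_c active clusters, cluster i is compared
#' against cluster i + ceiling(L_c/2) for i = 1..floor(L_c/2) (the middle
#' element of an odd list is carried unchanged); each pair passing the
#' probability-isomorphism test is merged. Passes repeat until one makes no
#' merge. The long stride keeps consecutive comparisons between clusters
#' that were far apart in the previous pass, so fresh merges keep meeting
#' fresh partners.
#'
#' Phase 2 (classical agglomeration): among the residual clusters, the pair
#' of representatives with the smallest voltage mismatch VMval that also
#' passes the isomorphism test is merged, repeatedly, until no pair passes.
#'
#' @param candidates a `candidate_set` from [collect_candidates] (or a list
#'   of `subgraph_instance` objects).
#' @param config a [mining_config].
#' @return list of `upm_cluster` objects; total support equals the number of
#'   candidates.
#' @export
two_step_clustering <- function(candidates, config) {
  instances <- if (inherits(candidates, "candidate_set")) candidates$instances
               else candidates
  if (!length(instances)) return(list())
  thr <- config_thresholds(config)
  clusters <- lapply(instances, new_cluster)
  # voltage matrices of the representatives, cached alongside the clusters
  # (memory stays linear in the number of active clusters)
  vms <- lapply(clusters, function(cl)
    voltage_matrix(cl$representative, augment = thr$augment))

  # Phase 1: stride-paired merging to fixpoint
  repeat {
    lc <- length(clusters)
    if (lc < 2L) break
    stride <- ceiling(lc / 2)
    half <- floor(lc / 2)
    merged_any <- FALSE
    nxt <- list(); nxt_vm <- list()
    taken <- logical(lc)
    for (i in seq_len(half)) {
      j <- i + stride
      v <- iso_test(clusters[[i]]$representative,
                    clusters[[j]]$representative, thr,
                    sa = vms[[i]], sb = vms[[j]])
      if (v$isomorphic) {
        m <- merge_clusters(clusters[[i]], clusters[[j]], v$mapping,
                            rule = config$merge_rule)
        nxt[[length(nxt) + 1L]] <- m
        nxt_vm[[length(nxt)]] <-
          voltage_matrix(m$representative, augment = thr$augment)
        merged_any <- TRUE
      } else {
        nxt[[length(nxt) + 1L]] <- clusters[[i]]
        nxt_vm[[length(nxt)]] <- vms[[i]]
        nxt[[length(nxt) + 1L]] <- clusters[[j]]
        nxt_vm[[length(nxt)]] <- vms[[j]]
      }
      taken[c(i, j)] <- TRUE
    }
    for (i in which(!taken)) {
      nxt[[length(nxt) + 1L]] <- clusters[[i]]
      nxt_vm[[length(nxt)]] <- vms[[i]]
    }
    clusters <- nxt
    vms <- nxt_vm
    if (!merged_any) break
  }

  # Phase 2: smallest-VMval agglomeration among residual clusters
  repeat {
    lc <- length(clusters)
    if (lc < 2L) break
    best <- NULL
    best_vm <- Inf
    for (i in seq_len(lc - 1L)) {
      for (j in seq((i + 1L), lc)) {
        v <- iso_test(clusters[[i]]$representative,
                      clusters[[j]]$representative, thr,
                      sa = vms[[i]], sb = vms[[j]])
        if (v$isomorphic && v$vmval < best_vm) {
          best_vm <- v$vmval
          best <- list(i = i, j = j, verdict = v)
        }
      }
    }
    if (is.null(best)) break
    merged <- merge_clusters(clusters[[best$i]], clusters[[best$j]],
                             best$verdict$mapping, rule = config$merge_rule)
    clusters[[best$i]] <- merged
    vms[[best$i]] <- voltage_matrix(merged$representative, augment = thr$augment)
    clusters[[best$j]] <- NULL
    vms[[best$j]] <- NULL
  }
  clusters
}

#' Filter clusters by minimum support
#'
#' @param clusters list of `upm_cluster` objects.
#' @param min_sup minimum support (>= 1).
#' @return clusters with support >= `min_sup`, sorted by descending support
#'   (stable: ties keep first-seen order).
#' @export
frequent_clusters <- function(clusters, min_sup) {
  min_sup <- as.integer(min_sup)
  if (is.na(min_sup) || min_sup < 1L) stop("min_sup must be >= 1")
  keep <- Filter(function(cl) cl$support >= min_sup, clusters)
  if (!length(keep)) return(list())
  keep[order(-vapply(keep, function(cl) cl$support, integer(1L)))]
}

#' Mine frequent probability patterns from an uncertain network
#'
#' The full pipeline: enumerate connected non-tree k-node induced subgraphs
#' of the host network, cluster them by probability isomorphism with the
#' two-step hierarchical clustering, and report the clusters whose support
#' reaches `min_sup` as frequent patterns. Support counts candidate
#' subgraphs probability-isomorphic to the pattern; frequency is support
#' divided by the number of candidates. (Whether a frequent pattern is a
#' *motif* additionally requires comparison against randomized networks,
#' which is outside this package's scope.)
#'
#' @param host a [probability_graph].
#' @param config a [mining_config].
#' @param max_instances safety cap on enumeration.
#' @return object of class `upm_patterns`: list with `config`,
#'   `n_candidates`, and `clusters` — each cluster carrying the
#'   representative graph, `support`, `frequency`, member host node sets,
#'   and mean/max PMval of members against the representative.
#' @examples
#' g <- example4_graph()
#' mine(g, mining_config(k = 4, min_sup = 1))
#' @export
mine <- function(host, config, max_instances = Inf) {
  stopifnot(inherits(host, "probability_graph"),
            inherits(config, "mining_config"))
  cands <- collect_candidates(host, config$k, max_instances = max_instances)
  clusters <- two_step_clustering(cands, config)
  freq <- frequent_clusters(clusters, config$min_sup)
  thr <- config_thresholds(config)
  n_cand <- length(cands$instances)
  summarize <- function(cl) {
    rep_vm <- voltage_matrix(cl$representative, augment = thr$augment)
    stats <- vapply(cl$members, function(m) {
      v <- iso_test(cl$representative, m$pattern, thr, sa = rep_vm)
      c(v$vmval, if (is.na(v$pmval)) Inf else v$pmval)
    }, numeric(2L))
    list(representative = cl$representative,
         support = cl$support,
         frequency = cl$support / n_cand,
         members = lapply(cl$members, function(m) m$host_node_ids),
         mean_vmval = mean(stats[1L, ]),
         mean_pmval = mean(stats[2L, ]),
         max_pmval = max(stats[2L, ]))
  }
  structure(list(config = config, n_candidates = n_cand,
                 clusters = lapply(freq, summarize)),
            class = "upm_patterns")
}

#' @export
print.upm_patterns <- function(x, ...) {
  cat(sprintf("Frequent probability patterns (k = %d)\n", x$config$k))
  cat(sprintf("  thresholds: epsilon = %.4g, theta = %.4g; min_sup = %d\n",
              x$config$epsilon, x$config$theta, x$config$min_sup))
  cat(sprintf("  candidates: %d non-tree subgraphs; frequent patterns: %d\n",
              x$n_candidates, length(x$clusters)))
  for (i in seq_along(x$clusters)) {
    cl <- x$clusters[[i]]
    cat(sprintf("  pattern %d: support %d (frequency %.3f), %d edges, mean PMval %.4g\n",
                i, cl$support, cl$frequency, nrow(cl$representative$edges),
                cl$mean_pmval))
  }
  invisible(x)
}

#' @export
summary.upm_patterns <- function(object, ...) {
  df <- data.frame(
    pattern = seq_along(object$clusters),
    support = vapply(object$clusters, `[[`, integer(1L), "support"),
    frequency = vapply(object$clusters, `[[`, numeric(1L), "frequency"),
    edges = vapply(object$clusters,
                   function(cl) nrow(cl$representative$edges), integer(1L)),
    mean_vmval = vapply(object$clusters, `[[`, numeric(1L), "mean_vmval"),
    mean_pmval = vapply(object$clusters, `[[`, numeric(1L), "mean_pmval"))
  structure(list(k = object$config$k, n_candidates = object$n_candidates,
                 table = df),
            class = "summary.upm_patterns")
}

#' @export
print.summary.upm_patterns <- function(x, ...) {
  cat(sprintf("Pattern mining summary: k = %d, %d candidates, %d frequent patterns\n",
              x$k, x$n_candidates, nrow(x$table)))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Plot frequent patterns
#'
#' Draws the representative graph of the top patterns (requires the igraph
#' package); edge labels give the representative probabilities.
#'
#' @param x an `upm_patterns` object.
#' @param max_patterns draw at most this many patterns.
#' @param ... passed to `igraph::plot.igraph`.
#' @export
plot.upm_patterns <- function(x, max_patterns = 4L, ...) {
  if (!requireNamespace("igraph", quietly = TRUE))
    stop("plotting requires the igraph package")
  n <- min(length(x$clusters), max_patterns)
  if (!n) { message("no frequent patterns to plot"); return(invisible(x)) }
  op <- graphics::par(mfrow = c(1L, n))
  on.exit(graphics::par(op))
  for (i in seq_len(n)) {
    cl <- x$clusters[[i]]
    e <- cl$representative$edges
    ig <- igraph::graph_from_data_frame(e, directed = cl$representative$directed,
                                        vertices = cl$representative$nodes)
    igraph::plot.igraph(ig, edge.label = sprintf("%.2f", e$p),
                        main = sprintf("support %d", cl$support), ...)
  }
  invisible(x)
}

#' Write a pattern report as JSON
#'
#' Serializes an `upm_patterns` object to the report schema: config,
#' candidate count, and per-cluster support, frequency, representative
#' (nodes and `[u, v, p]` edges), member node sets and mean PMval. Output is
#' deterministic (fixed key order, 9 significant digits) so identical runs
#' diff byte-for-byte.
#'
#' @param report an `upm_patterns` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pattern_report <- function(report, path) {
  cfg <- report$config
  obj <- list(
    config = list(k = cfg$k, epsilon = cfg$epsilon, theta = cfg$theta,
                  alpha = if (is.null(cfg$alpha)) NA else cfg$alpha,
                  augment = cfg$augment, min_sup = cfg$min_sup,
                  seed = if (is.null(cfg$seed)) NA else cfg$seed,
                  directed = cfg$directed, merge_rule = cfg$merge_rule),
    n_candidates = report$n_candidates,
    clusters = lapply(report$clusters, function(cl) {
      e <- cl$representative$edges
      list(support = cl$support,
           frequency = cl$frequency,
           representative = list(
             nodes = cl$representative$nodes,
             edges = lapply(seq_len(nrow(e)), function(i)
               list(e$from[i], e$to[i], e$p[i]))),
           members = cl$members,
           mean_pmval = cl$mean_pmval)
    }))
  json <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 9, null = "null",
                           na = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}
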