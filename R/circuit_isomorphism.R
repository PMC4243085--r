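#' Reduced conductance matrix of the associated circuit
#'
#' The associated circuit of a probability graph replaces every edge of
#' probability p with a resistor of resistance 1/p, so the branch
#' conductance equals the edge probability: an edge with p near 1 is a near
#' short-circuit, an edge with p near 0 is nearly open. Choosing a reference
#' node and eliminating its row and column from the weighted Laplacian gives
#' the (k-1) x (k-1) reduced conductance matrix of node-voltage analysis:
#' diagonal entries are self-admittances (sum of incident conductances),
#' off-diagonal entries are mutual admittances (minus the edge conductance).
#' Under complete excitation of the reference node a unit current source
#' feeds every non-reference node, so the excitation vector is all ones.
#'
#' For directed graphs the circuit is built on the symmetrized conductance:
#' antiparallel edges act as parallel resistors and their conductances add.
#'
#' @param g a connected [probability_graph].
#' @param reference node label (or index) of the reference node.
#' @return object of class `circuit_system`: list with `reference` (label),
#'   `conductance_matrix` ((k-1) x (k-1), dimnames = non-reference labels)
#'   and `excitation_vector` (all ones).
#' @export
reduced_conductance_matrix <- function(g, reference) {
  ref <- resolve_node(g, reference)
  if (!is_connected(g))
    stop("circuit undefined for disconnected graph")
  A <- probability_adjacency(g)
  if (g$directed) A <- A + t(A)           # parallel resistors add
  L <- diag(rowSums(A), nrow = nrow(A)) - A
  dimnames(L) <- dimnames(A)
  idx <- setdiff(seq_along(g$nodes), ref)
  structure(list(reference = g$nodes[ref],
                 conductance_matrix = L[idx, idx, drop = FALSE],
                 excitation_vector = rep(1, length(idx))),
            class = "circuit_system")
}

resolve_node <- function(g, node) {
  if (is.numeric(node)) {
    node <- as.integer(node)
    if (is.na(node) || node < 1L || node > length(g$nodes))
      stop("node index out of range")
    return(node)
  }
  i <- match(as.character(node), g$nodes)
  if (is.na(i)) stop("unknown node label: ", node)
  i
}

#' Node voltage sequence for one reference node
#'
#' Solves the node-voltage system G U = I of the associated circuit under
#' complete excitation of the reference node and returns the k-1 voltages of
#' the non-reference nodes sorted ascending. For a connected graph with all
#' probabilities positive the reduced conductance matrix is an irreducibly
#' diagonally dominant M-matrix, so the system is nonsingular and every
#' voltage is strictly positive.
#'
#' @param g a connected [probability_graph] with k >= 2 nodes.
#' @param reference reference node label or index.
#' @return numeric vector of length k-1, ascending.
#' @export
node_voltage_sequence <- function(g, reference) {
  cs <- reduced_conductance_matrix(g, reference)
  u <- tryCatch(solve(cs$conductance_matrix, cs$excitation_vector),
                error = function(e)
                  stop(sprintf("singular node-voltage system (reference '%s', %d nodes): %s",
                               cs$reference, length(g$nodes), conditionMessage(e))))
  sort(as.numeric(u))
}

#' Voltage sequence matrix of a probability graph
#'
#' Stacks the node voltage sequences for every choice of reference node into
#' a k x (k-1) matrix: row i is the ascending voltage sequence with node i as
#' reference. This matrix is the circuit signature used for probability
#' isomorphism: relabelling the graph only permutes its rows. With
#' `augment = TRUE` (the default) each row is extended with the mean and the
#' population variance of its voltages, sharpening the voltage-mismatch
#' filter as a cheap stand-in for per-edge comparisons.
#'
#' @param g a connected [probability_graph], k >= 2.
#' @param augment append per-row mean and population variance.
#' @return numeric matrix, k rows (named by reference node), k-1 columns
#'   (k+1 when augmented), with attribute `augmented`.
#' @export
voltage_matrix <- function(g, augment = TRUE) {
  k <- length(g$nodes)
  if (k < 2L) stop("voltage matrix needs at least 2 nodes")
  if (!is_connected(g)) stop("circuit undefined for disconnected graph")
  A <- probability_adjacency(g)
  if (g$directed) A <- A + t(A)
  L <- diag(rowSums(A), nrow = k) - A
  ncol <- if (augment) k + 1L else k - 1L
  S <- matrix(NA_real_, k, ncol, dimnames = list(g$nodes, NULL))
  ones <- rep(1, k - 1L)
  for (i in seq_len(k)) {
    idx <- seq_len(k)[-i]
    u <- sort(as.numeric(solve(L[idx, idx, drop = FALSE], ones)))
    S[i, seq_len(k - 1L)] <- u
    if (augment) {
      m <- mean(u)
      S[i, k] <- m
      S[i, k + 1L] <- mean((u - m)^2)    # population variance
    }
  }
  attr(S, "augmented") <- isTRUE(augment)
  S
}

#' Squared-distance matrix between two voltage sequence matrices
#'
#' Entry (i, j) is the squared Euclidean distance between row i of `sa` and
#' row j of `sb`, computed through the Gram expansion
#' \eqn{\|a\|^2 + \|b\|^2 - 2 a \cdot b}. No square root is taken: the
#' assignment below only needs relative order, and the mismatch threshold is
#' calibrated on this scale.
#'
#' @param sa,sb voltage matrices from [voltage_matrix] with equal column
#'   counts (same k, same augmentation).
#' @return k x k numeric matrix of squared distances.
#' @export
voltage_distance_matrix <- function(sa, sb) {
  if (!is.matrix(sa) || !is.matrix(sb) || ncol(sa) != ncol(sb) ||
      nrow(sa) != nrow(sb))
    stop("voltage matrices must have identical dimensions (same k and augmentation)")
  na2 <- rowSums(sa^2)
  nb2 <- rowSums(sb^2)
  D <- outer(na2, nb2, "+") - 2 * tcrossprod(sa, sb)
  D[D < 0] <- 0                          # clip float negatives
  dimnames(D) <- list(rownames(sa), rownames(sb))
  D
}

#' Optimal node mapping by the Hungarian algorithm
#'
#' Solves the linear sum assignment problem on the voltage distance matrix:
#' the minimum-cost bijection between the two graphs' reference nodes. The
#' total assigned cost is the voltage-matrix mismatch VMval, a necessary-
#' condition statistic for probability isomorphism (isomorphic graphs have
#' VMval = 0 up to floating point).
#'
#' @param dist square non-negative cost matrix (from
#'   [voltage_distance_matrix]).
#' @return object of class `assignment_result`: `mapping` (integer vector,
#'   row i assigned to column `mapping[i]`), `assignment_matrix` (0/1), and
#'   `vmval` (the minimum assigned-cost sum).
#' @export
optimal_node_mapping <- function(dist) {
  if (!is.matrix(dist) || nrow(dist) != ncol(dist))
    stop("cost matrix must be square")
  if (any(!is.finite(dist))) stop("cost matrix must be finite")
  map <- as.integer(clue::solve_LSAP(dist))
  M <- matrix(0L, nrow(dist), nrow(dist))
  M[cbind(seq_len(nrow(dist)), map)] <- 1L
  structure(list(mapping = map, assignment_matrix = M,
                 vmval = sum(dist[cbind(seq_len(nrow(dist)), map)])),
            class = "assignment_result")
}

#' Adjacency mismatch (PMval) under a node mapping
#'
#' The probability-adjacency mismatch of two k-node graphs under a bijection:
#' the sum over all ordered index pairs of the absolute difference between
#' corresponding adjacency entries, a missing edge contributing probability
#' 0. For undirected graphs each edge difference is therefore counted twice
#' (both orientations of the pair); thresholds are calibrated on this scale.
#'
#' @param ga,gb [probability_graph]s with the same node count k.
#' @param mapping integer vector of length k: node i of `ga` corresponds to
#'   node `mapping[i]` of `gb`.
#' @return numeric PMval.
#' @export
adjacency_mismatch <- function(ga, gb, mapping) {
  k <- length(ga$nodes)
  if (length(gb$nodes) != k) stop("graphs must have the same node count")
  mapping <- as.integer(mapping)
  if (length(mapping) != k || anyDuplicated(mapping) ||
      any(mapping < 1L | mapping > k))
    stop("`mapping` must be a bijection on 1..k")
  A <- probability_adjacency(ga)
  B <- probability_adjacency(gb)
  sum(abs(A - B[mapping, mapping, drop = FALSE]))
}

#' Thresholds for probability-isomorphism decisions
#'
#' @param epsilon voltage-matrix mismatch threshold (>= 0). Two graphs whose
#'   VMval exceeds `epsilon` are rejected without any adjacency comparison.
#' @param theta adjacency mismatch threshold (>= 0) on PMval.
#' @param alpha optional per-edge threshold in [0, 1]; when set, an accepted
#'   mapping must additionally satisfy max |p - p'| <= alpha on every node
#'   pair (strict mode; off by default, the voltage filter standing in for
#'   the per-edge comparison).
#' @param augment use mean/variance augmentation in the voltage matrices.
#' @param max_permutation_k largest k for which the exhaustive mapping
#'   search of the final stage is permitted.
#' @return object of class `iso_thresholds`.
#' @export
iso_thresholds <- function(epsilon, theta, alpha = NULL, augment = TRUE,
                           max_permutation_k = 8L) {
  stopifnot(is.numeric(epsilon), epsilon >= 0,
            is.numeric(theta), theta >= 0)
  if (!is.null(alpha)) stopifnot(is.numeric(alpha), alpha >= 0, alpha <= 1)
  structure(list(epsilon = epsilon, theta = theta, alpha = alpha,
                 augment = isTRUE(augment),
                 max_permutation_k = as.integer(max_permutation_k)),
            class = "iso_thresholds")
}

#' Default mismatch threshold for scale-k subgraphs
#'
#' The heuristic upper limit ln(k(k-1)) for both the voltage threshold
#' epsilon and the adjacency threshold theta, which gives compact clusters
#' that still capture known motifs on regulatory-network data.
#'
#' @param k subgraph scale.
#' @return numeric threshold.
#' @export
default_threshold <- function(k) log(k * (k - 1))

#' Probability-isomorphism test of two probability graphs
#'
#' Decides probability isomorphism in three stages:
#' \enumerate{
#'   \item Voltage filter: build both voltage matrices, their squared-
#'     distance matrix and the Hungarian assignment. If the minimum voltage
#'     mismatch VMval exceeds `epsilon` the graphs cannot be probability
#'     isomorphic (necessary condition) and the test rejects.
#'   \item Hungarian mapping check: compute the adjacency mismatch PMval
#'     under the assignment's node mapping; accept if PMval <= `theta`.
#'   \item Mapping enumeration: the Hungarian mapping is optimal for
#'     voltages, not for adjacencies, so remaining bijections are searched
#'     (branch and bound on the partial mismatch, deterministic
#'     lexicographic order, early exit) for any mapping with
#'     PMval <= `theta`.
#' }
#' When `thresholds$alpha` is set, stages 2-3 additionally require every
#' per-edge difference to be at most alpha.
#'
#' @param ga,gb connected [probability_graph]s.
#' @param thresholds an [iso_thresholds] object (or a single number used for
#'   both epsilon and theta).
#' @param sa,sb optional precomputed [voltage_matrix] results for `ga` and
#'   `gb` (with augmentation matching `thresholds$augment`); a performance
#'   hook for callers that test one graph against many.
#' @return object of class `iso_verdict`: `isomorphic`, `vmval`, `pmval`,
#'   `mapping` (the bijection that achieved the verdict, ga index ->
#'   gb index), and `stage`, one of `"size-mismatch"`,
#'   `"voltage-filter-reject"`, `"hungarian-accept"`, `"permutation-accept"`,
#'   `"permutation-reject"`.
#' @export
iso_test <- function(ga, gb, thresholds, sa = NULL, sb = NULL) {
  if (is.numeric(thresholds))
    thresholds <- iso_thresholds(thresholds, thresholds)
  stopifnot(inherits(thresholds, "iso_thresholds"))
  k <- length(ga$nodes)
  if (length(gb$nodes) != k)
    return(structure(list(isomorphic = FALSE, vmval = NA_real_,
                          pmval = NA_real_, mapping = NULL,
                          stage = "size-mismatch"),
                     class = "iso_verdict"))
  if (is.null(sa)) sa <- voltage_matrix(ga, augment = thresholds$augment)
  if (is.null(sb)) sb <- voltage_matrix(gb, augment = thresholds$augment)
  D <- voltage_distance_matrix(sa, sb)
  asg <- optimal_node_mapping(D)
  if (asg$vmval > thresholds$epsilon)
    return(structure(list(isomorphic = FALSE, vmval = asg$vmval,
                          pmval = NA_real_, mapping = asg$mapping,
                          stage = "voltage-filter-reject"),
                     class = "iso_verdict"))
  A <- probability_adjacency(ga)
  B <- probability_adjacency(gb)
  pm <- sum(abs(A - B[asg$mapping, asg$mapping, drop = FALSE]))
  ok_alpha <- is.null(thresholds$alpha) ||
    max(abs(A - B[asg$mapping, asg$mapping, drop = FALSE])) <= thresholds$alpha
  if (pm <= thresholds$theta && ok_alpha)
    return(structure(list(isomorphic = TRUE, vmval = asg$vmval, pmval = pm,
                          mapping = asg$mapping, stage = "hungarian-accept"),
                     class = "iso_verdict"))
  if (k > thresholds$max_permutation_k)
    stop(sprintf(paste0("mapping enumeration needed for k=%d but the cap is ",
                        "max_permutation_k=%d; raise the cap to proceed"),
                 k, thresholds$max_permutation_k))
  found <- search_mapping(A, B, thresholds$theta, thresholds$alpha,
                          skip = asg$mapping)
  if (!is.null(found))
    return(structure(list(isomorphic = TRUE, vmval = asg$vmval,
                          pmval = found$pmval, mapping = found$mapping,
                          stage = "permutation-accept"),
                     class = "iso_verdict"))
  structure(list(isomorphic = FALSE, vmval = asg$vmval, pmval = pm,
                 mapping = asg$mapping, stage = "permutation-reject"),
            class = "iso_verdict")
}

#' @export
print.iso_verdict <- function(x, ...) {
  cat(sprintf("Probability isomorphism: %s (stage: %s)\n",
              if (x$isomorphic) "YES" else "no", x$stage))
  if (!is.na(x$vmval)) cat(sprintf("  VMval = %.9g\n", x$vmval))
  if (!is.na(x$pmval)) cat(sprintf("  PMval = %.9g\n", x$pmval))
  if (!is.null(x$mapping))
    cat("  mapping:", paste(x$mapping, collapse = " "), "\n")
  invisible(x)
}

# Depth-first branch-and-bound over bijections (lexicographic order).
# Position i of A is assigned a node of B; the partial PMval (both
# orientations of every decided pair) is pruned against theta. `skip`: a
# mapping already tested (the Hungarian one), skipped when encountered.
# Returns list(mapping, pmval) for the first acceptable mapping, else NULL.
search_mapping <- function(A, B, theta, alpha = NULL, skip = NULL) {
  k <- nrow(A)
  assign_vec <- integer(k)
  used <- logical(k)
  recurse <- function(i, partial) {
    if (i > k) {
      if (!is.null(skip) && all(assign_vec == skip)) return(NULL)
      return(list(mapping = assign_vec, pmval = partial))
    }
    for (b in seq_len(k)) {
      if (used[b]) next
      add <- 0
      ok <- TRUE
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          d1 <- abs(A[i, j] - B[b, assign_vec[j]])
          d2 <- abs(A[j, i] - B[assign_vec[j], b])
          if (!is.null(alpha) && (d1 > alpha || d2 > alpha)) { ok <- FALSE; break }
          add <- add + d1 + d2
        }
      }
      if (!ok || partial + add > theta) next
      assign_vec[i] <<- b
      used[b] <<- TRUE
      res <- recurse(i + 1L, partial + add)
      used[b] <<- FALSE
      if (!is.null(res)) return(res)
    }
    NULL
  }
  recurse(1L, 0)
}

#' Exhaustive probability-isomorphism oracle
#'
#' Tests all k! bijections between two k-node probability graphs against the
#' definitional criterion: some bijection must keep every per-edge
#' probability difference at most `alpha` and the total absolute difference
#' (over ordered pairs, absent edges counting as probability 0) at most
#' `theta`. Intended as an independent reference for small graphs; refuses
#' k > 8.
#'
#' @param ga,gb [probability_graph]s with equal node counts, k <= 8.
#' @param alpha per-edge threshold in [0, 1] (use 1 to disable).
#' @param theta total mismatch threshold (>= 0).
#' @return list with `isomorphic` (logical), `best_mapping` (bijection
#'   minimizing the total mismatch), `best_pmval` (that minimum).
#' @export
brute_force_iso <- function(ga, gb, alpha = 1, theta) {
  k <- length(ga$nodes)
  if (length(gb$nodes) != k)
    return(list(isomorphic = FALSE, best_mapping = NULL, best_pmval = NA_real_))
  if (k > 8L) stop("brute_force_iso refuses k > 8 (factorial search)")
  A <- probability_adjacency(ga)
  B <- probability_adjacency(gb)
  perms <- all_permutations(k)
  best <- Inf
  best_map <- NULL
  iso <- FALSE
  for (r in seq_len(nrow(perms))) {
    m <- perms[r, ]
    Dm <- abs(A - B[m, m, drop = FALSE])
    s <- sum(Dm)
    if (s < best) { best <- s; best_map <- m }
    if (!iso && max(Dm) <= alpha && s <= theta) iso <- TRUE
  }
  list(isomorphic = iso, best_mapping = as.integer(best_map), best_pmval = best)
}

# All permutations of 1..n, lexicographic order, one per row.
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 0L
  for (first in seq_len(n)) {
    rest <- setdiff(seq_len(n), first)
    for (r in seq_len(nrow(sub))) {
      row <- row + 1L
      out[row, ] <- c(first, rest[sub[r, ]])
    }
  }
  out
}
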