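# Shared test fixtures: small random probability graphs and brute-force
# reference implementations kept deliberately independent of the package's
# own algorithms.

# Random connected probability graph on k nodes: random spanning tree plus
# each remaining pair with probability p_extra; edge probabilities uniform
# in [p_lo, 1]. Uses the session RNG (tests set the seed).
rand_connected_pg <- function(k, p_extra = 0.5, p_lo = 0.1) {
  labs <- sprintf("x%d", seq_len(k))
  from <- character(); to <- character()
  for (v in 2:k) {                      # random tree: attach v to earlier node
    u <- sample.int(v - 1L, 1L)
    from <- c(from, labs[u]); to <- c(to, labs[v])
  }
  pairs <- utils::combn(k, 2L)
  have <- paste(from, to)
  for (c_i in seq_len(ncol(pairs))) {
    a <- labs[pairs[1L, c_i]]; b <- labs[pairs[2L, c_i]]
    if (paste(a, b) %in% have) next
    if (stats::runif(1L) < p_extra) { from <- c(from, a); to <- c(to, b) }
  }
  p <- stats::runif(length(from), p_lo, 1)
  probability_graph(data.frame(from = from, to = to, p = p,
                               stringsAsFactors = FALSE), nodes = labs)
}

# Relabelled copy of g: node at position i of the new order is old node
# perm[i]; adjacency of the result equals A[perm, perm] with fresh labels.
relabel_pg <- function(g, perm, prefix = "y") {
  A <- probability_adjacency(g)[perm, perm, drop = FALSE]
  dimnames(A) <- rep(list(sprintf("%s%d", prefix, seq_along(perm))), 2L)
  upm:::graph_from_adjacency(A, directed = g$directed)
}

# Jitter every edge probability by at most `amount`, clipped to [0.01, 1].
jitter_pg <- function(g, amount) {
  e <- g$edges
  e$p <- pmin(pmax(e$p + stats::runif(nrow(e), -amount, amount), 0.01), 1)
  probability_graph(e, nodes = g$nodes, directed = g$directed)
}

# Brute-force enumeration of connected k-subsets over all C(|V|, k) choices.
brute_connected_subsets <- function(g, k) {
  if (k > length(g$nodes)) return(list())
  subs <- utils::combn(g$nodes, k, simplify = FALSE)
  Filter(function(s) is_connected(induced_subgraph(g, s)), subs)
}

# Brute-force linear sum assignment minimum.
brute_min_assignment <- function(cost) {
  perms <- upm:::all_permutations(nrow(cost))
  best <- Inf
  for (r in seq_len(nrow(perms)))
    best <- min(best, sum(cost[cbind(seq_len(nrow(cost)), perms[r, ])]))
  best
}

# Canonical set-of-node-sets representation for order-free comparison.
as_subset_key <- function(sets) sort(vapply(sets, function(s)
  paste(sort(s), collapse = "|"), character(1L)))

example4_printed_S <- rbind(
  c(1.413642, 1.724302, 2.629848),
  c(1.034504, 1.069194, 1.077705),
  c(2.726954, 3.548548, 3.675701),
  c(1.277978, 1.580127, 2.367031))
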