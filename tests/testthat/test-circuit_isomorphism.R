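g4 <- example4_graph()

test_that("reduced conductance matrix has the node-voltage structure", {
  cs <- reduced_conductance_matrix(g4, "v4")
  expect_equal(unname(cs$conductance_matrix),
               matrix(c(1.92, -0.92, 0,
                        -0.92, 2.83, -0.97,
                        0, -0.97, 1.07), 3, 3, byrow = TRUE),
               tolerance = 1e-12)
  expect_equal(cs$excitation_vector, rep(1, 3))
  # unit triangle and single edge
  tri1 <- probability_graph(data.frame(f = c("a", "b", "a"),
                                       t = c("b", "c", "c"), p = rep(1, 3)))
  expect_equal(unname(reduced_conductance_matrix(tri1, "c")$conductance_matrix),
               matrix(c(2, -1, -1, 2), 2, 2))
  e1 <- probability_graph(data.frame(f = "a", t = "b", p = 0.5))
  expect_equal(unname(reduced_conductance_matrix(e1, "b")$conductance_matrix),
               matrix(0.5, 1, 1))
  # structural invariants on a random graph
  set.seed(41)
  g <- rand_connected_pg(6)
  G <- reduced_conductance_matrix(g, 1)$conductance_matrix
  expect_true(isSymmetric(G))
  expect_true(all(diag(G) > 0))
  expect_true(all(G[upper.tri(G)] <= 0))
  expect_true(all(rowSums(G) >= -1e-12))
  disc <- probability_graph(data.frame(f = "a", t = "b", p = 0.5),
                            nodes = c("a", "b", "c"))
  expect_error(reduced_conductance_matrix(disc, "a"), "disconnected")
})

test_that("node voltage sequences reproduce the four-node benchmark", {
  expect_equal(node_voltage_sequence(g4, "v4"),
               c(1.277978, 1.580127, 2.367031), tolerance = 5e-7)
  expect_equal(node_voltage_sequence(g4, "v2"),
               c(1.034504, 1.069194, 1.077705), tolerance = 5e-7)
  tri1 <- probability_graph(data.frame(f = c("a", "b", "a"),
                                       t = c("b", "c", "c"), p = rep(1, 3)))
  expect_equal(node_voltage_sequence(tri1, "a"), c(1, 1))
})

test_that("voltage matrix stacks all reference nodes, optionally augmented", {
  S <- voltage_matrix(g4, augment = FALSE)
  expect_equal(unname(S), example4_printed_S, tolerance = 5e-7,
               ignore_attr = TRUE)
  expect_true(all(diff(t(S)) >= 0) || all(apply(S, 1, function(r) !is.unsorted(r))))
  Sa <- voltage_matrix(g4, augment = TRUE)
  expect_equal(ncol(Sa), 5L)
  expect_equal(Sa[, 4], rowMeans(S), ignore_attr = TRUE)
  expect_equal(Sa[, 5], apply(S, 1, function(r) mean((r - mean(r))^2)),
               ignore_attr = TRUE)
  tri1 <- probability_graph(data.frame(f = c("a", "b", "a"),
                                       t = c("b", "c", "c"), p = rep(1, 3)))
  expect_equal(unname(voltage_matrix(tri1, augment = TRUE)),
               matrix(1, 3, 4) %*% diag(c(1, 1, 1, 0)), ignore_attr = TRUE)
})

test_that("voltages are positive and permutation-invariant as a row multiset", {
  set.seed(42)
  for (rep in 1:10) {
    k <- sample(3:6, 1L)
    g <- rand_connected_pg(k)
    S <- voltage_matrix(g, augment = FALSE)
    expect_true(all(S > 0))
    perm <- sample(k)
    S2 <- voltage_matrix(relabel_pg(g, perm), augment = FALSE)
    # row i of the relabelled graph equals row perm[i] of the original
    expect_equal(unname(S2), unname(S[perm, , drop = FALSE]),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("scaling all probabilities by c scales every voltage by 1/c", {
  half <- g4$edges
  half$p <- half$p * 0.5
  g_half <- probability_graph(half)
  expect_equal(voltage_matrix(g_half, augment = FALSE),
               2 * voltage_matrix(g4, augment = FALSE), tolerance = 1e-12)
  set.seed(43)
  g <- rand_connected_pg(5)
  e <- g$edges; e$p <- e$p * 0.25
  expect_equal(voltage_matrix(probability_graph(e, nodes = g$nodes), augment = FALSE),
               4 * voltage_matrix(g, augment = FALSE), tolerance = 1e-12)
})

test_that("distance matrix is the squared Euclidean distance of rows", {
  S <- voltage_matrix(g4, augment = FALSE)
  D <- voltage_distance_matrix(S, S)
  expect_equal(unname(diag(D)), rep(0, 4), tolerance = 1e-12)
  expect_true(all(D >= 0))
  # frozen from direct subtraction of the printed S1 and S3 rows
  expect_equal(D[1, 3], sum((example4_printed_S[1, ] - example4_printed_S[3, ])^2),
               tolerance = 1e-4)
  expect_equal(D[1, 3], 6.146469, tolerance = 1e-4)
  expect_equal(unname(voltage_distance_matrix(matrix(c(0, 0), 1), matrix(c(1, 1), 1))),
               matrix(2, 1, 1))
  expect_error(voltage_distance_matrix(S, S[, 1:2]), "identical dimensions")
})

test_that("Hungarian assignment achieves the exhaustive minimum", {
  r <- optimal_node_mapping(matrix(c(0, 2, 2, 0), 2, 2))
  expect_equal(r$mapping, 1:2)
  expect_equal(r$vmval, 0)
  r <- optimal_node_mapping(matrix(c(5, 1, 1, 5), 2, 2))
  expect_equal(r$mapping, 2:1)
  expect_equal(r$vmval, 2)
  set.seed(44)
  for (rep in 1:25) {
    C <- matrix(runif(25), 5, 5)
    r <- optimal_node_mapping(C)
    expect_equal(r$vmval, brute_min_assignment(C), tolerance = 1e-12)
    expect_equal(which(t(r$assignment_matrix) == 1L) %% 5,
                 r$mapping %% 5)  # matrix consistent with mapping
  }
  expect_error(optimal_node_mapping(matrix(1, 2, 3)), "square")
})

test_that("adjacency mismatch matches its matrix-level definition", {
  expect_equal(adjacency_mismatch(g4, g4, 1:4), 0)
  bumped <- g4$edges
  bumped$p[bumped$from == "v3" & bumped$to == "v4"] <- 0.2
  g4b <- probability_graph(bumped)
  expect_equal(adjacency_mismatch(g4, g4b, 1:4), 0.2)  # 0.1 in both orders
  set.seed(45)
  for (rep in 1:10) {
    ga <- rand_connected_pg(4); gb <- rand_connected_pg(4)
    m <- sample(4)
    P <- probability_adjacency(gb)[m, m]
    expect_equal(adjacency_mismatch(ga, gb, m),
                 sum(abs(probability_adjacency(ga) - P)))
  }
  expect_error(adjacency_mismatch(g4, g4, c(1, 1, 2, 3)), "bijection")
})

test_that("self-comparison and exact relabelled copies are isomorphic at tol 0", {
  v <- iso_test(g4, g4, iso_thresholds(1e-9, 1e-9))
  expect_true(v$isomorphic)
  expect_lte(v$vmval, 1e-9)
  expect_equal(v$pmval, 0)
  set.seed(46)
  for (rep in 1:10) {
    k <- sample(3:5, 1L)
    g <- rand_connected_pg(k)
    g2 <- relabel_pg(g, sample(k))
    v <- iso_test(g, g2, iso_thresholds(1e-9, 1e-9))
    expect_true(v$isomorphic)
    expect_lte(v$vmval, 1e-9)
  }
})

test_that("clearly different graphs are rejected and stages are honest", {
  c4 <- probability_graph(data.frame(f = c("a", "b", "c", "d"),
                                     t = c("b", "c", "d", "a"), p = rep(0.5, 4)))
  v <- iso_test(g4, c4, iso_thresholds(0.1, 0.1))
  expect_false(v$isomorphic)
  # independent confirmation: no bijection reaches pmval 0.1
  expect_gt(brute_force_iso(g4, c4, alpha = 1, theta = 0.1)$best_pmval, 0.1)
  if (v$stage == "voltage-filter-reject") expect_gt(v$vmval, 0.1)
  tri <- induced_subgraph(g4, c("v1", "v2", "v4"))
  expect_equal(iso_test(g4, tri, iso_thresholds(1, 1))$stage, "size-mismatch")
})

test_that("perturbed relabelled copies pass at the default k=4 thresholds", {
  set.seed(47)
  pert <- g4$edges
  pert$p <- pmin(pert$p + c(0.01, -0.01, 0.01, 0.01, -0.01), 1)
  gp <- probability_graph(pert)
  g2 <- relabel_pg(gp, c(3, 1, 4, 2))
  thr <- iso_thresholds(default_threshold(4), default_threshold(4))
  v <- iso_test(g4, g2, thr)
  expect_true(v$isomorphic)
  # oracle agrees that a mapping within theta exists
  expect_true(brute_force_iso(g4, g2, alpha = 1,
                              theta = default_threshold(4))$isomorphic)
})

test_that("iso_test with the voltage filter off matches the exhaustive oracle", {
  set.seed(48)
  n_checked <- 0L
  for (rep in 1:40) {
    k <- sample(3:5, 1L)
    ga <- rand_connected_pg(k)
    gb <- if (rep %% 2) jitter_pg(relabel_pg(ga, sample(k)), 0.3)
          else rand_connected_pg(k)
    for (theta in c(0.1, 0.5, 1.0, default_threshold(k))) {
      got <- iso_test(ga, gb, iso_thresholds(Inf, theta))$isomorphic
      want <- brute_force_iso(ga, gb, alpha = 1, theta = theta)$isomorphic
      expect_identical(got, want)
      n_checked <- n_checked + 1L
    }
  }
  expect_gte(n_checked, 160L)
})

test_that("verdicts are monotone in both thresholds", {
  set.seed(49)
  for (rep in 1:10) {
    k <- sample(3:4, 1L)
    ga <- rand_connected_pg(k)
    gb <- jitter_pg(relabel_pg(ga, sample(k)), 0.2)
    grid <- c(0.05, 0.2, 0.8, 3)
    verdicts <- outer(grid, grid, Vectorize(function(e, t)
      iso_test(ga, gb, iso_thresholds(e, t))$isomorphic))
    # raising epsilon (rows) or theta (cols) never flips TRUE -> FALSE
    expect_true(all(apply(verdicts, 2, function(col) all(diff(col) >= 0))))
    expect_true(all(apply(verdicts, 1, function(row) all(diff(row) >= 0))))
  }
})

test_that("strict per-edge mode rejects a single large edge difference", {
  # best mapping has one edge off by 0.15: total within theta, per-edge not
  ga <- probability_graph(data.frame(f = c("a", "b", "a"), t = c("b", "c", "c"),
                                     p = c(0.5, 0.6, 0.7)))
  gb <- probability_graph(data.frame(f = c("a", "b", "a"), t = c("b", "c", "c"),
                                     p = c(0.5, 0.6, 0.85)))
  expect_false(brute_force_iso(ga, gb, alpha = 0.1, theta = 1)$isomorphic)
  expect_true(brute_force_iso(ga, gb, alpha = 0.2, theta = 1)$isomorphic)
  v_strict <- iso_test(ga, gb, iso_thresholds(Inf, 1, alpha = 0.1))
  expect_false(v_strict$isomorphic)
  v_loose <- iso_test(ga, gb, iso_thresholds(Inf, 1))
  expect_true(v_loose$isomorphic)
})

test_that("the mapping-enumeration cap refuses oversized graphs", {
  set.seed(50)
  g <- rand_connected_pg(5)
  gb <- rand_connected_pg(5)
  expect_error(iso_test(g, gb, iso_thresholds(Inf, 1e-12, max_permutation_k = 4L)),
               "max_permutation_k")
  expect_error(brute_force_iso(rand_connected_pg(9), rand_connected_pg(9),
                               theta = 1), "k > 8")
})
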