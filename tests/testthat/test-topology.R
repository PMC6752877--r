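test_that("network density counts unique nonzero pairs", {
  full <- matrix(1, 5, 5) - diag(1, 5)
  expect_equal(network_density(full), 1)
  expect_equal(network_density(matrix(0, 5, 5)), 0)
  path4 <- matrix(0, 4, 4)
  path4[1, 2] <- path4[2, 3] <- path4[3, 4] <- 1
  path4 <- path4 + t(path4)
  expect_equal(network_density(path4), 0.5)
})

test_that("clustering coefficient reduces to triangle fractions", {
  tri <- matrix(1, 3, 3) - diag(1, 3)
  expect_equal(unname(clustering_coefficient(tri)$per_node), rep(1, 3))

  star <- unit_star(6)
  expect_equal(unname(clustering_coefficient(star)$per_node), rep(0, 6))

  # weighted triangle 1, 1, 0.5: node opposite the weak edge scores the
  # geometric mean of the scaled weights
  w <- matrix(0, 3, 3)
  w[1, 2] <- w[2, 1] <- 1
  w[1, 3] <- w[3, 1] <- 1
  w[2, 3] <- w[3, 2] <- 0.5
  cc <- clustering_coefficient(w)$per_node
  expect_equal(unname(cc), oracle_onnela(w), tolerance = 1e-15)
  expect_equal(unname(cc[1]), 0.5^(1 / 3), tolerance = 1e-12)
})

test_that("weighted clustering equals binary clustering on 0/1 matrices", {
  for (sd_ in 1:20) {
    set.seed(sd_)
    n <- sample(6:12, 1)
    A <- matrix(rbinom(n * n, 1, 0.4), n, n)
    A[lower.tri(A, diag = TRUE)] <- 0
    A <- A + t(A)
    expect_equal(unname(clustering_coefficient(A)$per_node), oracle_onnela(A),
                 tolerance = 1e-12)
  }
})

test_that("clustering matches the geometric-mean oracle on weighted graphs", {
  for (sd_ in 1:3) {
    W <- random_weight_matrix(8, seed = sd_)
    W[W < 0.3] <- 0  # sparsify
    expect_equal(unname(clustering_coefficient(W)$per_node), oracle_onnela(W),
                 tolerance = 1e-12)
  }
})

test_that("modularity Q matches the formula and known optima", {
  W <- two_cliques()
  # planted two-clique partition scores exactly 0.5
  expect_equal(modularity_q(W, rep(1:2, each = 4)), 0.5)
  # exhaustive search over all partitions of 8 nodes confirms the optimum
  best <- oracle_best_partition(W)
  expect_equal(best$q, 0.5)
  # Louvain attains it
  res <- modularity(W, seed = 1)
  expect_equal(res$q, 0.5)
  expect_equal(res$n_communities, 2)

  # complete graph, single community: direct evaluation with delta == 1
  K5 <- matrix(1, 5, 5) - diag(1, 5)
  expect_equal(modularity_q(K5, rep(1, 5)),
               oracle_modularity_q(K5, rep(1, 5)), tolerance = 1e-12)

  # all-singleton partition: Q = -sum(s_i^2) / (2m)^2 <= 0 on any graph
  for (sd_ in 1:5) {
    W <- random_weight_matrix(7, seed = sd_)
    s <- rowSums(W)
    q_single <- modularity_q(W, seq_len(7))
    expect_equal(q_single, -sum(s^2) / sum(W)^2, tolerance = 1e-12)
    expect_lte(q_single, 0)
  }

  expect_error(modularity(matrix(0, 4, 4)), "edgeless")
})

test_that("Louvain recovers planted blocks and is deterministic", {
  for (sd_ in 1:3) {
    W <- generate_planted_network(30, "modular", k = 3, p_between = 0.1,
                                  seed = sd_)
    res <- modularity(W, seed = sd_)
    ari <- mclust::adjustedRandIndex(res$partition, attr(W, "membership"))
    expect_gt(ari, 0.9)
    res2 <- modularity(W, seed = sd_)
    expect_identical(res, res2)
  }
})

test_that("strength assortativity matches the edge-list Pearson oracle", {
  expect_equal(as.numeric(assortativity_strength(unit_star(7))), -1,
               tolerance = 1e-12)

  ring <- unit_ring(8)
  r <- assortativity_strength(ring)
  expect_true(is.na(r))
  expect_true(attr(r, "undefined"))

  # two 4-cliques joined by one bridge: enumeration gives exactly -1/12
  # (the bridge joins the two strongest nodes, whose remaining edges mix
  # strengths 4 and 3, tipping the endpoint correlation slightly negative)
  bc <- bridged_cliques()
  r <- as.numeric(assortativity_strength(bc))
  expect_equal(r, oracle_assortativity(bc), tolerance = 1e-12)
  expect_equal(r, -1 / 12, tolerance = 1e-12)

  # degree variant agrees with igraph's binary degree assortativity
  expect_equal(as.numeric(assortativity_strength(bc, variant = "degree")),
               oracle_assortativity(bc, use_strength = FALSE),
               tolerance = 1e-12)

  expect_error(assortativity_strength(matrix(0, 4, 4)), "2 edges")
})

test_that("assortativity agrees with igraph on weighted fixtures", {
  for (sd_ in 1:3) {
    W <- random_weight_matrix(10, seed = sd_)
    W[W < 0.4] <- 0
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    ref <- igraph::assortativity(g, values = igraph::strength(g),
                                 directed = FALSE)
    expect_equal(as.numeric(assortativity_strength(W)), ref, tolerance = 1e-10)
  }
})

test_that("all metrics are invariant under node relabeling", {
  W <- generate_planted_network(20, "modular", k = 2, p_between = 0.2, seed = 9)
  set.seed(10)
  perm <- sample(20)
  Wp <- W[perm, perm]
  expect_equal(network_density(Wp), network_density(W))
  expect_equal(unname(clustering_coefficient(Wp)$per_node[order(perm)]),
               unname(clustering_coefficient(W)$per_node), tolerance = 1e-12)
  expect_equal(as.numeric(assortativity_strength(Wp)),
               as.numeric(assortativity_strength(W)), tolerance = 1e-12)
  qa <- modularity(W, seed = 4)
  qb <- modularity(Wp, seed = 4)
  expect_equal(qb$q, qa$q, tolerance = 1e-9)
})

test_that("topology_report handles degenerate networks and recovers structure", {
  # empty after threshold
  cm <- connectivity_matrix(matrix(0, 6, 6))
  net <- absolute_threshold(cm, 0.9)
  rep_ <- topology_report(net)
  expect_equal(rep_$density, 0)
  expect_true(all(rep_$clustering_per_node == 0))
  expect_true(is.na(rep_$modularity_q))
  expect_true(is.na(rep_$assortativity_r))
  expect_true(all(c("modularity_undefined", "assortativity_undefined")
                  %in% rep_$flags))

  # planted assortative structure survives a proportional threshold
  W <- generate_planted_network(30, "assortative")
  cmw <- connectivity_matrix(W)
  netw <- proportional_threshold(cmw, 0.5)
  repw <- topology_report(netw, seed = 2)
  expect_gt(repw$assortativity_r, 0)

  # planted modular(3) blocks recovered through the report
  for (sd_ in 1:3) {
    Wm <- generate_planted_network(24, "modular", k = 3, p_between = 0.05,
                                   seed = sd_)
    repm <- topology_report(proportional_threshold(connectivity_matrix(Wm), 0.4),
                            seed = sd_)
    ari <- mclust::adjustedRandIndex(repm$partition, attr(Wm, "membership"))
    expect_gt(ari, 0.9)
  }
})

test_that("negative weights are clipped for the weighted metrics", {
  rho <- matrix(0, 4, 4)
  rho[1, 2] <- rho[2, 1] <- 0.9
  rho[1, 3] <- rho[3, 1] <- 0.8
  rho[2, 3] <- rho[3, 2] <- 0.7
  rho[3, 4] <- rho[4, 3] <- -0.5
  net <- proportional_threshold(connectivity_matrix(rho), 1)
  expect_message(cc <- clustering_coefficient(net), "clipping")
  expect_equal(unname(cc$per_node[4]), 0)  # clipped edge carries no triangles
  rep_ <- topology_report(net)
  expect_true("negative_weights_clipped" %in% rep_$flags)
})
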