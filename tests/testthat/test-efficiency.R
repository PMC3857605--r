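test_that("weighted edge lengths are l/w with Inf off-edges", {
  W <- matrix(0, 2, 2); L <- matrix(0, 2, 2)
  W[1, 2] <- W[2, 1] <- 1
  L[1, 2] <- L[2, 1] <- 10
  expect_equal(weighted_edge_lengths(connectome(W, L))[1, 2], 10)

  # strength 2 rescales to 1 (subject maximum), so the edge length is 10
  W[1, 2] <- W[2, 1] <- 2
  cn <- rescale_weights(connectome(W, L))
  expect_equal(weighted_edge_lengths(cn)[1, 2], 10)

  # halved strength doubles the effective length
  W3 <- matrix(0, 3, 3); L3 <- matrix(0, 3, 3)
  W3[1, 2] <- W3[2, 1] <- 1; W3[1, 3] <- W3[3, 1] <- 0.5
  L3[1, 2] <- L3[2, 1] <- 10; L3[1, 3] <- L3[3, 1] <- 10
  E <- weighted_edge_lengths(connectome(W3, L3))
  expect_equal(E[1, 3], 20)
  expect_identical(E[2, 3], Inf) # absent edge

  cn_bad <- connectome(W3, L3)
  cn_bad$L[1, 2] <- cn_bad$L[2, 1] <- 0
  expect_error(weighted_edge_lengths(cn_bad), "non-positive length")
})

test_that("shortest path distances are exact travel distances", {
  cn <- chain3()
  D <- shortest_path_distances(weighted_edge_lengths(cn))
  expect_equal(D[1, 3], 4) # 2 + 2 through the middle node
  expect_equal(D[1, 2], 2)
  expect_equal(unname(diag(D)), rep(0, 3))

  # fully disconnected: all off-diagonal Inf
  E <- matrix(Inf, 4, 4)
  D2 <- shortest_path_distances(E)
  expect_true(all(is.infinite(D2[!diag(4)])))
  expect_equal(diag(D2), rep(0, 4))

  # a direct edge is beaten by a shorter two-hop path
  E3 <- matrix(Inf, 3, 3)
  E3[1, 3] <- E3[3, 1] <- 5
  E3[1, 2] <- E3[2, 1] <- 2
  E3[2, 3] <- E3[3, 2] <- 2
  expect_equal(shortest_path_distances(E3)[1, 3], 4)

  expect_error(shortest_path_distances(matrix(-1, 2, 2)), "negative")
})

test_that("distances satisfy symmetry and the triangle inequality", {
  set.seed(21)
  for (rep in 1:20) {
    cn <- rand_connectome(sample(5:12, 1), p_edge = runif(1, 0.3, 0.9))
    D <- shortest_path_distances(weighted_edge_lengths(cn))
    expect_equal(D, t(D))
    fin <- is.finite(D)
    for (k in seq_len(nrow(D))) {
      lhs <- D
      rhs <- outer(D[, k], D[k, ], `+`)
      ok <- !is.finite(rhs) | lhs <= rhs + 1e-9
      expect_true(all(ok))
    }
  }
})

test_that("distances agree with igraph's Dijkstra on random graphs", {
  skip_if_not_installed("igraph")
  set.seed(33)
  for (rep in 1:15) {
    n <- sample(5:30, 1)
    cn <- rand_connectome(n, p_edge = runif(1, 0.2, 0.8))
    E <- weighted_edge_lengths(rescale_weights(cn))
    D <- shortest_path_distances(E)
    adj <- ifelse(is.finite(E), E, 0)
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             weighted = TRUE)
    Dref <- igraph::distances(g, algorithm = "dijkstra")
    expect_equal(unname(D), unname(Dref), tolerance = 1e-9)
  }
})

test_that("nodal global efficiency matches the worked chain example", {
  g <- nodal_global_efficiency(chain3(), weighted = TRUE)
  expect_equal(unname(g[1]), 0.375) # (1/2) * (1/2 + 1/4)
  expect_equal(unname(g[2]), 0.5)

  # complete graph, all lengths 1, all weights 1: raw 1 at every node
  expect_equal(unname(nodal_global_efficiency(complete_uniform(5))),
               rep(1, 5))

  # isolated node scores 0
  W <- matrix(0, 3, 3); W[1, 2] <- W[2, 1] <- 1
  L <- 1 * (W > 0)
  g2 <- nodal_global_efficiency(connectome(W, L))
  expect_equal(unname(g2[3]), 0)

  cn1 <- connectome(matrix(0, 1, 1), matrix(0, 1, 1))
  expect_error(nodal_global_efficiency(cn1), "at least 2")
})

test_that("nodal local efficiency follows the neighborhood-subgraph rule", {
  # star center: leaves mutually unconnected, all subgraph distances Inf
  expect_equal(unname(nodal_local_efficiency(star_graph(4))),
               rep(0, 5))

  # uniform triangle: every node scores 1 under the weighted formula
  expect_equal(unname(nodal_local_efficiency(complete_uniform(3),
                                             weighted = TRUE)),
               rep(1, 3))

  # a node with a single neighbor scores 0
  cn <- chain3()
  le <- nodal_local_efficiency(cn)
  expect_equal(unname(le[1]), 0)
  expect_equal(unname(le[3]), 0)
  # the middle node's two neighbors are not connected to each other
  expect_equal(unname(le[2]), 0)
})

test_that("whole-network efficiency matches hand-computed values", {
  ne <- network_efficiency(complete_uniform(4))
  expect_equal(ne$global, 1)
  expect_equal(ne$local, 1)

  # empty graph: 0 / 0
  empty <- connectome(matrix(0, 3, 3), matrix(0, 3, 3))
  ne0 <- network_efficiency(empty)
  expect_equal(ne0$global, 0)
  expect_equal(ne0$local, 0)

  # chain: (1/6) (2*(1/2) + 2*(1/2) + 2*(1/4)) = 5/12
  expect_equal(network_efficiency(chain3())$global, 5 / 12)
})

test_that("ideal-network normalization maps the chain to 0.75", {
  cn <- chain3() # l_min = 2, ideal nodal global = 1/2
  raw <- nodal_global_efficiency(cn)
  norm <- normalize_efficiency(raw, cn, "global")
  expect_equal(unname(norm[1]), 0.75) # 0.375 / 0.5

  # graph already complete-uniform at the ideal edge length: exactly 1
  cu <- complete_uniform(5)
  expect_equal(unname(normalize_efficiency(
    nodal_global_efficiency(cu), cu, "global")), rep(1, 5))
  expect_equal(unname(normalize_efficiency(
    nodal_local_efficiency(cu), cu, "local")), rep(1, 5))

  # raw zero stays zero; empty graph normalizes to zero
  empty <- connectome(matrix(0, 3, 3), matrix(0, 3, 3))
  expect_equal(unname(normalize_efficiency(rep(0, 3), empty, "global")),
               rep(0, 3))
})

test_that("normalized efficiencies stay in [0, 1] on random graphs", {
  set.seed(77)
  for (rep in 1:40) {
    cn <- rescale_weights(rand_connectome(sample(4:12, 1),
                                          p_edge = runif(1, 0.2, 1)))
    for (weighted in c(TRUE, FALSE)) {
      ng <- normalize_efficiency(nodal_global_efficiency(cn, weighted),
                                 cn, "global", weighted)
      nl <- normalize_efficiency(nodal_local_efficiency(cn, weighted),
                                 cn, "local", weighted)
      expect_true(all(ng >= 0 & ng <= 1 + 1e-12))
      expect_true(all(nl >= 0 & nl <= 1 + 1e-12))
      expect_true(all(is.finite(c(ng, nl))))
    }
  }
})

test_that("relabeling nodes permutes every efficiency output identically", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(5:9, 1)
    cn <- rescale_weights(rand_connectome(n, p_edge = 0.6))
    perm <- sample(n)
    cnp <- connectome(cn$W[perm, perm], cn$L[perm, perm])
    for (weighted in c(TRUE, FALSE)) {
      expect_equal(unname(nodal_global_efficiency(cnp, weighted)),
                   unname(nodal_global_efficiency(cn, weighted))[perm],
                   tolerance = 1e-12)
      expect_equal(unname(nodal_local_efficiency(cnp, weighted)),
                   unname(nodal_local_efficiency(cn, weighted))[perm],
                   tolerance = 1e-12)
    }
  }
})

test_that("normalized nodal global efficiency tends to 1 toward the ideal", {
  # shrink all lengths to l_min and complete the graph at maximal weight:
  # normalized nodal global efficiency converges to 1
  set.seed(91)
  cn <- rescale_weights(rand_connectome(8, p_edge = 0.5))
  l_min <- min(cn$L[cn$W > 0])
  vals <- sapply(c(0.5, 0.99, 0.9999), function(a) {
    W <- (1 - a) * cn$W + a * (1 - diag(8))
    L <- (1 - a) * cn$L + a * l_min
    diag(L) <- 0
    cni <- connectome(W, L)
    mean(normalize_efficiency(nodal_global_efficiency(cni), cni, "global"))
  })
  expect_true(all(diff(vals) > 0))
  expect_gt(vals[3], 0.99)
})

test_that("efficiency tables are tidy and complete", {
  cfg <- generator_config(n_per_group = 2, n_regions = 10, seed = 4)
  coh <- generate_cohort(cfg)
  eff <- compute_efficiency(coh$connectomes)
  expect_s3_class(eff, "neteff_efficiency")
  expect_equal(nrow(eff), 4 * 10)
  expect_true(all(eff$nodal_global >= 0 & eff$nodal_global <= 1))
  expect_true(all(eff$nodal_local >= 0 & eff$nodal_local <= 1))
  expect_true(all(eff$weighted))
  expect_error(compute_efficiency(unname(coh$connectomes)), "named")
})
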