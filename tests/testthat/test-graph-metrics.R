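test_that("two disjoint triangles yield Q = 0.5 in two modules", {
  W <- matrix(0, 6, 6)
  W[1:3, 1:3] <- 1
  W[4:6, 4:6] <- 1
  diag(W) <- 0
  set.seed(301)
  p <- louvain_signed(W, n_restarts = 10)
  expect_equal(p$Q, 0.5, tolerance = 1e-12)
  expect_equal(length(unique(p$membership)), 2)
  expect_true(all(p$membership[1:3] == p$membership[1]))
  expect_true(all(p$membership[4:6] == p$membership[4]))
})

test_that("the single-module partition of a uniform complete graph scores Q = 0", {
  W <- matrix(1, 8, 8)
  diag(W) <- 0
  expect_equal(modularity_signed(W, rep(1, 8)), 0, tolerance = 1e-12)
  set.seed(302)
  p <- louvain_signed(W, n_restarts = 5)
  expect_lte(p$Q, 1e-12) # no merge can improve on the null-model equality
})

test_that("the all-zero matrix collapses to a single module with Q = 0", {
  p <- louvain_signed(matrix(0, 5, 5))
  expect_equal(p$membership, rep(1L, 5))
  expect_equal(p$Q, 0)
})

test_that("positive-only signed Q reduces to Newman-Girvan weighted modularity", {
  skip_if_not_installed("igraph")
  set.seed(303)
  for (i in 1:20) {
    n <- sample(6:12, 1)
    W <- abs(random_signed_graph(n, p_neg = 0))
    memb <- sample(1:3, n, replace = TRUE)
    g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                             weighted = TRUE)
    expect_equal(modularity_signed(W, memb),
                 igraph::modularity(g, memb, weights = igraph::E(g)$weight),
                 tolerance = 1e-12)
  }
})

test_that("Q is invariant to node permutation and module relabelling", {
  set.seed(304)
  W <- random_signed_graph(10)
  memb <- sample(1:3, 10, replace = TRUE)
  q0 <- modularity_signed(W, memb)
  perm <- sample(10)
  expect_equal(modularity_signed(W[perm, perm], memb[perm]), q0,
               tolerance = 1e-12)
  relab <- c(3, 1, 2)[memb]
  expect_equal(modularity_signed(W, relab), q0, tolerance = 1e-12)
})

test_that("restarted Louvain attains the exhaustive maximum on small signed graphs", {
  set.seed(305)
  hits <- 0
  n_graphs <- 15
  for (i in seq_len(n_graphs)) {
    n <- sample(5:7, 1)
    W <- random_signed_graph(n)
    best <- oracle_max_q(W)
    p <- louvain_signed(W, n_restarts = 100)
    expect_lte(p$Q, best + 1e-9) # never exceeds the true maximum
    if (p$Q >= best - 1e-9) hits <- hits + 1
  }
  expect_gte(hits / n_graphs, 0.95)
})

test_that("consensus equals the single run for an unambiguous structure", {
  W <- matrix(-0.2, 8, 8)
  W[1:4, 1:4] <- 1
  W[5:8, 5:8] <- 1
  diag(W) <- 0
  set.seed(306)
  single <- louvain_signed(W)
  cons <- consensus_partition(W, n_runs = 20)
  expect_equal(outer(cons$membership, cons$membership, "=="),
               outer(single$membership, single$membership, "=="))
  expect_equal(cons$Q, single$Q, tolerance = 1e-12)
})

test_that("a one-run consensus degenerates to plain Louvain", {
  set.seed(307)
  W <- random_signed_graph(10)
  set.seed(42)
  single <- louvain_signed(W)
  set.seed(42)
  cons <- consensus_partition(W, n_runs = 1)
  expect_equal(outer(cons$membership, cons$membership, "=="),
               outer(single$membership, single$membership, "=="))
})

test_that("consensus Q is at least the median single-run Q on a modular matrix", {
  set.seed(308)
  bl <- block_corr(5, 3, 0.6, -0.1)
  W <- bl$W + matrix(rnorm(225, sd = 0.15), 15)
  W <- (W + t(W)) / 2
  diag(W) <- 0
  qs <- replicate(25, louvain_signed(W)$Q)
  cons <- consensus_partition(W, n_runs = 25)
  expect_gte(cons$Q, stats::median(qs) - 1e-9)
})

test_that("participation coefficient and module-degree z follow their closed forms", {
  # node 1: all strength inside its own module -> PC 0
  W <- matrix(0, 6, 6)
  W[1, 2] <- W[2, 1] <- 1
  W[1, 3] <- W[3, 1] <- 1
  W[4, 5] <- W[5, 4] <- 1
  memb <- c(1, 1, 1, 2, 2, 2)
  expect_warning(carto <- node_cartography(W, memb), "isolated")
  expect_equal(carto$pc[1], 0)
  # equal split across two modules -> PC = 1 - 2 (1/2)^2 = 0.5
  W2 <- matrix(0, 4, 4)
  W2[1, 2] <- W2[2, 1] <- 1
  W2[1, 3] <- W2[3, 1] <- 1
  memb2 <- c(1, 1, 2, 2)
  carto2 <- suppressWarnings(node_cartography(W2, memb2))
  expect_equal(carto2$pc[1], 0.5)
  # identical within-module strengths -> MDZ all zero in that module
  W3 <- matrix(1, 4, 4)
  diag(W3) <- 0
  carto3 <- node_cartography(W3, rep(1, 4))
  expect_equal(carto3$mdz, rep(0, 4))
})

test_that("network summaries are order-invariant and handle single-node networks", {
  set.seed(309)
  atlas <- network_atlas(1:5, c("A", "A", "B", "B", "C"))
  carto <- data.frame(node = 1:5, module = 1, pc = runif(5), mdz = rnorm(5))
  s <- network_summarize(carto, atlas)
  expect_equal(s$mean_pc[s$network == "C"], carto$pc[5])
  expect_equal(s$mean_mdz[s$network == "A"], mean(carto$mdz[1:2]))
})
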