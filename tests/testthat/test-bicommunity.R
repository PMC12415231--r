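test_that("edge features are the sigma-scaled source/target embeddings", {
  g <- four_node_graph()
  comp <- svd_components(g, N = 2)
  f <- edge_features(g, comp, N = 1)
  expect_equal(ncol(f$F), 2)
  expect_equal(nrow(f$F), 2)
  # edge (1,3): (sigma1 u1[1], sigma1 v1[3]); edge (2,4) is its antipode
  expect_equal(unname(f$F[1, ]), c(1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(f$F[2, ]), -c(1, 1) / sqrt(2), tolerance = 1e-12)

  # features are linear in sigma
  comp2 <- comp
  comp2$sigma <- 2 * comp2$sigma
  f2 <- edge_features(g, comp2, N = 1)
  expect_equal(f2$F, 2 * f$F)

  expect_error(edge_features(g, comp, N = 3), "exceeds")
  empty <- directed_graph(matrix(0, 4, 4))
  expect_error(edge_features(empty, comp, N = 1), "no edges")
})

test_that("edge clustering is seeded, size-ordered, and validates K", {
  g <- four_node_graph()
  f <- edge_features(g, svd_components(g, N = 1), N = 1)
  expect_equal(cluster_edges(f, K = 1), c(1L, 1L))
  lab <- cluster_edges(f, K = 2, seed = 1)
  expect_setequal(lab, 1:2)
  expect_true(lab[1] != lab[2])  # antipodal features must separate
  expect_error(cluster_edges(f, K = 3), "exceeds the number of edges")

  # determinism and size-descending label numbering on a bigger problem
  sim <- generate_block_cycle(n_blocks = 3, block_size = 12, seed = 4)
  res <- detect_bicommunities(sim$graph, N = 2, K = 6, seed = 2)
  res2 <- detect_bicommunities(sim$graph, N = 2, K = 6, seed = 2)
  expect_identical(res$labels, res2$labels)
  sizes <- tabulate(res$labels)
  expect_true(all(diff(sizes) <= 0))
})

test_that("jointly negating a component's (u, v) pair leaves clusters unchanged", {
  sim <- generate_block_cycle(n_blocks = 3, block_size = 10, seed = 8)
  comp <- svd_components(sim$graph, N = 2)
  f <- edge_features(sim$graph, comp, N = 2)
  flipped <- comp
  flipped$U[, 2] <- -flipped$U[, 2]
  flipped$V[, 2] <- -flipped$V[, 2]
  f_flip <- edge_features(sim$graph, flipped, N = 2)
  lab <- cluster_edges(f, K = 5, seed = 3)
  lab_flip <- cluster_edges(f_flip, K = 5, seed = 3)
  expect_identical(lab, lab_flip)  # reflection is an isometry of feature space
})

test_that("bicommunity extraction derives node sets, scores and kinds", {
  g <- four_node_graph()
  bc <- extract_bicommunities(g, labels = c(1L, 2L))
  expect_length(bc, 2)
  b1 <- bc[[1]]
  expect_equal(b1$sending_nodes, "1")
  expect_equal(b1$receiving_nodes, "3")
  expect_equal(b1$qbi, 0.25)        # B[1,3] / m = 0.5 / 2
  expect_equal(b1$kind, "directed")
  expect_equal(unname(b1$node_roles), c("sending", "receiving"))
  expect_equal(unname(b1$send_recv_score), c(1, -1))

  # an all-within cluster is a self community with "both" roles
  tri <- two_triangles_graph()
  labels <- ifelse(structural_edges(tri)$source <= 3 &
                   structural_edges(tri)$target <= 3, 1L, 2L)
  bc_tri <- extract_bicommunities(tri, labels)
  self <- Filter(function(b) all(c("1", "2", "3") %in% b$sending_nodes), bc_tri)[[1]]
  expect_equal(self$kind, "self")
  expect_true(all(self$node_roles[c("1", "2", "3")] == "both"))
  expect_true(all(abs(self$send_recv_score) <= 1))

  expect_error(extract_bicommunities(g, labels = 1L), "cover all")
})

test_that("cluster qbi values sum to the induced K-community bimodularity", {
  g <- four_node_graph()
  bc <- extract_bicommunities(g, labels = c(1L, 2L))
  expect_equal(sum(vapply(bc, `[[`, 0, "qbi")),
               bimodularity(g, c(1, 2, 2, 1), c(2, 1, 1, 2)),
               tolerance = 1e-12)
  # results come sorted by qbi descending
  qbis <- vapply(bc, `[[`, 0, "qbi")
  expect_true(all(diff(qbis) <= 0))
})

test_that("edge clusters partition the edge set while node sets may overlap", {
  sim <- generate_block_cycle(n_blocks = 4, block_size = 10, seed = 5)
  res <- detect_bicommunities(sim$graph, N = 2, K = 8, seed = 5)
  e <- structural_edges(sim$graph)
  expect_length(res$labels, nrow(e))          # every edge exactly one label
  expect_true(all(res$labels %in% 1:8))
  senders <- unlist(lapply(res$bicommunities, `[[`, "sending_nodes"))
  expect_gt(length(senders), length(unique(senders)))  # overlap across clusters
})

test_that("adjusted Rand index behaves as a recovery score", {
  expect_equal(recovery_score(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  set.seed(21)
  const <- rep(1, 40)
  balanced <- rep(1:4, 10)
  expect_lt(abs(recovery_score(const, balanced)), 0.1)
  expect_error(recovery_score(1:3, 1:4), "different lengths")
})

test_that("bicommunity JSON and edge-cluster CSV exports are readable", {
  sim <- generate_block_cycle(n_blocks = 3, block_size = 8, seed = 2)
  res <- detect_bicommunities(sim$graph, N = 2, K = 4, seed = 2)
  jpath <- withr::local_tempfile(fileext = ".json")
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_bicommunities(res$bicommunities, jpath)
  write_edge_clusters(sim$graph, res$labels, cpath)
  parsed <- jsonlite::read_json(jpath)
  expect_length(parsed, 4)
  expect_true(all(c("cluster_id", "kind", "qbi", "sending_nodes",
                    "receiving_nodes", "node_roles", "send_recv_scores")
                  %in% names(parsed[[1]])))
  clusters <- utils::read.csv(cpath)
  expect_equal(nrow(clusters), length(res$labels))
  expect_equal(names(clusters), c("source", "target", "cluster"))
})
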