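test_that("degrees return row/column strengths that both sum to m", {
  g <- directed_graph(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  d <- degrees(g)
  expect_equal(unname(d$k_out), c(1, 0))
  expect_equal(unname(d$k_in), c(0, 1))

  cyc <- matrix(0, 3, 3); cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1
  d <- degrees(directed_graph(cyc))
  expect_equal(unname(d$k_out), rep(1, 3))
  expect_equal(unname(d$k_in), rep(1, 3))

  gw <- directed_graph(matrix(c(0, 2.5, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(unname(degrees(gw)$k_out), c(2.5, 0))
  expect_equal(total_weight(gw), 2.5)
})

test_that("modularity matrix matches closed forms on small graphs", {
  # a single edge equals its own configuration-model expectation
  g <- directed_graph(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  expect_equal(unname(modularity_matrix(g)$B), matrix(0, 2, 2))

  # 3-cycle: uniform degrees, B = A - 1/3 everywhere
  cyc <- matrix(0, 3, 3); cyc[1, 2] <- cyc[2, 3] <- cyc[3, 1] <- 1
  expect_equal(unname(modularity_matrix(directed_graph(cyc))$B),
               unname(cyc - 1 / 3))

  # worked 4-node example: +/- 0.5 in the upper-right block
  B <- modularity_matrix(four_node_graph())$B
  expect_equal(unname(B),
               rbind(c(0, 0, 0.5, -0.5),
                     c(0, 0, -0.5, 0.5),
                     c(0, 0, 0, 0),
                     c(0, 0, 0, 0)))

  expect_error(modularity_matrix(directed_graph(matrix(0, 2, 2))),
               "empty graph")
})

test_that("B has vanishing row and column sums on random graphs", {
  set.seed(1)
  for (trial in 1:20) {
    g <- random_graph(sample(3:15, 1), weighted = trial %% 2 == 0)
    bm <- modularity_matrix(g)
    expect_lt(max(abs(rowSums(bm$B))), 1e-9 * bm$m)
    expect_lt(max(abs(colSums(bm$B))), 1e-9 * bm$m)
    # symmetric input gives symmetric B
    gs <- directed_graph(g$A + t(g$A))
    Bs <- modularity_matrix(gs)$B
    expect_equal(Bs, t(Bs))
  }
})

test_that("bimodularity matches brute-force oracle and known values", {
  g <- four_node_graph()
  # one sending and one receiving community covering the whole graph
  expect_equal(bimodularity(g, rep(1, 4), rep(1, 4)), 0)
  # K = 2 mapping {1}->{3}, {2}->{4}: the two +0.5 blocks
  expect_equal(bimodularity(g, c(1, 2, 2, 1), c(2, 1, 1, 2)), 0.5)

  # literal-definition oracle on random partitions of random graphs
  set.seed(3)
  for (trial in 1:15) {
    n <- sample(4:12, 1)
    gr <- random_graph(n)
    K <- sample(1:4, 1)
    ao <- sample(K, n, replace = TRUE)
    ai <- sample(K, n, replace = TRUE)
    expect_equal(bimodularity(gr, ao, ai),
                 bimodularity_oracle(gr$A, ao, ai), tolerance = 1e-12)
  }

  expect_error(bimodularity(g, c(1, 1, 1), c(1, 1, 1, 1)), "one label per node")
  expect_error(bimodularity(g, c(0, 1, 1, 1), c(1, 1, 1, 1)), "positive")
})

test_that("two-community sign-vector form agrees with the partition form", {
  g <- four_node_graph()
  expect_equal(bimodularity_vectors(g, rep(1, 4), rep(1, 4)), 0)
  expect_equal(bimodularity_vectors(g, c(1, -1, 1, 1), c(1, 1, 1, -1)), 0.5)
  expect_error(bimodularity_vectors(g, c(1, 0, 1, 1), rep(1, 4)), "-1 and \\+1")

  set.seed(5)
  for (trial in 1:30) {
    n <- sample(3:20, 1)
    gr <- random_graph(n)
    s_out <- sample(c(-1, 1), n, replace = TRUE)
    s_in <- sample(c(-1, 1), n, replace = TRUE)
    q_vec <- bimodularity_vectors(gr, s_out, s_in)
    # the same bipartition in 1..2 label form
    q_part <- bimodularity(gr, ifelse(s_out > 0, 1, 2), ifelse(s_in > 0, 1, 2))
    expect_equal(q_vec, q_part, tolerance = 1e-12)
    # global sign symmetry
    expect_equal(bimodularity_vectors(gr, -s_out, -s_in), q_vec,
                 tolerance = 1e-12)
  }
})

test_that("undirected symmetric graphs reduce bimodularity to classical modularity", {
  g <- two_triangles_graph()
  member <- c(1, 1, 1, 2, 2, 2)
  q <- bimodularity(g, member, member)
  expect_equal(q, modularity_eq1(g$A, member), tolerance = 1e-12)
  expect_equal(q, 5 / 14, tolerance = 1e-12)

  s <- ifelse(member == 1, 1, -1)
  expect_equal(bimodularity_vectors(g, s, s), 5 / 14, tolerance = 1e-12)
})

test_that("exhaustive bipartition search finds the known optimum with its tie-break", {
  bb <- best_bipartition(four_node_graph())
  expect_equal(bb$qbi, 0.5)
  # lexicographically smallest optimum with s_out[1] fixed to +1
  expect_equal(bb$s_out, c(1, -1, 1, 1))
  expect_equal(bb$s_in, c(1, 1, 1, -1))

  # B = 0 graph: everything is optimal at 0; all-ones wins the tie-break
  g0 <- directed_graph(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
  bb0 <- best_bipartition(g0)
  expect_equal(bb0$qbi, 0)
  expect_equal(bb0$s_out, c(1, 1))
  expect_equal(bb0$s_in, c(1, 1))

  expect_error(best_bipartition(random_graph(13)), "max_n")

  # the optimum can never beat the spectral relaxation bound n * sigma1 / (2m)
  set.seed(9)
  for (trial in 1:10) {
    gr <- random_graph(sample(3:7, 1))
    bm <- modularity_matrix(gr)
    s1 <- svd_components(bm, N = 1)$sigma[1]
    expect_lte(best_bipartition(bm)$qbi, bm$n * s1 / (2 * bm$m) + 1e-12)
  }
})
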