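# Shared fixtures and independent oracles, built in code.

# Worked 4-node example: two parallel directed edges 1 -> 3 and 2 -> 4.
# B has +0.5 at (1,3), (2,4) and -0.5 at (1,4), (2,3); sigma_1 = 1, m = 2.
four_node_graph <- function() {
  A <- matrix(0, 4, 4)
  A[1, 3] <- 1
  A[2, 4] <- 1
  directed_graph(A)
}

# Two undirected triangles {1,2,3} and {4,5,6} joined by the edge 3-4,
# encoded as a symmetric binary adjacency (each undirected edge appears in
# both directions), so directed total weight m = 14.
two_triangles_graph <- function() {
  A <- matrix(0, 6, 6)
  und <- rbind(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6), c(3, 4))
  A[und] <- 1
  directed_graph(A + t(A))
}

# Random dense-ish directed graph with at least one edge.
random_graph <- function(n, p = 0.35, weighted = FALSE) {
  repeat {
    A <- matrix(stats::rbinom(n * n, 1, p), n, n)
    diag(A) <- 0
    if (sum(A) > 0) break
  }
  if (weighted) A <- A * matrix(stats::rexp(n * n) + 0.1, n, n)
  directed_graph(A)
}

# Independent oracle for classical (undirected) modularity, evaluated
# directly from its definition: Q = (1/2M) * sum_{i,j same community}
# (A_ij - k_i k_j / (2M)) with M undirected edges. For a symmetric directed
# encoding, sum(A) = 2M and k = rowSums(A), giving
# Q = (1/m) * sum_same (A_ij - k_i k_j / m) with m = sum(A).
modularity_eq1 <- function(A, membership) {
  m <- sum(A)
  k <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + A[i, j] - k[i] * k[j] / m
      }
    }
  }
  unname(q) / m
}

# Independent oracle for the K-community bimodularity index: literal block
# sum over sending/receiving label pairs of (A_ij - k_out_i k_in_j / m) / m.
bimodularity_oracle <- function(A, assign_out, assign_in) {
  m <- sum(A)
  ko <- rowSums(A)
  ki <- colSums(A)
  q <- 0
  for (k in unique(c(assign_out, assign_in))) {
    for (i in which(assign_out == k)) {
      for (j in which(assign_in == k)) {
        q <- q + A[i, j] - ko[i] * ki[j] / m
      }
    }
  }
  unname(q) / m
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
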