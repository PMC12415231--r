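#' Out- and in-degrees (strengths) of a directed graph
#'
#' For a weighted graph these are out- and in-strengths: `k_out[i]` is the
#' row sum of `A` and `k_in[j]` the column sum, so that
#' `sum(k_out) = sum(k_in) = m`.
#'
#' @param g a `directed_graph`.
#' @return list with numeric vectors `k_out` and `k_in`, named by node id.
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "directed_graph"))
  list(k_out = rowSums(g$A), k_in = colSums(g$A))
}

#' Directed modularity matrix
#'
#' Builds `B = A - k_out %*% t(k_in) / m`, the adjacency minus its
#' expectation under the directed configuration model, which redistributes
#' the `m` units of edge weight proportionally to out- and in-degrees. All
#' row sums and column sums of `B` are zero, so the whole-graph "community"
#' always has bimodularity zero; community structure lives in how sign mass
#' concentrates in blocks of `B`.
#'
#' The representation is dense: target graphs are at most a few thousand
#' nodes (a connectome, not a web graph).
#'
#' @param g a `directed_graph` with positive total weight.
#' @return object of class `modularity_matrix`: list with the `n x n` matrix
#'   `B`, degree vectors `k_out`, `k_in`, total weight `m`, node count `n`
#'   and `node_ids`.
#' @export
#' @examples
#' g <- directed_graph(matrix(c(0, 0, 1, 0,
#'                              0, 0, 0, 1,
#'                              0, 0, 0, 0,
#'                              0, 0, 0, 0), 4, 4, byrow = TRUE))
#' modularity_matrix(g)$B   # +/- 0.5 in the 2 x 2 corner blocks
modularity_matrix <- function(g) {
  stopifnot(inherits(g, "directed_graph"))
  m <- total_weight(g)
  if (m <= 0) stop("empty graph: total edge weight must be positive")
  d <- degrees(g)
  B <- g$A - tcrossprod(d$k_out, d$k_in) / m
  structure(list(B = B, k_out = d$k_out, k_in = d$k_in, m = m,
                 n = nrow(B), node_ids = g$node_ids),
            class = "modularity_matrix")
}

#' @export
print.modularity_matrix <- function(x, ...) {
  cat("modularity_matrix: ", x$n, " nodes, m = ", format(x$m), "\n", sep = "")
  invisible(x)
}

# Expected adjacency under the directed configuration model null.
null_expectation <- function(bm) {
  stopifnot(inherits(bm, "modularity_matrix"))
  tcrossprod(bm$k_out, bm$k_in) / bm$m
}

as_modularity_matrix <- function(x) {
  if (inherits(x, "modularity_matrix")) x
  else if (inherits(x, "directed_graph")) modularity_matrix(x)
  else stop("expected a directed_graph or modularity_matrix")
}

#' Bimodularity index of a sending/receiving partition pair
#'
#' The bimodularity index scores K paired communities: a sending partition
#' `assign_out` and a receiving partition `assign_in` over the same label set
#' `1..K`, with the implicit mapping that label k sends to label k. It is the
#' excess weight of edges running from each sending community to its mapped
#' receiving community over the configuration-model expectation:
#' `Qbi = (1/m) * sum_k sum_{i in C_k^out, j in C_k^in} B[i, j]`.
#'
#' For an undirected (symmetric) graph with `assign_out == assign_in` this
#' reduces to the classical modularity of that partition.
#'
#' @param x a `directed_graph` or a precomputed `modularity_matrix`.
#' @param assign_out integer vector of sending-community labels in `1..K`,
#'   one per node.
#' @param assign_in integer vector of receiving-community labels in `1..K`.
#' @return the bimodularity index, a single number.
#' @export
bimodularity <- function(x, assign_out, assign_in) {
  bm <- as_modularity_matrix(x)
  n <- bm$n
  assign_out <- as.integer(assign_out)
  assign_in <- as.integer(assign_in)
  if (length(assign_out) != n || length(assign_in) != n) {
    stop("partition vectors must have one label per node")
  }
  if (anyNA(assign_out) || anyNA(assign_in)) stop("labels must not be NA")
  labs <- sort(unique(c(assign_out, assign_in)))
  if (any(assign_out < 1L) || any(assign_in < 1L)) {
    stop("labels must be positive integers from a common 1..K set")
  }
  tot <- 0
  for (k in labs) {
    io <- assign_out == k
    ji <- assign_in == k
    if (any(io) && any(ji)) tot <- tot + sum(bm$B[io, ji, drop = FALSE])
  }
  tot / bm$m
}

#' Bimodularity of a two-community split in indicator-vector form
#'
#' The two-community case is encoded by sign vectors: `s_out[i] = +/-1`
#' places node i in one of the two sending communities and `s_in[j]` in one
#' of the two receiving ones, paired by sign. In this form
#' `Qbi = t(s_out) %*% B %*% s_in / (2m)`, the bilinear form whose convex
#' relaxation is solved by the SVD of B (see [svd_components()]).
#'
#' @param x a `directed_graph` or `modularity_matrix`.
#' @param s_out,s_in numeric vectors with entries in `{-1, +1}`, length n.
#' @return the bimodularity index; identical to [bimodularity()] on the
#'   corresponding two-community partition pair.
#' @export
bimodularity_vectors <- function(x, s_out, s_in) {
  bm <- as_modularity_matrix(x)
  if (length(s_out) != bm$n || length(s_in) != bm$n) {
    stop("sign vectors must have length n")
  }
  if (!all(s_out %in% c(-1, 1)) || !all(s_in %in% c(-1, 1))) {
    stop("sign vectors must contain only -1 and +1")
  }
  as.numeric(crossprod(s_out, bm$B %*% s_in)) / (2 * bm$m)
}

# all sign vectors of length n as rows, lexicographic with +1 before -1;
# row 1 is all +1.
all_sign_vectors <- function(n, fix_first = FALSE) {
  stopifnot(n >= 1)
  r <- 0:(2^(n - ifelse(fix_first, 1L, 0L)) - 1L)
  k <- if (fix_first) n - 1L else n
  S <- matrix(1, length(r), n)
  if (k > 0) {
    for (b in seq_len(k)) {
      bit <- bitwAnd(r %/% 2^(k - b), 1L)
      S[, b + ifelse(fix_first, 1L, 0L)] <- 1 - 2 * bit
    }
  }
  S
}

#' Exhaustive best two-community bipartition (testing oracle)
#'
#' Maximizes the bilinear bimodularity `t(s_out) B s_in / (2m)` over all
#' sign-vector pairs by brute force. Intended as an independent oracle for
#' small graphs; cost grows as `4^n`. The global sign symmetry
#' `Qbi(-s_out, -s_in) = Qbi(s_out, s_in)` is quotiented by fixing
#' `s_out[1] = +1`; ties are broken by the lexicographically smallest
#' `(s_out, s_in)` with `+1` ordered before `-1`.
#'
#' @param x a `directed_graph` or `modularity_matrix` with at most `max_n`
#'   nodes.
#' @param max_n guard on the exhaustive search (default 12).
#' @return list with `s_out`, `s_in` and the maximum `qbi`.
#' @export
best_bipartition <- function(x, max_n = 12L) {
  bm <- as_modularity_matrix(x)
  n <- bm$n
  if (n > max_n) {
    stop("exhaustive search limited to max_n = ", max_n, " nodes, got ", n)
  }
  S_out <- all_sign_vectors(n, fix_first = TRUE)
  S_in <- all_sign_vectors(n)
  vals <- (S_out %*% bm$B %*% t(S_in)) / (2 * bm$m)
  best <- max(vals)
  hits <- which(vals == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  list(s_out = S_out[hits[1, 1], ], s_in = S_in[hits[1, 2], ], qbi = best)
}
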