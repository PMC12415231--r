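#' Directed stochastic-block-model generator
#'
#' Generates binary directed graphs with planted block structure, built so
#' that the symmetrized graph `A + t(A)` is an ordinary undirected SBM:
#'
#' * Within each block, every unordered node pair gets an edge with
#'   probability `p_within`; the edge is then oriented from the lower-index
#'   node to the higher-index one with probability `p_dir` (default 0.5, in
#'   which case the convention is immaterial), otherwise reversed.
#' * Between blocks a and b, every node pair gets an edge with probability
#'   `between[a, b] + between[b, a]`; the edge is oriented a -> b with
#'   conditional probability `between[a, b] / (between[a, b] + between[b, a])`.
#'   The block-cycle model sets `between[k, k+1] = p_con` and everything
#'   else 0, so all between-block edges run one way around the cycle.
#'
#' Every node pair receives at most one directed edge (no bidirectional
#' pairs) and no self-loops are created, so `A * t(A) == 0` elementwise on
#' every draw and the within-block symmetrized density estimates `p_within`.
#'
#' @param block_sizes integer vector of node counts per block.
#' @param p_within within-block undirected edge probability.
#' @param between square matrix over blocks: `between[a, b]` is the
#'   probability of an edge between a node of block a and one of block b
#'   oriented a -> b (diagonal ignored). `between[a, b] + between[b, a]`
#'   must not exceed 1.
#' @param p_dir probability a within-block edge points from the lower to
#'   the higher node index.
#' @param seed RNG seed; the same seed reproduces the graph exactly.
#' @return list with `graph` (a [directed_graph()] with node ids
#'   `n1, n2, ...`), `node_blocks` (integer block label per node) and
#'   `edge_labels` (character `"a->b"` ground-truth label per edge in the
#'   canonical row-major edge order).
#' @export
generate_sbm <- function(block_sizes, p_within, between, p_dir = 0.5,
                         seed = 1L) {
  block_sizes <- as.integer(block_sizes)
  if (any(block_sizes < 1L)) stop("block sizes must be positive")
  nb <- length(block_sizes)
  between <- as.matrix(between)
  if (!all(dim(between) == nb)) stop("between must be ", nb, " x ", nb)
  if (p_within < 0 || p_within > 1 || p_dir < 0 || p_dir > 1 ||
      any(between < 0) || any(between + t(between) - diag(diag(between)) > 1 + 1e-12)) {
    stop("probabilities must lie in [0, 1] (and between[a,b] + between[b,a] <= 1)")
  }
  n <- sum(block_sizes)
  blocks <- rep(seq_len(nb), block_sizes)
  offsets <- c(0L, cumsum(block_sizes))

  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(seed)

  A <- matrix(0, n, n)
  # within-block edges
  for (b in seq_len(nb)) {
    nodes <- offsets[b] + seq_len(block_sizes[b])
    if (length(nodes) < 2L) next
    pairs <- which(upper.tri(diag(length(nodes))), arr.ind = TRUE)
    has <- stats::runif(nrow(pairs)) < p_within
    if (!any(has)) next
    fwd <- stats::runif(sum(has)) < p_dir
    i <- nodes[pairs[has, 1]]
    j <- nodes[pairs[has, 2]]
    A[cbind(ifelse(fwd, i, j), ifelse(fwd, j, i))] <- 1
  }
  # between-block edges, one unordered block pair at a time
  for (a in seq_len(nb)) {
    for (b in seq_len(nb)) {
      if (b <= a) next
      p_ab <- between[a, b]
      p_ba <- between[b, a]
      p_tot <- p_ab + p_ba
      if (p_tot <= 0) next
      na <- block_sizes[a]; nbb <- block_sizes[b]
      ia <- offsets[a] + seq_len(na)
      ib <- offsets[b] + seq_len(nbb)
      grid <- expand.grid(i = ia, j = ib)
      has <- stats::runif(nrow(grid)) < p_tot
      if (!any(has)) next
      fwd <- stats::runif(sum(has)) < p_ab / p_tot
      i <- grid$i[has]; j <- grid$j[has]
      A[cbind(ifelse(fwd, i, j), ifelse(fwd, j, i))] <- 1
    }
  }

  g <- directed_graph(A, paste0("n", seq_len(n)))
  e <- structural_edges(g)
  list(graph = g, node_blocks = blocks,
       edge_labels = paste0(blocks[e$source], "->", blocks[e$target]))
}

#' Block-cycle directed stochastic block graph
#'
#' The canonical planted structure for bimodularity: `n_blocks` dense
#' self-communities arranged in a cycle, with all between-block edges
#' oriented one way around the cycle (block k sends to block k+1). The
#' reference configuration is 4 blocks of 50 nodes with within- and
#' between-block density 0.3; its edge clustering at N = 2 components and
#' K = 8 clusters recovers 4 self-communities and 4 directed bicommunities.
#'
#' @param n_blocks number of blocks (>= 2).
#' @param block_size nodes per block.
#' @param p_self within-block undirected edge density.
#' @param p_con density of edges between consecutive blocks.
#' @param p_dir within-block orientation probability (see [generate_sbm()]).
#' @param seed RNG seed.
#' @return same structure as [generate_sbm()].
#' @export
#' @examples
#' sim <- generate_block_cycle(n_blocks = 4, block_size = 20, seed = 1)
#' graph_summary(sim$graph)
generate_block_cycle <- function(n_blocks = 4L, block_size = 50L,
                                 p_self = 0.3, p_con = 0.3, p_dir = 0.5,
                                 seed = 1L) {
  if (n_blocks < 2L) stop("n_blocks must be at least 2")
  between <- matrix(0, n_blocks, n_blocks)
  for (k in seq_len(n_blocks)) {
    between[k, k %% n_blocks + 1L] <- p_con
  }
  generate_sbm(rep(block_size, n_blocks), p_within = p_self,
               between = between, p_dir = p_dir, seed = seed)
}

#' Ground-truth edge labels for a node block assignment
#'
#' Labels every edge of `g` by its `(source block) -> (target block)` pair
#' in the canonical row-major edge order, for comparison against detected
#' edge clusters with [recovery_score()].
#'
#' @param g a `directed_graph`.
#' @param node_blocks block label per node.
#' @return character vector, one `"a->b"` label per edge.
#' @export
edge_block_labels <- function(g, node_blocks) {
  stopifnot(inherits(g, "directed_graph"))
  if (length(node_blocks) != n_nodes(g)) {
    stop("node_blocks must have one label per node")
  }
  e <- structural_edges(g)
  paste0(node_blocks[e$source], "->", node_blocks[e$target])
}
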