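#' Construct a directed graph from a weight matrix
#'
#' The universal input object of the package: an ordered node set together
#' with a dense nonnegative weight matrix `A`, where `A[i, j]` is the weight
#' of the edge running from source node `i` (row) to target node `j`
#' (column). The total directed edge weight `m = sum(A)` plays the role of
#' the edge count for binary graphs and must be positive for all downstream
#' spectral computations.
#'
#' @param A square numeric matrix of nonnegative edge weights; rows are
#'   sources, columns are targets.
#' @param node_ids optional character or integer vector of unique node
#'   identifiers, one per row of `A`. Defaults to existing dimnames or
#'   `1:n`.
#' @param metadata optional data frame of per-node annotations with a
#'   `node` column matching `node_ids` (e.g. neuron type, body position).
#' @return An object of class `directed_graph` with elements `A`,
#'   `node_ids` and `metadata`.
#' @seealso [read_edge_list()], [read_adjacency()], [graph_summary()]
#' @export
#' @examples
#' g <- directed_graph(matrix(c(0, 1, 0, 0), 2, 2, byrow = TRUE))
#' total_weight(g)
directed_graph <- function(A, node_ids = NULL, metadata = NULL) {
  A <- as.matrix(A)
  if (nrow(A) != ncol(A)) {
    stop("adjacency matrix must be square, got ", nrow(A), " x ", ncol(A))
  }
  if (!is.numeric(A)) stop("adjacency matrix must be numeric")
  if (anyNA(A)) stop("adjacency matrix contains missing values")
  if (any(A < 0)) stop("negative edge weights are not allowed")
  n <- nrow(A)
  if (is.null(node_ids)) {
    node_ids <- if (!is.null(rownames(A))) rownames(A) else as.character(seq_len(n))
  }
  node_ids <- as.character(node_ids)
  if (length(node_ids) != n) stop("node_ids length must match matrix dimension")
  if (anyDuplicated(node_ids)) stop("node_ids must be unique")
  dimnames(A) <- list(node_ids, node_ids)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"node" %in% names(metadata)) stop("metadata must have a 'node' column")
    metadata$node <- as.character(metadata$node)
  }
  structure(list(A = A, node_ids = node_ids, metadata = metadata),
            class = "directed_graph")
}

#' @export
print.directed_graph <- function(x, ...) {
  s <- graph_summary(x)
  cat("directed_graph: ", s$n_nodes, " nodes, ", s$n_edges,
      " directed edges (total weight ", format(s$total_weight), ")\n", sep = "")
  invisible(x)
}

#' Total directed edge weight of a graph
#'
#' Sum of all adjacency entries; for a binary graph this is the number of
#' directed edges. Denoted `m` throughout.
#'
#' @param g a `directed_graph`.
#' @return a single nonnegative number.
#' @export
total_weight <- function(g) {
  stopifnot(inherits(g, "directed_graph"))
  sum(g$A)
}

#' Number of nodes in a graph
#' @param g a `directed_graph`.
#' @return integer node count.
#' @export
n_nodes <- function(g) length(g$node_ids)

#' Structural edge list in canonical order
#'
#' Lists the nonzero entries of the adjacency matrix in the package-wide
#' canonical order: a row-major scan of `A` (all targets of node 1, then of
#' node 2, ...). Every per-edge quantity in the package — feature rows,
#' cluster labels, ground-truth labels — uses this single ordering.
#'
#' @param g a `directed_graph`.
#' @return data frame with integer columns `source`, `target` (node
#'   indices) and numeric `weight`, one row per structural edge.
#' @export
structural_edges <- function(g) {
  A <- g$A
  n <- nrow(A)
  idx <- which(t(A) > 0)
  src <- (idx - 1L) %/% n + 1L
  tgt <- (idx - 1L) %% n + 1L
  data.frame(source = src, target = tgt,
             weight = A[cbind(src, tgt)],
             stringsAsFactors = FALSE)
}

#' Read a directed graph from a delimited edge list
#'
#' Accepts TSV or CSV text with at least source and target columns and an
#' optional weight column; lines starting with `#` are comments. Node ids are
#' arbitrary tokens and nodes are ordered by first occurrence (sources before
#' targets within a row), so repeated runs give identical node orderings and
#' hence reproducible embeddings. Duplicate `(source, target)` rows are
#' aggregated by summing their weights; a missing weight column means weight
#' 1 per row.
#'
#' A header row is assumed when the first row's first two tokens are
#' non-numeric (e.g. `source  target  weight`); override with `header`.
#'
#' @param path path to the edge-list file.
#' @param weight_col name of the weight column when a header is present
#'   (default `"weight"`); ignored for headerless files, where the third
#'   column (if any) is the weight.
#' @param header `TRUE`/`FALSE` to force header handling, or `NULL` (default)
#'   to auto-detect.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma vs
#'   whitespace.
#' @param binarize if `TRUE`, all positive aggregated weights are set to 1
#'   (a binary graph); useful when the edge list stores multiplicities such
#'   as synapse counts.
#' @param zero_index if `TRUE`, purely integer node tokens are shifted by +1
#'   (0-based files).
#' @return a [directed_graph()].
#' @export
read_edge_list <- function(path, weight_col = "weight", header = NULL,
                           sep = NULL, binarize = FALSE, zero_index = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) stop("no edges: file '", path, "' has no data rows")

  if (is.null(sep)) {
    first <- lines[[1]]
    sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else "[[:space:]]+"
  }
  fields <- strsplit(lines, sep)

  tok_numeric <- function(x) !is.na(suppressWarnings(as.numeric(x)))
  if (is.null(header)) {
    f1 <- fields[[1]]
    header <- length(f1) >= 2 && !tok_numeric(f1[[1]]) && !tok_numeric(f1[[2]]) &&
      any(tolower(f1) %in% c("source", "target", "from", "to"))
  }
  wcol <- 3L
  if (header) {
    hd <- tolower(fields[[1]])
    wmatch <- match(tolower(weight_col), hd)
    if (!is.na(wmatch)) wcol <- wmatch
    fields <- fields[-1L]
    line_no <- line_no[-1L]
    if (length(fields) == 0L) stop("no edges: file '", path, "' has a header but no data rows")
  }

  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("malformed row at line ", line_no[which(nf < 2L)[1]],
         ": need at least source and target")
  }
  src <- vapply(fields, `[[`, "", 1L)
  tgt <- vapply(fields, `[[`, "", 2L)
  w <- rep(1, length(fields))
  has_w <- nf >= wcol
  if (any(has_w)) {
    wtok <- vapply(fields[has_w], `[[`, "", wcol)
    wnum <- suppressWarnings(as.numeric(wtok))
    if (anyNA(wnum)) {
      stop("malformed row at line ", line_no[has_w][which(is.na(wnum))[1]],
           ": non-numeric weight '", wtok[which(is.na(wnum))[1]], "'")
    }
    w[has_w] <- wnum
  }
  if (any(w < 0)) {
    stop("negative weight at line ", line_no[which(w < 0)[1]])
  }

  if (zero_index) {
    shift <- function(x) {
      ints <- grepl("^[0-9]+$", x)
      x[ints] <- as.character(as.integer(x[ints]) + 1L)
      x
    }
    src <- shift(src); tgt <- shift(tgt)
  }

  # first-occurrence node order over the interleaved (source, target) stream
  stream <- as.vector(rbind(src, tgt))
  node_ids <- unique(stream)
  n <- length(node_ids)
  i <- match(src, node_ids)
  j <- match(tgt, node_ids)
  A <- matrix(0, n, n)
  for (e in seq_along(i)) A[i[e], j[e]] <- A[i[e], j[e]] + w[e]
  if (binarize) A <- (A > 0) * 1
  if (any(diag(A) > 0)) warning("edge list contains self-loops; they are kept and counted in degrees")
  directed_graph(A, node_ids)
}

#' Read a directed graph from a dense adjacency matrix file
#'
#' Expects a square numeric matrix in delimited text, rows = source nodes.
#' If the first row is non-numeric it is taken as node ids (a header), and a
#' matching first column of ids is used as row names.
#'
#' @param path path to the matrix file.
#' @param node_ids optional node identifiers overriding any found in the file.
#' @param sep field separator passed to [utils::read.table()] (default
#'   whitespace/tab; use `","` for CSV).
#' @return a [directed_graph()].
#' @export
read_adjacency <- function(path, node_ids = NULL, sep = "") {
  first <- readLines(path, n = 1L, warn = FALSE)
  toks <- strsplit(first, if (nzchar(sep)) sep else "[[:space:],]+")[[1]]
  has_header <- any(is.na(suppressWarnings(as.numeric(toks[nzchar(toks)]))))
  tab <- utils::read.table(path, header = has_header, sep = sep,
                           comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- NULL
  if (has_header && ncol(tab) == nrow(tab) + 1L &&
      !is.numeric(tab[[1]])) {  # leading id column
    ids <- as.character(tab[[1]])
    tab <- tab[, -1L, drop = FALSE]
  } else if (has_header) {
    ids <- colnames(tab)
  }
  M <- as.matrix(tab)
  if (!is.numeric(M)) stop("adjacency file contains non-numeric entries")
  if (nrow(M) != ncol(M)) {
    stop("adjacency matrix must be square, got ", nrow(M), " x ", ncol(M))
  }
  if (any(M < 0)) stop("negative entries in adjacency matrix")
  if (!is.null(node_ids)) ids <- node_ids
  if (any(diag(M) > 0)) warning("adjacency contains self-loops; they are kept and counted in degrees")
  directed_graph(unname(M), ids)
}

#' Read per-node metadata and attach it to a graph
#'
#' The metadata file is a CSV/TSV with a `node` column plus arbitrary
#' annotation columns (e.g. `type`, `position`).
#'
#' @param g a `directed_graph`.
#' @param path path to the metadata table.
#' @return `g` with its `metadata` field set (rows ordered as `g$node_ids`;
#'   nodes without a metadata row get `NA`s).
#' @export
attach_node_metadata <- function(g, path) {
  stopifnot(inherits(g, "directed_graph"))
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           comment.char = "#", stringsAsFactors = FALSE)
  if (!"node" %in% names(tab)) stop("metadata must have a 'node' column")
  tab$node <- as.character(tab$node)
  g$metadata <- tab[match(g$node_ids, tab$node), , drop = FALSE]
  g$metadata$node <- g$node_ids
  rownames(g$metadata) <- NULL
  g
}

#' Write a graph as a delimited edge list
#'
#' Emits a headered TSV with columns `source`, `target`, `weight` in the
#' canonical row-major edge order, suitable for [read_edge_list()] (the
#' round trip preserves the weight matrix up to text precision).
#'
#' @param g a `directed_graph`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(g, path) {
  stopifnot(inherits(g, "directed_graph"))
  e <- structural_edges(g)
  out <- data.frame(source = g$node_ids[e$source],
                    target = g$node_ids[e$target],
                    weight = format(e$weight, digits = 17, scientific = FALSE,
                                    trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summarize a directed graph
#'
#' Counts nodes, structural edges (nonzero entries), total weight, and the
#' symmetry pattern of connections: an ordered pair `(i, j)` with
#' `A[i,j] > 0` and `A[j,i] = 0` is unidirectional, an unordered pair with
#' both directions present is bidirectional, and nonzero diagonal entries
#' are self-loops. The classification is structural (nonzero pattern), not
#' weight-based, and the counts satisfy
#' `n_edges = n_unidirectional + 2 * n_bidirectional + n_self_loops`.
#'
#' @param g a `directed_graph`.
#' @return an object of class `graph_summary`: a list with `n_nodes`,
#'   `n_edges`, `total_weight`, `n_unidirectional`, `n_bidirectional`,
#'   `n_self_loops`.
#' @export
graph_summary <- function(g) {
  stopifnot(inherits(g, "directed_graph"))
  A <- g$A > 0
  diag_hits <- sum(diag(A))
  off <- A
  diag(off) <- FALSE
  both <- off & t(off)
  s <- list(
    n_nodes = nrow(A),
    n_edges = sum(A),
    total_weight = sum(g$A),
    n_unidirectional = sum(off & !both),
    n_bidirectional = sum(both) / 2L,
    n_self_loops = diag_hits
  )
  structure(s, class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat("nodes:          ", x$n_nodes, "\n",
      "edges:          ", x$n_edges, "\n",
      "total weight:   ", format(x$total_weight), "\n",
      "unidirectional: ", x$n_unidirectional, "\n",
      "bidirectional:  ", x$n_bidirectional, " pairs\n",
      "self-loops:     ", x$n_self_loops, "\n", sep = "")
  invisible(x)
}
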