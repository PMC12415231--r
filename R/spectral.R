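#' Bimodular components: SVD of the directed modularity matrix
#'
#' Relaxing the sign vectors of the two-community bimodularity to unit-norm
#' vectors turns maximization of `t(s_out) B s_in` into the classical
#' variational problem solved by the singular value decomposition
#' `B = U Sigma t(V)`. Column k of `U` is the sending embedding `u_k`,
#' column k of `V` the receiving embedding `v_k`, and the singular value
#' `sigma_k` gives the component's (relaxed) bimodularity
#' `sigma_k / (2m)`; components are returned by decreasing `sigma`.
#'
#' Two conventions remove the inherent SVD ambiguities:
#' * Orientation: `(u_k, v_k)` may be jointly negated without changing
#'   anything; the pair is flipped so the entry of `u_k` with largest
#'   absolute value is positive (ties: lowest index). This makes repeated
#'   runs bitwise identical.
#' * Sign: `sigma_k` is nonnegative by construction, so the
#'   assortative/disassortative character that the eigenvalue sign carries
#'   in the undirected case is recovered from the dot product of the two
#'   singular vectors: `signed_mu_k = sign(t(u_k) v_k) * sigma_k`. A
#'   positive value means the sending and receiving sets overlap
#'   (assortative, a conventional community); a negative one means edges run
#'   between largely disjoint sets (disassortative). When `|t(u) v|` is
#'   below 1e-10 the sign is taken as positive. `signed_mu` is reporting
#'   metadata only; all downstream computation uses the nonnegative `sigma`.
#'
#' @param x a `directed_graph` or `modularity_matrix`.
#' @param N number of leading components to keep, `1 <= N <= n`.
#' @return object of class `bimodular_components`: list with matrices
#'   `U` (`n x N`), `V` (`n x N`), vectors `sigma`, `cos_uv`, `signed_mu`,
#'   `qbi` (`= sigma / (2m)`), plus `m`, `n`, `N`, `node_ids`.
#' @export
#' @examples
#' g <- directed_graph(matrix(c(0, 0, 1, 0,
#'                              0, 0, 0, 1,
#'                              0, 0, 0, 0,
#'                              0, 0, 0, 0), 4, 4, byrow = TRUE))
#' svd_components(g, N = 1)  # sigma_1 = 1, u1 = (1, -1, 0, 0)/sqrt(2)
svd_components <- function(x, N = NULL) {
  bm <- as_modularity_matrix(x)
  n <- bm$n
  if (is.null(N)) N <- n
  if (N < 1 || N > n) stop("N must be between 1 and n = ", n)
  dec <- svd(bm$B, nu = n, nv = n)
  U <- dec$u[, seq_len(N), drop = FALSE]
  V <- dec$v[, seq_len(N), drop = FALSE]
  sigma <- dec$d[seq_len(N)]
  for (k in seq_len(N)) {
    pivot <- which.max(abs(U[, k]))        # ties: lowest index
    if (U[pivot, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  cos_uv <- colSums(U * V)
  sgn <- ifelse(abs(cos_uv) < 1e-10, 1, sign(cos_uv))
  structure(list(U = U, V = V, sigma = sigma, cos_uv = cos_uv,
                 signed_mu = sgn * sigma, qbi = sigma / (2 * bm$m),
                 m = bm$m, n = n, N = N, node_ids = bm$node_ids),
            class = "bimodular_components")
}

#' @export
print.bimodular_components <- function(x, ...) {
  cat("bimodular_components: N = ", x$N, " of n = ", x$n, " (m = ",
      format(x$m), ")\n", sep = "")
  print(utils::head(spectrum_table(x), 10))
  invisible(x)
}

#' Per-component bimodularity
#'
#' The bimodularity achieved by one relaxed component,
#' `Qbi(u_k, v_k) = t(u_k) B v_k / (2m) = sigma_k / (2m)`.
#'
#' @param components a `bimodular_components` object.
#' @param k component index (default all computed components).
#' @return numeric vector of `sigma_k / (2m)` values.
#' @export
component_bimodularity <- function(components, k = NULL) {
  stopifnot(inherits(components, "bimodular_components"))
  if (is.null(k)) components$qbi else components$qbi[k]
}

#' Spectrum table
#'
#' One row per component: index, singular value, signed value (dot-product
#' sign convention) and per-component bimodularity.
#'
#' @param components a `bimodular_components` object.
#' @return data frame with columns `k`, `sigma`, `signed_mu`, `qbi`.
#' @export
spectrum_table <- function(components) {
  stopifnot(inherits(components, "bimodular_components"))
  data.frame(k = seq_len(components$N), sigma = components$sigma,
             signed_mu = components$signed_mu, qbi = components$qbi)
}

#' Node embedding coordinates
#'
#' Projects every node onto the sending/receiving axes of the leading
#' components: node i gets the 2N coordinates
#' `(u_1[i], v_1[i], ..., u_N[i], v_N[i])`. Plotting `u_1` against `v_1`
#' reproduces the standard bimodular node map (senders spread along the
#' horizontal axis, receivers along the vertical one).
#'
#' @param components a `bimodular_components` object.
#' @param N number of components to include (default all computed).
#' @return data frame with a `node` column and columns `u1, v1, ..., uN, vN`.
#' @export
node_embedding <- function(components, N = components$N) {
  stopifnot(inherits(components, "bimodular_components"))
  if (N < 1 || N > components$N) stop("N must be between 1 and ", components$N)
  out <- data.frame(node = components$node_ids, stringsAsFactors = FALSE)
  for (k in seq_len(N)) {
    out[[paste0("u", k)]] <- components$U[, k]
    out[[paste0("v", k)]] <- components$V[, k]
  }
  out
}

#' Write the node embedding as CSV
#' @param components a `bimodular_components` object.
#' @param path output path.
#' @param N number of components to export.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(components, path, N = components$N) {
  utils::write.csv(node_embedding(components, N), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Write the singular-value spectrum as CSV
#' @param components a `bimodular_components` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(components, path) {
  utils::write.csv(spectrum_table(components), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
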