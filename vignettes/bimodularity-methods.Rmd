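---
title: "Bimodularity: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bimodularity: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bimodularity)
```

# The problem

Directed networks carry structure that a single node partition cannot
express: a set of nodes can collectively project onto a *different* set.
The package formalizes this as paired **sending** and **receiving**
communities with an implicit one-to-one mapping between them, and scores a
pairing by the **bimodularity index**

$$Q_{bi} = \frac{1}{m} \sum_{k=1}^{K} \sum_{i \in C_k^{out},\, j \in C_k^{in}}
  \left( A_{ij} - \frac{k_i^{out} k_j^{in}}{m} \right),$$

the excess weight of edges running from each sending community to its
mapped receiving community over the directed configuration model, which
redistributes the $m$ units of edge weight proportionally to out- and
in-degrees. The bracketed term is the directed modularity matrix
$B = A - k^{out} (k^{in})^\top / m$; all its row and column sums vanish, so
the trivial whole-graph pairing always scores zero.

Two structural facts drive the rest of the design:

* For a **two-way** pairing encoded by sign vectors,
  $Q_{bi}(s^{out}, s^{in}) = s^{out\top} B\, s^{in} / (2m)$. Relaxing the
  signs to unit-norm vectors makes this a bilinear Rayleigh problem whose
  stationary points are exactly the singular vector pairs of $B$, with
  $Q_{bi}(u_k, v_k) = \sigma_k / (2m)$. The SVD is therefore the single
  spectral engine of the package (the eigendecomposition of $B B^\top$ /
  $B^\top B$ is mathematically the same and is not implemented separately).
* On a symmetric graph with coinciding partitions the index reduces to
  classical Newman modularity; the test suite asserts this reduction
  against an independent, literal evaluation of the classical formula.

# From embeddings to bicommunities

Node embeddings ($u_k$ for sending behaviour, $v_k$ for receiving) do not
by themselves yield the mapping between partitions. The detection step
therefore clusters **edges**: edge $(i,j)$ is described by

$$f(i,j) = (\sigma_1 u_1[i],\ \sigma_1 v_1[j],\ \ldots,\
            \sigma_N u_N[i],\ \sigma_N v_N[j]),$$

so edges with similar sending *and* receiving profiles land together.
Scaling by $\sigma_k$ weights each component by its bimodularity, which
damps the influence of the cut-off $N$ — a standard spectral-clustering
device. k-means on these features partitions the edge set; each cluster's
source-node set is its sending community and its target-node set the
receiving one. Node sets of different clusters may overlap (a node can
send in one bicommunity and receive in another); edge clusters never do.

Per cluster the package reports:

* `qbi`: the block sum $\sum_{i \in C^{out}, j \in C^{in}} B_{ij} / m$.
  This is the form the index itself takes for block-structured pairings; a
  variant restricted to the cluster's own edges is exposed as `qbi_edges`
  for comparison, since for overlapping clusters the block sums need not
  add up to a partition-level index.
* `kind`: `"self"` when the Jaccard overlap of sending and receiving sets
  is at least 0.5, else `"directed"`. A threshold is unavoidable when
  turning the visual self-vs-directed distinction into code; 0.5 is the
  natural midpoint, and on the block-cycle benchmark the two classes sit
  far from it (Jaccard 1 vs 0), so the classification is insensitive to
  the exact value. The threshold is an argument (`self_jaccard`) for
  borderline real data.
* `node_roles` and `send_recv_score`: per member node, whether it sends,
  receives or does both within the cluster, and the signed imbalance
  $(w_{out} - w_{in})/(w_{out} + w_{in})$ over its cluster-incident edge
  weight ($+1$ = pure sender).

# Tunable parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `N` | 2 | SVD components in the edge features. Choose from the spectrum: the block-cycle benchmark has exactly two dominant singular values. $\sigma$-scaling makes moderate over-shoot benign. |
| `K` | 8 | k-means cluster count; one cluster per expected community pair (4 self + 4 directed for the 4-block cycle). Not auto-selected — both `N` and `K` are deliberately user-facing. |
| `n_init` | 20 | k-means++ restarts; the best total within-cluster sum of squares wins. 20 restarts make the clustering outcome stable across seeds at benchmark sizes. |
| `seed` | 1 | controls k-means++ sampling (and graph generation in the study helpers); same seed, same input ⇒ identical labels. |
| `p_self`, `p_con` | 0.3 | within-/between-block undirected densities of the generator's reference configuration (4 blocks × 50 nodes). |
| `p_dir` | 0.5 | probability a within-block edge is oriented low→high node index. At 0.5 the convention is immaterial; defining "forward" by index order is what makes other values well-defined at all. |

# Numerical conventions

* **Orientation of singular vectors.** $(u_k, v_k) \to (-u_k, -v_k)$ is a
  symmetry of the SVD. The pair is flipped so the largest-magnitude entry
  of $u_k$ is positive (ties: lowest index), making repeated runs bitwise
  identical. A joint flip is an isometry of the edge-feature space, so it
  cannot change clustering results — a property the tests assert directly.
* **Assortativity sign.** $\sigma_k \ge 0$ by construction, so the sign
  that distinguishes assortative from disassortative structure in the
  symmetric case is recovered as $\mathrm{sign}(u_k^\top v_k)\,\sigma_k$
  (`signed_mu`). When $|u_k^\top v_k| < 10^{-10}$ the sign is reported
  positive (the orthogonal case is exactly attained by small examples).
  `signed_mu` is reporting metadata; all computation uses $\sigma_k$.
* **Tolerances.** Floating-point identities (zero row/column sums,
  $u^\top B v = \sigma$) are checked at $10^{-9}$ relative to $m$ or
  $\sigma_1$.
* **k-means.** k-means++ seeding with Lloyd iterations (cap 100),
  `n_init` restarts; restarts that empty a cluster are discarded. Labels
  are renumbered by decreasing cluster size (ties: original label order).
* **Brute-force oracle.** The exhaustive bipartition search fixes
  $s^{out}_1 = +1$ to quotient the global sign symmetry and breaks ties by
  the lexicographically smallest pair with $+1$ ordered first. It is
  $O(4^n)$ and capped at $n \le 12$; it exists to validate the spectral
  path, not to be used on data.
* **Dense algebra.** $B$ is dense and the SVD is the full `svd()`; target
  graphs are connectome-sized (hundreds to a few thousand nodes). A
  factored representation of $B$ (sparse $A$ minus a rank-1 term) is a
  noted future optimization.
* **Weights.** Weighted graphs are supported throughout by reading
  "fraction of edges" as fraction of total edge weight; this degenerates
  exactly to the binary case. The benchmark path is binary, so binary
  inputs are the well-exercised one. Each structural edge contributes one
  unweighted row to the k-means sample regardless of its weight.
* **Degenerate inputs.** Isolated nodes embed at the origin and may carry
  a sending label (their $B$ rows are pure null-model terms — well defined,
  no special casing). Self-loops are accepted on input with a warning and
  count toward degrees and $m$; the generators never emit them. An empty
  graph ($m = 0$) is rejected by `modularity_matrix()`.

# What the generator does and does not emulate

`generate_sbm()` / `generate_block_cycle()` produce binary directed
stochastic block graphs: undirected edges drawn per block pair, then
oriented — within blocks by a fair coin (`p_dir = 0.5`), between blocks
deterministically along the prescribed direction (cyclically for the
block-cycle). One direction per node pair, never both, and no self-loops,
so the symmetrized graph is an ordinary undirected SBM with the stated
densities. Source/sink-style structures can be built by giving a block
out-only or in-only rows in the `between` matrix.

Real directed networks differ in ways the generator deliberately ignores:
reciprocal (bidirectional) edges — about a tenth of the connections in a
nematode chemical-synapse network — heavy-tailed degrees (no degree
correction), weights, and self-interactions. Passing the recovery
benchmarks therefore demonstrates correctness of the pipeline under the
planted model, not performance guarantees on arbitrary data; the method
itself handles reciprocal and weighted edges, they are simply not what the
synthetic validation stresses.

# Problem sizes used in validation

The test suite validates identities on 100 random directed graphs of up to
20 nodes, the exhaustive-oracle bound on 50 graphs of up to 8 nodes, and
recovery on 20 independent block-cycle graphs at the reference
configuration (200 nodes, ≈ 4 470 edges, `N = 2`, `K = 8`) — sizes at which
each property is fully exercised while the whole suite runs in well under a
minute. `scripts/acceptance.R` reruns the 20-replicate recovery study and
reports the median number of directed bicommunities detected.

# Known limitations

* As a modularity-type score, bimodularity inherits the resolution limit;
  small paired structures can be absorbed at coarse `K`.
* `N` and `K` are parameters, not estimates; the spectrum plot is the
  practical guide for `N`.
* k-means is the only clusterer; the feature matrix is exposed, so any
  other algorithm can be applied to it externally.
* The dense SVD bounds practical graph sizes to a few thousand nodes.
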