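# bimodularity

Community detection for **directed** graphs via paired sending/receiving
partitions.

In an undirected network, a community is a set of nodes with more internal
edges than a degree-preserving null model predicts. In a directed network —
a neuronal wiring diagram, a food web, a follower graph — the edges that
exceed expectation need not stay inside one node set: they can run *from*
one group of nodes *to* a different one. This package scores and detects
such paired structures.

## The model

For a directed graph with weight matrix `A` (rows = sources), out-/in-degree
vectors `k_out`, `k_in` and total edge weight `m`, the directed modularity
matrix is

```
B = A − k_out k_inᵀ / m
```

i.e. adjacency minus its expectation under the directed configuration model.
The **bimodularity index** of K paired communities — sending sets `C_k^out`
mapped to receiving sets `C_k^in` — is

```
Qbi = (1/m) Σ_k Σ_{i ∈ C_k^out, j ∈ C_k^in} B_ij
```

For a two-way split encoded by sign vectors `s_out`, `s_in` this is the
bilinear form `s_outᵀ B s_in / (2m)`, whose unit-norm relaxation is maximized
by the singular value decomposition `B = U Σ Vᵀ`: component k attains
`Qbi(u_k, v_k) = σ_k / (2m)`. On a symmetric graph with `s_out = s_in` the
index falls back to classical Newman modularity, and the sign of `u_kᵀ v_k`
distinguishes assortative (conventional) from disassortative structure.

Bicommunities are then extracted by clustering **edges**: edge `(i, j)` gets
the feature vector `(σ₁u₁[i], σ₁v₁[j], …, σ_N u_N[i], σ_N v_N[j])`, k-means
groups edges with similar sending and receiving profiles, and each cluster's
source/target node sets are its sending/receiving communities.

## Worked example

The canonical benchmark is a block-cycle stochastic block graph: 4 blocks of
50 nodes, undirected edge density 0.3 within blocks and between consecutive
blocks, between-block edges all oriented one way around the cycle.

```r
library(bimodularity)

sim <- generate_block_cycle(n_blocks = 4, block_size = 50,
                            p_self = 0.3, p_con = 0.3, seed = 1)
spectrum_table(svd_components(sim$graph, N = 4))
#>   k   sigma signed_mu    qbi
#> 1 1 18.1949   18.1949 0.0020
#> 2 2 17.8189   17.8189 0.0020
#> 3 3 10.1040  -10.1040 0.0011
#> 4 4  7.9647   -7.9647 0.0009

res <- detect_bicommunities(sim$graph, N = 2, K = 8, seed = 1)
bicommunity_table(res$bicommunities)
#>   cluster_id     kind    qbi n_edges n_sending n_receiving
#> 1          1 directed 0.1082     774        50          50
#> 2          3 directed 0.1078     756        50          50
#> 3          2 directed 0.1040     758        50          50
#> 4          4 directed 0.1017     753        50          50
#> 5          5     self 0.0234     402        50          50
#> 6          6     self 0.0217     394        50          50
#> 7          7     self 0.0190     363        50          50
#> 8          8     self 0.0142     328        50          50

recovery_score(res$labels, sim$edge_labels)
#> [1] 1
```

Two singular values dominate the spectrum (the two bimodular components of
the planted cycle), and clustering the edge features into 8 groups recovers
the full model: the 4 "self" clusters are the conventional within-block
communities (sending and receiving sets coincide) and the 4 "directed"
clusters are the block-to-block bicommunities, each sending from one block
of 50 nodes to the next. The per-cluster `qbi` is each cluster's
contribution to the bimodularity index, and the edge-label adjusted Rand
index of 1 means the detected clusters match the generator's ground truth
exactly.

Real edge lists load with `read_edge_list()` (TSV/CSV, `source`, `target`,
optional `weight`; `binarize = TRUE` collapses synapse-count
multiplicities), and `graph_summary()` reports uni-/bidirectional pair
counts.

## Command line

A thin CLI over the same functions lives at `inst/cli/bimod.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","bimod.R",package="bimodularity"))')" \
    generate --blocks 4 --size 50 --seed 1 --outdir run/
Rscript .../bimod.R detect --input run/edges.tsv -N 2 -K 8 --seed 1 --outdir run/
```

Every run writes a `manifest.json` with the exact parameters alongside its
outputs.

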