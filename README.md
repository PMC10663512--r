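# sdembed

Multidimensional hyperbolic embedding of networks under the S^D geometric
soft configuration model.

Many real networks — connectomes, trade, infrastructure, social systems —
are well described by a latent geometry in which the probability that two
nodes connect decreases with their distance in hyperbolic space. One-
dimensional similarity spaces (maps in the hyperbolic plane) are often a
good approximation, but some networks need a higher-dimensional similarity
sphere to be represented faithfully. `sdembed` is for network scientists
who want model-based multidimensional maps: it infers, from nothing but an
edge list, each node's hidden degree `kappa_i`, its position on a D-sphere,
and the global inverse temperature `beta`, then expresses the map in purely
geometric (D+1)-hyperbolic coordinates. An accompanying generator produces
synthetic ground-truth networks from the same model, and an evaluation
suite (greedy routing, geometric community concentration, coordinate
alignment, partition quality) quantifies map quality and estimates a
network's intrinsic dimension.

## The model

A node has hidden degree `kappa` and position `v` on a D-sphere of radius
`R = [N Γ((D+1)/2) / (2 π^((D+1)/2))]^(1/D)` (node density one). Pairs link
independently with the gravity-law probability

    p_ij = 1 / (1 + chi_ij^beta),   chi_ij = R Δθ_ij / (mu kappa_i kappa_j)^(1/D)

with `beta > D` and `mu = beta Γ(D/2) sin(Dπ/beta) / (2 π^(1+D/2) <k>)`.
Mapping `kappa` to a radial coordinate `r = R_hat − (2/D) ln(kappa/kappa_0)`
turns this into the purely geometric `p_ij = 1 / (1 + exp[(beta/2)(x_ij −
R_hat)])` with `x_ij = r_i + r_j + 2 ln(Δθ_ij/2)` — the (D+1)-hyperbolic
picture. Embedding inverts the model in four stages: hidden degrees and
`beta` by matching expected degrees and mean local clustering; initial
positions from model-corrected Laplacian Eigenmaps; likelihood
maximization sweeps in onion-decomposition order; and a final hidden-degree
readjustment. See the methods vignette
(`vignettes/sd-embedding-methods.Rmd`) for the full account.

## Worked example

Generate a synthetic S^2 network with known ground truth, embed it, and
compare the inferred coordinates with the planted ones:

```r
library(sdembed)

net <- generate_sd_network(N = 500, D = 2, beta = 5, gamma = 2.7,
                           mean_degree = 9, seed = 5)
net
#> Synthetic S^2 network: N = 500, <k> = 8.056 (nominal 9), gamma = 2.7, beta = 5

# embed the largest connected component
comp <- igraph::components(net$graph)
keep <- which(comp$membership == which.max(comp$csize))
g <- igraph::induced_subgraph(net$graph, keep)
emb <- embed_network(g, D = 2, seed = 7)
emb
#> S^2 embedding of 497 nodes: beta = 4.7645, mu = 0.0288409, R_hat = 11.3794
#>   log-likelihood -2890.47 after 6 sweep(s); final degree residual 0.00988

al <- align_to_reference(emb$positions, net$positions[keep, ])
round(al$per_axis_r, 3)
#> [1] 0.947 0.963 0.969
```

The inferred inverse temperature (4.76) sits within ~5% of the generating
value 5 (the clustering match has tolerance 0.01), and after the optimal
orthogonal alignment each Cartesian axis of the inferred sphere positions
correlates with the planted ones at r ≈ 0.95–0.97 (rising above 0.96 on
all axes at the benchmark size N = 2000). The realized mean degree (8.06)
is below the nominal 9 because hidden degrees are truncated at the natural
cutoff — a finite-size property of the model itself, discussed in the
vignette.

Evaluation and dimension selection:

```r
ev <- evaluate_embedding(g, emb, n_pairs = 2000, seed = 1)
ev[, c("p_s", "stretch")]
#>     p_s  stretch
#> 1 0.959 1.098899
```

`select_dimension(graph, dims = 1:3, labels = ...)` embeds at each
candidate dimension and reports the consensus of `p_s`, stretch, `c_C`,
modularity and NMI. A thin command-line front end with `generate`, `embed`,
`evaluate` and `select-dim` subcommands lives in `inst/cli/sdembed.R`.

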