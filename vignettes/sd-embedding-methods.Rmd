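---
title: "Methods: multidimensional hyperbolic embedding under the S^D model"
author: "sdembed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multidimensional hyperbolic embedding under the S^D model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The model

`sdembed` assumes that an undirected simple network is well described by the
geometric soft configuration model on a D-sphere (the S^D model). Each node
carries a hidden degree $\kappa_i > 0$ (its popularity / expected degree) and
a position $\mathbf{v}_i$ on a D-dimensional sphere whose radius
$R = [N\,\Gamma(\tfrac{D+1}{2}) / (2\pi^{(D+1)/2})]^{1/D}$ fixes the node
density to one. An unordered pair is linked independently with the
gravity-law probability

$$p_{ij} = \frac{1}{1+\chi_{ij}^{\beta}}, \qquad
  \chi_{ij} = \frac{R\,\Delta\theta_{ij}}{(\mu\kappa_i\kappa_j)^{1/D}},$$

where $\Delta\theta_{ij}$ is the angular separation, $\beta > D$ (the inverse
temperature) couples topology to geometry and controls clustering, and
$\mu = \beta\,\Gamma(D/2)\sin(D\pi/\beta) / (2\pi^{1+D/2}\langle k\rangle)$
calibrates the mean degree. Mapping $\kappa_i$ to a radial coordinate
$r_i = \hat R - \tfrac{2}{D}\ln(\kappa_i/\kappa_0)$ with
$\hat R = 2\ln[2R/(\mu\kappa_0^2)^{1/D}]$ turns the same probability into the
purely geometric form $p_{ij} = 1/(1+e^{(\beta/2)(x_{ij}-\hat R)})$ with the
effective hyperbolic distance $x_{ij} = r_i + r_j + 2\ln(\Delta\theta_{ij}/2)$;
the two pictures are algebraically identical (the package asserts agreement
to 1e-12) and `to_hyperbolic()` performs the conversion. $x$ approximates the
true geodesic only for pairs with
$\Delta\theta \gg 2\sqrt{e^{-2r_i}+e^{-2r_j}}$; the package documents and uses
it as an *effective* distance (greedy routing ranks neighbours by it), never
as an exact geodesic.

Embedding means reverse-engineering $\{\kappa_i, \mathbf{v}_i\}$ and $\beta$
from an observed adjacency matrix so that the model reproduces the network as
closely as possible. The geometric regime requires $\beta > D$; the weak
regime $\beta \le D$ is out of scope.

## The pipeline (`embed_network()`)

1. **Hidden degrees and $\beta$** (`fit_hidden_degrees()`, `infer_beta()`).
   Expected degrees under the model are the quadrature
   $\bar k(\kappa_i) \propto \sum_{j\ne i}\int_0^\pi
   \sin^{D-1}\theta\,[1+(R\theta/(\mu\kappa_i\kappa_j)^{1/D})^\beta]^{-1}d\theta$,
   evaluated per degree class through a 200-point log-log spline of the kernel
   (adaptive Gauss–Kronrod per table node, with the integrand's shoulder at
   $\theta \approx z$ passed as a breakpoint; absolute accuracy ~1e-12).
   Hidden degrees start at the observed degrees and follow the noisy
   contracting update $|\kappa + (k-\bar k)u| \to \kappa$, $u\sim U(0,1)$,
   shared within each degree class, until
   $\max_i|\bar k(\kappa_i)-k_i| \le \epsilon$ (default 0.01). $\beta$ is
   matched to the empirical mean local clustering (computed over nodes with
   $k\ge 2$; below that local clustering is undefined — the model-side
   estimator averages over the same classes for consistency): starting
   uniformly in $(D, D+1)$, $\beta$ is multiplied by 1.5 while the model
   clustering is low, then bisected, refitting the hidden degrees and
   recomputing $\mu$ from the observed mean degree at every evaluation. The
   model clustering is a Monte-Carlo estimator (default $m = 600$ samples per
   degree class; standard error shrinks as $m^{-1/2}$): neighbour degrees are
   drawn from $P(k'|k) = k'P(k')/\langle k\rangle$, separations from the
   connected-pair density
   $\rho(\Delta\theta\,|\,a{=}1) \propto \sin^{D-1}\Delta\theta\,p(\Delta\theta)$
   via a 2048-point tabulated inverse CDF cached per degree-class pair, and
   azimuths uniformly.

2. **Spectral initialization** (`laplacian_initial_positions()`). Each edge
   gets the model-expected chord $2\sin(\langle\Delta\theta_{ij}\rangle/2)$,
   where $\langle\Delta\theta_{ij}\rangle$ is the conditional mean separation
   of a connected pair (ratio of two quadratures, cached per degree-class
   pair). Weights are $\omega_{ij} = a_{ij}e^{-|v_i-v_j|^2/t}$ and the
   coordinates are the D+1 eigenvectors of the weighted Laplacian with the
   smallest non-null eigenvalues, each node then projected onto the unit
   sphere. **Choice of $t$:** we set $t$ to the variance of the chord
   *displacements*, i.e. the mean squared contributing chord length. Reading
   "variance" as the central variance of the chord magnitudes makes $t$ an
   order of magnitude too small in weakly coupled regimes
   ($\beta \lesssim D+1$): hub–hub weights then fall below 1e-16, the weight
   graph effectively fragments, and the low end of the spectrum fills with
   localized modes that carry no coordinate information (we measured
   per-axis correlations of 0.1–0.3 instead of >0.95 at
   $N=2000,\beta=3,\gamma=2.5$). The mean-square reading is the standard
   heat-kernel bandwidth and restores the expected behaviour; it is our
   resolution of a genuinely ambiguous one-clause prescription.
   Degree-one nodes carry no geometric information: they are pruned
   *recursively* (a removal can create new leaves; chains collapse entirely),
   and reattached in reverse removal order at separations drawn from
   $\rho(\Delta\theta|a{=}1)$ around their anchor with uniform azimuth. If
   the remaining core is too small for the eigenproblem (fewer than D+3
   nodes), core nodes are placed uniformly at random.

3. **Likelihood refinement** (`refine_positions()`). Nodes are visited in
   onion-decomposition order — layers from iterated minimum-degree peeling;
   we traverse deepest layers first so the well-constrained core settles
   before the periphery, with within-layer order reshuffled every sweep. For
   each node, $100\max(\ln N, 1)$ candidate positions are drawn from an
   isotropic normal in the ambient space around the $\kappa^{-2}$-weighted
   neighbour mean and projected onto the sphere; the node moves to the
   candidate with the highest local log-likelihood
   $\ln L_i = \sum_{j\ne i} a_{ij}\ln p_{ij} + (1-a_{ij})\ln(1-p_{ij})$
   (probabilities clamped to $[10^{-15}, 1-10^{-15}]$; sums are exact over
   all $j$, non-neighbours are never truncated). The incumbent position is
   always in the comparison set, so the global log-likelihood is
   non-decreasing sweep by sweep (asserted in the tests). The printed spread
   formula $\sigma = \max(\pi/2, \Delta\theta_{\max}/2)$ is constantly
   $\pi/2$ because $\Delta\theta_{\max}\le\pi$; we implement it literally as
   the default and expose `proposal_spread = "min"` for the localized
   alternative, since a minimum is plausibly what was intended. Sweeps stop
   when the relative log-likelihood change drops below `plateau_tol` (1e-4)
   or after `max_sweeps`. The default cap is 6 sweeps: on synthetic
   benchmarks the coordinate quality (aligned per-axis correlation) saturates
   by sweep 2–3 while each sweep is a full $O(100\,N^2\ln N)$ likelihood
   scan, so the strict plateau criterion rarely fires first and the cap is
   the effective stop. An optional extra LE→MLE round (`refine_rounds`)
   restarts the sweep schedule from the refined configuration.

4. **Final hidden-degree adjustment** (`final_degree_adjustment()`). With
   positions fixed, expected degrees become the exact pairwise sums
   $\bar k(\kappa_i) = \sum_{j\ne i} p_{ij}$, and the same noisy update runs
   per node (not per class) until the $\epsilon$ contract holds. We use the
   contracting sign $|\kappa + (k-\bar k)u|$: the printed form of the final
   adjustment subtracts the deficit, which walks $\kappa$ *away* from the
   target whenever $\bar k < k$ and cannot converge; the initial-stage update
   uses the contracting sign, and we follow it in both places.

## The synthetic generator (`generate_sd_network()`)

The generator is the package's ground-truth instrument: hidden degrees from
$\rho(\kappa)\propto\kappa^{-\gamma}$ on $[\kappa_0,\kappa_c]$ by inverse
transform with $\kappa_0 = \tfrac{\gamma-2}{\gamma-1}\langle k\rangle$ and the
natural cutoff $\kappa_c = \kappa_0 N^{1/(\gamma-1)}$; positions uniform on
the sphere (D+1 standard normals, normalized) or, for planted communities,
uniform by surface measure inside spherical caps of polar angle
$\Delta\theta_T$ (default 0.7, which keeps caps non-overlapping) whose apices
are spread evenly — exact layouts on the circle and for platonic counts on
S^2, a maximin repulsion layout otherwise; node-to-cap assignment is
round-robin so community sizes differ by at most one (the allotment rule is
not pinned down elsewhere; this is our choice). All $N(N-1)/2$ pairs are then
linked by independent Bernoulli draws — exact and adequate at the scales the
package targets.

Two deliberate calibration points. First, $\mu$ is computed from the
*realized mean of the drawn hidden degrees*, not the nominal
$\langle k\rangle$: this preserves the identity that expected degrees are
proportional to $\kappa$ with unit constant, while the natural cutoff makes
$E[\kappa]$ fall below the nominal target (7.37 vs 8 at
$\gamma=2.5, N=2000$) — a deterministic truncation effect, so the realized
mean degree sits below the nominal value by the same margin. Second, the
thermodynamic-limit calibration itself is only asymptotic: at finite $R$ the
quadrature expectation $\bar k(\kappa)$ bends below $\kappa$ for hubs
(down to $\approx 0.66\kappa$ near $\kappa_c$ at $\beta = D+1$, where the
kernel tail decays slowly). Generated networks therefore *match the model's
own finite-size expectation* — which the test suite asserts — while the
naive expectations "realized mean degree equals nominal" and "degree-vs-
$\kappa$ slope equals one" do **not** hold in this regime; the embedding's
first stage exists precisely to absorb such finite-size distortions when
inverting the model. What passing generator tests show about real data is
therefore limited: the generator produces exactly the model's ensemble, not
networks with prescribed degree sequences (a microcanonical generator is a
non-goal).

## Evaluation suite

* `greedy_routing()`: messages hop to the neighbour with smallest effective
  hyperbolic distance $x$ to the target; failure on revisiting a node (loop)
  or exceeding $N$ hops — the revisit rule is the standard convention, the
  field's texts do not pin it down. Ties break toward the smallest node
  index. Success rate $p_s$ and mean stretch (greedy hops / BFS shortest
  path, successes only) are reported over a sample of ordered pairs
  (default 10^4, or all pairs for small networks).
* `community_concentration()`: for each node, the fraction of its
  $n_g = \lceil 0.1N\rceil$ angularly nearest nodes (self excluded, index
  tie-break) sharing its community, normalized by community size:
  $\rho_{i,l} = (n_{i,l}/n_{i,g}) (N/N_l)$; the scalar $c_C$ is the mean
  over nodes. Random labels give $1/N_C$; $n_g \to N$ forces 1. Invariant
  under global orthogonal transforms.
* `align_to_reference()`: closed-form orthogonal Procrustes (rotations and
  reflections, no centring or scaling — both clouds live on the unit
  sphere), reporting per-axis Pearson correlations and the mean residual
  angle.
* `detect_geometric_communities()` / `partition_quality()`:
  average-linkage agglomerative clustering on angular distance cut at a
  prescribed cluster count; Newman–Girvan modularity and NMI with
  arithmetic-mean normalization (the normalization is not pinned down
  elsewhere; the arithmetic form is the common default).
* `consensus_dimension()`: per metric, the dimension where it peaks
  (stretch peaks downward); consensus is the modal optimum, ties flagged
  unresolved with the full table.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `epsilon` | 0.01 | max allowed deviation of expected from observed degrees |
| `epsilon_clust` | 0.01 | clustering match tolerance for the beta search |
| `m` | 600 | Monte-Carlo samples per degree class in the clustering estimator |
| `candidates` | `100 max(ln N,1)` | candidate positions per node and sweep |
| `max_sweeps` | 6 | cap on likelihood sweeps per refinement round |
| `plateau_tol` | 1e-4 | relative log-likelihood change declaring a plateau |
| `proposal_spread` | `"max"` | literal spread formula; `"min"` localizes proposals |
| `refine_rounds` | 1 | LE→MLE rounds |
| `le_dense_cutoff` | 4000 | below this core size the eigenproblem is dense |

All angles are radians; hidden degrees are dimensionless expected degrees.

## Numerical choices and degenerate inputs

Dot products are clipped to $[-1,1]$ before `acos`; positions are stored as
unit vectors and $R$ enters only where distances are formed; probabilities
are clamped before logarithms; all randomness flows through R's RNG, seeded
once per top-level call (`seed` arguments), which is the R idiom for a
single explicitly seeded generator. Disconnected inputs reduce to the
largest component with a warning; self-loops and duplicate edges are dropped
on read; degree-one chains prune recursively; a tree input collapses to a
single-node core placed randomly and rebuilt outward by the reattachment
law. Quadrature failures and non-convergent adjustment loops raise errors
carrying the residual.

Three guards keep the iterative loops well behaved. The initial $\beta$ is
drawn uniformly in $(D+0.05, D+1)$ rather than $(D, D+1)$ — the inference
result does not depend on the initial guess, but a draw within $\sim 10^{-4}$
of the degenerate edge $\beta = D$ makes expected degrees nearly insensitive
to $\kappa$ and stalls the class fit; the bisection bracket is floored at the
same offset. The noisy degree update halves its step amplitude whenever the
residual fails to improve for 200 consecutive iterations (the $u\sim U(0,1)$
draw is otherwise untouched). And the log-log kernel table floors the
quadrature values at `1e-300`: adaptive quadrature may return tiny negative
values for segments whose integral underflows, which would otherwise poison
the spline.

## Problem sizes used by the checks

The validation suite reproduces the method's claims at problem sizes
chosen for a desk-scale run, with thresholds unchanged. Coordinate recovery
is checked at $N=2000$ (the weakly coupled fixture; $r \ge 0.96$ is a
large-$N$ property — at $N=1000$ the aligned correlations saturate around
0.94 regardless of how many sweeps are run) and $N=1500$ for the strongly
coupled fixture; three refinement sweeps are used, which is where the
correlations saturate on these fixtures. Beta recovery runs at $N=1000$
with 3 seeds per dimension, navigability at $N=400$ with 3 seeds,
community concentration at $N=300$ with 4 seeds, clustering-oracle and
generator-calibration checks at $N=1000$ and $N=2000$. The standalone
acceptance script runs the two coordinate-recovery benchmarks at the full
$N=2000$ with the same three-sweep schedule.

## Known limitations

The likelihood landscape is non-convex; the sweep is a greedy local search
started from the spectral solution, and pathological inputs can settle in
local optima (validating against synthetic ground truth, as the test suite
does, exists for exactly this reason). The method targets sparse,
clustered, heavy-tailed networks in the geometric regime $\beta > D$;
unclustered networks make the beta search fail by construction (an error,
not a silent fallback). Weighted, directed, bipartite and multilayer
variants, non-uniform latent densities, and landmark approximations for
very large graphs are out of scope.
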