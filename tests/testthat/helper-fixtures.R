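# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(key, build) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- build()
  .fixtures[[key]]
}

# A synthetic network restricted to its largest component, with the
# ground-truth positions/kappas subset accordingly.
lcc_network <- function(...) {
  net <- generate_sd_network(...)
  comp <- igraph::components(net$graph)
  keep <- which(comp$membership == which.max(comp$csize))
  net$graph <- igraph::induced_subgraph(net$graph, keep)
  net$positions <- net$positions[keep, , drop = FALSE]
  net$kappa <- net$kappa[keep]
  if (!is.null(net$labels)) net$labels <- net$labels[keep]
  net$kept <- keep
  net
}

# Independent brute-force onion peeling used as the ordering oracle.
brute_onion <- function(graph) {
  g <- graph
  ids <- seq_len(igraph::vcount(graph))
  layer <- integer(igraph::vcount(graph))
  l <- 0L
  while (igraph::vcount(g) > 0L) {
    l <- l + 1L
    deg <- igraph::degree(g)
    sel <- which(deg <= min(deg))
    layer[ids[sel]] <- l
    ids <- ids[-sel]
    g <- igraph::delete_vertices(g, sel)
  }
  layer
}

# Numeric CDF of the connected-pair separation density (independent of the
# package's tabulated sampler: plain pointwise quadrature).
connected_sep_cdf_oracle <- function(kappa_i, kappa_j, params, n = 400L) {
  z <- (params$mu * kappa_i * kappa_j)^(1 / params$D) / params$R
  dens <- function(th) sin(th)^(params$D - 1) / (1 + (th / z)^params$beta)
  total <- integrate(dens, 0, pi, rel.tol = 1e-10)$value
  grid <- seq(0, pi, length.out = n)
  cdf <- vapply(grid[-1L], function(u)
    integrate(dens, 0, u, rel.tol = 1e-9)$value / total, numeric(1))
  approxfun(grid, c(0, cdf), rule = 2)
}

expect_unit_rows <- function(M, tol = 1e-12) {
  expect_lt(max(abs(sqrt(rowSums(M^2)) - 1)), tol)
}
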