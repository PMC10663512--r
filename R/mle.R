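# Stages 3-4: likelihood maximization and final hidden-degree adjustment.

#' Onion decomposition layers
#'
#' Iterated minimum-degree peeling: repeatedly remove every node whose
#' current degree equals the current minimum; each batch forms one layer.
#' This refines the k-core decomposition (all nodes of a layer share the
#' core number in force when they are peeled).
#'
#' @param graph an igraph object.
#' @return Integer vector of layer indices (1 = first peeled periphery).
#' @export
onion_layers <- function(graph) {
  N <- igraph::vcount(graph)
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  deg <- lengths(adj)
  alive <- rep(TRUE, N)
  layer <- integer(N)
  l <- 0L
  while (any(alive)) {
    l <- l + 1L
    dmin <- min(deg[alive])
    sel <- alive & deg <= dmin
    layer[sel] <- l
    for (i in which(sel)) {
      nb <- adj[[i]][alive[adj[[i]]] & !sel[adj[[i]]]]
      deg[nb] <- deg[nb] - 1L
    }
    alive[sel] <- FALSE
  }
  layer
}

#' Node visitation order for the likelihood sweeps
#'
#' Orders nodes by decreasing onion layer (deepest, most constrained nodes
#' first) with random order inside each layer.
#'
#' @param graph an igraph object.
#' @param layers optional precomputed [onion_layers] result.
#' @return A permutation of 1..N.
#' @export
onion_ordering <- function(graph, layers = NULL) {
  if (is.null(layers)) layers <- onion_layers(graph)
  N <- length(layers)
  order(-layers, sample.int(N))
}

#' Local log-likelihood of a node's position
#'
#' \eqn{\ln L_i = \sum_{j\ne i} a_{ij}\ln p_{ij} + (1-a_{ij})\ln(1-p_{ij})}
#' with the gravity-law p and probabilities clamped to \[1e-15, 1-1e-15\]
#' before the logarithms.
#'
#' @param node node index.
#' @param positions unit-row position matrix.
#' @param kappa hidden degrees.
#' @param graph igraph object.
#' @param params an [sd_params].
#' @return The local log-likelihood (scalar).
#' @export
local_log_likelihood <- function(node, positions, kappa, graph, params) {
  N <- nrow(positions)
  v <- positions[node, ]
  dth <- acos(clip1(as.vector(positions %*% v)))
  p <- connection_probability(kappa[node], kappa, dth, params)$p
  p <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  a <- rep(0, N)
  a[as.integer(igraph::neighbors(graph, node))] <- 1
  idx <- setdiff(seq_len(N), node)
  sum(a[idx] * log(p[idx]) + (1 - a[idx]) * log(1 - p[idx]))
}

adjacency_list0 <- function(graph) {
  lapply(igraph::as_adj_list(graph), function(v) as.integer(v) - 1L)
}

#' Refine node positions by per-node likelihood maximization
#'
#' Visits nodes in onion order; for each node, candidate positions are drawn
#' from an isotropic normal in the ambient (D+1)-space around the
#' kappa^(-2)-weighted mean vector of its neighbours, projected onto the
#' sphere, and the node moves to the candidate (incumbent included in the
#' comparison) with the highest local log-likelihood — so the global
#' log-likelihood is non-decreasing across sweeps. Sweeps repeat until the
#' relative change of the global log-likelihood falls below
#' `config$plateau_tol` or `config$max_sweeps` is reached (warning).
#'
#' @param graph igraph object.
#' @param kappa hidden degrees.
#' @param positions initial unit-row positions (from
#'   [laplacian_initial_positions]).
#' @param params an [sd_params].
#' @param config an [sd_config].
#' @return List with refined `positions`, the global log-likelihood `trace`
#'   (one entry before the first sweep, one per sweep), and `sweeps` used.
#' @export
refine_positions <- function(graph, kappa, positions, params,
                             config = sd_config()) {
  N <- igraph::vcount(graph)
  stopifnot(nrow(positions) == N, length(kappa) == N)
  adj0 <- adjacency_list0(graph)
  layers <- onion_layers(graph)
  nc <- config$candidates
  if (is.null(nc)) nc <- as.integer(round(100 * max(log(N), 1)))
  spread_min <- identical(config$proposal_spread, "min")
  V <- positions
  ll <- cpp_global_loglik(V, kappa, adj0, params$beta, params$R, params$mu,
                          params$D)
  trace <- ll
  sweeps <- 0L
  converged <- FALSE
  for (s in seq_len(config$max_sweeps)) {
    ord0 <- onion_ordering(graph, layers) - 1L
    V <- cpp_sweep_refine(V, kappa, adj0, ord0, params$beta, params$R,
                          params$mu, params$D, nc, spread_min)
    ll_new <- cpp_global_loglik(V, kappa, adj0, params$beta, params$R,
                                params$mu, params$D)
    trace <- c(trace, ll_new)
    sweeps <- s
    rel <- abs(ll_new - ll) / max(abs(ll), 1)
    ll <- ll_new
    if (rel < config$plateau_tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning(sprintf("likelihood plateau not reached within %d sweeps",
                    config$max_sweeps))
  list(positions = V, trace = trace, sweeps = sweeps, converged = converged)
}

#' Final adjustment of hidden degrees given inferred positions
#'
#' With positions fixed, the expected degree of node i is the sum of the
#' gravity-law probabilities to every other node. Hidden degrees are
#' adjusted per node with the noisy contracting update
#' `|kappa_i + (k_i - kbar_i) u| -> kappa_i` until the maximal deviation
#' from the observed degrees falls below `config$epsilon`.
#'
#' @param graph igraph object.
#' @param kappa starting hidden degrees (from the initial inference).
#' @param positions unit-row positions.
#' @param params an [sd_params].
#' @param config an [sd_config].
#' @return List with adjusted `kappa`, final residual `eps_max`, iterations.
#' @export
final_degree_adjustment <- function(graph, kappa, positions, params,
                                    config = sd_config()) {
  k <- igraph::degree(graph)
  N <- length(k)
  stopifnot(length(kappa) == N, nrow(positions) == N)
  it <- 0L
  eps <- Inf
  repeat {
    kbar <- cpp_expected_degrees_pos(positions, kappa, params$beta, params$R,
                                     params$mu, params$D)
    eps <- max(abs(kbar - k))
    if (eps <= config$epsilon) break
    it <- it + 1L
    if (it > config$max_iter)
      stop(sprintf(
        "final hidden-degree adjustment did not reach epsilon = %g (residual %g)",
        config$epsilon, eps), call. = FALSE)
    u <- runif(N)
    kappa <- abs(kappa + (k - kbar) * u)
    kappa <- pmin(pmax(kappa, 1e-8), 1e7)
  }
  list(kappa = kappa, eps_max = eps, iterations = it)
}
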