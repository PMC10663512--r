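# Stage 2: initial positions from model-corrected Laplacian Eigenmaps.

#' Expected angular separation of a connected pair
#'
#' Conditional mean of the angular distance between two nodes with hidden
#' degrees kappa_i, kappa_j given that they are connected: the ratio of the
#' two quadratures of the connected-pair distance density. Vectorized over
#' pairs (recycled); values lie strictly inside (0, pi).
#'
#' @param kappa_i,kappa_j hidden degrees (> 0).
#' @param params an [sd_params] object.
#' @return Expected separation(s) in radians.
#' @export
expected_connected_distance <- function(kappa_i, kappa_j, params) {
  stopifnot(all(kappa_i > 0), all(kappa_j > 0))
  pr <- kappa_i * kappa_j
  z <- (params$mu * pr)^(1 / params$D) / params$R
  uz <- unique(z)
  f1 <- sd_kernel_f1(uz, params$D, params$beta)
  f0 <- sd_kernel_f0(uz, params$D, params$beta)
  (f1 / f0)[match(z, uz)]
}

# Recursively peel degree-one nodes; returns removal order with anchors.
# A removal can create new degree-one nodes (chains), so a queue is used;
# nodes left with degree zero stay in the core.
prune_degree_one <- function(graph) {
  N <- igraph::vcount(graph)
  adj <- lapply(igraph::as_adj_list(graph), as.integer)
  deg <- lengths(adj)
  alive <- rep(TRUE, N)
  removed <- integer(0)
  anchors <- integer(0)
  queue <- which(deg == 1)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    if (!alive[i] || deg[i] != 1L) next
    nb <- adj[[i]][alive[adj[[i]]]]
    alive[i] <- FALSE
    removed <- c(removed, i)
    anchors <- c(anchors, nb[1L])
    deg[nb] <- deg[nb] - 1L
    if (deg[nb[1L]] == 1L) queue <- c(queue, nb[1L])
  }
  list(core = which(alive), removed = removed, anchors = anchors)
}

# Weighted-Laplacian eigenproblem: coordinates from the D+1 eigenvectors
# with the smallest non-null eigenvalues.
laplacian_eigenmaps <- function(W, D, dense_cutoff = 4000L) {
  n <- nrow(W)
  L <- diag(rowSums(W)) - W
  if (n <= dense_cutoff) {
    eg <- eigen(L, symmetric = TRUE)
    vals <- rev(eg$values)
    vecs <- eg$vectors[, rev(seq_len(n)), drop = FALSE]
  } else {
    res <- igraph::arpack(function(x, extra) as.vector(L %*% x),
                          sym = TRUE,
                          options = list(n = n, nev = min(D + 3L, n - 1L),
                                         ncv = min(n, 4L * (D + 3L)),
                                         which = "SA", maxiter = 10000L))
    ord <- order(res$values)
    vals <- res$values[ord]
    vecs <- res$vectors[, ord, drop = FALSE]
  }
  keep <- which(vals > 1e-10)
  if (length(keep) < D + 1L)
    stop("Laplacian eigenproblem returned fewer than D+1 non-null modes ",
         "(is the core connected?)", call. = FALSE)
  sel <- keep[seq_len(D + 1L)]
  list(coords = vecs[, sel, drop = FALSE], eigenvalues = vals[sel])
}

le_loss <- function(coords, W) {
  idx <- which(W > 0, arr.ind = TRUE)
  d2 <- rowSums((coords[idx[, 1L], , drop = FALSE] -
                 coords[idx[, 2L], , drop = FALSE])^2)
  sum(W[idx] * d2) # ordered pairs: each edge counted in both directions
}

#' Initial node positions on the D-sphere via model-corrected Laplacian Eigenmaps
#'
#' Builds edge weights `w_ij = exp(-|v_i - v_j|^2 / t)` from the model-expected
#' chord lengths `|v_i - v_j| = 2 sin(<dtheta_ij>/2)` between connected nodes
#' (t, the variance of the contributing chord displacements, equals the mean
#' squared chord length), solves
#' the weighted-Laplacian eigenproblem on the 2-core, projects every node
#' onto the unit D-sphere, and finally reattaches recursively pruned
#' degree-one nodes at separations drawn from the connected-pair distance
#' distribution around their anchor (uniform azimuth), in reverse removal
#' order so each anchor is already placed.
#'
#' @param graph connected igraph object.
#' @param kappa per-node hidden degrees.
#' @param params an [sd_params].
#' @param config an [sd_config].
#' @return List with unit-row `positions`, the LE `loss` at the raw
#'   eigencoordinates, the scale `t`, core indices and eigenvalues.
#' @export
laplacian_initial_positions <- function(graph, kappa, params,
                                        config = sd_config()) {
  N <- igraph::vcount(graph)
  stopifnot(length(kappa) == N)
  if (igraph::components(graph)$no != 1L)
    stop("the network must be connected (largest component) for the spectral ",
         "initialization", call. = FALSE)
  D <- params$D
  pr <- prune_degree_one(graph)
  positions <- matrix(NA_real_, N, D + 1L)
  loss <- NA_real_; tscale <- NA_real_; evals <- NULL
  if (length(pr$core) > D + 2L) {
    sub <- igraph::induced_subgraph(graph, pr$core)
    el <- igraph::as_edgelist(sub, names = FALSE)
    kap_core <- kappa[pr$core]
    edth <- expected_connected_distance(kap_core[el[, 1L]], kap_core[el[, 2L]],
                                        params)
    chord <- 2 * sin(edth / 2)
    # heat-kernel bandwidth: variance of the chord displacements, i.e. the
    # mean squared contributing distance (a central variance of the chord
    # magnitudes collapses hub-hub weights and yields localized modes)
    tscale <- mean(chord^2)
    wts <- exp(-chord^2 / tscale)
    n <- length(pr$core)
    W <- matrix(0, n, n)
    W[el] <- wts; W[el[, c(2L, 1L)]] <- wts
    sol <- laplacian_eigenmaps(W, D, config$le_dense_cutoff)
    loss <- le_loss(sol$coords, W)
    evals <- sol$eigenvalues
    raw <- sol$coords
    nrm <- sqrt(rowSums(raw^2))
    bad <- nrm < 1e-12
    if (any(bad)) raw[bad, ] <- sample_uniform_sphere(sum(bad), D)
    positions[pr$core, ] <- raw / sqrt(rowSums(raw^2))
  } else {
    # tiny or tree-like core: no usable spectral information
    positions[pr$core, ] <- sample_uniform_sphere(length(pr$core), D)
  }
  draw_sep <- separation_sampler_cache(D, params$beta, params$mu, params$R)
  for (idx in rev(seq_along(pr$removed))) {
    i <- pr$removed[idx]; a <- pr$anchors[idx]
    th <- draw_sep(kappa[i], kappa[a], runif(1))
    positions[i, ] <- sample_at_separation(positions[a, ], th)
  }
  list(positions = positions, loss = loss, t = tscale,
       core = pr$core, reattached = pr$removed, eigenvalues = evals)
}
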