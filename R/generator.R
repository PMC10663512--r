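# Synthetic S^D networks with known ground truth.

#' Sample hidden degrees from a truncated power law
#'
#' Draws kappa from rho(kappa) proportional to kappa^(-gamma) on
#' \[kappa_0, kappa_c\] by inverse transform, with
#' kappa_0 = (gamma-2)/(gamma-1) * mean_degree and the natural cutoff
#' kappa_c = kappa_0 N^(1/(gamma-1)) that tames the extreme fluctuations of
#' the maximum hidden degree for gamma < 3.
#'
#' @param N number of draws.
#' @param gamma power-law exponent; the scale-free regime is 2 < gamma < 3
#'   (values >= 3 are accepted with a warning, gamma <= 2 is an error since
#'   kappa_0 would not be positive).
#' @param mean_degree nominal mean degree setting kappa_0.
#' @return List with `kappa`, `kappa0`, `kappa_c`, `gamma`.
#' @export
sample_hidden_degrees <- function(N, gamma, mean_degree) {
  check_count(N, 2, "N")
  if (gamma <= 2) stop("`gamma` must exceed 2 (kappa_0 would be non-positive)",
                       call. = FALSE)
  if (gamma >= 3) warning("gamma >= 3 is outside the heavy-tailed regime")
  stopifnot(mean_degree > 0)
  kappa0 <- (gamma - 2) / (gamma - 1) * mean_degree
  kappac <- kappa0 * N^(1 / (gamma - 1))
  u <- runif(N)
  a <- 1 - gamma
  kappa <- (kappa0^a + u * (kappac^a - kappa0^a))^(1 / a)
  list(kappa = kappa, kappa0 = kappa0, kappa_c = kappac, gamma = gamma)
}

# Vertices of the platonic solids used as evenly spread cap apices on S^2.
platonic_vertices <- function(n) {
  phi <- (1 + sqrt(5)) / 2
  V <- switch(as.character(n),
    "4" = rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1)),
    "6" = rbind(diag(3), -diag(3)),
    "8" = as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1))),
    "12" = {
      b <- rbind(c(0, 1, phi), c(0, 1, -phi), c(0, -1, phi), c(0, -1, -phi))
      rbind(b, b[, c(3, 1, 2)], b[, c(2, 3, 1)])
    },
    "20" = {
      cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
      b <- rbind(c(0, 1 / phi, phi), c(0, 1 / phi, -phi),
                 c(0, -1 / phi, phi), c(0, -1 / phi, -phi))
      rbind(cube, b, b[, c(3, 1, 2)], b[, c(2, 3, 1)])
    },
    NULL)
  if (is.null(V)) return(NULL)
  V <- unname(as.matrix(V))
  V / sqrt(rowSums(V^2))
}

# Maximin-style repulsion layout of n points on S^D (used when no closed
# layout exists); deterministic given the RNG state.
repulsion_points <- function(n, D, iters = 600L) {
  X <- sample_uniform_sphere(n, D)
  for (it in seq_len(iters)) {
    step <- 0.1 / sqrt(it)
    G <- matrix(0, n, D + 1)
    for (i in seq_len(n)) {
      dif <- sweep(-X[-i, , drop = FALSE], 2, X[i, ], "+") # x_i - x_j
      d3 <- pmax(sqrt(rowSums(dif^2)), 1e-6)^3
      G[i, ] <- colSums(dif / d3)
    }
    X <- X + step * G / pmax(sqrt(rowSums(G^2)), 1e-12)
    X <- X / sqrt(rowSums(X^2))
  }
  X
}

# Evenly spread apices: closed forms where they exist, repulsion otherwise.
even_apices <- function(n, D) {
  check_count(n, 2, "n_communities")
  if (D == 1) {
    ang <- 2 * pi * (seq_len(n) - 1) / n
    return(cbind(cos(ang), sin(ang)))
  }
  if (D == 2) {
    if (n == 2) return(rbind(c(0, 0, 1), c(0, 0, -1)))
    if (n == 3) {
      ang <- 2 * pi * (0:2) / 3
      return(cbind(cos(ang), sin(ang), 0))
    }
    V <- platonic_vertices(n)
    if (!is.null(V)) return(V)
  }
  repulsion_points(n, D)
}

# Polar angle inside a cap, density proportional to sin^(D-1) on [0, cap].
sample_cap_angles <- function(n, D, cap_angle) {
  if (D == 1) return(runif(n, 0, cap_angle))
  if (D == 2) return(acos(1 - runif(n) * (1 - cos(cap_angle))))
  grid <- seq(0, cap_angle, length.out = 2048L)
  dens <- sin(grid)^(D - 1)
  cdf <- c(0, cumsum((dens[-1L] + dens[-length(dens)]) / 2 * diff(grid)))
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  approx(cdf[keep], grid[keep], xout = runif(n), rule = 2, ties = "ordered")$y
}

#' Plant community positions inside spherical caps
#'
#' Places community apices evenly on the D-sphere (equally spaced angles for
#' D = 1, platonic layouts on S^2 where available, maximin repulsion
#' otherwise), assigns nodes to communities round-robin so sizes differ by at
#' most one, and samples each node uniformly (by surface measure) inside the
#' cap of polar angle `cap_angle` around its apex.
#'
#' @param N node count.
#' @param D sphere dimension.
#' @param n_communities number of caps (>= 2).
#' @param cap_angle cap polar angle in (0, pi\]; caps stay non-overlapping for
#'   layouts with inter-apex separation above twice this angle.
#' @return List with unit-row matrix `positions`, integer `labels`, and
#'   `apices`.
#' @export
generate_community_positions <- function(N, D, n_communities, cap_angle = 0.7) {
  stopifnot(cap_angle > 0, cap_angle <= pi)
  apices <- even_apices(n_communities, D)
  labels <- rep_len(seq_len(n_communities), N)
  th <- sample_cap_angles(N, D, cap_angle)
  P <- matrix(0, N, D + 1)
  for (i in seq_len(N)) P[i, ] <- sample_at_separation(apices[labels[i], ], th[i])
  list(positions = P, labels = labels, apices = apices)
}

#' Generate a synthetic S^D network with known ground truth
#'
#' Draws hidden degrees from the truncated power law, positions uniformly on
#' the D-sphere (or clustered in spherical caps when `n_communities` is
#' given), and links every unordered pair independently with the gravity-law
#' probability. mu is calibrated from the realized mean of the drawn hidden
#' degrees, which makes the model identity kbar(kappa) = kappa hold exactly;
#' with the natural cutoff in force the realized mean degree therefore sits
#' slightly below the nominal `mean_degree` (a deterministic truncation
#' effect, strongest for small gamma).
#'
#' @param N node count.
#' @param D similarity dimension.
#' @param beta inverse temperature (> D).
#' @param gamma hidden-degree power-law exponent.
#' @param mean_degree nominal mean degree.
#' @param n_communities optional number of planted spherical-cap communities.
#' @param cap_angle cap polar angle (radians) when communities are planted.
#' @param kappa,positions optional prescribed hidden degrees / unit-row
#'   position matrix overriding the random draws.
#' @param seed optional RNG seed.
#' @return An object of class `sd_network`: `graph` (igraph), `positions`
#'   (unit rows), `kappa`, `params` ([sd_params]), `labels` (or NULL),
#'   `gamma`, `kappa0`, `kappa_c`, `cap_angle`.
#' @export
generate_sd_network <- function(N, D, beta, gamma = 2.5, mean_degree = 10,
                                n_communities = NULL, cap_angle = 0.7,
                                kappa = NULL, positions = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(kappa)) {
    hd <- sample_hidden_degrees(N, gamma, mean_degree)
    kappa <- hd$kappa; kappa0 <- hd$kappa0; kappac <- hd$kappa_c
  } else {
    stopifnot(length(kappa) == N, all(kappa > 0))
    kappa0 <- min(kappa); kappac <- max(kappa)
  }
  labels <- NULL
  if (is.null(positions)) {
    if (is.null(n_communities)) {
      positions <- sample_uniform_sphere(N, D)
    } else {
      cp <- generate_community_positions(N, D, n_communities, cap_angle)
      positions <- cp$positions
      labels <- cp$labels
    }
  } else stopifnot(nrow(positions) == N, ncol(positions) == D + 1)
  params <- sd_params(N, D, beta, mean_degree = mean(kappa))
  dth <- angular_distance_matrix(positions)
  chi <- params$R * dth / (params$mu * outer(kappa, kappa))^(1 / D)
  prob <- 1 / (1 + chi^beta)
  ut <- upper.tri(prob)
  hit <- ut & (matrix(runif(N * N), N) < prob)
  idx <- which(hit, arr.ind = TRUE)
  g <- igraph::make_empty_graph(N, directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(idx)))
  structure(list(graph = g, positions = positions, kappa = kappa,
                 params = params, labels = labels, gamma = gamma,
                 kappa0 = kappa0, kappa_c = kappac,
                 cap_angle = if (is.null(n_communities)) NULL else cap_angle,
                 nominal_mean_degree = mean_degree),
            class = "sd_network")
}

#' @export
print.sd_network <- function(x, ...) {
  g <- x$graph
  cat(sprintf(
    "Synthetic S^%d network: N = %d, <k> = %.3f (nominal %.3g), gamma = %.3g, beta = %.3g%s\n",
    x$params$D, igraph::vcount(g), mean(igraph::degree(g)),
    x$nominal_mean_degree, x$gamma, x$params$beta,
    if (is.null(x$labels)) "" else sprintf(", %d planted communities",
                                           length(unique(x$labels)))))
  invisible(x)
}
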