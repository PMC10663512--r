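# Closed-form quantities and sampling primitives of the S^D model.

check_count <- function(x, min, name) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x) ||
      x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

# clip to [-1, 1] preserving dim attributes (pmin/pmax with a scalar first
# argument would drop them)
clip1 <- function(x) {
  x[x > 1] <- 1
  x[x < -1] <- -1
  x
}

#' Radius of the similarity D-sphere at unit node density
#'
#' The similarity space of the S^D model is a D-dimensional sphere whose
#' radius is fixed so that the surface density of the N nodes equals one:
#' \deqn{R = \left[\frac{N}{2\pi^{(D+1)/2}} \Gamma\!\left(\frac{D+1}{2}\right)\right]^{1/D}.}
#' For D = 1 this is the circle of circumference N, R = N / (2 pi).
#'
#' @param N node count (integer >= 2).
#' @param D similarity dimension (integer >= 1).
#' @return The sphere radius R.
#' @export
#' @examples
#' sphere_radius(100, 1) # 100 / (2 * pi)
sphere_radius <- function(N, D) {
  check_count(N, 2, "N")
  check_count(D, 1, "D")
  (N * gamma((D + 1) / 2) / (2 * pi^((D + 1) / 2)))^(1 / D)
}

#' Density parameter mu of the S^D model
#'
#' mu calibrates the average degree of the model:
#' \deqn{\mu = \frac{\beta \Gamma(D/2) \sin(D\pi/\beta)}{2\pi^{1+D/2}\langle k\rangle}.}
#' The geometric regime requires beta > D (otherwise the sine argument leaves
#' (0, pi) and the model loses its metric character).
#'
#' @param beta inverse temperature (> D).
#' @param D similarity dimension (integer >= 1).
#' @param mean_degree target average degree (> 0).
#' @return mu (> 0).
#' @export
compute_mu <- function(beta, D, mean_degree) {
  check_count(D, 1, "D")
  if (!is.numeric(beta) || length(beta) != 1L || beta <= D)
    stop("`beta` must be a single number > D (geometric regime)", call. = FALSE)
  if (!is.numeric(mean_degree) || length(mean_degree) != 1L || mean_degree <= 0)
    stop("`mean_degree` must be positive", call. = FALSE)
  beta * gamma(D / 2) * sin(D * pi / beta) / (2 * pi^(1 + D / 2) * mean_degree)
}

#' Angular separation of two points on a sphere
#'
#' Returns arccos of the normalized dot product, clipped to \[-1, 1\] to absorb
#' floating-point overshoot; the result lies in \[0, pi\] and is symmetric.
#'
#' @param v1,v2 nonzero numeric vectors of equal length.
#' @return Separation in radians.
#' @export
angular_distance <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0)
    stop("angular distance undefined for a zero vector", call. = FALSE)
  acos(clip1(sum(v1 * v2) / (n1 * n2)))
}

# Pairwise angular separations of the rows of a unit-vector matrix.
angular_distance_matrix <- function(V) {
  acos(clip1(tcrossprod(V)))
}

#' Gravity-law connection probability of the S^D model
#'
#' Computes the rescaled distance
#' \eqn{\chi_{ij} = R\Delta\theta / (\mu\kappa_i\kappa_j)^{1/D}} and the
#' connection probability \eqn{p_{ij} = 1/(1+\chi_{ij}^\beta)}. Vectorized
#' over the first three arguments (recycled).
#'
#' @param kappa_i,kappa_j hidden degrees (> 0).
#' @param dtheta angular separation(s) in \[0, pi\].
#' @param params an [sd_params] object (uses R, mu, D, beta).
#' @return List with components `p` and `chi`.
#' @export
connection_probability <- function(kappa_i, kappa_j, dtheta, params) {
  stopifnot(all(kappa_i > 0), all(kappa_j > 0),
            all(dtheta >= 0), all(dtheta <= pi + 1e-12))
  chi <- params$R * dtheta / (params$mu * kappa_i * kappa_j)^(1 / params$D)
  list(p = 1 / (1 + chi^params$beta), chi = chi)
}

#' Uniform sample of points on the D-sphere
#'
#' Draws n unit vectors in R^(D+1) from the rotationally invariant
#' distribution (D+1 independent standard normal entries, normalized).
#' Positions are stored as unit vectors; the model radius R is applied only
#' where distances enter formulas.
#'
#' @param n number of points.
#' @param D sphere dimension.
#' @return An n x (D+1) matrix with unit-norm rows.
#' @export
sample_uniform_sphere <- function(n, D) {
  check_count(n, 1, "n")
  check_count(D, 1, "D")
  X <- matrix(rnorm(n * (D + 1)), nrow = n)
  nrm <- sqrt(rowSums(X^2))
  while (any(nrm < 1e-12)) { # astronomically rare, but keep the contract exact
    bad <- nrm < 1e-12
    X[bad, ] <- rnorm(sum(bad) * (D + 1))
    nrm <- sqrt(rowSums(X^2))
  }
  X / nrm
}

#' Random point at a fixed angular separation from a reference point
#'
#' Returns a unit vector w with `angular_distance(v, w) == dtheta` (to
#' numerical precision), with uniform azimuthal orientation in the hyperplane
#' orthogonal to v. Shared primitive used by the cap-community generator, the
#' clustering estimator and degree-one reattachment.
#'
#' @param v reference unit vector (length D+1).
#' @param dtheta separation in \[0, pi\].
#' @return A unit vector of the same length as v.
#' @export
sample_at_separation <- function(v, dtheta) {
  stopifnot(dtheta >= 0, dtheta <= pi)
  v <- v / sqrt(sum(v^2))
  if (dtheta == 0) return(v)
  if (dtheta == pi) return(-v)
  x <- rnorm(length(v))
  u <- x - sum(x * v) * v
  nu <- sqrt(sum(u^2))
  while (nu < 1e-12) {
    x <- rnorm(length(v))
    u <- x - sum(x * v) * v
    nu <- sqrt(sum(u^2))
  }
  w <- cos(dtheta) * v + sin(dtheta) * u / nu
  w / sqrt(sum(w^2))
}

#' Density of angular separations on the D-sphere
#'
#' Distribution of the angular distance between two independently uniform
#' points: \eqn{\rho(\Delta\theta) = \Gamma((D+1)/2)\sin^{D-1}(\Delta\theta) /
#' (\Gamma(D/2)\sqrt{\pi})}, constant 1/pi for D = 1 and increasingly peaked
#' at pi/2 as D grows.
#'
#' @param dtheta separation(s) in \[0, pi\].
#' @param D sphere dimension.
#' @return Density value(s).
#' @export
angular_distance_pdf <- function(dtheta, D) {
  check_count(D, 1, "D")
  stopifnot(all(dtheta >= 0), all(dtheta <= pi))
  gamma((D + 1) / 2) * sin(dtheta)^(D - 1) / (gamma(D / 2) * sqrt(pi))
}

#' Global parameters of an S^D model
#'
#' Bundles N, D, beta, mu, R and the nominal mean degree. R is always the
#' unit-density closed form for (N, D); mu defaults to the closed form for
#' (beta, D, mean_degree) but can be fixed by the caller (the embedding
#' pipeline recomputes it from the observed mean degree at every beta).
#'
#' @param N node count.
#' @param D similarity dimension.
#' @param beta inverse temperature (> D).
#' @param mean_degree average degree used to calibrate mu.
#' @param mu optional fixed density parameter; computed from `mean_degree`
#'   when `NULL`.
#' @return An object of class `sd_params`.
#' @export
sd_params <- function(N, D, beta, mean_degree, mu = NULL) {
  check_count(N, 2, "N")
  check_count(D, 1, "D")
  if (beta <= D) stop("`beta` must exceed D", call. = FALSE)
  if (mean_degree <= 0) stop("`mean_degree` must be positive", call. = FALSE)
  if (is.null(mu)) mu <- compute_mu(beta, D, mean_degree)
  if (mu <= 0) stop("`mu` must be positive", call. = FALSE)
  structure(list(N = as.integer(N), D = as.integer(D), beta = beta,
                 mu = mu, R = sphere_radius(N, D),
                 mean_degree = mean_degree),
            class = "sd_params")
}

#' @export
print.sd_params <- function(x, ...) {
  cat(sprintf(
    "S^%d model parameters: N = %d, beta = %.4g, mu = %.6g, R = %.6g, <k> = %.4g\n",
    x$D, x$N, x$beta, x$mu, x$R, x$mean_degree))
  invisible(x)
}
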