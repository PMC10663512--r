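# Purely geometric H^(D+1) representation of an S^D embedding.

#' Map an S^D embedding to hyperbolic coordinates
#'
#' Maps hidden degrees to radial coordinates,
#' \deqn{r_i = \hat R - \frac{2}{D}\ln\frac{\kappa_i}{\kappa_0}, \qquad
#'       \hat R = 2\ln\frac{2R}{(\mu\kappa_0^2)^{1/D}},}
#' so that the gravity-law connection probability becomes the purely
#' geometric form \eqn{p_{ij} = 1/(1+e^{(\beta/2)(x_{ij}-\hat R)})} with the
#' effective hyperbolic distance \eqn{x_{ij} = r_i + r_j + 2\ln(\Delta\theta_{ij}/2)}.
#' x approximates the true geodesic only for pairs with
#' \eqn{\Delta\theta \gg 2\sqrt{e^{-2r_i}+e^{-2r_j}}}; it is the distance used
#' by greedy routing here.
#'
#' @param embedding an `sd_embedding`, or a list with `positions` (unit
#'   rows), `kappa` and `params`.
#' @param kappa0 radial reference hidden degree; defaults to `min(kappa)`
#'   (for generated networks the generator's kappa_0 can be passed).
#' @return An object of class `hyperbolic_coordinates`: `radial`, `R_hat`,
#'   unit `directions`, `D`, `beta`.
#' @export
to_hyperbolic <- function(embedding, kappa0 = NULL) {
  kappa <- embedding$kappa
  params <- embedding$params
  if (any(kappa <= 0)) stop("hidden degrees must be positive", call. = FALSE)
  if (is.null(kappa0)) kappa0 <- min(kappa)
  D <- params$D
  R_hat <- 2 * log(2 * params$R / (params$mu * kappa0^2)^(1 / D))
  r <- R_hat - (2 / D) * log(kappa / kappa0)
  structure(list(radial = r, R_hat = R_hat,
                 directions = embedding$positions, D = D,
                 beta = params$beta, kappa0 = kappa0),
            class = "hyperbolic_coordinates")
}

#' @export
print.hyperbolic_coordinates <- function(x, ...) {
  cat(sprintf(
    "H^%d coordinates: %d nodes, disk radius R_hat = %.4f, radial range [%.4f, %.4f]\n",
    x$D + 1L, length(x$radial), x$R_hat, min(x$radial), max(x$radial)))
  invisible(x)
}

#' Connection probability in the hyperbolic picture
#'
#' For index vectors i, j (recycled pairwise), computes the effective
#' hyperbolic distance `x = r_i + r_j + 2 ln(dtheta/2)` and
#' `p = 1/(1 + exp((beta/2)(x - R_hat)))`. Coincident directions give
#' x = -Inf and p = 1 (the limit of the formula).
#'
#' @param coords a `hyperbolic_coordinates` object.
#' @param i,j node index vectors.
#' @param beta inverse temperature; defaults to the embedding's.
#' @return List with components `p` and `x`.
#' @export
hyperbolic_connection_probability <- function(coords, i, j, beta = NULL) {
  if (is.null(beta)) beta <- coords$beta
  n <- max(length(i), length(j))
  i <- rep_len(i, n); j <- rep_len(j, n)
  dth <- acos(clip1(rowSums(coords$directions[i, , drop = FALSE] *
                            coords$directions[j, , drop = FALSE])))
  x <- coords$radial[i] + coords$radial[j] + 2 * log(dth / 2)
  list(p = 1 / (1 + exp((beta / 2) * (x - coords$R_hat))), x = x)
}
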