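# Stage 1 of the embedding: hidden degrees and inverse temperature.

#' Tolerances and iteration caps of the embedding pipeline
#'
#' @param epsilon tolerance on the max deviation between expected and
#'   observed degrees (default 0.01).
#' @param epsilon_clust tolerance on the mean local clustering match used by
#'   the beta search (default 0.01).
#' @param m Monte-Carlo samples per degree class in the clustering estimator
#'   (default 600; the estimator's standard error shrinks as m^(-1/2)).
#' @param max_iter safety cap on hidden-degree adjustment iterations.
#' @param ramp_cap maximum number of beta *= 1.5 ramp steps when bracketing.
#' @param bisect_cap maximum number of bisection steps for beta.
#' @param candidates number of candidate positions per node in the likelihood
#'   sweep; `NULL` means the default 100 * max(ln N, 1).
#' @param max_sweeps cap on likelihood sweeps per refinement round.
#' @param plateau_tol relative change of the global log-likelihood across a
#'   sweep below which the refinement is declared converged.
#' @param proposal_spread `"max"` applies the proposal spread
#'   sigma = max(pi/2, dtheta_max/2) literally (which is constantly pi/2 since
#'   dtheta_max <= pi); `"min"` uses min(pi/2, dtheta_max/2), localizing
#'   proposals around the neighbour mean. Both are exposed because the two
#'   readings differ materially; the default is the literal form.
#' @param refine_rounds number of LE-seeded likelihood refinement rounds.
#' @param le_dense_cutoff below this core size the Laplacian eigenproblem is
#'   solved densely; above it a sparse Lanczos solver is used.
#' @param verbose emit progress messages.
#' @return A list of settings of class `sd_config`.
#' @export
sd_config <- function(epsilon = 0.01, epsilon_clust = 0.01, m = 600L,
                      max_iter = 2000L, ramp_cap = 40L, bisect_cap = 40L,
                      candidates = NULL, max_sweeps = 6L, plateau_tol = 1e-4,
                      proposal_spread = c("max", "min"), refine_rounds = 1L,
                      le_dense_cutoff = 4000L, verbose = FALSE) {
  stopifnot(epsilon > 0, epsilon_clust > 0, m >= 1)
  structure(list(
    epsilon = epsilon, epsilon_clust = epsilon_clust, m = as.integer(m),
    max_iter = as.integer(max_iter), ramp_cap = as.integer(ramp_cap),
    bisect_cap = as.integer(bisect_cap), candidates = candidates,
    max_sweeps = as.integer(max_sweeps), plateau_tol = plateau_tol,
    proposal_spread = match.arg(proposal_spread),
    refine_rounds = as.integer(refine_rounds),
    le_dense_cutoff = as.integer(le_dense_cutoff), verbose = isTRUE(verbose)),
    class = "sd_config")
}

# Prefactor of the expected-degree quadrature; equals 1/pi for D = 1.
degree_prefactor <- function(D) gamma((D + 1) / 2) / (sqrt(pi) * gamma(D / 2))

#' Model-expected degrees for a set of hidden degrees
#'
#' Evaluates, by adaptive quadrature, the S^D expectation
#' \deqn{\bar k(\kappa_i) = \frac{\Gamma((D+1)/2)}{\sqrt{\pi}\,\Gamma(D/2)}
#'   \sum_{j\ne i}\int_0^\pi
#'   \frac{\sin^{D-1}\theta\,d\theta}{1+(R\theta/(\mu\kappa_i\kappa_j)^{1/D})^\beta}.}
#'
#' @param kappa vector of hidden degrees (> 0).
#' @param params an [sd_params] object.
#' @return Vector of expected degrees, each in \[0, N - 1\].
#' @export
expected_sd_degrees <- function(kappa, params) {
  stopifnot(all(kappa > 0), length(kappa) == params$N)
  pr <- outer(kappa, kappa)
  z <- (params$mu * pr)^(1 / params$D) / params$R
  uz <- sort(unique(as.vector(z)))
  f0 <- sd_kernel_f0(uz, params$D, params$beta)
  F0 <- matrix(f0[match(as.vector(z), uz)], nrow = length(kappa))
  degree_prefactor(params$D) * (rowSums(F0) - diag(F0))
}

# Class-level expected degrees using a spline table of the kernel; the
# workhorse inside the iterative fits (identical integrand, much faster).
class_expected_degrees <- function(kappa_cls, counts, D, mu, R, f0_table) {
  Z <- (mu * outer(kappa_cls, kappa_cls))^(1 / D) / R
  F0 <- f0_table$eval(Z)
  degree_prefactor(D) * (as.vector(F0 %*% counts) - diag(F0))
}

#' Fit hidden degrees to an observed degree sequence
#'
#' Iterates the noisy adjustment `|kappa + (k - kbar(kappa)) u| -> kappa`
#' (u ~ U(0,1)) per degree class, starting from kappa = k, until the maximal
#' deviation between expected and observed degrees drops below
#' `config$epsilon`. Nodes with equal observed degree share one kappa.
#'
#' @param degrees observed degree sequence (all >= 1).
#' @param beta inverse temperature (> D).
#' @param D similarity dimension.
#' @param config an [sd_config] object.
#' @param mean_degree mean degree used in the mu closed form; defaults to
#'   `mean(degrees)`.
#' @return A list of class `sd_degree_fit` with per-class and per-node
#'   hidden degrees, the mu in force, and convergence diagnostics.
#' @export
fit_hidden_degrees <- function(degrees, beta, D, config = sd_config(),
                               mean_degree = NULL) {
  stopifnot(all(degrees >= 1))
  N <- length(degrees)
  if (is.null(mean_degree)) mean_degree <- mean(degrees)
  mu <- compute_mu(beta, D, mean_degree)
  R <- sphere_radius(N, D)
  ks <- sort(unique(degrees))
  counts <- tabulate(match(degrees, ks), nbins = length(ks))
  kap_lo <- max(min(ks) * 1e-3, 1e-5)
  kap_hi <- max(ks) * 200
  tab <- make_f0_table(D, beta,
                       (mu * kap_lo^2)^(1 / D) / R,
                       (mu * kap_hi^2)^(1 / D) / R)
  kappa <- as.numeric(ks)
  eps_max <- Inf
  it <- 0L
  best_eps <- Inf
  stall <- 0L
  damp <- 1
  while (it < config$max_iter) {
    it <- it + 1L
    kbar <- class_expected_degrees(kappa, counts, D, mu, R, tab)
    eps_max <- max(abs(kbar - ks))
    if (eps_max <= config$epsilon) break
    if (eps_max < best_eps * 0.999) {
      best_eps <- eps_max
      stall <- 0L
    } else if ((stall <- stall + 1L) > 200L) {
      damp <- damp / 2 # shrink the noisy step when the residual stalls
      stall <- 0L
    }
    u <- runif(length(ks)) * damp
    kappa <- abs(kappa + (ks - kbar) * u)
    kappa <- pmin(pmax(kappa, kap_lo), kap_hi)
  }
  if (eps_max > config$epsilon)
    stop(sprintf(
      "hidden-degree fit did not reach epsilon = %g in %d iterations (residual %g)",
      config$epsilon, config$max_iter, eps_max), call. = FALSE)
  structure(list(
    kappa_class = kappa, degree_class = ks, counts = counts,
    kappa = kappa[match(degrees, ks)], degrees = degrees,
    beta = beta, D = D, mu = mu, R = R, N = N,
    eps_max = eps_max, iterations = it), class = "sd_degree_fit")
}

#' @export
print.sd_degree_fit <- function(x, ...) {
  cat(sprintf(
    "Hidden-degree fit: %d nodes, %d degree classes, beta = %.4g, residual %.2g (%d iterations)\n",
    x$N, length(x$degree_class), x$beta, x$eps_max, x$iterations))
  invisible(x)
}

#' Model-expected mean local clustering
#'
#' Monte-Carlo estimator of the mean local clustering coefficient of the S^D
#' ensemble implied by a hidden-degree fit. For every degree class, two
#' neighbour degrees are drawn from the uncorrelated distribution
#' P(k'|k) = k'P(k')/<k>, their separations from the central node are drawn
#' from the connected-pair distribution rho(dtheta | a = 1), the two
#' neighbours are placed with uniform azimuths, and the probability that they
#' are connected is accumulated. Classes of degree one are excluded from the
#' average (local clustering is undefined below k = 2).
#'
#' @param fit an `sd_degree_fit`.
#' @param config an [sd_config] (uses `m`).
#' @return The estimated mean local clustering; the per-class spectrum is
#'   attached as attribute `"spectrum"`.
#' @export
estimate_mean_clustering <- function(fit, config = sd_config()) {
  D <- fit$D; beta <- fit$beta; mu <- fit$mu; R <- fit$R
  m <- config$m
  C <- length(fit$degree_class)
  w <- fit$degree_class * fit$counts # degree-biased neighbour distribution
  draw_sep <- separation_sampler_cache(D, beta, mu, R)
  cbar_k <- rep(NA_real_, C)
  for (a in seq_len(C)) {
    if (fit$degree_class[a] < 2) next
    c1 <- sample.int(C, m, replace = TRUE, prob = w)
    c2 <- sample.int(C, m, replace = TRUE, prob = w)
    th1 <- th2 <- numeric(m)
    for (b in unique(c1)) {
      idx <- which(c1 == b)
      th1[idx] <- draw_sep(fit$kappa_class[a], fit$kappa_class[b], runif(length(idx)))
    }
    for (b in unique(c2)) {
      idx <- which(c2 == b)
      th2[idx] <- draw_sep(fit$kappa_class[a], fit$kappa_class[b], runif(length(idx)))
    }
    # azimuthal placement in the hyperplane orthogonal to the central node
    if (D == 1) {
      dot <- sample(c(-1, 1), m, replace = TRUE) * sample(c(-1, 1), m, replace = TRUE)
    } else {
      W1 <- matrix(rnorm(m * D), m); W1 <- W1 / sqrt(rowSums(W1^2))
      W2 <- matrix(rnorm(m * D), m); W2 <- W2 / sqrt(rowSums(W2^2))
      dot <- rowSums(W1 * W2)
    }
    dth12 <- acos(clip1(cos(th1) * cos(th2) + sin(th1) * sin(th2) * dot))
    chi <- R * dth12 / (mu * fit$kappa_class[c1] * fit$kappa_class[c2])^(1 / D)
    cbar_k[a] <- mean(1 / (1 + chi^beta))
  }
  keep <- !is.na(cbar_k)
  cbar <- sum(cbar_k[keep] * fit$counts[keep]) / sum(fit$counts[keep])
  attr(cbar, "spectrum") <- data.frame(degree = fit$degree_class[keep],
                                       cbar = cbar_k[keep])
  cbar
}

#' Mean local clustering of a graph
#'
#' Average of the local clustering coefficient over nodes of degree >= 2,
#' the empirical target matched by the beta search.
#'
#' @param graph an igraph object.
#' @return Scalar in \[0, 1\].
#' @export
mean_local_clustering <- function(graph) {
  lt <- igraph::transitivity(graph, type = "local", isolates = "NaN")
  deg <- igraph::degree(graph)
  mean(lt[deg >= 2], na.rm = TRUE)
}

#' Infer the inverse temperature beta of a network
#'
#' Matches the model-expected mean local clustering to the empirical one.
#' beta starts uniformly in (D, D+1); while the expected clustering is below
#' the target, beta is multiplied by 1.5; the two last values then bracket
#' the solution and bisection runs until the clustering tolerance is met.
#' Hidden degrees are refitted (and mu recomputed) at every beta evaluation.
#'
#' @param graph an igraph object (connected, simple).
#' @param D embedding dimension.
#' @param config an [sd_config].
#' @param seed optional RNG seed.
#' @return List with `beta`, the final `fit` (an `sd_degree_fit`), `mu`,
#'   the matched clustering values and the search trace.
#' @export
infer_beta <- function(graph, D, config = sd_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  degrees <- igraph::degree(graph)
  cemp <- mean_local_clustering(graph)
  if (!is.finite(cemp) || cemp <= 0)
    stop("the network has no measurable clustering; beta cannot be matched",
         call. = FALSE)
  trace <- list()
  evaluate <- function(beta) {
    fit <- fit_hidden_degrees(degrees, beta, D, config)
    cbar <- estimate_mean_clustering(fit, config)
    trace[[length(trace) + 1L]] <<- c(beta = beta, cbar = as.numeric(cbar))
    list(fit = fit, cbar = as.numeric(cbar))
  }
  # the initial guess is immaterial to the result, but a draw too close to
  # the degenerate beta = D edge makes the degree fit ill-conditioned
  beta <- runif(1, D + 0.05, D + 1)
  ev <- evaluate(beta)
  best <- list(beta = beta, ev = ev, err = abs(ev$cbar - cemp))
  lo <- D + 0.05
  hi <- NA_real_
  if (ev$cbar < cemp) {
    ramp <- 0L
    while (ev$cbar < cemp && abs(ev$cbar - cemp) >= config$epsilon_clust) {
      ramp <- ramp + 1L
      if (ramp > config$ramp_cap)
        stop(sprintf(
          "failed to bracket beta after %d ramp steps (clustering target %.4f unreachable?)",
          config$ramp_cap, cemp), call. = FALSE)
      lo <- beta
      beta <- beta * 1.5
      ev <- evaluate(beta)
      if (abs(ev$cbar - cemp) < best$err)
        best <- list(beta = beta, ev = ev, err = abs(ev$cbar - cemp))
    }
    hi <- beta
  } else {
    hi <- beta
  }
  it <- 0L
  while (best$err >= config$epsilon_clust && it < config$bisect_cap) {
    it <- it + 1L
    beta <- (lo + hi) / 2
    ev <- evaluate(beta)
    if (abs(ev$cbar - cemp) < best$err)
      best <- list(beta = beta, ev = ev, err = abs(ev$cbar - cemp))
    if (ev$cbar < cemp) lo <- beta else hi <- beta
    if ((hi - lo) < 1e-6 * hi) break
  }
  if (best$err >= config$epsilon_clust)
    warning(sprintf(
      "beta bisection stopped with |cbar - cemp| = %.4g (tolerance %.4g)",
      best$err, config$epsilon_clust))
  list(beta = best$beta, fit = best$ev$fit, mu = best$ev$fit$mu,
       cbar_model = best$ev$cbar, cbar_emp = cemp,
       trace = do.call(rbind, trace))
}
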