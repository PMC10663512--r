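# The full embedding pipeline.

#' Embed a network into (D+1)-dimensional hyperbolic space
#'
#' Runs the four inference stages of the model-based embedding:
#' \enumerate{
#'   \item hidden degrees and inverse temperature beta are inferred by
#'     matching expected degrees and the mean local clustering (skipped for
#'     beta when `beta` is supplied, which supports controlled experiments);
#'   \item initial positions on the D-sphere come from model-corrected
#'     Laplacian Eigenmaps (degree-one nodes pruned and reattached);
#'   \item positions are refined by per-node likelihood maximization in
#'     onion order;
#'   \item hidden degrees are readjusted given the final positions.
#' }
#' The run is fully reproducible under `seed`.
#'
#' @param x an igraph object or the path to an edge-list file
#'   (see [read_edgelist]). Must be simple and connected (the largest
#'   component is used otherwise).
#' @param D embedding similarity dimension (>= 1).
#' @param beta optional fixed inverse temperature (> D); when `NULL` it is
#'   inferred from the clustering.
#' @param config an [sd_config].
#' @param seed optional RNG seed.
#' @return An object of class `sd_embedding`: `graph`, `labels`, unit-row
#'   `positions`, `kappa`, `params` (with fitted beta, mu), `radial`,
#'   `R_hat`, and `diagnostics` (beta search trace, LE loss, log-likelihood
#'   trace, final degree residual).
#' @export
embed_network <- function(x, D, beta = NULL, config = sd_config(),
                          seed = NULL) {
  graph <- if (is.character(x)) read_edgelist(x) else x
  check_count(D, 1, "D")
  if (!is.null(seed)) set.seed(seed)
  if (igraph::any_multiple(graph) || any(igraph::which_loop(graph)))
    graph <- igraph::simplify(graph)
  comp <- igraph::components(graph)
  if (comp$no > 1L) {
    warning("disconnected input: embedding the largest component")
    graph <- igraph::induced_subgraph(graph,
                                      which(comp$membership ==
                                            which.max(comp$csize)))
  }
  N <- igraph::vcount(graph)
  degrees <- igraph::degree(graph)
  say <- function(...) if (config$verbose) message(sprintf(...))

  # Stage 1: hidden degrees and beta
  beta_trace <- NULL
  if (is.null(beta)) {
    say("inferring beta and hidden degrees (D = %d) ...", D)
    bi <- infer_beta(graph, D, config)
    beta <- bi$beta
    fit <- bi$fit
    beta_trace <- bi$trace
    say("beta = %.4f (model clustering %.4f vs empirical %.4f)",
        beta, bi$cbar_model, bi$cbar_emp)
  } else {
    if (beta <= D) stop("`beta` must exceed D", call. = FALSE)
    say("fitting hidden degrees at fixed beta = %.4f ...", beta)
    fit <- fit_hidden_degrees(degrees, beta, D, config)
  }
  params <- sd_params(N, D, beta, mean_degree = mean(degrees), mu = fit$mu)
  kappa <- fit$kappa

  # Stage 2: spectral initialization
  say("Laplacian Eigenmaps initialization ...")
  le <- laplacian_initial_positions(graph, kappa, params, config)

  # Stage 3: likelihood refinement (optionally repeated)
  positions <- le$positions
  trace <- numeric(0)
  sweeps <- 0L
  for (round in seq_len(max(config$refine_rounds, 1L))) {
    say("likelihood refinement round %d ...", round)
    ref <- refine_positions(graph, kappa, positions, params, config)
    positions <- ref$positions
    trace <- c(trace, ref$trace)
    sweeps <- sweeps + ref$sweeps
  }

  # Stage 4: final hidden-degree adjustment
  say("final hidden-degree adjustment ...")
  adj <- final_degree_adjustment(graph, kappa, positions, params, config)
  kappa <- adj$kappa

  emb <- structure(list(
    graph = graph,
    labels = if (is.null(igraph::V(graph)$name)) as.character(seq_len(N))
             else igraph::V(graph)$name,
    positions = positions, kappa = kappa, params = params,
    diagnostics = list(beta_trace = beta_trace, le_loss = le$loss,
                       le_t = le$t, loglik_trace = trace, sweeps = sweeps,
                       degree_residual = adj$eps_max,
                       degree_iterations = adj$iterations)),
    class = "sd_embedding")
  hyp <- to_hyperbolic(emb)
  emb$radial <- hyp$radial
  emb$R_hat <- hyp$R_hat
  emb
}

#' @export
print.sd_embedding <- function(x, ...) {
  cat(sprintf(
    "S^%d embedding of %d nodes: beta = %.4f, mu = %.6g, R_hat = %.4f\n",
    x$params$D, x$params$N, x$params$beta, x$params$mu, x$R_hat))
  cat(sprintf(
    "  log-likelihood %.2f after %d sweep(s); final degree residual %.3g\n",
    utils::tail(x$diagnostics$loglik_trace, 1L), x$diagnostics$sweeps,
    x$diagnostics$degree_residual))
  invisible(x)
}
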