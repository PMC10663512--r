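# Embedding quality metrics and dimension selection.

#' Greedy routing on a hyperbolic map
#'
#' Messages hop from the current node to its neighbour with the smallest
#' effective hyperbolic distance to the target; delivery succeeds when the
#' target is reached, and fails when a node is revisited or the hop count
#' exceeds the number of nodes. The stretch of a successful path is its hop
#' length divided by the shortest-path length; the mean is taken over
#' successful deliveries only.
#'
#' @param graph connected igraph object.
#' @param coords a [to_hyperbolic] result for the same nodes.
#' @param n_pairs number of ordered source-target pairs; when
#'   `N (N-1) <= n_pairs` all ordered pairs are used.
#' @param seed optional RNG seed for the pair sample.
#' @return List with `success_rate`, `mean_stretch`, `n_pairs`.
#' @export
greedy_routing <- function(graph, coords, n_pairs = 10000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  N <- igraph::vcount(graph)
  stopifnot(length(coords$radial) == N)
  if (N * (N - 1L) <= n_pairs) {
    grid <- expand.grid(src = seq_len(N), dst = seq_len(N))
    grid <- grid[grid$src != grid$dst, ]
    src <- grid$src; dst <- grid$dst
  } else {
    src <- sample.int(N, n_pairs, replace = TRUE)
    dst <- sample.int(N, n_pairs, replace = TRUE)
    while (any(src == dst)) {
      eq <- src == dst
      dst[eq] <- sample.int(N, sum(eq), replace = TRUE)
    }
  }
  adj0 <- adjacency_list0(graph)
  hops <- cpp_greedy_route(adj0, coords$directions, coords$radial,
                           as.integer(src) - 1L, as.integer(dst) - 1L, N)
  ok <- hops > 0L
  stretch <- NA_real_
  if (any(ok)) {
    sp <- igraph::distances(graph, v = seq_len(N), mode = "all")
    spl <- sp[cbind(src[ok], dst[ok])]
    stretch <- mean(hops[ok] / spl)
  }
  list(success_rate = mean(ok), mean_stretch = stretch,
       n_pairs = length(src))
}

#' Geometric concentration of communities around nodes
#'
#' For each node i, takes its `n_g = ceiling(fraction * N)` angularly
#' closest other nodes and computes the enrichment of the node's own
#' community among them, `rho_i = (n_il / n_g) (N / N_l)`. The scalar
#' concentration `c_C` is the mean of rho over nodes (at fraction 0.1 this
#' is the community concentration used for dimension selection). Under this
#' size-normalized enrichment, labels carrying no geometric signal give
#' `c_C ~ 1` and `fraction -> 1` forces rho -> 1; the reported `rho_random
#' = 1/N_C` is the corresponding baseline of the raw own-community fraction
#' `n_il/n_g` (enrichment and raw fraction differ by the factor `N/N_l`,
#' i.e. `N_C` for balanced communities).
#'
#' @param positions unit-row position matrix.
#' @param labels community label per node.
#' @param fraction fraction of the network counted as the geometric
#'   neighbourhood, in (0, 1\].
#' @return List with per-node `rho`, `c_C`, the random baseline
#'   `rho_random = 1/N_C` and `n_g`.
#' @export
community_concentration <- function(positions, labels, fraction = 0.1) {
  N <- nrow(positions)
  stopifnot(length(labels) == N, fraction > 0, fraction <= 1)
  labels <- as.integer(factor(labels))
  sizes <- tabulate(labels)
  n_g <- min(as.integer(ceiling(fraction * N)), N - 1L)
  dth <- angular_distance_matrix(positions)
  diag(dth) <- Inf
  rho <- rep(NA_real_, N)
  skip <- sizes[labels] < 2L
  if (any(skip))
    warning(sprintf("%d node(s) in singleton communities skipped", sum(skip)))
  for (i in which(!skip)) {
    nb <- order(dth[i, ])[seq_len(n_g)]
    rho[i] <- sum(labels[nb] == labels[i]) / n_g * N / sizes[labels[i]]
  }
  list(rho = rho, c_C = mean(rho, na.rm = TRUE),
       rho_random = 1 / length(unique(labels)), n_g = n_g)
}

#' Align inferred coordinates to a reference by orthogonal Procrustes
#'
#' Finds the orthogonal transform (rotations and reflections) of the
#' inferred configuration minimizing the summed squared chord displacement
#' to the reference — the closed-form solution W = U V' from the SVD of
#' X'Y — and reports per-axis Pearson correlations and the mean residual
#' angle. Configurations are not centred or scaled: both live on the unit
#' sphere around the origin.
#'
#' @param inferred,reference n x (D+1) matrices with unit rows.
#' @return List with `aligned`, `rotation`, `per_axis_r`,
#'   `mean_angle` (radians).
#' @export
align_to_reference <- function(inferred, reference) {
  if (!all(dim(inferred) == dim(reference)))
    stop("inferred and reference configurations must have identical dimensions",
         call. = FALSE)
  s <- svd(crossprod(inferred, reference))
  W <- s$u %*% t(s$v)
  aligned <- inferred %*% W
  list(aligned = aligned, rotation = W,
       per_axis_r = vapply(seq_len(ncol(aligned)),
                           function(m) cor(aligned[, m], reference[, m]),
                           numeric(1)),
       mean_angle = mean(acos(clip1(rowSums(aligned * reference)))))
}

#' Empirical connection probability versus rescaled distance
#'
#' Bins all node pairs by their rescaled distance chi (log-spaced bins) and
#' returns the fraction of connected pairs per bin together with the
#' gravity-law overlay 1/(1 + chi^beta) at the bin centre. Empty bins are
#' dropped.
#'
#' @param graph igraph object.
#' @param kappa hidden degrees.
#' @param positions unit-row positions.
#' @param params an [sd_params].
#' @param n_bins number of log-spaced bins.
#' @return data.frame with `chi` (geometric bin centre), `fraction`,
#'   `n_pairs`, `theory`.
#' @export
empirical_connection_curve <- function(graph, kappa, positions, params,
                                       n_bins = 25L) {
  N <- igraph::vcount(graph)
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE) > 0
  dth <- angular_distance_matrix(positions)
  chi <- params$R * dth / (params$mu * outer(kappa, kappa))^(1 / params$D)
  ut <- upper.tri(chi)
  x <- chi[ut]; a <- A[ut]
  pos <- x > 0
  x <- x[pos]; a <- a[pos]
  brk <- exp(seq(log(min(x)), log(max(x)), length.out = n_bins + 1L))
  brk[1L] <- brk[1L] * (1 - 1e-12); brk[n_bins + 1L] <- brk[n_bins + 1L] * (1 + 1e-12)
  bin <- cut(x, brk, labels = FALSE)
  out <- do.call(rbind, lapply(seq_len(n_bins), function(b) {
    sel <- which(bin == b)
    if (!length(sel)) return(NULL)
    centre <- sqrt(brk[b] * brk[b + 1L])
    data.frame(chi = centre, fraction = mean(a[sel]), n_pairs = length(sel),
               theory = 1 / (1 + centre^params$beta))
  }))
  out
}

#' Geometric community detection by agglomerative clustering
#'
#' Average-linkage agglomerative clustering of the nodes by angular distance
#' in the similarity space, cut at a prescribed number of clusters.
#' Deterministic for a given input order.
#'
#' @param positions unit-row position matrix.
#' @param n_clusters number of communities (2 <= n_clusters <= N).
#' @return Integer label vector.
#' @export
detect_geometric_communities <- function(positions, n_clusters) {
  N <- nrow(positions)
  if (n_clusters > N) stop("n_clusters exceeds the number of nodes",
                           call. = FALSE)
  dth <- angular_distance_matrix(positions)
  hc <- hclust(as.dist(dth), method = "average")
  unname(cutree(hc, k = n_clusters))
}

#' Modularity and normalized mutual information of a partition
#'
#' Newman-Girvan modularity of the labels on the graph, and NMI (arithmetic
#' normalization, 2 I / (H1 + H2)) against reference labels. A partition
#' with zero entropy on either side yields NMI = 0 with a warning.
#'
#' @param graph igraph object.
#' @param labels candidate partition.
#' @param reference_labels reference partition (e.g. metadata); optional.
#' @return List with `Q` and `NMI` (NA when no reference given).
#' @export
partition_quality <- function(graph, labels, reference_labels = NULL) {
  stopifnot(length(labels) == igraph::vcount(graph))
  labels <- as.integer(factor(labels))
  Q <- igraph::modularity(graph, labels)
  nmi <- NA_real_
  if (!is.null(reference_labels)) {
    reference_labels <- as.integer(factor(reference_labels))
    if (length(unique(labels)) < 2L || length(unique(reference_labels)) < 2L) {
      warning("NMI undefined against a single-community partition; reporting 0")
      nmi <- 0
    } else {
      nmi <- igraph::compare(labels, reference_labels, method = "nmi")
    }
  }
  list(Q = Q, NMI = nmi)
}

#' Consensus embedding dimension across quality metrics
#'
#' For each metric, the dimension at which it peaks is recorded (metrics
#' named in `minimize` peak downwards, e.g. stretch); the consensus is the
#' modal optimum. Ties are reported as unresolved with the full table.
#'
#' @param report data.frame with a `dimension` column and one column per
#'   metric.
#' @param minimize metric names for which smaller is better.
#' @return List with `dimension` (NA when unresolved), `unresolved`,
#'   `per_metric` (named optimal dimension per metric) and the input table.
#' @export
consensus_dimension <- function(report, minimize = "stretch") {
  stopifnot(is.data.frame(report), "dimension" %in% names(report),
            nrow(report) >= 2L)
  metrics <- setdiff(names(report), "dimension")
  per_metric <- vapply(metrics, function(mt) {
    v <- report[[mt]]
    if (all(is.na(v))) return(NA_real_)
    if (mt %in% minimize) v <- -v
    report$dimension[which.max(v)]
  }, numeric(1))
  votes <- table(per_metric[!is.na(per_metric)])
  if (!length(votes)) return(list(dimension = NA, unresolved = TRUE,
                                  per_metric = per_metric, table = report))
  top <- names(votes)[votes == max(votes)]
  unresolved <- length(top) > 1L
  list(dimension = if (unresolved) NA_real_ else as.numeric(top),
       unresolved = unresolved, per_metric = per_metric, table = report)
}

#' Evaluate one embedding
#'
#' Computes greedy-routing success and stretch on the hyperbolic map and,
#' when labels are available, the geometric community concentration plus the
#' modularity and NMI of the agglomerative geometric partition with as many
#' clusters as labelled communities.
#'
#' @param graph igraph object.
#' @param embedding an `sd_embedding` (or list with `positions`, `kappa`,
#'   `params`).
#' @param labels optional reference community labels.
#' @param n_pairs greedy-routing pair budget.
#' @param fraction concentration neighbourhood fraction.
#' @param seed optional RNG seed.
#' @return One-row data.frame: dimension, p_s, stretch, c_C, Q, NMI.
#' @export
evaluate_embedding <- function(graph, embedding, labels = NULL,
                               n_pairs = 10000L, fraction = 0.1,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  coords <- to_hyperbolic(embedding)
  gr <- greedy_routing(graph, coords, n_pairs = n_pairs)
  cc <- q <- nmi <- NA_real_
  if (!is.null(labels)) {
    cc <- community_concentration(embedding$positions, labels, fraction)$c_C
    det <- detect_geometric_communities(embedding$positions,
                                        length(unique(labels)))
    pq <- partition_quality(graph, det, labels)
    q <- pq$Q; nmi <- pq$NMI
  }
  data.frame(dimension = embedding$params$D, p_s = gr$success_rate,
             stretch = gr$mean_stretch, c_C = cc, Q = q, NMI = nmi)
}

#' Embed a network over a range of dimensions and pick the consensus
#'
#' Runs the full embedding pipeline at each candidate dimension, evaluates
#' each map, and returns the consensus dimension across the metrics.
#'
#' @param graph igraph object (or edge-list path).
#' @param dims candidate dimensions (>= 2 values).
#' @param labels optional reference community labels.
#' @param config an [sd_config].
#' @param n_pairs greedy-routing pair budget per dimension.
#' @param seed optional RNG seed.
#' @return List with the per-dimension `report`, the `consensus` result and
#'   the `embeddings`.
#' @export
select_dimension <- function(graph, dims, labels = NULL,
                             config = sd_config(), n_pairs = 10000L,
                             seed = NULL) {
  if (is.character(graph)) graph <- read_edgelist(graph)
  stopifnot(length(dims) >= 2L)
  if (!is.null(seed)) set.seed(seed)
  embeddings <- list()
  rows <- list()
  for (D in dims) {
    emb <- embed_network(graph, D = D, config = config)
    embeddings[[as.character(D)]] <- emb
    rows[[as.character(D)]] <- evaluate_embedding(graph, emb, labels,
                                                  n_pairs = n_pairs)
  }
  report <- do.call(rbind, rows)
  row.names(report) <- NULL
  keep <- c("dimension",
            names(report)[vapply(report, function(v) !all(is.na(v)),
                                 logical(1))])
  report <- report[, unique(keep)]
  list(report = report, consensus = consensus_dimension(report),
       embeddings = embeddings)
}
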