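make_coords <- function(positions, kappa, params) {
  to_hyperbolic(list(positions = positions, kappa = kappa, params = params))
}

test_that("greedy routing is perfect on a complete graph and a true-circle map", {
  p <- sd_params(12, 1, beta = 3, mean_degree = 11)
  full <- igraph::make_full_graph(12)
  ang <- 2 * pi * (0:11) / 12
  coords <- make_coords(cbind(cos(ang), sin(ang)), rep(11, 12), p)
  gr <- greedy_routing(full, coords, n_pairs = 200L)
  expect_equal(gr$success_rate, 1)
  expect_equal(gr$mean_stretch, 1)
  # cycle C8 with exact D = 1 model coordinates: all 56 ordered pairs succeed
  # along shortest arcs
  p8 <- sd_params(8, 1, beta = 3, mean_degree = 2)
  ang8 <- 2 * pi * (0:7) / 8
  ring <- igraph::make_ring(8)
  c8 <- make_coords(cbind(cos(ang8), sin(ang8)), rep(2, 8), p8)
  gr8 <- greedy_routing(ring, c8, n_pairs = 56L)
  expect_equal(gr8$n_pairs, 56L)
  expect_equal(gr8$success_rate, 1)
  expect_equal(gr8$mean_stretch, 1)
})

test_that("greedy routing fails cleanly on adversarial coordinates", {
  # a path routed with coordinates pointing the wrong way cannot loop forever
  g <- igraph::make_ring(6, circular = FALSE)
  p <- sd_params(6, 1, beta = 3, mean_degree = 2)
  set.seed(61)
  coords <- make_coords(sample_uniform_sphere(6, 1), rep(2, 6), p)
  gr <- greedy_routing(g, coords, n_pairs = 30L)
  expect_true(gr$success_rate >= 0 && gr$success_rate <= 1)
})

test_that("community concentration matches exact and null constructions", {
  set.seed(62)
  # two antipodal caps of 50: every top-10% neighbourhood is co-communal,
  # rho = N / N_l = 2 exactly for every node
  cp1 <- generate_community_positions(100, 2, 2, cap_angle = 0.4)
  cc <- community_concentration(cp1$positions, cp1$labels, fraction = 0.1)
  expect_equal(cc$c_C, 2, tolerance = 1e-12)
  # fraction -> 1 forces rho -> 1 (self excluded, hence tolerance 1/N)
  cc1 <- community_concentration(cp1$positions, cp1$labels, fraction = 1)
  expect_equal(cc1$c_C, 1, tolerance = 2 / 100)
  # random labels carry no geometric signal: the size-normalized enrichment
  # (n_il / n_g)(N / N_l) averages to 1 (the raw own-community fraction
  # averages to the 1/N_C baseline reported alongside)
  pos <- sample_uniform_sphere(2000, 2)
  lab <- sample(1:4, 2000, TRUE)
  ccr <- community_concentration(pos, lab, fraction = 0.1)
  expect_lt(abs(ccr$c_C - 1), 0.05)
  expect_equal(ccr$rho_random, 0.25)
  # invariant under global orthogonal transforms
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  ccq <- community_concentration(pos %*% Q, lab, fraction = 0.1)
  expect_equal(ccq$c_C, ccr$c_C, tolerance = 1e-12)
})

test_that("Procrustes alignment recovers planted orthogonal transforms", {
  set.seed(63)
  X <- sample_uniform_sphere(500, 2)
  al0 <- align_to_reference(X, X)
  expect_equal(al0$per_axis_r, rep(1, 3), tolerance = 1e-12)
  expect_lt(al0$mean_angle, 1e-7)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  al <- align_to_reference(X %*% Q, X)
  expect_equal(al$per_axis_r, rep(1, 3), tolerance = 1e-10)
  expect_lt(al$mean_angle, 1e-6) # acos loses ~sqrt(eps) near perfect overlap
  # residual invariant to a second orthogonal transform of either argument
  Q2 <- qr.Q(qr(matrix(rnorm(9), 3)))
  set.seed(64)
  Y <- sample_uniform_sphere(500, 2)
  expect_equal(align_to_reference(X %*% Q2, Y)$mean_angle,
               align_to_reference(X, Y)$mean_angle, tolerance = 1e-10)
  # unrelated clouds have no axis correlation
  expect_true(all(abs(align_to_reference(
    sample_uniform_sphere(1000, 2), sample_uniform_sphere(1000, 2)
  )$per_axis_r) < 0.1))
  expect_error(align_to_reference(X, X[, 1:2]), "dimensions")
})

test_that("empirical connection curve tracks the gravity law on a fixture", {
  set.seed(65)
  net <- lcc_network(N = 600, D = 2, beta = 4, gamma = 2.6, mean_degree = 8)
  cur <- empirical_connection_curve(net$graph, net$kappa, net$positions,
                                    net$params, n_bins = 18)
  # monotone non-increasing trend (allow binomial noise via isotonic check)
  big <- cur[cur$n_pairs >= 100, ]
  iso <- stats::isoreg(seq_len(nrow(big)), rev(big$fraction))
  expect_gt(cor(iso$yf, rev(big$fraction)), 0.97)
  # populated bins sit within 3 binomial sigmas of the theory
  dev <- abs(big$fraction - big$theory) /
    sqrt(pmax(big$theory * (1 - big$theory) / big$n_pairs, 1e-12))
  expect_gt(mean(dev < 3), 0.9)
  # the bin nearest chi = 1 is close to 1/2
  b1 <- big[which.min(abs(log(big$chi))), ]
  expect_lt(abs(b1$fraction - 0.5),
            3 * sqrt(0.25 / b1$n_pairs) + abs(b1$theory - 0.5) + 0.05)
})

test_that("geometric clustering recovers planted caps", {
  set.seed(66)
  cp <- generate_community_positions(200, 2, 2, cap_angle = 0.4)
  lab <- detect_geometric_communities(cp$positions, 2)
  expect_equal(partition_quality(igraph::make_full_graph(200), lab,
                                 cp$labels)$NMI, 1)
  # S^1 4-cap fixture on true coordinates
  cp4 <- generate_community_positions(400, 1, 4, cap_angle = 0.7)
  lab4 <- detect_geometric_communities(cp4$positions, 4)
  g4 <- igraph::make_full_graph(400)
  expect_gt(partition_quality(g4, lab4, cp4$labels)$NMI, 0.9)
  # degenerate cut into singletons
  expect_equal(sort(unique(detect_geometric_communities(cp$positions, 200))),
               1:200)
  expect_error(detect_geometric_communities(cp$positions, 300), "exceeds")
})

test_that("partition quality reproduces closed-form modularity and null Q", {
  # two disjoint triangles split by component: Q = 1/2
  tri2 <- igraph::make_ring(3) + igraph::make_ring(3)
  q <- partition_quality(tri2, c(1, 1, 1, 2, 2, 2), c(1, 1, 1, 2, 2, 2))
  expect_equal(q$Q, 0.5, tolerance = 1e-12)
  expect_equal(q$NMI, 1)
  # random labels on an ER graph: modularity indistinguishable from zero at
  # the seed-to-seed spread (its mean carries a small negative O(1/N) bias)
  set.seed(67)
  qs <- vapply(1:50, function(s) {
    g <- igraph::sample_gnp(60, 0.15)
    partition_quality(g, sample(1:3, 60, TRUE))$Q
  }, numeric(1))
  expect_lt(abs(mean(qs)), 3 * sd(qs))
  # single-community reference: NMI reported as 0 with warning
  expect_warning(
    out <- partition_quality(tri2, c(1, 1, 1, 2, 2, 2), rep(1, 6)),
    "single-community")
  expect_equal(out$NMI, 0)
})

test_that("consensus dimension takes the modal per-metric optimum", {
  rep1 <- data.frame(dimension = 1:3,
                     p_s = c(0.5, 0.9, 0.7),
                     c_C = c(1.2, 2.5, 2.0),
                     stretch = c(1.4, 1.1, 1.2))
  out <- consensus_dimension(rep1)
  expect_equal(out$dimension, 2)
  expect_false(out$unresolved)
  expect_equal(unname(out$per_metric["stretch"]), 2) # minimized metric
  rep2 <- data.frame(dimension = 1:2, p_s = c(0.9, 0.2), c_C = c(0.5, 2))
  out2 <- consensus_dimension(rep2)
  expect_true(out2$unresolved)
  expect_true(is.na(out2$dimension))
})
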