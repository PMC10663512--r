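test_that("hidden-degree sampler respects cutoffs and closed forms", {
  set.seed(3)
  hd <- sample_hidden_degrees(2000, gamma = 2.5, mean_degree = 8)
  expect_equal(hd$kappa0, 8 / 3, tolerance = 1e-12)
  expect_equal(hd$kappa_c, (8 / 3) * 2000^(1 / 1.5), tolerance = 1e-12)
  expect_true(all(hd$kappa >= hd$kappa0 - 1e-12))
  expect_true(all(hd$kappa <= hd$kappa_c + 1e-12))
  expect_error(sample_hidden_degrees(100, gamma = 2, mean_degree = 8), "gamma")
  expect_warning(sample_hidden_degrees(100, gamma = 3.2, mean_degree = 8),
                 "regime")
})

test_that("generated adjacency is simple, symmetric and label-consistent", {
  set.seed(4)
  net <- generate_sd_network(N = 300, D = 2, beta = 3.5, gamma = 2.6,
                             mean_degree = 8)
  A <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  expect_true(all(diag(A) == 0))
  expect_identical(A, t(A))
  expect_true(all(A %in% c(0, 1)))
  expect_identical(igraph::degree(net$graph), rowSums(A))
  expect_unit_rows(net$positions)
})

test_that("infinite-beta limit is the deterministic threshold graph", {
  set.seed(5)
  N <- 120
  pos <- sample_uniform_sphere(N, 2)
  kap <- rep(5, N)
  net <- generate_sd_network(N = N, D = 2, beta = 1e8, gamma = 2.5,
                             mean_degree = 5, kappa = kap, positions = pos)
  dth <- acos(pmin(1, pmax(-1, tcrossprod(pos))))
  chi <- net$params$R * dth / (net$params$mu * outer(kap, kap))^(1 / 2)
  A <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE)
  expect_identical(unname(A[upper.tri(A)]),
                   as.numeric(chi[upper.tri(chi)] < 1))
})

test_that("realized degrees follow the model's finite-size expectation", {
  # the structural calibration check: frequencies of k_i track the Eq-13-style
  # position-marginal expectation computed from the generated kappas
  set.seed(6)
  deg <- numeric(0); kbar <- numeric(0)
  for (s in 1:5) {
    net <- generate_sd_network(N = 600, D = 2, beta = 3.5, gamma = 2.6,
                               mean_degree = 8)
    p <- net$params
    tab <- sdembed:::make_f0_table(2, p$beta,
                                   (p$mu * min(net$kappa)^2)^(1 / 2) / p$R,
                                   (p$mu * max(net$kappa)^2)^(1 / 2) / p$R)
    Z <- (p$mu * outer(net$kappa, net$kappa))^(1 / 2) / p$R
    F0 <- tab$eval(Z)
    kb <- sdembed:::degree_prefactor(2) * (rowSums(F0) - diag(F0))
    deg <- c(deg, igraph::degree(net$graph))
    kbar <- c(kbar, kb)
  }
  # pooled realized degrees regress on their model expectation with slope 1
  sl <- coef(lm(deg ~ kbar))[2]
  expect_lt(abs(sl - 1), 0.05)
  expect_lt(abs(mean(deg) - mean(kbar)), 3 * sd(deg - kbar) / sqrt(length(deg)))
})

test_that("connection frequency binned by chi matches the gravity law", {
  # expected edge counts are accumulated from the per-pair gravity-law
  # probabilities inside each bin (a bin-centre theory would add
  # discretization bias on log-wide bins)
  set.seed(8)
  for (D in 1:3) {
    brk <- exp(seq(log(0.05), log(20), length.out = 13))
    agg_n <- agg_e <- agg_p <- agg_v <- numeric(12)
    for (s in 1:3) {
      net <- generate_sd_network(N = 400, D = D, beta = D + 1.5, gamma = 2.6,
                                 mean_degree = 8)
      A <- igraph::as_adjacency_matrix(net$graph, sparse = FALSE) > 0
      n <- nrow(net$positions)
      dth <- matrix(acos(pmin(1, pmax(-1, tcrossprod(net$positions)))), n, n)
      chi <- net$params$R * dth /
        (net$params$mu * outer(net$kappa, net$kappa))^(1 / D)
      pth <- 1 / (1 + chi^(D + 1.5))
      ut <- upper.tri(chi)
      bin <- cut(chi[ut], brk, labels = FALSE)
      ok <- !is.na(bin)
      b <- bin[ok]
      agg_n <- agg_n + tabulate(b, 12)
      agg_e <- agg_e + tabulate(b[A[ut][ok]], 12)
      pv <- pth[ut][ok]
      agg_p <- agg_p + vapply(1:12, function(k) sum(pv[b == k]), numeric(1))
      agg_v <- agg_v + vapply(1:12, function(k)
        sum(pv[b == k] * (1 - pv[b == k])), numeric(1))
    }
    sel <- agg_n >= 50 & agg_v > 0
    dev <- abs(agg_e[sel] - agg_p[sel]) / sqrt(agg_v[sel])
    # within 3 sigma in the vast majority of populated bins
    expect_gt(mean(dev < 3), 0.9)
  }
})

test_that("community apices are evenly spread and caps contain their nodes", {
  # D = 1, 4 caps: apices at multiples of pi/2
  ap <- sdembed:::even_apices(4, 1)
  seps <- sort(round(as.vector(acos(pmin(1, pmax(-1, tcrossprod(ap))))), 10))
  expect_equal(unique(seps), c(0, pi / 2, pi), tolerance = 1e-9)
  # D = 2, 6 caps: octahedron, inter-apex separations pi/2 or pi
  ap6 <- sdembed:::even_apices(6, 2)
  s6 <- matrix(acos(pmin(1, pmax(-1, tcrossprod(ap6)))), 6, 6)
  off <- s6[upper.tri(s6)]
  expect_true(all(abs(off - pi / 2) < 1e-9 | abs(off - pi) < 1e-9))
  # every node lies within the cap polar angle of its apex; sizes balanced
  set.seed(9)
  cp <- generate_community_positions(403, 2, 6, cap_angle = 0.7)
  expect_unit_rows(cp$positions)
  seps <- acos(pmin(1, pmax(-1,
    rowSums(cp$positions * cp$apices[cp$labels, ]))))
  expect_true(all(seps <= 0.7 + 1e-9))
  expect_lte(diff(range(tabulate(cp$labels))), 1)
})

test_that("cap communities are non-overlapping regions below pi/4", {
  set.seed(10)
  net <- generate_sd_network(N = 400, D = 2, beta = 4, gamma = 2.7,
                             mean_degree = 8, n_communities = 6,
                             cap_angle = 0.7)
  ap <- sdembed:::even_apices(6, 2)
  # every node is strictly closer to its own apex than to any other
  d2ap <- matrix(acos(pmin(1, pmax(-1, tcrossprod(net$positions, ap)))),
                 nrow(net$positions), 6)
  expect_identical(unname(apply(d2ap, 1, which.min)), as.integer(net$labels))
})

test_that("repulsion apices keep a healthy minimum separation", {
  set.seed(12)
  for (spec in list(c(5, 2), c(7, 2), c(4, 3))) {
    ap <- sdembed:::even_apices(spec[1], spec[2])
    s <- matrix(acos(pmin(1, pmax(-1, tcrossprod(ap)))), spec[1], spec[1])
    expect_gt(min(s[upper.tri(s)]), 0.7) # > 2 * default cap angle / 2
  }
})
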