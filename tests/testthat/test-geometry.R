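test_that("sphere radius matches the unit-density closed form", {
  expect_equal(sphere_radius(100, 1), 100 / (2 * pi), tolerance = 1e-12)
  expect_equal(sphere_radius(400, 2), sqrt(400 / (4 * pi)), tolerance = 1e-12)
  expect_equal(sphere_radius(1000, 3), (1000 / (2 * pi^2))^(1 / 3),
               tolerance = 1e-12)
  # surface measure of the D-sphere at this radius equals N
  surf <- function(R, D) 2 * pi^((D + 1) / 2) / gamma((D + 1) / 2) * R^D
  for (D in 1:4) expect_equal(surf(sphere_radius(777, D), D), 777,
                              tolerance = 1e-10)
  expect_error(sphere_radius(1, 1), "N")
  expect_error(sphere_radius(10.5, 1), "N")
  expect_error(sphere_radius(10, 0), "D")
})

test_that("mu closed form reduces correctly and rejects beta <= D", {
  expect_equal(compute_mu(2, 1, 10), 1 / (10 * pi), tolerance = 1e-12)
  # D = 1 reduction beta sin(pi/beta) / (2 pi <k>)
  expect_equal(compute_mu(3.5, 1, 7), 3.5 * sin(pi / 3.5) / (2 * pi * 7),
               tolerance = 1e-12)
  # beta -> D+ drives mu -> 0
  expect_lt(compute_mu(2 + 1e-9, 2, 10), 1e-9)
  expect_error(compute_mu(2, 2, 10), "beta")
  expect_error(compute_mu(1.5, 2, 10), "beta")
})

test_that("angular distance handles the canonical configurations", {
  v <- c(1, 0, 0)
  expect_equal(angular_distance(v, v), 0)
  expect_equal(angular_distance(v, -v), pi)
  expect_equal(angular_distance(v, c(0, 1, 0)), pi / 2)
  expect_equal(angular_distance(c(2, 0), c(1, 1)), pi / 4, tolerance = 1e-12)
  expect_error(angular_distance(v, c(0, 0, 0)), "zero")
  # symmetric and clipped against floating-point overshoot
  set.seed(1)
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(4)
    expect_identical(angular_distance(a, b), angular_distance(b, a))
  }
})

test_that("gravity-law connection probability behaves per the model", {
  p <- sd_params(N = 100, D = 2, beta = 3, mean_degree = 10)
  # chi = 1 gives p = 1/2 for any beta
  for (beta in c(2.5, 5, 20)) {
    pp <- sd_params(N = 100, D = 2, beta = beta, mean_degree = 10)
    dth <- (pp$mu * 4 * 9)^(1 / 2) / pp$R # makes chi exactly 1 for kappas 4, 9
    out <- connection_probability(4, 9, dth, pp)
    expect_equal(out$chi, 1, tolerance = 1e-12)
    expect_equal(out$p, 0.5, tolerance = 1e-12)
  }
  # zero separation connects with probability one, exactly
  expect_identical(connection_probability(2, 3, 0, p)$p, 1)
  # direct evaluation: D=1, beta=3, mu k k' = 1, R dtheta = 2 -> p = 1/9
  p1 <- sd_params(N = 100, D = 1, beta = 3, mean_degree = 10, mu = 1)
  out <- connection_probability(1, 1, 2 / p1$R, p1)
  expect_equal(out$chi, 2, tolerance = 1e-12)
  expect_equal(out$p, 1 / 9, tolerance = 1e-12)
})

test_that("connection probability is monotone in separation and in kappas", {
  set.seed(42)
  for (D in 1:3) {
    pp <- sd_params(N = 500, D = D, beta = D + 1.5, mean_degree = 8)
    for (rep in 1:20) {
      ki <- runif(1, 1, 50); kj <- runif(1, 1, 50)
      dth <- sort(runif(8, 0, pi))
      pv <- connection_probability(ki, kj, dth, pp)$p
      expect_true(all(diff(pv) <= 1e-15))
      kk <- sort(runif(8, 1, 100))
      pv2 <- connection_probability(kk, kj, runif(1, 0, pi), pp)$p
      expect_true(all(diff(pv2) >= -1e-15))
    }
  }
})

test_that("uniform sphere samples are unit norm with the right separation law", {
  set.seed(7)
  X <- sample_uniform_sphere(3000, 2)
  expect_unit_rows(X)
  # mean pairwise separation is pi/2 by symmetry of the separation density
  i <- sample.int(3000, 20000, replace = TRUE)
  j <- sample.int(3000, 20000, replace = TRUE)
  ok <- i != j
  dth <- acos(pmin(1, pmax(-1, rowSums(X[i[ok], ] * X[j[ok], ]))))
  se <- sd(dth) / sqrt(sum(ok))
  expect_lt(abs(mean(dth) - pi / 2), 3 * se)
  # D = 1: separations are uniform on [0, pi] (chi-square GOF at 1%)
  Y <- sample_uniform_sphere(4000, 1)
  i <- sample.int(4000, 20000, replace = TRUE)
  j <- sample.int(4000, 20000, replace = TRUE)
  ok <- i != j
  d1 <- acos(pmin(1, pmax(-1, rowSums(Y[i[ok], ] * Y[j[ok], ]))))
  cnt <- tabulate(cut(d1, seq(0, pi, length.out = 21), labels = FALSE), 20)
  gof <- suppressWarnings(chisq.test(cnt))
  expect_gt(gof$p.value, 0.01)
})

test_that("sample_at_separation hits the requested separation exactly", {
  set.seed(11)
  v <- sample_uniform_sphere(1, 2)[1, ]
  expect_equal(sample_at_separation(v, 0), v)
  expect_equal(sample_at_separation(v, pi), -v)
  for (rep in 1:200) {
    d <- runif(1, 0, pi)
    w <- sample_at_separation(v, d)
    expect_lt(abs(angular_distance(v, w) - d), 1e-10)
  }
  # azimuth is uniform in the plane orthogonal to v (KS at 1%)
  v <- c(0, 0, 1)
  W <- t(vapply(1:2000, function(i) sample_at_separation(v, 1.0),
                numeric(3)))
  az <- atan2(W[, 2], W[, 1])
  ks <- suppressWarnings(stats::ks.test(az, "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
})

test_that("separation density matches its closed forms and normalization", {
  expect_equal(angular_distance_pdf(0.3, 1), 1 / pi, tolerance = 1e-12)
  expect_equal(angular_distance_pdf(pi / 2, 2), 1 / 2, tolerance = 1e-12)
  for (D in 1:5) {
    nrm <- integrate(angular_distance_pdf, 0, pi, D = D, rel.tol = 1e-10)$value
    expect_equal(nrm, 1, tolerance = 1e-8)
  }
})

test_that("separation density matches sampled pairwise separations", {
  set.seed(19)
  for (D in 1:3) {
    X <- sample_uniform_sphere(2500, D)
    i <- sample.int(2500, 10000, replace = TRUE)
    j <- sample.int(2500, 10000, replace = TRUE)
    ok <- i != j
    dth <- acos(pmin(1, pmax(-1, rowSums(X[i[ok], , drop = FALSE] *
                                         X[j[ok], , drop = FALSE]))))
    brk <- seq(0, pi, length.out = 16)
    obs <- tabulate(cut(dth, brk, labels = FALSE), 15)
    pr <- vapply(seq_len(15), function(b)
      integrate(angular_distance_pdf, brk[b], brk[b + 1], D = D)$value,
      numeric(1))
    gof <- suppressWarnings(chisq.test(obs, p = pr / sum(pr)))
    expect_gt(gof$p.value, 0.01)
  }
})
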