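# Numerical kernels shared by the inference stages.
#
# Every expectation of the S^D model used here reduces to integrals of
#   sin^(D-1)(theta) / (1 + (theta/z)^beta)        over [0, pi],
# with z = (mu kappa_i kappa_j)^(1/D) / R. The integrand has a shoulder at
# theta ~ z, which is passed to the adaptive quadrature as a breakpoint.

sd_kernel_integrand <- function(theta, z, D, beta) {
  sin(theta)^(D - 1) / (1 + (theta / z)^beta)
}

# Integrate f over [0, pi] with breakpoints around the shoulder at z.
integrate_with_shoulder <- function(f, z, ..., rel.tol = 1e-10, abs.tol = 1e-12) {
  brk <- sort(unique(pmin(pi, pmax(0, c(0, z / 2, z, 2 * z, pi)))))
  brk <- brk[!duplicated(signif(brk, 12))]
  total <- 0
  for (i in seq_len(length(brk) - 1L)) {
    r <- tryCatch(
      integrate(f, brk[i], brk[i + 1L], ..., rel.tol = rel.tol,
                abs.tol = abs.tol, stop.on.error = FALSE),
      error = function(e) NULL)
    if (is.null(r) || !is.finite(r$value))
      stop("quadrature failed on [", signif(brk[i], 6), ", ",
           signif(brk[i + 1L], 6), "] (z = ", signif(z, 6), ")", call. = FALSE)
    total <- total + r$value
  }
  total
}

# F0(z) = int_0^pi sin^(D-1) / (1 + (theta/z)^beta); F1 carries an extra theta.
sd_kernel_f0 <- function(z, D, beta) {
  vapply(z, function(zz)
    integrate_with_shoulder(function(th) sd_kernel_integrand(th, zz, D, beta), zz),
    numeric(1))
}

sd_kernel_f1 <- function(z, D, beta) {
  vapply(z, function(zz)
    integrate_with_shoulder(function(th) th * sd_kernel_integrand(th, zz, D, beta), zz),
    numeric(1))
}

# Log-log spline table of F0 over a z range wide enough for a whole
# hidden-degree fit; evaluating the table is then a vectorized lookup.
make_f0_table <- function(D, beta, z_lo, z_hi, n_grid = 200L) {
  z_lo <- max(z_lo, 1e-9)
  z_hi <- max(min(z_hi, 1e7), z_lo * 10)
  lz <- seq(log(z_lo), log(z_hi), length.out = n_grid)
  f0 <- sd_kernel_f0(exp(lz), D, beta)
  # adaptive quadrature may return (tiny) non-positive values where the
  # integral underflows; floor them so the log-log spline stays finite
  f0 <- pmax(f0, 1e-300)
  if (any(!is.finite(f0)))
    stop("expected-degree kernel table failed (non-finite quadrature)",
         call. = FALSE)
  sf <- stats::splinefun(lz, log(f0), method = "monoH.FC")
  list(
    eval = function(z) {
      lq <- pmin(pmax(log(z), lz[1L]), lz[n_grid])
      out <- exp(sf(lq))
      dim(out) <- dim(z)
      out
    },
    z_lo = z_lo, z_hi = z_hi)
}

# Inverse-CDF sampler of the separation between two *connected* nodes,
# rho(dtheta | a = 1) proportional to sin^(D-1)(dtheta)/(1+(dtheta/z)^beta),
# tabulated on a grid refined around the shoulder.
connected_separation_quantile <- function(z, D, beta, n_grid = 2048L) {
  lo <- max(min(z, pi) * 1e-4, 1e-10)
  th <- sort(unique(c(
    exp(seq(log(lo), log(pi), length.out = n_grid - 512L)),
    seq(0, pi, length.out = 512L))))
  dens <- sd_kernel_integrand(th, z, D, beta)
  dth <- diff(th)
  cdf <- c(0, cumsum((dens[-1L] + dens[-length(dens)]) / 2 * dth))
  cdf <- cdf / cdf[length(cdf)]
  keep <- !duplicated(cdf)
  cdf <- cdf[keep]; th <- th[keep]
  function(u) approx(cdf, th, xout = u, rule = 2, ties = "ordered")$y
}

# Small per-call cache of quantile samplers keyed by a degree-class pair.
separation_sampler_cache <- function(D, beta, mu, R) {
  cache <- new.env(parent = emptyenv())
  function(kappa_a, kappa_b, u) {
    key <- paste0(signif(kappa_a * kappa_b, 12))
    qf <- cache[[key]]
    if (is.null(qf)) {
      z <- (mu * kappa_a * kappa_b)^(1 / D) / R
      qf <- connected_separation_quantile(z, D, beta)
      cache[[key]] <- qf
    }
    qf(u)
  }
}
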