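# Box-Cox family numerics: densities, cdf/quantile consistency, reductions.

test_that("BCPE with nu=1, tau=2 reduces to the normal distribution", {
  # Normal(10, 1): sigma*mu = 1
  expect_equal(dbcx(10, "BCPE", mu = 10, sigma = 0.1, nu = 1, tau = 2),
               dnorm(10, 10, 1), tolerance = 1e-6)
  expect_equal(qbcx(0.975, "BCPE", mu = 10, sigma = 0.1, nu = 1, tau = 2),
               qnorm(0.975, 10, 1), tolerance = 1e-6)
  # log-likelihood reduction on simulated normal data
  set.seed(1)
  y <- rnorm(50, 10, 1)
  expect_equal(bcx_loglik(y, "BCPE", 10, 0.1, 1, 2),
               sum(dnorm(y, 10, 1, log = TRUE)), tolerance = 1e-7)
})

test_that("BCPE density matches an independently coded formula", {
  got <- dbcx(8, "BCPE", mu = 10, sigma = 0.15, nu = 0.5, tau = 3)
  want <- oracle_bcpe_pdf(8, 10, 0.15, 0.5, 3)
  expect_equal(got, want, tolerance = 1e-7)
  # and the oracle itself carries unit mass
  mass <- integrate(function(y) oracle_bcpe_pdf(y, 10, 0.15, 0.5, 3),
                    0, Inf, rel.tol = 1e-9)$value
  expect_equal(mass, 1, tolerance = 1e-6)
})

test_that("densities integrate to one across the parameter grid", {
  grid <- paramset_grid()
  mass <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    f <- function(y) dbcx(y, g$family, g$mu, g$sigma, g$nu, g$tau)
    # split at the median so the density peak sits at an endpoint
    integrate(f, 0, g$mu, rel.tol = 1e-9)$value +
      integrate(f, g$mu, Inf, rel.tol = 1e-9)$value
  }, numeric(1))
  expect_true(all(abs(mass - 1) < 1e-6))
})

test_that("BCPE with tau=2 equals BCCG pointwise", {
  grid <- paramset_grid(12)
  y <- c(0.5, 2, 5, 8, 12, 19)
  q <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_equal(dbcx(y, "BCPE", g$mu, g$sigma, g$nu, tau = 2),
                 dbcx(y, "BCCG", g$mu, g$sigma, g$nu), tolerance = 1e-10)
    expect_equal(pbcx(y, "BCPE", g$mu, g$sigma, g$nu, tau = 2),
                 pbcx(y, "BCCG", g$mu, g$sigma, g$nu), tolerance = 1e-10)
    expect_equal(qbcx(q, "BCPE", g$mu, g$sigma, g$nu, tau = 2),
                 qbcx(q, "BCCG", g$mu, g$sigma, g$nu), tolerance = 1e-10)
  }
})

test_that("BCT approaches BCCG as the degrees of freedom grow", {
  y <- seq(2, 18, by = 0.5)
  expect_equal(pbcx(y, "BCT", 10, 0.2, 0.8, tau = 1e6),
               pbcx(y, "BCCG", 10, 0.2, 0.8), tolerance = 1e-4)
})

test_that("cdf and quantile are exact inverses across the grid", {
  grid <- paramset_grid()
  q <- c(0.01, 0.05, 0.25, 0.5, 0.75, 0.95, 0.99)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    yq <- qbcx(q, g$family, g$mu, g$sigma, g$nu, g$tau)
    expect_equal(pbcx(yq, g$family, g$mu, g$sigma, g$nu, g$tau), q,
                 tolerance = 1e-8)
    yy <- g$mu * c(0.6, 0.9, 1, 1.1, 1.5)
    u <- pbcx(yy, g$family, g$mu, g$sigma, g$nu, g$tau)
    ok <- u > 1e-10 & u < 1 - 1e-10
    expect_equal(qbcx(u[ok], g$family, g$mu, g$sigma, g$nu, g$tau), yy[ok],
                 tolerance = 1e-6)
  }
})

test_that("the median is mu up to the truncation convention", {
  # negligible truncation: exact to near machine precision
  expect_equal(qbcx(0.5, "BCPE", 10, 0.1, 1, 2), 10, tolerance = 1e-12)
  # t tails make the truncation correction larger but still tiny
  expect_equal(qbcx(0.5, "BCT", 8, 0.2, 0.5, 5), 8, tolerance = 1e-4)
  expect_equal(pbcx(10, "BCCG", 10, 0.15, -0.5), 0.5, tolerance = 1e-10)
  # quantiles are strictly increasing in the level
  grid <- paramset_grid(20)
  q <- c(0.05, 0.25, 0.5, 0.75, 0.95)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    yq <- qbcx(q, g$family, g$mu, g$sigma, g$nu, g$tau)
    expect_true(all(diff(yq) > 0))
  }
})

test_that("nu branches join continuously at nu = 0", {
  y <- c(4, 8, 12)
  for (fam in bcx_families) {
    expect_equal(dbcx(y, fam, 10, 0.2, 1e-6, 3),
                 dbcx(y, fam, 10, 0.2, 0, 3), tolerance = 1e-4)
    expect_equal(pbcx(y, fam, 10, 0.2, -1e-6, 3),
                 pbcx(y, fam, 10, 0.2, 0, 3), tolerance = 1e-4)
  }
})

test_that("random draws are reproducible and match the quantile function", {
  set.seed(99)
  x1 <- rbcx(1e5, "BCPE", 10, 0.1, 1, 2)
  set.seed(99)
  x2 <- rbcx(1e5, "BCPE", 10, 0.1, 1, 2)
  expect_identical(x1, x2)
  # normal reduction: sample mean near 10 (sd 1, n = 1e5 -> SE ~ 0.003)
  expect_lt(abs(mean(x1) - 10), 0.02)
  # empirical 5th percentile vs quantile(): |diff| < 3 SE of the order stat
  q05 <- qbcx(0.05, "BCPE", 10, 0.1, 1, 2)
  se <- sqrt(0.05 * 0.95 / 1e5) / dbcx(q05, "BCPE", 10, 0.1, 1, 2)
  expect_lt(abs(quantile(x1, 0.05, names = FALSE) - q05), 3 * se)
})

test_that("loglik is additive and rejects nonpositive responses", {
  set.seed(3)
  y <- runif(50, 2, 18)
  mu <- runif(50, 8, 12); sigma <- runif(50, 0.1, 0.3)
  nu <- runif(50, -1, 2); tau <- runif(50, 2, 6)
  expect_equal(bcx_loglik(y, "BCT", mu, sigma, nu, tau),
               sum(vapply(seq_along(y), function(i)
                 dbcx(y[i], "BCT", mu[i], sigma[i], nu[i], tau[i], log = TRUE),
                 numeric(1))), tolerance = 1e-10)
  expect_equal(bcx_loglik(5, "BCPE", 10, 0.2, 1, 3),
               dbcx(5, "BCPE", 10, 0.2, 1, 3, log = TRUE))
  expect_error(bcx_loglik(c(5, -1, 3), "BCPE", 10, 0.2, 1, 3), "index 2")
})

test_that("invalid arguments raise domain errors", {
  expect_error(dbcx(-1, "BCPE", 10, 0.2, 1, 3), "y must be")
  expect_error(dbcx(5, "BCPE", -10, 0.2, 1, 3), "mu")
  expect_error(dbcx(5, "BCPE", 10, 0, 1, 3), "sigma")
  expect_error(dbcx(5, "BCT", 10, 0.2, 1, -3), "tau")
  expect_error(qbcx(1.2, "BCPE", 10, 0.2, 1, 3), "strictly inside")
  expect_error(dbcx(5, "GAMMA", 10, 0.2, 1, 3), "unknown family")
  # BCCG ignores tau entirely
  expect_equal(dbcx(5, "BCCG", 10, 0.2, 1, tau = -99),
               dbcx(5, "BCCG", 10, 0.2, 1))
})
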