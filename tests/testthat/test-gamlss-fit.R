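# Backfitting engine: oracle agreement, recovery, determinism, invariants.

make_cohort <- function(n, family, mu, sigma, nu, tau, seed) {
  set.seed(seed)
  age <- runif(n, 12, 36)
  list(age = age, y = rbcx(n, family, mu, sigma, nu, tau))
}

direct_ml <- function(y, family, start) {
  nll <- function(p) {
    v <- tryCatch(
      -bcx_loglik(y, family, exp(p[1]), exp(p[2]), p[3],
                  if (family == "BCCG") 2 else exp(p[4])),
      error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  o <- optim(start, nll, method = "BFGS",
             control = list(reltol = 1e-14, maxit = 2000))
  -o$value
}

test_that("intercept-only backfitting agrees with direct maximum likelihood", {
  tight <- bcx_control(tol = 1e-8, maxit = 3000)
  cases <- list(
    list(family = "BCCG", mu = 10, sigma = 0.2, nu = 1, tau = 2),
    list(family = "BCT", mu = 10, sigma = 0.15, nu = 0.8, tau = 6),
    list(family = "BCPE", mu = 10, sigma = 0.2, nu = 1.5, tau = 3))
  for (cs in cases) {
    for (seed in 1:2) {
      d <- make_cohort(800, cs$family, cs$mu, cs$sigma, cs$nu, cs$tau,
                       seed = 1000 + seed)
      m <- suppressWarnings(
        fit_bcx_gamlss(d$age, d$y, cs$family, df_mu = 1, df_sigma = 1,
                       control = tight))
      Lref <- direct_ml(d$y, cs$family,
                        c(log(cs$mu), log(cs$sigma), cs$nu, log(cs$tau)))
      expect_lt(abs(m$loglik - Lref), 1e-4,
                label = paste(cs$family, "seed", seed, "|L diff|"))
    }
  }
})

test_that("refitting identical data is deterministic", {
  d <- make_cohort(600, "BCPE", 9, 0.2, 1.2, 3, seed = 5)
  m1 <- fit_bcx_gamlss(d$age, d$y, "BCPE", df_mu = 4, df_sigma = 2)
  m2 <- fit_bcx_gamlss(d$age, d$y, "BCPE", df_mu = 4, df_sigma = 2)
  expect_equal(m1$loglik, m2$loglik, tolerance = 1e-10)
  expect_identical(m1$coefs, m2$coefs)
})

test_that("global deviance is non-increasing across outer cycles", {
  d <- make_cohort(1500, "BCT", 12, 0.25, 0.5, 5, seed = 8)
  m <- suppressWarnings(
    fit_bcx_gamlss(d$age, d$y, "BCT", df_mu = 5, df_sigma = 3))
  expect_true(all(diff(m$dev_path) <= 1e-8))
})

test_that("a smooth median curve is recovered from parametric truth", {
  set.seed(31)
  n <- 3000
  age <- runif(n, 12, 36)
  mu_true <- function(a) 10 + 4 * sin(a / 8)
  y <- rbcx(n, "BCPE", mu_true(age), 0.15, 1.3, 2.5)
  m <- suppressWarnings(
    fit_bcx_gamlss(age, y, "BCPE", df_mu = 6, df_sigma = 2))
  grid <- seq(12.5, 35.5, by = 0.5)
  rmse <- sqrt(mean((predict_params(m, grid)$mu - mu_true(grid))^2))
  expect_lt(rmse, 0.25)
  # fitted median curve stays within the response's convex hull
  muhat <- predict_params(m, age)$mu
  expect_true(all(muhat > min(y) & muhat < max(y)))
})

test_that("zero counts trigger the +0.5 offset and centiles remove it", {
  set.seed(12)
  n <- 400
  age <- runif(n, 12, 36)
  y <- pmax(round(rbcx(n, "BCCG", 3 + (age - 12) / 3, 0.4, 0.8)), 0)
  stopifnot(any(y == 0))
  m <- suppressWarnings(
    fit_bcx_gamlss(age, y, "BCCG", df_mu = 3, df_sigma = 1))
  expect_equal(m$offset, 0.5)
  ct <- centile_table(m, ages = 13:35)
  # reported values live on the original count scale
  expect_true(all(ct$rounded$p50 >= 0 & ct$rounded$p50 <= 20))
  expect_equal(ct$raw$p50 + 0.5,
               qbcx(0.5, "BCCG", predict_params(m, 13:35)$mu,
                    predict_params(m, 13:35)$sigma,
                    predict_params(m, 13:35)$nu), tolerance = 1e-9)
})

test_that("precondition violations are informative errors", {
  d <- make_cohort(100, "BCPE", 10, 0.2, 1, 2, seed = 2)
  expect_error(fit_bcx_gamlss(d$age[1:30], d$y[1:30]), "at least 50")
  expect_error(fit_bcx_gamlss(d$age + 60, d$y), "months")
  expect_error(fit_bcx_gamlss(d$age, rep(7, 100)), "degenerate")
  expect_error(fit_bcx_gamlss(d$age, d$y - 30), "nonnegative")
})

test_that("fitted models serialize to JSON and reload for prediction", {
  d <- make_cohort(600, "BCPE", 9, 0.2, 1.2, 3, seed = 44)
  m <- suppressWarnings(
    fit_bcx_gamlss(d$age, d$y, "BCPE", df_mu = 4, df_sigma = 2, xi = 0.75))
  path <- tempfile(fileext = ".json")
  write_bcx_model(m, path)
  m2 <- read_bcx_model(path)
  ages <- c(13, 20, 27, 34)
  expect_equal(predict_params(m2, ages), predict_params(m, ages),
               tolerance = 1e-10)
  expect_equal(m2$loglik, m$loglik, tolerance = 1e-12)
  expect_equal(gaic(m2, 3.3), gaic(m, 3.3), tolerance = 1e-10)
})

test_that("gaic is the penalized deviance and increases in b", {
  m <- structure(list(loglik = -100, edf_total = 5), class = "bcx_gamlss")
  expect_equal(gaic(m, 2), 210)
  expect_equal(gaic(m, log(1000)), -2 * -100 + log(1000) * 5)
  bs <- c(0.5, 1, 2, 4, 8)
  expect_true(all(diff(vapply(bs, function(b) gaic(m, b), numeric(1))) > 0))
  expect_error(gaic(m, 0), "positive")
  expect_error(gaic(m, -2), "positive")
})

test_that("family selection follows the smallest GAIC with a fixed tie-break", {
  # worked example: the reported criterion triple picks BCPE
  expect_identical(
    select_from_gaic(c(BCCG = 19345.32, BCT = 19345.68, BCPE = 19344.16)),
    "BCPE")
  expect_identical(select_from_gaic(c(BCT = 5, BCCG = 7, BCPE = 6)), "BCT")
  expect_message(
    out <- select_from_gaic(c(BCCG = 10, BCT = 10, BCPE = 10)), "tie")
  expect_identical(out, "BCPE")
  expect_message(out2 <- select_from_gaic(c(BCCG = 4, BCT = 4, BCPE = 9)),
                 "tie")
  expect_identical(out2, "BCCG")
})

test_that("select_family fits all candidates and returns the table", {
  d <- make_cohort(1200, "BCT", 10, 0.15, 1, 4, seed = 77)
  sf <- suppressWarnings(select_family(d$age, d$y, df_mu = 1, df_sigma = 1))
  expect_equal(nrow(sf$gaic_table), 3)
  expect_setequal(sf$gaic_table$family, c("BCCG", "BCT", "BCPE"))
  expect_identical(sf$family,
                   sf$gaic_table$family[which.min(sf$gaic_table$gaic)])
  expect_s3_class(sf$model, "bcx_gamlss")
})

test_that("smoothing search is exhaustive and returns the best grid point", {
  d <- make_cohort(800, "BCPE", 8, 0.2, 1, 2.5, seed = 13)
  # single-point grids return that point
  s1 <- suppressWarnings(
    select_smoothing(d$age, d$y, df_mu_grid = 4, df_sigma_grid = 2,
                     xi_grid = 1))
  expect_equal(c(s1$df_mu, s1$df_sigma, s1$xi), c(4, 2, 1))
  expect_equal(nrow(s1$table), 1)
  # table rows = product of grid sizes; winner has minimal GAIC
  s2 <- suppressWarnings(
    select_smoothing(d$age, d$y, df_mu_grid = c(3, 5), df_sigma_grid = 2,
                     xi_grid = c(0.75, 1)))
  expect_equal(nrow(s2$table), 4)
  ok <- s2$table$converged
  expect_equal(min(s2$table$gaic[ok]),
               s2$table$gaic[s2$table$df_mu == s2$df_mu &
                             s2$table$df_sigma == s2$df_sigma &
                             s2$table$xi == s2$xi])
})

test_that("strong median curvature drives the selected df_mu above 3", {
  hits <- 0
  for (seed in 1:3) {
    set.seed(400 + seed)
    age <- runif(1500, 12, 36)
    y <- rbcx(1500, "BCPE", 10 + 4 * sin((age - 12) / 4), 0.12, 1, 2)
    s <- suppressWarnings(
      select_smoothing(age, y, df_mu_grid = c(3, 5, 7, 9),
                       df_sigma_grid = 2, xi_grid = 1))
    hits <- hits + (s$df_mu > 3)
  }
  expect_gte(hits, 2)
})
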