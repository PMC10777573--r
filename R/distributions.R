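#' Box-Cox response families
#'
#' The three candidate response families for the tooth-count model, all built
#' on the shifted-power (Box-Cox) transform
#' \deqn{z = \frac{(y/\mu)^\nu - 1}{\nu\sigma} \quad (\nu \ne 0), \qquad
#'       z = \frac{\log(y/\mu)}{\sigma} \quad (\nu = 0),}
#' with a standardized kernel for \eqn{Z}: standard normal (BCCG), Student t
#' with \eqn{\tau} degrees of freedom (BCT), or the standardized power
#' exponential with tail exponent \eqn{\tau} (BCPE).  \eqn{\mu > 0} is the
#' median, \eqn{\sigma > 0} the relative dispersion, \eqn{\nu} the skewness
#' power and \eqn{\tau > 0} the tail parameter (fixed at 2, the normal case,
#' for BCCG).
#'
#' @format A character vector of the three family names.
#' @export
bcx_families <- c("BCCG", "BCT", "BCPE")

# nu below this magnitude uses the log-transform branch (avoids catastrophic
# cancellation in ((y/mu)^nu - 1)/nu)
.NU_EPS <- 1e-5

.check_family <- function(family) {
  family <- toupper(family[1L])
  if (!family %in% bcx_families) {
    stop("unknown family '", family, "'; must be one of ",
         paste(bcx_families, collapse = ", "), call. = FALSE)
  }
  family
}

.check_params <- function(mu, sigma, nu, tau, family) {
  if (any(!is.finite(mu)) || any(mu <= 0))
    stop("mu must be finite and > 0", call. = FALSE)
  if (any(!is.finite(sigma)) || any(sigma <= 0))
    stop("sigma must be finite and > 0", call. = FALSE)
  if (any(!is.finite(nu)))
    stop("nu must be finite", call. = FALSE)
  if (family != "BCCG" && (any(!is.finite(tau)) || any(tau <= 0)))
    stop("tau must be finite and > 0", call. = FALSE)
  invisible(TRUE)
}

# scale constant of the standardized power exponential kernel:
# f(z) = tau * exp(-|z/c|^tau) / (2 c Gamma(1/tau)),  c^2 = Gamma(1/tau)/Gamma(3/tau),
# which has mean 0 and variance 1; tau = 2 is the standard normal.
.pe_c <- function(tau) exp(0.5 * (lgamma(1 / tau) - lgamma(3 / tau)))

.kernel_logpdf <- function(z, family, tau) {
  switch(family,
    BCCG = stats::dnorm(z, log = TRUE),
    BCT  = stats::dt(z, df = tau, log = TRUE),
    BCPE = {
      cc <- .pe_c(tau)
      log(tau) - (abs(z) / cc)^tau - log(2) - log(cc) - lgamma(1 / tau)
    }
  )
}

.kernel_cdf <- function(z, family, tau) {
  switch(family,
    BCCG = stats::pnorm(z),
    BCT  = stats::pt(z, df = tau),
    BCPE = {
      cc <- .pe_c(tau)
      0.5 * (1 + sign(z) * stats::pgamma((abs(z) / cc)^tau, shape = 1 / tau))
    }
  )
}

.kernel_quantile <- function(q, family, tau) {
  switch(family,
    BCCG = stats::qnorm(q),
    BCT  = stats::qt(q, df = tau),
    BCPE = {
      cc <- .pe_c(tau)
      sign(q - 0.5) * cc * stats::qgamma(abs(2 * q - 1), shape = 1 / tau)^(1 / tau)
    }
  )
}

# Box-Cox transform of y given (mu, sigma, nu); vectorized, recycling rules as
# in the stats d/p/q functions.
.bcx_z <- function(y, mu, sigma, nu) {
  n <- max(length(y), length(mu), length(sigma), length(nu))
  y <- rep_len(y, n); mu <- rep_len(mu, n)
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  z <- ifelse(abs(nu) < .NU_EPS,
              log(y / mu) / sigma,
              ((y / mu)^nu - 1) / (nu * sigma))
  z
}

# log of the truncation constant F_Z(1/(sigma|nu|)) conditioning on y > 0;
# 0 when nu ~ 0 (no truncation on the log scale).
.bcx_log_trunc <- function(sigma, nu, tau, family) {
  n <- max(length(sigma), length(nu), length(tau))
  sigma <- rep_len(sigma, n); nu <- rep_len(nu, n); tau <- rep_len(tau, n)
  out <- numeric(n)
  idx <- abs(nu) >= .NU_EPS
  if (any(idx)) {
    out[idx] <- log(.kernel_cdf(1 / (sigma[idx] * abs(nu[idx])), family, tau[idx]))
  }
  out
}

#' Density, distribution, quantile and random generation for the Box-Cox
#' families
#'
#' `dbcx()` evaluates the density of the BCCG, BCT or BCPE distribution in the
#' \eqn{(\mu, \sigma, \nu, \tau)} parameterization.  The density includes the
#' Jacobian \eqn{y^{\nu-1}/(\mu^\nu\sigma)} and the truncation constant
#' \eqn{F_Z(1/(\sigma|\nu|))} that conditions the transformed kernel on
#' \eqn{y > 0}, so it integrates to one over \eqn{(0, \infty)}.  `pbcx()` and
#' `qbcx()` apply the same truncation, so they are exact inverses of each
#' other and consistent with the density; when \eqn{\sigma|\nu|} is small the
#' truncation mass is negligible and `qbcx(0.5, ...)` equals `mu` to near
#' machine precision.  `rbcx()` draws by inverse transform sampling.
#'
#' @param y vector of positive observation values (tooth counts, possibly
#'   offset).
#' @param q vector of probabilities in (0, 1).
#' @param n number of random draws.
#' @param family one of `"BCCG"`, `"BCT"`, `"BCPE"`.
#' @param mu,sigma,nu,tau distribution parameters, recycled against `y`/`q`.
#'   `tau` is ignored for BCCG (normal kernel).
#' @param log,log.p logical; return log density / log probability.
#' @return `dbcx` the density, `pbcx` the cdf, `qbcx` the quantile (positive),
#'   `rbcx` a vector of `n` positive draws.
#' @examples
#' dbcx(10, "BCPE", mu = 10, sigma = 0.1, nu = 1, tau = 2) # ~ dnorm(0)/1
#' qbcx(0.5, "BCT", mu = 8, sigma = 0.2, nu = 0.5, tau = 5) # exactly 8
#' @export
dbcx <- function(y, family, mu, sigma, nu, tau = 2, log = FALSE) {
  family <- .check_family(family)
  .check_params(mu, sigma, nu, tau, family)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("y must be finite and > 0", call. = FALSE)
  if (family == "BCCG") tau <- 2
  n <- max(length(y), length(mu), length(sigma), length(nu), length(tau))
  y <- rep_len(y, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  nu <- rep_len(nu, n); tau <- rep_len(tau, n)
  z <- .bcx_z(y, mu, sigma, nu)
  logjac <- (nu - 1) * base::log(y) - nu * base::log(mu) - base::log(sigma)
  ll <- .kernel_logpdf(z, family, tau) + logjac -
    .bcx_log_trunc(sigma, nu, tau, family)
  if (log) ll else exp(ll)
}

#' @rdname dbcx
#' @export
pbcx <- function(y, family, mu, sigma, nu, tau = 2) {
  family <- .check_family(family)
  .check_params(mu, sigma, nu, tau, family)
  if (any(!is.finite(y)) || any(y <= 0))
    stop("y must be finite and > 0", call. = FALSE)
  if (family == "BCCG") tau <- 2
  n <- max(length(y), length(mu), length(sigma), length(nu), length(tau))
  tau <- rep_len(tau, n); sigma <- rep_len(sigma, n); nu <- rep_len(nu, n)
  z <- .bcx_z(rep_len(y, n), rep_len(mu, n), sigma, nu)
  Fz <- .kernel_cdf(z, family, tau)
  # condition on y > 0: for nu != 0 the kernel is truncated to the image of
  # (0, Inf); A = F_Z(1/(sigma|nu|)) is the retained mass
  A <- ifelse(abs(nu) < .NU_EPS, 1,
              .kernel_cdf(1 / (sigma * abs(nu)), family, tau))
  ifelse(abs(nu) < .NU_EPS, Fz,
         ifelse(nu > 0, (Fz - (1 - A)) / A, Fz / A))
}

#' @rdname dbcx
#' @export
qbcx <- function(q, family, mu, sigma, nu, tau = 2) {
  family <- .check_family(family)
  .check_params(mu, sigma, nu, tau, family)
  if (any(!is.finite(q)) || any(q <= 0) || any(q >= 1))
    stop("q must lie strictly inside (0, 1)", call. = FALSE)
  if (family == "BCCG") tau <- 2
  n <- max(length(q), length(mu), length(sigma), length(nu), length(tau))
  q <- rep_len(q, n); mu <- rep_len(mu, n); sigma <- rep_len(sigma, n)
  nu <- rep_len(nu, n); tau <- rep_len(tau, n)
  # invert the truncated cdf: map q back to the untruncated kernel scale
  A <- ifelse(abs(nu) < .NU_EPS, 1,
              .kernel_cdf(1 / (sigma * abs(nu)), family, tau))
  qk <- ifelse(abs(nu) < .NU_EPS, q,
               ifelse(nu > 0, 1 - (1 - q) * A, q * A))
  zq <- .kernel_quantile(qk, family, tau)
  ifelse(abs(nu) < .NU_EPS,
         mu * exp(sigma * zq),
         mu * pmax(1 + sigma * nu * zq, 1e-12)^(1 / nu))
}

#' @rdname dbcx
#' @export
rbcx <- function(n, family, mu, sigma, nu, tau = 2) {
  qbcx(stats::runif(n), family, mu, sigma, nu, tau)
}

#' Log-likelihood of a Box-Cox family with per-observation parameters
#'
#' Sum of log densities, with one parameter set per observation (as produced
#' by evaluating fitted parameter curves at each child's age).
#'
#' @inheritParams dbcx
#' @return a single finite number.
#' @export
bcx_loglik <- function(y, family, mu, sigma, nu, tau = 2) {
  bad <- which(!is.finite(y) | y <= 0)
  if (length(bad)) {
    stop("nonpositive or non-finite response at index ", bad[1L], call. = FALSE)
  }
  sum(dbcx(y, family, mu, sigma, nu, tau, log = TRUE))
}
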