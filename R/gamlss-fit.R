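# Penalized-likelihood backfitting for Box-Cox distributional regression.
#
# Every distribution parameter gets a link (log for mu, sigma, tau; identity
# for nu) and, on the link scale, either a constant, a linear trend, or a
# P-spline in transformed age x = age^xi.  Fitting cycles through the
# parameters (Rigby-Stasinopoulos style): score and curvature of the
# log-likelihood with respect to the predictor give a working response and
# weights, a penalized WLS step updates the curve, and step-halving enforces
# a non-increasing global deviance.

.PARAMS <- c("mu", "sigma", "nu", "tau")

.LINK_INV <- list(
  mu    = function(eta) exp(eta),
  sigma = function(eta) exp(eta),
  nu    = function(eta) eta,
  tau   = function(eta) exp(eta)
)
.LINK <- list(
  mu    = function(th) log(th),
  sigma = function(th) log(th),
  nu    = function(th) th,
  tau   = function(th) log(th)
)
.ETA_CLAMP <- list(
  mu    = c(log(1e-3), log(1e4)),
  sigma = c(log(1e-4), log(5)),
  nu    = c(-10, 10),
  tau   = c(log(0.2), log(1e6))
)

.clamp <- function(x, b) pmin(pmax(x, b[1]), b[2])

#' Control settings for the backfitting algorithm
#'
#' @param tol relative global-deviance change declaring convergence.
#' @param maxit maximum number of outer backfitting cycles.
#' @param step_halving_max maximum step-halvings per parameter update before
#'   the update is reverted.
#' @param deriv_h step for the numerical score/curvature on the link scale.
#' @param trace print the deviance each cycle.
#' @return a list of class `bcx_control`.
#' @export
bcx_control <- function(tol = 1e-5, maxit = 200, step_halving_max = 15,
                        deriv_h = 1e-3, trace = FALSE) {
  stopifnot(tol > 0, maxit >= 1)
  structure(list(tol = tol, maxit = maxit,
                 step_halving_max = step_halving_max,
                 deriv_h = deriv_h, trace = trace), class = "bcx_control")
}

# pointwise log-likelihood given link-scale predictors
.bcx_pll <- function(y, family, etas) {
  dbcx(y, family,
       mu = exp(etas$mu), sigma = exp(etas$sigma),
       nu = etas$nu, tau = exp(etas$tau), log = TRUE)
}

#' Fit a Box-Cox distributional regression of tooth count on age
#'
#' Fits \eqn{Y \sim D(\mu, \sigma, \nu, \tau)} with each parameter a smooth
#' function of \eqn{x = \mathrm{age}^\xi}, by cyclic penalized-likelihood
#' backfitting.  The flexibility of each parameter curve is fixed by its
#' target effective degrees of freedom: `df = 1` is a constant, `df = 2` a
#' linear trend in `x`, larger values a P-spline whose smoothing parameter is
#' re-solved each cycle to hold the requested edf.
#'
#' Zero counts are handled by fitting on `y + 0.5` (the Box-Cox families need
#' a positive response); the offset is removed again when centiles are
#' reported.
#'
#' @param age corrected ages in months, in (0, 60].
#' @param y erupted-tooth counts (nonnegative; zeros trigger the +0.5 offset).
#' @param family `"BCPE"`, `"BCCG"` or `"BCT"`.
#' @param df_mu,df_sigma,df_nu,df_tau target effective df per parameter curve
#'   (defaults: smooth median, linear dispersion, constant shape).
#' @param xi power transform exponent applied to age.
#' @param n_interior,degree,penalty_order P-spline settings, see [ps_spec()].
#' @param control a [bcx_control()].
#' @return an object of class `bcx_gamlss` with fitted parameter curves,
#'   log-likelihood `loglik`, total effective df `edf_total`, AIC/BIC values,
#'   convergence metadata and normalized quantile residuals.
#' @seealso [gaic()], [centile_table()], [nq_residuals()]
#' @export
fit_bcx_gamlss <- function(age, y, family = "BCPE",
                           df_mu = 4, df_sigma = 2, df_nu = 1, df_tau = 1,
                           xi = 1, n_interior = 20, degree = 3,
                           penalty_order = 2, control = bcx_control()) {
  family <- .check_family(family)
  stopifnot(length(age) == length(y), xi > 0)
  keep <- is.finite(age) & is.finite(y)
  if (!all(keep)) stop("non-finite age or count values", call. = FALSE)
  n <- length(y)
  if (n < 50) stop("need at least 50 observations", call. = FALSE)
  if (any(age <= 0) || any(age > 60))
    stop("ages must lie in (0, 60] months", call. = FALSE)
  if (any(y < 0)) stop("counts must be nonnegative", call. = FALSE)
  if (length(unique(y)) == 1L)
    stop("degenerate data: all counts are equal", call. = FALSE)

  offset <- if (any(y == 0)) 0.5 else 0
  yy <- y + offset
  x <- age^xi
  spec <- ps_spec(range(x), n_interior = n_interior, degree = degree,
                  penalty_order = penalty_order)
  dfs <- c(mu = df_mu, sigma = df_sigma, nu = df_nu, tau = df_tau)
  if (any(dfs < 1)) stop("df targets must be >= 1", call. = FALSE)

  active <- .PARAMS
  if (family == "BCCG") active <- setdiff(active, "tau")

  ptype <- vapply(.PARAMS, function(k) {
    if (!(k %in% active) || dfs[k] <= 1 + 1e-8) "const"
    else if (dfs[k] <= penalty_order + 0.049) "poly"
    else "smooth"
  }, character(1))
  names(ptype) <- .PARAMS
  FIXED_LAMBDA <- 1e12  # infinite-penalty limit: edf -> penalty_order

  B <- ps_basis(x, spec)

  # --- initialization ----------------------------------------------------
  mu0 <- if (ptype["mu"] == "const") rep(median(yy), n) else {
    lw <- stats::lowess(x, yy, f = 0.4)
    m <- stats::approx(lw$x, lw$y, xout = x, rule = 2)$y
    pmax(m, 0.55 * min(yy))
  }
  sigma0 <- max(stats::sd(yy / mu0), 0.02)
  tau0 <- if (family == "BCT") 10 else 2
  etas <- list(mu = log(mu0),
               sigma = rep(log(sigma0), n),
               nu = rep(1, n),
               tau = rep(log(tau0), n))
  for (k in .PARAMS) etas[[k]] <- .clamp(etas[[k]], .ETA_CLAMP[[k]])

  coefs <- setNames(vector("list", 4L), .PARAMS)
  lambdas <- setNames(rep(NA_real_, 4L), .PARAMS)
  edfs <- setNames(c(1, 1, 1, 1), .PARAMS)
  w1 <- rep(1, n)
  for (k in .PARAMS) {
    if (ptype[k] == "smooth") {
      lam <- ps_lambda_for_edf(B, w1, spec, dfs[k])
      sf <- ps_wls(B, etas[[k]], w1, lam, spec)
      coefs[[k]] <- sf$coef; lambdas[k] <- lam; edfs[k] <- sf$edf
      etas[[k]] <- .clamp(sf$fitted, .ETA_CLAMP[[k]])
    } else if (ptype[k] == "poly") {
      sf <- ps_wls(B, etas[[k]], w1, FIXED_LAMBDA, spec)
      coefs[[k]] <- sf$coef; lambdas[k] <- FIXED_LAMBDA; edfs[k] <- sf$edf
      etas[[k]] <- .clamp(sf$fitted, .ETA_CLAMP[[k]])
    }
  }

  h <- control$deriv_h
  f0 <- .bcx_pll(yy, family, etas)
  dev <- -2 * sum(f0)
  dev_path <- dev
  converged <- FALSE
  iter <- 0L

  for (iter in seq_len(control$maxit)) {
    dev_start <- dev
    for (k in active) {
      eta <- etas[[k]]
      ep <- etas; ep[[k]] <- eta + h
      em <- etas; em[[k]] <- eta - h
      fp <- .bcx_pll(yy, family, ep)
      fm <- .bcx_pll(yy, family, em)
      score <- (fp - fm) / (2 * h)
      curv <- -(fp - 2 * f0 + fm) / h^2
      bad <- !is.finite(score) | !is.finite(curv)
      score[bad] <- 0
      # observed curvature where concave, a typical positive curvature
      # elsewhere; flooring w at |score|/10 bounds each observation's working
      # step at 10 link units while keeping w*(u - eta) = score exactly, so
      # the aggregated step is always an ascent direction
      pos <- !bad & curv > 1e-8
      wfill <- if (any(pos)) stats::median(curv[pos]) else 1
      w <- pmax(ifelse(pos, curv, wfill), abs(score) / 10)
      u <- eta + score / w

      if (ptype[k] == "const") {
        eta_new <- rep(weighted.mean(u, w), n)
        coef_new <- NULL; lam_new <- NA_real_; edf_new <- 1
      } else {
        lam_new <- if (ptype[k] == "poly") FIXED_LAMBDA else
          tryCatch(ps_lambda_for_edf(B, w, spec, dfs[k]),
                   error = function(e) lambdas[k])
        sf <- ps_wls(B, u, w, lam_new, spec)
        eta_new <- sf$fitted; coef_new <- sf$coef; edf_new <- sf$edf
      }
      eta_new <- .clamp(eta_new, .ETA_CLAMP[[k]])

      # step-halving: accept only if the global deviance does not increase
      accepted <- FALSE
      for (half in 0:control$step_halving_max) {
        etas_try <- etas; etas_try[[k]] <- eta_new
        f_try <- .bcx_pll(yy, family, etas_try)
        dev_try <- -2 * sum(f_try)
        if (is.finite(dev_try) && dev_try <= dev + 1e-8) {
          etas <- etas_try; f0 <- f_try; dev <- dev_try
          if (!is.null(coef_new)) {
            old <- if (is.null(coefs[[k]])) coef_new else coefs[[k]]
            coefs[[k]] <- coef_new * (0.5^half) + old * (1 - 0.5^half)
          }
          lambdas[k] <- lam_new; edfs[k] <- edf_new
          accepted <- TRUE
          break
        }
        eta_new <- (eta_new + etas[[k]]) / 2
        if (is.null(coef_new)) next
      }
      if (!accepted) next  # revert this parameter for the cycle
    }
    dev_path <- c(dev_path, dev)
    if (control$trace)
      message(sprintf("cycle %3d  deviance %.6f", iter, dev))
    if (abs(dev_start - dev) / (abs(dev) + 0.1) < control$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("backfitting did not converge in ", control$maxit,
            " cycles (last relative change above tolerance)", call. = FALSE)

  edf_total <- sum(edfs[active])
  loglik <- sum(f0)
  const_theta <- lapply(.PARAMS, function(k)
    if (ptype[k] == "const") .LINK_INV[[k]](etas[[k]][1]) else NULL)
  names(const_theta) <- .PARAMS
  if (family == "BCCG") const_theta$tau <- 2

  model <- structure(list(
    family = family, xi = xi, offset = offset, n = n,
    age_range = range(age), spec = spec,
    ptype = ptype, dfs = dfs, coefs = coefs, lambdas = lambdas,
    edfs = edfs, const_theta = const_theta,
    loglik = loglik, edf_total = edf_total, deviance = dev,
    gaic_table = c(AIC = -2 * loglik + 2 * edf_total,
                   BIC = -2 * loglik + log(n) * edf_total),
    converged = converged, n_iterations = iter,
    dev_path = dev_path,
    age = age, y = y
  ), class = "bcx_gamlss")
  model$residuals <- nq_residuals(y, age, model)
  model
}

#' Evaluate the fitted parameter curves at new ages
#'
#' @param model a fitted [fit_bcx_gamlss()] model (or one reloaded with
#'   [read_bcx_model()]).
#' @param age ages in months.
#' @param allow_extrapolation if `FALSE` (default), ages outside the training
#'   range are an error; if `TRUE`, curves are extended linearly on the link
#'   scale and flagged.
#' @return a data.frame with columns `age, mu, sigma, nu, tau, extrapolated`.
#' @export
predict_params <- function(model, age, allow_extrapolation = FALSE) {
  stopifnot(inherits(model, "bcx_gamlss"))
  outside <- age < model$age_range[1] - 1e-9 | age > model$age_range[2] + 1e-9
  if (any(outside) && !allow_extrapolation)
    stop("ages outside the fitted range [",
         round(model$age_range[1], 2), ", ", round(model$age_range[2], 2),
         "] months; set allow_extrapolation = TRUE to extend the curves",
         call. = FALSE)
  x <- age^model$xi
  out <- data.frame(age = age)
  extrap <- rep(FALSE, length(age))
  for (k in .PARAMS) {
    if (model$ptype[k] == "const") {
      out[[k]] <- rep(model$const_theta[[k]], length(age))
    } else {
      pr <- ps_predict(model$coefs[[k]], model$spec, x)
      eta <- .clamp(pr$value, .ETA_CLAMP[[k]])
      out[[k]] <- .LINK_INV[[k]](eta)
      extrap <- extrap | pr$extrapolated
    }
  }
  if (model$family == "BCCG") out$tau <- 2
  out$extrapolated <- extrap
  out
}

#' @export
print.bcx_gamlss <- function(x, ...) {
  cat("Box-Cox distributional regression (", x$family, ")\n", sep = "")
  cat(sprintf("  n = %d, age range %.1f-%.1f months, xi = %g%s\n",
              x$n, x$age_range[1], x$age_range[2], x$xi,
              if (x$offset > 0) sprintf(", response offset +%g", x$offset) else ""))
  cat(sprintf("  edf: mu %.2f, sigma %.2f, nu %.2f, tau %.2f (total %.2f)\n",
              x$edfs["mu"], x$edfs["sigma"], x$edfs["nu"],
              if (x$family == "BCCG") 0 else x$edfs["tau"], x$edf_total))
  cat(sprintf("  logLik %.3f, AIC %.2f, BIC %.2f, %s in %d cycles\n",
              x$loglik, x$gaic_table["AIC"], x$gaic_table["BIC"],
              if (x$converged) "converged" else "NOT converged",
              x$n_iterations))
  invisible(x)
}

#' @export
logLik.bcx_gamlss <- function(object, ...) {
  structure(object$loglik, df = object$edf_total, class = "logLik")
}

#' @export
fitted.bcx_gamlss <- function(object, ...) {
  predict_params(object, object$age)$mu - object$offset
}

#' @export
residuals.bcx_gamlss <- function(object, ...) object$residuals

#' Save / reload a fitted model as JSON
#'
#' Stores everything needed to evaluate the fitted parameter curves (family,
#' age transform, knots, coefficients, smoothing parameters, edf), plus the
#' log-likelihood, GAIC values and convergence metadata, so centile tables and
#' per-child assessments can be produced without refitting.
#'
#' @param model a `bcx_gamlss` fit.
#' @param path file to write / read.
#' @return `read_bcx_model()` returns a `bcx_gamlss` object without the
#'   training data or residuals.
#' @export
write_bcx_model <- function(model, path) {
  stopifnot(inherits(model, "bcx_gamlss"))
  keep <- model[c("family", "xi", "offset", "n", "age_range", "ptype",
                  "dfs", "coefs", "lambdas", "edfs", "const_theta",
                  "loglik", "edf_total", "deviance", "gaic_table",
                  "converged", "n_iterations")]
  keep$spec <- unclass(model$spec)
  # named vectors as JSON objects so names survive the round trip
  for (f in c("ptype", "dfs", "lambdas", "edfs", "gaic_table"))
    keep[[f]] <- as.list(keep[[f]])
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_bcx_model
#' @export
read_bcx_model <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$spec <- structure(m$spec, class = "ps_spec")
  m$ptype <- unlist(m$ptype)
  m$dfs <- unlist(m$dfs); m$lambdas <- unlist(m$lambdas)
  m$edfs <- unlist(m$edfs); m$gaic_table <- unlist(m$gaic_table)
  m$coefs <- lapply(m$coefs, function(co) if (length(co)) unlist(co) else NULL)
  m$const_theta <- lapply(m$const_theta,
                          function(v) if (length(v)) unname(unlist(v)) else NULL)
  structure(m, class = "bcx_gamlss")
}
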