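#' P-spline basis specification
#'
#' Describes the penalized B-spline smoother used for each distribution
#' parameter: a B-spline basis of given degree on equally spaced knots over
#' the transformed-age range, with a discrete difference penalty on the
#' coefficients.  Defaults follow the standard P-spline recipe: cubic basis,
#' 20 equally spaced interior knots, second-order difference penalty.
#'
#' @param x_range numeric length-2: domain of the (transformed) covariate.
#' @param n_interior number of interior knots.
#' @param degree B-spline degree (3 = cubic).
#' @param penalty_order order of the difference penalty.
#' @return an object of class `ps_spec` with the full (extended) knot vector.
#' @export
ps_spec <- function(x_range, n_interior = 20, degree = 3, penalty_order = 2) {
  stopifnot(length(x_range) == 2, is.finite(x_range), diff(x_range) > 0,
            n_interior >= 1, degree >= 1, penalty_order >= 1)
  lo <- x_range[1]; hi <- x_range[2]
  inner <- seq(lo, hi, length.out = n_interior + 2)
  h <- inner[2] - inner[1]
  knots <- c(lo - (degree:1) * h, inner, hi + (1:degree) * h)
  structure(
    list(lo = lo, hi = hi, degree = degree, n_interior = n_interior,
         penalty_order = penalty_order, knots = knots,
         n_coef = n_interior + degree + 1),
    class = "ps_spec")
}

#' Build a B-spline design matrix
#'
#' Evaluates the basis of a [ps_spec()] at covariate values.  Rows sum to one
#' (partition of unity) everywhere on the domain; values outside the domain
#' are an error -- no silent extrapolation at build time.
#'
#' @param x covariate values within the spec's domain; at least two distinct.
#' @param spec a [ps_spec()].
#' @return an `length(x) x n_coef` design matrix.
#' @export
ps_basis <- function(x, spec) {
  stopifnot(inherits(spec, "ps_spec"))
  if (length(unique(x)) < 2)
    stop("need at least 2 distinct covariate values", call. = FALSE)
  eps <- 1e-10 * (spec$hi - spec$lo)
  if (any(x < spec$lo - eps) || any(x > spec$hi + eps))
    stop("covariate values outside the basis domain [", spec$lo, ", ",
         spec$hi, "]; extrapolation must be requested explicitly",
         call. = FALSE)
  x <- pmin(pmax(x, spec$lo), spec$hi)
  splines::splineDesign(spec$knots, x, ord = spec$degree + 1)
}

# difference penalty matrix D (penalty_order-th differences)
ps_penalty <- function(spec) {
  diff(diag(spec$n_coef), differences = spec$penalty_order)
}

# Penalized normal equations pieces shared by ps_wls / edf / lambda search.
.ps_system <- function(B, w, spec) {
  sw <- sqrt(w)
  BtWB <- crossprod(B * sw)
  D <- ps_penalty(spec)
  list(BtWB = BtWB, P = crossprod(D))
}

.ps_edf_from_sys <- function(sys, lambda) {
  M <- sys$BtWB + lambda * sys$P
  H <- tryCatch(solve(M, sys$BtWB), error = function(e) NULL)
  if (is.null(H)) return(NA_real_)
  sum(diag(H))
}

#' Penalized weighted least squares for a P-spline smoother
#'
#' Minimizes \eqn{\sum_i w_i (u_i - (Ba)_i)^2 + \lambda \|\Delta^d a\|^2} and
#' returns the coefficient vector, fitted values and effective degrees of
#' freedom (trace of the hat matrix
#' \eqn{B (B^\top WB + \lambda D^\top D)^{-1} B^\top W}).
#'
#' @param B design matrix from [ps_basis()].
#' @param u working response.
#' @param w nonnegative working weights (at least one positive).
#' @param lambda nonnegative smoothing parameter.
#' @param spec the [ps_spec()] that produced `B`.
#' @return a list of class `ps_fit`: `coef`, `fitted`, `lambda`, `edf`.
#' @export
ps_wls <- function(B, u, w, lambda, spec) {
  stopifnot(nrow(B) == length(u), length(u) == length(w),
            all(w >= 0), any(w > 0), lambda >= 0)
  sys <- .ps_system(B, w, spec)
  M <- sys$BtWB + lambda * sys$P
  a <- tryCatch(solve(M, crossprod(B, w * u)),
                error = function(e)
                  stop("penalized system is singular; raise lambda or ",
                       "reduce the number of knots", call. = FALSE))
  edf <- .ps_edf_from_sys(sys, lambda)
  structure(list(coef = drop(a), fitted = drop(B %*% a),
                 lambda = lambda, edf = edf),
            class = "ps_fit")
}

#' Effective degrees of freedom of a P-spline smoother
#'
#' @inheritParams ps_wls
#' @return trace of the smoother (hat) matrix.
#' @export
ps_edf <- function(B, w, lambda, spec) {
  .ps_edf_from_sys(.ps_system(B, w, spec), lambda)
}

#' Find the smoothing parameter matching a target effective df
#'
#' `edf(lambda)` decreases continuously from the number of basis columns (at
#' `lambda = 0`) to the penalty order (as `lambda` grows); the target is found
#' by bisection on `log(lambda)`.
#'
#' @inheritParams ps_wls
#' @param target_edf requested effective degrees of freedom; must satisfy
#'   `penalty_order < target_edf <= n_coef`.
#' @param tol absolute tolerance on the achieved edf.
#' @return the smoothing parameter `lambda`.
#' @export
ps_lambda_for_edf <- function(B, w, spec, target_edf, tol = 0.01) {
  sys <- .ps_system(B, w, spec)
  lo <- -12; hi <- 14  # log10 lambda bracket
  edf_lo <- .ps_edf_from_sys(sys, 10^lo)  # ~ n_coef
  edf_hi <- .ps_edf_from_sys(sys, 10^hi)  # ~ penalty_order
  if (!is.finite(edf_lo) || !is.finite(edf_hi))
    stop("penalized system is singular; raise lambda or reduce knots",
         call. = FALSE)
  if (target_edf > edf_lo + tol || target_edf < edf_hi - tol)
    stop(sprintf(
      "target edf %.3f outside the attainable range (%.3f, %.3f]",
      target_edf, edf_hi, edf_lo), call. = FALSE)
  if (target_edf >= edf_lo - tol) return(10^lo)
  if (target_edf <= edf_hi + tol) return(10^hi)
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    e <- .ps_edf_from_sys(sys, 10^mid)
    if (abs(e - target_edf) < tol / 2) return(10^mid)
    if (e > target_edf) lo <- mid else hi <- mid
  }
  10^((lo + hi) / 2)
}

# Evaluate a fitted smoother at new covariate values; inside the domain the
# spline itself, beyond the boundary a linear extension (value + slope at the
# boundary).  Returns list(value, extrapolated flag vector).
ps_predict <- function(coef, spec, x) {
  inside <- x >= spec$lo & x <= spec$hi
  out <- numeric(length(x))
  if (any(inside)) {
    xi <- x[inside]
    # splineDesign needs >= 2 values through ps_basis; call directly here
    Bi <- splines::splineDesign(spec$knots, xi, ord = spec$degree + 1)
    out[inside] <- drop(Bi %*% coef)
  }
  if (any(!inside)) {
    xo <- x[!inside]
    bnd <- ifelse(xo < spec$lo, spec$lo, spec$hi)
    val <- numeric(length(xo))
    for (b in unique(bnd)) {
      sel <- bnd == b
      f0 <- drop(splines::splineDesign(spec$knots, b, ord = spec$degree + 1) %*% coef)
      f1 <- drop(splines::splineDesign(spec$knots, b, ord = spec$degree + 1,
                                       derivs = 1L) %*% coef)
      val[sel] <- f0 + f1 * (xo[sel] - b)
    }
    out[!inside] <- val
  }
  list(value = out, extrapolated = !inside)
}
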