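# Model selection by the generalized Akaike information criterion.

#' Generalized Akaike information criterion
#'
#' \eqn{\mathrm{GAIC}(b) = -2L + b \cdot \mathrm{edf}} where \eqn{L} is the
#' fitted log-likelihood and edf the total effective degrees of freedom.
#' `b = 2` gives AIC; `b = log(n)` gives BIC.
#'
#' @param model a fitted `bcx_gamlss` model.
#' @param b positive penalty per effective degree of freedom.
#' @return the criterion value (smaller is better).
#' @export
gaic <- function(model, b = 2) {
  stopifnot(inherits(model, "bcx_gamlss"))
  if (!is.numeric(b) || length(b) != 1 || b <= 0)
    stop("b must be a positive number", call. = FALSE)
  -2 * model$loglik + b * model$edf_total
}

# preference order used to break exact GAIC ties: the lighter-tailed /
# simpler-kernel family wins
.FAMILY_TIE_ORDER <- c("BCPE", "BCCG", "BCT")

#' Pick the family with the smallest GAIC from a criterion table
#'
#' Exact ties are broken deterministically in the order BCPE, BCCG, BCT
#' (simpler-tail preference) and reported with a message.
#'
#' @param gaic_values named numeric vector of GAIC values (names are family
#'   names).
#' @return the winning family name.
#' @export
select_from_gaic <- function(gaic_values) {
  stopifnot(is.numeric(gaic_values), !is.null(names(gaic_values)),
            all(names(gaic_values) %in% bcx_families))
  best <- min(gaic_values)
  winners <- names(gaic_values)[gaic_values == best]
  if (length(winners) > 1) {
    winners <- winners[order(match(winners, .FAMILY_TIE_ORDER))]
    message("GAIC tie between ", paste(winners, collapse = ", "),
            "; choosing ", winners[1])
  }
  winners[1]
}

#' Fit all candidate families and select by GAIC
#'
#' Fits the same model specification under BCCG, BCT and BCPE and returns the
#' family with the lowest GAIC together with the criterion table.
#' Non-converged fits are excluded with a warning; if no fit converges this is
#' an error.
#'
#' @inheritParams fit_bcx_gamlss
#' @param families candidate families.
#' @param b GAIC penalty (2 = AIC).
#' @param ... further arguments passed to [fit_bcx_gamlss()].
#' @return a list: `family` (winner), `model` (its fit), `gaic_table`
#'   (data.frame of family, gaic, loglik, edf, converged), `models` (all fits).
#' @export
select_family <- function(age, y, families = c("BCCG", "BCT", "BCPE"),
                          b = 2, ...) {
  fits <- lapply(families, function(fam)
    tryCatch(fit_bcx_gamlss(age, y, family = fam, ...),
             error = function(e) e))
  names(fits) <- families
  ok <- vapply(fits, function(f)
    inherits(f, "bcx_gamlss") && isTRUE(f$converged), logical(1))
  if (any(!ok))
    warning("excluded non-converged/failed fits: ",
            paste(families[!ok], collapse = ", "), call. = FALSE)
  if (!any(ok)) stop("no candidate family converged", call. = FALSE)
  gvals <- vapply(fits[ok], gaic, numeric(1), b = b)
  winner <- select_from_gaic(gvals)
  tab <- data.frame(
    family = families,
    gaic = ifelse(ok, vapply(fits, function(f)
      if (inherits(f, "bcx_gamlss")) gaic(f, b) else NA_real_, numeric(1)),
      NA_real_),
    loglik = vapply(fits, function(f)
      if (inherits(f, "bcx_gamlss")) f$loglik else NA_real_, numeric(1)),
    edf = vapply(fits, function(f)
      if (inherits(f, "bcx_gamlss")) f$edf_total else NA_real_, numeric(1)),
    converged = ok, row.names = NULL)
  list(family = winner, model = fits[[winner]], gaic_table = tab,
       models = fits)
}

#' Grid search over smoothing df and the age-transform exponent
#'
#' Exhaustive search over `df_mu x df_sigma x xi`, holding `nu` and `tau`
#' constant, minimizing GAIC(b).  The full search table is returned.  Fits
#' that fail fall back to `NA` rows; if everything fails the smallest grid
#' point is returned with a warning.
#'
#' @inheritParams fit_bcx_gamlss
#' @param df_mu_grid,df_sigma_grid,xi_grid candidate values.
#' @param b GAIC penalty.
#' @param control a [bcx_control()]; the default is looser than the final-fit
#'   default since the search only ranks specifications.
#' @param ... passed to [fit_bcx_gamlss()].
#' @return a list: `df_mu`, `df_sigma`, `xi` (the winners), `model` (the
#'   winning fit), `table` (one row per grid point with gaic/edf/convergence).
#' @export
select_smoothing <- function(age, y, family = "BCPE",
                             df_mu_grid = 3:8, df_sigma_grid = 2:4,
                             xi_grid = c(0.5, 0.75, 1, 1.25, 1.5),
                             b = 2,
                             control = bcx_control(tol = 1e-4, maxit = 60),
                             ...) {
  stopifnot(length(df_mu_grid) >= 1, length(df_sigma_grid) >= 1,
            length(xi_grid) >= 1)
  grid <- expand.grid(df_mu = df_mu_grid, df_sigma = df_sigma_grid,
                      xi = xi_grid, KEEP.OUT.ATTRS = FALSE)
  fits <- vector("list", nrow(grid))
  res <- data.frame(grid, gaic = NA_real_, loglik = NA_real_,
                    edf = NA_real_, converged = FALSE)
  for (i in seq_len(nrow(grid))) {
    f <- tryCatch(suppressWarnings(
      fit_bcx_gamlss(age, y, family = family,
                     df_mu = grid$df_mu[i], df_sigma = grid$df_sigma[i],
                     xi = grid$xi[i], control = control, ...)),
      error = function(e) NULL)
    fits[[i]] <- f
    if (!is.null(f)) {
      res$gaic[i] <- gaic(f, b)
      res$loglik[i] <- f$loglik
      res$edf[i] <- f$edf_total
      res$converged[i] <- f$converged
    }
  }
  usable <- which(res$converged)
  if (!length(usable)) {
    warning("no grid point converged; falling back to the smallest grid point",
            call. = FALSE)
    usable <- 1L
  }
  best <- usable[which.min(res$gaic[usable])]
  list(df_mu = grid$df_mu[best], df_sigma = grid$df_sigma[best],
       xi = grid$xi[best], model = fits[[best]], table = res)
}
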