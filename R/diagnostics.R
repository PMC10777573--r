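# Residual diagnostics: normalized quantile residuals, worm plots,
# Q-statistics by age group.

#' Normalized quantile residuals
#'
#' \eqn{r_i = \Phi^{-1}(F(y_i \mid \hat\theta(\mathrm{age}_i)))}; under the
#' true model the residuals are iid standard normal.  The response is an
#' integer count treated as continuous (as in the fitted model); a randomized
#' variant draws the residual uniformly within the count's probability cell
#' \eqn{(F(y-1), F(y)]}, which removes the banding that discreteness induces.
#' The randomized variant is off by default.
#'
#' @param y observed counts.
#' @param age corrected ages (months).
#' @param model a fitted `bcx_gamlss` model.
#' @param randomized draw uniformly within each count's probability cell.
#' @param allow_extrapolation passed to [predict_params()].
#' @return numeric vector of residuals; the number of cdf values clipped away
#'   from 0/1 is reported in attribute `n_clipped`.
#' @export
nq_residuals <- function(y, age, model, randomized = FALSE,
                         allow_extrapolation = FALSE) {
  stopifnot(length(y) == length(age))
  p <- predict_params(model, age, allow_extrapolation = allow_extrapolation)
  yy <- y + model$offset
  if (any(yy <= 0)) stop("counts must be positive after the offset",
                         call. = FALSE)
  u <- pbcx(yy, model$family, p$mu, p$sigma, p$nu, p$tau)
  if (randomized) {
    ylo <- yy - 1
    ulo <- ifelse(ylo > 0,
                  pbcx(pmax(ylo, 1e-12), model$family,
                       p$mu, p$sigma, p$nu, p$tau), 0)
    u <- ulo + stats::runif(length(u)) * (u - ulo)
  }
  n_clip <- sum(u < 1e-12 | u > 1 - 1e-12)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  r <- stats::qnorm(u)
  attr(r, "n_clipped") <- n_clip
  r
}

#' Worm plot coordinates
#'
#' De-trended normal Q-Q plot of residuals: ordinate
#' \eqn{r_{(i)} - \Phi^{-1}(p_i)} with \eqn{p_i = (i - 0.5)/n}, against the
#' theoretical quantile, with point-wise 95% bands of half-width
#' \eqn{1.96\sqrt{p_i(1-p_i)/n}/\phi(\Phi^{-1}(p_i))}.  Many points outside
#' the bands indicate an inappropriate model.
#'
#' @param r residual vector (n >= 20).
#' @return a data.frame of class `worm_data`: `theoretical`, `ordinate`,
#'   `band` (half-width), `outside` (logical).
#' @export
worm <- function(r) {
  n <- length(r)
  if (n < 20) stop("need at least 20 residuals", call. = FALSE)
  p <- (seq_len(n) - 0.5) / n
  q <- stats::qnorm(p)
  ord <- sort(r) - q
  band <- 1.96 * sqrt(p * (1 - p) / n) / stats::dnorm(q)
  structure(data.frame(theoretical = q, ordinate = ord, band = band,
                       outside = abs(ord) > band),
            class = c("worm_data", "data.frame"))
}

#' Plot a worm plot
#'
#' @param wd a [worm()] result.
#' @return a ggplot object.
#' @export
plot_worm <- function(wd) {
  stopifnot(inherits(wd, "worm_data"))
  ggplot2::ggplot(wd, ggplot2::aes(x = .data$theoretical)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$band), linetype = "dotted") +
    ggplot2::geom_line(ggplot2::aes(y = -.data$band), linetype = "dotted") +
    ggplot2::geom_point(ggplot2::aes(y = .data$ordinate), size = 0.8) +
    ggplot2::labs(x = "Unit normal quantile", y = "Deviation",
                  title = "Worm plot of normalized quantile residuals")
}

# D'Agostino (1970) transformation of sample skewness to an approximate
# standard normal deviate.
.z_skewness <- function(r) {
  n <- length(r)
  m <- mean(r)
  m2 <- mean((r - m)^2); m3 <- mean((r - m)^3)
  if (m2 <= 0) return(NA_real_)
  b1 <- m3 / m2^1.5
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  delta * asinh(Y / alpha)
}

# Anscombe-Glynn (1983) transformation of sample kurtosis.
.z_kurtosis <- function(r) {
  n <- length(r)
  m <- mean(r)
  m2 <- mean((r - m)^2); m4 <- mean((r - m)^4)
  if (m2 <= 0) return(NA_real_)
  b2 <- m4 / m2^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xx <- (b2 - eb2) / sqrt(vb2)
  beta <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta * (2 / beta + sqrt(1 + 4 / beta^2))
  ((1 - 2 / (9 * A)) -
     ((1 - 2 / A) / (1 + xx * sqrt(2 / (A - 4))))^(1/3)) / sqrt(2 / (9 * A))
}

#' Q-statistics by age group
#'
#' Splits the residuals into age groups (quantile-based) and, within each
#' group, computes standardized z statistics for the first four moments:
#' location (\eqn{\sqrt{n_g}\,\bar r}), scale (Wilson-Hilferty transform of
#' the sample variance), skewness and kurtosis (D'Agostino-type transforms).
#' The Q statistic for each moment is the sum of squared group z values,
#' referred to a chi-square whose df is the number of groups minus the
#' effective df spent on the corresponding parameter curve (clamped at 1).
#'
#' @param r residuals.
#' @param age ages (months), same length as `r`.
#' @param n_groups number of age groups; default `ceiling(n/250)` clamped to
#'   `[4, 12]`.  Groups smaller than 25 trigger regrouping with a warning.
#' @param model_edf optional named vector `c(mu=, sigma=, nu=, tau=)` of edf
#'   spent on each parameter curve (used for the chi-square df); defaults to
#'   zeros (pure calibration check).
#' @return a list of class `q_table`: `groups` (per-group z statistics and
#'   counts), `Q` (per-moment statistic, df, p-value).
#' @export
q_statistics <- function(r, age, n_groups = NULL, model_edf = NULL) {
  stopifnot(length(r) == length(age))
  n <- length(r)
  if (stats::var(r) <= 0)
    stop("degenerate residuals: zero variance", call. = FALSE)
  if (is.null(n_groups)) n_groups <- min(12L, max(4L, ceiling(n / 250)))
  if (n_groups < 2) stop("need at least 2 groups", call. = FALSE)
  if (is.null(model_edf))
    model_edf <- c(mu = 0, sigma = 0, nu = 0, tau = 0)

  make_groups <- function(k) {
    br <- unique(stats::quantile(age, probs = seq(0, 1, length.out = k + 1)))
    if (length(br) < 3) return(NULL)
    g <- cut(age, breaks = br, include.lowest = TRUE)
    g
  }
  g <- make_groups(n_groups)
  while (!is.null(g) && min(table(g)) < 25 && n_groups > 2) {
    warning("age group smaller than 25; regrouping with ", n_groups - 1,
            " groups", call. = FALSE)
    n_groups <- n_groups - 1
    g <- make_groups(n_groups)
  }
  if (is.null(g)) stop("could not form age groups", call. = FALSE)

  idx <- split(seq_len(n), g)
  zs <- t(vapply(idx, function(ii) {
    rg <- r[ii]; ng <- length(rg)
    z1 <- sqrt(ng) * mean(rg)
    k <- ng - 1
    X <- k * stats::var(rg)
    z2 <- ((X / k)^(1/3) - (1 - 2 / (9 * k))) / sqrt(2 / (9 * k))
    c(location = z1, scale = z2,
      skewness = .z_skewness(rg), kurtosis = .z_kurtosis(rg))
  }, numeric(4)))
  counts <- vapply(idx, length, integer(1))

  param_for <- c(location = "mu", scale = "sigma",
                 skewness = "nu", kurtosis = "tau")
  Q <- colSums(zs^2, na.rm = TRUE)
  df <- pmax(length(idx) - unname(model_edf[param_for]), 1)
  pval <- stats::pchisq(Q, df = df, lower.tail = FALSE)
  structure(list(
    groups = data.frame(group = names(idx), n = counts, zs,
                        row.names = NULL, check.names = FALSE),
    Q = data.frame(moment = names(Q), Q = unname(Q), df = unname(df),
                   p_value = unname(pval), row.names = NULL)
  ), class = "q_table")
}

#' @export
print.q_table <- function(x, ...) {
  cat("Q-statistics by age group (", nrow(x$groups), " groups)\n", sep = "")
  print(x$Q, digits = 4)
  invisible(x)
}
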