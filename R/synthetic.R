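# Synthetic cohort generators and corrected-age arithmetic.
#
# The anchored generator encodes the published monthly reference centiles
# (its calibration contract: empirical centiles of large draws reproduce the
# anchor table to rounding granularity).  The mechanistic generator builds
# counts the way dentitions actually produce them -- 20 per-tooth eruption
# thresholds -- and the parametric generator draws from a known Box-Cox truth
# for parameter-recovery testing.

.DAYS_PER_MONTH <- 30.4375  # mean Gregorian month
.FULL_TERM_WEEKS <- 40

#' Gestational-age-corrected age
#'
#' Chronological age minus the shortfall from a 40-week gestation, in mean
#' Gregorian months: `chronological - (40 - ga_weeks) * 7 / 30.4375`.
#' Applied to every child; a full-term (40-week) birth is the identity and a
#' post-term birth increases the age.
#'
#' @param chronological_months chronological age in months (> 0).
#' @param gestational_weeks gestational age at birth in weeks, within
#'   \[22, 44\].
#' @return corrected age in months.
#' @examples
#' corrected_age(13, 40) # 13
#' corrected_age(13, 36) # ~ 12.08
#' @export
corrected_age <- function(chronological_months, gestational_weeks) {
  if (any(!is.finite(gestational_weeks)) ||
      any(gestational_weeks < 22) || any(gestational_weeks > 44))
    stop("gestational age must lie in [22, 44] weeks", call. = FALSE)
  if (any(!is.finite(chronological_months)) || any(chronological_months <= 0))
    stop("chronological age must be positive", call. = FALSE)
  chronological_months -
    (.FULL_TERM_WEEKS - gestational_weeks) * 7 / .DAYS_PER_MONTH
}

#' Inverse of [corrected_age()]
#' @inheritParams corrected_age
#' @param corrected_months corrected age in months.
#' @return chronological age in months.
#' @export
chronological_age <- function(corrected_months, gestational_weeks) {
  corrected_months +
    (.FULL_TERM_WEEKS - gestational_weeks) * 7 / .DAYS_PER_MONTH
}

#' Monthly reference centile anchors
#'
#' The published reference table of erupted-deciduous-teeth counts at the
#' 5th, 25th, 50th, 75th and 95th centiles for each integer corrected age
#' 12..36 months.  Counts are nondecreasing across levels within each age
#' and bounded by the 20-tooth complete dentition.
#'
#' @return a data.frame with columns `age_months, p5, p25, p50, p75, p95`.
#' @export
tooth_centile_anchors <- function() {
  data.frame(
    age_months = 12:36,
    p5  = c(2, 3, 3, 4, 5, 5, 6, 7, 9, 10, 11, 11, 12, 13, 13, 13, 14, 14,
            15, 15, 16, 16, 17, 17, 17),
    p25 = c(4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 15, 15, 16, 16, 17,
            17, 18, 18, 18, 18, 19, 19, 19),
    p50 = c(5, 6, 8, 9, 10, 11, 12, 13, 14, 15, 15, 16, 16, 17, 17, 17, 18,
            18, 19, 19, 19, 19, 20, 20, 20),
    p75 = c(7, 8, 10, 11, 12, 13, 14, 15, 16, 16, 17, 17, 18, 19, 19, 18,
            19, 19, 20, 20, 20, 20, 20, 20, 20),
    p95 = c(11, 12, 13, 14, 15, 16, 17, 17, 18, 18, 18, 19, 19, 20, 20, 20,
            20, 20, 20, 20, 20, 20, 20, 20, 20)
  )
}

# Vectorized monotone (Fritsch-Carlson) cubic Hermite interpolation through a
# shared probability grid: Q is an n x m matrix of quantile anchors, p the
# m-vector of probabilities, u an n-vector of evaluation points (one per row).
.monotone_q_eval <- function(p, Q, u) {
  n <- nrow(Q); m <- ncol(Q)
  dp <- diff(p)                                   # m-1
  S <- (Q[, -1, drop = FALSE] - Q[, -m, drop = FALSE]) /
    rep(dp, each = n)                             # secant slopes, n x (m-1)
  Tg <- matrix(0, n, m)                           # tangents
  Tg[, 1] <- S[, 1]; Tg[, m] <- S[, m - 1]
  if (m > 2) for (j in 2:(m - 1)) {
    s1 <- S[, j - 1]; s2 <- S[, j]
    t <- ifelse(s1 * s2 <= 0, 0,
                2 * s1 * s2 / (s1 + s2))          # harmonic mean keeps monotone
    Tg[, j] <- t
  }
  k <- pmin(pmax(findInterval(u, p), 1L), m - 1L) # segment per row
  i <- seq_len(n)
  p0 <- p[k]; h <- p[k + 1L] - p0
  t <- (u - p0) / h
  q0 <- Q[cbind(i, k)]; q1 <- Q[cbind(i, k + 1L)]
  t0 <- Tg[cbind(i, k)]; t1 <- Tg[cbind(i, k + 1L)]
  h00 <- (1 + 2 * t) * (1 - t)^2
  h10 <- t * (1 - t)^2
  h01 <- t^2 * (3 - 2 * t)
  h11 <- t^2 * (t - 1)
  h00 * q0 + h10 * h * t0 + h01 * q1 + h11 * h * t1
}

.draw_sex_ga <- function(n, preterm_fraction, female_fraction = 0.49) {
  sex <- ifelse(stats::rbinom(n, 1, female_fraction) == 1, "female", "male")
  preterm <- stats::rbinom(n, 1, preterm_fraction) == 1
  ga <- ifelse(preterm, stats::runif(n, 30, 36.9), stats::runif(n, 37, 42))
  list(sex = sex, ga = ga)
}

#' Generate a cohort anchored to the reference centile table
#'
#' For a child of corrected age `t`, the five anchor centiles are linearly
#' interpolated in age, extended with tail points at p = 0.001
#' (`max(0, p5 - 2)`) and p = 0.999 (`min(20, p95 + 2)`), and joined into a
#' valid quantile function by shape-preserving monotone cubic interpolation.
#' A uniform draw through that quantile function, rounded and clamped to
#' \[0, 20\], gives the count.  Sex is Bernoulli (49% female) with no effect
#' on the count; about 11% of births are preterm (< 37 weeks) and get a
#' nontrivial age correction.
#'
#' @param n cohort size.
#' @param anchors anchor table as from [tooth_centile_anchors()].
#' @param age_range corrected-age range, ages drawn uniformly.
#' @param preterm_fraction fraction of preterm (< 37 week) births.
#' @param seed integer seed; recorded in the result's attributes.
#' @return a data.frame cohort (`child_id, sex, chron_age_months, ga_weeks,
#'   corrected_age_months, n_teeth`) with attributes `seed` and `generator`.
#' @export
simulate_anchored_cohort <- function(n, anchors = tooth_centile_anchors(),
                                     age_range = c(12, 36),
                                     preterm_fraction = 0.11, seed = 1) {
  stopifnot(n >= 1, preterm_fraction >= 0, preterm_fraction < 1)
  set.seed(seed)
  age <- stats::runif(n, age_range[1], age_range[2])
  sg <- .draw_sex_ga(n, preterm_fraction)
  lv <- c("p5", "p25", "p50", "p75", "p95")
  A <- vapply(lv, function(cn)
    stats::approx(anchors$age_months, anchors[[cn]], xout = age,
                  rule = 2)$y, numeric(n))
  # tail extension; a degenerate (zero-spread) anchor row stays degenerate
  spread <- A[, "p95"] > A[, "p5"]
  Q <- cbind(ifelse(spread, pmax(0, A[, "p5"] - 2), A[, "p5"]), A,
             ifelse(spread, pmin(20, A[, "p95"] + 2), A[, "p95"]))
  p <- c(0.001, 0.05, 0.25, 0.50, 0.75, 0.95, 0.999)
  # enforce nondecreasing anchors row-wise (interpolation already is)
  u <- stats::runif(n, 0.001, 0.999)
  q <- .monotone_q_eval(p, Q, u)
  count <- pmin(pmax(round(q), 0L), 20L)
  out <- data.frame(
    child_id = sprintf("A%06d", seq_len(n)),
    sex = sg$sex,
    chron_age_months = chronological_age(age, sg$ga),
    ga_weeks = sg$ga,
    corrected_age_months = age,
    n_teeth = as.integer(count))
  attr(out, "seed") <- seed
  attr(out, "generator") <- "anchored"
  out
}

#' Default deciduous eruption chronology for the mechanistic generator
#'
#' Median eruption ages per FDI tooth code from the classical chronology,
#' shifted later by `shift` months (default +2, reflecting the delay reported
#' for low-income populations), with a common spread.
#'
#' @param shift months added to every median.
#' @param spread standard deviation of eruption age, months.
#' @return data.frame `fdi, median_months, sd_months` (20 rows).
#' @export
eruption_chronology <- function(shift = 2, spread = 2.5) {
  base <- c(`51` = 10, `61` = 10, `52` = 11, `62` = 11, `53` = 19, `63` = 19,
            `54` = 16, `64` = 16, `55` = 29, `65` = 29,
            `71` = 8, `81` = 8, `72` = 13, `82` = 13, `73` = 20, `83` = 20,
            `74` = 16, `84` = 16, `75` = 27, `85` = 27)
  data.frame(fdi = as.integer(names(base)),
             median_months = unname(base) + shift,
             sd_months = spread)
}

#' Generate a cohort from per-tooth eruption thresholds
#'
#' Each tooth `j` erupts at an age `E_j ~ Normal(m_j, s_j)` truncated to be
#' positive (independent across teeth); tooth `j` is present at age `t` iff
#' `E_j <= t`, and the count is the number of present teeth.  This is the
#' true bounded-count mechanism behind the data and stress-tests the
#' continuous-family approximation.
#'
#' @inheritParams simulate_anchored_cohort
#' @param chronology data.frame as from [eruption_chronology()].
#' @return a cohort data.frame with the 20 per-tooth flag columns `t51..t85`
#'   in addition to the standard columns; `n_teeth` equals the flag sum.
#' @export
simulate_mechanistic_cohort <- function(n, chronology = eruption_chronology(),
                                        age_range = c(12, 36),
                                        preterm_fraction = 0.11, seed = 1) {
  stopifnot(n >= 1, nrow(chronology) == 20)
  if (any(!is.finite(chronology$median_months)) ||
      any(chronology$median_months <= 0) ||
      any(!is.finite(chronology$sd_months)) || any(chronology$sd_months <= 0))
    stop("invalid chronology medians/spreads", call. = FALSE)
  set.seed(seed)
  age <- stats::runif(n, age_range[1], age_range[2])
  sg <- .draw_sex_ga(n, preterm_fraction)
  flags <- matrix(NA, n, 20)
  for (j in seq_len(20)) {
    m <- chronology$median_months[j]; s <- chronology$sd_months[j]
    # truncated-positive normal by inverse cdf
    u <- stats::runif(n, stats::pnorm(0, m, s), 1)
    E <- stats::qnorm(u, m, s)
    flags[, j] <- E <= age
  }
  colnames(flags) <- paste0("t", chronology$fdi)
  out <- data.frame(
    child_id = sprintf("M%06d", seq_len(n)),
    sex = sg$sex,
    chron_age_months = chronological_age(age, sg$ga),
    ga_weeks = sg$ga,
    corrected_age_months = age,
    n_teeth = as.integer(rowSums(flags)))
  out <- cbind(out, as.data.frame(flags + 0L))
  attr(out, "seed") <- seed
  attr(out, "generator") <- "mechanistic"
  out
}

#' Generate a cohort from a known Box-Cox truth
#'
#' Draws counts from the family with parameter curves evaluated at each
#' child's age, then rounds and clamps to \[0, 20\] (optional).  The exact
#' generating parameters are retained per child for recovery tests.
#'
#' @inheritParams simulate_anchored_cohort
#' @param family response family.
#' @param mu_fun,sigma_fun,nu_fun,tau_fun functions of age giving the true
#'   parameter curves (constants may be given as single numbers).
#' @param round_clamp round to integers and clamp to \[0, 20\].
#' @return a cohort data.frame with additional truth columns
#'   `true_mu, true_sigma, true_nu, true_tau` and raw draws `y_raw`.
#' @export
simulate_parametric_cohort <- function(n, family, mu_fun, sigma_fun,
                                       nu_fun = 1, tau_fun = 2,
                                       age_range = c(12, 36),
                                       preterm_fraction = 0.11,
                                       round_clamp = TRUE, seed = 1) {
  as_fun <- function(f) if (is.function(f)) f else function(a) rep(f, length(a))
  mu_fun <- as_fun(mu_fun); sigma_fun <- as_fun(sigma_fun)
  nu_fun <- as_fun(nu_fun); tau_fun <- as_fun(tau_fun)
  set.seed(seed)
  age <- stats::runif(n, age_range[1], age_range[2])
  sg <- .draw_sex_ga(n, preterm_fraction)
  mu <- mu_fun(age); sigma <- sigma_fun(age)
  nu <- nu_fun(age); tau <- tau_fun(age)
  y_raw <- rbcx(n, family, mu, sigma, nu, tau)
  count <- if (round_clamp) pmin(pmax(round(y_raw), 0L), 20L) else y_raw
  out <- data.frame(
    child_id = sprintf("P%06d", seq_len(n)),
    sex = sg$sex,
    chron_age_months = chronological_age(age, sg$ga),
    ga_weeks = sg$ga,
    corrected_age_months = age,
    n_teeth = count,
    y_raw = y_raw,
    true_mu = mu, true_sigma = sigma, true_nu = nu, true_tau = tau)
  attr(out, "seed") <- seed
  attr(out, "generator") <- "parametric"
  out
}
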