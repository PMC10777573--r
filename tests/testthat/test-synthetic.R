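# Cohort generators and corrected-age arithmetic.

test_that("corrected age follows the 40-week reference formula", {
  expect_equal(corrected_age(13, 40), 13)
  # 4 missing weeks = 28 days = 0.92 months on the mean Gregorian month
  expect_equal(corrected_age(13, 36), 13 - 28 / 30.4375, tolerance = 1e-12)
  expect_equal(corrected_age(13, 36), 12.08, tolerance = 1e-3)
  # post-term births get older, symmetrically
  expect_equal(corrected_age(12, 44), 12.92, tolerance = 1e-3)
  # exact round trip with the inverse
  ga <- c(28, 34, 37, 40, 42)
  ca <- corrected_age(rep(18, 5), ga)
  expect_equal(chronological_age(ca, ga), rep(18, 5), tolerance = 1e-12)
  expect_error(corrected_age(13, 20), "22")
  expect_error(corrected_age(0, 40), "positive")
})

test_that("the anchor table is valid and matches its key rows", {
  a <- tooth_centile_anchors()
  expect_equal(a$age_months, 12:36)
  M <- as.matrix(a[, c("p5", "p25", "p50", "p75", "p95")])
  expect_true(all(M >= 0 & M <= 20))
  # nondecreasing across levels within each age
  expect_true(all(apply(M, 1, function(r) all(diff(r) >= 0))))
  expect_equal(unname(M[a$age_months == 12, ]), c(2, 4, 5, 7, 11))
  expect_equal(unname(M[a$age_months == 24, ]), c(12, 15, 16, 18, 19))
  expect_equal(unname(M[a$age_months == 34, ]), c(17, 19, 20, 20, 20))
  expect_equal(unname(M[a$age_months == 36, ]), c(17, 19, 20, 20, 20))
})

test_that("anchored cohorts reproduce the reference centiles at fixed age", {
  co <- simulate_anchored_cohort(1e5, age_range = c(24, 24 + 1e-9), seed = 7)
  q <- quantile(co$n_teeth, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 1,
                names = FALSE)
  expect_true(all(abs(q - c(12, 15, 16, 18, 19)) <= 1))
})

test_that("anchored calibration holds at every integer age", {
  a <- tooth_centile_anchors()
  for (ag in seq(12, 36, by = 4)) {
    co <- simulate_anchored_cohort(2e4, age_range = c(ag, ag + 1e-9),
                                   seed = 100 + ag)
    q <- quantile(co$n_teeth, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 1,
                  names = FALSE)
    ref <- unlist(a[a$age_months == ag, c("p5", "p25", "p50", "p75", "p95")])
    expect_true(all(abs(q - ref) <= 1), label = paste("age", ag))
  }
})

test_that("constant anchors give a constant cohort", {
  a <- tooth_centile_anchors()
  a$p5 <- a$p25 <- a$p50 <- a$p75 <- a$p95 <- 9
  co <- simulate_anchored_cohort(2000, anchors = a, seed = 3)
  expect_true(all(co$n_teeth == 9))
})

test_that("anchored cohorts are seeded and sex-neutral", {
  c1 <- simulate_anchored_cohort(5000, seed = 42)
  c2 <- simulate_anchored_cohort(5000, seed = 42)
  expect_identical(c1, c2)
  c3 <- simulate_anchored_cohort(5000, seed = 43)
  expect_false(identical(c1$n_teeth, c3$n_teeth))
  # no sex effect on counts
  co <- simulate_anchored_cohort(1e4, seed = 11)
  mm <- tapply(co$n_teeth, co$sex, mean)
  vv <- tapply(co$n_teeth, co$sex, var)
  nn <- table(co$sex)
  pooled_se <- sqrt(vv[1] / nn[1] + vv[2] / nn[2])
  expect_lt(abs(mm[1] - mm[2]), 3 * pooled_se)
  # preterm fraction near its target and corrected ages never exceed
  # chronological ages for preterm children
  expect_lt(abs(mean(co$ga_weeks < 37) - 0.11), 0.02)
  pre <- co$ga_weeks < 40
  expect_true(all(co$corrected_age_months[pre] < co$chron_age_months[pre]))
})

test_that("mechanistic cohorts respect the threshold structure", {
  chron <- eruption_chronology()
  expect_equal(nrow(chron), 20)
  # ages far beyond every median + 6 sd: dentition complete
  co <- simulate_mechanistic_cohort(300, age_range = c(55, 56), seed = 5)
  expect_true(all(co$n_teeth == 20))
  # flags sum to the count
  co2 <- simulate_mechanistic_cohort(2000, seed = 6)
  flag_cols <- grep("^t[5-8]", names(co2), value = TRUE)
  expect_equal(length(flag_cols), 20)
  expect_equal(unname(rowSums(co2[flag_cols])), co2$n_teeth)
  # per-tooth presence frequency matches the closed form Phi((t - m)/s)
  ag <- 18
  co3 <- simulate_mechanistic_cohort(1e5, age_range = c(ag, ag + 1e-9),
                                     seed = 7)
  m51 <- chron$median_months[chron$fdi == 51]
  s51 <- chron$sd_months[chron$fdi == 51]
  want <- pnorm((ag - m51) / s51) / pnorm(m51 / s51)  # truncated positive
  expect_lt(abs(mean(co3$t51) - want), 0.005)
  expect_error(simulate_mechanistic_cohort(10,
    chronology = transform(chron, sd_months = -1)), "invalid")
})

test_that("parametric cohorts retain their generating truth", {
  co <- simulate_parametric_cohort(500, "BCPE", mu_fun = 10, sigma_fun = 0.2,
                                   nu_fun = 1.5, tau_fun = 3, seed = 9)
  expect_true(all(co$true_mu == 10 & co$true_tau == 3))
  expect_true(all(co$n_teeth == pmin(pmax(round(co$y_raw), 0), 20)))
  # sigma -> 0 collapses every count onto round(mu)
  co0 <- simulate_parametric_cohort(200, "BCCG", mu_fun = 7.2,
                                    sigma_fun = 1e-8, seed = 10)
  expect_true(all(co0$n_teeth == 7))
  # age-varying truth evaluated at each child's age
  co1 <- simulate_parametric_cohort(100, "BCPE",
                                    mu_fun = function(a) a / 2,
                                    sigma_fun = 0.1, seed = 11)
  expect_equal(co1$true_mu, co1$corrected_age_months / 2)
})
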