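test_that("cumulative risk follows the exponential conversion", {
  expect_equal(cumulativeRisk(0, 7), 0)
  expect_equal(cumulativeRisk(0.02, 0), 0)
  # series oracle for exp(-x): sum_k (-x)^k / k!
  x <- 0.01 * 5
  series <- sum(vapply(0:20, function(k) (-x)^k / factorial(k), 0))
  expect_equal(cumulativeRisk(0.01, 5), 1 - series, tolerance = 1e-12)
  expect_equal(cumulativeRisk(0.01, 5), 0.04877, tolerance = 1e-4)
  expect_error(cumulativeRisk(-0.01, 5), ">= 0")
})

test_that("cumulative risk is monotone and linear in the small-rate limit", {
  r <- seq(0, 0.2, by = 0.01)
  expect_true(all(diff(cumulativeRisk(r, 5)) > 0))
  expect_true(all(diff(vapply(1:10, function(t_)
    cumulativeRisk(0.03, t_), 0)) > 0))
  small <- c(1e-4, 5e-4, 1e-3)
  expect_true(all(abs(cumulativeRisk(small, 5) / (small * 5) - 1) < 0.01))
})

test_that("history categories map deterministically from findings", {
  expect_equal(assignHistoryCategory(character()), "none")
  expect_equal(assignHistoryCategory("none"), "none")
  expect_equal(assignHistoryCategory("hyperplastic_polyp"), "none")
  expect_equal(assignHistoryCategory("small_adenoma"), "low")
  expect_equal(assignHistoryCategory("advanced_adenoma"), "high")
  expect_equal(assignHistoryCategory(c("small_adenoma", "cancer")), "high")
  expect_error(assignHistoryCategory("polypoid_thing"), "unknown finding")
})

test_that("population risk reduces correctly and matches hand arithmetic", {
  params <- riskModelParams(aa_r = c(none = 0.5, low = 0.6, high = 0.7),
                            crc_m = 0.09)
  # n_c = 0, constant AA->CRC: risk = AAr * c
  r1 <- populationRisk(3, 0, rep(0.04, 3), params, history = "none")
  expect_equal(r1$risk, 0.5 * 0.04, tolerance = 1e-12)
  # n_a = 0: risk = CRCm
  r2 <- populationRisk(0, 4, numeric(), params)
  expect_equal(r2$risk, 0.09)
  # printed-formula hand oracle: (0.5*(0.02+0.04) + 1*0.09)/3 = 0.04
  r3 <- populationRisk(2, 1, c(0.02, 0.04), params, history = "none")
  expect_equal(r3$risk, 0.04, tolerance = 1e-12)
  expect_equal(r3$components$adenoma_term, 0.03, tolerance = 1e-12)
  expect_error(populationRisk(0, 0, numeric(), params), "empty")
  expect_error(populationRisk(2, 0, 0.05, params), "length n_a")
})

test_that("population risk stays within the component range", {
  params <- riskModelParams()
  withr::with_seed(31, for (i in 1:20) {
    n_a <- sample(1:10, 1); n_c <- sample(0:5, 1)
    per <- runif(n_a, 0, 0.3)
    hist <- sample(c("none", "low", "high"), 1)
    r <- populationRisk(n_a, n_c, per, params, history = hist)
    comp <- c(unname(params@aa_r[hist]) * per,
              if (n_c) rep(params@crc_m, n_c))
    expect_gte(r$risk, min(comp) - 1e-12)
    expect_lte(r$risk, max(comp) + 1e-12)
  })
})

test_that("sex/age strata only change the affected patient's term", {
  params <- riskModelParams()
  base <- aaToCrcCumulative(c("male", "female", "male"), c(60, 60, 85),
                            params)
  changed <- aaToCrcCumulative(c("male", "female", "female"),
                               c(60, 60, 85), params)
  expect_equal(base[1:2], changed[1:2])
  expect_false(base[3] == changed[3])
  expect_equal(base[3],
               cumulativeRisk(params@annual_aa_to_crc[["male_ge80"]], 5))
})

test_that("risk-D regression matches closed-form OLS and flags degeneracy", {
  d <- c(2.5, 2.6, 2.7)
  r <- c(0.02, 0.05, 0.08)
  fit <- riskDRegression(d, r)
  beta <- cov(d, r) / var(d)
  expect_equal(fit$slope, beta, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_error(riskDRegression(rep(2.5, 3), r), "constant")
  expect_error(riskDRegression(d[1:2], r[1:2]), "at least 3")
})

test_that("monotone group D with monotone risks yields a strong fit", {
  d <- seq(2.50, 2.74, length.out = 6)
  risk <- seq(0.02, 0.07, length.out = 6) +
    withr::with_seed(2, rnorm(6, 0, 0.002))
  expect_gte(riskDRegression(d, risk)$r_squared, 0.9)
})

test_that("cohort risk populations follow the severity gradient", {
  co <- generateCohort(cohortConfig(seed = 11))
  rk <- cohortRisk(co)
  rk <- rk[match(diagnosticGroups(), rk$label), ]
  expect_gt(rk$risk[rk$label == "AA"], rk$risk[rk$label == "control"])
  expect_true(all(rk$risk >= 0 & rk$risk <= 1))
  rkh <- cohortRisk(co, by = "group_history")
  expect_gt(rkh$risk[rkh$label == "control/high"],
            rkh$risk[rkh$label == "control/none"])
  expect_gt(rkh$risk[rkh$label == "AA/high"],
            rkh$risk[rkh$label == "AA/none"])
})
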