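test_that("the default design reproduces the study structure", {
  co <- generateCohort(cohortConfig(seed = 3))
  pat <- cohortPatients(co)
  expect_equal(nrow(pat), 256)
  expect_equal(as.vector(table(pat$group)[diagnosticGroups()]),
               c(135, 13, 15, 74, 9, 10))
  expect_gte(nrow(cohortCells(co)), 30 * 256)
  expect_true(all(table(cohortCells(co)$patient_id) == 31))
  expect_true(all(pat$history %in% c("none", "low", "high")))
  # patient mean_d consistent with cell values
  m <- tapply(cohortCells(co)$d_truth, cohortCells(co)$patient_id, mean)
  expect_equal(as.numeric(m[pat$patient_id]), pat$mean_d,
               tolerance = 1e-12)
})

test_that("with all variance sources off, truth D equals the group mean", {
  cfg <- cohortConfig(group_sizes = c(control = 4, AA = 4),
                      group_mean_D = c(control = 2.5, AA = 2.6),
                      between_patient_sd = 0, within_patient_sd = 0,
                      age_slope = 0,
                      history_effect = c(none = 0, low = 0, high = 0),
                      seed = 5)
  co <- generateCohort(cfg)
  cells <- cohortCells(co)
  grp <- cohortPatients(co)$group[match(cells$patient_id,
                                        cohortPatients(co)$patient_id)]
  expect_equal(cells$d_truth,
               unname(c(control = 2.5, AA = 2.6)[grp]))
})

test_that("generated group means follow the configured ordering", {
  cfg <- cohortConfig(age_slope = 0,
                      history_effect = c(none = 0, low = 0, high = 0),
                      between_patient_sd = 0.02, seed = 8)
  pat <- cohortPatients(generateCohort(cfg))
  gm <- tapply(pat$mean_d, pat$group, mean)[diagnosticGroups()]
  expect_true(all(diff(gm) > 0))
})

test_that("the configured age slope is recovered by OLS on the truth", {
  cfg <- cohortConfig(group_sizes = c(control = 135),
                      group_mean_D = c(control = 2.5),
                      between_patient_sd = 0, within_patient_sd = 0.02,
                      age_slope = -0.008, seed = 21)
  co <- generateCohort(cfg)
  fit <- ageRegression(co, adjust = "none")
  expect_lt(abs(fit$slope - (-0.008)), 0.002)
  # closed-form OLS oracle
  pat <- cohortPatients(co)
  beta <- cov(pat$age, pat$mean_d) / var(pat$age)
  expect_equal(fit$slope, beta, tolerance = 1e-12)
})

test_that("identical config and seed give identical manifests", {
  cfg <- cohortConfig(group_sizes = c(control = 3, AA = 3),
                      group_mean_D = c(control = 2.5, AA = 2.6),
                      seed = 77)
  d1 <- file.path(tempdir(), "coh1"); d2 <- file.path(tempdir(), "coh2")
  generateCohort(cfg, out_dir = d1)
  generateCohort(cfg, out_dir = d2)
  for (f in c("patients.csv", "cells.csv", "config.yaml"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("invalid configurations are rejected", {
  expect_error(cohortConfig(group_sizes = numeric()), "empty")
  expect_error(cohortConfig(
    group_sizes = c(control = 5, AA = 5),
    group_mean_D = c(control = 2.6, AA = 2.5)), "severity")
  expect_error(cohortConfig(cells_per_patient = 30), "30-cell")
})

test_that("materialized cells carry masks and truth maps", {
  cfg <- cohortConfig(group_sizes = c(control = 2, AA = 2),
                      group_mean_D = c(control = 2.4, AA = 2.7),
                      cells_per_patient = 31, seed = 13)
  co <- generateCohort(cfg, materialize = "dmaps", frame = c(32, 32))
  expect_length(cohortImages(co), nrow(cohortCells(co)))
  dm <- cellDMap(co, 1)
  expect_s4_class(dm, "DMap")
  expect_gt(maskArea(dm@mask), 30)
  inm <- imageValues(dm)[imageValues(dm@mask)]
  expect_lt(abs(mean(inm) - cohortCells(co)$d_truth[1]), 0.1)
})
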