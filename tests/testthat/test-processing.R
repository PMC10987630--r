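test_that("reference normalization is the stated pointwise division", {
  lam <- seq(500, 520, by = 2)
  ref <- seq(1, 2, length.out = length(lam))
  raw <- array(rep(ref, each = 6 * 5), c(6, 5, length(lam)))
  cube <- normalizeByReference(raw, ref, lambda_grid = lam)
  expect_equal(cubeData(cube), array(1, c(6, 5, length(lam))))
  half <- normalizeByReference(raw, 2 * ref, lambda_grid = lam)
  expect_equal(cubeData(half), array(0.5, c(6, 5, length(lam))))
  expect_error(normalizeByReference(raw, ref[-1]), "lambda axes differ")
  expect_error(normalizeByReference(raw, ref * 0), "strictly positive")
})

test_that("Sigma of a spectrally constant cube is zero", {
  lam <- seq(500, 700, by = 2)
  cube <- new("SpectralCube", data = array(1.3, c(4, 4, length(lam))),
              lambda_grid = lam, pixel_pitch = 150)
  expect_equal(max(imageValues(computeSigmaMap(cube))), 0)
})

test_that("Sigma of a sinusoid matches the closed form on the 101-point grid", {
  lam <- seq(500, 700, by = 2)     # the printed acquisition grid
  spec <- 1 + 0.1 * sin(2 * pi * (lam - 500) / 40)
  cube <- new("SpectralCube",
              data = aperm(array(spec, c(length(lam), 3, 3)), c(2, 3, 1)),
              lambda_grid = lam, pixel_pitch = 150)
  sig0 <- imageValues(computeSigmaMap(cube, detrend_order = 0))[1, 1]
  expect_lt(abs(sig0 - 0.1 / sqrt(2)) / (0.1 / sqrt(2)), 0.02)
  # oracle: direct numerical standard deviation of the sampled sinusoid
  expect_equal(sig0, sd(spec), tolerance = 1e-12)
})

test_that("order-1 detrending removes a linear tilt exactly", {
  lam <- seq(500, 700, by = 2)
  base <- 1 + 0.05 * sin(2 * pi * (lam - 500) / 30)
  tilt <- 0.002 * (lam - 600)
  mk <- function(s) new("SpectralCube",
                        data = aperm(array(s, c(length(lam), 2, 2)),
                                     c(2, 3, 1)),
                        lambda_grid = lam, pixel_pitch = 150)
  s_plain <- imageValues(computeSigmaMap(mk(base), detrend_order = 1))
  s_tilt <- imageValues(computeSigmaMap(mk(base + tilt),
                                        detrend_order = 1))
  expect_equal(s_plain, s_tilt, tolerance = 1e-10)
})

test_that("non-finite spectra are reported with their pixel", {
  lam <- seq(500, 510, by = 2)
  arr <- array(1, c(3, 4, length(lam)))
  arr[2, 3, 1] <- NA
  cube <- new("SpectralCube", data = array(1, c(3, 4, length(lam))),
              lambda_grid = lam, pixel_pitch = 150)
  cube@data <- arr                # bypass validity to test the guard
  expect_error(computeSigmaMap(cube), "pixel \\(2, 3\\)")
})

test_that("segmentation recovers generator ellipses with Dice >= 0.95", {
  for (s in 1:20) {
    nuc <- synthesizeNucleusImage(
      2.4 + 0.02 * s, calib = defaultCalib, frame = c(48, 48),
      morphology = list(semiaxes = c(12 + s %% 5, 9 + s %% 3),
                        angle = s / 7),
      jitter_sd = 0.05, noise_sd = 0.002, seed = s)
    masks <- segmentNuclei(imageValues(computeSigmaMap(nuc$cube)),
                           min_area = 30)
    expect_length(masks, 1)
    expect_gte(diceCoefficient(masks[[1]], nuc$mask), 0.95)
  }
})

test_that("blank images yield no masks and two ellipses yield two", {
  expect_identical(segmentNuclei(matrix(0.5, 30, 30)), list())
  img <- matrix(0, 60, 60)
  img[imageValues(ellipseMask(c(60, 60), center = c(15, 15),
                              semiaxes = c(8, 6)))] <- 1
  img[imageValues(ellipseMask(c(60, 60), center = c(45, 45),
                              semiaxes = c(9, 7)))] <- 1
  masks <- segmentNuclei(img, min_area = 20)
  expect_length(masks, 2)
  expect_gte(maskArea(masks[[1]]), maskArea(masks[[2]]))
})

test_that("inversion is exact at calibration grid points", {
  ix <- c(5, 30, 80)
  sig <- new("SigmaMap",
             values = matrix(sigmaOfD(defaultCalib)[ix], 1, 3),
             provenance = "test")
  dm <- estimateDMap(sig, defaultCalib, fullMask(1, 3))
  expect_equal(as.vector(imageValues(dm)), dGrid(defaultCalib)[ix],
               tolerance = 1e-12)
  expect_equal(clampFraction(dm), 0)
})

test_that("out-of-range Sigma clamps to grid ends and is flagged", {
  hi <- max(sigmaOfD(defaultCalib)) * 1.5
  lo <- min(sigmaOfD(defaultCalib)) * 0.5
  sig <- new("SigmaMap", values = matrix(c(hi, lo, hi, hi), 2, 2),
             provenance = "test")
  expect_warning(dm <- estimateDMap(sig, defaultCalib, fullMask(2, 2)),
                 "clamped")
  expect_equal(clampFraction(dm), 1)
  expect_error(nuclearAverageD(dm), "clamped")
})

test_that("noiseless round trips recover D to 0.01", {
  for (D in c(2.1, 2.4, 2.7)) {
    cube <- simulateSpectralCube(matrix(D, 40, 40), defaultInstrument,
                                 defaultCalib, noise_sd = 0, seed = 2)
    dhat <- nuclearAverageD(estimateDMap(computeSigmaMap(cube),
                                         defaultCalib, fullMask(40)))
    expect_lt(abs(dhat - D), 0.01)
  }
})

test_that("noisy round trips recover D to 0.05 over a 10^4-pixel nucleus", {
  for (s in 1:5) {
    cube <- simulateSpectralCube(matrix(2.6, 100, 100),
                                 defaultInstrument, defaultCalib,
                                 noise_sd = 0.01, seed = s)
    dhat <- nuclearAverageD(estimateDMap(computeSigmaMap(cube),
                                         defaultCalib, fullMask(100),
                                         noise_sd = 0.01))
    expect_lt(abs(dhat - 2.6), 0.05)
  }
})

test_that("D is non-decreasing in Sigma through the inversion", {
  s_seq <- seq(min(sigmaOfD(defaultCalib)), max(sigmaOfD(defaultCalib)),
               length.out = 50)
  sig <- new("SigmaMap", values = matrix(s_seq, 1), provenance = "test")
  d <- as.vector(imageValues(estimateDMap(sig, defaultCalib,
                                          fullMask(1, 50))))
  expect_true(all(diff(d) >= 0))
})

test_that("masked statistics equal brute-force loops on toy maps", {
  vals <- matrix(NA_real_, 5, 5)
  mk <- matrix(FALSE, 5, 5)
  mk[2:4, 2:4] <- TRUE
  vals[mk] <- c(2.4, 2.6, 2.4, 2.6, 2.4, 2.6, 2.5, 2.5, 2.5)
  dm <- dMap <- new("DMap", values = vals,
                    mask = new("NucleusMask", values = mk),
                    clamped = matrix(FALSE, 5, 5), pixel_window = 458,
                    clamp_fraction = 0)
  acc <- 0; cnt <- 0
  for (i in 1:5) for (j in 1:5) if (mk[i, j]) {
    acc <- acc + vals[i, j]; cnt <- cnt + 1
  }
  expect_equal(nuclearAverageD(dm), acc / cnt)
  half <- matrix(c(rep(2.4, 8), rep(2.6, 8)), 4, 4)
  dm2 <- new("DMap", values = half, mask = fullMask(4),
             clamped = matrix(FALSE, 4, 4), pixel_window = 458,
             clamp_fraction = 0)
  expect_equal(nuclearAverageD(dm2), 2.5)
})

test_that("patient-level summaries follow the t interval and flag small n", {
  one <- patientAverageD(2.5)
  expect_equal(one$mean, 2.5)
  expect_true(one$below_floor)
  expect_equal(one$ci, c(-Inf, Inf))
  same <- patientAverageD(rep(2.5, 31))
  expect_equal(same$sd, 0)
  expect_equal(diff(same$ci), 0)
  expect_false(same$below_floor)
  covered <- withr::with_seed(99, vapply(1:1000, function(i) {
    ci <- patientAverageD(rnorm(31, 2.5, 0.05))$ci
    ci[1] <= 2.5 && 2.5 <= ci[2]
  }, TRUE))
  expect_gt(mean(covered), 0.93)
  expect_lt(mean(covered), 0.97)
  expect_error(patientAverageD(numeric()), "non-empty")
})
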