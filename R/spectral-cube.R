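# Shared spectral synthesis: per-pixel fluctuation processes with an exactly
# prescribed detrended standard deviation over wavelength. The raw Gaussian
# draws are projected onto the orthocomplement of the degree<=1 polynomial
# baseline and rescaled so that the order-1-detrended sample SD equals 1
# exactly; multiplying by the per-pixel Sigma then realizes the forward map
# by construction, and additive white measurement noise contributes its
# variance on top.
synthesizeCubeFromSigma <- function(sigma_mat, lambda, pixel_pitch,
                                    noise_sd = 0, seed = 1L) {
  stopIfNot(noise_sd >= 0, "'noise_sd' must be >= 0")
  n <- nrow(sigma_mat); m <- ncol(sigma_mat)
  L <- length(lambda)
  stopIfNot(L >= 4, "need at least 4 wavelength samples")
  npx <- n * m
  lam_c <- (lambda - mean(lambda)) / (diff(range(lambda)) / 2)
  Q <- qr.Q(qr(cbind(1, lam_c)))
  flat <- withSeed(seed, {
    z <- matrix(rnorm(L * npx), L, npx)
    z <- z - Q %*% crossprod(Q, z)
    scl <- sqrt(colSums(z^2) / (L - 2))
    z <- sweep(z, 2, scl, "/")
    out <- 1 + sweep(z, 2, as.vector(sigma_mat), "*")
    if (noise_sd > 0) out <- out + rnorm(L * npx, sd = noise_sd)
    out
  })
  cube <- aperm(array(flat, c(L, n, m)), c(2, 3, 1))
  new("SpectralCube", data = cube, lambda_grid = lambda,
      pixel_pitch = pixel_pitch)
}

#' Simulate a csPWS spectral cube from a density field or D map
#'
#' Synthesizes the reference-normalized interference cube corresponding to a
#' known packing-scaling configuration. Each pixel's spectrum is
#' 1 + Sigma(D, phi) * z(lambda) + noise, where z is a unit-variance
#' fluctuation process (orthogonal to a linear baseline, so the detrended
#' spectral SD reproduces the forward model exactly at zero noise) and the
#' per-pixel Sigma comes from the calibration table at the pixel's local D.
#' Spectra are synthesized as a calibrated stationary fluctuation process,
#' not by electromagnetic simulation; physical realism of the density
#' statistics is carried by \code{\link{sampleDensityField}} and tested at
#' the field-ACF level.
#'
#' @param field A \linkS4class{DensityField} (constant truth D taken from
#'   its ACF model) or a numeric matrix of per-pixel D values.
#' @param inst An \linkS4class{InstrumentModel} providing the wavelength
#'   grid.
#' @param calib A \linkS4class{CalibrationTable} covering the field's D.
#' @param noise_sd Standard deviation of additive white measurement noise.
#' @param seed Integer seed.
#' @return A \linkS4class{SpectralCube}.
#' @export
simulateSpectralCube <- function(field, inst, calib, noise_sd = 0,
                                 seed = 1L) {
  stopIfNot(is(inst, "InstrumentModel"), "'inst' must be an InstrumentModel")
  stopIfNot(is(calib, "CalibrationTable"),
            "'calib' must be a CalibrationTable")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (is(field, "DensityField")) {
    D <- field@acf_truth@D
    if (D < min(calib@D_grid) || D > max(calib@D_grid))
      stop(sprintf("calibration does not cover the field's true D (%.3f)",
                   D))
    d_mat <- matrix(D, nrow(field@values), ncol(field@values))
    pitch <- field@pixel_pitch
  } else if (is.matrix(field) && is.numeric(field)) {
    d_mat <- field
    pitch <- inst@pixel_pitch
  } else stop("'field' must be a DensityField or a numeric matrix of D")
  sigma_mat <- sigmaForward(calib, d_mat)
  synthesizeCubeFromSigma(sigma_mat, inst@lambda_grid, pitch, noise_sd,
                          seed)
}

#' Elliptical nucleus mask
#'
#' @param frame Frame dimensions c(rows, cols).
#' @param center Ellipse center in pixels (defaults to the frame center).
#' @param semiaxes Semi-axes in pixels c(a, b).
#' @param angle Rotation in radians.
#' @return A \linkS4class{NucleusMask}; errors if the ellipse does not fit
#'   inside the frame.
#' @export
ellipseMask <- function(frame, center = NULL, semiaxes = c(20, 14),
                        angle = 0) {
  if (is.null(center)) center <- (frame + 1) / 2
  a <- semiaxes[1]; b <- semiaxes[2]
  half_r <- sqrt((a * cos(angle))^2 + (b * sin(angle))^2)
  half_c <- sqrt((a * sin(angle))^2 + (b * cos(angle))^2)
  if (center[1] - half_r < 1 || center[1] + half_r > frame[1] ||
      center[2] - half_c < 1 || center[2] + half_c > frame[2])
    stop("ellipse exceeds the image frame; reduce semiaxes or recenter")
  rr <- matrix(seq_len(frame[1]), frame[1], frame[2]) - center[1]
  cc <- matrix(seq_len(frame[2]), frame[1], frame[2], byrow = TRUE) -
    center[2]
  u <- rr * cos(angle) + cc * sin(angle)
  v <- -rr * sin(angle) + cc * cos(angle)
  nucleusMask((u / a)^2 + (v / b)^2 <= 1)
}

#' Synthesize a single-nucleus csPWS image with known D
#'
#' Generates a spectral cube containing one elliptical nucleus on a clean
#' background. In-mask pixels carry truth packing scaling
#' \code{D_target}, optionally with correlated intra-nuclear jitter: the
#' jitter field is a Gaussian random field whose ACF exponent is the
#' nucleus's own D (a self-similarity assumption - pixel-scale heterogeneity
#' of D inherits the packing-domain correlation structure), so both the
#' level and the spatial texture of the resulting D map depend on D_target.
#' Background pixels fluctuate at a small fraction of the nuclear Sigma.
#'
#' @param D_target Truth packing scaling of the nucleus.
#' @param phi Chromatin volume concentration (used for a default
#'   calibration).
#' @param inst An \linkS4class{InstrumentModel}.
#' @param calib A \linkS4class{CalibrationTable}; built from \code{inst} and
#'   \code{phi} when NULL.
#' @param frame Image dimensions in pixels.
#' @param morphology List with optional center, semiaxes (px), angle (rad).
#' @param jitter_sd Intra-nuclear SD of truth D (D units); 0 for a uniform
#'   nucleus.
#' @param noise_sd White measurement noise SD.
#' @param background_sigma_frac Background fluctuation as a fraction of the
#'   nuclear Sigma.
#' @param seed Integer seed; morphology is seed-independent.
#' @return List with elements \code{cube} (\linkS4class{SpectralCube}),
#'   \code{mask} (\linkS4class{NucleusMask}), and \code{d_truth} (matrix, NA
#'   outside the nucleus).
#' @export
synthesizeNucleusImage <- function(D_target, phi = 0.35,
                                   inst = instrumentModel(), calib = NULL,
                                   frame = c(64, 64),
                                   morphology = list(),
                                   jitter_sd = 0, noise_sd = 0,
                                   background_sigma_frac = 0.02,
                                   seed = 1L) {
  if (is.null(calib)) calib <- buildCalibration(inst, phi)
  mask <- ellipseMask(frame,
                      center = morphology$center,
                      semiaxes = morphology$semiaxes %||% c(20, 14),
                      angle = morphology$angle %||% 0)
  d_truth <- matrix(NA_real_, frame[1], frame[2])
  d_in <- rep(D_target, sum(mask@values))
  if (jitter_sd > 0) {
    pitch <- inst@pixel_pitch
    jac <- acfModel(D = min(max(D_target, 1.05), 3), phi = phi,
                    r_min = pitch, r_max = min(frame) * pitch / 6)
    jf <- sampleDensityField(jac, shape = frame, pitch = pitch,
                             seed = childSeed(seed, 1))
    j <- jf@values
    j <- (j - mean(j)) / sd(j)
    d_in <- D_target + jitter_sd * j[mask@values]
  }
  d_truth[mask@values] <- d_in
  sigma_mat <- matrix(background_sigma_frac *
                        sigmaForward(calib, D_target),
                      frame[1], frame[2])
  sigma_mat[mask@values] <- sigmaForward(calib, d_in)
  cube <- synthesizeCubeFromSigma(sigma_mat, inst@lambda_grid,
                                  inst@pixel_pitch, noise_sd,
                                  childSeed(seed, 2))
  list(cube = cube, mask = mask, d_truth = d_truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
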