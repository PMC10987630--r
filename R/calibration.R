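#' Build the Sigma(D) forward-model calibration table
#'
#' The spectral fluctuation statistic Sigma measured by csPWS reflects the
#' chromatin density ACF integrated against the coherence volume of the
#' instrument. The forward model used here is
#' \deqn{\Sigma^2(D) = A\,\phi(1-\phi)\int_{r_{min}}^{r_{max}}
#'   B_D(r)\, S(r)\, r\, dr \times \ell_z}
#' with \eqn{B_D(r) = (r/r_{min})^{D-3}} the windowed power-law ACF
#' (normalized at the lower sensitivity bound so Sigma increases with D),
#' \eqn{S(r) = \exp(-r^2 / 2\ell_t^2)} a separable Gaussian coherence kernel
#' with transverse scale \eqn{\ell_t} (coherence_xy) and axial extent
#' \eqn{\ell_z} (depth_of_field), and A an instrument proportionality
#' constant. When \code{A} is NULL it is set so that
#' \code{Sigma(D_ref) = sigma_ref}, which defines the package's internal
#' Sigma scale; absolute D is therefore self-consistently defined by this
#' forward model rather than cross-calibrated to any physical instrument.
#'
#' The table must come out strictly increasing in D; otherwise construction
#' aborts with advice to review the grid or kernel.
#'
#' @param inst An \linkS4class{InstrumentModel}.
#' @param phi Chromatin volume concentration in (0, 1).
#' @param D_grid Ascending packing-scaling grid within (1, 3].
#' @param A Instrument constant scaling Sigma^2; NULL to normalize at
#'   \code{D_ref}.
#' @param sigma_ref,D_ref Normalization point used when A is NULL.
#' @param r_min,r_max Sensitivity window in nm (23-334 by default).
#' @param rel_tol Relative tolerance of the quadrature.
#' @return A \linkS4class{CalibrationTable}.
#' @examples
#' calib <- buildCalibration(instrumentModel(), phi = 0.35)
#' all(diff(sigmaOfD(calib)) > 0)
#' @export
buildCalibration <- function(inst, phi = 0.35,
                             D_grid = seq(2, 3, by = 0.01), A = NULL,
                             sigma_ref = 0.02, D_ref = 2.5,
                             r_min = 23, r_max = 334, rel_tol = 1e-8) {
  stopIfNot(is(inst, "InstrumentModel"), "'inst' must be an InstrumentModel")
  validObject(inst)
  stopIfNot(phi > 0 && phi < 1, "'phi' must lie in (0, 1)")
  stopIfNot(all(D_grid > 1 & D_grid <= 3), "D_grid must lie within (1, 3]")
  stopIfNot(all(diff(D_grid) > 0), "D_grid must be ascending")
  lt <- inst@coherence_xy
  raw <- vapply(D_grid, function(D)
    sigmaIntegral(D, r_min, r_max, lt, rel_tol), 0) *
    phi * (1 - phi) * inst@depth_of_field
  if (is.null(A)) {
    ref <- sigmaIntegral(D_ref, r_min, r_max, lt, rel_tol) *
      phi * (1 - phi) * inst@depth_of_field
    A <- sigma_ref^2 / ref
  }
  sig <- sqrt(A * raw)
  if (any(diff(sig) <= 0))
    stop(paste("Sigma(D) is not strictly increasing for this instrument;",
               "review the D grid and coherence kernel"))
  new("CalibrationTable", D_grid = D_grid, sigma_of_D = sig, phi = phi,
      A = A, r_min = r_min, r_max = r_max, coherence_xy = lt,
      depth_of_field = inst@depth_of_field,
      instrument = sprintf("NA%.2f/%.2f", inst@na_illumination,
                           inst@na_collection))
}

# Radial part of the forward integral: int B_D(r) S(r) r dr over the window.
sigmaIntegral <- function(D, r_min, r_max, lt, rel_tol = 1e-8) {
  integrate(function(r) (r / r_min)^(D - 3) * exp(-r^2 / (2 * lt^2)) * r,
            lower = r_min, upper = r_max, rel.tol = rel_tol)$value
}

#' Forward-map packing scaling to Sigma
#'
#' Linear interpolation of the calibration table at the requested D values
#' (clamped to the table ends).
#'
#' @param calib A \linkS4class{CalibrationTable}.
#' @param D Numeric vector (or matrix) of packing scaling values.
#' @return Sigma values with the shape of \code{D}.
#' @export
sigmaForward <- function(calib, D) {
  stopIfNot(is(calib, "CalibrationTable"),
            "'calib' must be a CalibrationTable")
  out <- approx(calib@D_grid, calib@sigma_of_D, xout = as.vector(D),
                rule = 2)$y
  if (is.matrix(D)) out <- matrix(out, nrow(D), ncol(D))
  out
}

#' Invert a Sigma map to a packing-scaling map
#'
#' Monotone inversion of the calibration table: each in-mask pixel's Sigma is
#' mapped to D by linear interpolation between table grid points. Sigma
#' values outside the tabulated range are clamped to the nearest grid end,
#' never extrapolated; clamped pixels are flagged and excluded from
#' \code{\link{nuclearAverageD}}. If more than half of the in-mask pixels
#' clamp, a warning-level diagnostic is attached (and emitted).
#'
#' Because white measurement noise adds its variance to the spectral
#' fluctuation, a known noise floor can be supplied: the map is inverted
#' from \eqn{\sqrt{\max(\Sigma^2 - noise\_sd^2, 0)}}.
#'
#' @param sigma A \linkS4class{SigmaMap}.
#' @param calib A \linkS4class{CalibrationTable}.
#' @param mask A \linkS4class{NucleusMask} of the same shape.
#' @param noise_sd Known white-noise standard deviation subtracted in
#'   quadrature before inversion (0 = no correction).
#' @return A \linkS4class{DMap} (NA outside the mask).
#' @export
estimateDMap <- function(sigma, calib, mask, noise_sd = 0) {
  stopIfNot(is(sigma, "SigmaMap"), "'sigma' must be a SigmaMap")
  stopIfNot(is(calib, "CalibrationTable"),
            "'calib' must be a CalibrationTable")
  stopIfNot(is(mask, "NucleusMask"), "'mask' must be a NucleusMask")
  sv <- sigma@values
  stopIfNot(identical(dim(sv), dim(mask@values)),
            "sigma and mask shapes differ")
  vals <- matrix(NA_real_, nrow(sv), ncol(sv))
  clamped <- matrix(FALSE, nrow(sv), ncol(sv))
  stopIfNot(noise_sd >= 0, "'noise_sd' must be >= 0")
  inm <- mask@values
  s_in <- sv[inm]
  if (noise_sd > 0) s_in <- sqrt(pmax(s_in^2 - noise_sd^2, 0))
  lo <- min(calib@sigma_of_D); hi <- max(calib@sigma_of_D)
  d_in <- approx(calib@sigma_of_D, calib@D_grid, xout = pmin(pmax(s_in, lo),
                                                             hi))$y
  vals[inm] <- d_in
  clamped[inm] <- s_in < lo | s_in > hi
  cf <- sum(clamped[inm]) / sum(inm)
  if (cf > 0.5)
    warning(sprintf(
      "%.0f%% of in-mask pixels fell outside the calibration Sigma range and were clamped",
      100 * cf))
  dMap(vals, mask, clamped = clamped, pixel_window = calib@coherence_xy,
       clamp_fraction = cf)
}

#' Nuclear-average packing scaling
#'
#' Arithmetic mean of D over in-mask pixels that were not clamped during
#' inversion.
#'
#' @param dmap A \linkS4class{DMap}.
#' @return The nuclear-mean D (scalar).
#' @export
nuclearAverageD <- function(dmap) {
  stopIfNot(is(dmap, "DMap"), "'dmap' must be a DMap")
  use <- dmap@mask@values & !dmap@clamped
  if (!any(use))
    stop("all in-mask pixels were clamped; no usable D values")
  mean(dmap@values[use])
}

#' Patient-level summary of nuclear-mean D
#'
#' Mean, sample SD, and t-based confidence interval of a patient's per-cell
#' nuclear-mean D values. Patients at or below the 30-cell inclusion floor
#' are flagged.
#'
#' @param cell_values Numeric vector of per-cell nuclear-mean D (n >= 1).
#' @param conf_level Confidence level (default 0.95).
#' @return List with mean, sd, n, ci (length 2), and below_floor flag.
#' @export
patientAverageD <- function(cell_values, conf_level = 0.95) {
  stopIfNot(length(cell_values) >= 1 && is.numeric(cell_values),
            "'cell_values' must be a non-empty numeric vector")
  n <- length(cell_values)
  m <- mean(cell_values)
  if (n == 1) {
    return(list(mean = m, sd = NA_real_, n = 1L, ci = c(-Inf, Inf),
                below_floor = TRUE))
  }
  s <- sd(cell_values)
  half <- qt(1 - (1 - conf_level) / 2, df = n - 1) * s / sqrt(n)
  list(mean = m, sd = s, n = as.integer(n), ci = c(m - half, m + half),
       below_floor = n <= 30)
}
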