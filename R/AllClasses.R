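#' Chromatin autocorrelation model
#'
#' Parameterizes the spatial autocorrelation function (ACF) \eqn{B(r)} of
#' chromatin mass density inside packing domains. Within the sensitivity
#' window \eqn{[r_{min}, r_{max}]} the ACF follows the mass-fractal power law
#' \eqn{B(r) \propto r^{D-3}}, where \eqn{D} is the chromatin packing scaling
#' exponent (\eqn{N_f \propto r^D}). Below \code{r_min} the ACF is flat and
#' beyond \code{r_max} it is rolled off smoothly to zero (see
#' \code{\link{acfProfile}}).
#'
#' @slot D Packing scaling exponent, in (1, 3].
#' @slot phi Chromatin volume concentration (fraction of nuclear volume
#'   occupied by chromatin), in (0, 1).
#' @slot Nf Genomic size of a packing domain, in monomers (dimensionless).
#' @slot r_min,r_max Lower/upper bound of the instrument sensitivity window
#'   in nm (defaults 23 and 334).
#' @slot Db Shape parameter of B(r); stored for completeness and treated as
#'   synonymous with the power-law exponent parameterization.
#' @export
setClass("ACFModel",
  representation(D = "numeric", phi = "numeric", Nf = "numeric",
                 r_min = "numeric", r_max = "numeric", Db = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@D) != 1 || !is.finite(object@D) ||
        object@D <= 1 || object@D > 3)
      msg <- c(msg, "D must be a single value in (1, 3]")
    if (length(object@phi) != 1 || !is.finite(object@phi) ||
        object@phi <= 0 || object@phi >= 1)
      msg <- c(msg, "phi must be a single value in (0, 1)")
    if (!(object@r_min > 0 && object@r_max > object@r_min))
      msg <- c(msg, "need 0 < r_min < r_max")
    if (length(msg)) msg else TRUE
  })

#' @param D,phi,Nf,r_min,r_max,Db See the corresponding slots.
#' @rdname ACFModel-class
#' @export
acfModel <- function(D, phi = 0.35, Nf = 4e5, r_min = 23, r_max = 334,
                     Db = D) {
  new("ACFModel", D = D, phi = phi, Nf = Nf, r_min = r_min, r_max = r_max,
      Db = Db)
}

#' csPWS instrument model
#'
#' Optical and sampling parameters of the chromatin-sensitive partial wave
#' spectroscopic (csPWS) microscope: numerical apertures of illumination and
#' collection, the acquired wavelength grid (500-700 nm in 2 nm steps by
#' default, 101 planes), the transverse spatial-coherence extent (458 nm) and
#' axial depth of field (~3 um) defining the coherence volume, the background
#' refractive index, the refraction increment alpha relating refractive index
#' to local macromolecular density (n(r) = n_media + alpha * rho(r)), and the
#' physical pixel pitch of the image plane.
#'
#' @slot na_illumination,na_collection Numerical apertures (0.6 / 0.8).
#' @slot lambda_grid Wavelength grid in nm, strictly increasing.
#' @slot coherence_xy Transverse coherence extent in nm.
#' @slot depth_of_field Axial extent of the coherence volume in nm.
#' @slot n_media Background refractive index.
#' @slot alpha Refraction increment per unit density.
#' @slot pixel_pitch Physical size of one image pixel in nm.
#' @export
setClass("InstrumentModel",
  representation(na_illumination = "numeric", na_collection = "numeric",
                 lambda_grid = "numeric", coherence_xy = "numeric",
                 depth_of_field = "numeric", n_media = "numeric",
                 alpha = "numeric", pixel_pitch = "numeric"),
  validity = function(object) {
    msg <- character()
    if (any(diff(object@lambda_grid) <= 0))
      msg <- c(msg, "lambda_grid must be strictly increasing")
    ext <- c(object@coherence_xy, object@depth_of_field, object@pixel_pitch)
    if (any(!is.finite(ext)) || any(ext <= 0))
      msg <- c(msg, "all physical extents must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @param na_illumination,na_collection,lambda_grid,coherence_xy,depth_of_field,n_media,alpha,pixel_pitch
#'   See the corresponding slots.
#' @rdname InstrumentModel-class
#' @export
instrumentModel <- function(na_illumination = 0.6, na_collection = 0.8,
                            lambda_grid = seq(500, 700, by = 2),
                            coherence_xy = 458, depth_of_field = 3000,
                            n_media = 1.337, alpha = 0.18,
                            pixel_pitch = 150) {
  new("InstrumentModel", na_illumination = na_illumination,
      na_collection = na_collection, lambda_grid = lambda_grid,
      coherence_xy = coherence_xy, depth_of_field = depth_of_field,
      n_media = n_media, alpha = alpha, pixel_pitch = pixel_pitch)
}

#' Stationary mass-density field with known packing scaling
#'
#' A zero-mean Gaussian random field realizing a target chromatin density ACF
#' whose log-log slope over the sensitivity window equals D - 3. Represents
#' the in-plane projection of local macromolecular density rho(r) through the
#' depth of field.
#'
#' @slot values Numeric matrix of density values (arbitrary units).
#' @slot pixel_pitch Grid spacing in nm.
#' @slot acf_truth The \linkS4class{ACFModel} used to generate the field.
#' @slot seed Integer seed the field was drawn with.
#' @export
setClass("DensityField",
  representation(values = "matrix", pixel_pitch = "numeric",
                 acf_truth = "ACFModel", seed = "numeric"),
  validity = function(object) {
    if (!all(is.finite(object@values))) return("values must be finite")
    if (object@pixel_pitch <= 0) return("pixel_pitch must be > 0")
    TRUE
  })

#' Reference-normalized spectral image cube
#'
#' The raw csPWS measurement: a (x, y, lambda) cube of back-scattered
#' reflectance divided by the reference wave acquired at a blank region, so
#' that values fluctuate around 1.
#'
#' @slot data 3D numeric array (x, y, lambda).
#' @slot lambda_grid Wavelengths in nm; length matches dim(data)[3].
#' @slot pixel_pitch Physical pixel size in nm.
#' @export
setClass("SpectralCube",
  representation(data = "array", lambda_grid = "numeric",
                 pixel_pitch = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@data)
    if (length(d) != 3)
      msg <- c(msg, "data must be a 3D (x, y, lambda) array")
    else if (d[3] != length(object@lambda_grid))
      msg <- c(msg, sprintf(
        "lambda axis length (%d) does not match lambda_grid length (%d)",
        d[3], length(object@lambda_grid)))
    if (any(!is.finite(object@data)) || any(object@data <= 0))
      msg <- c(msg, "normalized reflectance must be finite and > 0")
    if (length(msg)) msg else TRUE
  })

#' Binary nucleus mask
#'
#' Single connected region marking in-nucleus pixels of one segmented cell.
#'
#' @slot values Logical matrix, TRUE inside the nucleus.
#' @export
setClass("NucleusMask",
  representation(values = "matrix"),
  validity = function(object) {
    if (!is.logical(object@values)) return("mask values must be logical")
    if (!any(object@values)) return("mask is empty")
    lab <- EBImage::bwlabel(EBImage::Image(object@values * 1))
    if (max(lab) > 1) return("mask must be a single connected component")
    TRUE
  })

nucleusMask <- function(values) new("NucleusMask", values = values)

#' Per-pixel spectral fluctuation map
#'
#' Sigma, the standard deviation over wavelength of the (detrended)
#' normalized interference spectrum at each pixel; the measured statistic
#' from which packing scaling D is inverted.
#'
#' @slot values Numeric matrix of Sigma values, all >= 0.
#' @slot provenance Identifier of the source cube.
#' @export
setClass("SigmaMap",
  representation(values = "matrix", provenance = "character"),
  validity = function(object) {
    if (any(!is.finite(object@values)) || any(object@values < 0))
      return("Sigma must be finite and >= 0 everywhere")
    TRUE
  })

#' Sigma-to-D calibration table
#'
#' Tabulated forward model Sigma(D) for a given instrument and chromatin
#' volume concentration phi, built by \code{\link{buildCalibration}}. The
#' table must be strictly monotone in D so that it can be inverted.
#'
#' @slot D_grid Ascending D values in (1, 3].
#' @slot sigma_of_D Sigma at each grid point, strictly increasing.
#' @slot phi Chromatin volume concentration assumed.
#' @slot A Instrument proportionality constant (Sigma^2 scale).
#' @slot r_min,r_max Sensitivity window in nm.
#' @slot coherence_xy,depth_of_field Coherence-kernel scales in nm.
#' @slot instrument Identifier of the instrument model used.
#' @export
setClass("CalibrationTable",
  representation(D_grid = "numeric", sigma_of_D = "numeric", phi = "numeric",
                 A = "numeric", r_min = "numeric", r_max = "numeric",
                 coherence_xy = "numeric", depth_of_field = "numeric",
                 instrument = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@D_grid) != length(object@sigma_of_D))
      msg <- c(msg, "D_grid and sigma_of_D lengths differ")
    if (any(diff(object@D_grid) <= 0))
      msg <- c(msg, "D_grid must be strictly ascending")
    if (any(object@D_grid <= 1) || any(object@D_grid > 3))
      msg <- c(msg, "D_grid must lie within (1, 3]")
    if (any(diff(object@sigma_of_D) <= 0))
      msg <- c(msg, "sigma_of_D must be strictly monotone increasing in D")
    if (length(msg)) msg else TRUE
  })

#' Per-pixel packing scaling map
#'
#' Packing scaling D estimated for each in-nucleus pixel (NA outside the
#' mask). Each pixel summarizes chromatin packing statistics within the
#' coherence area (458 x 458 nm^2 by default).
#'
#' @slot values Numeric matrix; NA outside the nucleus.
#' @slot mask The \linkS4class{NucleusMask} the map was estimated on.
#' @slot clamped Logical matrix marking pixels whose Sigma fell outside the
#'   calibration range and were clamped to a grid end.
#' @slot pixel_window Physical side of the per-pixel coherence area in nm.
#' @slot clamp_fraction Fraction of in-mask pixels clamped.
#' @export
setClass("DMap",
  representation(values = "matrix", mask = "NucleusMask",
                 clamped = "matrix", pixel_window = "numeric",
                 clamp_fraction = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@values), dim(object@mask@values)))
      msg <- c(msg, "values and mask shapes differ")
    if (object@pixel_window <= 0)
      msg <- c(msg, "pixel_window must be > 0")
    inm <- object@values[object@mask@values]
    if (any(!is.finite(inm)))
      msg <- c(msg, "in-mask D values must be finite")
    if (length(msg)) msg else TRUE
  })

dMap <- function(values, mask, clamped = NULL, pixel_window = 458,
                 clamp_fraction = 0) {
  if (is.null(clamped))
    clamped <- matrix(FALSE, nrow(values), ncol(values))
  new("DMap", values = values, mask = mask, clamped = clamped,
      pixel_window = pixel_window, clamp_fraction = clamp_fraction)
}

#' Synthetic cohort configuration
#'
#' Study-design parameters of the synthetic csPWS cohort generator: group
#' sizes and group-mean nuclear D (ordered by severity), between-patient and
#' within-patient (cell-level) standard deviations of D, cells per patient
#' (> 30, the inclusion floor), the age regression coefficient of D, and
#' per-group demographics and colonoscopy-history models.
#'
#' @slot group_sizes Named integer vector over \code{\link{diagnosticGroups}}.
#' @slot group_mean_D Named numeric vector, strictly increasing in severity
#'   order.
#' @slot between_patient_sd,within_patient_sd D units.
#' @slot cells_per_patient Cells imaged per patient (> 30).
#' @slot age_slope D units per year of age (default -0.008).
#' @slot demographics Per-group list with age_mean, age_sd, age_range,
#'   p_female, p_smoking, p_drinking.
#' @slot history_probs Matrix (group x \{none, low, high\}) of history-category
#'   probabilities; rows sum to 1.
#' @slot history_effect Named additive shift of patient D per history
#'   category (none/low/high): mucosa-wide chromatin alterations track past
#'   findings as well as current ones.
#' @slot p_prior_cancer Probability that a high-risk history reflects prior
#'   cancer rather than prior advanced adenoma.
#' @slot intra_nuclear_jitter Pixel-level D heterogeneity inside one nucleus
#'   (D units), realized as a correlated field; see
#'   \code{\link{synthesizeNucleusImage}}.
#' @slot seed Master seed for the cohort.
#' @export
setClass("CohortConfig",
  representation(group_sizes = "numeric", group_mean_D = "numeric",
                 between_patient_sd = "numeric",
                 within_patient_sd = "numeric",
                 cells_per_patient = "numeric", age_slope = "numeric",
                 demographics = "list", history_probs = "matrix",
                 history_effect = "numeric", p_prior_cancer = "numeric",
                 intra_nuclear_jitter = "numeric", seed = "numeric"),
  validity = function(object) {
    msg <- character()
    g <- names(object@group_sizes)
    if (length(object@group_sizes) == 0 || sum(object@group_sizes) == 0)
      msg <- c(msg, "group_sizes is empty")
    if (!all(g %in% diagnosticGroups()))
      msg <- c(msg, "group_sizes names must come from diagnosticGroups()")
    md <- object@group_mean_D[g]
    if (any(is.na(md)))
      msg <- c(msg, "group_mean_D must cover every group in group_sizes")
    ord <- intersect(diagnosticGroups(), g)
    if (length(ord) > 1 && any(diff(object@group_mean_D[ord]) <= 0))
      msg <- c(msg, paste("group_mean_D must increase along the severity",
                          "ordering control < DA < NDA < AA < HNPCC < cancer"))
    if (object@cells_per_patient <= 30)
      msg <- c(msg, "cells_per_patient must exceed the 30-cell inclusion floor")
    if (any(object@history_probs < 0) ||
        any(abs(rowSums(object@history_probs) - 1) > 1e-8))
      msg <- c(msg, "history_probs rows must be probabilities summing to 1")
    if (!all(historyCategories() %in% names(object@history_effect)))
      msg <- c(msg, "history_effect needs entries none, low, high")
    if (length(msg)) msg else TRUE
  })

#' Synthetic cohort
#'
#' Patient- and cell-level tables of a generated cohort, plus optional
#' materialized per-cell images.
#'
#' @slot patients data.frame with one row per patient: patient_id, group,
#'   age, sex, smoking, drinking, history, prior_cancer, mean_d.
#' @slot cells data.frame with one row per cell: patient_id, cell, d_truth.
#' @slot config The \linkS4class{CohortConfig} used.
#' @slot images List of per-cell image payloads (possibly empty), parallel to
#'   rows of \code{cells} when materialized.
#' @export
setClass("Cohort",
  representation(patients = "data.frame", cells = "data.frame",
                 config = "CohortConfig", images = "list"),
  validity = function(object) {
    msg <- character()
    need <- c("patient_id", "group", "age", "sex", "smoking", "drinking",
              "history", "prior_cancer", "mean_d")
    if (!all(need %in% names(object@patients)))
      msg <- c(msg, paste("patients lacks columns:",
                          paste(setdiff(need, names(object@patients)),
                                collapse = ", ")))
    if (!all(c("patient_id", "cell", "d_truth") %in% names(object@cells)))
      msg <- c(msg, "cells must have patient_id, cell, d_truth")
    if (length(msg)) msg else TRUE
  })

#' Five-year CRC risk-model parameters
#'
#' Inputs of the cumulative 5-year colorectal-cancer risk model. The numeric
#' rates are literature-derived quantities that are study configuration, not
#' package estimates; the defaults are documented placeholders of plausible
#' magnitude and every analysis should supply its own values.
#'
#' @slot annual_aa_to_crc Named annual probabilities of progression from
#'   advanced adenoma to CRC by stratum: male_lt80, male_ge80, female_lt80,
#'   female_ge80 (age boundary fixed at 80 years).
#' @slot aa_r Named cumulative probabilities of developing a future advanced
#'   adenoma per history category (none, low, high).
#' @slot crc_m Cumulative probability of metachronous CRC for patients with a
#'   cancer history.
#' @slot horizon Risk horizon in years (5).
#' @export
setClass("RiskModelParams",
  representation(annual_aa_to_crc = "numeric", aa_r = "numeric",
                 crc_m = "numeric", horizon = "numeric"),
  validity = function(object) {
    msg <- character()
    need <- c("male_lt80", "male_ge80", "female_lt80", "female_ge80")
    if (!all(need %in% names(object@annual_aa_to_crc)))
      msg <- c(msg, paste("annual_aa_to_crc needs strata:",
                          paste(need, collapse = ", ")))
    if (!all(historyCategories() %in% names(object@aa_r)))
      msg <- c(msg, "aa_r needs categories none, low, high")
    p <- c(object@annual_aa_to_crc, object@aa_r, object@crc_m)
    if (any(p < 0) || any(p > 1))
      msg <- c(msg, "all probabilities must lie in [0, 1]")
    if (object@horizon <= 0) msg <- c(msg, "horizon must be > 0")
    if (length(msg)) msg else TRUE
  })

#' @param annual_aa_to_crc,aa_r,crc_m,horizon See the corresponding slots.
#' @rdname RiskModelParams-class
#' @export
riskModelParams <- function(annual_aa_to_crc = c(male_lt80 = 0.026,
                                                 male_ge80 = 0.046,
                                                 female_lt80 = 0.019,
                                                 female_ge80 = 0.037),
                            aa_r = c(none = 0.06, low = 0.16, high = 0.36),
                            crc_m = 0.08, horizon = 5) {
  new("RiskModelParams", annual_aa_to_crc = annual_aa_to_crc, aa_r = aa_r,
      crc_m = crc_m, horizon = horizon)
}

#' Cross-validation report
#'
#' Per-fold AUC, sensitivity, specificity, and cutpoint of the repeated
#' stratified cross-validated classifier, with mean +/- SD summaries, the
#' configuration snapshot, the master seed, and a per-fold audit of the
#' patient identifiers on each side of the split.
#'
#' @slot folds data.frame with columns repeat_, fold, auc, sensitivity,
#'   specificity, threshold.
#' @slot auc_mean,auc_sd,se_mean,se_sd,sp_mean,sp_sd Summary statistics.
#' @slot config Configuration snapshot list.
#' @slot seed Master seed.
#' @slot audit Per-fold list of train/validation patient ids (leakage audit).
#' @export
setClass("CVReport",
  representation(folds = "data.frame", auc_mean = "numeric",
                 auc_sd = "numeric", se_mean = "numeric", se_sd = "numeric",
                 sp_mean = "numeric", sp_sd = "numeric", config = "list",
                 seed = "numeric", audit = "list"),
  validity = function(object) {
    m <- unlist(object@folds[c("auc", "sensitivity", "specificity")])
    if (any(m < 0 | m > 1, na.rm = TRUE))
      return("all metrics must lie in [0, 1]")
    TRUE
  })
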