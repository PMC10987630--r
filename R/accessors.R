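#' Accessors for cspws objects
#'
#' Small generic accessors for the imaging and cohort classes; user code
#' should use these rather than reaching into slots.
#'
#' @param x An object of the documented class.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imageValues", function(x) standardGeneric("imageValues"))
#' @rdname accessors
#' @export
setMethod("imageValues", "DensityField", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("imageValues", "SigmaMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("imageValues", "DMap", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("imageValues", "NucleusMask", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("lambdaGrid", function(x) standardGeneric("lambdaGrid"))
#' @rdname accessors
#' @export
setMethod("lambdaGrid", "SpectralCube", function(x) x@lambda_grid)
#' @rdname accessors
#' @export
setMethod("lambdaGrid", "InstrumentModel", function(x) x@lambda_grid)

#' @rdname accessors
#' @export
setGeneric("cubeData", function(x) standardGeneric("cubeData"))
#' @rdname accessors
#' @export
setMethod("cubeData", "SpectralCube", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("pixelPitch", function(x) standardGeneric("pixelPitch"))
#' @rdname accessors
#' @export
setMethod("pixelPitch", "SpectralCube", function(x) x@pixel_pitch)
#' @rdname accessors
#' @export
setMethod("pixelPitch", "DensityField", function(x) x@pixel_pitch)
#' @rdname accessors
#' @export
setMethod("pixelPitch", "InstrumentModel", function(x) x@pixel_pitch)

#' @rdname accessors
#' @export
setGeneric("maskArea", function(x) standardGeneric("maskArea"))
#' @rdname accessors
#' @export
setMethod("maskArea", "NucleusMask", function(x) sum(x@values))

#' @rdname accessors
#' @export
setGeneric("clampFraction", function(x) standardGeneric("clampFraction"))
#' @rdname accessors
#' @export
setMethod("clampFraction", "DMap", function(x) x@clamp_fraction)

#' @rdname accessors
#' @export
setGeneric("dGrid", function(x) standardGeneric("dGrid"))
#' @rdname accessors
#' @export
setMethod("dGrid", "CalibrationTable", function(x) x@D_grid)

#' @rdname accessors
#' @export
setGeneric("sigmaOfD", function(x) standardGeneric("sigmaOfD"))
#' @rdname accessors
#' @export
setMethod("sigmaOfD", "CalibrationTable", function(x) x@sigma_of_D)

#' @rdname accessors
#' @export
setGeneric("cohortPatients", function(x) standardGeneric("cohortPatients"))
#' @rdname accessors
#' @export
setMethod("cohortPatients", "Cohort", function(x) x@patients)

#' @rdname accessors
#' @export
setGeneric("cohortCells", function(x) standardGeneric("cohortCells"))
#' @rdname accessors
#' @export
setMethod("cohortCells", "Cohort", function(x) x@cells)

#' @rdname accessors
#' @export
setGeneric("cohortImages", function(x) standardGeneric("cohortImages"))
#' @rdname accessors
#' @export
setMethod("cohortImages", "Cohort", function(x) x@images)

#' @rdname accessors
#' @export
setGeneric("cvFolds", function(x) standardGeneric("cvFolds"))
#' @rdname accessors
#' @export
setMethod("cvFolds", "CVReport", function(x) x@folds)

#' @rdname accessors
#' @export
setGeneric("cvSummary", function(x) standardGeneric("cvSummary"))
#' @rdname accessors
#' @export
setMethod("cvSummary", "CVReport", function(x)
  c(auc_mean = x@auc_mean, auc_sd = x@auc_sd, se_mean = x@se_mean,
    se_sd = x@se_sd, sp_mean = x@sp_mean, sp_sd = x@sp_sd))

setMethod("show", "ACFModel", function(object) {
  cat(sprintf(
    "ACFModel: D = %.3f, phi = %.2f, window [%g, %g] nm, Nf = %g\n",
    object@D, object@phi, object@r_min, object@r_max, object@Nf))
})

setMethod("show", "InstrumentModel", function(object) {
  lg <- object@lambda_grid
  cat(sprintf(
    paste0("csPWS InstrumentModel: NA %.2f/%.2f, %d wavelengths ",
           "[%g, %g] nm, coherence %g nm x %g nm depth, pitch %g nm\n"),
    object@na_illumination, object@na_collection, length(lg), min(lg),
    max(lg), object@coherence_xy, object@depth_of_field,
    object@pixel_pitch))
})

setMethod("show", "DensityField", function(object) {
  cat(sprintf("DensityField %d x %d (pitch %g nm), truth D = %.3f\n",
              nrow(object@values), ncol(object@values), object@pixel_pitch,
              object@acf_truth@D))
})

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@data)
  cat(sprintf("SpectralCube %d x %d x %d (lambda %g-%g nm, pitch %g nm)\n",
              d[1], d[2], d[3], min(object@lambda_grid),
              max(object@lambda_grid), object@pixel_pitch))
})

setMethod("show", "NucleusMask", function(object) {
  cat(sprintf("NucleusMask %d x %d, area %d px\n", nrow(object@values),
              ncol(object@values), sum(object@values)))
})

setMethod("show", "SigmaMap", function(object) {
  cat(sprintf("SigmaMap %d x %d, Sigma in [%.4g, %.4g]\n",
              nrow(object@values), ncol(object@values), min(object@values),
              max(object@values)))
})

setMethod("show", "CalibrationTable", function(object) {
  cat(sprintf(
    "CalibrationTable: D in [%.2f, %.2f] (%d points), Sigma in [%.4g, %.4g], phi = %.2f\n",
    min(object@D_grid), max(object@D_grid), length(object@D_grid),
    min(object@sigma_of_D), max(object@sigma_of_D), object@phi))
})

setMethod("show", "DMap", function(object) {
  inm <- object@values[object@mask@values]
  cat(sprintf(
    "DMap %d x %d, nucleus %d px, D in [%.3f, %.3f], clamped %.1f%%\n",
    nrow(object@values), ncol(object@values), sum(object@mask@values),
    min(inm), max(inm), 100 * object@clamp_fraction))
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:\n  groups:",
      paste(sprintf("%s=%d", names(object@group_sizes),
                    as.integer(object@group_sizes)), collapse = ", "),
      sprintf("\n  cells/patient %d, between-sd %.3f, within-sd %.3f, age slope %.4f\n",
              as.integer(object@cells_per_patient),
              object@between_patient_sd, object@within_patient_sd,
              object@age_slope))
})

setMethod("show", "Cohort", function(object) {
  cat(sprintf("Cohort: %d patients, %d cells (%s)\n",
              nrow(object@patients), nrow(object@cells),
              if (length(object@images)) "images materialized"
              else "truth only"))
})

setMethod("show", "RiskModelParams", function(object) {
  cat(sprintf(
    "RiskModelParams: horizon %g y, CRCm = %.3f, AAr = [%s]\n",
    object@horizon, object@crc_m,
    paste(sprintf("%s %.2f", names(object@aa_r), object@aa_r),
          collapse = ", ")))
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf(
    "CVReport: %d folds, AUC %.3f +/- %.3f, Se %.3f +/- %.3f, Sp %.3f +/- %.3f\n",
    nrow(object@folds), object@auc_mean, object@auc_sd, object@se_mean,
    object@se_sd, object@sp_mean, object@sp_sd))
})
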