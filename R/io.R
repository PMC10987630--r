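parseError <- function(msg, file) {
  stop(errorCondition(sprintf("%s [%s]", msg, file),
                      class = c("cspwsParseError", "error", "condition")))
}

sidecarPath <- function(path) paste0(path, ".json")

#' Write / read a spectral cube
#'
#' Cubes are stored as multi-page 32-bit TIFF with the wavelength as the
#' page axis, affinely mapped to [0, 1] (offset/scale recorded in a JSON
#' sidecar next to the image, together with lambda_grid and pixel_pitch).
#' The write-then-read round trip is lossless to better than float32
#' precision.
#'
#' @param cube A \linkS4class{SpectralCube}.
#' @param path Output .tif path; the sidecar is written at
#'   \code{paste0(path, ".json")}.
#' @return \code{writeCube} returns the path invisibly; \code{readCube}
#'   returns the \linkS4class{SpectralCube}.
#' @export
writeCube <- function(cube, path) {
  stopIfNot(is(cube, "SpectralCube"), "'cube' must be a SpectralCube")
  lo <- min(cube@data); hi <- max(cube@data)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_along(cube@lambda_grid), function(l)
    (cube@data[, , l] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L,
                  compression = "none", reduce = FALSE)
  jsonlite::write_json(list(lambda_grid = cube@lambda_grid,
                            pixel_pitch = cube@pixel_pitch,
                            offset = lo, scale = scale),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @param path Path of a cube written by \code{writeCube}.
#' @rdname writeCube
#' @export
readCube <- function(path) {
  sc <- sidecarPath(path)
  if (!file.exists(sc))
    parseError("missing lambda metadata sidecar for cube", path)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  if (is.null(meta$lambda_grid))
    parseError("sidecar lacks lambda_grid", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      parseError(paste("unreadable TIFF:",
                                       conditionMessage(e)), path))
  if (length(pages) != length(meta$lambda_grid))
    parseError(sprintf("cube has %d planes but lambda_grid has %d entries",
                       length(pages), length(meta$lambda_grid)), path)
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (l in seq_along(pages))
    arr[, , l] <- meta$offset + pages[[l]] * meta$scale
  new("SpectralCube", data = arr, lambda_grid = meta$lambda_grid,
      pixel_pitch = meta$pixel_pitch)
}

#' Write / read a nucleus mask as PNG
#'
#' @param mask A \linkS4class{NucleusMask}.
#' @param path Output .png path.
#' @return \code{writeMask} returns the path invisibly; \code{readMask} the
#'   \linkS4class{NucleusMask}.
#' @export
writeMask <- function(mask, path) {
  png::writePNG(mask@values * 1, path)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  v <- tryCatch(png::readPNG(path),
                error = function(e)
                  parseError(paste("unreadable PNG:",
                                   conditionMessage(e)), path))
  if (length(dim(v)) == 3) v <- v[, , 1]
  nucleusMask(v > 0.5)
}

#' Write / read a D map as float TIFF with a JSON sidecar
#'
#' The sidecar records the pixel window, clamp fraction, and value range;
#' out-of-nucleus pixels are stored as the mask complement (the mask itself
#' travels as a second page).
#'
#' @param dmap A \linkS4class{DMap}.
#' @param path Output .tif path.
#' @return \code{writeDMap} returns the path invisibly; \code{readDMap} the
#'   \linkS4class{DMap}.
#' @export
writeDMap <- function(dmap, path) {
  v <- dmap@values
  inm <- dmap@mask@values
  lo <- min(v[inm]); hi <- max(v[inm])
  scale <- if (hi > lo) hi - lo else 1
  page <- (ifelse(inm, v, lo) - lo) / scale
  tiff::writeTIFF(list(page, inm * 1, dmap@clamped * 1), path,
                  bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(list(offset = lo, scale = scale,
                            pixel_window = dmap@pixel_window,
                            clamp_fraction = dmap@clamp_fraction),
                       sidecarPath(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeDMap
#' @export
readDMap <- function(path) {
  sc <- sidecarPath(path)
  if (!file.exists(sc)) parseError("missing D-map sidecar", path)
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e)
                      parseError(paste("unreadable TIFF:",
                                       conditionMessage(e)), path))
  mask <- nucleusMask(pages[[2]] > 0.5)
  vals <- meta$offset + pages[[1]] * meta$scale
  vals[!mask@values] <- NA_real_
  dMap(vals, mask, clamped = pages[[3]] > 0.5,
       pixel_window = meta$pixel_window,
       clamp_fraction = meta$clamp_fraction)
}

cohortConfigAsList <- function(cfg) {
  list(group_sizes = as.list(cfg@group_sizes),
       group_mean_D = as.list(cfg@group_mean_D),
       between_patient_sd = cfg@between_patient_sd,
       within_patient_sd = cfg@within_patient_sd,
       cells_per_patient = cfg@cells_per_patient,
       age_slope = cfg@age_slope,
       history_effect = as.list(cfg@history_effect),
       p_prior_cancer = cfg@p_prior_cancer,
       intra_nuclear_jitter = cfg@intra_nuclear_jitter,
       seed = cfg@seed)
}

#' Write a cohort manifest (and any materialized images) to disk
#'
#' Writes \code{patients.csv}, \code{cells.csv} and \code{config.yaml} under
#' \code{dir}; materialized cell images (cubes as float TIFF + sidecar,
#' masks as PNG, D maps as float TIFF) go under \code{dir/cells}. The cells
#' table gains file-path columns for whatever was materialized.
#'
#' @param cohort A \linkS4class{Cohort}.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- cohort@cells
  if (length(cohort@images)) {
    cdir <- file.path(dir, "cells")
    dir.create(cdir, showWarnings = FALSE)
    stem <- sprintf("%s_c%02d", cells$patient_id, cells$cell)
    for (k in seq_len(nrow(cells))) {
      img <- cohort@images[[k]]
      if (!is.null(img$cube)) {
        writeCube(img$cube, file.path(cdir, paste0(stem[k], ".tif")))
        cells$cube_file[k] <- file.path("cells", paste0(stem[k], ".tif"))
      }
      if (!is.null(img$mask)) {
        writeMask(img$mask, file.path(cdir, paste0(stem[k], "_mask.png")))
        cells$mask_file[k] <- file.path("cells",
                                        paste0(stem[k], "_mask.png"))
      }
      if (!is.null(img$d_truth) && !is.null(img$mask)) {
        dm <- dMap(img$d_truth, img$mask)
        writeDMap(dm, file.path(cdir, paste0(stem[k], "_dmap.tif")))
        cells$dmap_file[k] <- file.path("cells",
                                        paste0(stem[k], "_dmap.tif"))
      }
    }
  }
  write.csv(cohort@patients, file.path(dir, "patients.csv"),
            row.names = FALSE)
  write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE)
  yaml::write_yaml(cohortConfigAsList(cohort@config),
                   file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read the tables of a written cohort
#'
#' @param dir Directory written by \code{\link{writeCohort}}.
#' @return List with \code{patients} and \code{cells} data.frames.
#' @export
readCohortTables <- function(dir) {
  pf <- file.path(dir, "patients.csv")
  if (!file.exists(pf)) parseError("no patients.csv in cohort dir", dir)
  list(patients = read.csv(pf, stringsAsFactors = FALSE),
       cells = read.csv(file.path(dir, "cells.csv"),
                        stringsAsFactors = FALSE))
}

#' Write a report object as stable JSON
#'
#' Fixed 10-digit formatting so identical analyses yield byte-identical
#' report files.
#'
#' @param x List to serialize.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeReportJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE)
  invisible(path)
}
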