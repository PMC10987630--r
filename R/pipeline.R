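#' Default pipeline configuration
#'
#' Assembles the configuration list consumed by \code{\link{runAll}}. The
#' defaults describe a small demonstration cohort (two arms, 31 cells per
#' patient, 32 px frames) sized to run end-to-end in minutes; any element
#' can be overridden, and the full study design of
#' \code{\link{cohortConfig}} is available through \code{cohort}.
#'
#' @param out_dir Output root directory.
#' @param seed Master seed for every stage.
#' @param cohort Named list of \code{\link{cohortConfig}} overrides.
#' @param frame Per-cell image frame in pixels.
#' @param noise_sd Measurement noise of simulated cubes.
#' @param phi Chromatin volume concentration of the calibration.
#' @param detrend_order Sigma detrending order.
#' @param min_area Minimum segmented-nucleus area in pixels.
#' @param case_groups Groups forming the classification case arm.
#' @param ai Named list: size, filters, latent_dim, epochs, k, repeats.
#' @param risk_params A \linkS4class{RiskModelParams}.
#' @param force Re-run stages even when their marker is current.
#' @return Configuration list.
#' @export
pipelineConfig <- function(out_dir, seed = 1L,
                           cohort = list(
                             group_sizes = c(control = 6, AA = 6),
                             group_mean_D = c(control = 2.45, AA = 2.62)),
                           frame = c(32, 32), noise_sd = 0.002,
                           phi = 0.35, detrend_order = 1, min_area = 20,
                           case_groups = c("NDA", "AA", "HNPCC", "cancer"),
                           ai = list(size = 32L, filters = c(8L, 16L, 48L),
                                     latent_dim = 40L, epochs = 50L,
                                     k = 4L, repeats = 5L,
                                     rf_grid = NULL),
                           risk_params = riskModelParams(),
                           force = FALSE) {
  list(out_dir = out_dir, seed = seed, cohort = cohort, frame = frame,
       noise_sd = noise_sd, phi = phi, detrend_order = detrend_order,
       min_area = min_area, case_groups = case_groups, ai = ai,
       risk_params = risk_params, force = force)
}

stageHash <- function(config, stage) {
  cfg <- config[setdiff(names(config), c("out_dir", "force"))]
  cfg$risk_params <- list(annual = config$risk_params@annual_aa_to_crc,
                          aa_r = config$risk_params@aa_r,
                          crc_m = config$risk_params@crc_m,
                          horizon = config$risk_params@horizon)
  configHash(list(stage = stage, cfg = cfg))
}

stageDone <- function(config, stage) {
  marker <- file.path(config$out_dir, paste0(".done_", stage))
  !isTRUE(config$force) && file.exists(marker) &&
    identical(readLines(marker, warn = FALSE)[1],
              stageHash(config, stage))
}

markStage <- function(config, stage) {
  writeLines(stageHash(config, stage),
             file.path(config$out_dir, paste0(".done_", stage)))
}

tryStage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full csPWS analysis pipeline
#'
#' Chains simulate -> process -> stats -> risk -> classify over one output
#' directory. Every stage is idempotent: a stage marker stores the hash of
#' the configuration it ran under, and stages whose marker is current are
#' skipped unless \code{force} is set (or the marker was tampered with).
#' All reports embed the configuration hash and master seed, and two runs
#' with identical configuration and seed produce byte-identical reports.
#'
#' @param config A list from \code{\link{pipelineConfig}} or the path of a
#'   YAML file of overrides for it (out_dir required).
#' @return Invisibly, a list of the report paths per stage.
#' @export
runAll <- function(config) {
  if (is.character(config)) {
    ov <- yaml::read_yaml(config)
    config <- do.call(pipelineConfig, ov)
  }
  stopIfNot(is.list(config) && !is.null(config$out_dir),
            "config must provide out_dir")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  chash <- stageHash(config, "all")
  cohort_dir <- file.path(config$out_dir, "cohort")
  report_dir <- file.path(config$out_dir, "reports")
  dir.create(report_dir, showWarnings = FALSE)
  inst <- instrumentModel()
  calib <- buildCalibration(inst, phi = config$phi)
  out <- list()

  if (!stageDone(config, "simulate")) {
    tryStage("simulate", {
      cfg <- do.call(cohortConfig, c(config$cohort,
                                     list(seed = config$seed)))
      generateCohort(cfg, materialize = "cubes", inst = inst,
                     calib = calib, frame = config$frame,
                     noise_sd = config$noise_sd, out_dir = cohort_dir)
    })
    markStage(config, "simulate")
  }
  out$cohort <- cohort_dir

  proc_csv <- file.path(config$out_dir, "processed_patients.csv")
  cell_csv <- file.path(config$out_dir, "processed_cells.csv")
  if (!stageDone(config, "process")) {
    tryStage("process", {
      tb <- readCohortTables(cohort_dir)
      ddir <- file.path(config$out_dir, "dmaps")
      dir.create(ddir, showWarnings = FALSE)
      d_hat <- numeric(nrow(tb$cells))
      est_file <- character(nrow(tb$cells))
      for (k in seq_len(nrow(tb$cells))) {
        cube <- readCube(file.path(cohort_dir, tb$cells$cube_file[k]))
        sig <- computeSigmaMap(cube, config$detrend_order)
        masks <- segmentNuclei(sig@values, min_area = config$min_area)
        mask <- if (length(masks)) masks[[1]]
        else readMask(file.path(cohort_dir, tb$cells$mask_file[k]))
        dm <- estimateDMap(sig, calib, mask, noise_sd = config$noise_sd)
        d_hat[k] <- nuclearAverageD(dm)
        est_file[k] <- file.path("dmaps", basename(tb$cells$cube_file[k]))
        writeDMap(dm, file.path(config$out_dir, est_file[k]))
      }
      cells <- cbind(tb$cells, d_hat = d_hat, est_dmap_file = est_file)
      write.csv(cells, cell_csv, row.names = FALSE)
      pat <- tb$patients
      pat$mean_d <- as.numeric(tapply(cells$d_hat, cells$patient_id,
                                      mean)[pat$patient_id])
      write.csv(pat, proc_csv, row.names = FALSE)
    })
    markStage(config, "process")
  }
  out$patients <- proc_csv

  tryNum <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))
  stats_json <- file.path(report_dir, "stats.json")
  if (!stageDone(config, "stats")) {
    tryStage("stats", {
      pat <- read.csv(proc_csv, stringsAsFactors = FALSE)
      case <- intersect(config$case_groups, unique(pat$group))
      ctrl <- setdiff(unique(pat$group), config$case_groups)
      rep_ <- list(config_hash = chash, seed = config$seed,
                   comparison = tryNum(compareGroups(pat, case, ctrl)),
                   age_regression = tryNum(ageRegression(pat)),
                   ancova = tryNum(ancovaConfounders(pat, case, ctrl)),
                   univariate_roc = tryNum(univariateRoc(
                     pat, case, ctrl, seed = config$seed)),
                   multiple_testing = "none; raw p-values reported")
      writeReportJson(rep_, stats_json)
    })
    markStage(config, "stats")
  }
  out$stats <- stats_json

  risk_json <- file.path(report_dir, "risk.json")
  if (!stageDone(config, "risk")) {
    tryStage("risk", {
      pat <- read.csv(proc_csv, stringsAsFactors = FALSE)
      rk <- cohortRisk(pat, config$risk_params, by = "group")
      reg <- if (nrow(rk) >= 3)
        tryNum(riskDRegression(rk$mean_d, rk$risk))
      else list(note = "fewer than 3 groups; regression skipped")
      writeReportJson(list(config_hash = chash, seed = config$seed,
                           populations = rk, regression = reg),
                      risk_json)
    })
    markStage(config, "risk")
  }
  out$risk <- risk_json

  cv_json <- file.path(report_dir, "cv_report.json")
  if (!stageDone(config, "classify")) {
    tryStage("classify", {
      cells <- read.csv(cell_csv, stringsAsFactors = FALSE)
      pat <- read.csv(proc_csv, stringsAsFactors = FALSE)
      backbone <- randomCnnBackbone(filters = config$ai$filters,
                                    seed = childSeed(config$seed, 77))
      feats <- t(vapply(seq_len(nrow(cells)), function(k) {
        dm <- readDMap(file.path(config$out_dir, cells$est_dmap_file[k]))
        extractFeatures(preprocessDMap(dm, size = config$ai$size),
                        backbone)
      }, numeric(backbone$n_features)))
      grp <- pat$group[match(cells$patient_id, pat$patient_id)]
      lab <- as.integer(grp %in% config$case_groups)
      cvr <- repeatedStratifiedCv(feats, cells$patient_id, lab,
                                  k = config$ai$k,
                                  repeats = config$ai$repeats,
                                  latent_dim = config$ai$latent_dim,
                                  epochs = config$ai$epochs,
                                  rf_grid = config$ai$rf_grid,
                                  seed = childSeed(config$seed, 88))
      write.csv(cvFolds(cvr), file.path(report_dir, "cv_folds.csv"),
                row.names = FALSE)
      writeReportJson(list(config_hash = chash, seed = config$seed,
                           summary = as.list(cvSummary(cvr)),
                           n_folds = nrow(cvFolds(cvr))),
                      cv_json)
    })
    markStage(config, "classify")
  }
  out$classify <- cv_json
  invisible(out)
}
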