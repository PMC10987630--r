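defaultDemographics <- function() {
  # per-group age means and covariate rates of the screening cohort;
  # the high-lifetime-risk hereditary group uses the pooled case rates
  list(
    control = list(age_mean = 57.4, age_sd = 8, age_range = c(40, 90),
                   p_female = 0.488, p_smoking = 0.167, p_drinking = 0.692),
    DA      = list(age_mean = 62.4, age_sd = 8, age_range = c(40, 90),
                   p_female = 0.357, p_smoking = 0.071, p_drinking = 0.643),
    NDA     = list(age_mean = 56.8, age_sd = 8, age_range = c(40, 90),
                   p_female = 0.450, p_smoking = 0.150, p_drinking = 0.800),
    AA      = list(age_mean = 64.9, age_sd = 8, age_range = c(40, 90),
                   p_female = 0.507, p_smoking = 0.178, p_drinking = 0.613),
    HNPCC   = list(age_mean = 61.7, age_sd = 8, age_range = c(40, 90),
                   p_female = 0.475, p_smoking = 0.158, p_drinking = 0.627),
    cancer  = list(age_mean = 65.8, age_sd = 8, age_range = c(40, 90),
                   p_female = 0.500, p_smoking = 0.200, p_drinking = 0.600))
}

defaultHistoryProbs <- function() {
  # probability of {none, low, high}-risk colonoscopy history per group;
  # the high-risk fraction grows with diagnostic severity
  m <- rbind(control = c(0.70, 0.20, 0.10),
             DA      = c(0.55, 0.30, 0.15),
             NDA     = c(0.45, 0.35, 0.20),
             AA      = c(0.35, 0.35, 0.30),
             HNPCC   = c(0.05, 0.20, 0.75),
             cancer  = c(0.10, 0.30, 0.60))
  colnames(m) <- historyCategories()
  m
}

#' Construct a synthetic cohort configuration
#'
#' Defaults reproduce the structure of the rectal-brushing screening study:
#' 256 patients split 135/13/15/74/9/10 across control, diminutive adenoma,
#' nondiminutive adenoma, advanced adenoma, HNPCC and cancer; >= 31 cells
#' per patient; group-mean nuclear D increasing with severity; an additive
#' shift of D for low/high-risk colonoscopy history; and an age coefficient
#' of -0.008 D units per year. The absolute D placeholders (2.50 control to
#' 2.74 cancer) span the package's internal calibration scale; the
#' advanced-adenoma vs control gap (0.14) and the between-patient SD (0.08)
#' are chosen so that, together with the age-induced spread (cases average
#' about 7 years older, contributing roughly 0.06 SD units through the age
#' slope), the realized patient-level standardized effect of advanced
#' adenoma vs control is about 0.8, matching the reported risk-history
#' effect-size range.
#'
#' @param group_sizes Named patient counts over \code{\link{diagnosticGroups}}.
#' @param group_mean_D Named group means, increasing with severity.
#' @param between_patient_sd,within_patient_sd Patient- and cell-level SD of
#'   D.
#' @param cells_per_patient Cells per patient (> 30).
#' @param age_slope D units per year.
#' @param demographics Per-group demographic model (see
#'   \code{\linkS4class{CohortConfig}}).
#' @param history_probs Matrix of history-category probabilities.
#' @param history_effect Named additive D shift per history category.
#' @param p_prior_cancer Within high-risk history, probability the history is
#'   prior cancer.
#' @param intra_nuclear_jitter Pixel-level D SD inside one nucleus.
#' @param seed Master seed.
#' @return A \linkS4class{CohortConfig}.
#' @export
cohortConfig <- function(group_sizes = c(control = 135, DA = 13, NDA = 15,
                                         AA = 74, HNPCC = 9, cancer = 10),
                         group_mean_D = c(control = 2.50, DA = 2.53,
                                          NDA = 2.57, AA = 2.64,
                                          HNPCC = 2.70, cancer = 2.74),
                         between_patient_sd = 0.08,
                         within_patient_sd = 0.10,
                         cells_per_patient = 31, age_slope = -0.008,
                         demographics = defaultDemographics(),
                         history_probs = defaultHistoryProbs(),
                         history_effect = c(none = 0, low = 0.03,
                                            high = 0.06),
                         p_prior_cancer = 0.25,
                         intra_nuclear_jitter = 0.05, seed = 1L) {
  new("CohortConfig", group_sizes = group_sizes,
      group_mean_D = group_mean_D,
      between_patient_sd = between_patient_sd,
      within_patient_sd = within_patient_sd,
      cells_per_patient = cells_per_patient, age_slope = age_slope,
      demographics = demographics,
      history_probs = history_probs[names(group_sizes), , drop = FALSE],
      history_effect = history_effect, p_prior_cancer = p_prior_cancer,
      intra_nuclear_jitter = intra_nuclear_jitter, seed = seed)
}

truncNorm <- function(n, mean, sd, range) {
  x <- rnorm(n, mean, sd)
  bad <- x < range[1] | x > range[2]
  while (any(bad)) {
    x[bad] <- rnorm(sum(bad), mean, sd)
    bad <- x < range[1] | x > range[2]
  }
  x
}

#' Generate a synthetic csPWS cohort
#'
#' Draws a full cohort under the configured study design. Every cell's truth
#' packing scaling is
#' \deqn{D = \bar{D}_{group} + \delta_{history} +
#'       slope_{age}(age - \overline{age}) + b_{patient} + e_{cell}}
#' with patient offsets N(0, between_patient_sd) and cell offsets
#' N(0, within_patient_sd). Demographics (age, sex, smoking, drinking) and
#' colonoscopy-history categories are drawn from the per-group models. All
#' randomness derives deterministically from the config seed via per-patient
#' and per-cell child seeds.
#'
#' @param cfg A \linkS4class{CohortConfig}.
#' @param materialize \code{"truth"} (tables only), \code{"dmaps"} (also
#'   synthesize per-cell truth D maps over random elliptical nuclei), or
#'   \code{"cubes"} (additionally simulate and keep per-cell spectral cubes).
#' @param inst Instrument model used when materializing images.
#' @param calib Calibration table (built on demand when NULL).
#' @param frame Per-cell image frame in pixels.
#' @param noise_sd Measurement noise for materialized cubes.
#' @param out_dir When not NULL, write the cohort (manifest + images) under
#'   this directory via \code{\link{writeCohort}}.
#' @return A \linkS4class{Cohort}.
#' @export
generateCohort <- function(cfg, materialize = c("truth", "dmaps", "cubes"),
                           inst = instrumentModel(), calib = NULL,
                           frame = c(48, 48), noise_sd = 0,
                           out_dir = NULL) {
  stopIfNot(is(cfg, "CohortConfig"), "'cfg' must be a CohortConfig")
  validObject(cfg)
  materialize <- match.arg(materialize)
  groups <- rep(names(cfg@group_sizes), times = cfg@group_sizes)
  n_pat <- length(groups)
  ncell <- as.integer(cfg@cells_per_patient)

  pat <- withSeed(childSeed(cfg@seed, 0), {
    age <- numeric(n_pat); sex <- character(n_pat)
    smoking <- logical(n_pat); drinking <- logical(n_pat)
    history <- character(n_pat); prior_cancer <- logical(n_pat)
    for (i in seq_len(n_pat)) {
      g <- groups[i]
      dm <- cfg@demographics[[g]]
      age[i] <- truncNorm(1, dm$age_mean, dm$age_sd, dm$age_range)
      sex[i] <- if (runif(1) < dm$p_female) "female" else "male"
      smoking[i] <- runif(1) < dm$p_smoking
      drinking[i] <- runif(1) < dm$p_drinking
      history[i] <- sample(historyCategories(), 1,
                           prob = cfg@history_probs[g, ])
      prior_cancer[i] <- history[i] == "high" &&
        runif(1) < cfg@p_prior_cancer
    }
    data.frame(patient_id = sprintf("P%03d", seq_len(n_pat)),
               group = groups, age = age, sex = sex, smoking = smoking,
               drinking = drinking, history = history,
               prior_cancer = prior_cancer, stringsAsFactors = FALSE)
  })
  offsets <- withSeed(childSeed(cfg@seed, 1),
                      rnorm(n_pat, 0, cfg@between_patient_sd))
  mean_age <- mean(pat$age)
  base_d <- cfg@group_mean_D[pat$group] +
    cfg@history_effect[pat$history] +
    cfg@age_slope * (pat$age - mean_age) + offsets

  cells <- withSeed(childSeed(cfg@seed, 2), {
    e <- rnorm(n_pat * ncell, 0, cfg@within_patient_sd)
    data.frame(patient_id = rep(pat$patient_id, each = ncell),
               cell = rep(seq_len(ncell), times = n_pat),
               d_truth = rep(base_d, each = ncell) + e,
               stringsAsFactors = FALSE)
  })
  pat$mean_d <- as.numeric(tapply(cells$d_truth, cells$patient_id,
                                  mean)[pat$patient_id])

  images <- list()
  stream <- !is.null(out_dir) && materialize == "cubes"
  if (stream) {
    cdir <- file.path(out_dir, "cells")
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
  }
  if (materialize != "truth") {
    if (is.null(calib)) calib <- buildCalibration(inst)
    images <- vector("list", nrow(cells))
    stem <- sprintf("%s_c%02d", cells$patient_id, cells$cell)
    for (k in seq_len(nrow(cells))) {
      cs <- childSeed(cfg@seed, 100 + k)
      morph <- withSeed(cs, list(
        semiaxes = c(runif(1, 0.26, 0.36), runif(1, 0.18, 0.28)) *
          min(frame),
        angle = runif(1, 0, pi),
        center = frame / 2 + runif(2, -0.04, 0.04) * min(frame)))
      nuc <- synthesizeNucleusImage(
        D_target = cells$d_truth[k], phi = calib@phi, inst = inst,
        calib = calib, frame = frame, morphology = morph,
        jitter_sd = cfg@intra_nuclear_jitter, noise_sd = noise_sd,
        seed = childSeed(cs, 1))
      if (stream) {
        # write each cell as generated so large cohorts never live in RAM
        writeCube(nuc$cube, file.path(cdir, paste0(stem[k], ".tif")))
        writeMask(nuc$mask, file.path(cdir, paste0(stem[k], "_mask.png")))
        writeDMap(dMap(nuc$d_truth, nuc$mask),
                  file.path(cdir, paste0(stem[k], "_dmap.tif")))
        cells$cube_file[k] <- file.path("cells", paste0(stem[k], ".tif"))
        cells$mask_file[k] <- file.path("cells",
                                        paste0(stem[k], "_mask.png"))
        cells$dmap_file[k] <- file.path("cells",
                                        paste0(stem[k], "_dmap.tif"))
      } else {
        images[[k]] <- if (materialize == "dmaps")
          list(mask = nuc$mask, d_truth = nuc$d_truth)
        else nuc
      }
    }
  }
  cohort <- new("Cohort", patients = pat, cells = cells, config = cfg,
                images = images)
  if (!is.null(out_dir)) writeCohort(cohort, out_dir)
  cohort
}

#' Truth D map of a materialized cohort cell as a DMap
#'
#' @param cohort A \linkS4class{Cohort} materialized with dmaps or cubes.
#' @param k Cell row index into \code{cohortCells(cohort)}.
#' @return A \linkS4class{DMap} holding the cell's truth D over its nucleus.
#' @export
cellDMap <- function(cohort, k) {
  stopIfNot(length(cohort@images) >= k && !is.null(cohort@images[[k]]),
            "cohort was not materialized with images")
  img <- cohort@images[[k]]
  dMap(img$d_truth, img$mask)
}
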