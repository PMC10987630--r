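#' Convert an annual risk to a cumulative risk
#'
#' Cumulative risk = 1 - exp(-annual_risk * time), the constant-hazard
#' conversion used by the 5-year risk model. Monotone increasing in both
#' arguments and approximately annual_risk * time for small rates.
#'
#' @param annual_risk Annual probability (>= 0), vectorized.
#' @param time Horizon in years (>= 0).
#' @return Cumulative probability in [0, 1).
#' @examples
#' cumulativeRisk(0.01, 5)  # 1 - exp(-0.05) = 0.04877
#' @export
cumulativeRisk <- function(annual_risk, time) {
  if (any(annual_risk < 0) || any(time < 0))
    stop("annual_risk and time must be >= 0")
  1 - exp(-annual_risk * time)
}

#' Assign a colonoscopy-history category
#'
#' Deterministic mapping from past colonoscopy findings to the three history
#' categories of the risk model: no prior findings give "none"; prior
#' non-advanced adenomas give "low"; prior advanced adenoma, many adenomas,
#' or cancer give "high". The mapping table is configuration.
#'
#' @param findings Character vector of past finding codes (may be empty).
#' @param mapping Named vector mapping finding codes to categories; see
#'   \code{\link{historyMapping}}.
#' @return One of "none", "low", "high" (the most severe category present).
#' @export
assignHistoryCategory <- function(findings, mapping = historyMapping()) {
  if (length(findings) == 0 || all(findings == "none")) return("none")
  findings <- findings[findings != "none"]
  unknown <- setdiff(findings, names(mapping))
  if (length(unknown))
    stop("unknown finding code(s): ", paste(unknown, collapse = ", "))
  cats <- mapping[findings]
  ord <- c(none = 0, low = 1, high = 2)
  names(which.max(ord[cats]))
}

#' Default finding-to-category mapping for prior colonoscopies
#'
#' @return Named character vector: finding code -> history category.
#' @export
historyMapping <- function() {
  c(hyperplastic_polyp = "none",
    diminutive_adenoma = "low",
    small_adenoma = "low",
    nonadvanced_adenoma = "low",
    advanced_adenoma = "high",
    many_adenomas = "high",
    cancer = "high")
}

#' Five-year cumulative CRC risk of a population
#'
#' Evaluates the population risk formula
#' \deqn{CRC\,risk = \frac{1}{N_a + N_c}\left[AA_r \sum_{i=1}^{N_a}
#'   AA{\to}CRC_i + N_c\, CRC_m\right]}
#' where Na patients have no history or a history of adenoma, Nc patients
#' have a history of cancer, AAr is the cumulative risk of developing a
#' future advanced adenoma (taken from the population's history category),
#' each AA->CRC_i is the cumulative conversion of the patient's sex- and
#' age-stratified annual advanced-adenoma-to-CRC rate (age boundary 80
#' years), and CRCm is the cumulative metachronous-CRC risk.
#'
#' @param n_a,n_c Patient counts (n_a + n_c >= 1).
#' @param per_patient_aa_to_crc Numeric vector of length n_a of cumulative
#'   AA->CRC risks (see \code{\link{aaToCrcCumulative}}).
#' @param params A \linkS4class{RiskModelParams}.
#' @param history History category selecting AAr.
#' @param label Population label carried into the output.
#' @return List with label, n_a, n_c, risk, and a per-term components
#'   breakdown.
#' @export
populationRisk <- function(n_a, n_c, per_patient_aa_to_crc, params,
                           history = "none", label = "") {
  stopIfNot(is(params, "RiskModelParams"),
            "'params' must be RiskModelParams")
  validObject(params)
  if (n_a + n_c < 1) stop("population is empty (n_a + n_c = 0)")
  stopIfNot(length(per_patient_aa_to_crc) == n_a,
            "per_patient_aa_to_crc must have length n_a")
  stopIfNot(history %in% historyCategories(), "unknown history category")
  aa_r <- unname(params@aa_r[history])
  adenoma_term <- aa_r * sum(per_patient_aa_to_crc)
  cancer_term <- n_c * params@crc_m
  risk <- (adenoma_term + cancer_term) / (n_a + n_c)
  list(label = label, n_a = as.integer(n_a), n_c = as.integer(n_c),
       risk = risk,
       components = list(aa_r = aa_r, adenoma_term = adenoma_term,
                         cancer_term = cancer_term))
}

#' Cumulative AA-to-CRC risk for given sex/age strata
#'
#' Looks up the annual advanced-adenoma-to-CRC progression rate for each
#' patient's stratum (male/female crossed with age below/at-or-above 80
#' years) and converts it to a cumulative risk over the model horizon.
#'
#' @param sex Character vector ("male"/"female").
#' @param age Numeric ages in years.
#' @param params A \linkS4class{RiskModelParams}.
#' @return Numeric vector of cumulative probabilities.
#' @export
aaToCrcCumulative <- function(sex, age, params) {
  stopIfNot(all(sex %in% c("male", "female")),
            "sex must be 'male' or 'female'")
  key <- paste0(sex, ifelse(age < 80, "_lt80", "_ge80"))
  cumulativeRisk(unname(params@annual_aa_to_crc[key]), params@horizon)
}

#' Future advanced-adenoma risk category of a current finding
#'
#' The risk model considers both the surveillance history and the current
#' colonic health: a patient currently harboring an advanced lesion carries
#' at least the future-AA risk of a high-risk history. This maps diagnostic
#' groups onto the AAr categories.
#'
#' @param group Character vector of diagnostic groups.
#' @return Character vector of AAr categories (none/low/high).
#' @export
groupFindingCategory <- function(group) {
  map <- c(control = "none", DA = "low", NDA = "low", AA = "high",
           HNPCC = "high", cancer = "high")
  unknown <- setdiff(group, names(map))
  if (length(unknown))
    stop("unknown diagnostic group(s): ", paste(unknown, collapse = ", "))
  unname(map[group])
}

#' Population risk estimates across a cohort
#'
#' Applies the 5-year risk model to populations of a cohort. With
#' \code{by = "group"} one population per diagnostic group is formed; with
#' \code{by = "group_history"} populations follow the (group, history
#' category) cross, mirroring the risk-history strata. Patients with a prior
#' cancer enter the metachronous term (Nc); all others enter the adenoma
#' term. Each patient's cumulative future-AA risk combines the history route
#' and the current-finding route as independent risks,
#' \eqn{AA_r = 1 - (1 - AA_r^{hist})(1 - AA_r^{current})}, and the
#' population AAr of the printed formula is the patient mean of these, so a
#' single AAr multiplies the stratified AA->CRC sum per population.
#'
#' @param cohort A \linkS4class{Cohort} or patient data.frame.
#' @param params A \linkS4class{RiskModelParams}.
#' @param by Population definition.
#' @return data.frame with label, n, n_a, n_c, mean_d, risk.
#' @export
cohortRisk <- function(cohort, params = riskModelParams(),
                       by = c("group", "group_history")) {
  by <- match.arg(by)
  pat <- patientTable(cohort)
  key <- if (by == "group") pat$group
  else paste(pat$group, pat$history, sep = "/")
  out <- lapply(unique(key), function(kk) {
    p <- pat[key == kk, ]
    is_c <- p$prior_cancer
    n_c <- sum(is_c); n_a <- sum(!is_c)
    pa <- p[!is_c, ]
    if (n_a) {
      per <- aaToCrcCumulative(pa$sex, pa$age, params)
      aa_hist <- params@aa_r[pa$history]
      aa_curr <- params@aa_r[groupFindingCategory(pa$group)]
      aa_r <- mean(1 - (1 - aa_hist) * (1 - aa_curr))
      adenoma_term <- aa_r * sum(per)
    } else adenoma_term <- 0
    risk <- (adenoma_term + n_c * params@crc_m) / (n_a + n_c)
    data.frame(label = kk, n = nrow(p), n_a = n_a, n_c = n_c,
               mean_d = mean(p$mean_d), risk = risk)
  })
  do.call(rbind, out)
}

#' Regression of modeled CRC risk on group-mean D
#'
#' Ordinary least squares of population 5-year risk on population mean
#' packing scaling D.
#'
#' @param group_mean_d Numeric vector of population mean D (>= 3 values).
#' @param group_risk Numeric vector of modeled risks, same length.
#' @return List with slope, intercept, r_squared.
#' @export
riskDRegression <- function(group_mean_d, group_risk) {
  stopIfNot(length(group_mean_d) == length(group_risk),
            "input lengths differ")
  stopIfNot(length(group_mean_d) >= 3, "need at least 3 populations")
  if (sd(group_mean_d) == 0) stop("mean D is constant across populations")
  fit <- lm(group_risk ~ group_mean_d)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = summary(fit)$r.squared)
}
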