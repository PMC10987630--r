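patientTable <- function(cohort) {
  if (is(cohort, "Cohort")) cohort@patients
  else if (is.data.frame(cohort)) cohort
  else stop("'cohort' must be a Cohort or a patient data.frame")
}

#' Compare patient-level D between two group sets
#'
#' Two-sided Welch t-test on patient mean D, with Cohen's d (pooled SD)
#' as the effect size. The sign convention is fixed: d is positive when the
#' case side exceeds the control side.
#'
#' @param cohort A \linkS4class{Cohort} or patient data.frame.
#' @param case_groups,control_groups Character vectors of group labels.
#' @return List with group labels, sample sizes, mean difference
#'   (case - control), t statistic, p value, effect size d, and a
#'   \code{degenerate} flag raised when the pooled SD is zero.
#' @export
compareGroups <- function(cohort, case_groups, control_groups) {
  pat <- patientTable(cohort)
  x <- pat$mean_d[pat$group %in% case_groups]
  y <- pat$mean_d[pat$group %in% control_groups]
  if (length(x) < 2 || length(y) < 2)
    stop("each side needs at least 2 patients")
  n1 <- length(x); n0 <- length(y)
  sp2 <- ((n1 - 1) * var(x) + (n0 - 1) * var(y)) / (n1 + n0 - 2)
  degenerate <- sp2 == 0
  diff_means <- mean(x) - mean(y)
  if (degenerate) {
    d <- if (diff_means == 0) 0 else sign(diff_means) * Inf
    tt <- list(statistic = if (diff_means == 0) 0 else
      sign(diff_means) * Inf, p.value = if (diff_means == 0) 1 else 0)
  } else {
    ht <- t.test(x, y)
    tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    d <- diff_means / sqrt(sp2)
  }
  list(case = case_groups, control = control_groups, n_case = n1,
       n_control = n0, mean_diff = diff_means,
       t = unname(tt$statistic), p_value = tt$p.value, effect_size = d,
       degenerate = degenerate)
}

#' Confounder screen by analysis of covariance
#'
#' Linear model of patient mean D on the case indicator plus age, sex,
#' smoking and drinking, over the control and case arms (case defined as
#' nondiminutive adenoma + advanced adenoma + cancer). Reports per-covariate
#' coefficients and p values; raw p values, no multiplicity adjustment.
#'
#' @param cohort A \linkS4class{Cohort} or patient data.frame.
#' @param case_groups Groups forming the case arm.
#' @param control_groups Groups forming the control arm.
#' @return data.frame with columns term, estimate, p_value.
#' @export
ancovaConfounders <- function(cohort,
                              case_groups = c("NDA", "AA", "cancer"),
                              control_groups = "control") {
  pat <- patientTable(cohort)
  pat <- pat[pat$group %in% c(case_groups, control_groups), ]
  if (sum(pat$group %in% case_groups) < 10 ||
      sum(pat$group %in% control_groups) < 10)
    stop("need at least 10 patients per arm")
  df <- data.frame(mean_d = pat$mean_d,
                   case = as.integer(pat$group %in% case_groups),
                   age = pat$age,
                   sex = as.integer(pat$sex == "female"),
                   smoking = as.integer(pat$smoking),
                   drinking = as.integer(pat$drinking))
  novar <- names(df)[-1][vapply(df[-1], function(v) var(v) == 0, TRUE)]
  if (length(novar))
    stop("zero-variance covariate(s): ", paste(novar, collapse = ", "))
  fit <- lm(mean_d ~ case + age + sex + smoking + drinking, data = df)
  if (fit$rank < 6) {
    alias <- colnames(stats::alias(fit)$Complete)
    stop("rank-deficient design; collinear columns: ",
         paste(alias, collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  data.frame(term = rownames(sm), estimate = sm[, 1],
             p_value = sm[, 4], row.names = NULL)
}

#' Age regression of patient mean D
#'
#' Ordinary least squares of patient mean D on age. With
#' \code{adjust = "group"} (the default) diagnostic group enters as a fixed
#' effect, so the age coefficient is estimated within groups and is not
#' confounded by cases being older; \code{adjust = "none"} is the plain
#' bivariate regression.
#'
#' @param cohort A \linkS4class{Cohort} or patient data.frame.
#' @param adjust \code{"group"} or \code{"none"}.
#' @return List with slope (D units per year), intercept, and r (Pearson
#'   correlation of D with age; partial within groups when adjusted).
#' @export
ageRegression <- function(cohort, adjust = c("group", "none")) {
  adjust <- match.arg(adjust)
  pat <- patientTable(cohort)
  if (length(unique(pat$age)) < 3)
    stop("need at least 3 distinct ages")
  if (adjust == "group" && length(unique(pat$group)) > 1) {
    fit <- lm(mean_d ~ factor(group) + age, data = pat)
    slope <- unname(coef(fit)["age"])
    res_d <- residuals(lm(mean_d ~ factor(group), data = pat))
    res_a <- residuals(lm(age ~ factor(group), data = pat))
    r <- if (sd(res_d) == 0 || sd(res_a) == 0) 0 else cor(res_d, res_a)
    intercept <- unname(coef(fit)[1])
  } else {
    fit <- lm(mean_d ~ age, data = pat)
    slope <- unname(coef(fit)["age"])
    intercept <- unname(coef(fit)[1])
    r <- if (sd(pat$mean_d) == 0) 0 else cor(pat$mean_d, pat$age)
  }
  list(slope = slope, intercept = intercept, r = r)
}

stratifiedSplit <- function(labels, fraction, seed) {
  idx <- withSeed(seed, {
    train <- logical(length(labels))
    for (cl in unique(labels)) {
      w <- which(labels == cl)
      n_tr <- round(length(w) * fraction)
      train[sample(w, n_tr)] <- TRUE
    }
    train
  })
  idx
}

#' Univariate split-sample ROC of patient mean D
#'
#' Stratified 50/50 split of patients into a development and a prospective
#' testing half; the decision threshold is the optimal cutpoint (maximum
#' correct classifications) on the development half, and AUC (rank
#' statistic), sensitivity and specificity are evaluated on the testing
#' half.
#'
#' @param cohort A \linkS4class{Cohort} or patient data.frame.
#' @param case_groups,control_groups Group labels defining the two classes.
#' @param split Fraction assigned to the development half.
#' @param seed Split seed.
#' @return List with auc, sensitivity, specificity, threshold, split_seed.
#' @export
univariateRoc <- function(cohort, case_groups = "AA",
                          control_groups = "control", split = 0.5,
                          seed = 1L) {
  pat <- patientTable(cohort)
  pat <- pat[pat$group %in% c(case_groups, control_groups), ]
  lab <- as.integer(pat$group %in% case_groups)
  train <- stratifiedSplit(lab, split, seed)
  if (length(unique(lab[train])) < 2 || length(unique(lab[!train])) < 2)
    stop("a class is absent from one half of the split; re-seed")
  cut <- optimalCutpoint(pat$mean_d[train], lab[train])
  s_te <- pat$mean_d[!train]; l_te <- lab[!train]
  pred <- as.integer(s_te >= cut$threshold)
  list(auc = rocAuc(s_te, l_te),
       sensitivity = sum(pred == 1 & l_te == 1) / sum(l_te == 1),
       specificity = sum(pred == 0 & l_te == 0) / sum(l_te == 0),
       threshold = cut$threshold, split_seed = seed)
}
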