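# Shared fixtures, all built in code.

defaultInstrument <- instrumentModel()

# one calibration table reused across tests (expensive-ish quadrature)
defaultCalib <- buildCalibration(defaultInstrument, phi = 0.35)

fullMask <- function(n, m = n) new("NucleusMask",
                                   values = matrix(TRUE, n, m))

# a small two-arm cohort config with a large, clean group separation
strongSignalConfig <- function(seed = 42L, n_per_arm = 12L) {
  cohortConfig(group_sizes = c(control = n_per_arm, AA = n_per_arm),
               group_mean_D = c(control = 2.2, AA = 2.8),
               between_patient_sd = 0.02, within_patient_sd = 0.02,
               age_slope = 0,
               history_effect = c(none = 0, low = 0, high = 0),
               intra_nuclear_jitter = 0.08, seed = seed)
}

# truth-level cohort free of any group/age effect (null conditions)
nullCohortConfig <- function(seed = 1L, n_per_arm = 30L) {
  cohortConfig(group_sizes = c(control = n_per_arm, NDA = 5,
                               AA = n_per_arm, cancer = 5),
               group_mean_D = c(control = 2.5, NDA = 2.5 + 1e-9,
                                AA = 2.5 + 2e-9, cancer = 2.5 + 3e-9),
               between_patient_sd = 0.08, within_patient_sd = 0.1,
               age_slope = 0,
               history_effect = c(none = 0, low = 0, high = 0),
               seed = seed)
}

# brute-force rank AUC over all case/control pairs
bruteForceAuc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ct))
}

# trapezoidal area under the empirical ROC curve
trapezoidAuc <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  tpr <- vapply(th, function(t_) sum(scores >= t_ & labels == 1) / n1, 0)
  fpr <- vapply(th, function(t_) sum(scores >= t_ & labels == 0) / n0, 0)
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# a small but complete pipeline configuration for end-to-end runs
miniPipelineConfig <- function(out_dir, seed = 5L) {
  pipelineConfig(
    out_dir = out_dir, seed = seed,
    cohort = list(group_sizes = c(control = 4, AA = 4),
                  group_mean_D = c(control = 2.40, AA = 2.65),
                  between_patient_sd = 0.03, within_patient_sd = 0.03,
                  intra_nuclear_jitter = 0.06),
    frame = c(32, 32), noise_sd = 0.002,
    ai = list(size = 32L, filters = c(8L, 16L, 48L), latent_dim = 20L,
              epochs = 15L, k = 4L, repeats = 5L,
              rf_grid = data.frame(ntree = 60L, mtry = 4L,
                                   nodesize = 1L)))
}

# small per-cell feature dataset with patient structure for CV tests
toyCellDataset <- function(n_per_class = 6L, cells = 4L, d = 8L,
                           shift = 3, seed = 1L) {
  withr::with_seed(seed, {
    n_pat <- 2L * n_per_class
    pid <- rep(sprintf("P%02d", seq_len(n_pat)), each = cells)
    lab_pat <- rep(c(0L, 1L), each = n_per_class)
    lab <- rep(lab_pat, each = cells)
    x <- matrix(rnorm(n_pat * cells * d), n_pat * cells, d)
    x[lab == 1, 1:2] <- x[lab == 1, 1:2] + shift
    list(features = x, patient_id = pid, label = lab)
  })
}
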