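toyDMap <- function(vals, mask_mat) {
  new("DMap", values = vals, mask = new("NucleusMask", values = mask_mat),
      clamped = matrix(FALSE, nrow(vals), ncol(vals)), pixel_window = 458,
      clamp_fraction = 0)
}

test_that("preprocessing crops, scales to [0, 1], and replicates channels", {
  mk <- imageValues(ellipseMask(c(40, 40), semiaxes = c(12, 6)))
  vals <- matrix(NA_real_, 40, 40)
  vals[mk] <- seq(2.3, 2.7, length.out = sum(mk))
  img <- preprocessDMap(toyDMap(vals, mk), size = 32)
  expect_equal(dim(img), c(32, 32, 3))
  expect_equal(range(img), c(0, 1))
  expect_equal(img[, , 1], img[, , 3])
  # constant nucleus maps to the 0.5 convention
  vals2 <- vals; vals2[mk] <- 2.5
  img2 <- preprocessDMap(toyDMap(vals2, mk), size = 32)
  expect_true(all(abs(img2[img2 > 0] - 0.5) < 1e-6))
  # 2:1 aspect still yields the square output (anisotropic resize)
  expect_equal(dim(preprocessDMap(toyDMap(vals, mk), size = 224)),
               c(224, 224, 3))
})

test_that("values outside the mask cannot influence preprocessing", {
  mk <- imageValues(ellipseMask(c(30, 30), semiaxes = c(9, 7)))
  vals <- matrix(NA_real_, 30, 30)
  vals[mk] <- seq(2.2, 2.8, length.out = sum(mk))
  a <- preprocessDMap(toyDMap(vals, mk), size = 24)
  vals2 <- vals; vals2[!mk] <- 99
  b <- preprocessDMap(toyDMap(vals2, mk), size = 24)
  expect_identical(a, b)
})

test_that("feature extraction is deterministic with the stated length", {
  bb <- randomCnnBackbone(filters = c(8, 16, 32), seed = 7)
  img <- withr::with_seed(1, array(runif(48 * 48 * 3), c(48, 48, 3)))
  f1 <- extractFeatures(img, bb)
  f2 <- extractFeatures(img, bb)
  expect_identical(f1, f2)
  expect_length(f1, 32)
  bb2 <- randomCnnBackbone(filters = c(8, 16, 32), seed = 7)
  expect_identical(f1, extractFeatures(img, bb2))  # weights are frozen
  ib <- identityBackbone(8)
  expect_length(extractFeatures(img, ib), 64)
  cb <- customBackbone(function(x) colMeans(matrix(x, ncol = 3)), 3)
  expect_length(extractFeatures(img, cb), 3)
  expect_error(extractFeatures(img[, , 1:2], bb), "H x W x 3")
})

test_that("autoencoder training decreases loss and records every epoch", {
  X <- withr::with_seed(2, matrix(rnorm(120 * 48), 120, 48))
  enc <- trainAutoencoder(X, latent_dim = 10, epochs = 30, seed = 3)
  expect_length(enc$loss_curve, 30)
  expect_lte(enc$loss_curve[30], enc$loss_curve[1])
  enc2 <- trainAutoencoder(X, latent_dim = 10, epochs = 30, seed = 3)
  expect_identical(enc$loss_curve, enc2$loss_curve)   # bit-reproducible
  expect_error(trainAutoencoder(X, latent_dim = 48), "smaller than")
  expect_error(trainAutoencoder(X[1:5, ], latent_dim = 10),
               "at least latent_dim")
})

test_that("a 40-dim code reconstructs 10-dim subspace data to near zero", {
  X <- withr::with_seed(5, matrix(rnorm(200 * 10), 200, 10) %*%
                          matrix(rnorm(10 * 64), 10, 64))
  enc <- trainAutoencoder(X, latent_dim = 40, epochs = 300, seed = 1)
  expect_lt(enc$loss_curve[300], 0.02 * enc$loss_curve[1])
})

test_that("encoding gives finite length-40 codes consistent with training", {
  X <- withr::with_seed(6, matrix(rnorm(100 * 48), 100, 48))
  enc <- trainAutoencoder(X, latent_dim = 40, epochs = 20, seed = 2)
  z <- encodeFeatures(X, enc)
  expect_equal(dim(z), c(100, 40))
  expect_identical(encodeFeatures(X[1, ], enc), encodeFeatures(X[1, ], enc))
  z0 <- encodeFeatures(rep(0, 48), enc)
  expect_true(all(is.finite(z0)))
  # latent of the training mean lies inside the training latent bounding box
  zm <- encodeFeatures(colMeans(X), enc)
  expect_true(all(zm >= apply(z, 2, min) - 1e-9 &
                    zm <= apply(z, 2, max) + 1e-9))
  expect_error(encodeFeatures(X[, 1:10], enc), "does not match")
})

test_that("rank AUC agrees with brute force and the trapezoid rule", {
  expect_equal(rocAuc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(rocAuc(1:6, c(0, 0, 0, 1, 1, 1)), 1)
  expect_equal(rocAuc(rep(1, 6), c(0, 0, 0, 1, 1, 1)), 0.5)
  withr::with_seed(8, for (i in 1:25) {
    n <- sample(4:10, 1)
    s <- round(rnorm(n), 1)          # induce ties
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(rocAuc(s, l), bruteForceAuc(s, l), tolerance = 1e-12)
    expect_equal(rocAuc(s, l), trapezoidAuc(s, l), tolerance = 1e-12)
  })
  expect_error(rocAuc(1:3, c(1, 1, 1)), "both classes")
})

test_that("rank AUC matches the independent pROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(9, {
    s <- rnorm(60); l <- rbinom(60, 1, 0.4)
  })
  l[1:2] <- c(0, 1)
  expect_equal(rocAuc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("the optimal cutpoint maximizes correct classifications", {
  perf <- optimalCutpoint(c(1, 2, 10, 11), c(0, 0, 1, 1))
  expect_equal(perf$sensitivity, 1)
  expect_equal(perf$specificity, 1)
  # documented tie rule: accuracy ties resolve toward higher sensitivity
  tie <- optimalCutpoint(c(1, 2, 3, 4), c(0, 1, 0, 1))
  expect_equal(tie$accuracy, 0.75)
  expect_equal(tie$sensitivity, 1)
  expect_equal(tie$specificity, 0.5)
  expect_lt(tie$threshold, 2)
  # shift invariance
  sh <- optimalCutpoint(c(1, 2, 3, 4) + 5, c(0, 1, 0, 1))
  expect_equal(sh$threshold, tie$threshold + 5)
  expect_equal(sh$sensitivity, tie$sensitivity)
  expect_equal(sh$specificity, tie$specificity)
})

test_that("cutpoint accuracy equals the brute-force maximum", {
  withr::with_seed(10, for (i in 1:25) {
    n <- sample(4:10, 1)
    s <- round(rnorm(n), 1)
    l <- c(0, 1, rbinom(n - 2, 1, 0.5))
    acc_all <- vapply(c(-Inf, sort(unique(s)), Inf), function(t_)
      mean((s >= t_) == (l == 1)), 0)
    expect_equal(optimalCutpoint(s, l)$accuracy, max(acc_all),
                 tolerance = 1e-12)
  })
})

test_that("grid search honors its contract", {
  ds <- toyCellDataset()
  one <- data.frame(ntree = 50L, mtry = 2L, nodesize = 1L)
  clf <- trainClassifier(ds$features, ds$label, grid = one, seed = 1)
  expect_equal(clf$chosen$ntree, 50L)
  expect_equal(clf$audit$n_train, nrow(ds$features))
  # linearly separable clusters -> perfect training AUC
  expect_equal(rocAuc(predictScores(clf, ds$features), ds$label), 1)
  expect_error(trainClassifier(ds$features, rep(1, nrow(ds$features))),
               "both classes")
})

test_that("repeated stratified CV emits k x repeats folds with stratification", {
  ds <- toyCellDataset(n_per_class = 6, cells = 4, d = 8)
  grid1 <- data.frame(ntree = 50L, mtry = 2L, nodesize = 1L)
  cv <- repeatedStratifiedCv(ds$features, ds$patient_id, ds$label,
                             k = 4, repeats = 5, latent_dim = 4,
                             epochs = 10, rf_grid = grid1, seed = 5)
  folds <- cvFolds(cv)
  expect_equal(nrow(folds), 20)
  expect_true(all(folds$auc >= 0 & folds$auc <= 1))
  # patient-level stratification: every fold holds 3 patients, at most
  # 2 (= ceil(6/4)) per class, and >= 1 of each class
  pat_lab <- setNames(rep(c(0, 1), each = 6),
                      unique(ds$patient_id))
  for (a in cv@audit) {
    vl <- pat_lab[a$val_patients]
    expect_true(all(table(factor(vl, levels = 0:1)) >= 1))
    expect_true(all(table(factor(vl, levels = 0:1)) <= 2))
  }
})

test_that("no fitted component ever sees validation-fold data", {
  ds <- toyCellDataset(n_per_class = 5, cells = 3, d = 8)
  grid1 <- data.frame(ntree = 40L, mtry = 2L, nodesize = 1L)
  cv <- repeatedStratifiedCv(ds$features, ds$patient_id, ds$label,
                             k = 4, repeats = 2, latent_dim = 4,
                             epochs = 5, rf_grid = grid1, seed = 9)
  for (a in cv@audit) {
    expect_length(intersect(a$train_patients, a$val_patients), 0)
    val_cells <- which(ds$patient_id %in% a$val_patients)
    expect_length(intersect(a$classifier_rows, val_cells), 0)
    train_cells <- which(ds$patient_id %in% a$train_patients)
    expect_setequal(a$classifier_rows, train_cells)
  }
})

test_that("CV rejects inconsistent labels and too-small classes", {
  ds <- toyCellDataset(n_per_class = 2, cells = 3, d = 8)
  expect_error(repeatedStratifiedCv(ds$features, ds$patient_id, ds$label,
                                    k = 4, latent_dim = 4),
               "at least k patients")
  bad_lab <- ds$label
  bad_lab[1] <- 1 - bad_lab[1]
  expect_error(repeatedStratifiedCv(ds$features, ds$patient_id, bad_lab,
                                    k = 2, latent_dim = 4),
               "not constant within patient")
})
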