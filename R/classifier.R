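#' Preprocess a D map for feature extraction
#'
#' Crops the map to the nucleus bounding box, min-max scales the in-mask D
#' values to [0, 1] (a constant nucleus maps to 0.5 by convention), zeroes
#' everything outside the mask, resizes (anisotropically) to the backbone
#' input size, and replicates to three channels.
#'
#' @param dmap A \linkS4class{DMap} with a non-empty mask.
#' @param size Output side length in pixels (default 224).
#' @return Numeric array size x size x 3 with values in [0, 1].
#' @export
preprocessDMap <- function(dmap, size = 224L) {
  stopIfNot(is(dmap, "DMap"), "'dmap' must be a DMap")
  m <- dmap@mask@values
  rr <- range(which(rowSums(m) > 0)); cc <- range(which(colSums(m) > 0))
  if (diff(rr) < 1 || diff(cc) < 1)
    stop("degenerate nucleus bounding box")
  v <- dmap@values[rr[1]:rr[2], cc[1]:cc[2]]
  mk <- m[rr[1]:rr[2], cc[1]:cc[2]]
  inv <- v[mk]
  rngd <- diff(range(inv))
  scaled <- if (rngd == 0) matrix(0, nrow(v), ncol(v))
  else (v - min(inv)) / rngd
  scaled[!mk] <- 0
  img <- EBImage::imageData(EBImage::resize(EBImage::Image(scaled),
                                            w = size, h = size))
  if (rngd == 0) {
    # constant nucleus: all in-mask pixels take 0.5 by convention
    mk_r <- EBImage::imageData(EBImage::resize(EBImage::Image(mk * 1),
                                               w = size, h = size))
    img <- matrix(0, size, size)
    img[mk_r >= 0.5] <- 0.5
  } else {
    img <- pmin(pmax(img, 0), 1)   # bilinear overshoot at mask edges
    if (max(img) > 0) img <- img / max(img)  # exact [0, 1] span
  }
  array(rep(img, 3), c(size, size, 3))
}

# 3x3-stride-2 convolution layer via im2col matrix multiplication.
convForward <- function(x, w, b) {
  k <- dim(w)[1]; cin <- dim(w)[3]; cout <- dim(w)[4]
  h <- dim(x)[1]; wd <- dim(x)[2]
  p <- (k - 1) %/% 2
  xp <- array(0, c(h + 2 * p, wd + 2 * p, cin))
  xp[p + seq_len(h), p + seq_len(wd), ] <- x
  i0 <- seq(1, h, by = 2); j0 <- seq(1, wd, by = 2)
  ho <- length(i0); wo <- length(j0)
  M <- matrix(0, ho * wo, k * k * cin)
  col <- 0
  for (c_ in seq_len(cin)) for (dj in 0:(k - 1)) for (di in 0:(k - 1)) {
    col <- col + 1
    M[, col] <- xp[i0 + di, j0 + dj, c_]
  }
  W <- matrix(w, k * k * cin, cout)   # matches (di, dj, c) unrolling
  y <- M %*% W
  y <- sweep(y, 2, b, "+")
  y[y < 0] <- 0
  array(y, c(ho, wo, cout))
}

#' Fixed-seed random-weight convolutional backbone
#'
#' A small convolutional feature extractor with frozen Gaussian (He-scaled)
#' random weights: stacked 3x3 stride-2 convolution + ReLU stages followed
#' by global average pooling of the final convolutional activation maps.
#' Random convolutional features preserve multi-scale texture statistics, so
#' the backbone discriminates spatial-frequency content of D maps while
#' remaining fully reproducible and dependency-free; a pretrained network
#' can be substituted via \code{\link{customBackbone}}.
#'
#' @param filters Integer vector of channel counts per stage; the last entry
#'   is the feature length.
#' @param seed Seed fixing the weights.
#' @return A backbone object for \code{\link{extractFeatures}}.
#' @export
randomCnnBackbone <- function(filters = c(16, 32, 64), seed = 2024L) {
  k <- 3L
  chans <- c(3L, filters)
  weights <- withSeed(seed, lapply(seq_along(filters), function(l) {
    fan_in <- k * k * chans[l]
    list(w = array(rnorm(k * k * chans[l] * chans[l + 1],
                         sd = sqrt(2 / fan_in)),
                   c(k, k, chans[l], chans[l + 1])),
         b = rep(0, chans[l + 1]))
  }))
  structure(list(name = sprintf("randomCNN-%s-s%d",
                                paste(filters, collapse = "."),
                                as.integer(seed)),
                 n_features = filters[length(filters)],
                 forward = function(img) {
                   x <- img
                   for (l in weights) x <- convForward(x, l$w, l$b)
                   colMeans(matrix(x, dim(x)[1] * dim(x)[2], dim(x)[3]))
                 }),
            class = "cspwsBackbone")
}

#' Identity-downsample baseline backbone
#'
#' Block-averages the channel-mean image on a coarse grid; the flattened
#' grid is the feature vector. A deliberately simple baseline extractor.
#'
#' @param grid Side length of the pooling grid (features = grid^2).
#' @return A backbone object for \code{\link{extractFeatures}}.
#' @export
identityBackbone <- function(grid = 8L) {
  structure(list(name = sprintf("identity-%d", grid),
                 n_features = as.integer(grid)^2,
                 forward = function(img) {
                   ch <- (img[, , 1] + img[, , 2] + img[, , 3]) / 3
                   as.vector(EBImage::imageData(
                     EBImage::resize(EBImage::Image(ch), w = grid,
                                     h = grid)))
                 }),
            class = "cspwsBackbone")
}

#' Wrap an arbitrary feature extractor as a backbone
#'
#' @param forward Function mapping an H x W x 3 array to a numeric vector.
#' @param n_features Output length of \code{forward}.
#' @param name Identifier recorded with extracted features.
#' @return A backbone object for \code{\link{extractFeatures}}.
#' @export
customBackbone <- function(forward, n_features, name = "custom") {
  structure(list(name = name, n_features = as.integer(n_features),
                 forward = forward),
            class = "cspwsBackbone")
}

#' Extract a deep-feature vector from a preprocessed image
#'
#' Deterministic map from image to fixed-length feature vector via the
#' backbone's forward pass (for convolutional backbones, the spatial average
#' of the final activation maps).
#'
#' @param image Numeric H x W x 3 array from \code{\link{preprocessDMap}}.
#' @param backbone A backbone object.
#' @return Numeric feature vector of length \code{backbone$n_features}.
#' @export
extractFeatures <- function(image, backbone) {
  stopIfNot(inherits(backbone, "cspwsBackbone"),
            "'backbone' must be a cspwsBackbone")
  stopIfNot(is.array(image) && length(dim(image)) == 3 &&
              dim(image)[3] == 3,
            "image must be an H x W x 3 array")
  v <- backbone$forward(image)
  if (length(v) != backbone$n_features || any(!is.finite(v)))
    stop("backbone returned an invalid feature vector")
  v
}

#' Feature matrix for the cells of a materialized cohort
#'
#' Preprocesses every cell's D map and runs the backbone, returning the
#' cells-by-features matrix used by the classifier.
#'
#' @param cohort A \linkS4class{Cohort} materialized with images.
#' @param backbone A backbone object.
#' @param size Preprocessing output size.
#' @return Numeric matrix (one row per cell).
#' @export
cellFeatureMatrix <- function(cohort, backbone, size = 64L) {
  n <- nrow(cohort@cells)
  stopIfNot(length(cohort@images) == n,
            "cohort must be materialized with per-cell images")
  t(vapply(seq_len(n), function(k)
    extractFeatures(preprocessDMap(cellDMap(cohort, k), size = size),
                    backbone),
    numeric(backbone$n_features)))
}

actFun <- function(x) tanh(x)
actGrad <- function(a) 1 - a^2

#' Train a symmetric autoencoder for feature compression
#'
#' Five-layer encoder and mirrored five-layer decoder with tanh hidden
#' activations and linear latent/output layers, layer widths tapering
#' geometrically from the input length to the latent dimension, trained
#' full-batch with Adam on mean-squared reconstruction error for a fixed
#' number of epochs. Inputs are standardized internally (the scaling is
#' stored in the encoder).
#'
#' @param features Numeric matrix (observations x input features).
#' @param latent_dim Compressed representation size (default 40), strictly
#'   less than the input dimension.
#' @param epochs Training epochs (default 50); the loss curve is recorded
#'   with exactly this many entries.
#' @param seed Seed for weight initialization.
#' @param lr Adam learning rate.
#' @param n_layers Encoder depth (default 5).
#' @return List of class \code{cspwsEncoder} with the encoder weights,
#'   standardization, and \code{loss_curve}.
#' @export
trainAutoencoder <- function(features, latent_dim = 40L, epochs = 50L,
                             seed = 1L, lr = 2e-3, n_layers = 5L) {
  stopIfNot(is.matrix(features) && nrow(features) >= latent_dim,
            "need at least latent_dim training vectors")
  d <- ncol(features)
  if (latent_dim >= d)
    stop(sprintf("latent_dim (%d) must be smaller than input dim (%d)",
                 latent_dim, d))
  ctr <- colMeans(features)
  scl <- apply(features, 2, sd); scl[scl == 0] <- 1
  X <- sweep(sweep(features, 2, ctr), 2, scl, "/")
  widths <- round(exp(seq(log(d), log(latent_dim),
                          length.out = n_layers + 1)))
  widths[1] <- d; widths[n_layers + 1] <- latent_dim
  dims <- c(widths, rev(widths)[-1])       # encoder then decoder
  n_w <- length(dims) - 1
  init <- withSeed(seed, lapply(seq_len(n_w), function(l)
    list(W = matrix(rnorm(dims[l] * dims[l + 1],
                          sd = sqrt(1 / dims[l])),
                    dims[l], dims[l + 1]),
         b = rep(0, dims[l + 1]))))
  layers <- init
  linear_out <- c(n_layers, n_w)           # latent and reconstruction layers
  mw <- lapply(layers, function(l) list(W = 0 * l$W, b = 0 * l$b))
  vw <- mw
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  loss_curve <- numeric(epochs)
  for (ep in seq_len(epochs)) {
    acts <- vector("list", n_w + 1)
    acts[[1]] <- X
    for (l in seq_len(n_w)) {
      z <- sweep(acts[[l]] %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
      acts[[l + 1]] <- if (l %in% linear_out) z else actFun(z)
    }
    err <- acts[[n_w + 1]] - X
    loss_curve[ep] <- mean(err^2)
    delta <- 2 * err / (n * d)
    for (l in rev(seq_len(n_w))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1) {
        delta <- delta %*% t(layers[[l]]$W)
        if (!((l - 1) %in% linear_out)) delta <- delta * actGrad(acts[[l]])
      }
      mw[[l]]$W <- b1 * mw[[l]]$W + (1 - b1) * gW
      mw[[l]]$b <- b1 * mw[[l]]$b + (1 - b1) * gb
      vw[[l]]$W <- b2 * vw[[l]]$W + (1 - b2) * gW^2
      vw[[l]]$b <- b2 * vw[[l]]$b + (1 - b2) * gb^2
      corr <- sqrt(1 - b2^ep) / (1 - b1^ep)
      layers[[l]]$W <- layers[[l]]$W -
        lr * corr * mw[[l]]$W / (sqrt(vw[[l]]$W) + eps)
      layers[[l]]$b <- layers[[l]]$b -
        lr * corr * mw[[l]]$b / (sqrt(vw[[l]]$b) + eps)
    }
  }
  structure(list(layers = layers[seq_len(n_layers)],
                 latent_dim = as.integer(latent_dim),
                 input_dim = d, center = ctr, scale = scl,
                 n_layers = as.integer(n_layers),
                 loss_curve = loss_curve),
            class = "cspwsEncoder")
}

#' Encode feature vectors to the latent representation
#'
#' @param features Numeric matrix (or single vector) of raw features with
#'   the encoder's input length.
#' @param encoder A \code{cspwsEncoder} from \code{\link{trainAutoencoder}}.
#' @return Matrix of latent vectors (rows match \code{features}).
#' @export
encodeFeatures <- function(features, encoder) {
  stopIfNot(inherits(encoder, "cspwsEncoder"),
            "'encoder' must be a cspwsEncoder")
  if (is.vector(features)) features <- matrix(features, nrow = 1)
  if (ncol(features) != encoder$input_dim)
    stop(sprintf("feature length %d does not match encoder input %d",
                 ncol(features), encoder$input_dim))
  a <- sweep(sweep(features, 2, encoder$center), 2, encoder$scale, "/")
  for (l in seq_len(encoder$n_layers)) {
    z <- sweep(a %*% encoder$layers[[l]]$W, 2, encoder$layers[[l]]$b, "+")
    a <- if (l == encoder$n_layers) z else actFun(z)
  }
  a
}

#' Rank-based area under the ROC curve
#'
#' Mann-Whitney AUC: the probability that a random case scores above a
#' random control, with ties contributing one half.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels (1/TRUE = case).
#' @return AUC in [0, 1].
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Optimal classification cutpoint
#'
#' Chooses the score threshold (among midpoints of sorted unique scores,
#' plus sentinels below and above the data) that maximizes the number of
#' correct classifications, predicting case for scores at or above the
#' threshold. Ties in accuracy are broken toward higher sensitivity, then
#' toward the lower threshold.
#'
#' @param scores Numeric scores (higher = more case-like).
#' @param labels Binary labels (1/TRUE = case).
#' @return List with threshold, sensitivity, specificity, accuracy.
#' @export
optimalCutpoint <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  u <- sort(unique(scores))
  thr <- c(u[1] - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
           u[length(u)] + 1)
  best <- NULL
  for (t_ in thr) {
    pred <- as.integer(scores >= t_)
    tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
    se <- tp / n1; sp <- tn / n0
    cand <- list(threshold = t_, sensitivity = se, specificity = sp,
                 accuracy = (tp + tn) / length(labels))
    if (is.null(best) || cand$accuracy > best$accuracy ||
        (cand$accuracy == best$accuracy &&
         (cand$sensitivity > best$sensitivity ||
          (cand$sensitivity == best$sensitivity &&
           cand$threshold < best$threshold))))
      best <- cand
  }
  best
}

defaultRfGrid <- function(n_features) {
  expand.grid(ntree = 150L,
              mtry = unique(pmax(1L, c(floor(sqrt(n_features)),
                                       floor(n_features / 3)))),
              nodesize = c(1L, 5L))
}

#' Train a grid-searched random-forest classifier
#'
#' Random-forest probability classifier with hyperparameters chosen by grid
#' search over an inner stratified cross-validation on the training data
#' only (selection by mean inner AUC). The returned object records the
#' chosen configuration, the grid results, and an audit of the row indices
#' seen during training.
#'
#' @param latents Numeric matrix of (latent) features, training rows only.
#' @param labels Binary labels (both classes required).
#' @param grid data.frame of configurations with columns ntree, mtry,
#'   nodesize; NULL for the default grid.
#' @param inner_folds Inner CV folds used by the grid search.
#' @param seed Seed for inner splits and forest growth.
#' @param row_ids Optional identifiers of the training rows, recorded in the
#'   audit.
#' @return List with model, chosen (1-row data.frame), grid_results, audit.
#' @export
trainClassifier <- function(latents, labels, grid = NULL, inner_folds = 3L,
                            seed = 1L, row_ids = NULL) {
  labels <- as.integer(as.logical(labels))
  if (length(unique(labels)) < 2)
    stop("both classes must be present in the training labels")
  if (is.null(grid)) grid <- defaultRfGrid(ncol(latents))
  y <- factor(labels, levels = c(0, 1))
  if (nrow(grid) > 1) {
    folds <- stratifiedFolds(labels, k = inner_folds,
                             seed = childSeed(seed, 1))
    grid$inner_auc <- vapply(seq_len(nrow(grid)), function(g) {
      aucs <- vapply(seq_len(inner_folds), function(f) {
        tr <- folds != f
        if (length(unique(labels[!tr])) < 2) return(NA_real_)
        fit <- withSeed(childSeed(seed, 10 + g * inner_folds + f),
          randomForest::randomForest(
            x = latents[tr, , drop = FALSE], y = y[tr],
            ntree = grid$ntree[g], mtry = grid$mtry[g],
            nodesize = grid$nodesize[g]))
        pr <- predict(fit, latents[!tr, , drop = FALSE],
                      type = "prob")[, "1"]
        rocAuc(pr, labels[!tr])
      }, 0)
      mean(aucs, na.rm = TRUE)
    }, 0)
    best <- which.max(grid$inner_auc)
  } else best <- 1L
  model <- withSeed(childSeed(seed, 2),
    randomForest::randomForest(x = latents, y = y,
                               ntree = grid$ntree[best],
                               mtry = grid$mtry[best],
                               nodesize = grid$nodesize[best]))
  list(model = model, chosen = grid[best, , drop = FALSE],
       grid_results = grid,
       audit = list(n_train = nrow(latents),
                    row_ids = row_ids %||% seq_len(nrow(latents))))
}

#' Classifier probability scores
#'
#' @param classifier Result of \code{\link{trainClassifier}}.
#' @param latents Numeric matrix of latent features.
#' @return Case-probability per row.
#' @export
predictScores <- function(classifier, latents) {
  predict(classifier$model, latents, type = "prob")[, "1"]
}

# Stratified fold assignment: within each class, a random permutation is
# dealt round-robin across folds, so fold class counts differ by at most 1.
stratifiedFolds <- function(labels, k, seed) {
  assign <- integer(length(labels))
  withSeed(seed, {
    for (cl in unique(labels)) {
      w <- which(labels == cl)
      assign[w] <- (sample(seq_along(w)) %% k) + 1L
    }
  })
  assign
}

#' Repeated stratified cross-validation of the AI pipeline
#'
#' Evaluates the full feature-compression + classification pipeline by
#' k-fold cross-validation stratified by class at the PATIENT level (all
#' cells of a patient stay on one side of every split), repeated with
#' reshuffled folds. In each of the k x repeats folds, the autoencoder and
#' the grid-searched random forest are fit on training-fold cells only;
#' validation cells are scored, scores are averaged per patient, and AUC,
#' sensitivity and specificity at the fold's optimal cutpoint are computed
#' on validation patients.
#'
#' @param features Cells-by-features matrix (see
#'   \code{\link{cellFeatureMatrix}}).
#' @param patient_id Patient identifier per cell.
#' @param label Binary class label per cell (constant within patient).
#' @param k Folds per repeat (default 4).
#' @param repeats Repeats (default 5), giving k x repeats fold entries.
#' @param latent_dim,epochs Autoencoder settings.
#' @param rf_grid Random-forest grid (NULL for default).
#' @param seed Master seed.
#' @return A \linkS4class{CVReport}.
#' @export
repeatedStratifiedCv <- function(features, patient_id, label, k = 4L,
                                 repeats = 5L, latent_dim = 40L,
                                 epochs = 50L, rf_grid = NULL, seed = 1L) {
  stopIfNot(nrow(features) == length(patient_id) &&
              nrow(features) == length(label),
            "features, patient_id and label sizes differ")
  label <- as.integer(as.logical(label))
  pats <- unique(patient_id)
  plab <- vapply(pats, function(p) {
    l <- unique(label[patient_id == p])
    if (length(l) != 1) stop("label not constant within patient ", p)
    l
  }, 0L)
  if (min(table(plab)) < k)
    stop("need at least k patients per class for stratified k-fold CV")
  rows <- list(); audit <- list()
  for (rep_ in seq_len(repeats)) {
    fold_of <- stratifiedFolds(plab, k, childSeed(seed, 1000 + rep_))
    for (f in seq_len(k)) {
      val_pat <- pats[fold_of == f]
      tr_cells <- which(!(patient_id %in% val_pat))
      va_cells <- which(patient_id %in% val_pat)
      if (length(intersect(patient_id[tr_cells], patient_id[va_cells])))
        stop("internal error: patient with cells on both sides of a split")
      fseed <- childSeed(seed, 2000 + rep_ * 10 + f)
      enc <- trainAutoencoder(features[tr_cells, , drop = FALSE],
                              latent_dim = latent_dim, epochs = epochs,
                              seed = childSeed(fseed, 1))
      lat_tr <- encodeFeatures(features[tr_cells, , drop = FALSE], enc)
      lat_va <- encodeFeatures(features[va_cells, , drop = FALSE], enc)
      clf <- trainClassifier(lat_tr, label[tr_cells], grid = rf_grid,
                             seed = childSeed(fseed, 2),
                             row_ids = tr_cells)
      sc <- predictScores(clf, lat_va)
      pv <- unique(patient_id[va_cells])
      pscore <- vapply(pv, function(p)
        mean(sc[patient_id[va_cells] == p]), 0)
      plv <- plab[match(pv, pats)]
      cut <- optimalCutpoint(pscore, plv)
      rows[[length(rows) + 1]] <- data.frame(
        repeat_ = rep_, fold = f, auc = rocAuc(pscore, plv),
        sensitivity = cut$sensitivity, specificity = cut$specificity,
        threshold = cut$threshold)
      audit[[length(audit) + 1]] <- list(
        repeat_ = rep_, fold = f,
        train_patients = sort(setdiff(pats, val_pat)),
        val_patients = sort(val_pat),
        classifier_rows = clf$audit$row_ids)
    }
  }
  folds <- do.call(rbind, rows)
  new("CVReport", folds = folds,
      auc_mean = mean(folds$auc), auc_sd = sd(folds$auc),
      se_mean = mean(folds$sensitivity), se_sd = sd(folds$sensitivity),
      sp_mean = mean(folds$specificity), sp_sd = sd(folds$specificity),
      config = list(k = k, repeats = repeats, latent_dim = latent_dim,
                    epochs = epochs,
                    rf_grid = rf_grid %||% "default"),
      seed = seed, audit = audit)
}
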