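#' Normalize a raw cube by the reference wave
#'
#' Divides every pixel's spectrum by the reference spectrum acquired at a
#' blank region of the slide: out(x, y, lambda) = raw(x, y, lambda) /
#' reference(lambda).
#'
#' @param raw 3D numeric array (x, y, lambda) of raw intensities.
#' @param reference_spectrum Per-wavelength reference intensities, strictly
#'   positive, same length as the cube's lambda axis.
#' @param lambda_grid Wavelengths in nm (defaults to the plane index).
#' @param pixel_pitch Physical pixel size in nm.
#' @return A \linkS4class{SpectralCube}.
#' @export
normalizeByReference <- function(raw, reference_spectrum,
                                 lambda_grid = NULL, pixel_pitch = 150) {
  stopIfNot(is.array(raw) && length(dim(raw)) == 3,
            "'raw' must be a 3D (x, y, lambda) array")
  if (dim(raw)[3] != length(reference_spectrum))
    stop(sprintf(
      "lambda axes differ: cube has %d planes, reference has %d entries",
      dim(raw)[3], length(reference_spectrum)))
  if (any(!is.finite(reference_spectrum)) || any(reference_spectrum <= 0))
    stop("reference spectrum must be strictly positive and finite")
  if (is.null(lambda_grid)) lambda_grid <- seq_len(dim(raw)[3])
  out <- sweep(raw, 3, reference_spectrum, "/")
  new("SpectralCube", data = out, lambda_grid = lambda_grid,
      pixel_pitch = pixel_pitch)
}

#' Compute the spectral fluctuation map Sigma
#'
#' Per pixel, Sigma is the standard deviation over wavelength of the
#' detrended normalized spectrum. Detrending subtracts a low-order
#' polynomial baseline (order 1 by default, removing the slowly varying
#' reflectance slope); the residual sum of squares is divided by
#' (n_lambda - 1 - order) so white noise contributes its variance without
#' bias. Order 0 reduces to the plain sample SD.
#'
#' @param cube A \linkS4class{SpectralCube} with >= 3 wavelength samples.
#' @param detrend_order Polynomial order of the per-pixel baseline (>= 0).
#' @return A \linkS4class{SigmaMap}.
#' @examples
#' lam <- seq(500, 700, by = 2)
#' arr <- array(1, c(4, 4, length(lam)))
#' arr <- sweep(arr, 3, 0.1 * sin(2 * pi * (lam - 500) / 50), "+")
#' cube <- new("SpectralCube", data = arr, lambda_grid = lam,
#'             pixel_pitch = 150)
#' imageValues(computeSigmaMap(cube, detrend_order = 0))[1, 1]  # ~ 0.1/sqrt(2)
#' @export
computeSigmaMap <- function(cube, detrend_order = 1) {
  stopIfNot(is(cube, "SpectralCube"), "'cube' must be a SpectralCube")
  stopIfNot(detrend_order >= 0, "'detrend_order' must be >= 0")
  d <- dim(cube@data)
  L <- d[3]
  stopIfNot(L >= 3, "need at least 3 wavelength samples")
  stopIfNot(L - 1 - detrend_order >= 1,
            "detrend order too high for the number of wavelengths")
  bad <- which(!is.finite(cube@data), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("non-finite spectrum at pixel (%d, %d)", bad[1, 1],
                 bad[1, 2]))
  flat <- matrix(aperm(cube@data, c(3, 1, 2)), L, d[1] * d[2])
  lam_c <- cube@lambda_grid - mean(cube@lambda_grid)
  if (diff(range(lam_c)) > 0) lam_c <- lam_c / (diff(range(lam_c)) / 2)
  X <- outer(lam_c, 0:detrend_order, "^")
  Q <- qr.Q(qr(X))
  res <- flat - Q %*% crossprod(Q, flat)
  sig <- sqrt(colSums(res^2) / (L - 1 - detrend_order))
  new("SigmaMap", values = matrix(sig, d[1], d[2]),
      provenance = sprintf("cube %dx%dx%d", d[1], d[2], d[3]))
}

#' Automated nucleus segmentation
#'
#' Automated stand-in for interactive nucleus outlining: global Otsu
#' threshold on a 2D summary image (typically the Sigma map), hole filling,
#' connected-component labelling, and an area filter. Masks are returned
#' sorted by area, largest first; an image where no component passes the
#' filter yields an empty list.
#'
#' @param image 2D numeric matrix (finite values).
#' @param min_area,max_area Component area bounds in pixels.
#' @param fill_holes Fill interior holes of each component.
#' @return List of \linkS4class{NucleusMask} objects.
#' @export
segmentNuclei <- function(image, min_area = 50, max_area = Inf,
                          fill_holes = TRUE) {
  stopIfNot(is.matrix(image) && all(is.finite(image)),
            "'image' must be a finite numeric matrix")
  rng <- range(image)
  if (diff(rng) == 0) return(list())
  norm <- (image - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm))
  bw <- EBImage::Image((norm > th) * 1)
  if (fill_holes) bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  labm <- EBImage::imageData(lab)
  if (max(labm) == 0) return(list())
  areas <- tabulate(labm[labm > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  keep <- keep[order(areas[keep], decreasing = TRUE)]
  lapply(keep, function(id) nucleusMask(labm == id))
}

#' Dice overlap coefficient between two masks
#'
#' @param a,b \linkS4class{NucleusMask} objects or logical matrices of equal
#'   shape.
#' @return Dice coefficient in [0, 1].
#' @export
diceCoefficient <- function(a, b) {
  av <- if (is(a, "NucleusMask")) a@values else a
  bv <- if (is(b, "NucleusMask")) b@values else b
  stopIfNot(identical(dim(av), dim(bv)), "mask shapes differ")
  2 * sum(av & bv) / (sum(av) + sum(bv))
}
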