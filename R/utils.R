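#' @importFrom stats rnorm runif rbinom approx integrate lm coef predict sd
#'   qt t.test quantile fft na.omit setNames complete.cases var cor cov
#'   residuals alias
#' @importFrom methods new validObject is slot slotNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Run expr with a fixed RNG seed, restoring the caller's RNG state afterwards.
# All stochastic operations in the package go through this so that a given
# (function, seed) pair is bit-reproducible regardless of surrounding code.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite integer")
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child-seed derivation (linear congruential step + stream
# offset), kept strictly below 2^31 so set.seed() accepts it everywhere.
childSeed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) + 1
  ((1103515245 * s + 12345 + 9973 * as.double(stream)) %% 2147483629)
}

# FNV-1a hash of a character scalar, returned as hex. Used to fingerprint
# configurations in reports and stage markers (no cryptographic intent).
fnv1a <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31 - 2^30), as.integer(b)) + 2^30
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%08x", as.integer(h %% 2^31))
}

configHash <- function(x) {
  fnv1a(jsonlite::toJSON(x, auto_unbox = TRUE, digits = 12, force = TRUE))
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

#' Diagnostic group vocabulary
#'
#' The fixed set of diagnostic endpoints used throughout the package, ordered
#' by severity of colonoscopic finding: healthy controls, diminutive adenoma
#' (< 5 mm), nondiminutive adenoma (5-9 mm), advanced adenoma (>= 10 mm,
#' > 25\% villous features or high-grade dysplasia), hereditary non-polyposis
#' colorectal cancer, and colorectal cancer.
#'
#' @return Character vector of group labels in severity order.
#' @export
diagnosticGroups <- function() {
  c("control", "DA", "NDA", "AA", "HNPCC", "cancer")
}

historyCategories <- function() c("none", "low", "high")
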