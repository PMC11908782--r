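# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Trapezoidal integral of y sampled at uniform spacing dx.
trapz <- function(y, dx) {
  n <- length(y)
  if (n < 2L) return(0)
  dx * sum((y[-1] + y[-n]) / 2)
}

# Discrete Gaussian kernel, truncated at 4 sigma (normalized to sum 1).
gaussianKernel <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- ceiling(4 * sigma)
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Reflection-padded index vector for a signal of length n and pad r
# (scipy 'reflect' style: abcd -> dcba|abcd|dcba).
reflectIndex <- function(n, r) {
  idx <- seq(1L - r, n + r)
  idx <- ifelse(idx < 1L, 1L - idx, idx)
  idx <- ifelse(idx > n, 2L * n + 1L - idx, idx)
  # repeated reflection for pads longer than the signal
  while (any(idx < 1L | idx > n)) {
    idx <- ifelse(idx < 1L, 2L - idx, idx)
    idx <- ifelse(idx > n, 2L * n - idx, idx)
  }
  idx
}

# 1-D convolution with reflection padding applied along the rows of a matrix
# (each column is an independent signal).
convolveColumns <- function(m, kernel) {
  if (length(kernel) == 1L) return(m)
  r <- (length(kernel) - 1L) %/% 2L
  n <- nrow(m)
  padded <- m[reflectIndex(n, r), , drop = FALSE]
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(kernel))
    out <- out + kernel[j] * padded[j:(j + n - 1L), , drop = FALSE]
  out
}

# One step of 8-neighbourhood binary dilation on a logical matrix.
dilateOnce <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  out <- mask
  shifts <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
                 c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  for (s in shifts) {
    sh <- matrix(FALSE, n, m)
    rsrc <- max(1, 1 - s[1]):min(n, n - s[1])
    csrc <- max(1, 1 - s[2]):min(m, m - s[2])
    sh[rsrc + s[1], csrc + s[2]] <- mask[rsrc, csrc]
    out <- out | sh
  }
  out
}

maskToMatrix <- function(maskLogical) {
  which(maskLogical, arr.ind = TRUE)[, 1:2, drop = FALSE]
}

matrixToMask <- function(coords, dimIm) {
  m <- matrix(FALSE, dimIm[1], dimIm[2])
  m[coords] <- TRUE
  m
}

# Pearson R^2 of an lm fit (guarding constant-response degeneracy).
r2OfFit <- function(fit, y) {
  ssTot <- sum((y - mean(y))^2)
  if (ssTot == 0) return(1)
  1 - sum(residuals(fit)^2) / ssTot
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write numbers losslessly (round-trip through as.numeric).
formatNum <- function(x) {
  ifelse(is.na(x), "", vapply(x, function(v) sprintf("%.17g", v), character(1)))
}
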