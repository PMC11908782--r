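#' Spatio-temporal Gaussian filtering of an image stack
#'
#' Separable smoothing: a 2-D Gaussian (sigma in pixels) applied per frame,
#' followed by a 1-D Gaussian along time (sigma in frames). Kernels are
#' truncated at 4 sigma and normalized; edges use reflection padding. The
#' study settings are sigma_xy = 1 px for surface views, 2 px for prism
#' views, and sigma_t = 2 frames. A sigma of 0 disables that axis.
#'
#' @param stack numeric array rows x cols x frames
#' @param sigmaXyPx spatial sigma in pixels (>= 0)
#' @param sigmaTFrames temporal sigma in frames (>= 0)
#' @return filtered array of the same shape (double)
#' @export
gaussianFilterStack <- function(stack, sigmaXyPx = 1, sigmaTFrames = 2) {
  if (sigmaXyPx < 0 || sigmaTFrames < 0)
    stop("invalid argument: sigma values must be >= 0")
  d <- dim(stack)
  stopifnot(length(d) == 3L)
  out <- stack * 1.0
  if (sigmaXyPx > 0) {
    k <- gaussianKernel(sigmaXyPx)
    for (t in seq_len(d[3])) {
      fr <- out[, , t]
      fr <- convolveColumns(fr, k)          # along rows
      fr <- t(convolveColumns(t(fr), k))    # along cols
      out[, , t] <- fr
    }
  }
  if (sigmaTFrames > 0) {
    k <- gaussianKernel(sigmaTFrames)
    # row-by-row to keep peak memory at one frame-row slab, not a full copy
    for (r in seq_len(d[1]))
      out[r, , ] <- t(convolveColumns(t(out[r, , ]), k))
  }
  out
}

#' Temporal Gaussian filtering of extracted traces
#'
#' The 1-D temporal arm of [gaussianFilterStack()] applied directly to a
#' frames x cells trace matrix, for workflows that start from pre-extracted
#' traces rather than image stacks. Same kernel (truncated at 4 sigma,
#' normalized) and reflection padding.
#'
#' @param mat frames x cells numeric matrix
#' @param sigmaTFrames temporal sigma in frames (0 returns the input)
#' @return filtered matrix
#' @export
gaussianFilterTraces <- function(mat, sigmaTFrames = 2) {
  if (sigmaTFrames < 0) stop("invalid argument: sigma must be >= 0")
  if (sigmaTFrames == 0) return(mat)
  convolveColumns(as.matrix(mat), gaussianKernel(sigmaTFrames))
}

# Grow an annulus around `mask` by repeated 8-neighbourhood dilation until
# its area (excluding every cell mask) reaches areaFactor x the ROI area.
growAnnulus <- function(mask, excludeMask, areaFactor, maxIter = 200L) {
  target <- areaFactor * sum(mask)
  current <- mask
  for (i in seq_len(maxIter)) {
    current <- dilateOnce(current)
    annulus <- current & !excludeMask
    if (sum(annulus) >= target) return(annulus)
  }
  NULL
}

#' Extract per-cell and neuropil traces from an image stack
#'
#' The cell trace is the mean pixel value inside the ROI mask per frame.
#' The neuropil trace is the mean over an annulus grown from the ROI by
#' binary dilation until its area is at least \code{neuropilAreaFactor}
#' times the ROI area (default 4), excluding all cell masks.
#'
#' @param stack numeric array rows x cols x frames
#' @param rois a [RoiSet]
#' @param neuropilAreaFactor minimum annulus-to-ROI area ratio
#' @param frameRateHz acquisition rate stored with the traces
#' @return a [RawTraces]
#' @export
extractSignals <- function(stack, rois, neuropilAreaFactor = 4,
                           frameRateHz = 29.9) {
  d <- dim(stack)
  stopifnot(length(d) == 3L)
  if (!all(d[1:2] == rois@imageDim))
    stop("invalid argument: stack and ROI image dimensions disagree")
  nF <- d[3]; nC <- length(rois@cellIds)
  flat <- matrix(stack, nrow = d[1] * d[2], ncol = nF)
  allCells <- matrix(FALSE, d[1], d[2])
  for (m in rois@masks) allCells[m] <- TRUE
  cellTr <- matrix(0, nF, nC)
  npTr <- matrix(0, nF, nC)
  for (i in seq_len(nC)) {
    m <- rois@masks[[i]]
    lin <- (m[, 2] - 1L) * d[1] + m[, 1]
    cellTr[, i] <- colMeans(flat[lin, , drop = FALSE])
    ann <- growAnnulus(matrixToMask(m, d[1:2]), allCells, neuropilAreaFactor)
    if (is.null(ann) || !any(ann))
      stop(sprintf("extraction error: empty neuropil annulus for cell '%s'",
                   rois@cellIds[i]))
    alin <- which(ann)
    npTr[, i] <- colMeans(flat[alin, , drop = FALSE])
  }
  new("RawTraces", traces = cellTr, neuropilTraces = npTr,
      frameRateHz = frameRateHz, cellIds = rois@cellIds)
}

#' Neuropil correction
#'
#' Subtracts a scaled neuropil signal from each somatic trace:
#' corrected = cell - coefficient x neuropil, element-wise. The default
#' coefficient is 0.4.
#'
#' @param raw a [RawTraces], or a numeric matrix (then \code{neuropilMat}
#'   must be supplied)
#' @param coefficient contamination coefficient in \[0, 1\]
#' @param neuropilMat neuropil matrix when \code{raw} is a plain matrix
#' @return corrected trace matrix (frames x cells)
#' @export
neuropilCorrect <- function(raw, coefficient = 0.4, neuropilMat = NULL) {
  if (coefficient < 0 || coefficient > 1)
    stop("invalid argument: coefficient must be in [0, 1]")
  if (is(raw, "RawTraces")) {
    cellM <- raw@traces; npM <- raw@neuropilTraces
  } else {
    cellM <- raw; npM <- neuropilMat
    if (is.null(npM) || !all(dim(cellM) == dim(npM)))
      stop("invalid argument: trace and neuropil matrices must match in shape")
  }
  cellM - coefficient * npM
}

# Fit the bleaching baseline of one trace. Returns list(baseline, intercept,
# slope). percentile_trend: robust line through the running low-percentile
# envelope; linear_trend: ordinary least squares on the trace itself.
fitBaseline <- function(x, frameRateHz, method, percentile, windowS) {
  n <- length(x)
  tIdx <- seq_len(n)
  if (method == "linear_trend") {
    fit <- stats::lm.fit(cbind(1, tIdx), x)
    co <- fit$coefficients
  } else {
    w <- max(3L, min(n, round(windowS * frameRateHz)))
    # a straight line is being fitted, so the running envelope is evaluated
    # on a coarse grid of window positions rather than at every frame
    at <- unique(round(seq(1, n, length.out = min(n, 256L))))
    env <- vapply(at, function(t0) {
      lo <- max(1L, t0 - w %/% 2L)
      hi <- min(n, lo + w - 1L)
      stats::quantile(x[lo:hi], probs = percentile, names = FALSE)
    }, numeric(1))
    tEnv <- at
    ols <- stats::lm(env ~ tEnv)
    co <- stats::coef(ols)
    if (sum(stats::residuals(ols)^2) > 1e-10 * max(1, mean(env)^2)) {
      rfit <- tryCatch(MASS::rlm(env ~ tEnv, maxit = 50),
                       error = function(e) NULL, warning = function(w2) NULL)
      if (!is.null(rfit)) co <- stats::coef(rfit)
    }
  }
  list(baseline = co[1] + co[2] * tIdx, intercept = unname(co[1]),
       slope = unname(co[2]))
}

#' Compute dF/F with a bleaching-corrected baseline
#'
#' \eqn{\Delta F/F(t) = (F(t) - B(t)) / B(t)}. The baseline \eqn{B(t)} is a
#' per-cell straight line capturing the slow photobleaching trend:
#' \describe{
#'   \item{percentile_trend (default)}{robust linear fit to the running
#'     10th-percentile envelope of the trace, so stimulus-evoked transients
#'     do not drag the baseline up;}
#'   \item{linear_trend}{plain least-squares line through the trace.}
#' }
#' A precomputed baseline matrix may be supplied instead via
#' \code{baseline}.
#'
#' @param corrected frames x cells matrix of neuropil-corrected
#'   fluorescence, or a [RawTraces] (corrected with coefficient 0.4 first)
#' @param frameRateHz frame rate
#' @param baselineMethod "percentile_trend" or "linear_trend"
#' @param percentile envelope percentile (default 0.1)
#' @param windowS running-envelope window in seconds (default 10)
#' @param baseline optional explicit baseline matrix (frames x cells)
#' @param cellIds optional cell identifiers
#' @return a [DffTraces]
#' @export
computeDff <- function(corrected, frameRateHz = 29.9,
                       baselineMethod = c("percentile_trend", "linear_trend"),
                       percentile = 0.1, windowS = 10, baseline = NULL,
                       cellIds = NULL) {
  baselineMethod <- match.arg(baselineMethod)
  if (is(corrected, "RawTraces")) {
    frameRateHz <- corrected@frameRateHz
    cellIds <- cellIds %||% corrected@cellIds
    corrected <- neuropilCorrect(corrected)
  }
  corrected <- as.matrix(corrected)
  if (nrow(corrected) < 2L)
    stop("invalid argument: need at least 2 frames")
  nC <- ncol(corrected)
  cellIds <- cellIds %||% colnames(corrected) %||% sprintf("cell_%03d",
                                                           seq_len(nC))
  out <- matrix(0, nrow(corrected), nC)
  info <- data.frame(cell_id = cellIds,
                     method = if (is.null(baseline)) baselineMethod
                              else "supplied",
                     intercept = NA_real_, slope = NA_real_)
  bad <- character(0)
  for (i in seq_len(nC)) {
    if (is.null(baseline)) {
      bl <- fitBaseline(corrected[, i], frameRateHz, baselineMethod,
                        percentile, windowS)
      b <- bl$baseline
      info$intercept[i] <- bl$intercept
      info$slope[i] <- bl$slope
    } else b <- baseline[, i]
    if (any(b <= 0)) { bad <- c(bad, cellIds[i]); next }
    out[, i] <- (corrected[, i] - b) / b
  }
  if (length(bad))
    stop("degenerate baseline (non-positive) for cells: ",
         paste(bad, collapse = ", "))
  new("DffTraces", dff = out, frameRateHz = frameRateHz, cellIds = cellIds,
      baselineInfo = info)
}
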