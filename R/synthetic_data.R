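#' Generate ground-truth cells for a synthetic experiment
#'
#' Cells are laid out in a square field of view. Under the gradient layout,
#' the latent preferred tone frequency (in log2 Hz) increases linearly with
#' each cell's projection onto the stated axis, spanning
#' \code{gradientSpanOct} octaves across the field, plus per-cell jitter —
#' an implantable tonotopic gradient. Under the random layout preferences
#' are drawn uniformly from the tone grid. The reported \code{true_btf_hz}
#' and \code{true_bmf_hz} are the grid frequencies with maximal expected
#' response under the cell's Gaussian tuning curve (the latent preference is
#' continuous), which makes exact-grid recovery well defined downstream.
#'
#' Module/matrix compartments are assigned by spatially contiguous circular
#' blobs whose total area matches \code{moduleFraction} of the field in
#' expectation.
#'
#' @param n number of cells (>= 1)
#' @param layout "gradient" or "random"
#' @param axisAngleDeg gradient axis angle in degrees (0 = +x)
#' @param gradientSpanOct octaves spanned by the gradient across the field
#' @param moduleFraction expected fraction of cells inside modules
#' @param fieldUm side of the square field of view in microns
#' @param gridFreqsHz tone-frequency grid (default the 5-40 kHz half-octave
#'   grid)
#' @param modGridHz AM-rate grid used for best-modulation-frequency draws
#' @param jitterOct SD of per-cell jitter on the latent preference (octaves)
#' @param responsiveFraction fraction of cells that respond at all
#' @param modalityProbs probabilities for aud_only / som_only / aud_som
#' @param timingProbs probabilities for onset / offset / onset_offset
#' @param ampRange range of peak evoked dF/F amplitudes
#' @param bwRange range of Gaussian tuning bandwidths (octaves)
#' @param thresholdDb per-compartment response threshold (dB SPL), named
#'   c(module=, matrix=)
#' @param unmodFactorRange range of the unmodulated-noise response relative
#'   to the best-frequency response
#' @param nBlobs number of module blobs
#' @param seed RNG seed
#' @return data.frame of ground-truth cells, one row per cell
#' @export
generateCells <- function(n, layout = c("gradient", "random"),
                          axisAngleDeg = 0, gradientSpanOct = 3,
                          moduleFraction = 0.3, fieldUm = 400,
                          gridFreqsHz = buildToneGrid(5000, 40000)@carrierFreqsHz,
                          modGridHz = c(2, 4, 8, 16, 32, 64, 128, 256),
                          jitterOct = 0.25, responsiveFraction = 0.85,
                          modalityProbs = c(aud_only = 0.7, som_only = 0.1,
                                            aud_som = 0.2),
                          timingProbs = c(onset = 0.7, offset = 0.2,
                                          onset_offset = 0.1),
                          ampRange = c(0.5, 1.5), bwRange = c(0.6, 1.0),
                          thresholdDb = c(module = 40, matrix = 40),
                          unmodFactorRange = c(0.2, 0.6), nBlobs = 3L,
                          seed = 1L) {
  layout <- match.arg(layout)
  stopifnot(n >= 1, moduleFraction >= 0, moduleFraction <= 1)
  withSeed(seed, {
    x <- stats::runif(n, 0, fieldUm)
    y <- stats::runif(n, 0, fieldUm)
    # compartments: circular module blobs totalling moduleFraction of area
    compartment <- rep("matrix", n)
    if (moduleFraction >= 1) {
      compartment <- rep("module", n)
    } else if (moduleFraction > 0) {
      rBlob <- sqrt(moduleFraction * fieldUm^2 / (pi * nBlobs))
      cx <- stats::runif(nBlobs, min(rBlob, fieldUm / 2),
                         fieldUm - min(rBlob, fieldUm / 2))
      cy <- stats::runif(nBlobs, min(rBlob, fieldUm / 2),
                         fieldUm - min(rBlob, fieldUm / 2))
      for (b in seq_len(nBlobs))
        compartment[(x - cx[b])^2 + (y - cy[b])^2 <= rBlob^2] <- "module"
    }
    logGrid <- log2(gridFreqsHz)
    if (layout == "gradient") {
      dir <- c(cos(axisAngleDeg * pi / 180), sin(axisAngleDeg * pi / 180))
      proj <- x * dir[1] + y * dir[2]
      rng <- range(proj)
      frac <- if (diff(rng) > 0) (proj - rng[1]) / diff(rng) else rep(0.5, n)
      latentBtf <- min(logGrid) + frac * gradientSpanOct +
        stats::rnorm(n, 0, jitterOct)
    } else {
      latentBtf <- sample(logGrid, n, replace = TRUE)
    }
    latentBmf <- sample(log2(modGridHz), n, replace = TRUE)
    snap <- function(latent, grid) grid[max.col(-abs(outer(latent, log2(grid),
                                                           "-")))]
    modality <- sample(names(modalityProbs), n, replace = TRUE,
                       prob = modalityProbs)
    data.frame(
      cell_id = sprintf("cell_%03d", seq_len(n)),
      x_um = x, y_um = y,
      compartment = compartment,
      latent_btf_oct = latentBtf,
      latent_bmf_oct = latentBmf,
      true_btf_hz = snap(latentBtf, gridFreqsHz),
      true_bmf_hz = snap(latentBmf, modGridHz),
      response_amp = stats::runif(n, ampRange[1], ampRange[2]),
      tuning_bw_oct = stats::runif(n, bwRange[1], bwRange[2]),
      threshold_db = unname(thresholdDb[ifelse(compartment == "module",
                                               "module", "matrix")]),
      unmod_factor = stats::runif(n, unmodFactorRange[1], unmodFactorRange[2]),
      response_timing = sample(names(timingProbs), n, replace = TRUE,
                               prob = timingProbs),
      modality = modality,
      bimodal_gain = stats::rlnorm(n, 0, 0.4),
      responsive = stats::runif(n) < responsiveFraction,
      stringsAsFactors = FALSE
    )
  })
}

# Calcium-transient kernel: difference of exponentials (rise ~50 ms, decay
# ~700 ms, resembling a red GECI), sampled at the frame rate and normalized
# to peak 1 so the evoked peak dF/F equals the stated amplitude exactly.
transientKernel <- function(frameRateHz, riseS = 0.05, decayS = 0.7) {
  t <- seq(0, 5 * decayS, by = 1 / frameRateHz)
  k <- exp(-t / decayS) - exp(-t / riseS)
  k / max(k)
}

# Evoked amplitude (peak dF/F) of each cell for one stimulus combination.
evokedAmps <- function(cells, combo, maxLevelDb) {
  n <- nrow(cells)
  amp <- numeric(n)
  aud <- cells$modality %in% c("aud_only", "aud_som")
  som <- cells$modality %in% c("som_only", "aud_som")
  lvl <- combo$level_db
  scale <- pmin(pmax((lvl - cells$threshold_db) /
                       pmax(maxLevelDb - cells$threshold_db, 1e-9), 0), 1)
  type <- combo$stimulus_type
  if (type == "pure_tone") {
    d <- log2(combo$freq_hz) - cells$latent_btf_oct
    amp <- ifelse(aud, cells$response_amp *
                    exp(-d^2 / (2 * cells$tuning_bw_oct^2)) * scale, 0)
  } else if (type == "am_noise") {
    if (combo$mod_hz > 0) {
      d <- log2(combo$mod_hz) - cells$latent_bmf_oct
      amp <- ifelse(aud, cells$response_amp *
                      exp(-d^2 / (2 * cells$tuning_bw_oct^2)) * scale, 0)
    } else {
      amp <- ifelse(aud, cells$response_amp * cells$unmod_factor * scale, 0)
    }
  } else if (type == "unmod_noise") {
    amp <- ifelse(aud, cells$response_amp * cells$unmod_factor * scale, 0)
  } else if (type == "somatosensory") {
    amp <- ifelse(som, cells$response_amp, 0)
  } else if (type == "bimodal") {
    amp <- ifelse(aud, cells$response_amp * cells$unmod_factor *
                    cells$bimodal_gain, 0)
  }
  amp * as.numeric(cells$responsive)
}

#' Simulate fluorescence traces for ground-truth cells under a schedule
#'
#' The recorded somatic trace is
#' \code{bleach(t) * (F0 + F0 * sum of transients) + neuropilMix * np(t) +
#' noise}; the companion neuropil trace is \code{np(t) + noise}. Transients
#' follow a difference-of-exponentials kernel; evoked magnitude follows a
#' Gaussian tuning surface in log frequency centered on the cell's latent
#' preference, scaled linearly with sound level from the cell's threshold
#' to the grid maximum. Offset-timing cells emit transients at stimulus
#' offset; onset/offset cells at both. Bimodal trials scale the auditory
#' response by the cell's \code{bimodal_gain}. Fully deterministic under a
#' fixed seed.
#'
#' @param cells data.frame from [generateCells()]
#' @param schedule a [StimulusSchedule]
#' @param frameRateHz sampling rate (default 29.9 Hz)
#' @param baselineF mean somatic baseline fluorescence (a.u.)
#' @param neuropilF neuropil baseline fluorescence (a.u.)
#' @param bleachTauS photobleaching exponential time constant (s; Inf
#'   disables bleaching)
#' @param noiseSd additive Gaussian noise SD (a.u.)
#' @param neuropilMix neuropil contamination coefficient in the somatic
#'   trace
#' @param riseS,decayS transient kernel time constants (s)
#' @param spontRateHz Poisson rate of spontaneous transients per cell (0
#'   disables; the spontaneous-activity tests use 0.05 Hz)
#' @param seed RNG seed
#' @return a [SyntheticExperiment]
#' @export
simulateTraces <- function(cells, schedule, frameRateHz = 29.9,
                           baselineF = 100, neuropilF = 50,
                           bleachTauS = Inf, noiseSd = 10,
                           neuropilMix = 0.4, riseS = 0.05, decayS = 0.7,
                           spontRateHz = 0, seed = 1L) {
  stopifnot(is(schedule, "StimulusSchedule"))
  if (frameRateHz <= 0)
    stop("invalid argument: frameRateHz must be positive")
  if (nrow(schedule@trials) == 0L) stop("schedule is empty")
  nF <- round(schedule@totalDurationS * frameRateHz)
  nC <- nrow(cells)
  kern <- transientKernel(frameRateHz, riseS, decayS)
  cb <- combos(schedule@grid)
  maxLevel <- max(schedule@grid@levelsDb)
  durS <- schedule@grid@durationMs / 1000
  ampByCombo <- matrix(0, nrow(cb), nC)          # combos x cells
  for (j in seq_len(nrow(cb)))
    ampByCombo[j, ] <- evokedAmps(cells, cb[j, ], maxLevel)
  withSeed(seed, {
    f0 <- baselineF * stats::runif(nC, 0.8, 1.2)
    sig <- matrix(0, nF, nC)                     # dF/F-scale transient sum
    addKernel <- function(col, frame0, amp) {
      if (amp == 0 || frame0 > nF) return()
      idx <- frame0:min(nF, frame0 + length(kern) - 1L)
      sig[idx, col] <<- sig[idx, col] + amp * kern[seq_along(idx)]
    }
    onsetOnly <- cells$response_timing == "onset"
    offsetOnly <- cells$response_timing == "offset"
    both <- cells$response_timing == "onset_offset"
    for (k in seq_len(nrow(schedule@trials))) {
      tr <- schedule@trials[k, ]
      onFrame <- round(tr$onset_s * frameRateHz) + 1L
      offFrame <- round((tr$onset_s + durS) * frameRateHz) + 1L
      amps <- ampByCombo[tr$combo_id, ]
      for (i in which(amps > 0)) {
        if (onsetOnly[i] || both[i]) addKernel(i, onFrame, amps[i])
        if (offsetOnly[i] || both[i]) addKernel(i, offFrame, amps[i])
      }
    }
    if (spontRateHz > 0) {
      for (i in seq_len(nC)) {
        nEv <- stats::rpois(1, spontRateHz * schedule@totalDurationS)
        if (nEv > 0) {
          at <- sort(stats::runif(nEv, 0, schedule@totalDurationS))
          for (a in at) addKernel(i, round(a * frameRateHz) + 1L,
                                  cells$response_amp[i])
        }
      }
    }
    tS <- (seq_len(nF) - 1) / frameRateHz
    bleach <- if (is.finite(bleachTauS)) exp(-tS / bleachTauS) else rep(1, nF)
    # shared neuropil signal: bleached baseline plus a weak evoked component
    drive <- numeric(nF)
    for (k in seq_len(nrow(schedule@trials))) {
      fr0 <- round(schedule@trials$onset_s[k] * frameRateHz) + 1L
      idx <- fr0:min(nF, fr0 + length(kern) - 1L)
      drive[idx] <- drive[idx] + kern[seq_along(idx)]
    }
    npClean <- neuropilF * bleach * (1 + 0.1 * drive)
    somatic <- bleach * (matrix(f0, nF, nC, byrow = TRUE) * (1 + sig)) +
      neuropilMix * npClean
    noise <- if (noiseSd > 0)
      matrix(stats::rnorm(nF * nC, 0, noiseSd), nF, nC) else 0
    npNoise <- if (noiseSd > 0)
      matrix(stats::rnorm(nF * nC, 0, noiseSd), nF, nC) else 0
    new("SyntheticExperiment",
        cells = cells, schedule = schedule, frameRateHz = frameRateHz,
        traces = somatic + noise,
        neuropilTraces = matrix(npClean, nF, nC) + npNoise,
        params = list(baselineF = baselineF, f0 = f0, neuropilF = neuropilF,
                      bleachTauS = bleachTauS, noiseSd = noiseSd,
                      neuropilMix = neuropilMix, riseS = riseS,
                      decayS = decayS, spontRateHz = spontRateHz,
                      neuropilClean = npClean),
        seed = as.integer(seed))
  })
}

#' Simulate stimulus-free traces with spontaneous transients
#'
#' For testing spontaneous-event detection: a polynomial-like bleaching
#' trend times a constant baseline, plus Poisson-timed calcium transients
#' and Gaussian noise. Event amplitude is expressed in units of the noise
#' SD. Returns the trace matrix with the ground-truth event frames as an
#' attribute.
#'
#' @param nCells number of cells
#' @param durationS recording length (s)
#' @param frameRateHz sampling rate
#' @param rateHz Poisson event rate per cell (default 0.05 Hz)
#' @param ampSd transient peak amplitude in noise-SD units (default 5)
#' @param noiseSd additive noise SD (a.u.)
#' @param baselineF baseline fluorescence (a.u.)
#' @param bleachTauS bleaching time constant (s)
#' @param seed RNG seed
#' @return frames x cells matrix with attribute "events" (list of frame
#'   vectors per cell)
#' @export
simulateSpontaneousTraces <- function(nCells, durationS, frameRateHz = 29.9,
                                      rateHz = 0.05, ampSd = 5, noiseSd = 5,
                                      baselineF = 100, bleachTauS = 300,
                                      seed = 1L) {
  nF <- round(durationS * frameRateHz)
  kern <- transientKernel(frameRateHz)
  withSeed(seed, {
    out <- matrix(stats::rnorm(nF * nCells, 0, noiseSd), nF, nCells)
    tS <- (seq_len(nF) - 1) / frameRateHz
    bleach <- if (is.finite(bleachTauS)) exp(-tS / bleachTauS) else rep(1, nF)
    events <- vector("list", nCells)
    for (i in seq_len(nCells)) {
      nEv <- stats::rpois(1, rateHz * durationS)
      frames <- integer(0)
      if (nEv > 0) {
        at <- sort(stats::runif(nEv, 2, durationS - 2))
        frames <- round(at * frameRateHz) + 1L
        # keep events separated by at least 2 s so hits are unambiguous
        if (length(frames) > 1L)
          frames <- frames[c(TRUE, diff(frames) > 2 * frameRateHz)]
        for (f in frames) {
          idx <- f:min(nF, f + length(kern) - 1L)
          out[idx, i] <- out[idx, i] + ampSd * noiseSd * kern[seq_along(idx)]
        }
      }
      events[[i]] <- frames
      out[, i] <- out[, i] + baselineF * bleach
    }
    attr(out, "events") <- events
    out
  })
}

#' Render a synthetic experiment as a pixel movie plus matching ROIs
#'
#' Each frame paints every cell's disk at its trace value over a uniform
#' neuropil background field (the clean neuropil signal). Cell positions
#' are scaled into the frame; overlapping somata are re-jittered up to 1000
#' times before a layout error is raised. The returned RoiSet uses the same
#' oval rasterization as the ImageJ ROI reader, so disk ROIs round-trip
#' exactly.
#'
#' @param experiment a [SyntheticExperiment]
#' @param imageSizePx side of the square frame in pixels
#' @param cellRadiusPx disk radius in pixels
#' @param tiffPath optional path; if given the stack is written as a
#'   multi-page 16-bit TIFF
#' @param seed RNG seed for jittering overlapping cells
#' @return list(stack = rows x cols x frames array, rois = [RoiSet],
#'   pixelSizeUm)
#' @export
renderMovie <- function(experiment, imageSizePx = 256, cellRadiusPx = 5,
                        tiffPath = NULL, seed = 1L) {
  cells <- experiment@cells
  nC <- nrow(cells)
  margin <- cellRadiusPx + 2
  span <- max(max(cells$x_um) - min(cells$x_um),
              max(cells$y_um) - min(cells$y_um), 1e-9)
  pixelSizeUm <- span / (imageSizePx - 2 * margin)
  px <- round((cells$x_um - min(cells$x_um)) / pixelSizeUm) + margin
  py <- round((cells$y_um - min(cells$y_um)) / pixelSizeUm) + margin
  minSep <- 2 * cellRadiusPx + 1
  withSeed(seed, {
    for (att in seq_len(1001L)) {
      d2 <- as.matrix(stats::dist(cbind(px, py)))
      diag(d2) <- Inf
      clash <- which(apply(d2 < minSep, 1, any))
      if (!length(clash)) break
      if (att > 1000L) stop("layout error: cells cannot be placed without overlap")
      j <- clash[1]
      px[j] <- sample(seq(margin, imageSizePx - margin), 1)
      py[j] <- sample(seq(margin, imageSizePx - margin), 1)
    }
  })
  maskList <- vector("list", nC)
  for (i in seq_len(nC)) {
    maskList[[i]] <- ovalMaskFromBox(py[i] - cellRadiusPx - 1L,
                                     px[i] - cellRadiusPx - 1L,
                                     py[i] + cellRadiusPx,
                                     px[i] + cellRadiusPx,
                                     c(imageSizePx, imageSizePx))
  }
  rois <- new("RoiSet", cellIds = cells$cell_id, masks = maskList,
              compartments = cells$compartment, pixelSizeUm = pixelSizeUm,
              imageDim = as.integer(c(imageSizePx, imageSizePx)))
  nF <- nrow(experiment@traces)
  npClean <- experiment@params$neuropilClean %||% rep(0, nF)
  stack <- array(rep(npClean, each = imageSizePx * imageSizePx),
                 c(imageSizePx, imageSizePx, nF))
  flatDim <- imageSizePx * imageSizePx
  frameOffsets <- (seq_len(nF) - 1L) * flatDim
  for (i in seq_len(nC)) {
    m <- maskList[[i]]
    lin <- (m[, 2] - 1L) * imageSizePx + m[, 1]
    stack[outer(lin, frameOffsets, "+")] <-
      rep(experiment@traces[, i], each = length(lin))
  }
  if (!is.null(tiffPath)) writeStack16(stack, tiffPath)
  list(stack = stack, rois = rois, pixelSizeUm = pixelSizeUm)
}

#' Write an image stack as a multi-page 16-bit TIFF
#'
#' Values are clamped at \[0, 65535\] and rounded.
#' @param stack rows x cols x frames array (a.u.)
#' @param path output file
#' @return invisibly, \code{path}
#' @export
writeStack16 <- function(stack, path) {
  d <- dim(stack)
  pages <- lapply(seq_len(d[3]), function(t)
    pmin(pmax(round(stack[, , t]), 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16, compression = "none")
  invisible(path)
}

#' Read a multi-page TIFF stack into an array
#'
#' @param path TIFF file
#' @param scale16 multiply by 65535 to recover a.u. values written by
#'   [writeStack16()] (default TRUE)
#' @return rows x cols x frames numeric array
#' @export
readStack <- function(path, scale16 = TRUE) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3L) p[, , 1] else p)
  d <- dim(pages[[1]])
  out <- array(unlist(pages), c(d[1], d[2], length(pages)))
  if (scale16) out <- out * 65535
  out
}
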