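#' StimulusGrid: a level-by-frequency stimulus grid
#'
#' Describes one acoustic (or somatosensory) stimulus set as the cross of
#' sound levels with carrier frequencies (pure tones) or amplitude-modulation
#' rates (AM noise). A modulation rate of 0 Hz denotes unmodulated broadband
#' noise. Somatosensory and bimodal "grids" hold a single combination.
#'
#' @slot stimulusType one of \code{"pure_tone"}, \code{"am_noise"},
#'   \code{"unmod_noise"}, \code{"somatosensory"}, \code{"bimodal"}
#' @slot levelsDb sound levels in dB SPL, strictly increasing
#' @slot carrierFreqsHz tone carrier frequencies in Hz (empty unless pure_tone)
#' @slot modFreqsHz AM rates in Hz, 0 allowed (empty unless am_noise)
#' @slot durationMs stimulus duration in ms
#' @slot isiMs inter-stimulus interval in ms
#' @export
setClass("StimulusGrid",
  representation(
    stimulusType  = "character",
    levelsDb      = "numeric",
    carrierFreqsHz = "numeric",
    modFreqsHz    = "numeric",
    durationMs    = "numeric",
    isiMs         = "numeric"
  ),
  prototype(carrierFreqsHz = numeric(0), modFreqsHz = numeric(0),
            durationMs = 500, isiMs = 600)
)

setValidity("StimulusGrid", function(object) {
  msg <- character(0)
  types <- c("pure_tone", "am_noise", "unmod_noise", "somatosensory", "bimodal")
  if (length(object@stimulusType) != 1L || !object@stimulusType %in% types)
    msg <- c(msg, sprintf("stimulusType must be one of %s",
                          paste(types, collapse = ", ")))
  if (length(object@levelsDb) < 1L)
    msg <- c(msg, "levelsDb must be non-empty")
  if (is.unsorted(object@levelsDb, strictly = TRUE))
    msg <- c(msg, "levelsDb must be strictly increasing")
  if (length(object@carrierFreqsHz)) {
    if (any(object@carrierFreqsHz <= 0))
      msg <- c(msg, "carrier frequencies must be positive")
    if (is.unsorted(object@carrierFreqsHz, strictly = TRUE))
      msg <- c(msg, "carrier frequencies must be strictly increasing")
  }
  if (length(object@modFreqsHz)) {
    if (any(object@modFreqsHz < 0))
      msg <- c(msg, "modulation frequencies must be >= 0")
    if (is.unsorted(object@modFreqsHz, strictly = TRUE))
      msg <- c(msg, "modulation frequencies must be strictly increasing")
  }
  if (object@durationMs <= 0 || object@isiMs < 0)
    msg <- c(msg, "durationMs must be > 0 and isiMs >= 0")
  if (length(msg)) msg else TRUE
})

#' StimulusSchedule: a randomized presentation order for a grid
#'
#' Each combination of the underlying [StimulusGrid] appears exactly
#' \code{nRepeats} times; onsets are regularly spaced by
#' duration + inter-stimulus interval.
#'
#' @slot grid the [StimulusGrid] the schedule draws from
#' @slot trials data.frame with columns \code{trial_index}, \code{combo_id},
#'   \code{onset_s}
#' @slot nRepeats presentations per combination
#' @slot totalDurationS schedule length in seconds
#' @slot seed randomization seed used for the permutation
#' @export
setClass("StimulusSchedule",
  representation(
    grid = "StimulusGrid",
    trials = "data.frame",
    nRepeats = "integer",
    totalDurationS = "numeric",
    seed = "integer"
  )
)

setValidity("StimulusSchedule", function(object) {
  msg <- character(0)
  tr <- object@trials
  need <- c("trial_index", "combo_id", "onset_s")
  if (!all(need %in% names(tr)))
    return(sprintf("trials must have columns %s", paste(need, collapse = ", ")))
  tab <- table(tr$combo_id)
  if (length(tab) && any(tab != object@nRepeats))
    msg <- c(msg, "every combo_id must appear exactly nRepeats times")
  step <- (object@grid@durationMs + object@grid@isiMs) / 1000
  if (nrow(tr) > 1L) {
    gaps <- diff(tr$onset_s)
    if (any(gaps < step - 1e-9))
      msg <- c(msg, "consecutive onsets must be separated by >= duration + ISI")
  }
  if (length(msg)) msg else TRUE
})

#' RoiSet: pixel masks for a set of cells
#'
#' @slot cellIds character cell identifiers
#' @slot masks list of two-column integer matrices (row, col), one per cell
#' @slot compartments per-cell compartment label: "module", "matrix" or
#'   "unknown"
#' @slot pixelSizeUm microns per pixel
#' @slot imageDim image dimensions c(rows, cols)
#' @export
setClass("RoiSet",
  representation(
    cellIds = "character",
    masks = "list",
    compartments = "character",
    pixelSizeUm = "numeric",
    imageDim = "integer"
  )
)

setValidity("RoiSet", function(object) {
  msg <- character(0)
  n <- length(object@cellIds)
  if (length(object@masks) != n || length(object@compartments) != n)
    msg <- c(msg, "cellIds, masks and compartments must have equal length")
  if (anyDuplicated(object@cellIds))
    msg <- c(msg, "cellIds must be unique")
  if (length(object@imageDim) != 2L || any(object@imageDim < 1L))
    msg <- c(msg, "imageDim must be two positive integers")
  ok <- vapply(object@masks, function(m) {
    is.matrix(m) && ncol(m) == 2L && nrow(m) >= 1L &&
      all(m[, 1] >= 1L) && all(m[, 1] <= object@imageDim[1]) &&
      all(m[, 2] >= 1L) && all(m[, 2] <= object@imageDim[2])
  }, logical(1))
  if (length(ok) && !all(ok))
    msg <- c(msg, "all masks must be non-empty (row, col) matrices inside the image")
  if (!all(object@compartments %in% c("module", "matrix", "unknown")))
    msg <- c(msg, "compartments must be module/matrix/unknown")
  if (object@pixelSizeUm <= 0)
    msg <- c(msg, "pixelSizeUm must be positive")
  if (length(msg)) msg else TRUE
})

#' RawTraces: per-cell fluorescence with companion neuropil
#'
#' @slot traces frames x cells matrix of mean ROI fluorescence (a.u.)
#' @slot neuropilTraces matrix of identical shape holding the surrounding
#'   neuropil signal
#' @slot frameRateHz acquisition frame rate
#' @slot cellIds column identifiers
#' @export
setClass("RawTraces",
  representation(
    traces = "matrix",
    neuropilTraces = "matrix",
    frameRateHz = "numeric",
    cellIds = "character"
  )
)

setValidity("RawTraces", function(object) {
  msg <- character(0)
  if (!all(dim(object@traces) == dim(object@neuropilTraces)))
    msg <- c(msg, "traces and neuropilTraces must have identical shape")
  if (nrow(object@traces) < 2L)
    msg <- c(msg, "need at least 2 frames")
  if (ncol(object@traces) != length(object@cellIds))
    msg <- c(msg, "one cellId per column required")
  if (!all(is.finite(object@traces)) || !all(is.finite(object@neuropilTraces)))
    msg <- c(msg, "all fluorescence values must be finite")
  if (object@frameRateHz <= 0)
    msg <- c(msg, "frameRateHz must be positive")
  if (length(msg)) msg else TRUE
})

#' DffTraces: fractional fluorescence change per cell
#'
#' \eqn{\Delta F/F(t) = (F(t) - B(t)) / B(t)} where \eqn{B(t)} is a
#' bleaching-corrected baseline model fitted per cell.
#'
#' @slot dff frames x cells matrix of dimensionless dF/F
#' @slot frameRateHz acquisition frame rate
#' @slot cellIds column identifiers
#' @slot baselineInfo data.frame (cell_id, method, intercept, slope)
#'   describing the fitted baseline model
#' @export
setClass("DffTraces",
  representation(
    dff = "matrix",
    frameRateHz = "numeric",
    cellIds = "character",
    baselineInfo = "data.frame"
  )
)

setValidity("DffTraces", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@dff)))
    msg <- c(msg, "dF/F values must be finite")
  if (ncol(object@dff) != length(object@cellIds))
    msg <- c(msg, "one cellId per column required")
  if (object@frameRateHz <= 0)
    msg <- c(msg, "frameRateHz must be positive")
  if (length(msg)) msg else TRUE
})

#' TrialTensor: stimulus-locked dF/F segments
#'
#' A 4-way array (cell x combo x repeat x time sample) of dF/F cut around
#' each stimulus presentation and grouped by stimulus combination.
#'
#' @slot data the 4-way array
#' @slot comboTable data.frame describing each combo (combo_id, stimulus_type,
#'   level_db, freq_hz, mod_hz)
#' @slot frameRateHz frame rate
#' @slot windowS trial window length in seconds
#' @slot preS seconds of pre-stimulus baseline included
#' @slot stimDurS stimulus duration in seconds
#' @slot cellIds cell identifiers along dim 1
#' @export
setClass("TrialTensor",
  representation(
    data = "array",
    comboTable = "data.frame",
    frameRateHz = "numeric",
    windowS = "numeric",
    preS = "numeric",
    stimDurS = "numeric",
    cellIds = "character"
  )
)

setValidity("TrialTensor", function(object) {
  msg <- character(0)
  d <- dim(object@data)
  if (length(d) != 4L)
    msg <- c(msg, "data must be a 4-way array (cell, combo, repeat, time)")
  else {
    if (d[1] != length(object@cellIds))
      msg <- c(msg, "dim 1 must match cellIds")
    if (d[2] != nrow(object@comboTable))
      msg <- c(msg, "dim 2 must match comboTable")
  }
  if (length(msg)) msg else TRUE
})

#' AxisSpec: an anatomical axis for tonotopy assessment
#'
#' @slot name axis label, e.g. "rostromedial-caudolateral"
#' @slot origin axis starting point (x, y) in microns
#' @slot direction unit direction vector
#' @export
setClass("AxisSpec",
  representation(name = "character", origin = "numeric", direction = "numeric")
)

setValidity("AxisSpec", function(object) {
  msg <- character(0)
  if (length(object@origin) != 2L || length(object@direction) != 2L)
    msg <- c(msg, "origin and direction must be length-2 numeric")
  else if (abs(sqrt(sum(object@direction^2)) - 1) > 1e-8)
    msg <- c(msg, "direction must have unit norm")
  if (length(msg)) msg else TRUE
})

#' TonotopyFit: binned geometric-mean BTF regression along an axis
#'
#' @slot axis the [AxisSpec] used
#' @slot binSizeUm distance bin size (microns)
#' @slot bins data.frame (distance_um, btf_hz, n_cells) of per-bin geometric
#'   means; empty bins absent
#' @slot scale "log2" (fit on log2 BTF) or "hz"
#' @slot r2Linear R-squared of the degree-1 fit
#' @slot r2Quadratic R-squared of the degree-2 fit (NA if < 4 bins)
#' @slot coefLinear linear fit coefficients
#' @slot coefQuadratic quadratic fit coefficients
#' @export
setClass("TonotopyFit",
  representation(
    axis = "AxisSpec",
    binSizeUm = "numeric",
    bins = "data.frame",
    scale = "character",
    r2Linear = "numeric",
    r2Quadratic = "numeric",
    coefLinear = "numeric",
    coefQuadratic = "numeric"
  )
)

#' SyntheticExperiment: ground-truthed simulated recording
#'
#' @slot cells data.frame of ground-truth cell parameters (one row per cell)
#' @slot schedule the [StimulusSchedule] that was "presented"
#' @slot frameRateHz sampling rate of the simulated traces
#' @slot traces frames x cells matrix of recorded somatic fluorescence (a.u.)
#' @slot neuropilTraces frames x cells matrix of measured neuropil signal
#' @slot params list of generator parameters (bleach tau, noise SD, mix, ...)
#' @slot seed simulation seed
#' @export
setClass("SyntheticExperiment",
  representation(
    cells = "data.frame",
    schedule = "StimulusSchedule",
    frameRateHz = "numeric",
    traces = "matrix",
    neuropilTraces = "matrix",
    params = "list",
    seed = "integer"
  )
)

setValidity("SyntheticExperiment", function(object) {
  msg <- character(0)
  if (!all(is.finite(object@traces)) || !all(is.finite(object@neuropilTraces)))
    msg <- c(msg, "all fluorescence values must be finite")
  nExp <- round(object@schedule@totalDurationS * object@frameRateHz)
  if (nrow(object@traces) != nExp)
    msg <- c(msg, "trace length must be round(totalDurationS * frameRateHz)")
  if (ncol(object@traces) != nrow(object@cells))
    msg <- c(msg, "one trace column per cell required")
  if (length(msg)) msg else TRUE
})

## ---- accessors ----

#' @rdname colliscope-generics
#' @aliases combos,StimulusGrid-method
#' @export
setMethod("combos", "StimulusGrid", function(x, ...) {
  type <- x@stimulusType
  if (type == "pure_tone") {
    df <- expand.grid(freq_hz = x@carrierFreqsHz, level_db = x@levelsDb,
                      KEEP.OUT.ATTRS = FALSE)
    df$mod_hz <- NA_real_
  } else if (type == "am_noise") {
    df <- expand.grid(mod_hz = x@modFreqsHz, level_db = x@levelsDb,
                      KEEP.OUT.ATTRS = FALSE)
    df$freq_hz <- NA_real_
  } else if (type == "unmod_noise") {
    df <- data.frame(level_db = x@levelsDb, freq_hz = NA_real_, mod_hz = 0)
  } else {
    df <- data.frame(level_db = max(x@levelsDb), freq_hz = NA_real_,
                     mod_hz = NA_real_)
  }
  df <- df[, c("level_db", "freq_hz", "mod_hz")]
  data.frame(combo_id = seq_len(nrow(df)), stimulus_type = type, df,
             row.names = NULL)
})

#' @rdname colliscope-generics
#' @aliases nCombos,StimulusGrid-method
#' @export
setMethod("nCombos", "StimulusGrid", function(x) nrow(combos(x)))

#' @rdname colliscope-generics
#' @aliases combos,StimulusSchedule-method
#' @export
setMethod("combos", "StimulusSchedule", function(x, ...) combos(x@grid))

#' @rdname colliscope-generics
#' @aliases trials,StimulusSchedule-method
#' @export
setMethod("trials", "StimulusSchedule", function(x) x@trials)

#' @rdname colliscope-generics
#' @aliases cellIds,RoiSet-method
#' @export
setMethod("cellIds", "RoiSet", function(x) x@cellIds)

#' @rdname colliscope-generics
#' @aliases masks,RoiSet-method
#' @export
setMethod("masks", "RoiSet", function(x) x@masks)

#' @rdname colliscope-generics
#' @aliases compartments,RoiSet-method
#' @export
setMethod("compartments", "RoiSet", function(x) x@compartments)

#' Centroids of an ROI set
#'
#' Mask-mean pixel positions scaled to microns. Returns a cells x 2 matrix
#' with columns \code{x_um} (column direction) and \code{y_um} (row
#' direction).
#' @rdname colliscope-generics
#' @aliases centroids,RoiSet-method
#' @export
setMethod("centroids", "RoiSet", function(x, ...) {
  out <- t(vapply(x@masks, function(m) {
    c(mean(m[, 2]) * x@pixelSizeUm, mean(m[, 1]) * x@pixelSizeUm)
  }, numeric(2)))
  dimnames(out) <- list(x@cellIds, c("x_um", "y_um"))
  out
})

#' @rdname colliscope-generics
#' @aliases traces,RawTraces-method
#' @export
setMethod("traces", "RawTraces", function(x) x@traces)

#' @rdname colliscope-generics
#' @aliases neuropil,RawTraces-method
#' @export
setMethod("neuropil", "RawTraces", function(x) x@neuropilTraces)

#' @rdname colliscope-generics
#' @aliases frameRate,RawTraces-method
#' @export
setMethod("frameRate", "RawTraces", function(x) x@frameRateHz)

#' @rdname colliscope-generics
#' @aliases cellIds,RawTraces-method
#' @export
setMethod("cellIds", "RawTraces", function(x) x@cellIds)

#' @rdname colliscope-generics
#' @aliases dff,DffTraces-method
#' @export
setMethod("dff", "DffTraces", function(x) x@dff)

#' @rdname colliscope-generics
#' @aliases frameRate,DffTraces-method
#' @export
setMethod("frameRate", "DffTraces", function(x) x@frameRateHz)

#' @rdname colliscope-generics
#' @aliases cellIds,DffTraces-method
#' @export
setMethod("cellIds", "DffTraces", function(x) x@cellIds)

#' @rdname colliscope-generics
#' @aliases cellIds,TrialTensor-method
#' @export
setMethod("cellIds", "TrialTensor", function(x) x@cellIds)

#' @rdname colliscope-generics
#' @aliases combos,TrialTensor-method
#' @export
setMethod("combos", "TrialTensor", function(x, ...) x@comboTable)

#' @rdname colliscope-generics
#' @aliases frameRate,TrialTensor-method
#' @export
setMethod("frameRate", "TrialTensor", function(x) x@frameRateHz)

#' @rdname colliscope-generics
#' @aliases traces,SyntheticExperiment-method
#' @export
setMethod("traces", "SyntheticExperiment", function(x) x@traces)

#' @rdname colliscope-generics
#' @aliases neuropil,SyntheticExperiment-method
#' @export
setMethod("neuropil", "SyntheticExperiment", function(x) x@neuropilTraces)

#' @rdname colliscope-generics
#' @aliases frameRate,SyntheticExperiment-method
#' @export
setMethod("frameRate", "SyntheticExperiment", function(x) x@frameRateHz)

#' @rdname colliscope-generics
#' @aliases cellIds,SyntheticExperiment-method
#' @export
setMethod("cellIds", "SyntheticExperiment", function(x) x@cells$cell_id)

## ---- show methods ----

setMethod("show", "StimulusGrid", function(object) {
  cat(sprintf("StimulusGrid [%s]: %d levels x %d frequencies = %d combos\n",
              object@stimulusType, length(object@levelsDb),
              max(1L, length(object@carrierFreqsHz), length(object@modFreqsHz)),
              nCombos(object)))
  cat(sprintf("  levels: %s dB SPL; duration %g ms, ISI %g ms\n",
              paste(object@levelsDb, collapse = ", "),
              object@durationMs, object@isiMs))
})

setMethod("show", "StimulusSchedule", function(object) {
  cat(sprintf(
    "StimulusSchedule: %d trials (%d combos x %d repeats), %.1f s, seed %d\n",
    nrow(object@trials), nCombos(object@grid), object@nRepeats,
    object@totalDurationS, object@seed))
})

setMethod("show", "RoiSet", function(object) {
  cat(sprintf("RoiSet: %d cells on a %d x %d image (%.3g um/px)\n",
              length(object@cellIds), object@imageDim[1], object@imageDim[2],
              object@pixelSizeUm))
  tab <- table(object@compartments)
  cat("  compartments:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
})

setMethod("show", "RawTraces", function(object) {
  cat(sprintf("RawTraces: %d frames x %d cells at %.1f Hz (with neuropil)\n",
              nrow(object@traces), ncol(object@traces), object@frameRateHz))
})

setMethod("show", "DffTraces", function(object) {
  cat(sprintf("DffTraces: %d frames x %d cells at %.1f Hz\n",
              nrow(object@dff), ncol(object@dff), object@frameRateHz))
  if (nrow(object@baselineInfo))
    cat("  baseline:", object@baselineInfo$method[1], "\n")
})

setMethod("show", "TrialTensor", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "TrialTensor: %d cells x %d combos x %d repeats x %d samples (%.2f s)\n",
    d[1], d[2], d[3], d[4], object@windowS))
})

setMethod("show", "AxisSpec", function(object) {
  cat(sprintf("AxisSpec '%s': origin (%g, %g) um, direction (%.3f, %.3f)\n",
              object@name, object@origin[1], object@origin[2],
              object@direction[1], object@direction[2]))
})

setMethod("show", "TonotopyFit", function(object) {
  cat(sprintf("TonotopyFit along '%s' (%g um bins, %s scale): %d bins\n",
              object@axis@name, object@binSizeUm, object@scale,
              nrow(object@bins)))
  cat(sprintf("  R2 linear = %.3f, R2 quadratic = %s\n", object@r2Linear,
              ifelse(is.na(object@r2Quadratic), "NA",
                     sprintf("%.3f", object@r2Quadratic))))
})

setMethod("show", "SyntheticExperiment", function(object) {
  cat(sprintf(
    "SyntheticExperiment: %d cells, %d frames at %.1f Hz, seed %d\n",
    nrow(object@cells), nrow(object@traces), object@frameRateHz, object@seed))
  cat(sprintf("  schedule: %d trials of '%s'\n", nrow(object@schedule@trials),
              object@schedule@grid@stimulusType))
})
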