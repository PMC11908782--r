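#' Run the full analysis pipeline and write its outputs
#'
#' Extraction (optional Gaussian filtering, ROI/neuropil averaging,
#' neuropil correction, dF/F) followed by trial segmentation, correlation
#' flagging, response magnitudes, best frequencies, receptive-field sums,
#' and (for tone grids with an axis) tonotopy fits and a pseudocolor BTF
#' map. Every output is a plain text table, JSON or PNG and the run is
#' fully deterministic, so two runs on the same inputs are byte-identical.
#'
#' @param schedule a [StimulusSchedule] describing the presented stimuli
#' @param stack optional rows x cols x frames array (requires \code{rois})
#' @param rois optional [RoiSet] (needed with \code{stack}, and for maps)
#' @param rawTraces optional [RawTraces] when extraction already happened
#' @param outDir output directory (created if absent)
#' @param sigmaXyPx,sigmaTFrames Gaussian filter sigmas (0 disables)
#' @param neuropilCoefficient neuropil correction coefficient
#' @param baselineMethod dF/F baseline model, see [computeDff()]
#' @param preS,postS trial window margins, see [segmentTrials()]
#' @param threshold correlation flagging threshold
#' @param axis optional [AxisSpec] for tonotopy assessment
#' @param binSizeUm tonotopy bin size
#' @return invisibly, a list with the main result objects
#' @export
runPipeline <- function(schedule, stack = NULL, rois = NULL,
                        rawTraces = NULL, outDir,
                        sigmaXyPx = 1, sigmaTFrames = 2,
                        neuropilCoefficient = 0.4,
                        baselineMethod = "percentile_trend",
                        preS = 0, postS = 0.6, threshold = 0.6,
                        axis = NULL, binSizeUm = 50) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(rawTraces)) {
    if (is.null(stack) || is.null(rois))
      stop("provide either rawTraces or both stack and rois")
    if (sigmaXyPx > 0 || sigmaTFrames > 0)
      stack <- gaussianFilterStack(stack, sigmaXyPx, sigmaTFrames)
    rawTraces <- extractSignals(stack, rois)
  } else if (sigmaTFrames > 0) {
    # trace-level input: apply the temporal arm of the filter only
    rawTraces <- new("RawTraces",
                     traces = gaussianFilterTraces(traces(rawTraces),
                                                   sigmaTFrames),
                     neuropilTraces = gaussianFilterTraces(
                       neuropil(rawTraces), sigmaTFrames),
                     frameRateHz = rawTraces@frameRateHz,
                     cellIds = rawTraces@cellIds)
  }
  corrected <- neuropilCorrect(rawTraces, neuropilCoefficient)
  dffObj <- computeDff(corrected, rawTraces@frameRateHz,
                       baselineMethod = baselineMethod,
                       cellIds = rawTraces@cellIds)

  trMat <- traces(rawTraces)
  colnames(trMat) <- rawTraces@cellIds
  utils::write.csv(data.frame(frame = seq_len(nrow(trMat)), trMat,
                              check.names = FALSE),
                   file.path(outDir, "traces.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(frame_rate_hz = rawTraces@frameRateHz,
         n_cells = ncol(trMat), n_frames = nrow(trMat),
         sigma_xy_px = sigmaXyPx, sigma_t_frames = sigmaTFrames,
         neuropil_coefficient = neuropilCoefficient,
         baseline_method = baselineMethod),
    file.path(outDir, "traces_meta.json"), auto_unbox = TRUE, digits = NA)

  tensor <- segmentTrials(dffObj, schedule, preS = preS, postS = postS)
  table <- flagResponsive(tensor, threshold = threshold)
  utils::write.csv(table, file.path(outDir, "response_table.csv"),
                   row.names = FALSE)

  domain <- if (schedule@grid@stimulusType == "pure_tone") "tone" else "am"
  bf <- suppressMessages(bestFrequency(table, domain))
  utils::write.csv(bf, file.path(outDir, "best_frequency.csv"),
                   row.names = FALSE)
  rfs <- receptiveFieldSum(table)
  utils::write.csv(rfs$perLevel, file.path(outDir, "rfs_per_level.csv"),
                   row.names = FALSE)
  utils::write.csv(rfs$total, file.path(outDir, "rfs_total.csv"),
                   row.names = FALSE)

  fit <- NULL
  if (!is.null(axis) && !is.null(rois) && nrow(bf) >= 1L) {
    cen <- centroids(rois)[bf$cell_id, , drop = FALSE]
    fit <- tryCatch(
      suppressMessages(assessTonotopy(cen, bf$best_hz, axis, binSizeUm)),
      error = function(e) NULL)
    if (!is.null(fit))
      writeTonotopyFit(fit, file.path(outDir, "tonotopy.json"),
                       file.path(outDir, "tonotopy_bins.csv"))
  }
  if (!is.null(rois)) {
    vals <- stats::setNames(rep(NA_real_, length(rois@cellIds)),
                            rois@cellIds)
    vals[bf$cell_id] <- bf$best_hz
    pal <- defaultPalette(sort(unique(bf$best_hz)))
    map <- renderMap(rois, vals, palette = pal)
    writeMapPng(map, file.path(outDir, "btf_map.png"))
  }
  jsonlite::write_json(
    list(threshold = threshold, pre_s = preS, post_s = postS,
         window_s = tensor@windowS, domain = domain,
         bin_size_um = binSizeUm,
         n_trials = nrow(schedule@trials),
         grid_type = schedule@grid@stimulusType),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(rawTraces = rawTraces, dff = dffObj, tensor = tensor,
                 responseTable = table, bestFrequency = bf, rfs = rfs,
                 tonotopy = fit))
}
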