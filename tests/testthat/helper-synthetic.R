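# Shared fixtures for the test suite: everything is generated in code.

# A small deterministic auditory experiment: tone grid, n repeats, cells of
# known ground truth, simulated traces.
makeToneExperiment <- function(nCells = 20, nRepeats = 5, seed = 1,
                               noiseSd = 10, layout = "random", ...) {
  grid <- buildToneGrid(5000, 40000)
  sch <- makeSchedule(grid, nRepeats = nRepeats, seed = seed)
  cells <- generateCells(nCells, layout = layout, seed = seed + 100)
  expt <- simulateTraces(cells, sch, noiseSd = noiseSd, bleachTauS = 600,
                         seed = seed + 200, ...)
  list(grid = grid, schedule = sch, cells = cells, expt = expt)
}

# Standard processing chain from a SyntheticExperiment to a flagged
# ResponseTable (temporal filter -> neuropil correction -> dF/F ->
# segmentation -> flagging).
processExperiment <- function(expt, schedule, threshold = 0.6,
                              sigmaT = 2) {
  corr <- neuropilCorrect(gaussianFilterTraces(traces(expt), sigmaT), 0.4,
                          gaussianFilterTraces(neuropil(expt), sigmaT))
  d <- computeDff(corr, frameRate(expt))
  tens <- segmentTrials(d, schedule)
  suppressMessages(flagResponsive(tens, threshold = threshold))
}

# Cells that all respond to auditory stimulation with fixed, hand-set
# parameters (for targeted single-cell assertions).
fixedCells <- function(btfHz, ampDff = 1, bwOct = 0.8, timing = "onset",
                       modality = "aud_only", bimodalGain = 1,
                       thresholdDb = 40, unmodFactor = 0.5) {
  n <- length(btfHz)
  data.frame(
    cell_id = sprintf("cell_%03d", seq_len(n)),
    x_um = seq(50, 350, length.out = n), y_um = rep(100, n),
    compartment = rep("matrix", n),
    latent_btf_oct = log2(btfHz),
    latent_bmf_oct = rep(log2(8), n),
    true_btf_hz = btfHz, true_bmf_hz = rep(8, n),
    response_amp = rep(ampDff, n), tuning_bw_oct = rep(bwOct, n),
    threshold_db = rep(thresholdDb, n),
    unmod_factor = rep(unmodFactor, n),
    response_timing = rep(timing, n), modality = rep(modality, n),
    bimodal_gain = rep(bimodalGain, n), responsive = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
}

# Ground truth for "responsive to this acoustic stimulation": responds at
# all AND has an auditory modality.
audResponsive <- function(cells) {
  cells$responsive & cells$modality %in% c("aud_only", "aud_som")
}
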