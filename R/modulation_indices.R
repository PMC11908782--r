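#' Spectral modulation index
#'
#' \code{(btf - unmod) / (btf + unmod)} for nonnegative response magnitudes
#' (AUC) to the best tone frequency and to unmodulated noise. Values near 1
#' mean tone-preferring, near -1 unmodulated-noise-preferring. Undefined
#' (NA) when both inputs are zero; those cells are excluded with a message.
#'
#' @param responseBtf AUC of the best-tone-frequency response (>= 0)
#' @param responseUnmod AUC of the unmodulated-noise response (>= 0)
#' @return numeric in \[-1, 1\] (vectorized)
#' @export
spectralModulationIndex <- function(responseBtf, responseUnmod) {
  if (any(responseBtf < 0, na.rm = TRUE) || any(responseUnmod < 0, na.rm = TRUE))
    stop("invalid argument: response magnitudes must be >= 0")
  denom <- responseBtf + responseUnmod
  out <- ifelse(denom == 0, NA_real_, (responseBtf - responseUnmod) / denom)
  if (any(denom == 0, na.rm = TRUE))
    message(sum(denom == 0, na.rm = TRUE),
            " cell(s) with both responses zero excluded (SMI undefined)")
  out
}

#' Temporal modulation index
#'
#' As [spectralModulationIndex()] with the best-modulation-frequency (AM)
#' response in place of the best tone response: values near 1 mean
#' AM-noise-preferring, near -1 unmodulated-noise-preferring.
#'
#' @param responseBmf AUC of the best-modulation-frequency response (>= 0)
#' @param responseUnmod AUC of the unmodulated-noise response (>= 0)
#' @return numeric in \[-1, 1\] (vectorized)
#' @export
temporalModulationIndex <- function(responseBmf, responseUnmod) {
  spectralModulationIndex(responseBmf, responseUnmod)
}

#' Bimodal response index
#'
#' RI = auditory response under simultaneous auditory + somatosensory
#' (bimodal) stimulation / auditory-alone response. RI > 1 marks enhanced
#' and RI < 1 suppressed auditory responses; exact equality (rare) is
#' classed "unchanged". Cells with a non-positive auditory-alone response
#' are excluded (NA) with a message.
#'
#' @param responseBimodal AUC under bimodal stimulation
#' @param responseAuditory AUC under auditory-alone stimulation (> 0)
#' @return data.frame (ri, bimodal_class)
#' @export
responseIndex <- function(responseBimodal, responseAuditory) {
  bad <- !(responseAuditory > 0)
  if (any(bad, na.rm = TRUE))
    message(sum(bad, na.rm = TRUE),
            " cell(s) with non-positive auditory response excluded (RI undefined)")
  ri <- ifelse(bad, NA_real_, responseBimodal / responseAuditory)
  cls <- ifelse(is.na(ri), NA_character_,
                ifelse(ri > 1, "enhanced",
                       ifelse(ri < 1, "suppressed", "unchanged")))
  data.frame(ri = ri, bimodal_class = cls, stringsAsFactors = FALSE)
}

#' Selectivity class from tone/AM responsiveness
#'
#' Cells responding only to pure tones are tone-selective, only to AM noise
#' noise-selective, to both non-selective, to neither unresponsive.
#'
#' @param toneAny logical: any flagged pure-tone combo
#' @param noiseAny logical: any flagged AM-noise combo
#' @return character vector: tone_sel / noise_sel / non_sel / unresponsive
#' @export
classifySelectivity <- function(toneAny, noiseAny) {
  ifelse(toneAny & !noiseAny, "tone_sel",
         ifelse(!toneAny & noiseAny, "noise_sel",
                ifelse(toneAny & noiseAny, "non_sel", "unresponsive")))
}

#' Modality class from auditory/somatosensory responsiveness
#'
#' Flags are computed at the 0.4 correlation threshold used for the
#' somatosensory comparisons.
#'
#' @param audFlag logical: responsive to auditory stimulation
#' @param somFlag logical: responsive to somatosensory stimulation
#' @return character vector: aud_sel / som_sel / aud_som_nonsel /
#'   unresponsive
#' @export
classifyModality <- function(audFlag, somFlag) {
  ifelse(audFlag & !somFlag, "aud_sel",
         ifelse(!audFlag & somFlag, "som_sel",
                ifelse(audFlag & somFlag, "aud_som_nonsel", "unresponsive")))
}

#' Response-timing class (onset / offset / onset-offset)
#'
#' Operationalizes ON/OFF labels: the peak of the trial-averaged dF/F is
#' measured separately in the stimulus window and the post-offset window
#' and compared against k times the pre-stimulus baseline SD. ON if only
#' the stimulus-window peak exceeds k*SD, OFF if only the offset-window
#' peak, ON/OFF if both, "none" if neither.
#'
#' @param trialAvg trial-averaged dF/F vector over the full window
#' @param frameRateHz frame rate
#' @param preS seconds of pre-stimulus baseline at the start of the window
#'   (must be > 0 to estimate the baseline SD)
#' @param stimDurS stimulus duration (s)
#' @param k SD multiplier (default 3)
#' @return one of "onset", "offset", "onset_offset", "none"
#' @export
classifyTiming <- function(trialAvg, frameRateHz, preS, stimDurS, k = 3) {
  nPre <- round(preS * frameRateHz)
  if (nPre < 2L)
    stop("invalid argument: need a pre-stimulus baseline (preS > 0)")
  base <- trialAvg[seq_len(nPre)]
  sdB <- stats::sd(base)
  if (sdB == 0) stop("degenerate baseline: zero SD in the pre-stimulus window")
  mB <- mean(base)
  stimEnd <- nPre + round(stimDurS * frameRateHz)
  stimPk <- max(trialAvg[(nPre + 1L):stimEnd]) - mB
  offPk <- if (stimEnd < length(trialAvg))
    max(trialAvg[(stimEnd + 1L):length(trialAvg)]) - mB else -Inf
  on <- stimPk > k * sdB
  off <- offPk > k * sdB
  if (on && off) "onset_offset" else if (on) "onset" else if (off) "offset"
  else "none"
}

#' Per-level spectral/temporal modulation flags
#'
#' A cell is spectrally modulated at a level when it is flagged for at
#' least one pure-tone combo or the unmodulated (0 Hz) noise combo at that
#' level and for no AM (> 0 Hz) combo there; temporally modulated when
#' flagged for at least one AM (> 0 Hz) combo at that level.
#'
#' @param table a ResponseTable covering tone and/or AM combos (rows from
#'   several grids may be concatenated)
#' @return data.frame (cell_id, level_db, spectrally_modulated,
#'   temporally_modulated)
#' @export
classifyModulated <- function(table) {
  key <- interaction(table$cell_id, table$level_db, drop = TRUE)
  res <- do.call(rbind, lapply(split(table, key), function(s) {
    toneOrUnmod <- any(s$responsive &
                         (!is.na(s$freq_hz) |
                            (!is.na(s$mod_hz) & s$mod_hz == 0)))
    am <- any(s$responsive & !is.na(s$mod_hz) & s$mod_hz > 0)
    data.frame(cell_id = s$cell_id[1], level_db = s$level_db[1],
               spectrally_modulated = toneOrUnmod && !am,
               temporally_modulated = am, stringsAsFactors = FALSE)
  }))
  res <- res[order(res$cell_id, res$level_db), ]
  rownames(res) <- NULL
  res
}

#' Per-cell, per-level SMI/TMI record
#'
#' Pairs the best response among flagged tone (or AM > 0 Hz) combos at each
#' sound level with the unmodulated-noise response at the same level. The
#' unmodulated response is taken from the 0 Hz AM combo of the same table;
#' unflagged responses count as magnitude 0 (no response).
#'
#' @param toneTable ResponseTable of the pure-tone grid
#' @param amTable ResponseTable of the AM-noise grid (contains the 0 Hz
#'   reference)
#' @param useGlobalBest use the cell's global best frequency at every level
#'   instead of the per-level best (default FALSE, per-level)
#' @return data.frame (cell_id, level_db, response_btf, response_bmf,
#'   response_unmod, smi, tmi)
#' @export
indexTable <- function(toneTable, amTable, useGlobalBest = FALSE) {
  aucOrZero <- function(s) if (nrow(s)) max(s$auc) else 0
  cellsAll <- sort(unique(c(toneTable$cell_id, amTable$cell_id)))
  levels <- sort(unique(c(toneTable$level_db, amTable$level_db)))
  globalBtf <- bestFrequency(toneTable, "tone")
  globalBmf <- bestFrequency(amTable, "am")
  rows <- list()
  for (cid in cellsAll) {
    for (lvl in levels) {
      tSub <- toneTable[toneTable$cell_id == cid & toneTable$level_db == lvl &
                          toneTable$responsive, , drop = FALSE]
      aSub <- amTable[amTable$cell_id == cid & amTable$level_db == lvl &
                        amTable$responsive & amTable$mod_hz > 0, , drop = FALSE]
      if (useGlobalBest) {
        bf <- globalBtf$best_hz[globalBtf$cell_id == cid]
        if (length(bf)) tSub <- tSub[tSub$freq_hz == bf, , drop = FALSE]
        bm <- globalBmf$best_hz[globalBmf$cell_id == cid]
        if (length(bm)) aSub <- aSub[aSub$mod_hz == bm, , drop = FALSE]
      }
      uSub <- amTable[amTable$cell_id == cid & amTable$level_db == lvl &
                        amTable$responsive & amTable$mod_hz == 0, , drop = FALSE]
      rBtf <- aucOrZero(tSub); rBmf <- aucOrZero(aSub); rUn <- aucOrZero(uSub)
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = cid, level_db = lvl, response_btf = rBtf,
        response_bmf = rBmf, response_unmod = rUn, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$smi <- suppressMessages(spectralModulationIndex(out$response_btf,
                                                      out$response_unmod))
  out$tmi <- suppressMessages(temporalModulationIndex(out$response_bmf,
                                                      out$response_unmod))
  out
}
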