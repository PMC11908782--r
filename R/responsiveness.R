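#' Segment dF/F traces into stimulus-locked trials
#'
#' Cuts a window \code{[onset - preS, onset + duration + postS]} around
#' every presentation and groups segments by stimulus combination (level x
#' frequency). The sample count is \code{round(window_s * frame_rate)}; the
#' default post-stimulus window of 0.6 s (one ISI) keeps offset responses
#' inside the window. Repeats may come from several runs of the same grid:
#' pass lists of traces and schedules and the segments are concatenated by
#' combo identity.
#'
#' @param dffObj a [DffTraces] (or list of them, one per run)
#' @param schedule a [StimulusSchedule] (or list matching \code{dffObj});
#'   all runs must share the same grid
#' @param preS seconds of pre-stimulus baseline to include (default 0)
#' @param postS seconds after stimulus offset to include (default 0.6)
#' @return a [TrialTensor] (cell x combo x repeat x time)
#' @export
segmentTrials <- function(dffObj, schedule, preS = 0, postS = 0.6) {
  dffList <- if (is.list(dffObj)) dffObj else list(dffObj)
  schedList <- if (is.list(schedule)) schedule else list(schedule)
  stopifnot(length(dffList) == length(schedList))
  g <- schedList[[1]]@grid
  cb <- combos(g)
  fr <- dffList[[1]]@frameRateHz
  durS <- g@durationMs / 1000
  winS <- preS + durS + postS
  nSamp <- round(winS * fr)
  ids <- dffList[[1]]@cellIds
  nCell <- length(ids)

  segs <- vector("list", nrow(cb))  # per combo: list of repeat matrices
  badTrials <- character(0)
  for (run in seq_along(dffList)) {
    dmat <- dffList[[run]]@dff
    sch <- schedList[[run]]
    if (!identical(combos(sch@grid), cb))
      stop("all runs must share the same stimulus grid")
    for (k in seq_len(nrow(sch@trials))) {
      tr <- sch@trials[k, ]
      i0 <- floor((tr$onset_s - preS) * fr) + 1L
      i1 <- i0 + nSamp - 1L
      if (i0 < 1L || i1 > nrow(dmat)) {
        badTrials <- c(badTrials, sprintf("run %d trial %d", run,
                                          tr$trial_index))
        next
      }
      segs[[tr$combo_id]] <- c(segs[[tr$combo_id]],
                               list(t(dmat[i0:i1, , drop = FALSE])))
    }
  }
  if (length(badTrials))
    stop("segmentation error: trial windows exceed trace bounds for: ",
         paste(badTrials, collapse = "; "))
  nRep <- unique(lengths(segs))
  if (length(nRep) != 1L)
    stop("segmentation error: unequal repeat counts across combos")
  tens <- array(0, c(nCell, nrow(cb), nRep, nSamp))
  for (j in seq_len(nrow(cb)))
    for (r in seq_len(nRep))
      tens[, j, r, ] <- segs[[j]][[r]]
  new("TrialTensor", data = tens, comboTable = cb, frameRateHz = fr,
      windowS = winS, preS = preS, stimDurS = durS, cellIds = ids)
}

#' Mean inter-trial Pearson correlation per cell and combo
#'
#' For every cell x combo, the Pearson correlation of the within-window
#' dF/F time series is computed for each unordered pair of repeats and
#' averaged. Pairs involving a zero-variance (constant) trial contribute
#' r = 0 (the correlation is undefined there); such pairs are counted and
#' reported via a message.
#'
#' @param tensor a [TrialTensor] with >= 2 repeats
#' @return cells x combos matrix of mean pairwise r
#' @export
trialCorrelation <- function(tensor) {
  d <- dim(tensor@data)
  if (d[3] < 2L)
    stop("insufficient repeats: need >= 2 presentations per combo")
  out <- matrix(0, d[1], d[2], dimnames = list(tensor@cellIds, NULL))
  nDegenerate <- 0L
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      m <- tensor@data[i, j, , ]            # repeats x time
      cm <- suppressWarnings(stats::cor(t(m)))
      up <- cm[upper.tri(cm)]
      if (anyNA(up)) {
        nDegenerate <- nDegenerate + sum(is.na(up))
        up[is.na(up)] <- 0
      }
      out[i, j] <- mean(up)
    }
  }
  if (nDegenerate > 0L)
    message(nDegenerate, " zero-variance trial pair(s) contributed r = 0")
  out
}

#' Flag responsive cell x combo pairs and quantify response magnitude
#'
#' A pair is flagged responsive when its mean inter-trial correlation is
#' strictly above the threshold (0.6 for the tone/AM grids; 0.4 for
#' somatosensory/bimodal comparisons). Response magnitude is the
#' trapezoidal AUC of the trial-averaged dF/F over the response window
#' (stimulus onset to window end), restricted to excitatory (positive)
#' deflections by default; set \code{positiveOnly = FALSE} for the signed
#' integral.
#'
#' @param tensor a [TrialTensor]
#' @param threshold correlation cutoff in (0, 1); strict inequality
#' @param rMatrix optional precomputed matrix from [trialCorrelation()]
#' @param positiveOnly integrate only dF/F > 0 (default TRUE)
#' @return a ResponseTable: data.frame with one row per cell x combo
#'   (cell_id, combo_id, stimulus_type, level_db, freq_hz, mod_hz, mean_r,
#'   responsive, auc, any_responsive)
#' @export
flagResponsive <- function(tensor, threshold = 0.6, rMatrix = NULL,
                           positiveOnly = TRUE) {
  if (threshold <= 0 || threshold >= 1)
    stop("invalid argument: threshold must be in (0, 1)")
  if (is.null(rMatrix)) rMatrix <- trialCorrelation(tensor)
  d <- dim(tensor@data)
  cb <- tensor@comboTable
  fr <- tensor@frameRateHz
  respStart <- round(tensor@preS * fr) + 1L   # stimulus onset sample
  nSamp <- d[4]
  auc <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) {
    for (j in seq_len(d[2])) {
      avg <- colMeans(matrix(tensor@data[i, j, , ], nrow = d[3]))
      y <- avg[respStart:nSamp]
      if (positiveOnly) y <- pmax(y, 0)
      auc[i, j] <- trapz(y, 1 / fr)
    }
  }
  flagged <- rMatrix > threshold
  out <- data.frame(
    cell_id = rep(tensor@cellIds, times = d[2]),
    combo_id = rep(cb$combo_id, each = d[1]),
    stimulus_type = rep(cb$stimulus_type, each = d[1]),
    level_db = rep(cb$level_db, each = d[1]),
    freq_hz = rep(cb$freq_hz, each = d[1]),
    mod_hz = rep(cb$mod_hz, each = d[1]),
    mean_r = as.vector(rMatrix),
    responsive = as.vector(flagged),
    auc = as.vector(auc),
    stringsAsFactors = FALSE
  )
  anyResp <- tapply(out$responsive, out$cell_id, any)
  out$any_responsive <- unname(anyResp[out$cell_id])
  attr(out, "threshold") <- threshold
  attr(out, "window_s") <- tensor@windowS
  out
}

#' Best tone or modulation frequency per cell
#'
#' The frequency of the flagged combo with the largest response AUC, taken
#' across all sound levels; exact ties resolve toward the lower frequency
#' (reported via a message). Cells without any flagged combo in the domain
#' are excluded.
#'
#' @param table a ResponseTable from [flagResponsive()]
#' @param domain "tone" (carrier frequencies) or "am" (modulation rates >
#'   0; the 0 Hz unmodulated condition is the reference, not a candidate)
#' @return data.frame (cell_id, best_hz, best_auc, level_db)
#' @export
bestFrequency <- function(table, domain = c("tone", "am")) {
  domain <- match.arg(domain)
  sel <- if (domain == "tone") {
    table$responsive & !is.na(table$freq_hz)
  } else {
    table$responsive & !is.na(table$mod_hz) & table$mod_hz > 0
  }
  sub <- table[sel, , drop = FALSE]
  if (!nrow(sub))
    return(data.frame(cell_id = character(0), best_hz = numeric(0),
                      best_auc = numeric(0), level_db = numeric(0)))
  sub$freq <- if (domain == "tone") sub$freq_hz else sub$mod_hz
  ties <- FALSE
  res <- do.call(rbind, lapply(split(sub, sub$cell_id), function(s) {
    best <- s[s$auc == max(s$auc), , drop = FALSE]
    if (nrow(best) > 1L) {
      ties <<- TRUE
      best <- best[order(best$freq), , drop = FALSE]
    }
    data.frame(cell_id = best$cell_id[1], best_hz = best$freq[1],
               best_auc = best$auc[1], level_db = best$level_db[1])
  }))
  if (ties) message("AUC ties broken toward the lower frequency")
  rownames(res) <- NULL
  res
}

#' Binarized receptive-field sum per cell
#'
#' RFS at a level is the count of flagged frequency combos at that level; a
#' cell responding to a single frequency/level combination scores 1, and
#' each additional responsive combination adds 1. Larger totals mean
#' broader receptive fields.
#'
#' @param table a ResponseTable from [flagResponsive()]
#' @return list(perLevel = data.frame(cell_id, level_db, rfs),
#'   total = data.frame(cell_id, rfs_total))
#' @export
receptiveFieldSum <- function(table) {
  agg <- stats::aggregate(responsive ~ cell_id + level_db, data = table,
                          FUN = sum)
  names(agg)[3] <- "rfs"
  agg <- agg[order(agg$cell_id, agg$level_db), ]
  rownames(agg) <- NULL
  tot <- stats::aggregate(rfs ~ cell_id, data = agg, FUN = sum)
  names(tot)[2] <- "rfs_total"
  list(perLevel = agg, total = tot)
}
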