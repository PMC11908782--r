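#' Polynomial detrending for photobleaching
#'
#' Fits a least-squares polynomial of the given order (default 2) to the
#' trace and subtracts it, adding back the fitted constant term so that the
#' corrected trace keeps the original baseline level.
#'
#' @param trace numeric vector
#' @param order polynomial order (>= 0 and < length(trace) - 1)
#' @return corrected trace
#' @export
detrendPolynomial <- function(trace, order = 2L) {
  n <- length(trace)
  if (order < 0L || order >= n - 1L)
    stop("invalid argument: order must be in [0, length(trace) - 2]")
  t0 <- seq_len(n) / n
  X <- stats::poly(t0, degree = max(order, 1L), raw = TRUE)
  if (order == 0L) X <- X[, 0, drop = FALSE]
  fit <- stats::lm.fit(cbind(1, X), trace)
  trace - fit$fitted.values + fit$coefficients[1]
}

#' Detect spontaneous calcium events by sliding-baseline z-score
#'
#' Each frame after the initial window is scored against the mean and SD of
#' the trailing (causal) 1 s baseline window — 29 frames at 29.9 Hz. The
#' window holds the most recent \emph{baseline} frames only: frames already
#' scoring above threshold are activity, not baseline, and do not enter it,
#' so the z-score stays referenced to quiescence throughout a transient. A
#' frame is supra-threshold when z exceeds the threshold strictly (z = 3.0
#' exactly is not an event). Consecutive supra-threshold frames merge into
#' one event, as do crossings separated by no more than
#' \code{mergeGapFrames} sub-threshold frames (shot noise briefly dipping a
#' single transient under threshold); events shorter than
#' \code{minDurationFrames} are then discarded as isolated noise crossings
#' (a ~100 ms floor, well below any credible calcium transient — without
#' it, per-frame 3-sigma crossings alone produce several false events per
#' minute on pure noise). Frames whose window SD is zero are skipped with a
#' message. With \code{sdMode = "global"} the SD of the whole trace
#' replaces the window SD.
#'
#' @param trace numeric vector (typically detrended with
#'   [detrendPolynomial()] first)
#' @param frameRateHz frame rate
#' @param windowS trailing baseline window length in seconds (default 1.0)
#' @param zThreshold detection threshold (default 3.0, strict)
#' @param minDurationFrames minimum event span in frames (default 3)
#' @param mergeGapFrames crossings separated by at most this many
#'   sub-threshold frames merge into one event (default 6, ~0.2 s)
#' @param sdMode "window" (default) or "global"
#' @return data.frame (onset_frame, z_at_detection, duration_frames) with
#'   parameter attributes
#' @export
detectEvents <- function(trace, frameRateHz = 29.9, windowS = 1.0,
                         zThreshold = 3.0, minDurationFrames = 3L,
                         mergeGapFrames = 6L,
                         sdMode = c("window", "global")) {
  sdMode <- match.arg(sdMode)
  n <- length(trace)
  w <- floor(windowS * frameRateHz)
  if (n <= w) stop("invalid argument: trace shorter than the window")
  # center the trace so detection is exactly invariant to additive offsets
  # (and the running second moment stays well conditioned)
  trace <- trace - mean(trace)
  globalSd <- stats::sd(trace)
  base <- trace[seq_len(w)]          # ring buffer of baseline frames
  bpos <- 1L
  bsum <- sum(base)
  bsum2 <- sum(base^2)
  z <- rep(-Inf, n)
  supra <- logical(n)
  nZero <- 0L
  for (t in (w + 1L):n) {
    m <- bsum / w
    v <- max((bsum2 - bsum^2 / w) / (w - 1), 0)
    s <- if (sdMode == "global") globalSd else sqrt(v)
    if (s == 0) {
      nZero <- nZero + 1L
      isBase <- TRUE
    } else {
      z[t] <- (trace[t] - m) / s
      supra[t] <- z[t] > zThreshold
      isBase <- !supra[t]
    }
    if (isBase) {
      old <- base[bpos]
      base[bpos] <- trace[t]
      bsum <- bsum + trace[t] - old
      bsum2 <- bsum2 + trace[t]^2 - old^2
      bpos <- if (bpos == w) 1L else bpos + 1L
    }
  }
  if (nZero > 0L)
    message(nZero, " frame(s) with zero sliding SD skipped")
  ev <- which(supra)
  out <- data.frame(onset_frame = integer(0), z_at_detection = numeric(0),
                    duration_frames = integer(0))
  if (length(ev)) {
    grp <- cumsum(c(1L, diff(ev) > mergeGapFrames + 1L))
    for (gi in unique(grp)) {
      fr <- ev[grp == gi]
      # the duration floor counts supra-threshold frames: a real transient
      # holds above threshold for many frames, noise crossings for 1-2
      if (length(fr) >= minDurationFrames)
        out[nrow(out) + 1L, ] <- list(min(fr), z[min(fr)],
                                      max(fr) - min(fr) + 1L)
    }
  }
  attr(out, "params") <- list(window_s = windowS, z_threshold = zThreshold,
                              min_duration_frames = minDurationFrames,
                              merge_gap_frames = mergeGapFrames,
                              sd_mode = sdMode, window_frames = w)
  out
}

#' Event tables and rates for a matrix of traces
#'
#' Runs [detrendPolynomial()] then [detectEvents()] per cell and summarizes
#' event rates in events/min.
#'
#' @param traceMat frames x cells matrix
#' @param frameRateHz frame rate
#' @param detrendOrder polynomial order for bleaching correction
#' @param ... passed to [detectEvents()]
#' @return list(events = tidy data.frame(cell_id, onset_frame,
#'   z_at_detection, duration_frames), rates = data.frame(cell_id,
#'   n_events, events_per_min))
#' @export
eventTables <- function(traceMat, frameRateHz = 29.9, detrendOrder = 2L,
                        ...) {
  traceMat <- as.matrix(traceMat)
  ids <- colnames(traceMat) %||% sprintf("cell_%03d", seq_len(ncol(traceMat)))
  minutes <- nrow(traceMat) / frameRateHz / 60
  evs <- vector("list", ncol(traceMat))
  for (i in seq_len(ncol(traceMat))) {
    tr <- detrendPolynomial(traceMat[, i], detrendOrder)
    ev <- detectEvents(tr, frameRateHz, ...)
    if (nrow(ev)) ev <- cbind(cell_id = ids[i], ev)
    evs[[i]] <- ev
  }
  evAll <- do.call(rbind, evs[vapply(evs, nrow, 1L) > 0])
  if (is.null(evAll))
    evAll <- data.frame(cell_id = character(0), onset_frame = integer(0),
                        z_at_detection = numeric(0),
                        duration_frames = integer(0))
  counts <- vapply(evs, nrow, 1L)
  list(events = evAll,
       rates = data.frame(cell_id = ids, n_events = counts,
                          events_per_min = counts / minutes))
}
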