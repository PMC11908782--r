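#' Build a pure-tone stimulus grid
#'
#' Carrier frequencies run from \code{fMinHz} upward in steps of
#' \code{stepOctaves} octaves while they remain at or below \code{fMaxHz}.
#' The top of the range is included when the computed frequency lands within
#' 0.1\% of \code{fMaxHz}, so a 5-40 kHz range with half-octave steps ends
#' exactly at 40 kHz and yields 7 carriers. Crossed with 5 sound levels that
#' is the standard 35-combination tone grid.
#'
#' @param fMinHz lowest carrier frequency (Hz)
#' @param fMaxHz highest carrier frequency (Hz)
#' @param stepOctaves spacing between carriers in octaves (default 0.5)
#' @param levelsDb sound levels in dB SPL (default 40-80 by 10)
#' @param durationMs stimulus duration (default 500 ms)
#' @param isiMs inter-stimulus interval (default 600 ms)
#' @return a [StimulusGrid]
#' @examples
#' g <- buildToneGrid(5000, 40000)
#' nCombos(g)  # 35
#' @export
buildToneGrid <- function(fMinHz, fMaxHz, stepOctaves = 0.5,
                          levelsDb = seq(40, 80, by = 10),
                          durationMs = 500, isiMs = 600) {
  if (fMinHz <= 0 || fMaxHz <= 0)
    stop("invalid grid: frequencies must be positive")
  if (fMinHz > fMaxHz)
    stop("invalid grid: fMinHz must not exceed fMaxHz")
  if (stepOctaves <= 0)
    stop("invalid grid: stepOctaves must be positive")
  if (length(levelsDb) == 0L)
    stop("invalid grid: empty level list")
  kMax <- floor(log2(fMaxHz / fMinHz) / stepOctaves + 1e-12)
  freqs <- fMinHz * 2^(seq(0, kMax) * stepOctaves)
  # floating-point guard at the top of the range
  nxt <- fMinHz * 2^((kMax + 1) * stepOctaves)
  if (abs(nxt - fMaxHz) / fMaxHz < 0.001) freqs <- c(freqs, fMaxHz)
  new("StimulusGrid", stimulusType = "pure_tone",
      levelsDb = as.numeric(sort(levelsDb)),
      carrierFreqsHz = as.numeric(freqs), modFreqsHz = numeric(0),
      durationMs = durationMs, isiMs = isiMs)
}

#' Build an amplitude-modulated noise grid
#'
#' Modulation rate 0 Hz denotes unmodulated broadband noise and is allowed
#' alongside positive AM rates; the default set (0, 2, 4, ..., 256 Hz)
#' crossed with 5 levels is the 45-combination AM grid.
#'
#' @param modFreqsHz modulation rates in Hz (0 allowed)
#' @param levelsDb sound levels in dB SPL
#' @inheritParams buildToneGrid
#' @return a [StimulusGrid]
#' @export
buildAmGrid <- function(modFreqsHz = c(0, 2, 4, 8, 16, 32, 64, 128, 256),
                        levelsDb = seq(40, 80, by = 10),
                        durationMs = 500, isiMs = 600) {
  if (length(modFreqsHz) == 0L)
    stop("invalid grid: empty modulation frequency list")
  if (anyDuplicated(modFreqsHz))
    stop("invalid grid: duplicate modulation frequencies")
  if (length(levelsDb) == 0L)
    stop("invalid grid: empty level list")
  new("StimulusGrid", stimulusType = "am_noise",
      levelsDb = as.numeric(sort(levelsDb)), carrierFreqsHz = numeric(0),
      modFreqsHz = as.numeric(sort(modFreqsHz)),
      durationMs = durationMs, isiMs = isiMs)
}

#' Build an unmodulated-noise, somatosensory or bimodal grid
#'
#' Unmodulated noise grids hold one combination per sound level.
#' Somatosensory (whisker deflection) and bimodal (simultaneous acoustic +
#' whisker) grids hold a single combination presented repeatedly; the study
#' design uses 500 ms stimuli at 80 dB SPL with a 600 ms ISI.
#'
#' @param type "unmod_noise", "somatosensory" or "bimodal"
#' @inheritParams buildToneGrid
#' @return a [StimulusGrid]
#' @export
buildSimpleGrid <- function(type = c("unmod_noise", "somatosensory", "bimodal"),
                            levelsDb = 80, durationMs = 500, isiMs = 600) {
  type <- match.arg(type)
  new("StimulusGrid", stimulusType = type,
      levelsDb = as.numeric(sort(levelsDb)),
      carrierFreqsHz = numeric(0), modFreqsHz = numeric(0),
      durationMs = durationMs, isiMs = isiMs)
}

#' Randomized presentation schedule for a stimulus grid
#'
#' All combo x repeat slots are permuted uniformly at random (single global
#' permutation, seeded and reproducible) and presented back to back, onset
#' \code{k} at \code{k * (duration + ISI)}. A 35-combo tone grid at one
#' repeat therefore spans 38.5 s and an AM grid 49.5 s, fitting the 40 s and
#' 52 s movie lengths used per run.
#'
#' @param grid a [StimulusGrid]
#' @param nRepeats presentations per combination (>= 1); repeats of the tone
#'   and AM grids usually come from separate runs, see [segmentTrials()]
#' @param seed integer randomization seed
#' @return a [StimulusSchedule]
#' @export
makeSchedule <- function(grid, nRepeats = 1L, seed = 1L) {
  stopifnot(is(grid, "StimulusGrid"))
  nRepeats <- as.integer(nRepeats)
  if (is.na(nRepeats) || nRepeats < 1L)
    stop("invalid argument: nRepeats must be >= 1")
  cb <- combos(grid)
  slots <- rep(cb$combo_id, times = nRepeats)
  ord <- withSeed(seed, sample.int(length(slots)))
  step <- (grid@durationMs + grid@isiMs) / 1000
  tr <- data.frame(
    trial_index = seq_along(slots),
    combo_id = slots[ord],
    onset_s = (seq_along(slots) - 1) * step
  )
  new("StimulusSchedule", grid = grid, trials = tr, nRepeats = nRepeats,
      totalDurationS = length(slots) * step, seed = as.integer(seed))
}

#' Write a schedule to a delimited file
#'
#' Columns are trial_index, onset_s, stimulus_type, level_db, freq_hz,
#' mod_hz. Grid metadata that the columns cannot carry (duration, ISI,
#' repeats, seed) is preserved in `#`-prefixed header lines so that
#' [readSchedule()] reproduces the object losslessly.
#'
#' @param schedule a [StimulusSchedule]
#' @param path output file
#' @param sep field separator ("," or "\t")
#' @return invisibly, \code{path}
#' @export
writeSchedule <- function(schedule, path, sep = ",") {
  stopifnot(is(schedule, "StimulusSchedule"))
  g <- schedule@grid
  hdr <- c(
    "# colliscope schedule v1",
    sprintf("# stimulus_type=%s", g@stimulusType),
    sprintf("# duration_ms=%s isi_ms=%s", formatNum(g@durationMs),
            formatNum(g@isiMs)),
    sprintf("# n_repeats=%d seed=%d", schedule@nRepeats, schedule@seed),
    sprintf("# levels_db=%s", paste(formatNum(g@levelsDb), collapse = ";")),
    sprintf("# carrier_freqs_hz=%s",
            paste(formatNum(g@carrierFreqsHz), collapse = ";")),
    sprintf("# mod_freqs_hz=%s", paste(formatNum(g@modFreqsHz), collapse = ";"))
  )
  cb <- combos(g)
  tr <- merge(schedule@trials, cb, by = "combo_id", sort = FALSE)
  tr <- tr[order(tr$trial_index), ]
  lines <- c(
    hdr,
    paste(c("trial_index", "onset_s", "stimulus_type", "level_db",
            "freq_hz", "mod_hz"), collapse = sep),
    paste(tr$trial_index, formatNum(tr$onset_s), tr$stimulus_type,
          formatNum(tr$level_db), formatNum(tr$freq_hz), formatNum(tr$mod_hz),
          sep = sep)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a schedule written by [writeSchedule()]
#'
#' @param path schedule file
#' @return a [StimulusSchedule]
#' @export
readSchedule <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  body <- lines[!grepl("^#", lines)]
  getField <- function(key, line = NULL) {
    src <- if (is.null(line)) paste(hdr, collapse = " ") else line
    m <- regmatches(src, regexpr(sprintf("%s=[^ ]*", key), src))
    if (!length(m)) stop(sprintf("schedule header missing '%s'", key))
    sub(sprintf("%s=", key), "", m)
  }
  parseVec <- function(s) if (nzchar(s)) as.numeric(strsplit(s, ";")[[1]]) else numeric(0)
  type <- getField("stimulus_type")
  grid <- new("StimulusGrid", stimulusType = type,
              levelsDb = parseVec(getField("levels_db")),
              carrierFreqsHz = parseVec(getField("carrier_freqs_hz")),
              modFreqsHz = parseVec(getField("mod_freqs_hz")),
              durationMs = as.numeric(getField("duration_ms")),
              isiMs = as.numeric(getField("isi_ms")))
  sep <- if (grepl("\t", body[1])) "\t" else ","
  df <- utils::read.table(text = paste(body, collapse = "\n"), sep = sep,
                          header = TRUE, stringsAsFactors = FALSE)
  cb <- combos(grid)
  key <- function(l, f, m) paste(formatNum(l), formatNum(f), formatNum(m))
  lut <- stats::setNames(cb$combo_id, key(cb$level_db, cb$freq_hz, cb$mod_hz))
  ids <- unname(lut[key(df$level_db, df$freq_hz, df$mod_hz)])
  if (anyNA(ids)) stop("schedule rows do not match the grid combos")
  tr <- data.frame(trial_index = df$trial_index, combo_id = ids,
                   onset_s = df$onset_s)
  nRep <- as.integer(getField("n_repeats"))
  step <- (grid@durationMs + grid@isiMs) / 1000
  new("StimulusSchedule", grid = grid, trials = tr, nRepeats = nRep,
      totalDurationS = nrow(tr) * step,
      seed = as.integer(getField("seed")))
}
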