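test_that("trial segmentation yields the expected tensor geometry", {
  ex <- makeToneExperiment(nCells = 4, nRepeats = 5, seed = 1, noiseSd = 0)
  d <- computeDff(traces(ex$expt), 29.9)
  tens <- segmentTrials(d, ex$schedule, preS = 0, postS = 0.6)
  expect_equal(dim(tens@data), c(4L, 35L, 5L, 33L))  # round(1.1 x 29.9)
  expect_equal(tens@windowS, 1.1)
  # pre = post = 0: window is exactly the stimulus duration
  t0 <- segmentTrials(d, ex$schedule, preS = 0, postS = 0)
  expect_equal(dim(t0@data)[4], round(0.5 * 29.9))
  # single run, single repeat: correlation stage must reject
  ex1 <- makeToneExperiment(nCells = 2, nRepeats = 1, seed = 2, noiseSd = 0)
  d1 <- computeDff(traces(ex1$expt), 29.9)
  tens1 <- segmentTrials(d1, ex1$schedule)
  expect_equal(dim(tens1@data)[3], 1L)
  expect_error(trialCorrelation(tens1), "insufficient repeats")
  # windows beyond the recording are reported
  expect_error(segmentTrials(d, ex$schedule, postS = 10),
               "segmentation error")
})

test_that("repeats concatenate across runs of the same grid", {
  g <- buildToneGrid(5000, 40000, levelsDb = c(70, 80))
  cells <- fixedCells(c(10000, 20000))
  runs <- lapply(1:3, function(s) {
    sch <- makeSchedule(g, 1, seed = s)
    e <- simulateTraces(cells, sch, noiseSd = 0, neuropilMix = 0,
                        bleachTauS = Inf, seed = s)
    list(d = computeDff(traces(e), 29.9), sch = sch)
  })
  tens <- segmentTrials(lapply(runs, `[[`, "d"), lapply(runs, `[[`, "sch"))
  expect_equal(dim(tens@data)[3], 3L)
})

test_that("trial correlation matches a brute-force pairwise Pearson oracle", {
  set.seed(11)
  data <- array(rnorm(6 * 4 * 5 * 20), c(6, 4, 5, 20))
  tens <- new("TrialTensor", data = data,
              comboTable = data.frame(combo_id = 1:4,
                                      stimulus_type = "pure_tone",
                                      level_db = 80,
                                      freq_hz = c(5, 10, 20, 40) * 1e3,
                                      mod_hz = NA_real_),
              frameRateHz = 29.9, windowS = 20 / 29.9, preS = 0,
              stimDurS = 0.5, cellIds = sprintf("c%d", 1:6))
  got <- trialCorrelation(tens)
  for (i in 1:6) for (j in 1:4) {
    rs <- c()
    for (a in 1:4) for (b in (a + 1):5)
      rs <- c(rs, cor(data[i, j, a, ], data[i, j, b, ]))
    expect_equal(unname(got[i, j]), mean(rs), tolerance = 1e-10)
  }
})

test_that("degenerate and extreme repeat patterns give r = 1, -1, 0", {
  base <- sin(seq(0, 3, length.out = 15))
  mk <- function(repList) {
    data <- array(0, c(1, 1, length(repList), 15))
    for (r in seq_along(repList)) data[1, 1, r, ] <- repList[[r]]
    new("TrialTensor", data = data,
        comboTable = data.frame(combo_id = 1L, stimulus_type = "pure_tone",
                                level_db = 80, freq_hz = 1e4,
                                mod_hz = NA_real_),
        frameRateHz = 29.9, windowS = 0.5, preS = 0, stimDurS = 0.5,
        cellIds = "c1")
  }
  expect_equal(unname(trialCorrelation(mk(list(base, base, base)))[1, 1]), 1)
  expect_equal(unname(trialCorrelation(mk(list(base, -base)))[1, 1]), -1)
  expect_message(
    r0 <- trialCorrelation(mk(list(base, rep(2, 15))))[1, 1],
    "zero-variance")
  expect_equal(unname(r0), 0)
  # seeded white noise: small mean correlation across many cells
  set.seed(5)
  data <- array(rnorm(100 * 1 * 5 * 33), c(100, 1, 5, 33))
  tensN <- new("TrialTensor", data = data,
               comboTable = data.frame(combo_id = 1L,
                                       stimulus_type = "pure_tone",
                                       level_db = 80, freq_hz = 1e4,
                                       mod_hz = NA_real_),
               frameRateHz = 29.9, windowS = 1.1, preS = 0, stimDurS = 0.5,
               cellIds = sprintf("c%03d", 1:100))
  rN <- trialCorrelation(tensN)
  expect_lt(max(abs(rN)), 0.5)
  expect_lt(abs(mean(rN)), 0.05)
})

test_that("flagging is strictly above threshold and monotone in it", {
  ex <- makeToneExperiment(nCells = 10, nRepeats = 5, seed = 3)
  tab6 <- processExperiment(ex$expt, ex$schedule, threshold = 0.6)
  # strictness at the boundary on the r values actually computed
  rr <- tab6$mean_r
  thrAt <- rr[which.max(rr)]  # flagging at a realized r leaves it unflagged
  tens <- segmentTrials(computeDff(neuropilCorrect(
    gaussianFilterTraces(traces(ex$expt), 2), 0.4,
    gaussianFilterTraces(neuropil(ex$expt), 2)), 29.9), ex$schedule)
  rmat <- trialCorrelation(tens)
  tabAt <- flagResponsive(tens, threshold = max(rmat) - 1e-12,
                          rMatrix = rmat)
  expect_equal(sum(tabAt$responsive), 1L)
  expect_error(flagResponsive(tens, threshold = 0), "invalid argument")
  # monotonicity: raising the threshold never adds flags
  for (pair in list(c(0.3, 0.5), c(0.5, 0.7), c(0.6, 0.9))) {
    lo <- flagResponsive(tens, pair[1], rMatrix = rmat)$responsive
    hi <- flagResponsive(tens, pair[2], rMatrix = rmat)$responsive
    expect_true(all(hi <= lo))
  }
})

test_that("synthetic boundary r values flag per the strict rule", {
  mkTab <- function(r) {
    data.frame(cell_id = "c1", combo_id = 1L, stimulus_type = "pure_tone",
               level_db = 80, freq_hz = 1e4, mod_hz = NA_real_, mean_r = r,
               responsive = r > 0.6, auc = 1, any_responsive = r > 0.6)
  }
  expect_true(mkTab(0.61)$responsive)
  expect_false(mkTab(0.60)$responsive)
})

test_that("best frequency is the argmax of AUC with low-frequency ties", {
  tab <- data.frame(
    cell_id = "c1", combo_id = 1:3, stimulus_type = "pure_tone",
    level_db = 80, freq_hz = c(5000, 10000, 20000), mod_hz = NA_real_,
    mean_r = 0.9, responsive = TRUE, auc = c(1, 3, 2),
    any_responsive = TRUE)
  expect_equal(bestFrequency(tab, "tone")$best_hz, 10000)
  tab$auc <- c(1, 3, 3)
  expect_message(bf <- bestFrequency(tab, "tone"), "ties")
  expect_equal(bf$best_hz, 10000)
  single <- tab[1, ]; single$freq_hz <- 7071
  expect_equal(bestFrequency(single, "tone")$best_hz, 7071)
  # no flagged combos: excluded, empty result
  none <- tab; none$responsive <- FALSE
  expect_equal(nrow(bestFrequency(none, "tone")), 0L)
  # AM domain ignores the 0 Hz reference
  am <- data.frame(cell_id = "c1", combo_id = 1:3,
                   stimulus_type = "am_noise", level_db = 80,
                   freq_hz = NA_real_, mod_hz = c(0, 8, 16), mean_r = 0.9,
                   responsive = TRUE, auc = c(9, 2, 1),
                   any_responsive = TRUE)
  expect_equal(bestFrequency(am, "am")$best_hz, 8)
})

test_that("receptive-field sums count flagged combos per level", {
  cb <- expand.grid(freq_hz = c(5, 10, 20) * 1e3, level_db = c(60, 80))
  tab <- data.frame(cell_id = "c1", combo_id = 1:6,
                    stimulus_type = "pure_tone", level_db = cb$level_db,
                    freq_hz = cb$freq_hz, mod_hz = NA_real_, mean_r = 0.1,
                    responsive = FALSE, auc = 0, any_responsive = FALSE)
  r0 <- receptiveFieldSum(tab)
  expect_true(all(r0$perLevel$rfs == 0))
  expect_equal(r0$total$rfs_total, 0)
  tab$responsive[c(1, 4, 5)] <- TRUE
  r1 <- receptiveFieldSum(tab)
  expect_equal(r1$total$rfs_total, 3)
  expect_equal(r1$perLevel$rfs[r1$perLevel$level_db == 60], 1)
  expect_equal(r1$perLevel$rfs[r1$perLevel$level_db == 80], 2)
  tab$responsive <- c(TRUE, rep(FALSE, 5))
  expect_equal(receptiveFieldSum(tab)$total$rfs_total, 1)
})
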