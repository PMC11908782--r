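test_that("SMI/TMI implement the normalized contrast with its boundaries", {
  expect_equal(spectralModulationIndex(3, 1), 0.5)
  expect_equal(spectralModulationIndex(2, 2), 0)
  expect_equal(spectralModulationIndex(0, 2), -1)
  expect_equal(temporalModulationIndex(1, 3), -0.5)
  expect_equal(temporalModulationIndex(2, 0), 1)
  expect_message(out <- spectralModulationIndex(0, 0), "excluded")
  expect_true(is.na(out))
  expect_error(spectralModulationIndex(-1, 2), "invalid argument")
})

test_that("SMI/TMI obey range, antisymmetry and scale invariance", {
  set.seed(21)
  a <- rexp(1e4); b <- rexp(1e4)
  smi <- spectralModulationIndex(a, b)
  expect_true(all(smi >= -1 & smi <= 1))
  expect_equal(smi, (a - b) / (a + b), tolerance = 1e-12)  # formula oracle
  expect_equal(smi, -spectralModulationIndex(b, a), tolerance = 1e-12)
  alpha <- rexp(1e4) + 0.1
  expect_equal(spectralModulationIndex(alpha * a, alpha * b), smi,
               tolerance = 1e-12)
})

test_that("RI classifies suppression and enhancement and is scale-invariant", {
  expect_equal(responseIndex(2, 4)$ri, 0.5)
  expect_equal(responseIndex(2, 4)$bimodal_class, "suppressed")
  expect_equal(responseIndex(3, 3)$bimodal_class, "unchanged")
  r <- responseIndex(6, 4)
  expect_equal(r$ri, 1.5)
  expect_equal(r$bimodal_class, "enhanced")
  expect_message(bad <- responseIndex(2, 0), "excluded")
  expect_true(is.na(bad$ri))
  set.seed(4)
  x <- rexp(500); y <- rexp(500) + 0.01; al <- rexp(500) + 0.01
  expect_equal(responseIndex(al * x, al * y)$ri, responseIndex(x, y)$ri,
               tolerance = 1e-12)
})

test_that("selectivity and modality classes map the four flag combinations", {
  expect_equal(classifySelectivity(TRUE, FALSE), "tone_sel")
  expect_equal(classifySelectivity(FALSE, TRUE), "noise_sel")
  expect_equal(classifySelectivity(TRUE, TRUE), "non_sel")
  expect_equal(classifySelectivity(FALSE, FALSE), "unresponsive")
  expect_equal(classifyModality(TRUE, FALSE), "aud_sel")
  expect_equal(classifyModality(FALSE, TRUE), "som_sel")
  expect_equal(classifyModality(TRUE, TRUE), "aud_som_nonsel")
  expect_equal(classifyModality(FALSE, FALSE), "unresponsive")
})

test_that("timing classes follow the window containing the transient", {
  fr <- 29.9; preS <- 0.4; durS <- 0.5; postS <- 0.7
  n <- round((preS + durS + postS) * fr)
  nPre <- round(preS * fr)
  nStim <- round(durS * fr)
  mk <- function(onPeak, offPeak) {
    x <- sin(seq_len(n)) * 0.01          # small baseline wiggle
    if (onPeak) x[nPre + 5] <- 1
    if (offPeak) x[nPre + nStim + 5] <- 1
    x
  }
  expect_equal(classifyTiming(mk(TRUE, FALSE), fr, preS, durS), "onset")
  expect_equal(classifyTiming(mk(FALSE, TRUE), fr, preS, durS), "offset")
  expect_equal(classifyTiming(mk(TRUE, TRUE), fr, preS, durS),
               "onset_offset")
  expect_equal(classifyTiming(mk(FALSE, FALSE), fr, preS, durS), "none")
  expect_error(classifyTiming(rep(1, n), fr, preS, durS),
               "degenerate baseline")
  expect_error(classifyTiming(mk(TRUE, FALSE), fr, 0, durS),
               "invalid argument")
})

test_that("per-level modulation flags split spectral from temporal cells", {
  mkRow <- function(level, freq, mod, resp)
    data.frame(cell_id = "c1", combo_id = 1L, stimulus_type = "x",
               level_db = level, freq_hz = freq, mod_hz = mod, mean_r = 0.9,
               responsive = resp, auc = 1, any_responsive = TRUE)
  # tone at 60 dB only: spectrally modulated there
  tab <- rbind(mkRow(60, 1e4, NA, TRUE), mkRow(60, NA, 8, FALSE),
               mkRow(80, 1e4, NA, FALSE), mkRow(80, NA, 8, FALSE))
  cm <- classifyModulated(tab)
  expect_true(cm$spectrally_modulated[cm$level_db == 60])
  expect_false(cm$temporally_modulated[cm$level_db == 60])
  expect_false(cm$spectrally_modulated[cm$level_db == 80])
  # AM at 60 dB: temporally modulated, not spectrally
  tab2 <- rbind(mkRow(60, NA, 8, TRUE), mkRow(60, 1e4, NA, FALSE))
  cm2 <- classifyModulated(tab2)
  expect_true(cm2$temporally_modulated)
  expect_false(cm2$spectrally_modulated)
  # unmodulated (0 Hz) counts as spectral when no AM flag at the level
  tab3 <- rbind(mkRow(60, NA, 0, TRUE), mkRow(60, NA, 8, FALSE))
  expect_true(classifyModulated(tab3)$spectrally_modulated)
})

test_that("bimodal gain sign is recovered for noise-free synthetic cells", {
  schB <- makeSchedule(buildSimpleGrid("bimodal"), 5, seed = 1)
  schA <- makeSchedule(buildSimpleGrid("unmod_noise"), 5, seed = 2)
  cells <- generateCells(40, layout = "random", seed = 5)
  cells$responsive <- TRUE
  cells$modality <- "aud_som"
  eB <- simulateTraces(cells, schB, noiseSd = 0, seed = 1)
  eA <- simulateTraces(cells, schA, noiseSd = 0, seed = 2)
  tB <- processExperiment(eB, schB, threshold = 0.4, sigmaT = 0)
  tA <- processExperiment(eA, schA, threshold = 0.4, sigmaT = 0)
  ri <- suppressMessages(responseIndex(tB$auc, tA$auc))
  truth <- ifelse(cells$bimodal_gain > 1, "enhanced",
                  ifelse(cells$bimodal_gain < 1, "suppressed", "unchanged"))
  expect_gte(mean(ri$bimodal_class == truth, na.rm = TRUE), 0.95)
})

test_that("indexTable pairs per-level best responses with the 0 Hz reference", {
  mk <- function(cell, type, level, freq, mod, auc, resp = TRUE)
    data.frame(cell_id = cell, combo_id = 1L, stimulus_type = type,
               level_db = level, freq_hz = freq, mod_hz = mod, mean_r = 0.9,
               responsive = resp, auc = auc, any_responsive = TRUE)
  tone <- rbind(mk("c1", "pure_tone", 80, 1e4, NA, 3),
                mk("c1", "pure_tone", 80, 2e4, NA, 2))
  am <- rbind(mk("c1", "am_noise", 80, NA, 8, 2),
              mk("c1", "am_noise", 80, NA, 0, 1))
  it <- indexTable(tone, am)
  expect_equal(it$response_btf, 3)
  expect_equal(it$response_bmf, 2)
  expect_equal(it$response_unmod, 1)
  expect_equal(it$smi, 0.5)
  expect_equal(it$tmi, 1 / 3)
})
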