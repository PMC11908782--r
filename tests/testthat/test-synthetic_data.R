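test_that("generation is bitwise deterministic under a fixed seed", {
  c1 <- generateCells(40, seed = 7)
  c2 <- generateCells(40, seed = 7)
  expect_identical(c1, c2)
  sch <- makeSchedule(buildToneGrid(5000, 40000), 2, seed = 1)
  e1 <- simulateTraces(c1, sch, seed = 9)
  e2 <- simulateTraces(c1, sch, seed = 9)
  expect_identical(traces(e1), traces(e2))
  expect_identical(neuropil(e1), neuropil(e2))
  expect_false(identical(traces(e1), traces(simulateTraces(c1, sch,
                                                           seed = 10))))
})

test_that("gradient layouts order preference along the axis; random layouts draw from the grid", {
  cells <- generateCells(100, layout = "gradient", axisAngleDeg = 0,
                         gradientSpanOct = 3, seed = 2)
  r <- cor(cells$x_um, cells$latent_btf_oct - 0)  # jittered latent
  expect_gt(cor(cells$x_um,
                cells$latent_btf_oct), 0.9)
  grid <- buildToneGrid(5000, 40000)@carrierFreqsHz
  rnd <- generateCells(10, layout = "random", seed = 3)
  expect_true(all(rnd$true_btf_hz %in% grid))
  expect_identical(rnd, generateCells(10, layout = "random", seed = 3))
})

test_that("realized module fraction tracks the requested fraction", {
  fr <- vapply(1:20, function(s)
    mean(generateCells(200, moduleFraction = 0.3,
                       seed = s)$compartment == "module"), numeric(1))
  expect_lt(abs(mean(fr) - 0.3), 0.1)
  expect_true(all(generateCells(20, moduleFraction = 0,
                                seed = 1)$compartment == "matrix"))
  expect_true(all(generateCells(20, moduleFraction = 1,
                                seed = 1)$compartment == "module"))
})

test_that("noise-free traces are baseline plus transients with exact peaks", {
  grid <- buildSimpleGrid("unmod_noise", levelsDb = 80, isiMs = 5000)
  sch <- makeSchedule(grid, 1, seed = 1)
  cells <- fixedCells(10000, ampDff = 1.2, unmodFactor = 0.5)
  e <- simulateTraces(cells, sch, noiseSd = 0, neuropilMix = 0,
                      bleachTauS = Inf, seed = 1)
  f0 <- e@params$f0
  for (i in seq_len(ncol(traces(e)))) {
    tr <- traces(e)[, i]
    expect_equal(min(tr), f0[i])                    # baseline
    # unmod response = amp x unmod_factor; peak = that fraction of baseline
    expect_equal(max(tr), f0[i] * (1 + 1.2 * 0.5), tolerance = 1e-12)
  }
  # unresponsive cells are flat
  cells$responsive <- FALSE
  e0 <- simulateTraces(cells, sch, noiseSd = 0, neuropilMix = 0,
                       bleachTauS = Inf, seed = 1)
  expect_equal(apply(traces(e0), 2, function(x) diff(range(x))),
               rep(0, nrow(cells)), ignore_attr = TRUE)
})

test_that("downstream dF/F recovers the injected transient shape exactly", {
  grid <- buildSimpleGrid("unmod_noise", levelsDb = 80, isiMs = 8000)
  sch <- makeSchedule(grid, 1, seed = 1)
  cells <- fixedCells(c(10000, 20000), ampDff = 0.9)
  e <- simulateTraces(cells, sch, noiseSd = 0, neuropilMix = 0,
                      bleachTauS = Inf, seed = 1)
  d <- computeDff(traces(e), frameRate(e))
  kern <- colliscope:::transientKernel(frameRate(e))
  inj <- matrix(0, nrow(traces(e)), 2)
  inj[seq_along(kern), ] <- 0.9 * 0.5 * kern       # amp x unmod_factor
  expect_equal(dff(d), inj, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("evoked AUC never decreases when response_amp increases", {
  grid <- buildToneGrid(5000, 40000, levelsDb = 80)
  sch <- makeSchedule(grid, 3, seed = 2)
  aucFor <- function(amp) {
    cells <- fixedCells(10000, ampDff = amp)
    e <- simulateTraces(cells, sch, noiseSd = 0, neuropilMix = 0,
                        bleachTauS = Inf, seed = 3)
    tab <- processExperiment(e, sch, sigmaT = 0)
    max(tab$auc)
  }
  aucs <- vapply(c(0.2, 0.5, 1, 1.5, 2.5), aucFor, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("rendered movies round-trip exactly through extraction", {
  # one cell at a constant value over zero background
  grid <- buildSimpleGrid("unmod_noise", levelsDb = 80)
  sch <- makeSchedule(grid, 2, seed = 1)
  cells <- fixedCells(10000)
  cells$responsive <- FALSE
  e <- simulateTraces(cells, sch, noiseSd = 0, neuropilMix = 0,
                      bleachTauS = Inf, seed = 1)
  e@params$neuropilClean <- rep(0, nrow(traces(e)))
  mov <- renderMovie(e, imageSizePx = 64, cellRadiusPx = 4, seed = 1)
  rt <- extractSignals(mov$stack, mov$rois)
  expect_equal(traces(rt), traces(e), ignore_attr = TRUE)
  # two cells with distinct constants stay distinct
  cells2 <- fixedCells(c(10000, 20000))
  cells2$responsive <- FALSE
  e2 <- simulateTraces(cells2, sch, noiseSd = 0, neuropilMix = 0,
                       bleachTauS = Inf, seed = 4)
  mov2 <- renderMovie(e2, imageSizePx = 64, cellRadiusPx = 4, seed = 1)
  rt2 <- extractSignals(mov2$stack, mov2$rois)
  expect_equal(traces(rt2), traces(e2), ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(traces(rt2)[, 1], traces(rt2)[, 2])))
})

test_that("impossible layouts raise a layout error", {
  cells <- generateCells(80, seed = 1)
  sch <- makeSchedule(buildSimpleGrid("unmod_noise"), 1, seed = 1)
  e <- simulateTraces(cells, sch, noiseSd = 0, seed = 1)
  expect_error(renderMovie(e, imageSizePx = 24, cellRadiusPx = 5, seed = 1),
               "layout error")
})
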