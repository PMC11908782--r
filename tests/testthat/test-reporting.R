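test_that("cell maps paint one uniform-radius circle per cell, deterministically", {
  ex <- makeToneExperiment(nCells = 6, nRepeats = 1, seed = 4)
  mov <- renderMovie(ex$expt, imageSizePx = 96, cellRadiusPx = 4, seed = 1)
  vals <- stats::setNames(ex$cells$true_btf_hz, ex$cells$cell_id)
  pal <- defaultPalette(sort(unique(vals)))
  m1 <- renderMap(mov$rois, vals, palette = pal)
  m2 <- renderMap(mov$rois, vals, palette = pal)
  expect_identical(m1$raster, m2$raster)
  # every plotted value appears in the key; same value -> same color
  expect_true(all(as.character(vals) %in% m1$key$value))
  same <- which(vals == vals[1])
  cols <- pal[as.character(vals[same])]
  expect_equal(length(unique(cols)), 1L)
  # number of distinct non-background colors <= palette size
  px <- apply(round(m1$raster * 255), c(1, 2), function(v)
    paste(v, collapse = ","))
  expect_lte(length(setdiff(unique(as.vector(px)), "255,255,255")),
             length(pal) + 1L)
  expect_error(renderMap(mov$rois, vals, palette = pal[-1]),
               "palette error")
  f <- withr::local_tempfile(fileext = ".png")
  writeMapPng(m1, f)
  expect_true(file.exists(f))
  expect_true(file.exists(sub("\\.png$", "_key.json", f)))
  expect_identical(png::readPNG(f), m1$raster)
})

test_that("BTF cumulative distributions match the sort-and-count oracle", {
  one <- cumulativeDistribution(rep(1e4, 8))
  expect_equal(one$cum_fraction, 1)
  grid <- buildToneGrid(5000, 40000)@carrierFreqsHz
  set.seed(13)
  btfs <- sample(grid, 60, replace = TRUE)
  cdf <- cumulativeDistribution(btfs, grid)
  expect_equal(cdf$cum_fraction[length(grid)], 1)
  oracle <- vapply(grid, function(f) sum(sort(btfs) <= f) / 60, numeric(1))
  expect_equal(cdf$cum_fraction, oracle)
  expect_true(all(diff(cdf$cum_fraction) >= 0))
  expect_error(cumulativeDistribution(numeric(0)), "invalid argument")
})

test_that("population summaries give per-compartment fractions summing to 1", {
  cls <- c(rep("tone_sel", 10))
  cmp <- rep("module", 10)
  s <- populationSummary(cls, cmp)
  expect_equal(s$fraction, 1)
  set.seed(8)
  cls2 <- sample(c("tone_sel", "noise_sel", "non_sel"), 300, replace = TRUE,
                 prob = c(0.5, 0.3, 0.2))
  cmp2 <- sample(c("module", "matrix"), 300, replace = TRUE)
  s2 <- populationSummary(cls2, cmp2)
  for (cp in unique(cmp2))
    expect_equal(sum(s2$fraction[s2$compartment == cp]), 1,
                 tolerance = 1e-9)
  # known mix recovered within binomial error (3 sigma)
  f <- s2$fraction[s2$compartment == "module" & s2$class == "tone_sel"]
  n <- sum(cmp2 == "module")
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n))
  # empty compartments are absent, not NaN
  expect_false("void" %in% populationSummary(cls, cmp)$compartment)
})

test_that("ROC validation reproduces exact separation and confusion arithmetic", {
  sep <- rocValidation(c(rep(0.9, 5), rep(0.1, 5)),
                       c(rep(TRUE, 5), rep(FALSE, 5)), threshold = 0.5)
  expect_equal(sep$auc, 1.0)
  expect_equal(unname(sep$counts), c(5L, 0L, 5L, 0L))
  # counts TP=72 FN=28 TN=87 FP=13 -> sensitivity 72%, specificity 87%
  scores <- c(rep(0.5, 72), rep(0.3, 28), rep(0.2, 87), rep(0.45, 13))
  labels <- c(rep(TRUE, 100), rep(FALSE, 100))
  v <- rocValidation(scores, labels, threshold = 0.4)
  expect_equal(v$sensitivity, 0.72)
  expect_equal(v$specificity, 0.87)
  expect_equal(v$ppv, 72 / 85)
  expect_equal(v$npv, 87 / 115)
  expect_error(rocValidation(1:5, rep(TRUE, 5)), "undefined AUC")
})

test_that("ROC AUC equals the Mann-Whitney estimate and pROC cross-check", {
  set.seed(17)
  scores <- runif(400)                      # tie-free
  labels <- runif(400) < plogis(6 * (scores - 0.5))
  if (all(labels) || !any(labels)) labels[1:2] <- c(TRUE, FALSE)
  v <- rocValidation(scores, labels)
  u <- wilcox.test(scores[labels], scores[!labels])$statistic
  expect_equal(v$auc, unname(u) / (sum(labels) * sum(!labels)),
               tolerance = 1e-9)
  skip_if_not_installed("pROC")
  pr <- suppressMessages(pROC::auc(pROC::roc(labels, scores, quiet = TRUE)))
  expect_equal(v$auc, as.numeric(pr), tolerance = 1e-9)
})

test_that("random scores against random labels give chance-level AUC", {
  set.seed(19)
  v <- rocValidation(runif(10000), runif(10000) < 0.5)
  expect_lt(abs(v$auc - 0.5), 0.02)
})
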