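test_that("distances follow the straight-line formula and exclusion rule", {
  ax <- axisFromAngle(53.13, origin = c(0, 0))
  expect_equal(projectDistance(rbind(c(3, 4)), ax, method = "euclidean"), 5)
  expect_equal(projectDistance(rbind(c(0, 0)), ax, method = "euclidean"), 0)
  set.seed(2)
  pts <- matrix(runif(40, 0, 300), 20, 2)
  got <- projectDistance(pts, axisFromAngle(30), method = "euclidean")
  expect_equal(got, sqrt(pts[, 1]^2 + pts[, 2]^2), tolerance = 1e-12,
               ignore_attr = TRUE)
  # projection equals the distance for cells on the axis line
  axX <- axisFromAngle(0)
  onAxis <- cbind(c(10, 50, 120), 0)
  expect_equal(projectDistance(onAxis, axX),
               projectDistance(onAxis, axX, method = "euclidean"))
  # cells behind the origin are excluded with a message
  expect_message(d <- projectDistance(rbind(c(-5, 0), c(5, 0)), axX),
                 "behind the axis origin")
  expect_true(is.na(d[1]) && d[2] == 5)
})

test_that("geometric binning takes exp-mean-log within half-open bins", {
  b <- binGeometric(c(10, 40), c(5000, 20000), 50)
  expect_equal(b$distance_um, 20)    # sqrt(10 * 40)
  expect_equal(b$btf_hz, 10000)      # sqrt(5000 * 20000)
  expect_equal(b$n_cells, 2L)
  # single cell: bin equals the cell
  b1 <- binGeometric(30, 7071, 50)
  expect_equal(b1$distance_um, 30)
  expect_equal(b1$btf_hz, 7071)
  # half-open membership: exactly 50 um falls in the second bin
  b2 <- binGeometric(c(49.999, 50), c(1e4, 1e4), 50)
  expect_equal(b2$bin, c(0, 1))
  # random data against the exp-mean-log oracle
  set.seed(6)
  dst <- runif(200, 0, 400); fq <- 2^runif(200, log2(5e3), log2(4e4))
  bb <- binGeometric(dst, fq, 50)
  for (k in bb$bin) {
    ix <- floor(dst / 50) == k
    expect_equal(bb$btf_hz[bb$bin == k], exp(mean(log(fq[ix]))),
                 tolerance = 1e-10)
    expect_equal(bb$distance_um[bb$bin == k], exp(mean(log(dst[ix]))),
                 tolerance = 1e-10)
  }
  expect_error(binGeometric(10, -5, 50), "invalid input")
  expect_message(z <- binGeometric(c(0, 10), c(1e4, 1e4), 50),
                 "substituted")
})

test_that("quadratic R2 never falls below linear R2 (nested OLS)", {
  # collinear bins: perfect linear fit
  bins <- data.frame(bin = 0:4, distance_um = seq(25, 225, 50),
                     btf_hz = 2^seq(12.3, 15.3, length.out = 5),
                     n_cells = 3L)
  fit <- fitTonotopy(bins)
  expect_equal(fit@r2Linear, 1, tolerance = 1e-9)
  expect_gte(fit@r2Quadratic, fit@r2Linear - 1e-12)
  # property over random datasets
  set.seed(9)
  for (i in 1:100) {
    nb <- sample(4:9, 1)
    bb <- data.frame(bin = seq_len(nb) - 1,
                     distance_um = sort(runif(nb, 10, 400)),
                     btf_hz = 2^runif(nb, 12, 15.3), n_cells = 1L)
    f <- fitTonotopy(bb)
    expect_gte(f@r2Quadratic, f@r2Linear - 1e-12)
  }
  # three bins: quadratic omitted; fewer: error
  f3 <- fitTonotopy(bins[1:3, ])
  expect_true(is.na(f3@r2Quadratic))
  expect_error(fitTonotopy(bins[1:2, ]), "insufficient data")
})

test_that("tonotopy assessment is translation invariant", {
  cells <- generateCells(80, layout = "gradient", seed = 12)
  cen <- cbind(cells$x_um, cells$y_um)
  ax1 <- axisFromAngle(0, origin = c(0, 0))
  ax2 <- axisFromAngle(0, origin = c(-137.5, 222.25))
  f1 <- suppressMessages(assessTonotopy(cen, cells$true_btf_hz, ax1))
  f2 <- suppressMessages(assessTonotopy(
    cen + matrix(c(-137.5, 222.25), 80, 2, byrow = TRUE),
    cells$true_btf_hz, ax2))
  expect_equal(f1@bins, f2@bins, tolerance = 1e-9)
  expect_equal(f1@r2Linear, f2@r2Linear, tolerance = 1e-9)
  expect_equal(f1@r2Quadratic, f2@r2Quadratic, tolerance = 1e-9)
})

test_that("an implanted gradient is recovered along its axis only", {
  r2True <- r2Orth <- numeric(5)
  for (s in 1:5) {
    cells <- generateCells(120, layout = "gradient", axisAngleDeg = 0,
                           gradientSpanOct = 3, jitterOct = 0.15, seed = s)
    cen <- cbind(cells$x_um, cells$y_um)
    r2True[s] <- suppressMessages(
      assessTonotopy(cen, cells$true_btf_hz, axisFromAngle(0)))@r2Linear
    r2Orth[s] <- suppressMessages(
      assessTonotopy(cen, cells$true_btf_hz, axisFromAngle(90)))@r2Linear
  }
  expect_gt(mean(r2True), 0.9)
  expect_lt(mean(r2Orth), 0.3)
})
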