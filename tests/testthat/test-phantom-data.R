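test_that("phantom sampling matches the dataset recipe", {
  set.seed(1)
  n <- 10000
  cats <- integer(n)
  for (i in seq_len(n)) cats[i] <- length(samplePhantom()@inclusions)
  # category proportions 1% / 44% / 55% (chi-square at alpha = 0.01)
  chi <- stats::chisq.test(tabulate(cats + 1L, 3L), p = c(0.01, 0.44, 0.55))
  expect_gt(chi$p.value, 0.01)
  # determinism: same seed gives the identical phantom
  p1 <- samplePhantom(seed = 99)
  p2 <- samplePhantom(seed = 99)
  expect_equal(p1, p2)
  # parameter ranges (spot check over a sample)
  set.seed(2)
  for (i in 1:50) {
    ph <- samplePhantom()
    expect_true(ph@diameter >= 60 && ph@diameter <= 150)
    expect_true(ph@backgroundMuA >= 0.005 && ph@backgroundMuA <= 0.03)
    expect_true(ph@backgroundMuSp >= 0.5 && ph@backgroundMuSp <= 3)
    expect_true(ph@frequency >= 10 && ph@frequency <= 100)
    for (inc in ph@inclusions) {
      expect_true(inc@radius >= 2 && inc@radius <= 30)
      expect_lte(sqrt(sum(inc@center^2)) + inc@radius, ph@diameter / 2 + 1e-9)
    }
  }
})

test_that("rasterization places inclusions by pixel-center membership", {
  ph <- testPhantom()
  img <- rasterizePhantom(ph)
  expect_equal(dim(propertyValues(img)), c(64L, 64L, 2L))
  expect_equal(img@pixelPitch, 60 / 64)
  # homogeneous phantom: constant channels
  expect_equal(max(propertyValues(img)[, , 1]), min(propertyValues(img)[, , 1]))
  # inclusion value = contrast x background at the inclusion center
  ph2 <- testPhantom(inclusions = list(testInclusion(c(10, 5), 10, 4, 2)))
  img2 <- rasterizePhantom(ph2)
  px <- fdDOT:::pixelCenters(60)
  i <- which.min(abs(px$x - 10)); j <- which.min(abs(px$y - 5))
  expect_equal(propertyValues(img2)[i, j, 1], 0.04)
  expect_equal(propertyValues(img2)[i, j, 2], 2)
  # inclusion pixel count close to pi r^2 / pitch^2 (one perimeter of slack)
  nIn <- sum(propertyValues(img2)[, , 1] > 0.01)
  expected <- pi * 100 / img2@pixelPitch^2
  perimeter <- 2 * pi * 10 / img2@pixelPitch
  expect_lt(abs(nIn - expected), perimeter)
})

test_that("homogeneous simulation is rotationally symmetric", {
  ph <- testPhantom()
  sim <- simulatePhantom(ph)
  la <- log(amplitude(sim$measurements))
  sep <- t(vapply(1:16, function(s) {
    d <- setdiff(1:16, s)
    pmin((d - s) %% 16, (s - d) %% 16)
  }, numeric(15)))
  spread <- vapply(1:8, function(k) diff(range(la[sep == k])), 0)
  # mesh asymmetry keeps same-separation readings within a few percent of
  # the full dynamic range
  expect_true(all(spread < 0.05 * diff(range(la))))
  expect_equal(dim(la), c(16L, 15L))
})

test_that("an absorbing inclusion attenuates transmission amplitudes", {
  ph0 <- testPhantom()
  ph1 <- testPhantom(inclusions = list(testInclusion(c(0, 0), 12, 6, 2)))
  m0 <- simulatePhantom(ph0)$measurements
  m1 <- simulatePhantom(ph1)$measurements
  # detector slots 7-9 sit roughly opposite each source (transmission)
  expect_true(all(amplitude(m1)[, 7:9] < amplitude(m0)[, 7:9]))
})

test_that("measurement noise has the configured relative spread", {
  ph <- testPhantom()
  m <- simulatePhantom(ph)$measurements
  expect_equal(addNoise(m, 0), m)
  set.seed(5)
  ratios <- replicate(200, {
    mn <- addNoise(m, 0.15)
    as.vector(amplitude(mn) / amplitude(m))
  })
  expect_lt(abs(mean(ratios) - 1), 3 * 0.15 / sqrt(length(ratios)))
  expect_lt(abs(sd(ratios) - 0.15), 0.05 * 0.15)
  expect_true(all(amplitude(addNoise(m, 0.15, seed = 1)) > 0))
  # determinism
  expect_equal(addNoise(m, 0.15, seed = 7), addNoise(m, 0.15, seed = 7))
})

test_that("calibration against the homogeneous reference behaves", {
  ph <- testPhantom(inclusions = list(testInclusion()))
  ref <- testPhantom()
  sim <- simulatePhantom(ph)
  simr <- simulatePhantom(ref, mesh = sim$mesh)
  # self-reference: zero difference channels before scaling
  self <- calibrateMeasurements(simr$measurements, simr$measurements,
                                rescale = FALSE)
  expect_equal(max(abs(self)), 0)
  x <- calibrateMeasurements(sim$measurements, simr$measurements)
  expect_equal(dim(x), c(16L, 15L, 2L))
  expect_true(all(x >= 0 & x <= 1))
  # min-max scaling preserves ordering within a channel
  raw <- calibrateMeasurements(sim$measurements, simr$measurements,
                               rescale = FALSE)
  expect_equal(order(raw[, , 1]), order(x[, , 1]))
})
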