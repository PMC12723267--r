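test_that("MSE and PSNR follow their definitions", {
  a <- matrix(0, 64, 64); b <- matrix(1, 64, 64)
  expect_equal(imageMSE(a, a), 0)
  expect_equal(imageMSE(a, b), 1)
  set.seed(3)
  x <- matrix(runif(64 * 64), 64); y <- matrix(runif(64 * 64), 64)
  # naive double-loop oracle
  acc <- 0
  for (i in 1:64) for (j in 1:64) acc <- acc + (x[i, j] - y[i, j])^2
  expect_equal(imageMSE(x, y), acc / 4096, tolerance = 1e-12)
  expect_error(imageMSE(x, matrix(0, 32, 32)), "mismatch")
  expect_equal(imagePSNR(matrix(0.1, 8, 8), matrix(0, 8, 8)), 20)
  expect_equal(imagePSNR(b, a), 0)
  expect_equal(imagePSNR(matrix(0.02, 8, 8), matrix(0, 8, 8)),
               10 * log10(1 / 4e-4), tolerance = 1e-9)  # 33.98 dB
  expect_equal(imagePSNR(a, a), Inf)
  # PSNR strictly decreasing in MSE
  mses <- c(1e-4, 1e-3, 1e-2, 1e-1)
  psnrs <- vapply(mses, function(m) 10 * log10(1 / m), 0)
  expect_true(all(diff(psnrs) < 0))
})

test_that("SSIM matches a global-statistics oracle and is symmetric", {
  set.seed(4)
  x <- matrix(runif(64), 8); y <- matrix(runif(64), 8)
  # image smaller than the window: single global window, closed form
  C1 <- 0.01^2; C2 <- 0.03^2
  mx <- mean(x); my <- mean(y)
  vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
  cxy <- mean((x - mx) * (y - my))
  oracle <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
            ((mx^2 + my^2 + C1) * (vx + vy + C2))
  expect_equal(imageSSIM(x, y), oracle, tolerance = 1e-10)
  X <- matrix(runif(4096), 64); Y <- matrix(runif(4096), 64)
  expect_equal(imageSSIM(X, X), 1)
  expect_equal(imageSSIM(X, Y), imageSSIM(Y, X), tolerance = 1e-12)
  expect_lt(imageSSIM(X, 1 - X), 1)
})

test_that("resolution indices reproduce the worked table rows", {
  # fold rule
  ph <- testPhantom(inclusions = list(testInclusion(c(8, 0), 9, 4, 3)))
  truth <- rasterizePhantom(ph)
  zones <- fdDOT:::inclusionZones(ph)
  cr <- contrastResolution(propertyValues(truth)[, , 1],
                           propertyValues(truth)[, , 1], zones, truth@mask)
  expect_equal(cr$r0, 1)
  expect_equal(cr$rContrast, 1)
  # explicit fold arithmetic
  expect_equal(csdResolution(1, 1), 1)
  fold <- function(r0) if (r0 > 1) 2 - r0 else r0
  expect_equal(fold(1.3), 0.7)
  expect_equal(fold(0.8), 0.8)
  # size resolution: perfect reconstruction
  base <- matrix(ph@backgroundMuA, 64, 64)
  sr <- sizeResolution(propertyValues(truth)[, , 1],
                       propertyValues(truth)[, , 1], base, zones, 0.7)
  expect_equal(sr$r0Size, 1)
  expect_equal(sr$rSize, sqrt(0.7))
  # printed worked examples (geometric-mean composition, 2 decimals)
  expect_equal(round(sqrt(0.50 * 0.70), 2), 0.59)
  expect_equal(round(sqrt(0.72 * 0.94), 2), 0.82)
  expect_equal(round(csdResolution(0.94, 0.82), 2), 0.88)
  expect_equal(round(csdResolution(0.70, 0.59), 2), 0.64, tolerance = 0.011)
  # product form stays available
  expect_equal(csdResolution(0.94, 0.82, form = "product"), 0.94 * 0.82)
  expect_error(sizeResolution(base, base, base, zones, 1), "baseline")
})

test_that("resolution report runs on a reconstruction-shaped input", {
  ph <- testPhantom(inclusions = list(testInclusion(c(8, 0), 9, 4, 3)))
  truth <- rasterizePhantom(ph)
  blur <- propertyValues(truth)
  blur[, , 1] <- 0.6 * blur[, , 1] + 0.4 * mean(blur[, , 1])
  blur[, , 2] <- 0.6 * blur[, , 2] + 0.4 * mean(blur[, , 2])
  rep <- resolutionReport(blur, ph)
  expect_equal(rep$channel, c("muA", "muSp"))
  expect_true(all(rep$rCSD >= 0 & rep$rCSD <= 1))
  expect_true(all(rep$rSize <= 1))
})

test_that("attention diagnostics report histogram entropy in bits", {
  d <- attentionDiagnostics(matrix(5, 10, 10), matrix(5, 10, 10))
  expect_equal(d$entropyBefore, 0)
  # uniform histogram over 256 bins -> 8 bits
  x <- rep(seq(0, 1, length.out = 256), each = 4)
  d2 <- attentionDiagnostics(x, x)
  expect_equal(d2$entropyBefore, 8, tolerance = 1e-9)
  expect_equal(sum(d2$histBefore$counts), length(x))
  expect_error(attentionDiagnostics(numeric(0), 1), "empty")
})

test_that("attention reduces feature-map entropy on a trained model", {
  ds <- tinyDataset()
  m <- buildCAFNet(cafnetConfig(automapWidth = 64L), seed = 6)
  # enough optimizer steps for the attention gates to differentiate
  m <- trainCAFNet(m, ds, trainConfig(epochs = 8L, batchSize = 8L, seed = 7L))
  te <- splitIndices(ds, "test")
  maps <- cabFeatureMaps(m, fdDOT:::inputMatrix(ds, te))
  expect_true(all(maps$weights > 0 & maps$weights < 1))
  d <- attentionDiagnostics(maps$before, maps$after)
  expect_lte(d$entropyAfter, d$entropyBefore)
})

test_that("cross-validation folds partition the data and report fold MSEs", {
  ds <- tinyDataset()
  cv <- crossValidate(ds, k = 2, config = cafnetConfig(automapWidth = 32L,
                                                       variant = "feb_only"),
                      tc = trainConfig(epochs = 1L, batchSize = 8L, seed = 2L),
                      seed = 3)
  expect_length(cv$perFold, 2)
  expect_true(all(cv$perFold > 0))
  expect_equal(cv$mean, mean(cv$perFold))
  expect_equal(cv$sd, sd(cv$perFold))
})
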