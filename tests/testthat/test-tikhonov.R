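test_that("adjoint Jacobian matches finite differences", {
  pc <- physicsConstants()
  mesh <- buildCircularMesh(60, 5)
  n <- nNodes(mesh)
  set.seed(2)
  muA <- 0.01 * runif(n, 0.8, 1.2)
  muSp <- runif(n, 0.9, 1.1)
  lay <- placeProbes(60, 1)
  jac <- computeJacobian(mesh, muA, muSp, 70, lay, pc)
  expect_equal(dim(jac$J), c(480L, 2L * n))
  D <- 1 / (3 * (muA + muSp))
  dataVec <- function(mA, mS) {
    j <- computeJacobian(mesh, mA, mS, 70, lay, pc)
    c(log(as.vector(amplitude(j$measured))), as.vector(phase(j$measured)))
  }
  for (k in c(5L, 40L, n %/% 2)) {
    dp <- 1e-6
    m2 <- muA; m2[k] <- m2[k] + dp
    m1 <- muA; m1[k] <- m1[k] - dp
    num <- (dataVec(m2, 1 / (3 * D) - m2) - dataVec(m1, 1 / (3 * D) - m1)) / (2 * dp)
    expect_lt(max(abs(num - jac$J[, k])) / max(abs(jac$J[, k])), 1e-3)
  }
  for (k in c(5L, 40L)) {
    dp <- 1e-7
    D2 <- D; D2[k] <- D2[k] + dp
    D1 <- D; D1[k] <- D1[k] - dp
    num <- (dataVec(muA, 1 / (3 * D2) - muA) -
            dataVec(muA, 1 / (3 * D1) - muA)) / (2 * dp)
    expect_lt(max(abs(num - jac$J[, n + k])) / max(abs(jac$J[, n + k])), 1e-3)
  }
})

test_that("absorption can only attenuate in a homogeneous medium", {
  pc <- physicsConstants()
  mesh <- buildCircularMesh(60, 5)
  n <- nNodes(mesh)
  lay <- placeProbes(60, 1)
  jac <- computeJacobian(mesh, rep(0.01, n), rep(1, n), 70, lay, pc)
  expect_true(all(jac$J[1:240, 1:n] <= 1e-12))
})

test_that("the regularized update solves the augmented least-squares problem", {
  expect_equal(trUpdate(diag(4), c(1, 0, 0, 0), 0), c(1, 0, 0, 0))
  set.seed(7)
  J <- matrix(rnorm(6 * 4), 6, 4)
  r <- rnorm(6)
  lam <- 0.3
  # oracle: ordinary least squares on the stacked augmented system [J; lam I]
  aug <- rbind(J, lam * diag(4))
  oracle <- qr.solve(aug, c(r, rep(0, 4)))
  expect_equal(trUpdate(J, r, lam), oracle, tolerance = 1e-10)
  # larger random instances
  for (i in 1:5) {
    J <- matrix(rnorm(50 * 30), 50, 30)
    r <- rnorm(50)
    lam <- runif(1, 0.1, 2)
    oracle <- qr.solve(rbind(J, lam * diag(30)), c(r, rep(0, 30)))
    expect_lt(max(abs(trUpdate(J, r, lam) - oracle)) / max(abs(oracle)), 1e-8)
  }
  # regularization limit: huge lambda shrinks the update to zero
  expect_lt(sqrt(sum(trUpdate(J, r, 1e8 * norm(J, "2"))^2)), 1e-10)
  # rank-deficient J with lambda 0 fails with advice
  Jr <- cbind(1:4, 1:4)
  expect_error(trUpdate(Jr, rnorm(4), 0), "lambda")
})

test_that("reconstruction is a fixed point on matching homogeneous data", {
  ph <- testPhantom()
  sim <- simulatePhantom(ph, meshSize = 60 / 15)  # same mesh as the solver
  rec <- reconstructTR(sim$measurements, 60, 0.01, 1)
  expect_equal(rec@iterations, 1L)
  expect_lt(rec@residualHistory[1], 1e-8)
  expect_equal(range(rec@nodalMuA), c(0.01, 0.01), tolerance = 1e-9)
})

test_that("background recovery from perturbed initial guess is within 5%", {
  ph <- testPhantom()
  sim <- simulatePhantom(ph, meshSize = 60 / 15)
  rec <- reconstructTR(sim$measurements, 60, 0.012, 1.2,
                       trConfig(maxIterations = 10))
  expect_lt(abs(mean(rec@nodalMuA) - 0.01) / 0.01, 0.05)
  expect_lt(abs(mean(rec@nodalMuSp) - 1), 0.05)
})

test_that("accepted residuals never increase and misfit grows with lambda", {
  ph <- testPhantom(inclusions = list(testInclusion(c(-8, 3), 8, 3, 3)),
                    freq = 30)
  sim <- simulatePhantom(ph)
  rec <- reconstructTR(sim$measurements, 60, 0.01, 1)
  expect_true(all(diff(rec@residualHistory) <= 1e-9))
  # sweep within the convergent regime (very small lambda can stall the
  # line search before reaching its better attainable misfit)
  mis <- vapply(c(0.03, 0.1, 0.3), function(l)
    tail(reconstructTR(sim$measurements, 60, 0.01, 1,
                       trConfig(lambdaRelative = l,
                                maxIterations = 12))@residualHistory, 1), 0)
  expect_true(all(diff(mis) >= -1e-9))
})

test_that("homogeneous background can be estimated from the data", {
  ph <- testPhantom(muA = 0.008, muSp = 0.9)
  sim <- simulatePhantom(ph, meshSize = 60 / 12)
  fit <- fitHomogeneousBackground(sim$measurements, 60, init = c(0.012, 1.3))
  expect_lt(abs(fit["muA"] - 0.008) / 0.008, 0.10)
  expect_lt(abs(fit["muSp"] - 0.9) / 0.9, 0.10)
})
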