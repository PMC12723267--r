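test_that("diffusion coefficient follows 1/(3(mua + musp))", {
  expect_equal(diffusionCoefficient(0, 1 / 3), 1.0)
  expect_equal(diffusionCoefficient(0.006, 0.6), 0.550055, tolerance = 1e-6)
  expect_equal(diffusionCoefficient(0.03, 3.0), 0.110011, tolerance = 1e-6)
  expect_error(diffusionCoefficient(-0.01, 1), "positive")
  expect_error(diffusionCoefficient(0, 0), "positive")
})

test_that("disk meshes are contained, conforming and convergent", {
  m <- buildCircularMesh(60, 5)
  r <- sqrt(rowSums(meshNodes(m)^2))
  expect_true(all(r <= 30 * (1 + 1e-6)))
  a <- triangleAreas(m)
  expect_true(all(a > 0))
  expect_lt(abs(sum(a) - pi * 900) / (pi * 900), 0.01)
  # interior edges shared by exactly two triangles, boundary edges by one
  tri <- m@triangles
  ed <- rbind(tri[, 1:2], tri[, 2:3], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  counts <- table(table(key))
  expect_true(all(names(counts) %in% c("1", "2")))
  expect_equal(unname(counts["1"]), sum(m@boundary))
  # refinement reduces the area discrepancy
  e1 <- abs(sum(triangleAreas(buildCircularMesh(80, 4))) - pi * 1600)
  e2 <- abs(sum(triangleAreas(buildCircularMesh(80, 2))) - pi * 1600)
  expect_lt(e2, e1)
  expect_error(buildCircularMesh(60, 10), "element size")
})

test_that("mesh text serialization round-trips", {
  m <- buildCircularMesh(70, 6)
  f <- tempfile(fileext = ".txt")
  writeMesh(m, f)
  m2 <- readMesh(f)
  expect_equal(meshNodes(m2), meshNodes(m))
  expect_equal(m2@triangles, m@triangles)
  expect_equal(m2@boundary, m@boundary)
  unlink(f)
})

test_that("point location returns valid barycentric weights", {
  m <- buildCircularMesh(60, 5)
  pts <- rbind(c(0, 0), c(12, -7), c(29.99, 0))
  loc <- locatePoints(m, pts)
  expect_false(anyNA(loc$triangle))
  expect_equal(rowSums(loc$weights), rep(1, 3))
  expect_true(all(loc$weights >= 0))
  # interpolating node coordinates reproduces the query point
  tri <- m@triangles[loc$triangle[2], ]
  rec <- colSums(loc$weights[2, ] * meshNodes(m)[tri, ])
  expect_equal(rec, pts[2, ], tolerance = 1e-9)
  expect_true(is.na(locatePoints(m, rbind(c(40, 0)))$triangle))
})

test_that("probe layout has 16 sources x 15 detectors at 22.5 degree spacing", {
  pl <- placeProbes(80, sourceDepth = 1.25)
  expect_equal(dim(pl@detectorIndex), c(16L, 15L))
  expect_equal(16 * 15, 240)
  ang <- atan2(pl@boundaryPositions[, 2], pl@boundaryPositions[, 1])
  d <- sort(diff(sort(ang)))
  expect_equal(d, rep(2 * pi / 16, 15), tolerance = 1e-12)
  # a source's detectors are the other 15 positions, own position excluded
  for (s in c(1, 7, 16))
    expect_equal(sort(pl@detectorIndex[s, ]), setdiff(1:16, s))
  # source points displaced radially inward by the requested depth
  rs <- sqrt(rowSums(pl@sourcePositions^2))
  expect_equal(rs, rep(40 - 1.25, 16))
})

test_that("FEM assembly matches hand-assembled P1 elements on a toy mesh", {
  m <- squareMesh()
  pc <- physicsConstants(robinA = 2)
  muA <- c(0.01, 0.02, 0.01, 0.03)
  muSp <- c(1, 1.2, 0.9, 1.1)
  sys <- assembleSystem(m, muA, muSp, 0, pc)
  D <- 1 / (3 * (muA + muSp))
  nodes <- m@nodes; tri <- m@triangles
  K <- matrix(0, 4, 4)
  mlump <- numeric(4)
  for (e in 1:2) {
    el <- oracleElement(nodes[tri[e, 1], ], nodes[tri[e, 2], ], nodes[tri[e, 3], ])
    De <- mean(D[tri[e, ]])
    K[tri[e, ], tri[e, ]] <- K[tri[e, ], tri[e, ]] + De * el$K
    mlump[tri[e, ]] <- mlump[tri[e, ]] + el$area / 3
  }
  A <- K + diag(muA * mlump)
  # Robin term: consecutive boundary edges around the square, edge mass len/6*[[2,1],[1,2]]
  edges <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1))
  for (i in 1:4) {
    len <- sqrt(sum((nodes[edges[i, 1], ] - nodes[edges[i, 2], ])^2))
    B <- len / 6 * matrix(c(2, 1, 1, 2), 2)
    A[edges[i, ], edges[i, ]] <- A[edges[i, ], edges[i, ]] + B / (2 * pc@robinA)
  }
  expect_equal(as.matrix(sys@Areal), A, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sys@imagDiag, rep(0, 4))
})

test_that("assembled system is symmetric, real at zero frequency, linear in omega", {
  pc <- physicsConstants()
  m <- buildCircularMesh(60, 60 / 20)
  n <- nNodes(m)
  s0 <- assembleSystem(m, rep(0.01, n), rep(1, n), 0, pc)
  expect_equal(max(abs(s0@Areal - Matrix::t(s0@Areal))), 0, tolerance = 1e-12)
  expect_equal(s0@imagDiag, rep(0, n))
  s1 <- assembleSystem(m, rep(0.01, n), rep(1, n), 50, pc)
  s2 <- assembleSystem(m, rep(0.01, n), rep(1, n), 100, pc)
  expect_equal(s2@imagDiag, 2 * s1@imagDiag, tolerance = 1e-12)
  expect_error(assembleSystem(m, rep(-0.01, n), rep(1, n), 50, pc), "positive")
})

test_that("forward solve is real at omega = 0 and reciprocal when heterogeneous", {
  pc <- physicsConstants()
  m <- buildCircularMesh(60, 60 / 20)
  n <- nNodes(m)
  lay <- placeProbes(60, 1)
  sys0 <- assembleSystem(m, rep(0.01, n), rep(1, n), 0, pc, lay)
  phi0 <- solveForward(sys0, 1)
  expect_lt(max(abs(Im(phi0))) / max(abs(Re(phi0))), 1e-10)
  set.seed(4)
  muA <- 0.01 * runif(n, 0.7, 1.3); muSp <- runif(n, 0.8, 1.2)
  sys <- assembleSystem(m, muA, muSp, 70, pc, lay)
  phi <- solveForward(sys)
  # discrete reciprocity: field of source s at the source functional of d
  G <- t(sys@sources) %*% phi
  expect_lt(max(Mod(G - t(G))) / max(Mod(G)), 1e-8)
})

test_that("boundary measurements decay with distance and behave linearly", {
  pc <- physicsConstants()
  m <- buildCircularMesh(60, 60 / 25)
  n <- nNodes(m)
  lay <- placeProbes(60, 1)
  sys <- assembleSystem(m, rep(0.01, n), rep(1, n), 100, pc, lay)
  fields <- solveForward(sys)
  ms <- measureBoundary(fields, lay, m, 100)
  expect_equal(dim(amplitude(ms)), c(16L, 15L))
  expect_true(all(amplitude(ms) > 0))
  expect_true(all(phase(ms) > -pi & phase(ms) <= pi))
  # amplitude decreases with chord distance (averaged over distance ties)
  d1 <- sqrt(rowSums(sweep(detectorPositions(lay, 1), 2,
                           lay@boundaryPositions[1, ])^2))
  ud <- sort(unique(round(d1, 9)))
  mm <- vapply(ud, function(d) mean(amplitude(ms)[1, round(d1, 9) == d]), 0)
  expect_true(all(diff(mm) < 0))
  # zero frequency: all phases zero
  sys0 <- assembleSystem(m, rep(0.01, n), rep(1, n), 0, pc, lay)
  ms0 <- measureBoundary(solveForward(sys0), lay, m, 0)
  expect_equal(max(abs(phase(ms0))), 0, tolerance = 1e-10)
  # scaling the sources scales amplitudes, not phases
  sys2 <- sys
  sys2@sources <- 3 * sys@sources
  sys2@cache <- new.env()
  ms2 <- measureBoundary(solveForward(sys2), lay, m, 100)
  expect_equal(amplitude(ms2), 3 * amplitude(ms), tolerance = 1e-12)
  expect_equal(phase(ms2), phase(ms), tolerance = 1e-12)
})
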