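# Shared fixtures, built in code.

# two-triangle square mesh inscribed in the circle of radius sqrt(2);
# all four corners are boundary nodes, the diagonal is interior
squareMesh <- function() {
  nodes <- rbind(c(1, 1), c(-1, 1), c(-1, -1), c(1, -1))
  tri <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
  new("DOTMesh", nodes = nodes, triangles = tri,
      boundary = rep(TRUE, 4), radius = sqrt(2), h = 2)
}

# independent P1 element matrices: shape-function coefficients from solving
# the 3x3 vertex interpolation system (a different route than the package's
# vectorized gradient formulas)
oracleElement <- function(v1, v2, v3) {
  V <- cbind(1, rbind(v1, v2, v3))
  C <- solve(V, diag(3))          # phi_l(x, y) = C[1,l] + C[2,l] x + C[3,l] y
  area <- abs(det(cbind(v2 - v1, v3 - v1))) / 2
  K <- matrix(0, 3, 3)
  for (l in 1:3) for (m in 1:3)
    K[l, m] <- area * (C[2, l] * C[2, m] + C[3, l] * C[3, m])
  list(K = K, area = area)
}

testPhantom <- function(diameter = 60, muA = 0.01, muSp = 1, freq = 50,
                        inclusions = list()) {
  new("Phantom", diameter = diameter, backgroundMuA = muA,
      backgroundMuSp = muSp, inclusions = inclusions, frequency = freq)
}

testInclusion <- function(center = c(10, 5), radius = 10, ca = 4, cs = 2) {
  new("Inclusion", center = center, radius = radius, contrastA = ca,
      contrastS = cs)
}

# tiny dataset for training smoke tests, memoized across test files
.fixtureCache <- new.env()
tinyDataset <- function(n = 40, seed = 11) {
  key <- paste0("ds", n, "_", seed)
  if (is.null(.fixtureCache[[key]]))
    .fixtureCache[[key]] <- generateDataset(n = n, seed = seed)
  .fixtureCache[[key]]
}
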