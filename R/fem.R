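#' Assemble the frequency-domain diffusion FEM system
#'
#' Discretizes \eqn{(-\nabla\cdot D\nabla + \mu_a - i\omega/c)\Phi = S_0} with
#' linear (P1) triangles: exact element stiffness with element-mean diffusion
#' coefficient, lumped (row-sum) nodal mass for the absorption and frequency
#' terms, and a consistent edge-mass Robin term \eqn{1/(2A)\oint\phi_i\phi_j}
#' on the boundary.  Source vectors place unit isotropic point sources at the
#' interior-offset source locations, distributed to the enclosing triangle's
#' nodes by barycentric weights.
#'
#' @param mesh a \linkS4class{DOTMesh}.
#' @param muA nodal absorption coefficients, 1/mm (length = node count).
#' @param muSp nodal reduced scattering coefficients, 1/mm.
#' @param frequencyMHz modulation frequency (MHz); 0 gives a real system.
#' @param constants a \linkS4class{PhysicsConstants}.
#' @param layout optional \linkS4class{ProbeLayout}; when supplied the 16
#'   source vectors are built, otherwise `sources` is a zero-column matrix.
#' @return a \linkS4class{FEMSystem}.
#' @export
assembleSystem <- function(mesh, muA, muSp, frequencyMHz, constants,
                           layout = NULL) {
  n <- nrow(mesh@nodes)
  stopifnot(length(muA) == n, length(muSp) == n)
  if (any(muA <= 0) || any(muSp <= 0)) stop("optical properties must be positive")
  g <- triangleGradients(mesh)
  tri <- mesh@triangles
  area <- g$area
  if (any(area < 1e-12)) stop(sprintf("degenerate triangle %d", which.min(area)))
  D <- diffusionCoefficient(muA, muSp)
  De <- rowMeans(matrix(D[tri], ncol = 3))
  # stiffness entries: K[e](l,m) = De * area * (bx_l bx_m + by_l by_m)
  ii <- jj <- xx <- vector("list", 11)
  k <- 0
  for (l in 1:3) for (m in 1:3) {
    k <- k + 1
    ii[[k]] <- tri[, l]; jj[[k]] <- tri[, m]
    xx[[k]] <- De * area * (g$bx[, l] * g$bx[, m] + g$by[, l] * g$by[, m])
  }
  # lumped nodal mass: m_i = sum over incident elements of area/3
  mlump <- as.numeric(Matrix::sparseMatrix(
    i = as.vector(tri), j = rep(1L, 3 * nrow(tri)),
    x = rep(area / 3, 3), dims = c(n, 1)))
  ii[[10]] <- seq_len(n); jj[[10]] <- seq_len(n); xx[[10]] <- muA * mlump
  # Robin boundary term: (1/(2A)) * edge mass [len/6 * [[2,1],[1,2]]]
  be <- boundaryEdges(mesh)
  len <- sqrt(rowSums((mesh@nodes[be[, 1], , drop = FALSE] -
                       mesh@nodes[be[, 2], , drop = FALSE])^2))
  coef <- 1 / (2 * constants@robinA)
  ii[[11]] <- c(be[, 1], be[, 2], be[, 1], be[, 2])
  jj[[11]] <- c(be[, 1], be[, 2], be[, 2], be[, 1])
  xx[[11]] <- coef * c(len / 3, len / 3, len / 6, len / 6)
  Areal <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                                dims = c(n, n))
  omega <- angularFrequency(frequencyMHz)
  imagDiag <- -(omega / constants@lightSpeed) * mlump
  sources <- matrix(0, n, 0)
  if (!is.null(layout)) {
    loc <- locatePoints(mesh, layout@sourcePositions)
    if (anyNA(loc$triangle)) stop("source point outside mesh")
    sources <- matrix(0, n, nrow(layout@sourcePositions))
    for (s in seq_len(ncol(sources)))
      sources[mesh@triangles[loc$triangle[s], ], s] <- loc$weights[s, ]
  }
  new("FEMSystem", Areal = Areal, imagDiag = imagDiag, sources = sources,
      omega = omega, mesh = mesh, cache = new.env(parent = emptyenv()))
}

# LU factorization of the equivalent 2n real block system for A = Ar + iE
# (E = imagDiag): (Ar + iE)(x + iy) = br + i bi  <=>  [Ar -E; E Ar][x;y]=[br;bi]
femFactor <- function(system) {
  if (!is.null(system@cache$lu)) return(system@cache$lu)
  n <- nrow(system@Areal)
  Em <- Matrix::Diagonal(n, x = system@imagDiag)
  blk <- rbind(cbind(system@Areal, -Em), cbind(Em, system@Areal))
  f <- Matrix::lu(blk)
  system@cache$lu <- f
  f
}

#' Solve the assembled system for complex nodal photon density
#'
#' Sparse LU on the equivalent real block system; the factorization is cached
#' on the \linkS4class{FEMSystem} and reused across all sources.
#'
#' @param system a \linkS4class{FEMSystem} with source vectors.
#' @param sourceIndex source index (1-16), or NULL for all sources at once.
#' @return complex matrix of nodal photon densities, one column per requested
#'   source (a plain complex vector when `sourceIndex` has length 1).
#' @export
solveForward <- function(system, sourceIndex = NULL) {
  b <- system@sources
  if (ncol(b) == 0) stop("system has no source vectors")
  if (!is.null(sourceIndex)) {
    if (any(sourceIndex < 1) || any(sourceIndex > ncol(b)))
      stop("invalid source index")
    b <- b[, sourceIndex, drop = FALSE]
  }
  phi <- femSolve(system, b + 0i)
  if (!is.null(sourceIndex) && length(sourceIndex) == 1L) phi[, 1] else phi
}

# Solve A z = rhs for complex rhs (n x k complex matrix), A = Ar - i D.
femSolve <- function(system, rhs) {
  n <- nrow(system@Areal)
  f <- femFactor(system)
  rr <- rbind(Re(rhs), Im(rhs))
  sol <- Matrix::solve(f, rr)
  sol <- as.matrix(sol)
  if (any(!is.finite(sol))) stop("singular FEM system")
  out <- sol[1:n, , drop = FALSE] + 1i * sol[(n + 1):(2 * n), , drop = FALSE]
  out
}

#' Extract boundary measurements from solved photon-density fields
#'
#' Interpolates the complex field of every source at its 15 detector
#' positions (barycentric P1 interpolation) and returns amplitude
#' \eqn{|\Phi|} and principal-value phase \eqn{\arg\Phi \in (-\pi, \pi]}.
#'
#' @param fields n x 16 complex matrix of nodal fields, one column per source.
#' @param layout a \linkS4class{ProbeLayout}.
#' @param mesh the \linkS4class{DOTMesh} the fields live on.
#' @param frequencyMHz modulation frequency recorded on the result.
#' @return a \linkS4class{MeasurementSet}.
#' @export
measureBoundary <- function(fields, layout, mesh, frequencyMHz) {
  stopifnot(ncol(fields) == 16L)
  P <- interpolationMatrix(mesh, layout@boundaryPositions)  # 16 x n
  # Matrix has no complex sparse classes; multiply parts separately
  vals <- as.matrix(P %*% Re(fields)) + 1i * as.matrix(P %*% Im(fields))
  amp <- matrix(0, 16, 15); ph <- matrix(0, 16, 15)
  for (s in 1:16) {
    v <- vals[layout@detectorIndex[s, ], s]
    amp[s, ] <- Mod(v)
    ph[s, ] <- Arg(v)
  }
  ph[ph <= -pi] <- pi
  new("MeasurementSet", amplitude = amp, phase = ph, frequency = frequencyMHz)
}
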