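#' Adjoint-method Jacobian of boundary data with respect to optical properties
#'
#' Computes the sensitivity of the 240 log-amplitude and 240 phase
#' measurements to the nodal absorption mu_a and diffusion coefficient D.
#' With the complex symmetric FEM system, the adjoint field of a detector is
#' obtained by solving with the detector's interpolation vector as source
#' (one factorization serves all 16 sources and 16 detector positions).  The
#' complex sensitivity of a source-detector pair is
#' \deqn{\partial\Phi_{sd}/\partial p_k = -\Psi_d^T (\partial A/\partial p_k) \Phi_s,}
#' converted to the real data parameterization via
#' \eqn{\partial\ln|\Phi|/\partial p = Re(\Phi^{-1}\partial\Phi/\partial p)} and
#' \eqn{\partial\arg\Phi/\partial p = Im(\Phi^{-1}\partial\Phi/\partial p)}.
#' For mu_a the lumped-mass discretization makes \eqn{\partial A/\partial\mu_{a,k}}
#' the diagonal unit m_k e_k e_k'; for D it is the element-mean stiffness
#' contribution (1/3 per vertex).
#'
#' @param mesh a \linkS4class{DOTMesh}.
#' @param muA,muSp nodal optical properties (1/mm).
#' @param layout a \linkS4class{ProbeLayout}.
#' @param frequencyMHz modulation frequency (MHz).
#' @param constants a \linkS4class{PhysicsConstants}.
#' @return list with `J` (480 x 2n matrix; rows = 240 log-amplitude then 240
#'   phase rows in source-major pair order; columns = n mu_a then n D
#'   sensitivities), `measured` (the model \linkS4class{MeasurementSet}), and
#'   `fields` (n x 16 complex forward fields).
#' @export
computeJacobian <- function(mesh, muA, muSp, frequencyMHz, layout,
                            constants = physicsConstants()) {
  n <- nrow(mesh@nodes)
  sys <- assembleSystem(mesh, muA, muSp, frequencyMHz, constants, layout)
  Phi <- solveForward(sys)                            # n x 16
  P <- interpolationMatrix(mesh, layout@boundaryPositions)  # 16 x n
  Psi <- femSolve(sys, t(as.matrix(P)) + 0i)          # n x 16 adjoint fields
  # measured complex values at the 16 positions for each source
  vals <- as.matrix(P %*% Re(Phi)) + 1i * as.matrix(P %*% Im(Phi))
  if (any(Mod(vals) == 0)) stop("zero photon density at a detector")
  g <- triangleGradients(mesh)
  tri <- mesh@triangles
  nE <- nrow(tri)
  # element-gradient operators (E x n): gx = sum_l bx_l phi_l
  Gx <- Matrix::sparseMatrix(i = rep(seq_len(nE), 3), j = as.vector(tri),
                             x = as.vector(g$bx), dims = c(nE, n))
  Gy <- Matrix::sparseMatrix(i = rep(seq_len(nE), 3), j = as.vector(tri),
                             x = as.vector(g$by), dims = c(nE, n))
  # node-element incidence with 1/3 weights (n x E)
  Tm <- Matrix::sparseMatrix(i = as.vector(tri), j = rep(seq_len(nE), 3),
                             x = rep(1 / 3, 3 * nE), dims = c(n, nE))
  cmul <- function(M, Z) as.matrix(M %*% Re(Z)) + 1i * as.matrix(M %*% Im(Z))
  GxPhi <- cmul(Gx, Phi); GyPhi <- cmul(Gy, Phi)      # E x 16
  GxPsi <- cmul(Gx, Psi); GyPsi <- cmul(Gy, Psi)
  mlump <- femLumpedMass(mesh)
  # pair bookkeeping: row p corresponds to element p of as.vector() of the
  # 16 x 15 measurement matrices (column-major, source index fastest)
  srcIdx <- rep(1:16, times = 15)
  slot <- rep(1:15, each = 16)
  detIdx <- layout@detectorIndex[cbind(srcIdx, slot)]
  Phid <- vals[cbind(detIdx, srcIdx)]                 # 240 complex
  # d mu_a block: -m_k Psi_k,d Phi_k,s
  dMua <- -(mlump * Psi[, detIdx, drop = FALSE]) * Phi[, srcIdx, drop = FALSE]
  # d D block: -(1/3) sum_{e in k} area_e (grad Psi . grad Phi)
  Se <- g$area * (GxPhi[, srcIdx, drop = FALSE] * GxPsi[, detIdx, drop = FALSE] +
                  GyPhi[, srcIdx, drop = FALSE] * GyPsi[, detIdx, drop = FALSE])
  dD <- -cmul(Tm, Se)                                 # n x 240
  rel <- rbind(dMua, dD)                              # 2n x 240
  rel <- sweep(rel, 2, Phid, "/")
  J <- rbind(t(Re(rel)), t(Im(rel)))                  # 480 x 2n
  amp <- matrix(0, 16, 15); phs <- matrix(0, 16, 15)
  for (s in 1:16) {
    v <- vals[layout@detectorIndex[s, ], s]
    amp[s, ] <- Mod(v); phs[s, ] <- Arg(v)
  }
  phs[phs <= -pi] <- pi
  list(J = J,
       measured = new("MeasurementSet", amplitude = amp, phase = phs,
                      frequency = frequencyMHz),
       fields = Phi)
}

# lumped nodal mass vector (sum of incident element areas / 3)
femLumpedMass <- function(mesh) {
  tri <- mesh@triangles
  area <- triangleAreas(mesh)
  as.numeric(Matrix::sparseMatrix(i = as.vector(tri),
                                  j = rep(1L, 3 * nrow(tri)),
                                  x = rep(area / 3, 3),
                                  dims = c(nrow(mesh@nodes), 1)))
}
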