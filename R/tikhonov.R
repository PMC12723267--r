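#' Construct a Tikhonov/Gauss-Newton reconstruction configuration
#'
#' @param lambdaRelative regularization weight relative to the largest
#'   diagonal entry of J'J (default 0.01).
#' @param maxIterations Gauss-Newton iteration cap (default 20).
#' @param tolerance stop when the relative residual change drops below this
#'   (default 1e-3).
#' @param positivityFloor lower bound for mu_a (1/mm) and the diffusion
#'   coefficient after each update.
#' @param meshDivisor reconstruction mesh element size is diameter/meshDivisor
#'   (default 15, deliberately coarser than the simulation mesh).
#' @return a list of settings for [reconstructTR()].
#' @export
trConfig <- function(lambdaRelative = 0.01, maxIterations = 20L,
                     tolerance = 1e-3, positivityFloor = 1e-5,
                     meshDivisor = 15) {
  stopifnot(lambdaRelative > 0, maxIterations >= 1)
  list(lambdaRelative = lambdaRelative,
       maxIterations = as.integer(maxIterations), tolerance = tolerance,
       positivityFloor = positivityFloor, meshDivisor = meshDivisor)
}

#' Regularized Gauss-Newton update
#'
#' Solves the normal equations of the Tikhonov-regularized linearized
#' problem, \eqn{(J'J + \lambda^2 I)\Delta x = J' r}, equivalent to the
#' least-squares solution of the augmented system [J; lambda I].
#'
#' @param J Jacobian matrix (m x p).
#' @param residual data residual (length m).
#' @param lambdaAbs absolute regularization parameter (>= 0).
#' @return the parameter update (length p).
#' @export
trUpdate <- function(J, residual, lambdaAbs) {
  if (length(residual) != nrow(J)) stop("residual length must match J rows")
  if (lambdaAbs < 0) stop("lambda must be >= 0")
  A <- crossprod(J) + diag(lambdaAbs^2, ncol(J))
  ch <- tryCatch(chol(A), error = function(e) NULL)
  if (is.null(ch) || min(diag(ch))^2 < 1e-12 * max(diag(ch))^2)
    stop("normal equations singular; use lambda > 0 for rank-deficient J")
  backsolve(ch, forwardsolve(t(ch), crossprod(J, residual)))[, 1]
}

#' Iterative Tikhonov-regularized reconstruction of optical properties
#'
#' Gauss-Newton iteration on the (log-amplitude, phase) data residual with
#' identity-matrix Tikhonov regularization: at each step the adjoint Jacobian
#' with respect to nodal (mu_a, D) is assembled, the regularized update
#' solved with \eqn{\lambda^2 = \lambda_{rel}\max\mathrm{diag}(J'J)} of the
#' parameter-scaled system, a backtracking line search enforces
#' non-increasing residuals, and physical box constraints are applied.
#' Iteration stops when the relative residual change falls below tolerance,
#' at the iteration cap, or when no damped step improves the residual
#' (flagged as diverged when even the first step cannot improve on the
#' initial guess).  The nodal result is interpolated to a 64 x 64
#' \linkS4class{PropertyImage}.
#'
#' @param measurements observed \linkS4class{MeasurementSet}.
#' @param diameter phantom diameter (mm).
#' @param backgroundMuA,backgroundMuSp homogeneous initial estimate (1/mm),
#'   e.g. from the calibration reference or [fitHomogeneousBackground()].
#' @param config settings from [trConfig()].
#' @param constants a \linkS4class{PhysicsConstants}.
#' @return a \linkS4class{ReconResult}.
#' @export
reconstructTR <- function(measurements, diameter, backgroundMuA,
                          backgroundMuSp, config = trConfig(),
                          constants = physicsConstants()) {
  mesh <- buildCircularMesh(diameter, diameter / config$meshDivisor)
  n <- nrow(mesh@nodes)
  layout <- placeProbes(diameter, sourceDepth = 1 / backgroundMuSp)
  muA <- rep(backgroundMuA, n)
  D <- rep(diffusionCoefficient(backgroundMuA, backgroundMuSp), n)
  dObs <- c(log(as.vector(measurements@amplitude)),
            as.vector(measurements@phase))
  resNorm <- function(jac) {
    dMod <- c(log(as.vector(jac$measured@amplitude)),
              as.vector(jac$measured@phase))
    r <- dObs - dMod
    # principal-value phase differences
    r[241:480] <- ((r[241:480] + pi) %% (2 * pi)) - pi
    r
  }
  # box constraints spanning the admissible optical range (mu_a up to
  # 8 x 0.03, mu_s' up to 8 x 3, down to well below the background minima)
  clampA <- function(x) pmin(pmax(x, config$positivityFloor), 0.5)
  clampD <- function(x) pmin(pmax(x, 0.012), 0.7)
  musp <- function(muA, D) pmax(1 / (3 * pmax(D, 0.012)) - muA, 1e-3)
  jac <- computeJacobian(mesh, muA, pmax(musp(muA, D), muA), measurements@frequency,
                         layout, constants)
  r <- resNorm(jac)
  hist <- sqrt(sum(r^2))
  best <- list(muA = muA, D = D, res = hist[1])
  diverged <- FALSE
  it <- 0L
  while (it < config$maxIterations) {
    it <- it + 1L
    if (tail(hist, 1) < 1e-10 * length(r)) break  # already at the fixed point
    # parameter-scaled (relative) update: scaling the columns of J by the
    # current parameter values puts mu_a and D on a common footing, so the
    # identity regularizer penalizes relative rather than absolute changes
    scale <- c(muA, D)
    Js <- sweep(jac$J, 2, scale, "*")
    lam <- sqrt(config$lambdaRelative * max(colSums(Js^2)))
    dx <- trUpdate(Js, r, lam) * scale
    step <- 1
    improved <- FALSE
    cur <- tail(hist, 1)
    for (ls in 1:4) {
      muA2 <- clampA(muA + step * dx[1:n])
      D2 <- clampD(D + step * dx[(n + 1):(2 * n)])
      jac2 <- tryCatch(
        computeJacobian(mesh, muA2, pmax(musp(muA2, D2), muA2),
                        measurements@frequency, layout, constants),
        error = function(e) NULL)
      if (!is.null(jac2)) {
        r2 <- resNorm(jac2)
        if (sqrt(sum(r2^2)) <= cur * (1 + 1e-9)) { improved <- TRUE; break }
      }
      step <- step / 2
    }
    if (!improved || is.null(jac2)) {
      # no damped step reduces the residual: the attainable (noise/model)
      # floor is reached; flag as diverged only when not even the first
      # Gauss-Newton step could improve on the initial guess
      diverged <- it == 1L
      break
    }
    newRes <- sqrt(sum(resNorm(jac2)^2))
    relChange <- abs(cur - newRes) / max(cur, 1e-300)
    muA <- muA2; D <- D2; jac <- jac2; r <- resNorm(jac)
    hist <- c(hist, newRes)
    if (newRes < best$res) best <- list(muA = muA, D = D, res = newRes)
    if (relChange < config$tolerance) break
  }
  if (best$res < tail(hist, 1)) { muA <- best$muA; D <- best$D }
  img <- nodalToImage(mesh, muA, musp(muA, D), diameter,
                      backgroundMuA, backgroundMuSp)
  new("ReconResult", propertyImage = img, nodalMuA = muA,
      nodalMuSp = musp(muA, D), residualHistory = hist,
      iterations = length(hist), diverged = diverged)
}

# barycentric interpolation of nodal values onto the 64 x 64 pixel raster;
# pixels outside the mesh take the background estimate
nodalToImage <- function(mesh, muA, muSp, diameter, bgA, bgS) {
  px <- pixelCenters(diameter)
  loc <- locatePoints(mesh, px$grid)
  vals <- array(0, c(64, 64, 2))
  va <- rep(bgA, nrow(px$grid)); vs <- rep(bgS, nrow(px$grid))
  ok <- !is.na(loc$triangle)
  tri <- mesh@triangles[loc$triangle[ok], , drop = FALSE]
  w <- loc$weights[ok, , drop = FALSE]
  va[ok] <- rowSums(w * matrix(muA[tri], ncol = 3))
  vs[ok] <- rowSums(w * matrix(muSp[tri], ncol = 3))
  vals[, , 1] <- matrix(va, 64, 64)
  vals[, , 2] <- matrix(vs, 64, 64)
  mask <- matrix(rowSums(px$grid^2) <= (diameter / 2)^2, 64, 64)
  new("PropertyImage", values = vals, pixelPitch = px$pitch, mask = mask)
}

#' Estimate a homogeneous background from boundary data
#'
#' Fits a two-parameter homogeneous model (background mu_a, mu_s') to a
#' measurement set by Nelder-Mead on the summed squared (log-amplitude,
#' phase) residual.
#'
#' @param measurements observed \linkS4class{MeasurementSet}.
#' @param diameter phantom diameter (mm).
#' @param init starting values c(muA, muSp).
#' @param constants a \linkS4class{PhysicsConstants}.
#' @param meshDivisor mesh coarseness for the fit (default 12, coarse).
#' @return named vector c(muA, muSp).
#' @export
fitHomogeneousBackground <- function(measurements, diameter,
                                     init = c(0.01, 1),
                                     constants = physicsConstants(),
                                     meshDivisor = 12) {
  mesh <- buildCircularMesh(diameter, diameter / meshDivisor)
  n <- nrow(mesh@nodes)
  dObs <- c(log(as.vector(measurements@amplitude)),
            as.vector(measurements@phase))
  obj <- function(p) {
    p <- exp(p)
    if (p[1] > p[2]) return(1e10)
    layout <- placeProbes(diameter, sourceDepth = 1 / p[2])
    sys <- assembleSystem(mesh, rep(p[1], n), rep(p[2], n),
                          measurements@frequency, constants, layout)
    m <- measureBoundary(solveForward(sys), layout, mesh,
                         measurements@frequency)
    dMod <- c(log(as.vector(m@amplitude)), as.vector(m@phase))
    sum((dObs - dMod)^2)
  }
  fit <- stats::optim(log(init), obj, method = "Nelder-Mead",
                      control = list(maxit = 120, reltol = 1e-6))
  out <- exp(fit$par)
  names(out) <- c("muA", "muSp")
  out
}
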