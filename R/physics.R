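#' Construct the physical-constant set for the forward model
#'
#' The speed of light in the medium is the vacuum speed divided by the
#' refractive index, in mm/ns so that all matrix entries stay O(1).  When
#' `robinA` is not supplied it is computed from the refractive-index mismatch
#' with the Groenhuis/Egan polynomial for the effective internal reflection
#' coefficient, A = (1 + R_eff) / (1 - R_eff).
#'
#' @param refractiveIndex refractive index of the tissue (default 1.33).
#' @param robinA optional explicit Robin reflection parameter A.
#' @return a \linkS4class{PhysicsConstants} object.
#' @examples
#' pc <- physicsConstants()
#' lightSpeed(pc)   # ~225.4 mm/ns at n = 1.33
#' @export
physicsConstants <- function(refractiveIndex = 1.33, robinA = NULL) {
  c0 <- 299.792458  # mm/ns in vacuum
  if (is.null(robinA)) {
    n <- refractiveIndex
    reff <- -1.440 / n^2 + 0.710 / n + 0.668 + 0.0636 * n
    robinA <- (1 + reff) / (1 - reff)
  }
  new("PhysicsConstants", refractiveIndex = refractiveIndex,
      lightSpeed = c0 / refractiveIndex, robinA = robinA)
}

#' Diffusion coefficient from absorption and reduced scattering
#'
#' D = 1 / (3 (mu_a + mu_s')), in mm.  Vectorized over its arguments.
#'
#' @param muA absorption coefficient, 1/mm (>= 0, not both zero).
#' @param muSp reduced scattering coefficient, 1/mm.
#' @return diffusion coefficient in mm.
#' @examples
#' diffusionCoefficient(0.006, 0.6)  # 0.550055 mm
#' @export
diffusionCoefficient <- function(muA, muSp) {
  if (any(muA < 0) || any(muSp <= 0) || any(muA + muSp <= 0))
    stop("optical properties must be positive")
  1 / (3 * (muA + muSp))
}

#' Angular frequency in rad/ns from a modulation frequency in MHz
#' @param frequencyMHz modulation frequency in MHz.
#' @return angular frequency in rad/ns.
#' @export
angularFrequency <- function(frequencyMHz) 2 * pi * frequencyMHz * 1e-3
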