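#' Place the 16-source / 15-detector probe layout on a phantom boundary
#'
#' Sixteen equidistant positions (22.5 degrees apart, starting at angle 0) on
#' the circle act as detector sites; for each source position the remaining 15
#' positions are its detectors, giving 240 source-detector pairs.  The
#' effective isotropic source point is displaced one transport mean free path
#' (1/mu_s', configurable) radially into the domain, the standard
#' diffusion-approximation source model.
#'
#' @param diameter phantom diameter (mm).
#' @param sourceDepth interior displacement of the effective source (mm);
#'   typically 1/mu_s' of the background.
#' @return a \linkS4class{ProbeLayout}.
#' @examples
#' pl <- placeProbes(60, sourceDepth = 1 / 0.6)
#' dim(pl@detectorIndex)  # 16 x 15
#' @export
placeProbes <- function(diameter, sourceDepth = 1) {
  if (diameter <= 0) stop("diameter must be positive")
  R <- diameter / 2
  th <- 2 * pi * (0:15) / 16
  bp <- cbind(R * cos(th), R * sin(th))
  sp <- cbind((R - sourceDepth) * cos(th), (R - sourceDepth) * sin(th))
  det <- t(vapply(1:16, function(s) setdiff(1:16, s), integer(15)))
  new("ProbeLayout", diameter = diameter, boundaryPositions = bp,
      sourcePositions = sp, detectorIndex = det, sourceDepth = sourceDepth)
}

#' Detector coordinates for one source
#' @param layout a \linkS4class{ProbeLayout}.
#' @param source source index (1-16).
#' @return 15 x 2 matrix of detector coordinates (mm).
#' @export
detectorPositions <- function(layout, source) {
  layout@boundaryPositions[layout@detectorIndex[source, ], , drop = FALSE]
}
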