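#' @import methods
#' @importFrom Matrix sparseMatrix Diagonal crossprod t solve lu
#' @importFrom stats rnorm runif sd optim quantile
#' @importFrom utils head tail
#' @useDynLib fdDOT, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Physical constants for the diffusion forward model
#'
#' Bundles the refractive index of the medium, the resulting speed of light
#' in the medium (mm/ns) and the Robin boundary-reflection parameter A used
#' in the mixed boundary condition \eqn{\Phi + 2AD\,\partial\Phi/\partial n = 0}.
#'
#' @slot refractiveIndex dimensionless refractive index (>= 1).
#' @slot lightSpeed speed of light in the medium, mm/ns.
#' @slot robinA dimensionless boundary reflection parameter (> 0).
#' @export
setClass("PhysicsConstants",
  representation(refractiveIndex = "numeric",
                 lightSpeed = "numeric",
                 robinA = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@refractiveIndex < 1) msg <- c(msg, "refractiveIndex must be >= 1")
    if (object@lightSpeed <= 0) msg <- c(msg, "lightSpeed must be > 0")
    if (object@robinA <= 0) msg <- c(msg, "robinA must be > 0")
    if (length(msg)) msg else TRUE
  })

#' Triangulated disk mesh
#'
#' A conforming P1 (linear triangle) mesh of a circular domain.  Nodes are in
#' mm, triangles are index triples (counter-clockwise), and boundary nodes lie
#' on the circle of the stored radius.
#'
#' @slot nodes n x 2 matrix of node coordinates (mm).
#' @slot triangles m x 3 integer matrix of node indices, positively oriented.
#' @slot boundary logical vector flagging boundary nodes.
#' @slot radius disk radius (mm).
#' @slot h characteristic element size (mm).
#' @export
setClass("DOTMesh",
  representation(nodes = "matrix", triangles = "matrix",
                 boundary = "logical", radius = "numeric", h = "numeric"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@nodes)
    if (ncol(object@nodes) != 2L) msg <- c(msg, "nodes must be n x 2")
    tri <- object@triangles
    if (any(tri < 1L) || any(tri > n)) msg <- c(msg, "triangle indices out of range")
    r <- sqrt(rowSums(object@nodes^2))
    if (any(r > object@radius * (1 + 1e-6)))
      msg <- c(msg, "node outside circumscribed radius")
    if (any(abs(r[object@boundary] - object@radius) > 0.01 * object@radius))
      msg <- c(msg, "boundary node off the circle by more than 1% of radius")
    a <- triangleAreas(object)
    if (any(a <= 0)) msg <- c(msg, "non-positive triangle area")
    if (length(msg)) msg else TRUE
  })

#' Source/detector layout on the phantom boundary
#'
#' 16 equidistant boundary positions serve alternately as source launch points
#' and detector sites; each source sees the remaining 15 positions as
#' detectors (240 pairs).  The effective isotropic source point is displaced
#' one transport mean free path into the domain.
#'
#' @slot diameter phantom diameter (mm).
#' @slot boundaryPositions 16 x 2 matrix of boundary positions (mm).
#' @slot sourcePositions 16 x 2 matrix of interior source points (mm).
#' @slot detectorIndex 16 x 15 integer matrix; row s holds the boundary-position
#'   indices acting as detectors for source s, in increasing angular order.
#' @slot sourceDepth interior displacement of the source point (mm).
#' @export
setClass("ProbeLayout",
  representation(diameter = "numeric", boundaryPositions = "matrix",
                 sourcePositions = "matrix", detectorIndex = "matrix",
                 sourceDepth = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@boundaryPositions) != 16L) msg <- c(msg, "need 16 boundary positions")
    if (!all(dim(object@detectorIndex) == c(16L, 15L)))
      msg <- c(msg, "detectorIndex must be 16 x 15")
    for (s in seq_len(nrow(object@detectorIndex)))
      if (s %in% object@detectorIndex[s, ])
        msg <- c(msg, "a source cannot be its own detector")
    if (length(msg)) msg else TRUE
  })

#' Assembled frequency-domain FEM system
#'
#' Discretization of the frequency-domain diffusion equation
#' \eqn{(-\nabla\cdot D\nabla + \mu_a - i\omega/c)\Phi = S_0}
#' with Robin boundary conditions: \eqn{A = K_D + M_{\mu_a} - i(\omega/c)M}.
#' The real part is sparse symmetric; the imaginary part is the (diagonal)
#' lumped mass scaled by \eqn{-\omega/c}.
#'
#' @slot Areal real sparse part of the system matrix (dgCMatrix).
#' @slot imagDiag diagonal of the imaginary part (vector, \eqn{-\omega/c\,m_i}).
#' @slot sources n x 16 matrix of real source vectors.
#' @slot omega angular frequency (rad/ns).
#' @slot mesh the DOTMesh the system was assembled on.
#' @slot cache environment memoizing the sparse factorization.
#' @export
setClass("FEMSystem",
  representation(Areal = "ANY", imagDiag = "numeric", sources = "matrix",
                 omega = "numeric", mesh = "DOTMesh", cache = "environment"),
  validity = function(object) {
    n <- nrow(object@mesh@nodes)
    msg <- character()
    if (nrow(object@Areal) != n) msg <- c(msg, "system dimension != node count")
    if (length(object@imagDiag) != n) msg <- c(msg, "imagDiag length != node count")
    if (max(abs(object@Areal - Matrix::t(object@Areal))) > 1e-9 * max(abs(object@Areal)))
      msg <- c(msg, "system matrix not symmetric")
    if (length(msg)) msg else TRUE
  })

#' Circular inclusion inside a phantom
#'
#' @slot center inclusion center (x, y) in mm.
#' @slot radius inclusion radius in mm.
#' @slot contrastA multiplicative absorption contrast over background.
#' @slot contrastS multiplicative scattering contrast over background.
#' @export
setClass("Inclusion",
  representation(center = "numeric", radius = "numeric",
                 contrastA = "numeric", contrastS = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@center) != 2L) msg <- c(msg, "center must be length 2")
    if (object@radius < 2 || object@radius > 30)
      msg <- c(msg, "inclusion radius outside [2, 30] mm")
    if (object@contrastA < 1.5 || object@contrastA > 8 ||
        object@contrastS < 1.5 || object@contrastS > 8)
      msg <- c(msg, "contrast outside [1.5, 8]")
    if (length(msg)) msg else TRUE
  })

#' Circular tissue phantom
#'
#' Generative unit of the synthetic dataset: a circular domain with uniform
#' background optical properties, up to two non-overlapping circular
#' inclusions, and a modulation frequency.
#'
#' @slot diameter phantom diameter (mm), 60-150.
#' @slot backgroundMuA background absorption coefficient (1/mm).
#' @slot backgroundMuSp background reduced scattering coefficient (1/mm).
#' @slot inclusions list of 0-2 \linkS4class{Inclusion} objects.
#' @slot frequency modulation frequency (MHz).
#' @export
setClass("Phantom",
  representation(diameter = "numeric", backgroundMuA = "numeric",
                 backgroundMuSp = "numeric", inclusions = "list",
                 frequency = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@diameter < 50 || object@diameter > 150)
      msg <- c(msg, "diameter outside [50, 150] mm")
    if (object@backgroundMuA <= 0 || object@backgroundMuSp <= 0)
      msg <- c(msg, "background properties must be positive")
    if (object@backgroundMuSp < object@backgroundMuA)
      msg <- c(msg, "diffusion approximation needs mu_s' >= mu_a")
    if (length(object@inclusions) > 2L) msg <- c(msg, "at most two inclusions")
    R <- object@diameter / 2
    for (inc in object@inclusions) {
      if (!is(inc, "Inclusion")) { msg <- c(msg, "inclusions must be Inclusion objects"); next }
      if (sqrt(sum(inc@center^2)) + inc@radius > R * (1 + 1e-9))
        msg <- c(msg, "inclusion not entirely inside the phantom")
    }
    if (length(object@inclusions) == 2L) {
      a <- object@inclusions[[1]]; b <- object@inclusions[[2]]
      if (sqrt(sum((a@center - b@center)^2)) < a@radius + b@radius)
        msg <- c(msg, "inclusions overlap")
    }
    if (length(msg)) msg else TRUE
  })

#' Frequency-domain boundary measurement set
#'
#' Amplitude and phase of the photon-density wave at each of the 240
#' source-detector pairs (16 sources x 15 detectors).
#'
#' @slot amplitude 16 x 15 matrix of positive amplitudes.
#' @slot phase 16 x 15 matrix of phases in (-pi, pi].
#' @slot frequency modulation frequency (MHz).
#' @export
setClass("MeasurementSet",
  representation(amplitude = "matrix", phase = "matrix", frequency = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@amplitude) == c(16L, 15L))) msg <- c(msg, "amplitude must be 16 x 15")
    if (!all(dim(object@phase) == c(16L, 15L))) msg <- c(msg, "phase must be 16 x 15")
    if (any(object@amplitude <= 0)) msg <- c(msg, "amplitudes must be positive")
    if (any(object@phase <= -pi | object@phase > pi)) msg <- c(msg, "phase outside (-pi, pi]")
    if (length(msg)) msg else TRUE
  })

#' Rasterized optical-property image
#'
#' 64 x 64 x 2 grid of absorption (channel 1) and reduced scattering
#' (channel 2) values covering the phantom bounding square, with a mask of
#' inside-disk pixels.  Pixels outside the disk carry the background value.
#'
#' @slot values 64 x 64 x 2 array (1/mm).
#' @slot pixelPitch pixel size (mm), diameter/64.
#' @slot mask 64 x 64 logical matrix of inside-disk pixels.
#' @export
setClass("PropertyImage",
  representation(values = "array", pixelPitch = "numeric", mask = "matrix"),
  validity = function(object) {
    msg <- character()
    if (!all(dim(object@values) == c(64L, 64L, 2L))) msg <- c(msg, "values must be 64 x 64 x 2")
    if (!all(dim(object@mask) == c(64L, 64L))) msg <- c(msg, "mask must be 64 x 64")
    v <- object@values
    if (any(!is.finite(v))) msg <- c(msg, "non-finite values")
    inside <- which(object@mask)
    if (length(inside) &&
        (any(v[, , 1][inside] <= 0) || any(v[, , 2][inside] <= 0)))
      msg <- c(msg, "non-positive values inside mask")
    if (length(msg)) msg else TRUE
  })

#' Paired simulation dataset with train/validation/test split
#'
#' Holds calibrated 16 x 15 x 2 network inputs, 64 x 64 x 2 ground-truth
#' property images, domain masks, per-sample phantom metadata, the split
#' assignment and the target normalization statistics (per-channel min/max
#' over the training split).
#'
#' @slot inputs N x 16 x 15 x 2 array of normalized inputs.
#' @slot targets N x 64 x 64 x 2 array of property images (1/mm).
#' @slot masks N x 64 x 64 logical array of inside-disk pixels.
#' @slot meta data.frame of per-sample phantom parameters.
#' @slot phantoms list of \linkS4class{Phantom} objects.
#' @slot split factor with levels train/val/test.
#' @slot stats list with per-channel target min/max (train split).
#' @slot seed integer seed the dataset was generated from.
#' @export
setClass("DOTDataset",
  representation(inputs = "array", targets = "array", masks = "array",
                 meta = "data.frame", phantoms = "list", split = "factor",
                 stats = "list", seed = "integer"),
  validity = function(object) {
    msg <- character()
    N <- dim(object@inputs)[1]
    if (!all(dim(object@inputs)[-1] == c(16L, 15L, 2L))) msg <- c(msg, "inputs must be N x 16 x 15 x 2")
    if (!all(dim(object@targets) == c(N, 64L, 64L, 2L))) msg <- c(msg, "targets must be N x 64 x 64 x 2")
    if (length(object@split) != N) msg <- c(msg, "split length != N")
    if (!all(levels(object@split) == c("train", "val", "test")))
      msg <- c(msg, "split levels must be train/val/test")
    if (length(msg)) msg else TRUE
  })

#' Gauss-Newton/Tikhonov reconstruction result
#'
#' @slot propertyImage reconstructed \linkS4class{PropertyImage}.
#' @slot nodalMuA reconstructed nodal absorption (1/mm).
#' @slot nodalMuSp reconstructed nodal reduced scattering (1/mm).
#' @slot residualHistory data-misfit norm of each accepted iterate.
#' @slot iterations number of iterations run.
#' @slot diverged TRUE when the best iterate was returned after divergence.
#' @export
setClass("ReconResult",
  representation(propertyImage = "PropertyImage", nodalMuA = "numeric",
                 nodalMuSp = "numeric", residualHistory = "numeric",
                 iterations = "integer", diverged = "logical"),
  validity = function(object) {
    if (length(object@residualHistory) != object@iterations)
      "residualHistory length must equal iterations" else TRUE
  })

#' CAFNet architecture configuration
#'
#' @slot automapWidth hidden width of the AUTOMAP transform (default 1024).
#' @slot febFilters filters per feature-extraction-block conv layer (8).
#' @slot febKernel kernel size of the first FEB (3).
#' @slot fusionKernels kernel sizes of the three fusion branches (1, 3, 5).
#' @slot fusionRefineFilters filters of the pooled-branch 1x1 conv (8).
#' @slot nFusionBlocks number of stacked fusion blocks (2).
#' @slot cabReduction channel-attention bottleneck reduction ratio (4).
#' @slot variant one of "full", "feb_only", "feb_fusion", "no_cab", "no_feb".
#' @export
setClass("CAFNetConfig",
  representation(automapWidth = "integer", febFilters = "integer",
                 febKernel = "integer", fusionKernels = "integer",
                 fusionRefineFilters = "integer", nFusionBlocks = "integer",
                 cabReduction = "integer", variant = "character"),
  prototype(automapWidth = 1024L, febFilters = 8L, febKernel = 3L,
            fusionKernels = c(1L, 3L, 5L), fusionRefineFilters = 8L,
            nFusionBlocks = 2L, cabReduction = 4L, variant = "full"),
  validity = function(object) {
    msg <- character()
    if (object@febFilters < 1L) msg <- c(msg, "febFilters must be >= 1")
    if (!object@variant %in% c("full", "feb_only", "feb_fusion", "no_cab", "no_feb"))
      msg <- c(msg, "unknown variant")
    if (length(msg)) msg else TRUE
  })

#' CAFNet training configuration
#'
#' Optimization settings: Adam with learning rate 0.001 and beta1 = 0.5,
#' batch size 64, weighted sum of per-channel MSE as loss.
#'
#' @slot learningRate Adam step size (0.001).
#' @slot beta1 Adam first-moment decay (0.5).
#' @slot beta2 Adam second-moment decay (0.999).
#' @slot batchSize minibatch size (64).
#' @slot epochs training epochs.
#' @slot lossWeights length-2 nonnegative weights (mu_a, mu_s') summing to 1.
#' @slot seed integer RNG seed for initialization and shuffling.
#' @export
setClass("TrainConfig",
  representation(learningRate = "numeric", beta1 = "numeric", beta2 = "numeric",
                 batchSize = "integer", epochs = "integer",
                 lossWeights = "numeric", seed = "integer"),
  prototype(learningRate = 1e-3, beta1 = 0.5, beta2 = 0.999, batchSize = 64L,
            epochs = 100L, lossWeights = c(0.5, 0.5), seed = 1L),
  validity = function(object) {
    msg <- character()
    if (object@epochs < 1L) msg <- c(msg, "epochs must be >= 1")
    if (any(object@lossWeights < 0) || abs(sum(object@lossWeights) - 1) > 1e-8)
      msg <- c(msg, "lossWeights must be nonnegative and sum to 1")
    if (length(msg)) msg else TRUE
  })

#' A built (possibly trained) CAFNet model
#'
#' @slot config the \linkS4class{CAFNetConfig} the model was built from.
#' @slot params named list of layer parameter sets (weights, biases,
#'   batch-norm scale/shift and running statistics).
#' @slot history list with per-epoch train/val loss after training.
#' @export
setClass("CAFNetModel",
  representation(config = "CAFNetConfig", params = "list", history = "list"))
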