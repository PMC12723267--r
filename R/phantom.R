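#' Default phantom parameter ranges
#'
#' The study conditions of the simulated dataset: circular phantoms of
#' 60-150 mm diameter, background mu_a 0.005-0.03 /mm, background mu_s'
#' 0.5-3 /mm, modulation frequency 10-100 MHz, 0-2 inclusions with radii
#' 2-30 mm and multiplicative contrasts 1.5-8, category probabilities
#' 1% homogeneous / 44% one inclusion / 55% two inclusions.
#'
#' @return named list of ranges and category probabilities.
#' @export
phantomRanges <- function() {
  list(diameter = c(60, 150), muA = c(0.005, 0.03), muSp = c(0.5, 3),
       frequency = c(10, 100), inclusionRadius = c(2, 30),
       contrast = c(1.5, 8), categoryProb = c(0.01, 0.44, 0.55))
}

runif1 <- function(r) stats::runif(1, r[1], r[2])

#' Sample a random phantom from the dataset parameter ranges
#'
#' Category (homogeneous / one inclusion / two inclusions) is drawn with the
#' configured probabilities; all continuous parameters are uniform in their
#' ranges.  Inclusions are rejected and resampled until they lie entirely
#' inside the phantom and do not overlap (up to 1000 tries, then an error).
#' Absorption and scattering contrasts are sampled independently.
#'
#' @param ranges parameter ranges as from [phantomRanges()].
#' @param seed optional integer seed; when supplied the RNG state is set
#'   locally so the same seed always returns the same phantom.
#' @return a \linkS4class{Phantom}.
#' @export
samplePhantom <- function(ranges = phantomRanges(), seed = NULL) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  d <- runif1(ranges$diameter)
  R <- d / 2
  nInc <- sample.int(3L, 1L, prob = ranges$categoryProb) - 1L
  incs <- list()
  if (nInc > 0L) {
    placed <- FALSE
    for (try in seq_len(1000L)) {
      # jointly resample the whole inclusion set so one oversized inclusion
      # cannot lock out the others
      cand <- vector("list", nInc)
      ok <- TRUE
      for (i in seq_len(nInc)) {
        r <- runif1(ranges$inclusionRadius)
        if (r >= R) { ok <- FALSE; break }
        rho <- (R - r) * sqrt(stats::runif(1))  # uniform over admissible centers
        th <- stats::runif(1, 0, 2 * pi)
        ctr <- c(rho * cos(th), rho * sin(th))
        if (i == 2L) {
          o <- cand[[1]]
          if (sqrt(sum((ctr - o@center)^2)) < r + o@radius) { ok <- FALSE; break }
        }
        cand[[i]] <- new("Inclusion", center = ctr, radius = r,
                         contrastA = runif1(ranges$contrast),
                         contrastS = runif1(ranges$contrast))
      }
      if (ok) { incs <- cand; placed <- TRUE; break }
    }
    if (!placed) stop("could not place inclusions after 1000 tries")
  }
  new("Phantom", diameter = d, backgroundMuA = runif1(ranges$muA),
      backgroundMuSp = runif1(ranges$muSp), inclusions = incs,
      frequency = runif1(ranges$frequency))
}

# optical properties at arbitrary coordinates (q x 2), by point-in-disk tests
phantomProperties <- function(phantom, points) {
  muA <- rep(phantom@backgroundMuA, nrow(points))
  muSp <- rep(phantom@backgroundMuSp, nrow(points))
  for (inc in phantom@inclusions) {
    inside <- (points[, 1] - inc@center[1])^2 +
              (points[, 2] - inc@center[2])^2 <= inc@radius^2
    muA[inside] <- phantom@backgroundMuA * inc@contrastA
    muSp[inside] <- phantom@backgroundMuSp * inc@contrastS
  }
  list(muA = muA, muSp = muSp)
}

# pixel-center coordinates of the 64 x 64 raster over the bounding square
pixelCenters <- function(diameter, n = 64L) {
  pitch <- diameter / n
  ax <- -diameter / 2 + (seq_len(n) - 0.5) * pitch
  list(x = ax, y = ax, pitch = pitch,
       grid = cbind(rep(ax, times = n), rep(ax, each = n)))
}

#' Rasterize a phantom to a 64 x 64 x 2 ground-truth property image
#'
#' Pixel membership is decided by the pixel-center point: centers inside an
#' inclusion disk get contrast x background, all other pixels (including those
#' outside the phantom disk) get the background value, so image metrics are
#' not dominated by the mask.  The inside-disk mask is stored alongside.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @return a \linkS4class{PropertyImage}.
#' @export
rasterizePhantom <- function(phantom) {
  px <- pixelCenters(phantom@diameter)
  pr <- phantomProperties(phantom, px$grid)
  vals <- array(0, c(64, 64, 2))
  vals[, , 1] <- matrix(pr$muA, 64, 64)
  vals[, , 2] <- matrix(pr$muSp, 64, 64)
  mask <- matrix(rowSums(px$grid^2) <= (phantom@diameter / 2)^2, 64, 64)
  new("PropertyImage", values = vals, pixelPitch = px$pitch, mask = mask)
}

#' Simulate noise-free boundary measurements for a phantom
#'
#' Builds a disk mesh, maps the phantom's optical properties onto the mesh
#' nodes by point-in-disk tests, places the 16/15 probe layout with the
#' effective source one transport mean free path (1/background mu_s') inside
#' the boundary, solves the frequency-domain diffusion FEM for all 16 sources
#' and extracts the 16 x 15 amplitude/phase arrays.
#'
#' @param phantom a \linkS4class{Phantom}.
#' @param constants a \linkS4class{PhysicsConstants}.
#' @param meshSize element size (mm); default diameter/25.
#' @param mesh optionally, a prebuilt mesh of the right diameter (reused
#'   across the sample and its homogeneous calibration reference).
#' @return list with `measurements` (\linkS4class{MeasurementSet}), `mesh`,
#'   and `layout`.
#' @export
simulatePhantom <- function(phantom, constants = physicsConstants(),
                            meshSize = phantom@diameter / 25, mesh = NULL) {
  if (is.null(mesh)) mesh <- buildCircularMesh(phantom@diameter, meshSize)
  pr <- phantomProperties(phantom, mesh@nodes)
  layout <- placeProbes(phantom@diameter, sourceDepth = 1 / phantom@backgroundMuSp)
  sys <- assembleSystem(mesh, pr$muA, pr$muSp, phantom@frequency, constants, layout)
  fields <- solveForward(sys)
  m <- measureBoundary(fields, layout, mesh, phantom@frequency)
  list(measurements = m, mesh = mesh, layout = layout)
}

#' Add measurement noise to a boundary measurement set
#'
#' Models the dataset's 15% additive noise as multiplicative zero-mean
#' Gaussian noise on amplitude (relative sigma = `level`) and additive
#' Gaussian noise on phase with sigma = `level` times the per-sample phase
#' spread.  Amplitudes are clipped to stay positive.
#'
#' @param m a \linkS4class{MeasurementSet}.
#' @param level relative noise level (default 0.15).
#' @param seed optional integer seed applied locally.
#' @return a noisy \linkS4class{MeasurementSet}.
#' @export
addNoise <- function(m, level = 0.15, seed = NULL) {
  if (level < 0) stop("noise level must be >= 0")
  if (level == 0) return(m)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  amp <- m@amplitude * (1 + level * matrix(stats::rnorm(240), 16, 15))
  amp <- pmax(amp, 1e-12 * max(m@amplitude))
  sphase <- stats::sd(as.vector(m@phase))
  ph <- m@phase + level * sphase * matrix(stats::rnorm(240), 16, 15)
  ph <- ((ph + pi) %% (2 * pi)) - pi
  ph[ph <= -pi] <- pi
  new("MeasurementSet", amplitude = amp, phase = ph, frequency = m@frequency)
}

#' Normalize a measurement set into the network input representation
#'
#' Direct per-sample normalization of the simulated boundary data: channel 1
#' is the logarithmic amplitude, channel 2 the phase, each min-max scaled to
#' [0, 1] per sample.  The relative decay pattern across source-detector
#' separations survives the scaling, so the input still encodes the
#' background optical properties.
#'
#' @param m a \linkS4class{MeasurementSet}.
#' @return 16 x 15 x 2 array in [0, 1].
#' @export
normalizeMeasurements <- function(m) {
  if (any(m@amplitude <= 0)) stop("non-positive amplitude")
  out <- array(0, c(16, 15, 2))
  out[, , 1] <- log(m@amplitude)
  out[, , 2] <- m@phase
  for (ch in 1:2) {
    v <- out[, , ch]
    rg <- range(v)
    out[, , ch] <- if (diff(rg) > 0) (v - rg[1]) / diff(rg) else 0 * v
  }
  out
}

#' Calibrate measurements against a homogeneous reference
#'
#' Emulates the experimental calibration: channel 1 is the difference of
#' logarithmic amplitudes, channel 2 the difference of phases, between the
#' sample and a noise-free homogeneous reference phantom of the same diameter,
#' background properties and frequency.  Each channel is then min-max scaled
#' to [0, 1] per sample (a constant channel maps to 0).
#'
#' @param m sample \linkS4class{MeasurementSet}.
#' @param reference homogeneous-reference \linkS4class{MeasurementSet}.
#' @param rescale min-max scale the channels (default TRUE); FALSE returns the
#'   raw difference channels.
#' @return 16 x 15 x 2 array (channel 1 normalized log-amplitude, channel 2
#'   normalized phase).
#' @export
calibrateMeasurements <- function(m, reference, rescale = TRUE) {
  if (any(m@amplitude <= 0) || any(reference@amplitude <= 0))
    stop("non-positive amplitude")
  dlog <- log(m@amplitude) - log(reference@amplitude)
  dph <- m@phase - reference@phase
  out <- array(0, c(16, 15, 2))
  out[, , 1] <- dlog
  out[, , 2] <- dph
  if (rescale) for (ch in 1:2) {
    v <- out[, , ch]
    rg <- range(v)
    out[, , ch] <- if (diff(rg) > 0) (v - rg[1]) / diff(rg) else 0 * v
  }
  out
}
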