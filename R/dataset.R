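#' Generate a paired simulation dataset
#'
#' Runs the full data-generation pipeline: sample phantoms, simulate
#' noise-free boundary data by FEM, add measurement noise, calibrate against
#' the matching noise-free homogeneous reference (same mesh), rasterize the
#' ground truth, split into train/validation/test and record the per-channel
#' target normalization statistics over the training split.
#'
#' @param n number of samples (>= 20).
#' @param ratios train/validation/test fractions (default 0.85/0.10/0.05).
#' @param seed integer seed controlling every random draw.
#' @param noiseLevel relative measurement noise (default 0.15).
#' @param ranges phantom parameter ranges, see [phantomRanges()].
#' @param constants a \linkS4class{PhysicsConstants}.
#' @param meshDivisor element size is diameter/meshDivisor (default 25).
#' @param calibration "direct" (default) normalizes log-amplitude and phase
#'   per sample; "reference" first subtracts a noise-free homogeneous
#'   reference of the same background (the experimental calibration
#'   emulation, see [calibrateMeasurements()]).
#' @param verbose print progress every 100 samples.
#' @return a \linkS4class{DOTDataset}.
#' @export
generateDataset <- function(n = 10000, ratios = c(0.85, 0.10, 0.05), seed = 1,
                            noiseLevel = 0.15, ranges = phantomRanges(),
                            constants = physicsConstants(), meshDivisor = 25,
                            calibration = c("direct", "reference"),
                            verbose = FALSE) {
  calibration <- match.arg(calibration)
  if (n < 20) stop("need at least 20 samples")
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  inputs <- array(0, c(n, 16, 15, 2))
  targets <- array(0, c(n, 64, 64, 2))
  masks <- array(FALSE, c(n, 64, 64))
  phantoms <- vector("list", n)
  meta <- data.frame(diameter = numeric(n), backgroundMuA = numeric(n),
                     backgroundMuSp = numeric(n), frequency = numeric(n),
                     nInclusions = integer(n))
  for (i in seq_len(n)) {
    ph <- samplePhantom(ranges)
    sim <- simulatePhantom(ph, constants, meshSize = ph@diameter / meshDivisor)
    noisy <- addNoise(sim$measurements, noiseLevel)
    inputs[i, , , ] <- if (calibration == "direct") {
      normalizeMeasurements(noisy)
    } else {
      refPh <- new("Phantom", diameter = ph@diameter,
                   backgroundMuA = ph@backgroundMuA,
                   backgroundMuSp = ph@backgroundMuSp,
                   inclusions = list(), frequency = ph@frequency)
      ref <- simulatePhantom(refPh, constants, mesh = sim$mesh)
      calibrateMeasurements(noisy, ref$measurements)
    }
    img <- rasterizePhantom(ph)
    targets[i, , , ] <- img@values
    masks[i, , ] <- img@mask
    phantoms[[i]] <- ph
    meta[i, ] <- list(ph@diameter, ph@backgroundMuA, ph@backgroundMuSp,
                      ph@frequency, length(ph@inclusions))
    if (verbose && i %% 100 == 0) message(i, " / ", n, " samples")
  }
  split <- splitAssignment(n, ratios)
  tr <- which(split == "train")
  stats <- list(
    targetMin = c(min(targets[tr, , , 1]), min(targets[tr, , , 2])),
    targetMax = c(max(targets[tr, , , 1]), max(targets[tr, , , 2])))
  new("DOTDataset", inputs = inputs, targets = targets, masks = masks,
      meta = meta, phantoms = phantoms, split = split, stats = stats,
      seed = as.integer(seed))
}

#' Deterministic train/validation/test split sizes and assignment
#'
#' Sizes are round(n * ratio) for train and validation with the remainder as
#' test, so n = 10000 at 0.85/0.10/0.05 gives 8500/1000/500.  Samples are
#' assigned in generation order (they are i.i.d.).
#'
#' @param n number of samples.
#' @param ratios length-3 fractions summing to 1.
#' @return factor of length n with levels train/val/test.
#' @export
splitAssignment <- function(n, ratios = c(0.85, 0.10, 0.05)) {
  nTrain <- round(n * ratios[1])
  nVal <- round(n * ratios[2])
  nTest <- n - nTrain - nVal
  if (min(nTrain, nVal, nTest) < 1) stop("split produces an empty partition")
  factor(rep(c("train", "val", "test"), c(nTrain, nVal, nTest)),
         levels = c("train", "val", "test"))
}

#' Normalize property images with dataset statistics
#'
#' Per-channel global min-max normalization using the statistics recorded
#' over the training split, mapping training targets into [0, 1].
#'
#' @param targets array with the last dimension indexing the 2 channels
#'   (e.g. 64 x 64 x 2 or N x 64 x 64 x 2).
#' @param stats the `stats` slot of a \linkS4class{DOTDataset}.
#' @return array of the same shape on the normalized scale.
#' @export
normalizeTargets <- function(targets, stats) {
  d <- dim(targets)
  nd <- length(d)
  out <- targets
  for (ch in 1:2) {
    sc <- stats$targetMax[ch] - stats$targetMin[ch]
    idx <- slice.index(targets, nd) == ch
    out[idx] <- (targets[idx] - stats$targetMin[ch]) / sc
  }
  out
}

#' Invert [normalizeTargets()]
#' @param normalized array on the normalized scale.
#' @param stats dataset statistics.
#' @return array in physical units (1/mm).
#' @export
denormalizeTargets <- function(normalized, stats) {
  d <- dim(normalized)
  nd <- length(d)
  out <- normalized
  for (ch in 1:2) {
    sc <- stats$targetMax[ch] - stats$targetMin[ch]
    idx <- slice.index(normalized, nd) == ch
    out[idx] <- normalized[idx] * sc + stats$targetMin[ch]
  }
  out
}

#' Number of samples in a dataset
#' @param ds a \linkS4class{DOTDataset}.
#' @return integer sample count.
#' @export
nSamples <- function(ds) dim(ds@inputs)[1]

#' Indices of a split partition
#' @param ds a \linkS4class{DOTDataset}.
#' @param which one of "train", "val", "test".
#' @return integer vector of sample indices.
#' @export
splitIndices <- function(ds, which = c("train", "val", "test")) {
  which <- match.arg(which)
  base::which(ds@split == which)
}

#' Write a dataset container to disk
#'
#' Plain directory layout: one `.rds` file per array plus a JSON manifest
#' holding the seed, split sizes and normalization statistics.
#'
#' @param ds a \linkS4class{DOTDataset}.
#' @param dir directory to create.
#' @return invisibly, `dir`.
#' @export
writeDataset <- function(ds, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create dataset directory: ", dir)
  tryCatch({
    saveRDS(ds@inputs, file.path(dir, "inputs.rds"))
    saveRDS(ds@targets, file.path(dir, "targets.rds"))
    saveRDS(ds@masks, file.path(dir, "masks.rds"))
    saveRDS(ds@phantoms, file.path(dir, "phantoms.rds"))
    saveRDS(ds@meta, file.path(dir, "meta.rds"))
    manifest <- list(seed = ds@seed, split = as.character(ds@split),
                     stats = ds@stats, n = nSamples(ds))
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }, error = function(e) stop("dataset write failed at ", dir, ": ",
                              conditionMessage(e)))
  invisible(dir)
}

#' Read a dataset container written by [writeDataset()]
#' @param dir dataset directory.
#' @return a \linkS4class{DOTDataset}.
#' @export
readDataset <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"), simplifyVector = TRUE)
  new("DOTDataset",
      inputs = readRDS(file.path(dir, "inputs.rds")),
      targets = readRDS(file.path(dir, "targets.rds")),
      masks = readRDS(file.path(dir, "masks.rds")),
      phantoms = readRDS(file.path(dir, "phantoms.rds")),
      meta = readRDS(file.path(dir, "meta.rds")),
      split = factor(man$split, levels = c("train", "val", "test")),
      stats = list(targetMin = man$stats$targetMin,
                   targetMax = man$stats$targetMax),
      seed = as.integer(man$seed))
}

# inputs of given sample indices as a 480 x B matrix (network input layout)
inputMatrix <- function(ds, idx) {
  m <- matrix(0, 480, length(idx))
  for (k in seq_along(idx)) m[, k] <- as.vector(ds@inputs[idx[k], , , ])
  m
}

# normalized targets of given samples as a 4096 x 2 x B array
targetArray <- function(ds, idx) {
  out <- array(0, c(4096, 2, length(idx)))
  for (k in seq_along(idx)) {
    y <- normalizeTargets(ds@targets[idx[k], , , ], ds@stats)
    out[, 1, k] <- as.vector(y[, , 1])
    out[, 2, k] <- as.vector(y[, , 2])
  }
  out
}
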