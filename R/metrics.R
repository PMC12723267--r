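#' Mean squared error between two images
#'
#' @param image,reference equal-shaped numeric arrays (typically on the
#'   normalized [0, 1] scale).
#' @return mean squared pixel difference.
#' @export
imageMSE <- function(image, reference) {
  if (!all(dim(image) == dim(reference))) stop("shape mismatch")
  mean((image - reference)^2)
}

#' Peak signal-to-noise ratio in dB
#'
#' \eqn{10\log_{10}(\mathrm{max}^2/\mathrm{MSE})} with the peak value
#' normalized to 1, so inputs must be on the normalized scale.  A zero MSE is
#' reported as `Inf`.
#'
#' @param image,reference normalized images.
#' @return PSNR in dB.
#' @examples
#' imagePSNR(matrix(0.1, 8, 8), matrix(0, 8, 8))  # MSE 0.01 -> 20 dB
#' @export
imagePSNR <- function(image, reference) {
  mse <- imageMSE(image, reference)
  if (mse == 0) return(Inf)
  10 * log10(1 / mse)
}

gaussianKernel1D <- function(size = 11, sigma = 1.5) {
  x <- seq_len(size) - (size + 1) / 2
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable valid-region filtering with a 1-D kernel
filterValid <- function(img, k) {
  n <- length(k)
  out <- apply(img, 2, function(col) as.numeric(stats::filter(col, k, sides = 2)))
  out <- t(apply(out, 1, function(row) as.numeric(stats::filter(row, k, sides = 2))))
  half <- (n - 1) / 2
  idx <- (half + 1):(nrow(img) - half)
  out[idx, idx, drop = FALSE]
}

#' Structural similarity index
#'
#' Local-window SSIM with an 11 x 11 Gaussian window (sigma 1.5) averaged over
#' the image.  The stabilizing constants default to the standard
#' \eqn{C_1 = (0.01 L)^2}, \eqn{C_2 = (0.03 L)^2} with dynamic range L = 1;
#' other values can be supplied.  Images smaller than the window fall back to
#' global statistics (a single window covering the whole image).
#'
#' @param image,reference normalized images (matrices).
#' @param C1,C2 stabilizing constants.
#' @param windowSize,sigma Gaussian window parameters.
#' @return SSIM value in [-1, 1].
#' @export
imageSSIM <- function(image, reference, C1 = 0.01^2, C2 = 0.03^2,
                      windowSize = 11, sigma = 1.5) {
  if (!all(dim(image) == dim(reference))) stop("shape mismatch")
  x <- as.matrix(image); y <- as.matrix(reference)
  if (min(dim(x)) < windowSize) {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
           ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  k <- gaussianKernel1D(windowSize, sigma)
  mx <- filterValid(x, k); my <- filterValid(y, k)
  vx <- filterValid(x * x, k) - mx^2
  vy <- filterValid(y * y, k) - my^2
  cxy <- filterValid(x * y, k) - mx * my
  s <- ((2 * mx * my + C1) * (2 * cxy + C2)) /
       ((mx^2 + my^2 + C1) * (vx + vy + C2))
  mean(s)
}

# inclusion-zone pixel masks of a phantom on the 64 x 64 raster
inclusionZones <- function(phantom) {
  px <- pixelCenters(phantom@diameter)
  lapply(phantom@inclusions, function(inc) {
    matrix((px$grid[, 1] - inc@center[1])^2 +
           (px$grid[, 2] - inc@center[2])^2 <= inc@radius^2, 64, 64)
  })
}

#' Contrast resolution of a reconstruction
#'
#' The raw index is the ratio of (mean of per-zone maxima) / (minimum over
#' the in-mask background) between reconstruction and original; values above
#' 1 (overshoot) are folded back as 2 - r0.
#'
#' @param recon,original 64 x 64 matrices of one property channel.
#' @param zones list of 64 x 64 logical inclusion masks (from the generating
#'   phantom).
#' @param mask 64 x 64 logical inside-disk mask.
#' @return list with `r0` (raw ratio) and `rContrast` (folded index).
#' @export
contrastResolution <- function(recon, original, zones, mask) {
  if (!length(zones)) stop("no inclusion zones")
  if (any(vapply(zones, sum, 0) == 0)) stop("empty inclusion zone")
  back <- mask & !Reduce(`|`, zones)
  ratio <- function(img) {
    mean(vapply(zones, function(z) max(img[z]), 0)) / min(img[back])
  }
  r0 <- ratio(recon) / ratio(original)
  # fold overshoot back (2 - r0); an overshoot beyond 2x has no meaningful
  # resolution left, so the folded index is floored at 0
  list(r0 = r0, rContrast = max(if (r0 > 1) 2 - r0 else r0, 0))
}

#' Size resolution of a reconstruction
#'
#' The raw index compares the RMSE between reconstruction and original over
#' the inclusion-zone pixels to the RMSE between the original and the
#' homogeneous baseline over the same pixels:
#' r0 = 1 - RMSE(recon, orig)/RMSE(orig, baseline), clipped to [0, 1].  The
#' composed index combines it with the contrast resolution; the
#' table-consistent composition is the geometric mean (the plain product is
#' available via `form`).
#'
#' @param recon,original,baseline 64 x 64 matrices (baseline = homogeneous
#'   background image).
#' @param zones list of inclusion masks.
#' @param rContrast the folded contrast-resolution index of the same image.
#' @param form "geometric" (default) or "product".
#' @return list with `r0Size` and `rSize`.
#' @export
sizeResolution <- function(recon, original, baseline, zones, rContrast,
                           form = c("geometric", "product")) {
  form <- match.arg(form)
  zone <- Reduce(`|`, zones)
  if (!any(zone)) stop("empty inclusion zone")
  num <- sqrt(mean((recon[zone] - original[zone])^2))
  den <- sqrt(mean((original[zone] - baseline[zone])^2))
  if (den == 0) stop("original equals baseline inside the zones")
  r0 <- min(max(1 - num / den, 0), 1)
  rSize <- if (form == "geometric") sqrt(r0 * rContrast) else r0 * rContrast
  list(r0Size = r0, rSize = rSize)
}

#' Contrast-size-detail resolution index
#'
#' Combines the contrast- and size-resolution indices; the table-consistent
#' composition is the geometric mean \eqn{\sqrt{R_{cont} R_{size}}} (the
#' plain product is available via `form`).
#'
#' @param rContrast,rSize component indices in [0, 1].
#' @param form "geometric" (default) or "product".
#' @return the combined index.
#' @examples
#' csdResolution(0.94, 0.82)  # 0.88
#' @export
csdResolution <- function(rContrast, rSize, form = c("geometric", "product")) {
  form <- match.arg(form)
  if (form == "geometric") sqrt(rContrast * rSize) else rContrast * rSize
}

#' Full resolution report for a reconstructed phantom
#'
#' Evaluates contrast, size and contrast-size-detail resolution per property
#' channel against the rasterized ground truth, using the generating
#' phantom's inclusion disks as zones and its homogeneous background as
#' baseline.
#'
#' @param recon 64 x 64 x 2 reconstructed property array (1/mm).
#' @param phantom the generating \linkS4class{Phantom}.
#' @param form composition form, see [csdResolution()].
#' @return data.frame with one row per channel and columns rContrast, r0Size,
#'   rSize, rCSD.
#' @export
resolutionReport <- function(recon, phantom, form = c("geometric", "product")) {
  form <- match.arg(form)
  truth <- rasterizePhantom(phantom)
  zones <- inclusionZones(phantom)
  bg <- c(phantom@backgroundMuA, phantom@backgroundMuSp)
  out <- data.frame(channel = c("muA", "muSp"), rContrast = NA_real_,
                    r0Size = NA_real_, rSize = NA_real_, rCSD = NA_real_)
  for (ch in 1:2) {
    cr <- contrastResolution(recon[, , ch], truth@values[, , ch], zones,
                             truth@mask)
    sr <- sizeResolution(recon[, , ch], truth@values[, , ch],
                         matrix(bg[ch], 64, 64), zones, cr$rContrast, form)
    out$rContrast[ch] <- cr$rContrast
    out$r0Size[ch] <- sr$r0Size
    out$rSize[ch] <- sr$rSize
    out$rCSD[ch] <- csdResolution(cr$rContrast, sr$rSize, form)
  }
  out
}

#' Histogram and entropy diagnostics of channel attention
#'
#' Histograms the activation values of feature-map stacks before and after
#' the channel attention block (256 bins over each observed range) and
#' reports the Shannon entropy of the normalized histograms in bits.  A
#' constant map has zero entropy; a uniform 256-bin histogram has 8 bits.
#'
#' @param before,after numeric arrays of activations (any shape).
#' @param bins number of histogram bins (default 256).
#' @return list with `histBefore`, `histAfter` (counts + breaks),
#'   `entropyBefore`, `entropyAfter` in bits.
#' @export
attentionDiagnostics <- function(before, after, bins = 256) {
  if (!length(before) || !length(after)) stop("empty feature maps")
  hist1 <- function(x) {
    rg <- range(x)
    if (diff(rg) == 0) {
      counts <- c(length(x), rep(0, bins - 1))
      breaks <- seq(rg[1] - 0.5, rg[1] + 0.5, length.out = bins + 1)
    } else {
      breaks <- seq(rg[1], rg[2], length.out = bins + 1)
      cuts <- findInterval(x, breaks, rightmost.closed = TRUE,
                           all.inside = TRUE)
      counts <- tabulate(cuts, nbins = bins)
    }
    list(counts = counts, breaks = breaks)
  }
  ent <- function(h) {
    p <- h$counts / sum(h$counts)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  hb <- hist1(as.numeric(before)); ha <- hist1(as.numeric(after))
  list(histBefore = hb, histAfter = ha,
       entropyBefore = ent(hb), entropyAfter = ent(ha))
}

#' Extract pre/post channel-attention feature maps of a model
#'
#' Runs the network forward on calibrated inputs and returns the feature-map
#' stacks entering and leaving the channel attention block (only defined for
#' variants with a CAB).
#'
#' @param model a trained \linkS4class{CAFNetModel} with a CAB.
#' @param inputs 480 x B matrix or N x 16 x 15 x 2 array of inputs.
#' @return list with `before` and `after` arrays (4096 x C x B) and the
#'   attention `weights` (C x B).
#' @export
cabFeatureMaps <- function(model, inputs) {
  if (!model@config@variant %in% c("full", "no_feb"))
    stop("model variant has no channel attention block")
  X <- if (is.matrix(inputs)) inputs else {
    if (length(dim(inputs)) == 3L) inputs <- array(inputs, c(1L, dim(inputs)))
    t(apply(inputs, 1, as.vector))
  }
  if (nrow(X) != 480L) X <- t(X)
  fw <- .cafnet_pass(model@params, X, array(0, c(0, 0, 0)), c(0.5, 0.5),
                     model@config@variant, model@config@nFusionBlocks,
                     FALSE, FALSE, TRUE)
  list(before = fw$preCAB, after = fw$postCAB, weights = fw$attWeights)
}

#' k-fold cross-validation of CAFNet training
#'
#' Partitions the dataset samples into k disjoint folds with a fixed seed,
#' trains on k-1 folds and evaluates the mean (normalized, equally weighted)
#' MSE on the held-out fold.
#'
#' @param ds a \linkS4class{DOTDataset}.
#' @param k number of folds (default 5).
#' @param config a \linkS4class{CAFNetConfig}.
#' @param tc a \linkS4class{TrainConfig} (epochs scaled to taste).
#' @param seed fold-assignment seed.
#' @return list with `perFold` MSE values, `mean` and `sd`.
#' @export
crossValidate <- function(ds, k = 5, config = cafnetConfig(),
                          tc = trainConfig(), seed = 1) {
  if (k < 2) stop("k must be >= 2")
  n <- nSamples(ds)
  if (n < k * tc@batchSize)
    warning("folds smaller than the batch size")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  fold <- sample(rep(seq_len(k), length.out = n))
  perFold <- numeric(k)
  for (f in seq_len(k)) {
    te <- which(fold == f)
    tr <- which(fold != f)
    if (length(te) < 1 || length(tr) < tc@batchSize)
      stop("fold too small for the batch size")
    dsf <- ds
    lev <- rep("train", n)
    lev[te] <- "test"
    # carve a small validation share out of the training part
    nv <- max(1L, floor(0.1 * length(tr)))
    lev[tr[seq_len(nv)]] <- "val"
    dsf@split <- factor(lev, levels = c("train", "val", "test"))
    model <- buildCAFNet(config, seed = seed + f)
    model <- trainCAFNet(model, dsf, tc)
    Xte <- inputMatrix(dsf, te)
    Yte <- targetArray(dsf, te)
    perFold[f] <- evalLoss(model@params, config, Xte, Yte, c(0.5, 0.5))
  }
  list(perFold = perFold, mean = mean(perFold), sd = stats::sd(perFold))
}
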