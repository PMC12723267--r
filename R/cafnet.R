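#' Build a CAFNet reconstruction model
#'
#' Assembles the channel attention fusion network: an AUTOMAP-style learned
#' domain transform (two fully connected tanh layers, 480 -> hidden -> 4096,
#' reshaped to 64 x 64), a feature extraction block (two conv+BN+ReLU stages),
#' a stack of multi-scale fusion blocks (1x1/3x3/5x5 FEB branches plus a
#' max-pooled branch refined by a 1x1 conv, concatenated), a channel attention
#' block, and a final 1x1 convolution producing the two 64 x 64 property maps.
#' Ablation variants drop individual modules:
#' \describe{
#'   \item{full}{AUTOMAP + FEB + fusion blocks + CAB + output head}
#'   \item{feb_only}{AUTOMAP + FEB + output head}
#'   \item{feb_fusion, no_cab}{AUTOMAP + FEB + fusion blocks + output head}
#'   \item{no_feb}{AUTOMAP + fusion blocks + CAB + output head}
#' }
#'
#' @param config a \linkS4class{CAFNetConfig}.
#' @param seed integer seed for (Glorot-uniform) weight initialization.
#' @return a \linkS4class{CAFNetModel}.
#' @examples
#' m <- buildCAFNet(cafnetConfig(automapWidth = 64L), seed = 1)
#' countParameters(m)
#' @export
buildCAFNet <- function(config = cafnetConfig(), seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  v <- config@variant
  hasFEB <- v != "no_feb"
  hasFusion <- !v %in% "feb_only"
  hasCAB <- v %in% c("full", "no_feb")
  p <- list(fc1 = initDense(480L, config@automapWidth),
            fc2 = initDense(config@automapWidth, 4096L))
  cin <- 1L
  if (hasFEB) {
    p$feb0 <- initFEBParams(cin, config@febFilters, config@febKernel)
    cin <- config@febFilters
  }
  if (hasFusion) for (i in seq_len(config@nFusionBlocks)) {
    p[[paste0("fusion", i)]] <- initFusionParams(cin, config)
    cin <- fusionOutChannels(config)
  }
  if (hasCAB) p$cab <- initCAB(cin, config@cabReduction)
  p$out <- initConv(cin, 2L, 1L)
  new("CAFNetModel", config = config, params = p, history = list())
}

#' Construct a CAFNet architecture configuration
#'
#' @param automapWidth hidden width of the AUTOMAP transform (default 1024).
#' @param febFilters conv filters per FEB layer (default 8).
#' @param febKernel kernel of the first FEB (default 3).
#' @param fusionKernels three fusion branch kernels (default 1, 3, 5).
#' @param fusionRefineFilters pooled-branch 1x1 filters (default 8).
#' @param nFusionBlocks stacked fusion blocks (default 2).
#' @param cabReduction attention bottleneck ratio (default 4).
#' @param variant architecture variant (see [buildCAFNet()]).
#' @return a \linkS4class{CAFNetConfig}.
#' @export
cafnetConfig <- function(automapWidth = 1024L, febFilters = 8L, febKernel = 3L,
                         fusionKernels = c(1L, 3L, 5L),
                         fusionRefineFilters = 8L, nFusionBlocks = 2L,
                         cabReduction = 4L, variant = "full") {
  new("CAFNetConfig", automapWidth = as.integer(automapWidth),
      febFilters = as.integer(febFilters), febKernel = as.integer(febKernel),
      fusionKernels = as.integer(fusionKernels),
      fusionRefineFilters = as.integer(fusionRefineFilters),
      nFusionBlocks = as.integer(nFusionBlocks),
      cabReduction = as.integer(cabReduction), variant = variant)
}

# full network forward pass; X is 480 x B
cafnetFw <- function(params, cfg, X, training = FALSE) {
  v <- cfg@variant
  B <- ncol(X)
  d1 <- denseFw(params$fc1, X, "tanh")
  d2 <- denseFw(params$fc2, d1$y, "tanh")
  x <- array(d2$y, c(4096L, 1L, B))
  caches <- list(d1 = d1$cache, d2 = d2$cache)
  stats <- list()
  if (v != "no_feb") {
    r <- febFw(params$feb0, x, training)
    x <- r$y; caches$feb0 <- r$cache; stats$feb0 <- r$stats
  }
  if (!v %in% "feb_only") for (i in seq_len(cfg@nFusionBlocks)) {
    nm <- paste0("fusion", i)
    r <- fusionFw(params[[nm]], x, training)
    x <- r$y; caches[[nm]] <- r$cache; stats[[nm]] <- r$stats
  }
  attWeights <- NULL
  if (v %in% c("full", "no_feb")) {
    caches$preCAB <- x
    r <- cabFw(params$cab, x)
    x <- r$y; caches$cab <- r$cache; attWeights <- r$weights
    caches$postCAB <- x
  }
  o <- convFw(params$out, x)
  caches$out <- o$cache
  list(y = o$y, caches = caches, stats = stats, attWeights = attWeights)
}

cafnetBw <- function(params, cfg, caches, dOut) {
  v <- cfg@variant
  g <- list()
  r <- convBw(params$out, caches$out, dOut); g$out <- r$grads; dx <- r$dx
  if (v %in% c("full", "no_feb")) {
    r <- cabBw(params$cab, caches$cab, dx); g$cab <- r$grads; dx <- r$dx
  }
  if (!v %in% "feb_only") for (i in rev(seq_len(cfg@nFusionBlocks))) {
    nm <- paste0("fusion", i)
    r <- fusionBw(params[[nm]], caches[[nm]], dx)
    g[[nm]] <- r$grads; dx <- r$dx
  }
  if (v != "no_feb") {
    r <- febBw(params$feb0, caches$feb0, dx); g$feb0 <- r$grads; dx <- r$dx
  }
  dflat <- matrix(dx, 4096L, dim(dx)[3])
  r <- denseBw(params$fc2, caches$d2, dflat); g$fc2 <- r$grads
  r2 <- denseBw(params$fc1, caches$d1, r$dx); g$fc1 <- r2$grads
  g
}

.trainableKeys <- c("W", "b", "gamma", "beta", "W1", "b1", "W2", "b2")

walkCount <- function(p) {
  if (!is.list(p)) return(0)
  tot <- 0
  for (nm in names(p)) {
    el <- p[[nm]]
    if (is.list(el)) tot <- tot + walkCount(el)
    else if (nm %in% .trainableKeys) tot <- tot + length(el)
  }
  tot
}

#' Count trainable parameters
#'
#' Sums the element counts of all trainable leaves (weights, biases,
#' batch-norm scales/shifts; running statistics excluded).
#'
#' @param model a \linkS4class{CAFNetModel} or a raw layer parameter list.
#' @return integer parameter count.
#' @examples
#' countParameters(list(fc = initDense(480L, 4096L)))  # 1970176
#' @export
countParameters <- function(model) {
  p <- if (is(model, "CAFNetModel")) model@params else model
  as.integer(walkCount(p))
}

# ---- optimizer -------------------------------------------------------------

adamInit <- function(params) {
  walk <- function(p) {
    out <- list()
    for (nm in names(p)) {
      el <- p[[nm]]
      if (is.list(el)) out[[nm]] <- walk(el)
      else if (nm %in% .trainableKeys)
        out[[nm]] <- list(m = 0 * el, v = 0 * el)
    }
    out
  }
  walk(params)
}

adamStep <- function(params, grads, state, lr, b1, b2, eps, t) {
  corr <- lr * sqrt(1 - b2^t) / (1 - b1^t)
  walk <- function(p, g, s) {
    for (nm in names(g)) {
      if (is.list(g[[nm]]) && !all(c("m", "v") %in% names(s[[nm]]))) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        p[[nm]] <- r$p; s[[nm]] <- r$s
      } else if (nm %in% .trainableKeys) {
        st <- s[[nm]]
        st$m <- b1 * st$m + (1 - b1) * g[[nm]]
        st$v <- b2 * st$v + (1 - b2) * g[[nm]]^2
        p[[nm]] <- p[[nm]] - corr * st$m / (sqrt(st$v) + eps)
        s[[nm]] <- st
      }
    }
    list(p = p, s = s)
  }
  walk(params, grads, state)
}

applyBNStats <- function(params, stats) {
  for (nm in names(stats)) {
    el <- stats[[nm]]
    if (all(c("rmean", "rvar") %in% names(el))) {
      params[[nm]]$rmean <- el$rmean
      params[[nm]]$rvar <- el$rvar
    } else {
      params[[nm]] <- applyBNStats(params[[nm]], el)
    }
  }
  params
}

# weighted two-channel MSE loss and its gradient on (4096, 2, B) arrays
weightedMSE <- function(yhat, y, weights) {
  B <- dim(y)[3]
  n <- 4096 * B
  d <- yhat - y
  l1 <- sum(d[, 1, ]^2) / n
  l2 <- sum(d[, 2, ]^2) / n
  g <- d
  g[, 1, ] <- 2 * weights[1] * d[, 1, ] / n
  g[, 2, ] <- 2 * weights[2] * d[, 2, ] / n
  list(loss = weights[1] * l1 + weights[2] * l2, grad = g,
       channelMSE = c(l1, l2))
}

#' Construct a training configuration
#'
#' @param learningRate Adam step size (default 0.001).
#' @param beta1 Adam first-moment decay (default 0.5).
#' @param beta2 Adam second-moment decay (default 0.999).
#' @param batchSize minibatch size (default 64).
#' @param epochs training epochs (default 100).
#' @param lossWeights per-channel MSE weights (default 0.5/0.5).
#' @param seed RNG seed for shuffling.
#' @return a \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(learningRate = 1e-3, beta1 = 0.5, beta2 = 0.999,
                        batchSize = 64L, epochs = 100L,
                        lossWeights = c(0.5, 0.5), seed = 1L) {
  new("TrainConfig", learningRate = learningRate, beta1 = beta1,
      beta2 = beta2, batchSize = as.integer(batchSize),
      epochs = as.integer(epochs), lossWeights = lossWeights,
      seed = as.integer(seed))
}

#' Train a CAFNet model on a dataset
#'
#' Minimizes the weighted sum of per-channel MSE between the network output
#' and the min-max-normalized ground-truth property images, with Adam
#' (learning rate 0.001, beta1 = 0.5) on shuffled minibatches.  Targets are
#' normalized with the dataset's training-split statistics; per-epoch train
#' and validation losses are recorded.
#'
#' @param model a \linkS4class{CAFNetModel}.
#' @param ds a \linkS4class{DOTDataset} with train and validation splits.
#' @param tc a \linkS4class{TrainConfig}.
#' @param snapshotEpochs integer epochs at which to store a copy of the
#'   parameters (e.g. for evaluating a shorter training budget).
#' @param verbose print the loss every epoch.
#' @return the trained \linkS4class{CAFNetModel}; `history` holds `train`,
#'   `val` (per-epoch losses) and `snapshots` (named list of parameter sets).
#' @export
trainCAFNet <- function(model, ds, tc = trainConfig(),
                        snapshotEpochs = integer(0), verbose = FALSE) {
  idxTr <- splitIndices(ds, "train")
  idxVal <- splitIndices(ds, "val")
  if (!length(idxTr)) stop("empty training split")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(tc@seed)
  X <- inputMatrix(ds, idxTr)
  Y <- targetArray(ds, idxTr)
  Xv <- if (length(idxVal)) inputMatrix(ds, idxVal) else matrix(0, 480, 0)
  Yv <- if (length(idxVal)) targetArray(ds, idxVal) else array(0, c(4096, 2, 0))
  cfg <- model@config
  nTr <- length(idxTr)
  perms <- vapply(seq_len(tc@epochs), function(i) sample.int(nTr),
                  integer(nTr))
  r <- .cafnet_train(model@params, X, Y, Xv, Yv, tc@lossWeights,
                     cfg@variant, cfg@nFusionBlocks, perms, tc@batchSize,
                     tc@learningRate, tc@beta1, tc@beta2,
                     as.integer(snapshotEpochs), verbose)
  hist <- list(train = as.numeric(r$train), val = as.numeric(r$val),
               snapshots = r$snapshots)
  new("CAFNetModel", config = cfg, params = r$params, history = hist)
}

evalLoss <- function(params, cfg, X, Y, weights, batch = 64L) {
  n <- ncol(X)
  tot <- 0
  for (s0 in seq(1L, n, by = batch)) {
    bi <- s0:min(s0 + batch - 1L, n)
    fw <- .cafnet_pass(params, X[, bi, drop = FALSE],
                       Y[, , bi, drop = FALSE], weights,
                       cfg@variant, cfg@nFusionBlocks, FALSE, FALSE, FALSE)
    tot <- tot + fw$loss * length(bi)
  }
  tot / n
}

#' Predict property images from calibrated boundary inputs
#'
#' Runs the network in inference mode (batch-norm running statistics), clamps
#' the normalized output to [0, 1] and inverts the per-channel min-max target
#' normalization back to physical units.
#'
#' @param model a trained \linkS4class{CAFNetModel}.
#' @param inputs N x 16 x 15 x 2 array (or 480 x N matrix) of calibrated inputs.
#' @param stats dataset normalization statistics (`stats` slot); required.
#' @param params optional parameter set overriding the model's (e.g. a
#'   training snapshot).
#' @return N x 64 x 64 x 2 array of property images in 1/mm.
#' @export
predictProperties <- function(model, inputs, stats, params = NULL) {
  if (is.null(stats)) stop("normalization statistics are required")
  if (is.null(params)) params <- model@params
  X <- if (is.matrix(inputs)) inputs
       else {
         if (length(dim(inputs)) == 3L) inputs <- array(inputs, c(1L, dim(inputs)))
         t(apply(inputs, 1, as.vector))
       }
  if (nrow(X) != 480L && ncol(X) != 480L) stop("inputs must have 480 values per sample")
  if (nrow(X) != 480L) X <- t(X)
  n <- ncol(X)
  out <- array(0, c(n, 64, 64, 2))
  for (s0 in seq(1L, n, by = 64L)) {
    bi <- s0:min(s0 + 63L, n)
    fw <- .cafnet_pass(params, X[, bi, drop = FALSE], array(0, c(0, 0, 0)),
                       c(0.5, 0.5), model@config@variant,
                       model@config@nFusionBlocks, FALSE, FALSE, FALSE)
    yn <- pmin(pmax(fw$y, 0), 1)
    for (k in seq_along(bi)) {
      img <- array(0, c(64, 64, 2))
      img[, , 1] <- matrix(yn[, 1, k], 64, 64)
      img[, , 2] <- matrix(yn[, 2, k], 64, 64)
      out[bi[k], , , ] <- denormalizeTargets(img, stats)
    }
  }
  out
}

#' Apply the learned AUTOMAP domain transform of a model
#'
#' Maps one 16 x 15 x 2 signal-domain input through the two fully connected
#' tanh layers to its 64 x 64 x 1 image-domain representation.
#'
#' @param model a \linkS4class{CAFNetModel}.
#' @param input 16 x 15 x 2 array (or length-480 vector).
#' @return 64 x 64 x 1 array.
#' @export
automapTransform <- function(model, input) {
  x <- matrix(as.vector(input), 480L, 1L)
  d1 <- denseFw(model@params$fc1, x, "tanh")
  d2 <- denseFw(model@params$fc2, d1$y, "tanh")
  array(d2$y, c(64L, 64L, 1L))
}

#' Apply a channel attention block to a feature map
#'
#' Computes the global-average and global-max channel summaries, combines
#' them additively, passes them through the shared bottleneck MLP (ReLU
#' between layers, sigmoid outside) and rescales each channel by its
#' attention weight.  With a zero-initialized MLP every weight is
#' sigmoid(0) = 0.5.
#'
#' @param x feature map, 64 x 64 x C array (or HW x C matrix).
#' @param params CAB parameter list from `initCAB`; NULL for a
#'   zero-initialized MLP.
#' @param reduction bottleneck reduction ratio (used when params is NULL).
#' @return list with `output` (same shape as `x`), `weights` (length C),
#'   `zavg` and `zmax`.
#' @examples
#' r <- channelAttention(array(rnorm(64 * 64 * 8), c(64, 64, 8)))
#' r$weights  # all 0.5 for the zero MLP
#' @export
channelAttention <- function(x, params = NULL, reduction = 4) {
  d <- dim(x)
  cube <- if (length(d) == 3L) array(x, c(d[1] * d[2], d[3], 1L))
          else array(x, c(d[1], d[2], 1L))
  C <- dim(cube)[2]
  if (is.null(params)) params <- initCAB(C, reduction, zero = TRUE)
  r <- cabFw(params, cube)
  list(output = array(r$y, d), weights = as.numeric(r$weights),
       zavg = as.numeric(colMeans(cube, dims = 1)),
       zmax = as.numeric(.gmp_fw(cube)$z))
}

#' Apply a feature extraction block
#'
#' Two conv(+batch-norm)+ReLU stages with same padding; spatial size is
#' preserved and the channel count becomes the block's filter count.
#'
#' @param x feature map, 64 x 64 x C array.
#' @param params FEB parameters from `initFEB`.
#' @param training use batch statistics (TRUE) or running statistics.
#' @return 64 x 64 x filters array.
#' @export
febBlock <- function(x, params, training = FALSE) {
  d <- dim(x)
  cube <- array(x, c(d[1] * d[2], d[3], 1L))
  r <- febFw(params, cube, training)
  array(r$y, c(d[1], d[2], dim(r$y)[2]))
}

#' Initialize feature-extraction-block parameters
#' @param cin input channels.
#' @param filters conv filters (default 8).
#' @param k kernel size (default 3).
#' @param zero zero-initialize the weights.
#' @return parameter list for [febBlock()].
#' @export
initFEB <- function(cin, filters = 8L, k = 3L, zero = FALSE)
  initFEBParams(as.integer(cin), as.integer(filters), as.integer(k), zero)

#' Apply a multi-scale fusion block
#'
#' Concatenates, along channels, three FEB branches with 1x1, 3x3 and 5x5
#' kernels and a 3x3 stride-1 max-pooled branch refined by a 1x1 convolution
#' with ReLU, in this fixed order.
#'
#' @param x feature map, 64 x 64 x C array.
#' @param params fusion parameters from [initFusion()].
#' @param training batch vs running statistics for the FEB batch norms.
#' @return 64 x 64 x (3 filters + refine filters) array.
#' @export
fusionBlock <- function(x, params, training = FALSE) {
  d <- dim(x)
  cube <- array(x, c(d[1] * d[2], d[3], 1L))
  r <- fusionFw(params, cube, training)
  array(r$y, c(d[1], d[2], dim(r$y)[2]))
}

#' Initialize fusion-block parameters
#' @param cin input channels.
#' @param config a \linkS4class{CAFNetConfig} providing filter counts/kernels.
#' @param zero zero-initialize the conv weights.
#' @return parameter list for [fusionBlock()].
#' @export
initFusion <- function(cin, config = cafnetConfig(), zero = FALSE)
  initFusionParams(as.integer(cin), config, zero)
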