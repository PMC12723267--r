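# Layer primitives for the reconstruction network.  Feature maps are cubes
# (4096 pixels, channels, batch); dense activations are matrices
# (features x batch).  Every layer has a forward returning (y, cache) and a
# backward returning (dx, grads); parameters live in flat named lists so the
# optimizer can walk them generically.

glorotInit <- function(nin, nout, fanIn = nin, fanOut = nout) {
  l <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(nin * nout, -l, l), nin, nout)
}

initDense <- function(nin, nout, zero = FALSE) {
  list(W = if (zero) matrix(0, nin, nout) else glorotInit(nin, nout),
       b = numeric(nout))
}

# conv weight layout: (cin * k^2) x cout, rows ordered channel-major to match
# the im2col kernel (row index = (c-1)*k^2 + t)
initConv <- function(cin, cout, k, zero = FALSE) {
  nin <- cin * k * k
  list(W = if (zero) matrix(0, nin, cout)
       else glorotInit(nin, cout, fanIn = nin, fanOut = cout * k * k),
       b = numeric(cout), k = k)
}

initBN <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c),
       rmean = numeric(c), rvar = rep(1, c))
}

initCAB <- function(c, ratio, zero = FALSE) {
  if (c %% ratio != 0) stop("reduction ratio must divide the channel count")
  h <- c %/% ratio
  list(W1 = if (zero) matrix(0, c, h) else glorotInit(c, h),
       b1 = numeric(h),
       W2 = if (zero) matrix(0, h, c) else glorotInit(h, c),
       b2 = numeric(c))
}

denseFw <- function(p, x, act = c("linear", "tanh")) {
  act <- match.arg(act)
  y <- crossprod(p$W, x) + p$b
  if (act == "tanh") y <- tanh(y)
  list(y = y, cache = list(x = x, y = y, act = act))
}

denseBw <- function(p, cache, dy) {
  if (cache$act == "tanh") dy <- dy * (1 - cache$y^2)
  list(dx = p$W %*% dy,
       grads = list(W = cache$x %*% t(dy), b = rowSums(dy)))
}

convFw <- function(p, x, H = 64L, W = 64L) {
  y <- .conv_fw(x, p$W, p$b, H, W, p$k)
  list(y = y, cache = list(x = x, H = H, W = W))
}

convBw <- function(p, cache, dy) {
  r <- .conv_bw(cache$x, p$W, dy, cache$H, cache$W, p$k)
  list(dx = r$dx, grads = list(W = r$dW, b = as.numeric(r$db)))
}

bnReluFw <- function(p, x, training, relu = TRUE, momentum = 0.9, eps = 1e-3) {
  r <- .bn_fw(x, p$gamma, p$beta, p$rmean, p$rvar, eps, momentum,
              training, relu)
  list(y = r$y,
       cache = list(x = x, y = r$y, mu = as.numeric(r$mu),
                    ivstd = as.numeric(r$ivstd), relu = relu),
       stats = list(rmean = as.numeric(r$rmean), rvar = as.numeric(r$rvar)))
}

bnReluBw <- function(p, cache, dy) {
  r <- .bn_bw(cache$x, cache$y, dy, p$gamma, cache$mu, cache$ivstd, cache$relu)
  list(dx = r$dx,
       grads = list(gamma = as.numeric(r$dgamma), beta = as.numeric(r$dbeta)))
}

reluFw <- function(x) list(y = pmax(x, 0))
reluBw <- function(y, dy) dy * (y > 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# channel attention: GAP + GMP summaries -> shared bottleneck MLP -> sigmoid
# gate, channelwise rescale.  x is a (HW, C, B) cube.
cabFw <- function(p, x) {
  HW <- dim(x)[1]
  zavg <- colMeans(x, dims = 1)              # C x B
  gm <- .gmp_fw(x)
  zmax <- gm$z
  z <- zavg + zmax
  h1 <- crossprod(p$W1, z) + p$b1
  a1 <- pmax(h1, 0)
  u <- crossprod(p$W2, a1) + p$b2
  w <- sigmoid(u)                            # C x B attention weights
  wfull <- array(rep(w, each = HW), dim(x))
  y <- x * wfull
  list(y = y, weights = w,
       cache = list(x = x, z = z, a1 = a1, w = w, wfull = wfull,
                    maxIdx = gm$idx, HW = HW))
}

cabBw <- function(p, cache, dy) {
  x <- cache$x; w <- cache$w; HW <- cache$HW
  C <- dim(x)[2]; B <- dim(x)[3]
  dxScale <- dy * cache$wfull
  dw <- colSums(dy * x, dims = 1)            # C x B
  du <- dw * w * (1 - w)
  dW2 <- cache$a1 %*% t(du)
  db2 <- rowSums(du)
  da1 <- p$W2 %*% du
  dh1 <- da1 * (cache$a1 > 0)
  dW1 <- cache$z %*% t(dh1)
  db1 <- rowSums(dh1)
  dz <- p$W1 %*% dh1                         # C x B, shared by both summaries
  dx <- dxScale + array(rep(dz / HW, each = HW), dim(x))
  # scatter the GMP part onto the argmax pixels
  pos <- as.vector(cache$maxIdx) + 1L +
    HW * (rep(seq_len(C) - 1L, times = B) +
          C * rep(seq_len(B) - 1L, each = C))
  dx[pos] <- dx[pos] + as.vector(dz)
  list(dx = dx,
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# ---- composite blocks ------------------------------------------------------

initFEBParams <- function(cin, filters = 8L, k = 3L, zero = FALSE) {
  list(conv1 = initConv(cin, filters, k, zero), bn1 = initBN(filters),
       conv2 = initConv(filters, filters, k, zero), bn2 = initBN(filters))
}

febFw <- function(p, x, training) {
  c1 <- convFw(p$conv1, x)
  b1 <- bnReluFw(p$bn1, c1$y, training)
  c2 <- convFw(p$conv2, b1$y)
  b2 <- bnReluFw(p$bn2, c2$y, training)
  list(y = b2$y,
       cache = list(c1 = c1$cache, b1 = b1$cache, c2 = c2$cache, b2 = b2$cache),
       stats = list(bn1 = b1$stats, bn2 = b2$stats))
}

febBw <- function(p, cache, dy) {
  g <- list()
  r <- bnReluBw(p$bn2, cache$b2, dy); g$bn2 <- r$grads
  r2 <- convBw(p$conv2, cache$c2, r$dx); g$conv2 <- r2$grads
  r3 <- bnReluBw(p$bn1, cache$b1, r2$dx); g$bn1 <- r3$grads
  r4 <- convBw(p$conv1, cache$c1, r3$dx); g$conv1 <- r4$grads
  list(dx = r4$dx, grads = g)
}

initFusionParams <- function(cin, cfg, zero = FALSE) {
  f <- cfg@febFilters
  list(feb1 = initFEBParams(cin, f, cfg@fusionKernels[1], zero),
       feb3 = initFEBParams(cin, f, cfg@fusionKernels[2], zero),
       feb5 = initFEBParams(cin, f, cfg@fusionKernels[3], zero),
       poolconv = initConv(cin, cfg@fusionRefineFilters, 1L, zero))
}

fusionOutChannels <- function(cfg) 3L * cfg@febFilters + cfg@fusionRefineFilters

# fusion block: three multi-scale FEB branches plus a smoothed (max-pooled)
# branch refined by a 1x1 conv with ReLU; concatenated channelwise in the
# fixed order [k1, k3, k5, pool].
fusionFw <- function(p, x, training) {
  d <- dim(x)
  b1 <- febFw(p$feb1, x, training)
  b3 <- febFw(p$feb3, x, training)
  b5 <- febFw(p$feb5, x, training)
  mp <- .maxpool3_fw(x, 64L, 64L)
  pc <- convFw(p$poolconv, mp$y)
  pr <- reluFw(pc$y)
  nb <- vapply(list(b1$y, b3$y, b5$y, pr$y), function(a) dim(a)[2], numeric(1))
  y <- array(0, c(d[1], sum(nb), d[3]))
  off <- cumsum(c(0, nb))
  y[, off[1] + seq_len(nb[1]), ] <- b1$y
  y[, off[2] + seq_len(nb[2]), ] <- b3$y
  y[, off[3] + seq_len(nb[3]), ] <- b5$y
  y[, off[4] + seq_len(nb[4]), ] <- pr$y
  list(y = y,
       cache = list(b1 = b1$cache, b3 = b3$cache, b5 = b5$cache,
                    mpIdx = mp$idx, pc = pc$cache, pry = pr$y, off = off,
                    nb = nb),
       stats = list(feb1 = b1$stats, feb3 = b3$stats, feb5 = b5$stats))
}

fusionBw <- function(p, cache, dy) {
  off <- cache$off; nb <- cache$nb
  g <- list()
  r1 <- febBw(p$feb1, cache$b1, dy[, off[1] + seq_len(nb[1]), , drop = FALSE])
  r3 <- febBw(p$feb3, cache$b3, dy[, off[2] + seq_len(nb[2]), , drop = FALSE])
  r5 <- febBw(p$feb5, cache$b5, dy[, off[3] + seq_len(nb[3]), , drop = FALSE])
  dpr <- reluBw(cache$pry, dy[, off[4] + seq_len(nb[4]), , drop = FALSE])
  rp <- convBw(p$poolconv, cache$pc, dpr)
  dmp <- .maxpool3_bw(rp$dx, cache$mpIdx)
  g$feb1 <- r1$grads; g$feb3 <- r3$grads; g$feb5 <- r5$grads
  g$poolconv <- rp$grads
  list(dx = r1$dx + r3$dx + r5$dx + dmp, grads = g)
}
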