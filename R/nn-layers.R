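# Low-level CNN layers on (H, W, N, C) arrays with hand-derived backward
# passes. Convolutions use "same" padding ((k-1)/2) and a memoized im2col
# gather followed by one matrix product, which vectorizes well at the small
# image sizes this package works at.

convForward <- function(x, W, b, stride = 1L) {
  d <- dim(x); h <- d[1]; w <- d[2]; n <- d[3]; cin <- d[4]
  k <- dim(W)[1]; cout <- dim(W)[4]
  stopifnot(dim(W)[3] == cin)
  p <- (k - 1L) %/% 2L
  hp <- h + 2L * p; wp <- w + 2L * p
  ho <- (hp - k) %/% stride + 1L
  wo <- (wp - k) %/% stride + 1L
  if (ho < 1L || wo < 1L)
    stop("convolution collapses spatial dims below 1x1 (input ", h, "x", w,
         ", kernel ", k, ", stride ", stride, ")")
  if (p > 0) {
    xp <- array(0, c(hp, wp, n, cin))
    xp[p + seq_len(h), p + seq_len(w), , ] <- x
  } else xp <- x
  m <- ho * wo * n
  idx <- convIndex(hp, wp, n, cin, k, stride, ho, wo)
  xcol <- xp; dim(xcol) <- NULL
  xcol <- xcol[idx]
  dim(xcol) <- c(m, k * k * cin)
  Wm <- W; dim(Wm) <- c(k * k * cin, cout)
  y <- xcol %*% Wm + rep(b, each = m)
  dim(y) <- c(ho, wo, n, cout)
  list(out = y, xcol = xcol, k = k, stride = stride, p = p, inDim = d,
       ho = ho, wo = wo)
}

# im2col linear-index table, memoized per geometry. Column order matches
# the (k, k, cin, cout) kernel layout flattened to (k*k*cin) x cout.
convIndexCache <- new.env(parent = emptyenv())
convIndex <- function(hp, wp, n, cin, k, stride, ho, wo) {
  key <- paste(hp, wp, n, cin, k, stride, sep = "_")
  hit <- convIndexCache[[key]]
  if (!is.null(hit)) return(hit)
  iV <- rep(seq_len(ho), times = wo)
  jV <- rep(seq_len(wo), each = ho)
  spat <- matrix(0L, ho * wo, k * k)
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    r <- di + (iV - 1L) * stride
    cc <- dj + (jV - 1L) * stride
    spat[, (dj - 1L) * k + di] <- r + (cc - 1L) * hp
  }
  sampOff <- rep((seq_len(n) - 1L) * (hp * wp), each = ho * wo)
  base <- spat[rep(seq_len(ho * wo), n), , drop = FALSE] + sampOff
  idx <- matrix(0L, nrow(base), k * k * cin)
  for (ch in seq_len(cin))
    idx[, (ch - 1L) * k * k + seq_len(k * k)] <-
      base + (ch - 1L) * (hp * wp * n)
  idx <- as.vector(idx)
  convIndexCache[[key]] <- idx
  idx
}

# Input gradient of a "same"-padded strided convolution, computed as a
# stride-1 convolution of the zero-dilated output gradient with the
# spatially flipped, channel-transposed kernel (exact for odd kernels).
convBackward <- function(dy, cache, W) {
  k <- cache$k; stride <- cache$stride
  d <- cache$inDim; ho <- cache$ho; wo <- cache$wo
  cin <- d[4]; cout <- dim(W)[4]; n <- d[3]
  m <- ho * wo * n
  dym <- dy; dim(dym) <- c(m, cout)
  db <- colSums(dym)
  dW <- crossprod(cache$xcol, dym)
  dim(dW) <- dim(W)
  if (stride == 1L && ho == d[1] && wo == d[2]) {
    dyUp <- dy
  } else {
    dyUp <- array(0, c(d[1], d[2], n, cout))
    dyUp[seq.int(1L, by = stride, length.out = ho),
         seq.int(1L, by = stride, length.out = wo), , ] <- dy
  }
  Wf <- W[k:1, k:1, , , drop = FALSE]
  Wf <- aperm(Wf, c(1, 2, 4, 3))
  dx <- convForward(dyUp, Wf, numeric(cin), 1L)$out
  list(dx = dx, dW = dW, db = db)
}

bnForward <- function(x, gamma, beta, stats, training, momentum = 0.9,
                      eps = 1e-5) {
  d <- dim(x); m <- prod(d[1:3])
  xm <- x; dim(xm) <- c(m, d[4])
  if (training) {
    mu <- colMeans(xm)
    xc <- xm - rep(mu, each = m)
    v <- colMeans(xc * xc)
    stats <- list(mean = momentum * stats$mean + (1 - momentum) * mu,
                  var = momentum * stats$var + (1 - momentum) * v)
  } else {
    mu <- stats$mean; v <- stats$var
    xc <- xm - rep(mu, each = m)
  }
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(invstd, each = m)
  y <- xhat * rep(gamma, each = m) + rep(beta, each = m)
  dim(y) <- d
  list(out = y, xhat = xhat, invstd = invstd, d = d, stats = stats,
       training = training)
}

bnBackward <- function(dy, cache, gamma) {
  d <- cache$d; m <- prod(d[1:3])
  dym <- dy; dim(dym) <- c(m, d[4])
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  dxhat <- dym * rep(gamma, each = m)
  if (cache$training) {
    mh <- colMeans(dxhat)
    mxh <- colMeans(dxhat * cache$xhat)
    dx <- (dxhat - rep(mh, each = m) - cache$xhat * rep(mxh, each = m)) *
      rep(cache$invstd, each = m)
  } else {
    dx <- dxhat * rep(cache$invstd, each = m)
  }
  dim(dx) <- d
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

reluForward <- function(x) {
  mask <- x > 0
  x[!mask] <- 0
  list(out = x, mask = mask)
}

reluBackward <- function(dy, cache) {
  dy[!cache$mask] <- 0
  dy
}

#' Spatial attention gate
#'
#' Pools the channel dimension into per-location mean and max maps,
#' convolves the two-channel pool with a single `k x k` filter and squashes
#' through a logistic, giving an attention map in (0, 1) that rescales every
#' channel of the input at each location.
#'
#' @param x numeric array H x W x N x C (a batch of feature maps) or
#'   C x H x W for a single sample (transposed internally).
#' @param Wa attention convolution weights, `k x k x 2 x 1`.
#' @param ba attention bias (length 1).
#' @return list with `out` (attended maps, same shape as the input) and
#'   `attention` (H x W x N x 1 map in (0, 1)).
#' @export
spatialAttention <- function(x, Wa, ba = 0) {
  chw <- length(dim(x)) == 3L
  if (chw) x <- aperm(array(x, c(dim(x), 1L)), c(2, 3, 4, 1))
  cache <- attForward(x, Wa, ba)
  out <- cache$out
  if (chw) out <- aperm(out, c(4, 1, 2, 3))[, , , 1]
  list(out = out, attention = cache$attention)
}

attForward <- function(x, Wa, ba) {
  d <- dim(x); m <- prod(d[1:3]); C <- d[4]
  xm <- x; dim(xm) <- c(m, C)
  mn <- rowMeans(xm)
  mx <- xm[, 1]; arg <- rep(1L, m)
  if (C > 1L) for (cc in 2:C) {
    u <- xm[, cc] > mx
    mx[u] <- xm[u, cc]; arg[u] <- cc
  }
  pooled <- array(c(mn, mx), c(d[1], d[2], d[3], 2L))
  cf <- convForward(pooled, Wa, ba, 1L)
  aV <- 1 / (1 + exp(-as.vector(cf$out)))
  y <- xm * aV  # recycles the map down every channel column
  dim(y) <- d
  list(out = y, attention = array(aV, c(d[1], d[2], d[3], 1L)),
       xm = xm, aV = aV, arg = arg, convCache = cf, d = d)
}

attBackward <- function(dy, cache, Wa) {
  d <- cache$d; m <- prod(d[1:3]); C <- d[4]
  dym <- dy; dim(dym) <- c(m, C)
  dx <- dym * cache$aV
  daV <- rowSums(dym * cache$xm)
  dsV <- daV * cache$aV * (1 - cache$aV)
  ds <- array(dsV, c(d[1], d[2], d[3], 1L))
  cb <- convBackward(ds, cache$convCache, Wa)
  dpm <- cb$dx; dim(dpm) <- c(m, 2L)
  dx <- dx + dpm[, 1] / C
  idx <- cbind(seq_len(m), cache$arg)
  dx[idx] <- dx[idx] + dpm[, 2]
  dim(dx) <- d
  list(dx = dx, dWa = cb$dW, dba = cb$db)
}
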