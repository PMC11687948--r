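#' Residual block specification
#'
#' @param nFilters number of convolution filters in the block.
#' @param kernelSize odd kernel size (symmetric "same" padding).
#' @param stride stride of the block's first convolution (and of the
#'   shortcut projection when shapes change).
#' @return a list of class `blockSpec`.
#' @export
blockSpec <- function(nFilters, kernelSize = 3L, stride = 1L) {
  nFilters <- as.integer(nFilters); kernelSize <- as.integer(kernelSize)
  stride <- as.integer(stride)
  if (nFilters < 1L || kernelSize < 1L || stride < 1L)
    stop("block spec fields must be positive")
  if (kernelSize %% 2L == 0L)
    stop("kernelSize must be odd for symmetric padding")
  structure(list(nFilters = nFilters, kernelSize = kernelSize,
                 stride = stride), class = "blockSpec")
}

heConv <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, sd = sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

initBlockParams <- function(cin, spec, attentionKernel) {
  k <- spec$kernelSize; cout <- spec$nFilters
  p <- list(
    W1 = heConv(k, cin, cout), b1 = numeric(cout),
    g1 = rep(1, cout), be1 = numeric(cout),
    W2 = heConv(k, cout, cout), b2 = numeric(cout),
    g2 = rep(1, cout), be2 = numeric(cout),
    Wa = heConv(attentionKernel, 2L, 1L), ba = numeric(1))
  if (spec$stride != 1L || cin != cout) {
    p$Ws <- heConv(1L, cin, cout); p$bs <- numeric(cout)
    p$gs <- rep(1, cout); p$bes <- numeric(cout)
  }
  p
}

initModelParams <- function(blocks, stemFilters, attentionKernel, nClasses,
                            headDim, seed) {
  withSeed(seed, {
    params <- list(
      stem = list(W = heConv(3L, 1L, stemFilters), b = numeric(stemFilters),
                  g = rep(1, stemFilters), be = numeric(stemFilters)),
      blocks = vector("list", length(blocks)),
      head = list())
    cin <- stemFilters
    for (i in seq_along(blocks)) {
      params$blocks[[i]] <- initBlockParams(cin, blocks[[i]],
                                            attentionKernel)
      cin <- blocks[[i]]$nFilters
    }
    params$head <- list(W = matrix(rnorm(headDim * nClasses,
                                         sd = sqrt(2 / headDim)),
                                   headDim, nClasses),
                        b = numeric(nClasses))
    params
  })
}

initModelStats <- function(blocks, stemFilters) {
  zed <- function(C) list(mean = numeric(C), var = rep(1, C))
  st <- list(stem = zed(stemFilters), blocks = vector("list",
                                                      length(blocks)))
  cin <- stemFilters
  for (i in seq_along(blocks)) {
    cout <- blocks[[i]]$nFilters
    st$blocks[[i]] <- list(bn1 = zed(cout), bn2 = zed(cout))
    if (blocks[[i]]$stride != 1L || cin != cout)
      st$blocks[[i]]$bnS <- zed(cout)
    cin <- cout
  }
  st
}

#' Forward pass of one residual block
#'
#' The block applies, in order: convolution, batch-normalization,
#' activation, convolution, batch-normalization, spatial attention, identity
#' shortcut addition, activation. The shortcut is a 1x1 strided convolution
#' plus batch-normalization whenever the stride or channel count changes the
#' shape, and the plain identity otherwise.
#'
#' @param x input array H x W x N x C.
#' @param bp block parameters (see internals of [buildModel()]).
#' @param st block batch-norm statistics.
#' @param spec a [blockSpec()].
#' @param training use batch statistics (TRUE) or running statistics.
#' @return list with `out`, updated `stats`, the layer `trace` (stage names
#'   in execution order) and caches for the backward pass.
#' @export
residualBlockForward <- function(x, bp, st, spec, training = FALSE) {
  c1 <- convForward(x, bp$W1, bp$b1, spec$stride)
  b1 <- bnForward(c1$out, bp$g1, bp$be1, st$bn1, training)
  r1 <- reluForward(b1$out)
  c2 <- convForward(r1$out, bp$W2, bp$b2, 1L)
  b2 <- bnForward(c2$out, bp$g2, bp$be2, st$bn2, training)
  at <- attForward(b2$out, bp$Wa, bp$ba)
  if (!is.null(bp$Ws)) {
    sc <- convForward(x, bp$Ws, bp$bs, spec$stride)
    sb <- bnForward(sc$out, bp$gs, bp$bes, st$bnS, training)
    short <- sb$out
  } else { sc <- NULL; sb <- NULL; short <- x }
  added <- at$out + short
  r2 <- reluForward(added)
  stats <- list(bn1 = b1$stats, bn2 = b2$stats)
  if (!is.null(sb)) stats$bnS <- sb$stats
  list(out = r2$out, stats = stats,
       trace = c("conv", "batchnorm", "activation", "conv", "batchnorm",
                 "spatial-attention", "identity-add", "activation"),
       cache = list(c1 = c1, b1 = b1, r1 = r1, c2 = c2, b2 = b2, at = at,
                    sc = sc, sb = sb, r2 = r2, projected = !is.null(bp$Ws)))
}

residualBlockBackward <- function(dy, cache, bp) {
  dAdded <- reluBackward(dy, cache$r2)
  g <- list()
  ab <- attBackward(dAdded, cache$at, bp$Wa)
  g$Wa <- ab$dWa; g$ba <- ab$dba
  bb2 <- bnBackward(ab$dx, cache$b2, bp$g2)
  g$g2 <- bb2$dgamma; g$be2 <- bb2$dbeta
  cb2 <- convBackward(bb2$dx, cache$c2, bp$W2)
  g$W2 <- cb2$dW; g$b2 <- cb2$db
  dr1 <- reluBackward(cb2$dx, cache$r1)
  bb1 <- bnBackward(dr1, cache$b1, bp$g1)
  g$g1 <- bb1$dgamma; g$be1 <- bb1$dbeta
  cb1 <- convBackward(bb1$dx, cache$c1, bp$W1)
  g$W1 <- cb1$dW; g$b1 <- cb1$db
  dx <- cb1$dx
  if (cache$projected) {
    sbb <- bnBackward(dAdded, cache$sb, bp$gs)
    g$gs <- sbb$dgamma; g$bes <- sbb$dbeta
    scb <- convBackward(sbb$dx, cache$sc, bp$Ws)
    g$Ws <- scb$dW; g$bs <- scb$db
    dx <- dx + scb$dx
  } else {
    dx <- dx + dAdded
  }
  list(dx = dx, grads = g[names(bp)])
}

#' Build an untrained residual spatial-attention CNN
#'
#' Stem convolution (3x3) with batch-norm and activation, the residual
#' blocks in order, and a linear softmax head. With the default
#' `headType = "flatten"` the last block's feature map is flattened into the
#' classifier, giving the head position-specific weights — essential for
#' fixed-layout taxa images, where the discriminative signal sits at fixed
#' pixels and disappears under spatial pooling. `headType = "gap"` applies
#' global average pooling instead (position-blind, fewer parameters). The
#' output of the last residual block (its post-attention feature map after
#' the shortcut) is the default saliency layer for [gradCAM()].
#'
#' @param blocks list of [blockSpec()]s (at least one).
#' @param nClasses number of classes (>= 2).
#' @param H,W input image height and width.
#' @param stemFilters channels of the stem convolution.
#' @param attentionKernel kernel size of the spatial-attention convolution.
#' @param headType "flatten" (default) or "gap".
#' @param classLevels optional class labels in output order.
#' @param seed seed for the parameter initialization.
#' @return an \linkS4class{AttentionCNN} (untrained).
#' @export
buildModel <- function(blocks, nClasses, H, W, stemFilters = 8L,
                       attentionKernel = 7L,
                       headType = c("flatten", "gap"),
                       classLevels = paste0("class", seq_len(nClasses)),
                       seed = 1L) {
  headType <- match.arg(headType)
  if (!length(blocks)) stop("at least one residual block is required")
  blocks <- lapply(blocks, function(b)
    if (inherits(b, "blockSpec")) b else do.call(blockSpec, as.list(b)))
  if (nClasses < 2L) stop("nClasses must be >= 2")
  h <- as.integer(H); w <- as.integer(W)
  for (i in seq_along(blocks)) {
    s <- blocks[[i]]$stride
    if (s > h || s > w)
      stop("spatial dimensions collapse below 1x1 at block ", i,
           " (stride ", s, " exceeds the ", h, "x", w, " input)")
    h <- (h - 1L) %/% s + 1L
    w <- (w - 1L) %/% s + 1L
  }
  lastC <- blocks[[length(blocks)]]$nFilters
  headDim <- if (headType == "flatten") h * w * lastC else lastC
  params <- initModelParams(blocks, as.integer(stemFilters),
                            as.integer(attentionKernel), nClasses, headDim,
                            seed)
  stats <- initModelStats(blocks, as.integer(stemFilters))
  new("AttentionCNN", blocks = blocks, stemFilters = as.integer(stemFilters),
      attentionKernel = as.integer(attentionKernel),
      inputDim = c(as.integer(H), as.integer(W)),
      classLevels = as.character(classLevels),
      params = list(learn = params, stats = stats, headType = headType),
      history = data.frame(), trained = FALSE, normMax = NA_real_)
}

applyInputStats <- function(x, inputStats) {
  if (is.null(inputStats)) return(x)
  # H x W stats recycle along samples for the single-channel layout
  (x - as.vector(inputStats$mean)) / as.vector(inputStats$sd)
}

# Full forward pass. Returns probabilities, logits, per-stage caches and
# updated batch-norm statistics. Per-pixel input standardization (stored at
# training time) is applied on entry.
modelForward <- function(model, x, training = FALSE) {
  x <- applyInputStats(x, model@params$inputStats)
  learn <- model@params$learn; stats <- model@params$stats
  cs <- convForward(x, learn$stem$W, learn$stem$b, 1L)
  bs <- bnForward(cs$out, learn$stem$g, learn$stem$be, stats$stem, training)
  rs <- reluForward(bs$out)
  stats$stem <- bs$stats
  h <- rs$out
  blockCaches <- vector("list", length(model@blocks))
  blockOut <- vector("list", length(model@blocks))
  for (i in seq_along(model@blocks)) {
    bf <- residualBlockForward(h, learn$blocks[[i]], stats$blocks[[i]],
                               model@blocks[[i]], training)
    stats$blocks[[i]][names(bf$stats)] <- bf$stats
    blockCaches[[i]] <- bf$cache
    h <- bf$out
    blockOut[[i]] <- h
  }
  d <- dim(h); m <- d[1] * d[2]
  if ((model@params$headType %||% "flatten") == "gap") {
    hm <- h; dim(hm) <- c(m, d[3] * d[4])
    gap <- matrix(colMeans(hm), d[3], d[4])
  } else {
    gap <- aperm(h, c(1, 2, 4, 3))      # flatten (h, w, C) per sample
    dim(gap) <- c(m * d[4], d[3])
    gap <- t(gap)
  }
  logits <- sweep(gap %*% learn$head$W, 2, learn$head$b, "+")
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  probs <- ez / rowSums(ez)
  list(probs = probs, logits = logits, gap = gap, lastDim = d,
       caches = list(stem = list(cs = cs, bs = bs, rs = rs),
                     blocks = blockCaches),
       blockOut = blockOut, stats = stats)
}

# Backward pass from dLogits. If stopAtBlock > 0, stops after propagating
# to the *output* of that block and returns the gradient there (used by
# Grad-CAM); gradients of earlier stages are then not computed.
modelBackward <- function(model, fw, dLogits, stopAtBlock = 0L) {
  learn <- model@params$learn
  d <- fw$lastDim; m <- d[1] * d[2]
  g <- list(head = list(W = crossprod(fw$gap, dLogits),
                        b = colSums(dLogits)))
  if ((model@params$headType %||% "flatten") == "gap") {
    dGap <- dLogits %*% t(learn$head$W)         # n x C
    dh <- matrix(rep(as.vector(dGap) / m, each = m), m, d[3] * d[4])
    dim(dh) <- d
  } else {
    dFlat <- t(dLogits %*% t(learn$head$W))     # (h*w*C) x n
    dim(dFlat) <- c(d[1], d[2], d[4], d[3])
    dh <- aperm(dFlat, c(1, 2, 4, 3))
  }
  nb <- length(model@blocks)
  g$blocks <- vector("list", nb)
  for (i in rev(seq_len(nb))) {
    if (stopAtBlock == i) return(list(grads = g, dAtBlock = dh))
    bb <- residualBlockBackward(dh, fw$caches$blocks[[i]],
                                learn$blocks[[i]])
    g$blocks[[i]] <- bb$grads
    dh <- bb$dx
  }
  drs <- reluBackward(dh, fw$caches$stem$rs)
  bbs <- bnBackward(drs, fw$caches$stem$bs, learn$stem$g)
  cbs <- convBackward(bbs$dx, fw$caches$stem$cs, learn$stem$W)
  g$stem <- list(W = cbs$dW, b = cbs$db, g = bbs$dgamma, be = bbs$dbeta)
  g$stem <- g$stem[names(learn$stem)]
  list(grads = g, dAtBlock = NULL)
}

#' Layer trace of a forward pass
#'
#' Names the stages executed inside each residual block, in order — useful
#' for verifying the architecture.
#'
#' @param model an \linkS4class{AttentionCNN}.
#' @return character vector of stage names for one block.
#' @export
layerTrace <- function(model) {
  x <- array(0, c(model@inputDim[1], model@inputDim[2], 1L, 1L))
  cs <- convForward(x, model@params$learn$stem$W, model@params$learn$stem$b,
                    1L)
  bf <- residualBlockForward(
    reluForward(bnForward(cs$out, model@params$learn$stem$g,
                          model@params$learn$stem$be,
                          model@params$stats$stem, FALSE)$out)$out,
    model@params$learn$blocks[[1]], model@params$stats$blocks[[1]],
    model@blocks[[1]], FALSE)
  bf$trace
}

#' Number of learnable parameters
#'
#' @param model an \linkS4class{AttentionCNN}.
#' @return integer count of all learnable parameter entries (convolution and
#'   head weights/biases, batch-norm scales/shifts, attention filters).
#' @export
parameterCount <- function(model) {
  sum(unlist(rapply(model@params$learn, length, how = "unlist")))
}

#' Class probabilities for a stack of images
#'
#' @param model a trained \linkS4class{AttentionCNN}.
#' @param images an \linkS4class{ImageStack} or H x W x N array (or a single
#'   H x W matrix).
#' @return n x nClasses matrix of probabilities, rows summing to 1.
#' @export
predictProb <- function(model, images) {
  x <- imagesToArray(images, model@inputDim)
  fw <- modelForward(model, x, training = FALSE)
  p <- fw$probs
  colnames(p) <- model@classLevels
  if (is(images, "ImageStack")) rownames(p) <- images@sampleIds
  p
}

imagesToArray <- function(images, inputDim) {
  d0 <- if (is(images, "ImageStack")) dim(images@data) else dim(images)
  x <- if (is(images, "ImageStack")) images@data else images
  if (length(d0) == 2L) x <- array(x, c(d0, 1L))
  d <- dim(x)
  if (d[1] != inputDim[1] || d[2] != inputDim[2])
    stop("image dims ", d[1], "x", d[2], " do not match model input ",
         inputDim[1], "x", inputDim[2])
  array(x, c(d[1], d[2], d[3], 1L))
}
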