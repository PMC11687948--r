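# Structural and numerical correctness of the residual attention network.

tinyModel <- function(seed = 1) {
  buildModel(list(blockSpec(3, 3, 1), blockSpec(4, 3, 2)), nClasses = 2,
             H = 6, W = 6, stemFilters = 2, attentionKernel = 3,
             seed = seed)
}

test_that("spatial attention gates lie in (0,1) and multiply exactly", {
  set.seed(31)
  Wa <- array(rnorm(3 * 3 * 2), c(3, 3, 2, 1))
  x <- array(rnorm(8 * 5 * 5), c(5, 5, 1, 8))  # H x W x N x C layout
  res <- taxapix:::attForward(x, Wa, 0.3)
  expect_true(all(res$attention > 0 & res$attention < 1))
  # attended map equals elementwise product with the returned map
  manual <- array(0, dim(x))
  for (cc in 1:8) manual[, , 1, cc] <- x[, , 1, cc] * res$attention[, , 1, 1]
  expect_equal(res$out, manual, tolerance = 1e-12)

  # spatially constant input gives a spatially constant attention map
  xc <- array(rep(c(0.4, -1.2), each = 25), c(5, 5, 1, 2))
  resc <- taxapix:::attForward(xc, Wa, 0)
  inner <- resc$attention[2:4, 2:4, 1, 1]  # away from zero padding
  expect_lt(diff(range(inner)), 1e-12)
})

test_that("the residual shortcut dominates when the main branch is zeroed", {
  m <- tinyModel()
  bp <- m@params$learn$blocks[[1]]  # stride 1, but 2 -> 3 channels projects
  # use a custom identity-shaped block: same channels, stride 1
  spec <- blockSpec(2, 3, 1)
  bp0 <- taxapix:::initBlockParams(2L, spec, 3L)
  st0 <- list(bn1 = list(mean = numeric(2), var = rep(1, 2)),
              bn2 = list(mean = numeric(2), var = rep(1, 2)))
  bp0$W2[] <- 0; bp0$b2[] <- 0; bp0$g2[] <- 0; bp0$be2[] <- 0
  x <- array(rnorm(6 * 6 * 3 * 2), c(6, 6, 3, 2))
  out <- residualBlockForward(x, bp0, st0, spec, training = FALSE)
  expect_equal(out$out, pmax(x, 0), tolerance = 1e-12)
})

test_that("strides halve spatial dims and the layer trace is in order", {
  m <- tinyModel()
  x <- array(rnorm(16 * 16 * 2 * 3), c(16, 16, 2, 3))
  spec <- blockSpec(5, 3, 2)
  bp <- taxapix:::initBlockParams(3L, spec, 3L)
  st <- list(bn1 = list(mean = numeric(5), var = rep(1, 5)),
             bn2 = list(mean = numeric(5), var = rep(1, 5)),
             bnS = list(mean = numeric(5), var = rep(1, 5)))
  out <- residualBlockForward(x, bp, st, spec, training = TRUE)
  expect_equal(dim(out$out), c(8L, 8L, 2L, 5L))
  expect_equal(out$trace,
               c("conv", "batchnorm", "activation", "conv", "batchnorm",
                 "spatial-attention", "identity-add", "activation"))
})

test_that("model head dimensions, probability normalization, param count", {
  m <- buildModel(list(blockSpec(8, 3, 1), blockSpec(16, 3, 2)),
                  nClasses = 3, H = 32, W = 32, stemFilters = 4,
                  attentionKernel = 7)
  x <- array(runif(32 * 32 * 5), c(32, 32, 5, 1))
  fw <- taxapix:::modelForward(m, x)
  expect_equal(dim(fw$blockOut[[2]]), c(16L, 16L, 5L, 16L))
  expect_equal(dim(fw$probs), c(5L, 3L))
  expect_true(all(abs(rowSums(fw$probs) - 1) < 1e-6))

  # closed-form parameter count for a 1-block model
  S <- 4; f <- 8; k <- 3; ka <- 7; K <- 2
  m1 <- buildModel(list(blockSpec(f, k, 1)), nClasses = K, H = 8, W = 8,
                   stemFilters = S, attentionKernel = ka)
  stem <- 3 * 3 * 1 * S + S + 2 * S
  blk <- (k^2 * S * f + f + 2 * f) +        # conv1 + bn1
    (k^2 * f * f + f + 2 * f) +             # conv2 + bn2
    (ka^2 * 2 + 1) +                        # attention conv
    (1 * S * f + f + 2 * f)                 # 1x1 projection + bn
  head <- (8 * 8 * f) * K + K  # flatten head: positions x channels
  expect_equal(parameterCount(m1), stem + blk + head)
  mg <- buildModel(list(blockSpec(f, k, 1)), nClasses = K, H = 8, W = 8,
                   stemFilters = S, attentionKernel = ka, headType = "gap")
  expect_equal(parameterCount(mg), stem + blk + f * K + K)

  expect_error(buildModel(list(blockSpec(4, 3, 64)), 2, 8, 8), "collapse")
  expect_error(blockSpec(4, 4, 1), "odd")
})

test_that("backpropagated gradients match numeric differentiation", {
  m <- tinyModel(seed = 5)
  set.seed(32)
  x <- array(runif(6 * 6 * 3 * 1), c(6, 6, 3, 1))
  yIdx <- c(1L, 2L, 1L)
  oneHot <- matrix(0, 3, 2); oneHot[cbind(1:3, yIdx)] <- 1
  lossAt <- function(params) {
    m2 <- m; m2@params$learn <- params
    fw <- taxapix:::modelForward(m2, x, training = TRUE)
    taxapix:::crossEntropy(fw$probs, yIdx, rep(1, 3))
  }
  fw <- taxapix:::modelForward(m, x, training = TRUE)
  dLogits <- (fw$probs - oneHot) / 3
  an <- taxapix:::modelBackward(m, fw, dLogits)$grads

  paths <- list(list("stem", "W"), list("stem", "g"), list("stem", "be"),
                list("head", "W"), list("head", "b"))
  for (b in 1:2) for (leaf in c("W1", "g1", "W2", "be2", "Wa", "ba",
                                "Ws", "gs"))
    paths[[length(paths) + 1]] <- list("blocks", b, leaf)
  for (pth in paths) {
    getLeaf <- function(pp) Reduce(function(o, k) o[[k]], pp, m@params$learn)
    leaf <- getLeaf(pth)
    if (is.null(leaf)) next
    aLeaf <- Reduce(function(o, k) o[[k]], pth, an)
    idx <- sample(length(leaf), min(3, length(leaf)))
    for (i in idx) {
      f <- function(v) {
        p2 <- m@params$learn
        expr <- leaf; expr[i] <- v
        p2 <- modifyListPath(p2, pth, expr)
        lossAt(p2)
      }
      num <- (f(leaf[i] + 1e-5) - f(leaf[i] - 1e-5)) / 2e-5
      expect_equal(aLeaf[i], num, tolerance = 1e-4)
    }
  }
})

test_that("forward pass is shape-sound over random block specs", {
  set.seed(33)
  for (rep in 1:5) {
    nb <- sample(1:3, 1)
    specs <- lapply(seq_len(nb), function(i)
      blockSpec(sample(c(2, 4, 6), 1), sample(c(3, 5), 1),
                sample(1:2, 1)))
    H <- sample(c(12, 16), 1)
    m <- buildModel(specs, nClasses = sample(2:4, 1), H = H, W = H,
                    stemFilters = 3, attentionKernel = 3)
    x <- array(runif(H * H * 2), c(H, H, 2, 1))
    fw <- taxapix:::modelForward(m, x)
    expect_true(all(abs(rowSums(fw$probs) - 1) < 1e-6))
  }
})
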