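# 2D taxa embedding: exact (O(n^2)) t-SNE and a full-batch UMAP-style
# cross-entropy optimizer. Both operate on a few hundred to a thousand taxa,
# where quadratic cost is negligible, and are deterministic given a seed.

# Conditional probabilities with per-point precision tuned by binary search
# so every row's perplexity matches the target.
tsneCondP <- function(D2, perplexity, tol = 1e-5) {
  n <- nrow(D2)
  targetH <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    beta <- 1; lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < .Machine$double.xmin) { H <- 0; p <- w }
      else {
        p <- w / sw
        H <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(H - targetH) < tol) break
      if (H > targetH) { lo <- beta; beta <- if (is.finite(hi))
        (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo))
        (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P
}

tsneEmbed <- function(D2, perplexity = 30, maxIter = 300, seed = 1L,
                      eta = 200) {
  n <- nrow(D2)
  P <- tsneCondP(D2, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  exaggerate <- min(100L, ceiling(maxIter / 3))
  withSeed(seed, {
    Y <- matrix(rnorm(n * 2, sd = 1e-4), n, 2)
    V <- matrix(0, n, 2)
    gains <- matrix(1, n, 2)
    for (it in seq_len(maxIter)) {
      Pe <- if (it <= exaggerate) P * 12 else P
      D2y <- as.matrix(dist(Y))^2
      num <- 1 / (1 + D2y); diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      W <- (Pe - Q) * num
      G <- 4 * (rowSums(W) * Y - W %*% Y)
      mom <- if (it <= exaggerate) 0.5 else 0.8
      gains <- ifelse(sign(G) != sign(V), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      V <- mom * V - eta * gains * G
      Y <- Y + V
      Y <- sweep(Y, 2, colMeans(Y), "-")
    }
    Y
  })
}

# Smooth kNN calibration: per point, sigma solves
# sum_j exp(-max(0, d_ij - rho_i) / sigma) = log2(k).
umapGraph <- function(D, nNeighbors) {
  n <- nrow(D)
  k <- min(nNeighbors, n - 1L)
  target <- log2(k)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- D[i, -i]
    ord <- order(di)[seq_len(k)]
    dk <- di[ord]
    rho <- if (any(dk > 0)) min(dk[dk > 0]) else 0
    lo <- 1e-6; hi <- 1e3
    for (it in 1:50) {
      sigma <- (lo + hi) / 2
      s <- sum(exp(-pmax(dk - rho, 0) / sigma))
      if (abs(s - target) < 1e-5) break
      if (s > target) hi <- sigma else lo <- sigma
    }
    P[i, seq_len(n)[-i][ord]] <- exp(-pmax(dk - rho, 0) / sigma)
  }
  P + t(P) - P * t(P)  # fuzzy set union
}

# Fit the low-dimensional kernel 1/(1 + a d^(2b)) to the piecewise target
# curve induced by minDist.
umapAbParams <- function(minDist) {
  x <- seq(0.05, 3, length.out = 300)
  y <- ifelse(x <= minDist, 1, exp(-(x - minDist)))
  fit <- tryCatch(
    nls(y ~ 1 / (1 + a * x^(2 * b)), start = list(a = 1.6, b = 0.9),
        control = nls.control(maxiter = 200, warnOnly = TRUE)),
    error = function(e) NULL)
  if (is.null(fit)) return(c(a = 1.577, b = 0.8951))
  cf <- coef(fit)
  c(a = unname(cf["a"]), b = unname(cf["b"]))
}

umapEmbed <- function(D, nNeighbors = 15, minDist = 0.1, nEpochs = 200,
                      seed = 1L) {
  n <- nrow(D)
  P <- umapGraph(D, nNeighbors)
  ab <- umapAbParams(minDist)
  a <- ab[1]; b <- ab[2]
  # spectral-style init from the graph Laplacian, jittered for symmetry ties
  deg <- pmax(rowSums(P), 1e-12)
  L <- diag(n) - diag(1 / sqrt(deg)) %*% P %*% diag(1 / sqrt(deg))
  ev <- eigen(L, symmetric = TRUE)
  init <- ev$vectors[, n - seq_len(2), drop = FALSE]
  init <- scale(init) * 1
  withSeed(seed, {
    Y <- init + matrix(rnorm(n * 2, sd = 1e-3), n, 2)
    for (it in seq_len(nEpochs)) {
      alpha <- 0.5 * (1 - (it - 1) / nEpochs)
      D2y <- as.matrix(dist(Y))^2
      kern <- 1 / (1 + a * D2y^b)
      attract <- P * (2 * a * b * D2y^pmax(b - 1, 0)) * kern
      repel <- (1 - P) * (2 * b) / ((0.001 + D2y) * (1 + a * D2y^b))
      diag(attract) <- 0; diag(repel) <- 0
      W <- attract - repel
      G <- rowSums(W) * Y - W %*% Y
      G[G > 4] <- 4; G[G < -4] <- -4
      Y <- Y - alpha * G
      Y <- sweep(Y, 2, colMeans(Y), "-")
    }
    Y
  })
}

#' Embed taxa into two dimensions
#'
#' Projects per-taxon feature vectors (or a precomputed pairwise distance
#' matrix) onto a 2D plane with t-SNE or a UMAP-style optimizer, so that
#' functionally or co-abundantly similar taxa land close together. The
#' resulting coordinates are the sole input of the pixel layout. Exact
#' quadratic-cost implementations are used; both are deterministic given
#' `seed`.
#'
#' @param input taxa x feature matrix (e.g. from [buildFeatureMatrix()]) or
#'   a symmetric taxa x taxa distance matrix with zero diagonal (e.g. from
#'   [correlationDistance()] or [copheneticDistance()]); distances are
#'   auto-detected and honoured via the precomputed-distance pathway.
#' @param method "tsne" or "umap".
#' @param params list of method parameters: `perplexity` (default 30) and
#'   `maxIter` (300) for t-SNE; `nNeighbors` (15), `minDist` (0.1) and
#'   `nEpochs` (200) for umap.
#' @param seed integer seed.
#' @return n x 2 coordinate matrix, rownames = taxa, with attributes
#'   `method`, `params`, `seed` recording provenance.
#' @export
embedTaxa <- function(input, method = c("tsne", "umap"), params = list(),
                      seed = 1L) {
  method <- match.arg(method)
  input <- as.matrix(input)
  n <- nrow(input)
  if (n < 3L) stop("embedding needs at least 3 taxa")
  isDist <- nrow(input) == ncol(input) &&
    !is.null(rownames(input)) && !is.null(colnames(input)) &&
    identical(rownames(input), colnames(input)) &&
    isSymmetric(unname(input), tol = 1e-8) &&
    all(abs(diag(input)) < 1e-8)
  D <- if (isDist) input else as.matrix(dist(input))
  if (method == "tsne") {
    perplexity <- params$perplexity %||% 30
    maxIter <- params$maxIter %||% 300
    if (perplexity >= n)
      stop("perplexity (", perplexity, ") must be smaller than the number ",
           "of taxa (", n, "); lower --perplexity or add taxa")
    Y <- tsneEmbed(D^2, perplexity = perplexity, maxIter = maxIter,
                   seed = seed)
    usedParams <- list(perplexity = perplexity, maxIter = maxIter)
  } else {
    nNeighbors <- params$nNeighbors %||% 15
    minDist <- params$minDist %||% 0.1
    nEpochs <- params$nEpochs %||% 200
    Y <- umapEmbed(D, nNeighbors = nNeighbors, minDist = minDist,
                   nEpochs = nEpochs, seed = seed)
    usedParams <- list(nNeighbors = nNeighbors, minDist = minDist,
                       nEpochs = nEpochs)
  }
  rownames(Y) <- rownames(input)
  colnames(Y) <- c("dim1", "dim2")
  attr(Y, "method") <- method
  attr(Y, "params") <- usedParams
  attr(Y, "seed") <- as.integer(seed)
  attr(Y, "precomputedDistance") <- isDist
  Y
}

`%||%` <- function(a, b) if (is.null(a)) b else a
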