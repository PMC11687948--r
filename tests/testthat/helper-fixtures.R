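# Shared fixtures and independent oracles used across the suite.

# Small random relative-abundance matrix (taxa x samples).
randAbund <- function(nTaxa, nSamples, seed = 1) {
  set.seed(seed)
  m <- matrix(rexp(nTaxa * nSamples), nTaxa, nSamples,
              dimnames = list(sprintf("taxon_%03d", seq_len(nTaxa)),
                              sprintf("sample_%03d", seq_len(nSamples))))
  sweep(m, 2, colSums(m), "/")
}

# Brute-force pairwise correlation-distance oracle: element-by-element loop.
corDistOracle <- function(a, method) {
  n <- nrow(a)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    r <- suppressWarnings(cor(a[i, ], a[j, ], method = method))
    d[i, j] <- 1 - ifelse(is.na(r), 0, r)
  }
  d
}

# Independent cophenetic oracle: depth(i) + depth(j) - 2 * depth(LCA),
# computed by walking parent pointers built directly from the edge table.
copheneticOracle <- function(phy) {
  nTip <- length(phy$tip.label)
  parent <- integer(max(phy$edge))
  elen <- numeric(max(phy$edge))
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  elen[phy$edge[, 2]] <- phy$edge.length
  pathToRoot <- function(v) {
    nodes <- v; depth <- 0
    while (parent[v] != 0) {
      depth <- depth + elen[v]
      v <- parent[v]
      nodes <- c(nodes, v)
    }
    list(nodes = nodes, depth = depth)
  }
  depthOf <- function(v) pathToRoot(v)$depth
  d <- matrix(0, nTip, nTip, dimnames = list(phy$tip.label, phy$tip.label))
  for (i in seq_len(nTip)) for (j in seq_len(nTip)) {
    if (i >= j) next
    pi <- pathToRoot(i); pj <- pathToRoot(j)
    lca <- intersect(pi$nodes, pj$nodes)[1]
    d[i, j] <- d[j, i] <- pi$depth + pj$depth - 2 * depthOf(lca)
  }
  d
}

# Rotation-grid oracle for the minimum-area rectangle: axis-aligned bbox
# area minimized over 0..90 degrees in fine steps.
minRectAreaOracle <- function(pts, stepDeg = 0.01) {
  th <- seq(0, 90, by = stepDeg) * pi / 180
  x <- pts[, 1]; y <- pts[, 2]
  xr <- outer(x, cos(th)) + outer(y, sin(th))
  yr <- -outer(x, sin(th)) + outer(y, cos(th))
  w <- apply(xr, 2, max) - apply(xr, 2, min)
  h <- apply(yr, 2, max) - apply(yr, 2, min)
  min(w * h)
}

# Mean silhouette width for 2 clusters, written directly from its
# definition.
silhouetteMean <- function(coords, labels) {
  d <- as.matrix(dist(coords))
  n <- nrow(d)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]; own[i] <- FALSE
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Numeric gradient of a scalar-valued function of one array parameter.
numGrad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Quick strongly-separable image fixture: two classes whose signal lives in
# one image quadrant.
quadrantImages <- function(n = 40, H = 12, W = 12, seed = 1) {
  set.seed(seed)
  arr <- array(runif(H * W * n, 0, 0.2), c(H, W, n))
  labels <- rep(c("a", "b"), length.out = n)
  for (i in which(labels == "b"))
    arr[1:(H / 2), 1:(W / 2), i] <- arr[1:(H / 2), 1:(W / 2), i] + 0.6
  list(images = arr / max(arr), labels = labels)
}

# Replace the leaf at a mixed character/integer path in a nested list.
modifyListPath <- function(lst, path, value) {
  if (length(path) == 1L) { lst[[path[[1]]]] <- value; return(lst) }
  lst[[path[[1]]]] <- modifyListPath(lst[[path[[1]]]], path[-1], value)
  lst
}

# Fast column-wise extrema for wide matrices with few rows.
colMaxFast <- function(m) do.call(pmax, asplit(m, 1))
colMinFast <- function(m) do.call(pmin, asplit(m, 1))
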