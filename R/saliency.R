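# Grad-CAM saliency, class-level averaging, and back-projection through the
# PixelMap into per-taxon importance.

bilinearUpsample <- function(m, H, W) {
  hi <- nrow(m); wi <- ncol(m)
  if (hi == H && wi == W) return(m)
  coord <- function(nOut, nIn) {
    t <- (seq_len(nOut) - 0.5) * nIn / nOut - 0.5
    j0 <- floor(t); frac <- t - j0
    j0c <- pmin(pmax(j0, 0), nIn - 1)
    j1c <- pmin(j0 + 1, nIn - 1)
    frac[j0 < 0] <- 0; frac[j0 + 1 > nIn - 1] <- 0
    list(j0 = j0c + 1L, j1 = j1c + 1L, frac = frac)
  }
  rc <- coord(H, hi); cc <- coord(W, wi)
  r0 <- m[rc$j0, , drop = FALSE]; r1 <- m[rc$j1, , drop = FALSE]
  rows <- r0 * (1 - rc$frac) + r1 * rc$frac
  c0 <- rows[, cc$j0, drop = FALSE]; c1 <- rows[, cc$j1, drop = FALSE]
  sweep(c0, 2, 1 - cc$frac, "*") + sweep(c1, 2, cc$frac, "*")
}

nearestUpsample <- function(m, H, W) {
  ri <- pmin(pmax(ceiling(seq_len(H) * nrow(m) / H), 1L), nrow(m))
  ci <- pmin(pmax(ceiling(seq_len(W) * ncol(m) / W), 1L), ncol(m))
  m[ri, ci, drop = FALSE]
}

#' Gradient-based class saliency map for one sample
#'
#' Combines the chosen residual block's feature maps with the gradient of
#' the class score with respect to them, keeps the positive part, upsamples
#' to image resolution and normalizes to a maximum of 1 (all-zero maps stay
#' zero). Two weightings are available: `"elementwise"` (default) multiplies
#' gradient and activation location by location before summing channels —
#' the faithful attribution when the classification head has
#' position-specific weights, as this package's default flatten head does;
#' `"pooled"` is the classic formulation (channel weights = spatial mean of
#' the gradient), which is equivalent under a global-average-pooling head
#' but can misattribute under a flatten head.
#'
#' @param model a trained \linkS4class{AttentionCNN}.
#' @param image H x W matrix (one sample).
#' @param classIndex class to explain: index or label.
#' @param layer residual block index; -1 (default) means the last block.
#' @param upsample "bilinear" or "nearest".
#' @param method "elementwise" or "pooled" gradient weighting.
#' @return H x W saliency matrix in [0, 1] with attribute `class`.
#' @export
gradCAM <- function(model, image, classIndex, layer = -1L,
                    upsample = c("bilinear", "nearest"),
                    method = c("elementwise", "pooled")) {
  upsample <- match.arg(upsample)
  method <- match.arg(method)
  if (!model@trained) stop("model must be trained before computing saliency")
  if (is.character(classIndex))
    classIndex <- match(classIndex, model@classLevels)
  if (is.na(classIndex) || classIndex < 1L ||
      classIndex > length(model@classLevels))
    stop("invalid class index")
  nb <- length(model@blocks)
  if (layer < 0L) layer <- nb + 1L + layer
  if (layer < 1L || layer > nb) stop("invalid block index")
  x <- imagesToArray(image, model@inputDim)
  fw <- modelForward(model, x, training = FALSE)
  dLogits <- matrix(0, 1, length(model@classLevels))
  dLogits[1, classIndex] <- 1
  bw <- modelBackward(model, fw, dLogits, stopAtBlock = layer)
  A <- fw$blockOut[[layer]]          # h x w x 1 x C
  dA <- bw$dAtBlock
  d <- dim(A); m <- d[1] * d[2]; C <- d[4]
  Am <- A; dim(Am) <- c(m, C)
  dAm <- dA; dim(dAm) <- c(m, C)
  cam <- if (method == "pooled") pmax(Am %*% colMeans(dAm), 0)
  else pmax(rowSums(Am * dAm), 0)
  dim(cam) <- c(d[1], d[2])
  up <- if (upsample == "bilinear")
    bilinearUpsample(cam, model@inputDim[1], model@inputDim[2])
  else nearestUpsample(cam, model@inputDim[1], model@inputDim[2])
  mx <- max(up)
  if (mx > 0) up <- up / mx
  attr(up, "class.label") <- model@classLevels[classIndex]
  up
}

#' Average class saliency over all samples of a class
#'
#' Per-sample Grad-CAM maps (each normalized to max 1) are arithmetically
#' averaged over every sample carrying `classValue`, then renormalized to
#' max 1 — highlighting regions that drive the class decision across
#' samples rather than in any single one.
#'
#' @param model a trained \linkS4class{AttentionCNN}.
#' @param images \linkS4class{ImageStack} or H x W x N array.
#' @param labels class label per sample.
#' @param classValue the class whose samples are averaged.
#' @param layer,upsample,method passed to [gradCAM()].
#' @return H x W saliency matrix in [0, 1] with attributes `class` and
#'   `nSamples`.
#' @export
classSaliency <- function(model, images, labels, classValue, layer = -1L,
                          upsample = "bilinear", method = "elementwise") {
  labels <- as.character(labels)
  idx <- which(labels == as.character(classValue))
  if (!length(idx)) stop("no samples with class ", sQuote(classValue))
  arr <- if (is(images, "ImageStack")) images@data else images
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  acc <- 0
  for (i in idx)
    acc <- acc + gradCAM(model, arr[, , i], classValue, layer, upsample,
                         method)
  avg <- acc / length(idx)
  mx <- max(avg)
  if (mx > 0) avg <- avg / mx
  attr(avg, "class.label") <- as.character(classValue)
  attr(avg, "nSamples") <- length(idx)
  avg
}

#' Occlusion saliency (reference method)
#'
#' Drop in the class probability when each pixel is zeroed in turn — an
#' independent, model-agnostic check of gradient-based saliency.
#'
#' @param model a trained \linkS4class{AttentionCNN}.
#' @param image H x W matrix.
#' @param classIndex class index or label.
#' @return H x W matrix of probability drops (can be negative).
#' @export
occlusionSaliency <- function(model, image, classIndex) {
  if (is.character(classIndex))
    classIndex <- match(classIndex, model@classLevels)
  base <- predictProb(model, image)[1, classIndex]
  H <- nrow(image); W <- ncol(image)
  out <- matrix(0, H, W)
  for (i in seq_len(H)) for (j in seq_len(W)) {
    if (image[i, j] == 0) next  # empty pixel: occlusion is a no-op
    im2 <- image; im2[i, j] <- 0
    out[i, j] <- base - predictProb(model, im2)[1, classIndex]
  }
  out
}

#' Back-project a saliency map into per-taxon importance
#'
#' Every taxon receives the saliency value of its pixel; taxa sharing a
#' pixel therefore receive identical scores (the model cannot distinguish
#' co-located taxa), and the shared-pixel count records that ambiguity.
#'
#' @param sal H x W saliency matrix (from [classSaliency()] or [gradCAM()]).
#' @param pmap the \linkS4class{PixelMap} the images were rendered with.
#' @return a \linkS4class{TaxaImportance} (nothing selected yet).
#' @export
taxaImportance <- function(sal, pmap) {
  stopifnot(is(pmap, "PixelMap"))
  if (nrow(sal) != pmap@height || ncol(sal) != pmap@width)
    stop("saliency dims ", nrow(sal), "x", ncol(sal),
         " do not match PixelMap ", pmap@height, "x", pmap@width)
  score <- sal[cbind(pmap@pixelRow, pmap@pixelCol)]
  key <- paste(pmap@pixelRow, pmap@pixelCol, sep = ",")
  shared <- as.integer(table(key)[key])
  new("TaxaImportance", taxa = pmap@taxa,
      classLabel = attr(sal, "class.label") %||% "unknown",
      score = pmin(pmax(as.numeric(score), 0), 1),
      selected = rep(FALSE, length(score)), sharedPixelCount = shared)
}

#' Partition taxa into important and unimportant sets
#'
#' A taxon is important when its score reaches the given percentile of the
#' nonzero scores (ties at the threshold are included, so with all-equal
#' nonzero scores every scoring taxon is selected).
#'
#' @param imp a \linkS4class{TaxaImportance}.
#' @param percentile percentile of nonzero scores in [0, 100).
#' @return the \linkS4class{TaxaImportance} with its `selected` flag set;
#'   use [importantTaxa()] for the two taxon sets.
#' @export
selectImportant <- function(imp, percentile = 90) {
  stopifnot(is(imp, "TaxaImportance"))
  if (percentile < 0 || percentile >= 100)
    stop("percentile must lie in [0, 100)")
  nz <- imp@score[imp@score > 0]
  if (!length(nz)) {
    imp@selected <- rep(FALSE, length(imp@score))
    return(imp)
  }
  thr <- as.numeric(quantile(nz, percentile / 100))
  imp@selected <- imp@score >= thr & imp@score > 0
  imp
}

#' Important / unimportant taxa of a selection
#' @param imp a \linkS4class{TaxaImportance} after [selectImportant()].
#' @return list with `important` and `unimportant` character vectors
#'   (exhaustive, disjoint).
#' @export
importantTaxa <- function(imp) {
  list(important = imp@taxa[imp@selected],
       unimportant = imp@taxa[!imp@selected])
}

#' Common and group-unique taxa across importance sets
#'
#' @param sets named list (>= 2) of character vectors of important taxa,
#'   e.g. one per cohort.
#' @return list with `common` (intersection over all groups) and `unique`
#'   (per group: its taxa absent from every other group).
#' @export
commonUniquePartition <- function(sets) {
  if (length(sets) < 2L) stop("at least two groups are required")
  common <- Reduce(intersect, sets)
  uniq <- lapply(seq_along(sets), function(g) {
    others <- unique(unlist(sets[-g]))
    setdiff(sets[[g]], others)
  })
  names(uniq) <- names(sets)
  list(common = common, unique = uniq)
}
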