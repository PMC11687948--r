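#' @import methods
#' @importFrom stats quantile rgamma rbinom rnorm runif rmultinom sd cor
#'   wilcox.test p.adjust median prcomp dist t.test setNames nls
#'   nls.control coef
#' @importFrom utils read.delim write.table head
NULL

#' Simulation parameters for the microbiome count generator
#'
#' Holds every knob of the sparse compositional count simulator: community
#' template, per-taxon variability, differential-abundance (DA) spike, target
#' sparsity and sampling depth. Construct with [simParams()].
#'
#' @slot nTaxa number of taxa simulated.
#' @slot nPerClass samples generated per class.
#' @slot nClasses number of phenotype classes (>= 2).
#' @slot librarySize reads per sample; column sums of the count matrix.
#' @slot templateIntensity expected relative abundance per taxon (sums to 1).
#' @slot variabilityCV per-taxon coefficient of variation of the gamma
#'   intensity noise.
#' @slot daIndices indices of the differentially abundant taxa.
#' @slot foldChange multiplicative effect applied to DA taxa in case classes.
#' @slot targetSparsity desired expected fraction of zero cells, in [0, 1).
#' @slot cohorts number of cohort levels crossed with phenotype (1 = none).
#' @slot cohortSigma lognormal sigma of cohort-specific template perturbation.
#' @slot urnFactor urn size as a multiple of librarySize for the
#'   without-replacement draw; at >= 100 a multinomial draw is used.
#' @slot seed integer seed making the simulation reproducible.
#' @export
setClass("SimParams", representation(
  nTaxa = "integer", nPerClass = "integer", nClasses = "integer",
  librarySize = "integer", templateIntensity = "numeric",
  variabilityCV = "numeric", daIndices = "integer", foldChange = "numeric",
  targetSparsity = "numeric", cohorts = "integer", cohortSigma = "numeric",
  urnFactor = "numeric", seed = "integer"))

setValidity("SimParams", function(object) {
  msg <- character()
  if (object@nTaxa < 1L) msg <- c(msg, "nTaxa must be positive")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (length(object@templateIntensity) != object@nTaxa)
    msg <- c(msg, "templateIntensity length must equal nTaxa")
  if (abs(sum(object@templateIntensity) - 1) > 1e-9)
    msg <- c(msg, "templateIntensity must sum to 1")
  if (any(object@templateIntensity < 0))
    msg <- c(msg, "templateIntensity must be nonnegative")
  if (length(object@variabilityCV) != object@nTaxa)
    msg <- c(msg, "variabilityCV length must equal nTaxa")
  if (any(object@variabilityCV < 0)) msg <- c(msg, "variabilityCV must be >= 0")
  if (length(object@daIndices) &&
      (min(object@daIndices) < 1L || max(object@daIndices) > object@nTaxa))
    msg <- c(msg, "daIndices out of range")
  if (object@foldChange <= 0) msg <- c(msg, "foldChange must be > 0")
  if (object@targetSparsity < 0 || object@targetSparsity >= 1)
    msg <- c(msg, "targetSparsity must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Fixed taxon-to-pixel layout shared by all sample images
#'
#' The dataset-wide assignment of each taxon to one pixel of an H x W image,
#' obtained by rotating the 2D taxa embedding into its minimum-area enclosing
#' rectangle and binning. The same map is applied to every sample so that a
#' pixel always represents the same taxa.
#'
#' @slot taxa taxon identifiers, one per mapped taxon.
#' @slot pixelRow,pixelCol 1-based pixel coordinates per taxon.
#' @slot height,width image dimensions in pixels.
#' @slot theta rotation angle (radians) of the minimum-area rectangle.
#' @slot corners 4 x 2 matrix of rectangle corner coordinates.
#' @slot embedding the n x 2 coordinates the map was built from.
#' @slot method embedding method tag ("tsne" or "umap").
#' @slot params embedding parameters and seed, kept for provenance.
#' @export
setClass("PixelMap", representation(
  taxa = "character", pixelRow = "integer", pixelCol = "integer",
  height = "integer", width = "integer", theta = "numeric",
  corners = "matrix", embedding = "matrix", method = "character",
  params = "list"))

setValidity("PixelMap", function(object) {
  n <- length(object@taxa)
  msg <- character()
  if (length(object@pixelRow) != n || length(object@pixelCol) != n)
    msg <- c(msg, "pixel coordinates must have one entry per taxon")
  if (anyDuplicated(object@taxa)) msg <- c(msg, "duplicated taxon ids")
  if (n && (min(object@pixelRow) < 1L || max(object@pixelRow) > object@height))
    msg <- c(msg, "pixelRow out of bounds")
  if (n && (min(object@pixelCol) < 1L || max(object@pixelCol) > object@width))
    msg <- c(msg, "pixelCol out of bounds")
  if (length(msg)) msg else TRUE
})

#' Stack of per-sample single-channel images
#'
#' Rasterized relative-abundance images, one H x W slice per sample, together
#' with the global normalization constant (maximum pixel value over the
#' training set) that scales all values into [0, 1].
#'
#' @slot data numeric array H x W x n_samples.
#' @slot sampleIds sample identifiers along the third dimension.
#' @slot normMax global maximum pixel value used for normalization.
#' @slot normalized whether `data` has been divided by `normMax`.
#' @export
setClass("ImageStack", representation(
  data = "array", sampleIds = "character", normMax = "numeric",
  normalized = "logical"))

setValidity("ImageStack", function(object) {
  d <- dim(object@data)
  msg <- character()
  if (length(d) != 3L) msg <- c(msg, "data must be an H x W x n array")
  if (length(object@sampleIds) != d[3])
    msg <- c(msg, "sampleIds must match the third dimension")
  if (any(object@data < 0)) msg <- c(msg, "image values must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Residual spatial-attention CNN
#'
#' A residual convolutional network whose blocks each carry a spatial
#' attention gate, specified as a list of `(nFilters, kernelSize, stride)`
#' block specs. Built untrained by [buildModel()] and fitted by
#' [trainModel()].
#'
#' @slot blocks list of block specs (see [blockSpec()]).
#' @slot stemFilters channels of the stem convolution.
#' @slot attentionKernel kernel size of the spatial-attention convolution.
#' @slot inputDim image height and width the model expects.
#' @slot classLevels class labels in fixed output order.
#' @slot params learned parameters (nested list of arrays).
#' @slot history per-epoch training history (data.frame).
#' @slot trained whether [trainModel()] has been run.
#' @slot normMax image normalization constant the model was trained with.
#' @export
setClass("AttentionCNN", representation(
  blocks = "list", stemFilters = "integer", attentionKernel = "integer",
  inputDim = "integer", classLevels = "character", params = "list",
  history = "data.frame", trained = "logical", normMax = "numeric"))

#' Per-taxon, per-class saliency-derived importance
#'
#' Back-projection of an averaged class saliency map through a [PixelMap]:
#' every taxon inherits the saliency of its pixel, so co-located taxa tie by
#' construction (the shared-pixel count records that ambiguity).
#'
#' @slot taxa taxon identifiers.
#' @slot classLabel class label the scores explain.
#' @slot score saliency score in [0, 1] per taxon.
#' @slot selected logical flag set by [selectImportant()].
#' @slot sharedPixelCount number of taxa sharing each taxon's pixel.
#' @export
setClass("TaxaImportance", representation(
  taxa = "character", classLabel = "character", score = "numeric",
  selected = "logical", sharedPixelCount = "integer"))

setValidity("TaxaImportance", function(object) {
  n <- length(object@taxa)
  if (length(object@score) != n || length(object@selected) != n ||
      length(object@sharedPixelCount) != n)
    return("all per-taxon slots must have equal length")
  if (n && (min(object@score) < 0 || max(object@score) > 1 + 1e-12))
    return("scores must lie in [0, 1]")
  TRUE
})
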