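#' Taxon identifiers of an object
#' @param x a \linkS4class{PixelMap} or \linkS4class{TaxaImportance}.
#' @return character vector of taxon ids.
#' @export
setGeneric("taxaIds", function(x) standardGeneric("taxaIds"))

#' Image dimensions (height, width)
#' @param x a \linkS4class{PixelMap} or \linkS4class{ImageStack}.
#' @return integer vector `c(H, W)`.
#' @export
setGeneric("imageDims", function(x) standardGeneric("imageDims"))

#' Pixel -> taxa inverse index
#' @param x a \linkS4class{PixelMap}.
#' @return named list mapping "row,col" keys to character vectors of taxa.
#' @export
setGeneric("inverseIndex", function(x) standardGeneric("inverseIndex"))

#' @rdname taxaIds
#' @export
setMethod("taxaIds", "PixelMap", function(x) x@taxa)

#' @rdname taxaIds
#' @export
setMethod("taxaIds", "TaxaImportance", function(x) x@taxa)

#' @rdname imageDims
#' @export
setMethod("imageDims", "PixelMap", function(x) c(x@height, x@width))

#' @rdname imageDims
#' @export
setMethod("imageDims", "ImageStack", function(x) dim(x@data)[1:2])

#' @rdname inverseIndex
#' @export
setMethod("inverseIndex", "PixelMap", function(x) {
  key <- paste(x@pixelRow, x@pixelCol, sep = ",")
  split(x@taxa, key)
})

setMethod("show", "PixelMap", function(object) {
  n <- length(object@taxa)
  npix <- length(unique(paste(object@pixelRow, object@pixelCol)))
  cat("PixelMap:", n, "taxa on a", object@height, "x", object@width,
      "grid (", npix, "occupied pixels,",
      sprintf("max %d taxa/pixel )\n", maxPixelLoad(object)))
  cat("  embedding:", object@method,
      "| rectangle angle:", sprintf("%.2f deg\n", object@theta * 180 / pi))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat("ImageStack:", d[3], "samples of", d[1], "x", d[2], "pixels;",
      if (object@normalized) "normalized" else "raw",
      sprintf("(normMax = %.4g)\n", object@normMax))
})

setMethod("show", "AttentionCNN", function(object) {
  cat("AttentionCNN:", length(object@blocks), "residual block(s) on",
      object@inputDim[1], "x", object@inputDim[2], "input ->",
      length(object@classLevels), "classes",
      if (object@trained) "[trained]\n" else "[untrained]\n")
  for (b in object@blocks)
    cat(sprintf("  block: %d filters, kernel %d, stride %d\n",
                b$nFilters, b$kernelSize, b$stride))
})

setMethod("show", "TaxaImportance", function(object) {
  cat("TaxaImportance for class", sQuote(object@classLabel), ":",
      length(object@taxa), "taxa,", sum(object@selected), "selected\n")
})

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nTaxa, "taxa,", object@nClasses, "classes x",
      object@nPerClass, "samples, library", object@librarySize, "\n")
  cat(sprintf("  %d DA taxa at fold change %.2f; target sparsity %.2f\n",
              length(object@daIndices), object@foldChange,
              object@targetSparsity))
})

#' Largest number of taxa sharing one pixel
#' @param x a \linkS4class{PixelMap}.
#' @return integer scalar.
#' @export
maxPixelLoad <- function(x) {
  stopifnot(is(x, "PixelMap"))
  if (!length(x@taxa)) return(0L)
  max(lengths(inverseIndex(x)))
}

#' Convert a TaxaImportance to a data.frame
#' @param x a \linkS4class{TaxaImportance}.
#' @param ... unused.
#' @return data.frame with columns taxon, class, score, selected,
#'   shared_pixel_count.
#' @export
setMethod("as.data.frame", "TaxaImportance", function(x, ...) {
  data.frame(taxon = x@taxa, class = x@classLabel, score = x@score,
             selected = x@selected, shared_pixel_count = x@sharedPixelCount,
             stringsAsFactors = FALSE)
})
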