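#' Render each sample as a single-channel image
#'
#' Every pixel takes the sum of the relative abundances of the taxa mapped
#' to it (summing preserves compositional mass: before normalization each
#' image sums to 1), and the whole stack is divided by a single global
#' maximum pixel value. When `normMax` is supplied (the constant stored from
#' a training set) it is reused, keeping train and test images on one scale.
#'
#' @param abund taxa x sample matrix of counts or relative abundances, or a
#'   SummarizedExperiment; columns are normalized to sum to 1.
#' @param pmap a \linkS4class{PixelMap}; its taxa must match the abundance
#'   rows exactly.
#' @param normMax optional normalization constant to reuse; computed from
#'   this stack when NULL.
#' @return an \linkS4class{ImageStack}.
#' @export
renderImages <- function(abund, pmap, normMax = NULL) {
  stopifnot(is(pmap, "PixelMap"))
  a <- relAbundance(abund)
  extra <- setdiff(rownames(a), pmap@taxa)
  if (length(extra))
    stop("taxa missing from PixelMap: ", paste(head(extra, 10),
         collapse = ", "), if (length(extra) > 10) " ...")
  missing <- setdiff(pmap@taxa, rownames(a))
  if (length(missing))
    stop("PixelMap taxa absent from abundance table: ",
         paste(head(missing, 10), collapse = ", "),
         if (length(missing) > 10) " ...")
  a <- a[pmap@taxa, , drop = FALSE]
  H <- pmap@height; W <- pmap@width
  pix <- (pmap@pixelCol - 1L) * H + pmap@pixelRow  # column-major linear index
  sums <- rowsum(a, group = pix)                   # occupied pixels x samples
  img <- matrix(0, H * W, ncol(a))
  img[as.integer(rownames(sums)), ] <- sums
  stack <- array(img, dim = c(H, W, ncol(a)))
  if (is.null(normMax)) normMax <- max(stack)
  if (normMax <= 0) normMax <- 1
  new("ImageStack", data = stack / normMax,
      sampleIds = colnames(a) %||% sprintf("sample_%04d", seq_len(ncol(a))),
      normMax = as.numeric(normMax), normalized = TRUE)
}

#' Undo image normalization
#'
#' @param stack an \linkS4class{ImageStack}.
#' @return the stack with raw pixel values (per-image sums of relative
#'   abundance, each summing to 1 over pixels).
#' @export
denormalize <- function(stack) {
  stopifnot(is(stack, "ImageStack"))
  if (!stack@normalized) return(stack)
  new("ImageStack", data = stack@data * stack@normMax,
      sampleIds = stack@sampleIds, normMax = stack@normMax,
      normalized = FALSE)
}
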