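# Tabular and tree I/O with schema validation and id-join diagnostics.

sniffDelim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read a taxa x sample abundance table
#'
#' TSV or CSV (delimiter sniffed), first column the taxon id, header the
#' sample ids. Integer tables are detected as counts, others as relative
#' abundances (a provenance note is logged); both are stored as the `counts`
#' assay and normalized on demand via [relAbundance()].
#'
#' @param path file path.
#' @return SummarizedExperiment with assay `counts` and
#'   `metadata()$abundanceType` in `c("counts", "relative")`.
#' @export
readAbundance <- function(path) {
  delim <- sniffDelim(path)
  df <- read.delim(path, sep = delim, check.names = FALSE,
                   stringsAsFactors = FALSE)
  taxa <- as.character(df[[1]])
  dup <- unique(taxa[duplicated(taxa)])
  if (length(dup))
    stop("duplicated taxon id(s): ", paste(dup, collapse = ", "))
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!is.finite(suppressWarnings(
    matrix(as.numeric(m), nrow(m), ncol(m)))), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-numeric abundance at row ", taxa[bad[1, 1]], ", column ",
         colnames(m)[bad[1, 2]])
  mode(m) <- "numeric"
  rownames(m) <- taxa
  type <- if (all(abs(m - round(m)) < 1e-9)) "counts" else "relative"
  stageLog("read ", nrow(m), " taxa x ", ncol(m), " samples (detected as ",
           type, ")")
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = m),
    metadata = list(abundanceType = type, source = path))
}

#' Write a taxa x sample abundance table as TSV
#' @param x SummarizedExperiment or matrix.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeAbundance <- function(x, path) {
  m <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else as.matrix(x)
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample label table
#'
#' Two or three tab-separated columns: sample_id, phenotype and optionally
#' cohort. When `sampleIds` is given the file must cover exactly those
#' samples.
#'
#' @param path file path.
#' @param sampleIds optional expected sample ids.
#' @return data.frame with columns sample_id, phenotype (and cohort).
#' @export
readLabels <- function(path, sampleIds = NULL) {
  df <- read.delim(path, sep = sniffDelim(path), stringsAsFactors = FALSE)
  names(df)[1:2] <- c("sample_id", "phenotype")
  if (ncol(df) >= 3L) names(df)[3] <- "cohort"
  if (!is.null(sampleIds)) {
    extra <- setdiff(df$sample_id, sampleIds)
    if (length(extra))
      stop("labels given for unknown sample(s): ",
           paste(head(extra, 10), collapse = ", "))
    missing <- setdiff(sampleIds, df$sample_id)
    if (length(missing))
      stop("samples without labels: ", paste(head(missing, 10),
                                             collapse = ", "))
    df <- df[match(sampleIds, df$sample_id), , drop = FALSE]
  }
  df
}

#' Read a taxa x metabolite annotation table
#'
#' First column taxon id, header metabolite ids. With `taxaIds` given, the
#' table is silently row-subset to those taxa (superset tables are fine; the
#' number of taxa without annotations is logged).
#'
#' @param path file path.
#' @param taxaIds optional taxa to subset to.
#' @return numeric taxa x metabolite matrix.
#' @export
readAnnotations <- function(path, taxaIds = NULL) {
  df <- read.delim(path, sep = sniffDelim(path), check.names = FALSE,
                   stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1]])
  if (any(m < 0, na.rm = TRUE)) stop("annotation weights must be nonnegative")
  if (!is.null(taxaIds)) {
    missing <- setdiff(taxaIds, rownames(m))
    if (length(missing))
      stageLog(length(missing), " taxa have no annotation rows")
    m <- m[intersect(taxaIds, rownames(m)), , drop = FALSE]
  }
  m
}

#' Read a functional-trait table
#' @param path TSV with columns taxon, gram, motility, oxygen, gene_count.
#' @return data.frame.
#' @export
readTraits <- function(path) {
  df <- read.delim(path, sep = sniffDelim(path), stringsAsFactors = FALSE)
  names(df)[1] <- "taxon"
  df
}

#' Write a functional-trait table
#' @param traits data.frame from [simulateTraits()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTraits <- function(traits, path) {
  write.table(traits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a newick tree
#' @param path newick file path.
#' @return an [ape::phylo] tree.
#' @export
readTree <- function(path) {
  phy <- tryCatch(ape::read.tree(path), error = function(e) NULL)
  if (is.null(phy)) stop("malformed newick file: ", path)
  phy
}

#' Serialize a PixelMap as TSV plus a JSON sidecar
#'
#' The TSV carries (taxon_id, row, col); the sidecar records the image size,
#' rectangle angle and corners, and the embedding method, parameters and
#' seed, so the layout is fully regenerable.
#'
#' @param pmap a \linkS4class{PixelMap}.
#' @param path TSV path; the sidecar is written at `<path>.json`.
#' @param extra optional named list merged into the sidecar (e.g. the image
#'   normalization constant).
#' @return invisibly, the TSV path.
#' @export
writePixelMap <- function(pmap, path, extra = list()) {
  stopifnot(is(pmap, "PixelMap"))
  write.table(data.frame(taxon_id = pmap@taxa, row = pmap@pixelRow,
                         col = pmap@pixelCol),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  side <- c(list(height = pmap@height, width = pmap@width,
                 theta = pmap@theta,
                 corners = unname(apply(pmap@corners, 1, as.numeric,
                                        simplify = FALSE)),
                 method = pmap@method, params = pmap@params), extra)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read back a serialized PixelMap
#' @param path TSV path written by [writePixelMap()].
#' @return a \linkS4class{PixelMap} (embedding coordinates are not
#'   round-tripped; the slot holds pixel centers).
#' @export
readPixelMap <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  new("PixelMap", taxa = as.character(df$taxon_id),
      pixelRow = as.integer(df$row), pixelCol = as.integer(df$col),
      height = as.integer(side$height), width = as.integer(side$width),
      theta = as.numeric(side$theta),
      corners = matrix(unlist(side$corners), ncol = 2, byrow = TRUE),
      embedding = cbind(as.numeric(df$col), as.numeric(df$row)),
      method = side$method %||% "unknown",
      params = as.list(side$params %||% list()))
}

#' Write a saliency map or image as a PNG heatmap
#'
#' Optional convenience output (requires the \pkg{png} package); values are
#' mapped to a dark-to-bright single-channel ramp.
#'
#' @param m numeric matrix in [0, 1].
#' @param path output PNG path.
#' @return invisibly TRUE if written, FALSE if \pkg{png} is unavailable.
#' @export
writeHeatmapPNG <- function(m, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stageLog("png package not available; skipping ", path)
    return(invisible(FALSE))
  }
  m <- pmin(pmax(m, 0), 1)
  png::writePNG(m, path)
  invisible(TRUE)
}
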