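#' Correlation distance between taxa abundance profiles
#'
#' Distance `d(i, j) = 1 - r(i, j)` where `r` is the Pearson or Spearman
#' correlation of the two taxa's abundance profiles across samples. Taxa with
#' zero variance carry no co-occurrence information; they receive the
#' maximal uninformative distance 1 (the r = 0 convention) to every other
#' taxon so downstream embedding never sees missing values.
#'
#' @param abund taxa x sample relative-abundance matrix (rownames = taxa) or
#'   a SummarizedExperiment with a `counts` assay.
#' @param method "pearson" or "spearman".
#' @return symmetric taxa x taxa distance matrix in [0, 2], zero diagonal;
#'   attribute `zeroVarTaxa` lists the flagged taxa.
#' @export
correlationDistance <- function(abund, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  a <- relAbundance(abund)
  if (ncol(a) < 3L) stop("correlation distance needs at least 3 samples")
  v <- apply(a, 1, sd)
  zv <- !is.finite(v) | v < 1e-12  # numerically constant profiles included
  r <- suppressWarnings(cor(t(a), method = method))
  r[zv, ] <- 0; r[, zv] <- 0
  d <- 1 - r
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(rownames(a), rownames(a))
  attr(d, "zeroVarTaxa") <- rownames(a)[zv]
  d
}

#' Cophenetic distance from a phylogenetic tree
#'
#' Patristic/cophenetic distance: the sum of branch lengths along the tree
#' path between every pair of leaves. Parsing and the distance itself are
#' delegated to \pkg{ape}; missing branch lengths are treated as 1 (with a
#' message), duplicate leaf labels are an error.
#'
#' @param tree an [ape::phylo] object, a newick string, or a path to a
#'   newick file.
#' @return symmetric leaf x leaf distance matrix with zero diagonal.
#' @examples
#' copheneticDistance("(A:1,B:1);")["A", "B"]  # 2
#' @export
copheneticDistance <- function(tree) {
  phy <- if (inherits(tree, "phylo")) tree
  else if (is.character(tree) && length(tree) == 1L) {
    txt <- if (file.exists(tree)) paste(readLines(tree), collapse = "") else
      tree
    out <- tryCatch(suppressWarnings(ape::read.tree(text = txt)),
                    error = function(e) NULL)
    if (is.null(out)) stop("unparseable newick input")
    out
  } else stop("tree must be a phylo object, newick text, or a file path")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]),
               collapse = ", "))
  if (is.null(phy$edge.length)) {
    stageLog("tree has no branch lengths; treating every branch as length 1")
    phy$edge.length <- rep(1, nrow(phy$edge))
  }
  d <- ape::cophenetic.phylo(phy)
  d[phy$tip.label, phy$tip.label]
}

#' Build the per-taxon feature matrix driving the 2D embedding
#'
#' Three modes mirror the similarity sources compared in this workflow:
#' `metabolic` passes the annotation rows through untouched (the annotation
#' resource itself is the similarity, no further computation); `abundance`
#' standardizes each taxon's abundance profile across samples; `combined`
#' concatenates both blocks after column-wise z-scoring so neither dominates
#' by scale. Taxa lacking annotations are retained with all-zero metabolite
#' vectors (count logged) so the image layout covers every observed taxon.
#'
#' @param abund taxa x sample relative-abundance matrix or
#'   SummarizedExperiment; may be NULL in `metabolic` mode.
#' @param annot taxa x metabolite annotation matrix (rownames = taxa); may be
#'   NULL in `abundance` mode.
#' @param mode "metabolic", "abundance" or "combined".
#' @return taxa x feature numeric matrix with attribute `mode`.
#' @export
buildFeatureMatrix <- function(abund = NULL, annot = NULL,
                               mode = c("metabolic", "abundance",
                                        "combined")) {
  mode <- match.arg(mode)
  zscoreCols <- function(m) {
    mu <- colMeans(m); s <- apply(m, 2, sd)
    s[s == 0 | !is.finite(s)] <- 1  # constant columns stay zero, not NaN
    sweep(sweep(m, 2, mu, "-"), 2, s, "/")
  }
  if (mode == "metabolic") {
    if (is.null(annot)) stop("metabolic mode needs an annotation table")
    out <- as.matrix(annot)
    if (is.null(abund)) {
      taxa <- rownames(out)
    } else {
      taxa <- rownames(relAbundance(abund))
      missing <- setdiff(taxa, rownames(out))
      if (length(missing))
        stageLog(length(missing), " taxa lack annotations; zero vectors used")
      full <- matrix(0, length(taxa), ncol(out),
                     dimnames = list(taxa, colnames(out)))
      present <- intersect(taxa, rownames(out))
      full[present, ] <- out[present, , drop = FALSE]
      out <- full
    }
  } else if (mode == "abundance") {
    if (is.null(abund)) stop("abundance mode needs an abundance table")
    a <- relAbundance(abund)
    mu <- rowMeans(a); s <- apply(a, 1, sd)
    s[s == 0 | !is.finite(s)] <- 1
    out <- sweep(sweep(a, 1, mu, "-"), 1, s, "/")
  } else {
    if (is.null(abund) || is.null(annot))
      stop("combined mode needs both abundance and annotation tables")
    a <- relAbundance(abund)
    taxa <- intersect(rownames(a), rownames(annot))
    if (!length(taxa))
      stop("no taxa shared between abundance and annotation tables")
    missing <- setdiff(rownames(a), rownames(annot))
    if (length(missing))
      stageLog(length(missing), " taxa lack annotations; zero vectors used")
    annFull <- matrix(0, nrow(a), ncol(annot),
                      dimnames = list(rownames(a), colnames(annot)))
    annFull[taxa, ] <- as.matrix(annot)[taxa, , drop = FALSE]
    out <- zscoreCols(cbind(a, annFull))
    out[!is.finite(out)] <- 0
  }
  mode(out) <- "numeric"
  attr(out, "mode") <- mode
  out
}
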