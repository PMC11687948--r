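# Downstream interpretation: metabolite aggregation over important taxa,
# differential metabolite statistics, and functional-trait summaries.

#' Per-group metabolite sums over important taxa, percentile-filtered
#'
#' For each group, sums the annotation weights of that group's important
#' taxa per metabolite (with binary annotations this is the producer count)
#' and retains metabolites at or above the stated within-group percentile of
#' nonzero sums. Also reports the metabolites retained in every group.
#'
#' @param importantSets named list of character vectors of important taxa,
#'   one per group.
#' @param annot taxa x metabolite annotation matrix.
#' @param percentile within-group retention percentile (default 99); at 0
#'   every metabolite with a nonzero sum is retained.
#' @return list with `perGroup` (named numeric vectors of retained sums),
#'   `common` (metabolites retained in all groups) and `table` (long
#'   data.frame group/metabolite/sum).
#' @export
metaboliteSums <- function(importantSets, annot, percentile = 99) {
  annot <- as.matrix(annot)
  if (!is.list(importantSets)) importantSets <- list(group1 = importantSets)
  if (is.null(names(importantSets)))
    names(importantSets) <- paste0("group", seq_along(importantSets))
  perGroup <- lapply(names(importantSets), function(g) {
    taxa <- importantSets[[g]]
    missing <- setdiff(taxa, rownames(annot))
    if (length(missing))
      stageLog(length(missing), " important taxa of group ", g,
               " missing from annotations; dropped")
    taxa <- intersect(taxa, rownames(annot))
    if (!length(taxa)) {
      warning("group ", sQuote(g), " has no annotated important taxa")
      return(numeric(0))
    }
    sums <- colSums(annot[taxa, , drop = FALSE])
    nz <- sums[sums > 0]
    if (!length(nz)) return(numeric(0))
    thr <- as.numeric(quantile(nz, percentile / 100))
    sort(sums[sums >= thr & sums > 0], decreasing = TRUE)
  })
  names(perGroup) <- names(importantSets)
  common <- Reduce(intersect, lapply(perGroup, names))
  tab <- do.call(rbind, lapply(names(perGroup), function(g) {
    if (!length(perGroup[[g]])) return(NULL)
    data.frame(group = g, metabolite = names(perGroup[[g]]),
               sum = unname(perGroup[[g]]), stringsAsFactors = FALSE)
  }))
  list(perGroup = perGroup, common = common,
       table = tab %||% data.frame(group = character(),
                                   metabolite = character(),
                                   sum = numeric()))
}

#' Differential metabolites between important and unimportant taxa
#'
#' Per metabolite: log2 fold change of mean annotation weight between the
#' two taxa sets (with pseudocount), a rank-sum (or t-) test of the weights,
#' and Benjamini-Hochberg adjustment across metabolites. The returned
#' columns are sufficient to draw volcano (log2FC vs -log10 p) and MA (mean
#' vs log2FC) plots.
#'
#' @param important,unimportant character vectors of taxa (both nonempty).
#' @param annot taxa x metabolite annotation matrix.
#' @param eps pseudocount guarding the fold change.
#' @param test "ranksum" (Wilcoxon) or "ttest".
#' @return data.frame (one row per metabolite) with means, log2FC,
#'   statistic, pvalue, padj and meanExpr; attribute `lowPower` flags sets
#'   smaller than 2.
#' @export
differentialMetabolites <- function(important, unimportant, annot,
                                    eps = 1e-3,
                                    test = c("ranksum", "ttest")) {
  test <- match.arg(test)
  annot <- as.matrix(annot)
  important <- intersect(important, rownames(annot))
  unimportant <- intersect(unimportant, rownames(annot))
  if (!length(important) || !length(unimportant))
    stop("both taxa sets must be nonempty (after matching to annotations)")
  lowPower <- length(important) < 2L || length(unimportant) < 2L
  if (lowPower)
    stageLog("a taxa set has fewer than 2 members; statistics are low-power")
  A1 <- annot[important, , drop = FALSE]
  A0 <- annot[unimportant, , drop = FALSE]
  m1 <- colMeans(A1); m0 <- colMeans(A0)
  res <- lapply(seq_len(ncol(annot)), function(j) {
    if (test == "ranksum") {
      ht <- suppressWarnings(wilcox.test(A1[, j], A0[, j], exact = FALSE))
    } else {
      ht <- tryCatch(t.test(A1[, j], A0[, j]),
                     error = function(e) list(statistic = 0, p.value = 1))
    }
    c(stat = unname(ht$statistic), p = ht$p.value)
  })
  res <- do.call(rbind, res)
  p <- res[, "p"]; p[is.na(p)] <- 1
  data.frame(metabolite = colnames(annot),
             meanImportant = m1, meanUnimportant = m0,
             log2FC = log2((m1 + eps) / (m0 + eps)),
             statistic = res[, "stat"], pvalue = p,
             padj = p.adjust(p, "BH"),
             meanExpr = (m1 + m0) / 2,
             row.names = NULL, stringsAsFactors = FALSE) -> out
  attr(out, "lowPower") <- lowPower
  out
}

#' Functional-trait summary of taxa sets
#'
#' For each set (e.g. the common and per-group unique important taxa):
#' counts of every gram / motility / oxygen category — taxa absent from the
#' trait table count as "unknown", so category counts always sum to the set
#' size — and the median gene count over taxa with a known count.
#'
#' @param taxaSets named list of character vectors.
#' @param traits trait data.frame with columns taxon, gram, motility,
#'   oxygen, gene_count (as from [simulateTraits()] or [readTraits()]).
#' @return named list; per set: `n`, tables `gram`, `motility`, `oxygen`,
#'   and `medianGeneCount` (NA for an empty set or no known counts).
#' @export
traitSummary <- function(taxaSets, traits) {
  if (!is.list(taxaSets)) taxaSets <- list(set1 = taxaSets)
  if (is.null(names(taxaSets)))
    names(taxaSets) <- paste0("set", seq_along(taxaSets))
  vocab <- list(gram = c("positive", "negative", "unknown"),
                motility = c("motile", "non-motile", "unknown"),
                oxygen = c("aerobic", "anaerobic", "facultative", "unknown"))
  rownames(traits) <- traits$taxon
  lapply(taxaSets, function(taxa) {
    known <- intersect(taxa, traits$taxon)
    out <- list(n = length(taxa))
    for (tr in names(vocab)) {
      vals <- rep("unknown", length(taxa))
      vals[match(known, taxa)] <- as.character(traits[known, tr])
      vals[!vals %in% vocab[[tr]]] <- "unknown"
      out[[tr]] <- table(factor(vals, levels = vocab[[tr]]))
    }
    gc <- traits[known, "gene_count"]
    gc <- gc[!is.na(gc)]
    out$medianGeneCount <- if (length(gc)) median(gc) else NA_real_
    out
  })
}
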