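test_that("metabolite sums match a sort-and-threshold oracle per group", {
  taxa <- sprintf("t%03d", 1:200)
  ann <- simulateAnnotations(taxa, nMetabolites = 40, daIndices = 1:45,
                             seed = 71)
  set.seed(72)
  sets <- lapply(1:4, function(i) sample(taxa, 30))
  names(sets) <- paste0("g", 1:4)
  res <- metaboliteSums(sets, ann, percentile = 90)
  for (g in names(sets)) {
    sums <- colSums(ann[sets[[g]], ])
    nz <- sums[sums > 0]
    thr <- quantile(nz, 0.9)
    oracle <- sort(sums[sums >= thr & sums > 0], decreasing = TRUE)
    expect_equal(res$perGroup[[g]], oracle)
  }
  expect_equal(res$common,
               Reduce(intersect, lapply(res$perGroup, names)))

  # single taxon producing one metabolite: sum equals its weight
  tiny <- matrix(c(1, 0, 0, 0), 2, 2,
                 dimnames = list(c("ta", "tb"), c("m1", "m2")))
  r1 <- metaboliteSums(list(s = "ta"), tiny, percentile = 0)
  expect_equal(r1$perGroup$s, c(m1 = 1))

  # percentile 0 retains every nonzero-sum metabolite
  r0 <- metaboliteSums(sets["g1"], ann, percentile = 0)
  expect_equal(length(r0$perGroup$g1),
               sum(colSums(ann[sets$g1, ]) > 0))

  # retained set shrinks monotonically in the percentile
  ns <- vapply(c(0, 50, 90, 99), function(p)
    length(metaboliteSums(sets["g2"], ann, percentile = p)$perGroup$g2),
    integer(1))
  expect_true(all(diff(ns) <= 0))

  expect_warning(metaboliteSums(list(empty = character(0)), ann), "no annotated")
})

test_that("differential metabolites behave at the boundaries", {
  taxa <- sprintf("t%03d", 1:60)
  ann <- simulateAnnotations(taxa, nMetabolites = 15, daIndices = 1:20,
                             enrichment = 0.7, backgroundRate = 0.3,
                             seed = 73)
  # identical membership in both groups: log2FC identically zero
  res0 <- differentialMetabolites(taxa[1:30], taxa[1:30], ann)
  expect_true(all(res0$log2FC == 0))

  # metabolite produced only by the important set
  ann2 <- ann
  ann2[, 1] <- as.integer(seq_along(taxa) <= 20)
  res1 <- differentialMetabolites(taxa[1:20], taxa[21:60], ann2, eps = 1e-3)
  expect_equal(res1$log2FC[1], log2((1 + 1e-3) / 1e-3))
  expect_equal(which.min(res1$pvalue), 1L)
  expect_true(all(res1$padj >= res1$pvalue - 1e-15))
})

test_that("enriched signal metabolites top the adjusted-p ranking", {
  taxa <- sprintf("t%03d", 1:200)
  da <- 1:45
  ann <- simulateAnnotations(taxa, nMetabolites = 50, daIndices = da,
                             enrichment = 0.9, backgroundRate = 0.2,
                             nSignal = 10, seed = 74)
  res <- differentialMetabolites(taxa[da], taxa[-da], ann)
  # independent per-column recomputation
  for (j in c(1, 5, 30)) {
    w <- suppressWarnings(wilcox.test(ann[da, j], ann[-da, j],
                                      exact = FALSE))
    expect_equal(res$pvalue[j], w$p.value, tolerance = 1e-12)
    expect_equal(res$log2FC[j],
                 log2((mean(ann[da, j]) + 1e-3) /
                        (mean(ann[-da, j]) + 1e-3)), tolerance = 1e-12)
  }
  sig <- attr(ann, "signalMetabolites")
  topTen <- res$metabolite[order(res$padj)][1:10]
  expect_gte(length(intersect(topTen, sig)), 8)
})

test_that("trait summaries count every taxon and median gene counts", {
  traits <- data.frame(
    taxon = c("a", "b", "c", "d"),
    gram = c("positive", "negative", "unknown", "positive"),
    motility = c("motile", "non-motile", "motile", "unknown"),
    oxygen = c("aerobic", "anaerobic", "facultative", "aerobic"),
    gene_count = c(100L, 200L, 900L, NA))
  s <- traitSummary(list(s1 = c("a", "b", "c"), s2 = c("a", "zz"),
                         empty = character(0)), traits)
  expect_equal(s$s1$medianGeneCount, 200)
  expect_equal(sum(s$s1$gram), 3)
  expect_equal(unname(s$s2$gram["positive"]), 1)
  expect_equal(unname(s$s2$gram["unknown"]), 1)  # zz missing -> unknown
  expect_equal(sum(s$s2$oxygen), 2)
  expect_equal(s$empty$n, 0)
  expect_true(is.na(s$empty$medianGeneCount))

  # random sets against a hand-tabulated recount
  set.seed(75)
  taxa <- sprintf("t%02d", 1:40)
  tr <- simulateTraits(taxa, seed = 76)
  sets <- list(x = sample(taxa, 15), y = sample(taxa, 10))
  ss <- traitSummary(sets, tr)
  for (nm in names(sets)) {
    sub <- tr[match(sets[[nm]], tr$taxon), ]
    expect_equal(as.integer(ss[[nm]]$gram),
                 as.integer(table(factor(sub$gram,
                                         c("positive", "negative",
                                           "unknown")))))
    expect_equal(ss[[nm]]$medianGeneCount, median(sub$gene_count))
  }
})
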