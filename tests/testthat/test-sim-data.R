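test_that("spikeFoldChange renormalizes correctly and guards inputs", {
  # identity at fold 1
  tmpl <- c(0.2, 0.3, 0.5)
  expect_equal(spikeFoldChange(tmpl, c(1L, 3L), 1), tmpl)
  # two-taxon hand case
  expect_equal(spikeFoldChange(c(0.5, 0.5), 1L, 3), c(0.75, 0.25))
  # general renormalization against a hand-computed constant
  set.seed(42)
  t0 <- rexp(200); t0 <- t0 / sum(t0)
  da <- sample(200, 45)
  out <- spikeFoldChange(t0, da, 1.5)
  z <- sum(t0[-da]) + 1.5 * sum(t0[da])  # normalization constant
  expect_equal(out[da], 1.5 * t0[da] / z, tolerance = 1e-12)
  expect_equal(out[-da], t0[-da] / z, tolerance = 1e-12)
  expect_equal(sum(out), 1)
  expect_error(spikeFoldChange(t0, da, -1), "positive")
  expect_error(spikeFoldChange(t0, 500L, 2), "range")
})

test_that("simulated counts are exhaustive compositions of the library", {
  p <- simParams(nTaxa = 1L, nPerClass = 4L, librarySize = 1000L,
                 targetSparsity = 0, variabilityCV = 0, seed = 3)
  se <- simulateCounts(p)
  expect_true(all(SummarizedExperiment::assay(se) == 1000L))

  p2 <- simParams(nTaxa = 40L, nPerClass = 10L, librarySize = 5000L,
                  targetSparsity = 0.5, seed = 4)
  se2 <- simulateCounts(p2)
  expect_true(all(colSums(SummarizedExperiment::assay(se2)) == 5000L))
})

test_that("per-taxon mean relative abundance recovers the template", {
  p <- simParams(nTaxa = 30L, nPerClass = 400L, librarySize = 20000L,
                 variabilityCV = 0, targetSparsity = 0, seed = 5,
                 templateSigma = 1)
  se <- simulateCounts(p)
  a <- relAbundance(se)
  ctrl <- SummarizedExperiment::colData(se)$phenotype == "control"
  mn <- rowMeans(a[, ctrl])
  se3 <- 3 * apply(a[, ctrl], 1, sd) / sqrt(sum(ctrl))
  expect_true(all(abs(mn - p@templateIntensity) <= se3 + 1e-4))
})

test_that("realized sparsity tracks the target and is monotone", {
  p <- simParams(nTaxa = 200L, nPerClass = 250L, librarySize = 10000L,
                 targetSparsity = 0.84, seed = 6)
  se <- simulateCounts(p)  # 500 samples x 200 taxa
  z <- mean(SummarizedExperiment::assay(se) == 0)
  expect_lt(abs(z - 0.84), 0.03)

  reals <- vapply(c(0.3, 0.6, 0.84), function(t) {
    m <- SummarizedExperiment::assay(simulateCounts(
      simParams(nTaxa = 100L, nPerClass = 40L, targetSparsity = t,
                seed = 7)))
    mean(m == 0)
  }, numeric(1))
  expect_true(all(diff(reals) >= 0))
})

test_that("the generator is deterministic and type-I-safe at fold 1", {
  p <- simParams(nTaxa = 25L, nPerClass = 30L, seed = 11,
                 targetSparsity = 0.3)
  se1 <- simulateCounts(p); se2 <- simulateCounts(p)
  expect_identical(SummarizedExperiment::assay(se1),
                   SummarizedExperiment::assay(se2))

  # with no DA signal, two-sample tests reject at roughly nominal rate
  a <- relAbundance(se1)
  grp <- SummarizedExperiment::colData(se1)$phenotype
  pv <- apply(a, 1, function(x)
    suppressWarnings(wilcox.test(x[grp == "control"],
                                 x[grp == "case"])$p.value))
  expect_lt(mean(pv < 0.05, na.rm = TRUE), 0.25)
})

test_that("annotation simulation produces the designed enrichment", {
  taxa <- sprintf("t%03d", 1:200)
  da <- 1:45
  # forced construction
  ann <- simulateAnnotations(taxa, nMetabolites = 20, daIndices = da,
                             enrichment = 1, backgroundRate = 0,
                             nSignal = 5, seed = 2)
  sig <- attr(ann, "signalMetabolites")
  expect_true(all(ann[da, sig] == 1))
  expect_true(all(ann[-da, sig] == 0))
  expect_true(all(ann[, setdiff(colnames(ann), sig)] == 0))

  # odds ratio > 1 for every signal metabolite by direct 2x2 tabulation
  ann2 <- simulateAnnotations(taxa, nMetabolites = 50, daIndices = da,
                              enrichment = 0.9, backgroundRate = 0.2,
                              nSignal = 10, seed = 3)
  for (m in attr(ann2, "signalMetabolites")) {
    tab <- table(factor(seq_along(taxa) %in% da, c(TRUE, FALSE)),
                 factor(ann2[, m] == 1, c(TRUE, FALSE)))
    orr <- (tab[1, 1] * tab[2, 2]) / max(tab[1, 2] * tab[2, 1], 1)
    expect_gt(orr, 1)
  }
  expect_error(simulateAnnotations(taxa, daIndices = da, enrichment = 0.1,
                                   backgroundRate = 0.5), ">=")
})

test_that("trait simulation is deterministic with a closed vocabulary", {
  taxa <- sprintf("t%02d", 1:60)
  tr1 <- simulateTraits(taxa, seed = 9, geneCountRange = c(500L, 900L))
  tr2 <- simulateTraits(taxa, seed = 9, geneCountRange = c(500L, 900L))
  expect_identical(tr1, tr2)
  expect_true(all(tr1$gram %in% c("positive", "negative", "unknown")))
  expect_true(all(tr1$motility %in% c("motile", "non-motile", "unknown")))
  expect_true(all(tr1$oxygen %in% c("aerobic", "anaerobic", "facultative",
                                    "unknown")))
  expect_true(all(tr1$gene_count >= 500L & tr1$gene_count <= 900L))
})
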