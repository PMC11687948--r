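fitQuadrantModel <- function(n = 40, H = 12, seed = 61) {
  fx <- quadrantImages(n = n, H = H, W = H, seed = seed)
  m <- buildModel(list(blockSpec(4, 3, 1), blockSpec(8, 3, 2)),
                  nClasses = 2, H = H, W = H, stemFilters = 4,
                  attentionKernel = 3, classLevels = c("a", "b"))
  fit <- trainModel(m, fx$images, fx$labels,
                    trainConfig(epochs = 40, batchSize = 16, patience = 40,
                                learningRate = 3e-3, seed = seed))
  list(fit = fit, fx = fx)
}

test_that("Grad-CAM maps are valid and localize a quadrant signal", {
  q <- fitQuadrantModel()
  sal <- gradCAM(q$fit, q$fx$images[, , 2], "b")
  expect_equal(dim(sal), c(12L, 12L))
  expect_true(all(sal >= 0 & sal <= 1))

  # signal quadrant dominates, paired over 20 class-b samples
  idx <- which(q$fx$labels == "b")[1:20]
  insideWins <- vapply(idx, function(i) {
    s <- gradCAM(q$fit, q$fx$images[, , i], "b")
    mean(s[1:6, 1:6]) > mean(s[7:12, 7:12])
  }, logical(1))
  expect_gt(mean(insideWins), 0.5)

  # saliency correlates positively with occlusion probability drops
  rhos <- vapply(idx[1:8], function(i) {
    s <- gradCAM(q$fit, q$fx$images[, , i], "b")
    o <- occlusionSaliency(q$fit, q$fx$images[, , i], "b")
    suppressWarnings(cor(as.vector(s), as.vector(o), method = "spearman"))
  }, numeric(1))
  expect_gt(mean(rhos, na.rm = TRUE), 0)

  expect_error(gradCAM(q$fit, q$fx$images[, , 1], "zz"), "class")
  untrained <- buildModel(list(blockSpec(4, 3, 1)), 2, 12, 12,
                          attentionKernel = 3)
  expect_error(gradCAM(untrained, q$fx$images[, , 1], 1), "trained")
})

test_that("a head that ignores spatial input yields an all-zero map", {
  q <- fitQuadrantModel(n = 16, H = 8)
  fit <- q$fit
  fit@params$learn$head$W[] <- 0  # class score no longer depends on features
  sal <- gradCAM(fit, q$fx$images[, , 1], 1)
  expect_true(all(sal == 0))
})

test_that("class saliency is the normalized mean of per-sample maps", {
  q <- fitQuadrantModel(n = 20, H = 8)
  one <- which(q$fx$labels == "b")[1]
  sOne <- classSaliency(q$fit, q$fx$images[, , one, drop = FALSE], "b", "b")
  expect_equal(unname(sOne), unname(gradCAM(q$fit, q$fx$images[, , one],
                                            "b")), tolerance = 1e-12,
               ignore_attr = TRUE)

  # duplicated sample set leaves the map unchanged (mean idempotence)
  idx <- which(q$fx$labels == "b")
  sAll <- classSaliency(q$fit, q$fx$images[, , idx], rep("b", length(idx)),
                        "b")
  sDup <- classSaliency(q$fit, q$fx$images[, , c(idx, idx)],
                        rep("b", 2 * length(idx)), "b")
  expect_equal(sAll, sDup, tolerance = 1e-12, ignore_attr = TRUE)

  # matches an independent loop-and-average recomputation
  acc <- 0
  for (i in idx) acc <- acc + gradCAM(q$fit, q$fx$images[, , i], "b")
  manual <- acc / length(idx); manual <- manual / max(manual)
  expect_equal(unname(sAll), unname(manual), tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_error(classSaliency(q$fit, q$fx$images, q$fx$labels, "zz"),
               "no samples")
})

test_that("taxa importance is an exact pixel lookup with tie recording", {
  set.seed(62)
  emb <- matrix(rnorm(600), 300, 2,
                dimnames = list(sprintf("t%03d", 1:300), NULL))
  pm <- suppressMessages(assignPixels(emb, 9, 9))
  sal <- matrix(runif(81), 9, 9)
  attr(sal, "class.label") <- "case"
  imp <- taxaImportance(sal, pm)

  # brute-force lookup through the serialized TSV
  tsv <- tempfile(fileext = ".tsv")
  writePixelMap(pm, tsv)
  df <- read.delim(tsv)
  expected <- sal[cbind(df$row, df$col)]
  expect_equal(imp@score[match(df$taxon_id, imp@taxa)], expected,
               tolerance = 1e-12)
  # co-located taxa always tie
  key <- paste(pm@pixelRow, pm@pixelCol)
  for (kk in unique(key[duplicated(key)]))
    expect_equal(length(unique(imp@score[key == kk])), 1L)

  # uniform saliency scores everyone equally
  uni <- matrix(1, 9, 9)
  expect_equal(length(unique(taxaImportance(uni, pm)@score)), 1L)

  # single hot pixel selects exactly its taxa
  hot <- matrix(0, 9, 9); hot[3, 4] <- 1
  ih <- taxaImportance(hot, pm)
  expect_setequal(ih@taxa[ih@score == 1],
                  pm@taxa[pm@pixelRow == 3 & pm@pixelCol == 4])
  expect_true(all(ih@score[pm@pixelRow != 3 | pm@pixelCol != 4] == 0))
  expect_error(taxaImportance(matrix(0, 5, 5), pm), "dims")
})

test_that("importance selection matches a sort-and-cut oracle", {
  set.seed(63)
  score <- runif(100)
  imp <- new("TaxaImportance", taxa = sprintf("t%03d", 1:100),
             classLabel = "case", score = score,
             selected = rep(FALSE, 100), sharedPixelCount = rep(1L, 100))
  sel <- selectImportant(imp, 90)
  cut <- sort(score[score > 0])[ceiling(0.9 * sum(score > 0))]
  oracle <- score >= cut  # quantile type-7 at p=0.9 of 100 values
  expect_equal(sum(sel@selected), sum(score >= quantile(score, 0.9)))
  expect_true(all(sel@score[sel@selected] >=
                    max(sel@score[!sel@selected])))

  # percentile 0 keeps every nonzero score
  score2 <- c(rep(0, 40), runif(60))
  imp2 <- new("TaxaImportance", taxa = sprintf("t%03d", 1:100),
              classLabel = "case", score = score2,
              selected = rep(FALSE, 100), sharedPixelCount = rep(1L, 100))
  sel2 <- selectImportant(imp2, 0)
  expect_equal(sum(sel2@selected), 60L)
  # all-equal nonzero scores: ties resolved by >=, all selected
  imp3 <- imp2; imp3@score <- rep(c(0, 0.5), 50)
  expect_equal(sum(selectImportant(imp3, 90)@selected), 50L)
  partition <- importantTaxa(sel2)
  expect_length(intersect(partition$important, partition$unimportant), 0)
  expect_setequal(c(partition$important, partition$unimportant), imp2@taxa)
})

test_that("common/unique partition equals direct set algebra", {
  s <- list(g1 = c("a", "b", "c"), g2 = c("b", "c", "d"),
            g3 = c("c", "e"))
  p <- commonUniquePartition(s)
  expect_equal(p$common, "c")
  expect_equal(p$unique$g1, "a")
  expect_equal(p$unique$g2, "d")
  expect_equal(p$unique$g3, "e")

  same <- list(x = c("a", "b"), y = c("a", "b"))
  ps <- commonUniquePartition(same)
  expect_setequal(ps$common, c("a", "b"))
  expect_length(unlist(ps$unique), 0)

  disj <- list(x = c("a", "b"), y = c("c", "d"))
  pd <- commonUniquePartition(disj)
  expect_length(pd$common, 0)
  expect_equal(pd$unique$x, c("a", "b"))

  set.seed(64)
  rnd <- lapply(1:4, function(i) sample(sprintf("t%03d", 1:200), 40))
  names(rnd) <- paste0("g", 1:4)
  pr <- commonUniquePartition(rnd)
  expect_equal(pr$common, Reduce(intersect, rnd))
  for (g in 1:4)
    expect_equal(pr$unique[[g]],
                 setdiff(rnd[[g]], unique(unlist(rnd[-g]))))
  expect_error(commonUniquePartition(rnd[1]), "two groups")
})
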