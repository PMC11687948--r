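test_that("training reaches high accuracy on separable images", {
  fx <- quadrantImages(n = 40, H = 12, W = 12, seed = 41)
  m <- buildModel(list(blockSpec(4, 3, 1), blockSpec(8, 3, 2)),
                  nClasses = 2, H = 12, W = 12, stemFilters = 4,
                  attentionKernel = 3, classLevels = c("a", "b"))
  fit <- trainModel(m, fx$images, fx$labels,
                    trainConfig(epochs = 40, batchSize = 16, patience = 40,
                                learningRate = 3e-3, seed = 2))
  p <- predictProb(fit, fx$images)
  acc <- mean(c("a", "b")[max.col(p)] == fx$labels)
  expect_gte(acc, 0.95)
  # best-so-far validation loss is non-increasing (early-stopping bookkeeping)
  expect_true(all(diff(fit@history$bestValLoss) <= 1e-12))
})

test_that("training is deterministic and guards label pathologies", {
  fx <- quadrantImages(n = 20, H = 8, W = 8, seed = 42)
  m <- buildModel(list(blockSpec(4, 3, 2)), 2, 8, 8, stemFilters = 2,
                  attentionKernel = 3, classLevels = c("a", "b"))
  cfg <- trainConfig(epochs = 3, batchSize = 8, seed = 7)
  f1 <- trainModel(m, fx$images, fx$labels, cfg)
  f2 <- trainModel(m, fx$images, fx$labels, cfg)
  expect_identical(f1@params, f2@params)
  expect_error(trainModel(m, fx$images, rep("a", 20), cfg), "two classes")
  expect_error(trainModel(m, fx$images, rep(c("a", "zz"), 10), cfg),
               "class set")
})

test_that("permuted labels leave held-out accuracy at chance", {
  fx <- quadrantImages(n = 40, H = 8, W = 8, seed = 43)
  accs <- vapply(1:5, function(s) {
    set.seed(100 + s)
    perm <- sample(fx$labels)
    m <- buildModel(list(blockSpec(4, 3, 2)), 2, 8, 8, stemFilters = 2,
                    attentionKernel = 3, classLevels = c("a", "b"))
    fit <- trainModel(m, fx$images[, , 1:30], perm[1:30],
                      trainConfig(epochs = 10, batchSize = 16,
                                  seed = 100 + s))
    mean(c("a", "b")[max.col(predictProb(fit, fx$images[, , 31:40]))] ==
           perm[31:40])
  }, numeric(1))
  expect_gte(mean(accs), 0.2)
  expect_lte(mean(accs), 0.8)
})

test_that("evaluation metrics match closed forms and an independent oracle", {
  # perfect predictions
  fx <- quadrantImages(n = 16, H = 8, W = 8, seed = 44)
  m <- buildModel(list(blockSpec(4, 3, 1)), 2, 8, 8, stemFilters = 2,
                  attentionKernel = 3, classLevels = c("a", "b"))
  fit <- trainModel(m, fx$images, fx$labels,
                    trainConfig(epochs = 25, batchSize = 8, patience = 25,
                                seed = 3))
  ev <- evaluateModel(fit, fx$images, fx$labels)
  if (ev$accuracy == 1) {
    expect_equal(ev$macroF1, 1)
    expect_equal(ev$auc, 1)
  }
  expect_equal(sum(ev$confusion), 16)

  # constant single-class prediction on balanced binary labels
  expect_equal(taxapix:::macroF1(rep(c("a", "b"), 8), rep("a", 16),
                                 c("a", "b")), 1 / 3)

  # random 3-class case against independently coded confusion tabulation
  set.seed(45)
  truth <- sample(c("x", "y", "z"), 60, replace = TRUE)
  pred <- sample(c("x", "y", "z"), 60, replace = TRUE)
  cm <- matrix(0, 3, 3, dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1
  f1s <- vapply(c("x", "y", "z"), function(cl) {
    prec <- cm[cl, cl] / sum(cm[, cl]); rec <- cm[cl, cl] / sum(cm[cl, ])
    if (is.nan(prec) || prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  }, numeric(1))
  expect_equal(taxapix:::macroF1(truth, pred, c("x", "y", "z")), mean(f1s))
})

test_that("rank AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(46)
  truth <- rbinom(50, 1, 0.4)
  score <- runif(50) + truth * 0.3
  expect_equal(taxapix:::rankAUC(score, truth),
               as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("stratified folds are balanced and seed-stable", {
  labels <- rep(c("a", "b"), c(23, 17))
  f1 <- taxapix:::stratifiedFolds(labels, 5, seed = 9)
  f2 <- taxapix:::stratifiedFolds(labels, 5, seed = 9)
  expect_identical(f1, f2)
  for (cl in c("a", "b")) {
    sizes <- table(f1[labels == cl])
    expect_lte(diff(range(sizes)), 1)
  }
  expect_error(taxapix:::stratifiedFolds(rep(c("a", "b"), c(3, 40)), 5),
               "exceeds")
})
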