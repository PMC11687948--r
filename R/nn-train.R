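#' Training configuration
#'
#' @param epochs maximum number of epochs.
#' @param batchSize minibatch size.
#' @param learningRate Adam learning rate.
#' @param patience early-stopping patience in epochs (on validation loss).
#' @param valFraction fraction of samples held out for validation, in
#'   (0, 0.5].
#' @param classWeights use inverse-frequency class weights in the loss.
#' @param seed seed controlling initialization, the split and shuffling.
#' @return list of class `trainConfig`.
#' @export
trainConfig <- function(epochs = 60L, batchSize = 32L, learningRate = 1e-3,
                        patience = 10L, valFraction = 0.2,
                        classWeights = FALSE, standardize = TRUE,
                        seed = 1L) {
  if (valFraction <= 0 || valFraction > 0.5)
    stop("valFraction must lie in (0, 0.5]")
  if (epochs < 1L || batchSize < 1L || patience < 1L)
    stop("epochs, batchSize and patience must be positive")
  structure(list(epochs = as.integer(epochs),
                 batchSize = as.integer(batchSize),
                 learningRate = learningRate, patience = as.integer(patience),
                 valFraction = valFraction, classWeights = classWeights,
                 standardize = standardize,
                 seed = as.integer(seed)), class = "trainConfig")
}

# Recursive Adam step over nested parameter lists.
adamStep <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    out <- list(p = p, m = m, v = v)
    for (nm in names(p)) {
      r <- adamStep(p[[nm]], g[[nm]], m[[nm]], v[[nm]], lr, t, b1, b2, eps)
      out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
    }
    out
  } else {
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g * g
    mh <- m2 / (1 - b1^t); vh <- v2 / (1 - b2^t)
    list(p = p - lr * mh / (sqrt(vh) + eps), m = m2, v = v2)
  }
}

zeroLike <- function(p) rapply(p, function(x) x * 0, how = "replace")

crossEntropy <- function(probs, yIdx, w) {
  -sum(w * log(pmax(probs[cbind(seq_len(nrow(probs)), yIdx)], 1e-12))) /
    sum(w)
}

#' Train the residual spatial-attention CNN
#'
#' Minimizes (optionally class-weighted) cross-entropy with Adam,
#' early-stops on validation loss, and returns the parameters of the best
#' validation epoch. A stratified validation split is carved from the
#' training samples. Deterministic given `cfg$seed` (parameters are
#' reinitialized from it, so repeated calls are reproducible fold by fold).
#'
#' @param model an \linkS4class{AttentionCNN} from [buildModel()].
#' @param images an \linkS4class{ImageStack} or H x W x N array.
#' @param labels class label per sample.
#' @param cfg a [trainConfig()]. With `standardize = TRUE` (default) every
#'   pixel is location-wise standardized using training-set mean and
#'   standard deviation; the statistics are stored in the model and applied
#'   to all later inputs, keeping train and test on one scale.
#' @return the fitted \linkS4class{AttentionCNN} with training history.
#' @export
trainModel <- function(model, images, labels, cfg = trainConfig()) {
  x <- imagesToArray(images, model@inputDim)
  if (isTRUE(cfg$standardize)) {
    mu <- apply(x[, , , 1, drop = FALSE], c(1, 2), mean)
    sdv <- apply(x[, , , 1, drop = FALSE], c(1, 2), sd)
    sdv[!is.finite(sdv) | sdv < 1e-8] <- 1
    model@params$inputStats <- list(mean = mu, sd = sdv)
  } else {
    model@params$inputStats <- NULL
  }
  # standardization itself happens inside modelForward, batch by batch
  labels <- as.character(labels)
  n <- dim(x)[3]
  if (length(labels) != n) stop("labels must align with images")
  lev <- model@classLevels
  if (!all(labels %in% lev))
    stop("labels outside the model's class set: ",
         paste(setdiff(unique(labels), lev), collapse = ", "))
  if (length(unique(labels)) < 2L)
    stop("training needs at least two classes present")
  yIdx <- match(labels, lev)
  K <- length(lev)
  withSeed(cfg$seed, {
    model@params$learn <- initModelParams(model@blocks, model@stemFilters,
                                          model@attentionKernel, K,
                                          nrow(model@params$learn$head$W),
                                          deriveSeed(cfg$seed, 31L))
    model@params$stats <- initModelStats(model@blocks, model@stemFilters)
    # stratified validation split
    valIdx <- integer(0)
    for (k in seq_len(K)) {
      ik <- which(yIdx == k)
      if (length(ik) >= 2L)
        valIdx <- c(valIdx, sample(ik, max(1L, round(length(ik) *
                                                       cfg$valFraction))))
    }
    trIdx <- setdiff(seq_len(n), valIdx)
    w <- rep(1, n)
    if (cfg$classWeights) {
      freq <- tabulate(yIdx, K) / n
      w <- (1 / freq[yIdx]); w <- w / mean(w)
    }
    oneHot <- matrix(0, n, K); oneHot[cbind(seq_len(n), yIdx)] <- 1

    mState <- zeroLike(model@params$learn)
    vState <- zeroLike(model@params$learn)
    best <- list(loss = Inf, params = model@params, epoch = 0L)
    hist <- vector("list", cfg$epochs)
    t <- 0L; wait <- 0L
    xv <- x[, , valIdx, , drop = FALSE]
    for (epoch in seq_len(cfg$epochs)) {
      ord <- sample(trIdx)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batchSize))
      epLoss <- 0
      for (bt in batches) {
        xb <- x[, , bt, , drop = FALSE]
        fw <- modelForward(model, xb, training = TRUE)
        model@params$stats <- fw$stats
        wb <- w[bt]
        epLoss <- epLoss + crossEntropy(fw$probs, yIdx[bt], wb) * length(bt)
        dLogits <- (fw$probs - oneHot[bt, , drop = FALSE]) * wb / sum(wb)
        bw <- modelBackward(model, fw, dLogits)
        t <- t + 1L
        upd <- adamStep(model@params$learn, bw$grads, mState, vState,
                        cfg$learningRate, t)
        model@params$learn <- upd$p; mState <- upd$m; vState <- upd$v
      }
      fv <- modelForward(model, xv, training = FALSE)
      valLoss <- crossEntropy(fv$probs, yIdx[valIdx], w[valIdx])
      valAcc <- mean(max.col(fv$probs) == yIdx[valIdx])
      hist[[epoch]] <- data.frame(epoch = epoch,
                                  trainLoss = epLoss / length(trIdx),
                                  valLoss = valLoss, valAcc = valAcc,
                                  bestValLoss = min(best$loss, valLoss))
      if (valLoss < best$loss - 1e-6) {
        best <- list(loss = valLoss, params = model@params, epoch = epoch)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
    model@params <- best$params
    model@history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
    model@trained <- TRUE
    if (is(images, "ImageStack")) model@normMax <- images@normMax
    model
  })
}

macroF1 <- function(truth, pred, levels) {
  f1 <- vapply(levels, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Evaluate a fitted model
#'
#' Accuracy, macro-averaged F1, AUC (binary: the positive-class probability;
#' multiclass: macro one-vs-rest, each class scored by its own probability)
#' and the confusion matrix.
#'
#' @param model a trained \linkS4class{AttentionCNN}.
#' @param images an \linkS4class{ImageStack} or array.
#' @param labels true class label per sample.
#' @return list with `accuracy`, `macroF1`, `auc`, `confusion`.
#' @export
evaluateModel <- function(model, images, labels) {
  labels <- as.character(labels)
  lev <- model@classLevels
  if (!all(labels %in% lev))
    stop("unseen label(s): ", paste(setdiff(unique(labels), lev),
                                    collapse = ", "))
  p <- predictProb(model, images)
  pred <- lev[max.col(p)]
  acc <- mean(pred == labels)
  f1 <- macroF1(labels, pred, lev)
  auc <- if (length(lev) == 2L) {
    rankAUC(p[, 2], labels == lev[2])
  } else {
    mean(vapply(seq_along(lev), function(k)
      rankAUC(p[, k], labels == lev[k]), numeric(1)), na.rm = TRUE)
  }
  confusion <- table(truth = factor(labels, lev), predicted = factor(pred,
                                                                     lev))
  list(accuracy = acc, macroF1 = f1, auc = auc, confusion = confusion)
}

#' Stratified repeated k-fold cross-validation of the full image pipeline
#'
#' For every fold, the taxa features (in sample-dependent modes), the 2D
#' embedding, the pixel layout and the image normalization constant are fit
#' on the training folds only and applied unchanged to the held-out fold —
#' the layout never sees test samples.
#'
#' @param abund taxa x sample counts/abundances or SummarizedExperiment.
#' @param labels class label per sample.
#' @param annot taxa x metabolite annotation matrix (modes metabolic /
#'   combined).
#' @param tree phylogenetic tree (mode cophenetic).
#' @param mode taxa-similarity mode: "metabolic", "abundance", "combined",
#'   "pearson", "spearman" or "cophenetic".
#' @param embedMethod,embedParams passed to [embedTaxa()].
#' @param imageSize integer `c(H, W)`.
#' @param blocks list of [blockSpec()]s.
#' @param stemFilters,attentionKernel passed to [buildModel()].
#' @param trainCfg a [trainConfig()]; its seed is re-derived per fold.
#' @param k number of folds (must not exceed the smallest class size).
#' @param repeats number of repetitions with fresh fold assignments.
#' @param seed root seed; folds, embeddings and training all derive from it.
#' @return list with `perFold` (data.frame of metrics), `mean` metrics,
#'   `folds` (assignment matrix), and `pixelMaps` (first repeat's per-fold
#'   \linkS4class{PixelMap}s).
#' @export
crossValidate <- function(abund, labels, annot = NULL, tree = NULL,
                          mode = "metabolic", embedMethod = "tsne",
                          embedParams = list(), imageSize = c(32L, 32L),
                          blocks = list(blockSpec(16, 3, 1),
                                        blockSpec(32, 3, 2)),
                          stemFilters = 8L, attentionKernel = 7L,
                          trainCfg = trainConfig(), k = 5L, repeats = 1L,
                          seed = 1L) {
  a <- relAbundance(abund)
  labels <- as.character(labels)
  if (min(table(labels)) < k)
    stop("fold count k = ", k, " exceeds the smallest class size")
  lev <- sort(unique(labels))
  perFold <- list()
  pixelMaps <- list()
  foldMat <- matrix(NA_integer_, length(labels), repeats)
  for (r in seq_len(repeats)) {
    folds <- stratifiedFolds(labels, k, deriveSeed(seed, 7L + r))
    foldMat[, r] <- folds
    for (f in seq_len(k)) {
      tr <- folds != f
      emb <- embedTaxaForMode(a[, tr, drop = FALSE], annot, tree, mode,
                              embedMethod, embedParams,
                              deriveSeed(seed, 100L + r * 10L + f))
      pmap <- assignPixels(emb, imageSize[1], imageSize[2])
      aUse <- a[pmap@taxa, , drop = FALSE]  # e.g. tree may cover fewer taxa
      trainImg <- renderImages(aUse[, tr, drop = FALSE], pmap)
      testImg <- renderImages(aUse[, !tr, drop = FALSE], pmap,
                              normMax = trainImg@normMax)
      model <- buildModel(blocks, length(lev), imageSize[1], imageSize[2],
                          stemFilters, attentionKernel, classLevels = lev)
      cfgF <- trainCfg
      cfgF$seed <- deriveSeed(seed, 500L + r * 10L + f)
      model <- trainModel(model, trainImg, labels[tr], cfgF)
      mets <- evaluateModel(model, testImg, labels[!tr])
      perFold[[length(perFold) + 1L]] <-
        data.frame(rep = r, fold = f, accuracy = mets$accuracy,
                   macroF1 = mets$macroF1, auc = mets$auc)
      if (r == 1L) pixelMaps[[f]] <- pmap
    }
  }
  perFold <- do.call(rbind, perFold)
  list(perFold = perFold,
       mean = c(accuracy = mean(perFold$accuracy),
                macroF1 = mean(perFold$macroF1),
                auc = mean(perFold$auc, na.rm = TRUE)),
       folds = foldMat, pixelMaps = pixelMaps)
}

# Features or distances for the chosen similarity mode, computed from the
# provided (training) abundance columns only.
embedTaxaForMode <- function(trainAbund, annot, tree, mode, embedMethod,
                             embedParams, seed) {
  input <- switch(mode,
    metabolic = buildFeatureMatrix(abund = trainAbund, annot = annot,
                                   mode = "metabolic"),
    abundance = buildFeatureMatrix(abund = trainAbund, mode = "abundance"),
    combined = buildFeatureMatrix(abund = trainAbund, annot = annot,
                                  mode = "combined"),
    pearson = correlationDistance(trainAbund, "pearson"),
    spearman = correlationDistance(trainAbund, "spearman"),
    cophenetic = {
      d <- copheneticDistance(tree)
      keep <- intersect(rownames(trainAbund), rownames(d))
      if (!length(keep)) stop("no taxa shared with the tree")
      d[keep, keep]
    },
    stop("unknown similarity mode: ", mode))
  embedTaxa(input, method = embedMethod, params = embedParams, seed = seed)
}
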