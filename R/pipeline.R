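#' Assemble and validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list. Referenced input paths are
#' checked at validation time, before any compute. Every stage draws its
#' seed from the single root `seed` by fixed offsets.
#'
#' @param config YAML path or named list with (all optional unless noted):
#'   `counts`, `labels`, `annotations`, `traits`, `tree` (paths), or
#'   `simulate` (list of [simParams()] arguments) replacing `counts`/
#'   `labels`; `mode` (similarity mode, default "metabolic"); `embedding`
#'   (list: method, perplexity, nNeighbors, minDist, maxIter, nEpochs);
#'   `imageSize` (default 32); `blocks` (list of `(nFilters, kernelSize,
#'   stride)`); `train` (list of [trainConfig()] arguments); `cv` (list: k,
#'   repeats; omit to train a single model); `saliencyLayer` (default -1);
#'   `percentile` (taxa importance, default 90); `metabolitePercentile`
#'   (default 99); `seed` (required).
#' @return validated config list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- config
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$mode <- cfg$mode %||% "metabolic"
  cfg$imageSize <- rep_len(as.integer(cfg$imageSize %||% 32L), 2L)
  cfg$embedding <- cfg$embedding %||% list()
  cfg$embedding$method <- cfg$embedding$method %||% "tsne"
  cfg$saliencyLayer <- as.integer(cfg$saliencyLayer %||% -1L)
  cfg$percentile <- cfg$percentile %||% 90
  cfg$metabolitePercentile <- cfg$metabolitePercentile %||% 99
  cfg$blocks <- lapply(cfg$blocks %||% list(c(16, 3, 1), c(32, 3, 2)),
                       function(b) if (inherits(b, "blockSpec")) b else
                         do.call(blockSpec, as.list(unlist(b))))
  if (is.null(cfg$simulate)) {
    if (is.null(cfg$counts))
      stop("config needs either a 'counts' path or a 'simulate' block")
    for (f in c("counts", "labels", "annotations", "traits", "tree")) {
      if (!is.null(cfg[[f]]) && is.character(cfg[[f]]) &&
          !file.exists(cfg[[f]]))
        stop("configured ", f, " path does not exist: ", cfg[[f]])
    }
  }
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

#' Run the full abundance-to-interpretation pipeline
#'
#' Executes simulate/read -> taxa similarity -> 2D embedding -> pixel layout
#' -> image rendering -> training (or cross-validation) -> class saliency ->
#' taxa importance -> metabolite/trait analysis, writing every artifact plus
#' a JSON manifest into `outDir`. Rerunning with the same config and seed
#' reproduces the PixelMap byte-for-byte and the metrics within
#' floating-point tolerance.
#'
#' @param config a [pipelineConfig()], list, or YAML path.
#' @param outDir output directory (created if needed).
#' @return invisibly, a result bundle: counts, labels, pixelMap, images,
#'   model, metrics (or cv), saliency maps, importance, metaboliteSums,
#'   differential, traitSummary, manifest.
#' @export
runPipeline <- function(config, outDir = tempfile("taxapix_")) {
  cfg <- if (inherits(config, "pipelineConfig")) config else
    pipelineConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    stageLog("stage ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           " (check the config section of the same name)", call. = FALSE))
  }

  bundle <- list()
  stage("input", {
    if (!is.null(cfg$simulate)) {
      sp <- do.call(simParams, c(cfg$simulate,
                                 list(seed = deriveSeed(cfg$seed, 1L))))
      se <- simulateCounts(sp)
      bundle$counts <- se
      bundle$labels <- SummarizedExperiment::colData(se)$label
      daIdx <- sp@daIndices
      taxa <- rownames(se)
      bundle$annotations <- if (!is.null(cfg$annotations) &&
                                is.character(cfg$annotations))
        readAnnotations(cfg$annotations, taxa)
      else simulateAnnotations(taxa, daIndices = daIdx,
                               seed = deriveSeed(cfg$seed, 2L))
      bundle$traits <- if (!is.null(cfg$traits) && is.character(cfg$traits))
        readTraits(cfg$traits)
      else simulateTraits(taxa, seed = deriveSeed(cfg$seed, 3L))
      writeAbundance(se, file.path(outDir, "counts.tsv"))
      write.table(data.frame(
        sample_id = colnames(se),
        phenotype = SummarizedExperiment::colData(se)$phenotype,
        cohort = SummarizedExperiment::colData(se)$cohort),
        file.path(outDir, "labels.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    } else {
      se <- readAbundance(cfg$counts)
      lab <- readLabels(cfg$labels, colnames(se))
      bundle$counts <- se
      bundle$labels <- if ("cohort" %in% names(lab))
        paste(lab$phenotype, lab$cohort, sep = ".") else lab$phenotype
      bundle$annotations <- if (!is.null(cfg$annotations))
        readAnnotations(cfg$annotations, rownames(se)) else NULL
      bundle$traits <- if (!is.null(cfg$traits)) readTraits(cfg$traits)
        else NULL
    }
    bundle$tree <- if (!is.null(cfg$tree)) readTree(cfg$tree) else NULL
  })

  a <- relAbundance(bundle$counts)
  labels <- as.character(bundle$labels)
  embedParams <- cfg$embedding[setdiff(names(cfg$embedding), "method")]

  if (!is.null(cfg$cv)) {
    stage("cross-validation", {
      bundle$cv <- crossValidate(
        a, labels, annot = bundle$annotations, tree = bundle$tree,
        mode = cfg$mode, embedMethod = cfg$embedding$method,
        embedParams = embedParams, imageSize = cfg$imageSize,
        blocks = cfg$blocks,
        trainCfg = do.call(trainConfig, cfg$train %||% list()),
        k = as.integer(cfg$cv$k %||% 5L),
        repeats = as.integer(cfg$cv$repeats %||% 1L), seed = cfg$seed)
      write.table(bundle$cv$perFold, file.path(outDir, "cv_metrics.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  stage("layout", {
    emb <- embedTaxaForMode(a, bundle$annotations, bundle$tree, cfg$mode,
                            cfg$embedding$method, embedParams,
                            deriveSeed(cfg$seed, 20L))
    bundle$pixelMap <- assignPixels(emb, cfg$imageSize[1], cfg$imageSize[2])
    bundle$images <- renderImages(a[bundle$pixelMap@taxa, , drop = FALSE],
                                  bundle$pixelMap)
    writePixelMap(bundle$pixelMap, file.path(outDir, "pixelmap.tsv"),
                  extra = list(normMax = bundle$images@normMax,
                               seed = cfg$seed))
  })

  stage("train", {
    lev <- sort(unique(labels))
    model <- buildModel(cfg$blocks, length(lev), cfg$imageSize[1],
                        cfg$imageSize[2], classLevels = lev)
    tc <- do.call(trainConfig, c(cfg$train %||% list()))
    tc$seed <- deriveSeed(cfg$seed, 30L)
    bundle$model <- trainModel(model, bundle$images, labels, tc)
    bundle$metrics <- evaluateModel(bundle$model, bundle$images, labels)
    saveRDS(bundle$model, file.path(outDir, "model.rds"))
    jsonlite::write_json(
      list(blocks = lapply(cfg$blocks, unclass),
           classLevels = lev, normMax = bundle$images@normMax,
           pixelMap = "pixelmap.tsv", seed = cfg$seed),
      file.path(outDir, "model_manifest.json"), auto_unbox = TRUE)
    write.table(
      data.frame(metric = c("accuracy", "macroF1", "auc"),
                 value = c(bundle$metrics$accuracy, bundle$metrics$macroF1,
                           bundle$metrics$auc)),
      file.path(outDir, "metrics.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  })

  stage("explain", {
    lev <- bundle$model@classLevels
    bundle$saliency <- lapply(setNames(lev, lev), function(cl)
      classSaliency(bundle$model, bundle$images, labels, cl,
                    layer = cfg$saliencyLayer))
    bundle$importance <- lapply(bundle$saliency, function(s)
      selectImportant(taxaImportance(s, bundle$pixelMap),
                      percentile = cfg$percentile))
    impTab <- do.call(rbind, lapply(bundle$importance, as.data.frame))
    write.table(impTab, file.path(outDir, "importance.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    for (cl in lev) {
      s <- bundle$saliency[[cl]]
      write.table(s, file.path(outDir, paste0("saliency_", cl, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
      writeHeatmapPNG(s, file.path(outDir, paste0("saliency_", cl, ".png")))
    }
  })

  stage("analyze", {
    if (!is.null(bundle$annotations)) {
      sets <- lapply(bundle$importance, function(i) importantTaxa(i)$important)
      bundle$metaboliteSums <- metaboliteSums(
        sets, bundle$annotations, percentile = cfg$metabolitePercentile)
      write.table(bundle$metaboliteSums$table,
                  file.path(outDir, "metabolite_sums.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      ref <- bundle$importance[[length(bundle$importance)]]
      part <- importantTaxa(ref)
      if (length(part$important) && length(part$unimportant)) {
        bundle$differential <- differentialMetabolites(
          part$important, part$unimportant, bundle$annotations)
        write.table(bundle$differential,
                    file.path(outDir, "differential_metabolites.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if (!is.null(bundle$traits)) {
      sets <- lapply(bundle$importance, function(i) importantTaxa(i)$important)
      allSets <- if (length(sets) >= 2L) {
        part <- commonUniquePartition(sets)
        c(list(common = part$common), part$unique)
      } else sets
      bundle$traitSummary <- traitSummary(allSets, bundle$traits)
      ts <- do.call(rbind, lapply(names(bundle$traitSummary), function(s) {
        x <- bundle$traitSummary[[s]]
        data.frame(set = s, n = x$n,
                   gram = paste(names(x$gram), x$gram, sep = ":",
                                collapse = ";"),
                   motility = paste(names(x$motility), x$motility,
                                    sep = ":", collapse = ";"),
                   oxygen = paste(names(x$oxygen), x$oxygen, sep = ":",
                                  collapse = ";"),
                   median_gene_count = x$medianGeneCount)
      }))
      write.table(ts, file.path(outDir, "trait_summary.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
  })

  stage("manifest", {
    manifest <- list(
      config = cfg[setdiff(names(cfg), "blocks")],
      blocks = lapply(cfg$blocks, unclass),
      seed = cfg$seed,
      configHash = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
      artifacts = list.files(outDir))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    bundle$manifest <- manifest
  })
  bundle$outDir <- outDir
  invisible(bundle)
}
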