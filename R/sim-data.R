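#' Construct simulation parameters
#'
#' Builds a validated \linkS4class{SimParams} object for the sparse
#' compositional count simulator. When `templateIntensity` is not given, a
#' skewed community template is drawn once (deterministically from `seed`)
#' as renormalized lognormal intensities, mimicking the long-tailed rank
#' abundance curves of 16S gut profiles.
#'
#' @param nTaxa number of taxa.
#' @param nPerClass samples per class.
#' @param nClasses number of phenotype classes (>= 2); class 1 uses the base
#'   template, every other class the fold-change-spiked template.
#' @param librarySize reads per sample.
#' @param templateIntensity optional expected relative abundances (sum 1).
#' @param variabilityCV per-taxon coefficient of variation of the gamma
#'   intensity noise; scalar recycled.
#' @param daIndices indices of differentially abundant taxa.
#' @param foldChange fold change applied to DA taxa in non-control classes.
#' @param targetSparsity desired expected zero fraction of the count matrix.
#' @param cohorts number of cohort levels crossed with phenotype.
#' @param cohortSigma lognormal sigma of the cohort template perturbation.
#' @param templateSigma lognormal sigma of the auto-generated template.
#' @param urnFactor urn size multiple for the without-replacement draw.
#' @param seed integer seed.
#' @return a \linkS4class{SimParams}.
#' @examples
#' p <- simParams(nTaxa = 50, nPerClass = 10, daIndices = 1:5, foldChange = 2)
#' @export
simParams <- function(nTaxa = 200L, nPerClass = 60L, nClasses = 2L,
                      librarySize = 10000L, templateIntensity = NULL,
                      variabilityCV = 0.3, daIndices = integer(0),
                      foldChange = 1, targetSparsity = 0.8, cohorts = 1L,
                      cohortSigma = 0.3, templateSigma = 1.5,
                      urnFactor = 100, seed = 1L) {
  nTaxa <- as.integer(nTaxa)
  if (is.null(templateIntensity)) {
    templateIntensity <- withSeed(deriveSeed(seed, 11L), {
      x <- exp(rnorm(nTaxa, 0, templateSigma))
      x / sum(x)
    })
  } else {
    s <- sum(templateIntensity)
    if (abs(s - 1) > 1e-6) stop("templateIntensity must sum to 1")
    templateIntensity <- templateIntensity / s
  }
  new("SimParams", nTaxa = nTaxa, nPerClass = as.integer(nPerClass),
      nClasses = as.integer(nClasses), librarySize = as.integer(librarySize),
      templateIntensity = as.numeric(templateIntensity),
      variabilityCV = rep_len(as.numeric(variabilityCV), nTaxa),
      daIndices = as.integer(daIndices), foldChange = as.numeric(foldChange),
      targetSparsity = as.numeric(targetSparsity),
      cohorts = as.integer(cohorts), cohortSigma = as.numeric(cohortSigma),
      urnFactor = as.numeric(urnFactor), seed = as.integer(seed))
}

#' Spike a fold change into a community template
#'
#' Multiplies the expected relative abundance of the differentially abundant
#' taxa by `fold`, then renormalizes so the template remains compositional.
#'
#' @param template nonnegative intensity vector summing to 1.
#' @param daIndices indices of the taxa receiving the fold change.
#' @param fold positive fold change.
#' @return intensity vector summing to 1.
#' @examples
#' spikeFoldChange(c(0.5, 0.5), 1L, 3)  # c(0.75, 0.25)
#' @export
spikeFoldChange <- function(template, daIndices, fold) {
  if (!is.numeric(fold) || length(fold) != 1L || fold <= 0)
    stop("fold must be a positive scalar")
  if (abs(sum(template) - 1) > 1e-6) stop("template must sum to 1")
  daIndices <- as.integer(daIndices)
  if (length(daIndices) &&
      (min(daIndices) < 1L || max(daIndices) > length(template)))
    stop("daIndices out of range")
  out <- template
  out[daIndices] <- out[daIndices] * fold
  out / sum(out)
}

# Exact multivariate hypergeometric draw: apportion `urn` balls to taxa by
# largest-remainder rounding of `prob`, then sample `n` without replacement.
rmvhyper <- function(n, prob, urn) {
  exact <- prob * urn
  balls <- floor(exact)
  short <- urn - sum(balls)
  if (short > 0) {
    ord <- order(exact - balls, decreasing = TRUE)
    balls[ord[seq_len(short)]] <- balls[ord[seq_len(short)]] + 1
  }
  cum <- cumsum(balls)
  drawn <- sample.int(urn, n)
  tabulate(findInterval(drawn - 1, cum) + 1L, nbins = length(prob))
}

# One sample: gamma intensity noise, Bernoulli dropout, compositional count
# draw of exactly `lib` reads.
drawSample <- function(template, cv, dropout, lib, urnFactor) {
  n <- length(template)
  intensity <- template
  pos <- template > 0 & cv > 0
  if (any(pos)) {
    shape <- 1 / cv[pos]^2
    intensity[pos] <- rgamma(sum(pos), shape = shape,
                             rate = shape / template[pos])
  }
  if (dropout > 0) {
    keep <- runif(n) >= dropout
    if (any(keep & intensity > 0)) intensity[!keep] <- 0
  }
  tot <- sum(intensity)
  if (tot <= 0) return(integer(n))
  prob <- intensity / tot
  if (urnFactor >= 100)
    as.integer(rmultinom(1, lib, prob))
  else
    rmvhyper(lib, prob, round(urnFactor * lib))
}

# Zero fraction of a pilot run at a given dropout rate.
pilotZeroFraction <- function(templates, cv, dropout, lib, urnFactor,
                              nPilot) {
  z <- 0L; tot <- 0L
  for (tmpl in templates) {
    for (s in seq_len(nPilot)) {
      x <- drawSample(tmpl, cv, dropout, lib, urnFactor)
      z <- z + sum(x == 0L); tot <- tot + length(x)
    }
  }
  z / tot
}

#' Simulate sparse compositional microbiome counts
#'
#' Draws taxa x sample counts class by class: per-sample taxon intensities
#' come from a gamma distribution with the class template as mean and the
#' stated coefficient of variation, a calibrated Bernoulli dropout thins taxa
#' to reach the target sparsity in expectation, and exactly `librarySize`
#' reads are then drawn compositionally — without replacement from a finite
#' urn of `urnFactor * librarySize` balls, or (the accepted approximation
#' when the urn is at least 100 libraries deep) from a multinomial. Column
#' sums therefore equal `librarySize` exactly. Non-control classes use the
#' fold-change-spiked template; with `cohorts > 1` labels are the phenotype x
#' cohort cross and each cohort perturbs the template lognormally.
#'
#' @param params a \linkS4class{SimParams}.
#' @return a [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, colData columns `phenotype`, `cohort`, `label`, and metadata
#'   recording the parameters, the calibrated dropout rate and the sampling
#'   approximation used.
#' @examples
#' se <- simulateCounts(simParams(nTaxa = 30, nPerClass = 5,
#'                                librarySize = 2000, seed = 7))
#' colSums(SummarizedExperiment::assay(se))  # all 2000
#' @export
simulateCounts <- function(params) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  p <- params
  withSeed(p@seed, {
    phenoLevels <- if (p@nClasses == 2L) c("control", "case") else
      paste0("class", seq_len(p@nClasses))
    baseTemplates <- lapply(seq_len(p@nClasses), function(k) {
      if (k == 1L) p@templateIntensity else
        spikeFoldChange(p@templateIntensity, p@daIndices, p@foldChange)
    })
    cohortLevels <- paste0("cohort", seq_len(p@cohorts))
    cohortShift <- lapply(seq_len(p@cohorts), function(g) {
      if (p@cohorts == 1L) rep(1, p@nTaxa) else
        exp(rnorm(p@nTaxa, 0, p@cohortSigma))
    })
    templates <- list()
    for (g in seq_len(p@cohorts)) for (k in seq_len(p@nClasses)) {
      t <- baseTemplates[[k]] * cohortShift[[g]]
      templates[[paste(k, g)]] <- t / sum(t)
    }

    # Calibrate dropout so realized zero fraction (dropout + sampling zeros)
    # matches targetSparsity; two pilot rounds, secant correction.
    dropout <- 0
    if (p@targetSparsity > 0) {
      nPilot <- max(5L, ceiling(200 / length(templates)))
      z0 <- pilotZeroFraction(templates, p@variabilityCV, 0, p@librarySize,
                              p@urnFactor, nPilot)
      if (z0 < p@targetSparsity) {
        d1 <- (p@targetSparsity - z0) / (1 - z0)
        z1 <- pilotZeroFraction(templates, p@variabilityCV, d1,
                                p@librarySize, p@urnFactor, nPilot)
        slope <- (z1 - z0) / d1
        d2 <- if (slope > 1e-6) d1 + (p@targetSparsity - z1) / slope else d1
        dropout <- min(max(d2, 0), 0.999)
      }
    }

    nSamp <- p@nClasses * p@cohorts * p@nPerClass
    counts <- matrix(0L, p@nTaxa, nSamp)
    phenotype <- character(nSamp); cohort <- character(nSamp)
    j <- 0L
    for (g in seq_len(p@cohorts)) for (k in seq_len(p@nClasses)) {
      tmpl <- templates[[paste(k, g)]]
      for (s in seq_len(p@nPerClass)) {
        j <- j + 1L
        counts[, j] <- drawSample(tmpl, p@variabilityCV, dropout,
                                  p@librarySize, p@urnFactor)
        phenotype[j] <- phenoLevels[k]
        cohort[j] <- cohortLevels[g]
      }
    }
    taxa <- sprintf("taxon_%03d", seq_len(p@nTaxa))
    samples <- sprintf("sample_%04d", seq_len(nSamp))
    dimnames(counts) <- list(taxa, samples)
    label <- if (p@cohorts > 1L) paste(phenotype, cohort, sep = ".") else
      phenotype
    SummarizedExperiment::SummarizedExperiment(
      assays = list(counts = counts),
      colData = S4Vectors::DataFrame(
        phenotype = phenotype, cohort = cohort, label = label,
        row.names = samples),
      metadata = list(
        simParams = p, dropoutRate = dropout,
        approximation = if (p@urnFactor >= 100) "multinomial" else
          "hypergeometric-urn",
        daTaxa = taxa[p@daIndices]))
  })
}

#' Relative abundances of a count container
#'
#' @param x a SummarizedExperiment with a `counts` assay, or a nonnegative
#'   taxa x sample matrix.
#' @return taxa x sample matrix with columns summing to 1 (all-zero columns
#'   stay zero).
#' @export
relAbundance <- function(x) {
  m <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts") else as.matrix(x)
  if (any(m < 0)) stop("abundances must be nonnegative")
  colNormalize(m)
}

#' Simulate a taxa x metabolite annotation table
#'
#' Emulates a production/consumption annotation resource: a block of signal
#' metabolites is produced by the differentially abundant taxa with
#' probability `enrichment` and by all other taxa with probability
#' `backgroundRate`; the remaining metabolites are background everywhere.
#'
#' @param taxaIds taxon identifiers (rows).
#' @param nMetabolites total number of metabolites (columns).
#' @param daIndices row indices of the DA taxa.
#' @param enrichment production probability of signal metabolites in DA taxa.
#' @param backgroundRate production probability elsewhere.
#' @param nSignal size of the signal metabolite block.
#' @param seed integer seed.
#' @return binary taxa x metabolite matrix with dimnames; attribute
#'   `signalMetabolites` names the signal block columns.
#' @export
simulateAnnotations <- function(taxaIds, nMetabolites = 50L, daIndices,
                                enrichment = 0.9, backgroundRate = 0.2,
                                nSignal = 10L, seed = 1L) {
  if (enrichment < 0 || enrichment > 1 || backgroundRate < 0 ||
      backgroundRate > 1)
    stop("enrichment and backgroundRate must lie in [0, 1]")
  if (enrichment < backgroundRate)
    stop("enrichment must be >= backgroundRate")
  nSignal <- min(as.integer(nSignal), as.integer(nMetabolites))
  n <- length(taxaIds)
  withSeed(seed, {
    m <- matrix(rbinom(n * nMetabolites, 1L, backgroundRate), n,
                nMetabolites)
    if (nSignal > 0 && length(daIndices))
      m[daIndices, seq_len(nSignal)] <-
        rbinom(length(daIndices) * nSignal, 1L, enrichment)
    mets <- c(sprintf("met_signal_%02d", seq_len(nSignal)),
              sprintf("met_bg_%03d", seq_len(nMetabolites - nSignal)))
    dimnames(m) <- list(taxaIds, mets)
    attr(m, "signalMetabolites") <- mets[seq_len(nSignal)]
    m
  })
}

#' Simulate a functional-trait table
#'
#' Draws per-taxon categorical gram status, motility and oxygen tolerance
#' (each including an "unknown" level, as real trait directories never cover
#' every taxon) plus an integer gene count in a configured range.
#'
#' @param taxaIds taxon identifiers.
#' @param seed integer seed.
#' @param geneCountRange integer `c(min, max)` of the uniform gene count.
#' @param unknownRate probability of the "unknown" level per trait.
#' @return data.frame with columns taxon, gram, motility, oxygen, gene_count.
#' @export
simulateTraits <- function(taxaIds, seed = 1L,
                           geneCountRange = c(1000L, 8000L),
                           unknownRate = 0.1) {
  n <- length(taxaIds)
  withSeed(seed, {
    pick <- function(levels) {
      x <- sample(levels, n, replace = TRUE)
      x[runif(n) < unknownRate] <- "unknown"
      x
    }
    data.frame(
      taxon = taxaIds,
      gram = pick(c("positive", "negative")),
      motility = pick(c("motile", "non-motile")),
      oxygen = pick(c("aerobic", "anaerobic", "facultative")),
      gene_count = sample(geneCountRange[1]:geneCountRange[2], n,
                          replace = TRUE),
      stringsAsFactors = FALSE)
  })
}
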