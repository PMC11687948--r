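# Internal helpers shared across modules.

# Evaluate expr under a fixed seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stage-specific seed from a root seed by fixed offsets, kept below
# 2^31 so it stays a valid R integer.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 1000 + offset) %% .Machine$integer.max)
}

stageLog <- function(...) message("[taxapix] ", ...)

# Column-normalize a nonnegative matrix to relative abundances; all-zero
# columns are left at zero.
colNormalize <- function(m) {
  cs <- colSums(m)
  cs[cs == 0] <- 1
  sweep(m, 2, cs, "/")
}

# Rank-based (Mann-Whitney) AUC of scores against a binary truth vector.
rankAUC <- function(score, truth) {
  truth <- as.logical(truth)
  n1 <- sum(truth); n0 <- sum(!truth)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score)
  (sum(r[truth]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Stratified fold assignment: per class, shuffle then deal round-robin, so
# fold sizes differ by at most one within every class.
stratifiedFolds <- function(labels, k, seed = NULL) {
  withSeed(seed, {
    fold <- integer(length(labels))
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      if (length(idx) < k)
        stop("fold count k = ", k, " exceeds size of class ", sQuote(cl))
      fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}
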