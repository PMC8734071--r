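# Independent reference computations used to check the fast implementations.

# Exhaustive path-sum posteriors and log-likelihood for tiny instances:
# enumerate all S^T state paths, weight each by its exact joint probability
# in log space, and marginalize. Deliberately shares no code with the
# package's scaled forward-backward.
enumeratePosteriors <- function(init, trans, emissions, obs) {
  S <- length(init)
  T <- nrow(obs)
  D <- ncol(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), T)))
  logp <- log(init[paths[, 1]])
  if (T >= 2) {
    for (t in 2:T) {
      logp <- logp + log(trans[cbind(paths[, t - 1], paths[, t])])
    }
  }
  for (t in seq_len(T)) {
    for (d in seq_len(D)) {
      o <- obs[t, d]
      if (o == 2) next
      e <- emissions[paths[, t], d]
      logp <- logp + if (o == 1) log(e) else log(1 - e)
    }
  }
  mx <- max(logp)
  w <- exp(logp - mx)
  total <- sum(w)
  gamma <- matrix(0, T, S)
  for (t in seq_len(T)) {
    for (s in seq_len(S)) gamma[t, s] <- sum(w[paths[, t] == s]) / total
  }
  list(gamma = gamma, logLik = mx + log(total))
}

# Random strictly-interior model for oracle comparisons.
randomTinyModel <- function(S, D, seed) {
  set.seed(seed)
  e <- matrix(runif(S * D, 0.02, 0.98), S, D)
  a <- matrix(rexp(S * S), S, S)
  a <- a / rowSums(a)
  p <- rexp(S)
  StackedHMM(e, a, p / sum(p))
}

randomTinyObs <- function(T, D, seed, missingRate = 0) {
  set.seed(seed)
  m <- matrix(as.integer(runif(T * D) < 0.5), T, D)
  if (missingRate > 0) m[runif(T * D) < missingRate] <- 2L
  m
}

# Greedy state matching by emission correlation, for parameter-recovery and
# decode-accuracy checks: truth state -> best-correlated fitted state.
matchStates <- function(truth, fit) {
  compareModels(truth, fit)$bestMatch
}

# Brute-force per-base fold enrichment on small genomes: paint every base.
bruteForceFE <- function(seg, annot) {
  cs <- chromSizes(seg)
  bs <- binSize(seg)
  S <- nStates(seg)
  stateOfBase <- integer(0)
  annotBase <- logical(0)
  for (chrom in names(cs)) {
    L <- cs[[chrom]]
    st <- stateIndices(seg, chrom)
    stateOfBase <- c(stateOfBase, st[((seq_len(L) - 1L) %/% bs) + 1L])
    hit <- logical(L)
    sel <- as.character(GenomicRanges::seqnames(annot)) == chrom
    for (i in which(sel)) {
      a <- max(1L, GenomicRanges::start(annot)[i])
      b <- min(L, GenomicRanges::end(annot)[i])
      if (a <= b) hit[a:b] <- TRUE
    }
    annotBase <- c(annotBase, hit)
  }
  G <- length(stateOfBase)
  X <- sum(annotBase)
  vapply(seq_len(S), function(s) {
    Sn <- sum(stateOfBase == s)
    if (Sn == 0 || X == 0) return(NA_real_)
    sum(annotBase & stateOfBase == s) * G / (Sn * X)
  }, numeric(1))
}

# Shared small simulated study used by several test files.
smallStudy <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulationConfig(chromSizes = c(chr1 = 2e5, chr2 = 2e5),
                              seed = 42)
      cache <<- c(list(config = cfg), simulateGenome(cfg))
    }
    cache
  }
})
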