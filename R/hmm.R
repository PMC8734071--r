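#' Stabilized relative emission products
#'
#' With a thousand-plus Bernoulli features the joint emission probability of
#' an observation underflows double precision in every state, which would
#' leave all posteriors zero. Only the products' ratios across states matter,
#' so after each feature is multiplied in, all state products are divided by
#' their maximum. The returned vector is proportional to the true joint
#' emission probability across states with maximum exactly 1. Missing calls
#' (code 2) are skipped.
#'
#' @param model a [StackedHMM-class].
#' @param observation integer vector over \{0,1,2\} of length `nFeatures(model)`,
#'   or a T x D matrix of such rows.
#' @return For a vector input, a length-S numeric vector; for a matrix, a
#'   T x S matrix. Attribute `logScale` holds the per-row log of the removed
#'   normalizers (true joint probability = value * exp(logScale)).
#' @export
stabilizedEmissionProducts <- function(model, observation) {
  obs <- if (is.matrix(observation)) observation else
    matrix(observation, nrow = 1)
  storage.mode(obs) <- "integer"
  res <- .cs_emission_products(emissionProbs(model), obs)
  out <- res$B
  if (!is.matrix(observation)) {
    out <- drop(out)
    attr(out, "logScale") <- res$logScale[1]
  } else {
    attr(out, "logScale") <- res$logScale
  }
  out
}

#' Forward-backward pass over one observation chunk
#'
#' Scaled forward-backward treating the chunk as an independent sequence
#' started from the model's initial distribution (chromosomes are split into
#' at most 1-Mb chunks and each chunk is its own sequence). Emission terms
#' use the stabilized relative products of
#' [stabilizedEmissionProducts()]; the log-likelihood is exact because the
#' removed normalizers are added back in log space.
#'
#' @param model a [StackedHMM-class].
#' @param chunk an [ObservationChunk-class] (or bare call matrix).
#' @return List with `gamma` (T x S posterior matrix, rows summing to 1),
#'   `logLik`, and expected sufficient statistics `transCounts` (S x S),
#'   `initCounts` (S), `presentCounts` and `absentCounts` (S x D).
#' @export
forwardBackward <- function(model, chunk) {
  calls <- if (is(chunk, "ObservationChunk")) binCalls(chunk) else chunk
  storage.mode(calls) <- "integer"
  if (nrow(calls) < 1) stop("empty observation chunk")
  .cs_forward_backward(
    initialProbs(model), transitionProbs(model), emissionProbs(model), calls
  )
}

#' Baum-Welch M-step with pseudo-counts
#'
#' Re-estimates all parameters from accumulated expected counts, adding a
#' pseudo-count to every cell: presence and absence of each feature from each
#' state, each transition pair, and each initial assignment. With
#' `pseudoCount > 0` no parameter can reach 0 or 1, which keeps training
#' numerically stable when features are sparse and each iteration sees only a
#' subsample of the genome.
#'
#' @param stats list with `presentCounts`, `absentCounts` (S x D),
#'   `transCounts` (S x S) and `initCounts` (S), as accumulated from
#'   [forwardBackward()].
#' @param pseudoCount non-negative pseudo-count (the method's default is 1).
#' @param featureNames optional dataset names for the new model.
#' @return A [StackedHMM-class] with the updated parameters.
#' @export
baumWelchUpdate <- function(stats, pseudoCount = 1, featureNames = NULL) {
  if (pseudoCount < 0) stop("pseudoCount must be non-negative")
  pr <- stats$presentCounts
  ab <- stats$absentCounts
  if (any(pr < 0) || any(ab < 0) || any(stats$transCounts < 0) ||
      any(stats$initCounts < 0))
    stop("sufficient statistics must be non-negative")
  e <- (pr + pseudoCount) / (pr + ab + 2 * pseudoCount)
  tc <- stats$transCounts + pseudoCount
  a <- tc / rowSums(tc)
  ic <- stats$initCounts + pseudoCount
  StackedHMM(e, a, ic / sum(ic), featureNames = featureNames)
}

#' Training configuration for the stacked HMM
#'
#' @param nStates number of chromatin states to fit.
#' @param nSampledChunks chunks drawn per iteration (the genome-scale run uses
#'   300 1-Mb regions); drawn without replacement, or with replacement when
#'   fewer chunks exist.
#' @param maxIterations iteration cap (default 200).
#' @param pseudoCount pseudo-count added in every M-step (default 1).
#' @param convergenceDelta stop when the sampled-data log-likelihood improves
#'   by less than this; `-1` (the default, matching the method) disables the
#'   likelihood stop, since each iteration evaluates a different subsample and
#'   decreases are expected.
#' @param seed integer seed fixing the chunk subsampling and the random
#'   initialization.
#' @return Validated configuration list.
#' @export
trainConfig <- function(nStates, nSampledChunks = 300L, maxIterations = 200L,
                        pseudoCount = 1, convergenceDelta = -1, seed = 1L) {
  stopifnot(nStates >= 1, nSampledChunks >= 1, maxIterations >= 1,
            pseudoCount >= 0)
  list(
    nStates = as.integer(nStates),
    nSampledChunks = as.integer(nSampledChunks),
    maxIterations = as.integer(maxIterations),
    pseudoCount = pseudoCount,
    convergenceDelta = convergenceDelta,
    seed = as.integer(seed)
  )
}

#' Random model initialization
#'
#' Emissions i.i.d. uniform on `(eps, 1 - eps)`; transition rows and the
#' initial distribution drawn flat on the simplex. Deterministic per seed.
#'
#' @param nStates,nFeatures model dimensions.
#' @param seed integer seed.
#' @param eps margin keeping emissions away from 0 and 1.
#' @param featureNames optional dataset names.
#' @return A [StackedHMM-class].
#' @export
initRandomHMM <- function(nStates, nFeatures, seed = 1L, eps = 0.001,
                          featureNames = NULL) {
  set.seed(seed)
  e <- matrix(runif(nStates * nFeatures, eps, 1 - eps), nStates, nFeatures)
  simplex <- function(n) { x <- -log(runif(n)); x / sum(x) }
  a <- t(vapply(seq_len(nStates), function(i) simplex(nStates),
                numeric(nStates)))
  StackedHMM(e, a, simplex(nStates), featureNames = featureNames)
}

#' Train the stacked HMM by subsampled Baum-Welch
#'
#' Each iteration draws `nSampledChunks` observation chunks at random
#' (without replacement; with replacement only when fewer chunks exist), runs
#' the E-step on the sample and the pseudo-count M-step on the accumulated
#' statistics. Training runs to `maxIterations` when `convergenceDelta = -1`.
#' The per-iteration log-likelihood of the sampled data is recorded; it need
#' not be monotone across iterations because the sample changes.
#'
#' @param chunks list of [ObservationChunk-class] (or bare call matrices).
#' @param config a [trainConfig()].
#' @param init optional [StackedHMM-class] starting point; defaults to
#'   [initRandomHMM()] under `config$seed`.
#' @return A [StackedHMMFit-class].
#' @export
trainStackedHMM <- function(chunks, config, init = NULL) {
  mats <- lapply(chunks, function(ch) {
    m <- if (is(ch, "ObservationChunk")) binCalls(ch) else ch
    storage.mode(m) <- "integer"
    m
  })
  D <- unique(vapply(mats, ncol, integer(1)))
  if (length(D) != 1) stop("chunks disagree on the number of features")
  feats <- if (is(chunks[[1]], "ObservationChunk") &&
               !is.null(colnames(binCalls(chunks[[1]]))))
    colnames(binCalls(chunks[[1]])) else NULL
  model <- if (is.null(init)) {
    initRandomHMM(config$nStates, D, seed = config$seed, featureNames = feats)
  } else init
  set.seed(config$seed + 1L)
  S <- config$nStates
  trace <- numeric(0)
  for (iter in seq_len(config$maxIterations)) {
    n <- length(mats)
    idx <- if (config$nSampledChunks >= n) {
      if (config$nSampledChunks > n)
        sample.int(n, config$nSampledChunks, replace = TRUE)
      else seq_len(n)
    } else sample.int(n, config$nSampledChunks, replace = FALSE)
    agg <- list(
      presentCounts = matrix(0, S, D), absentCounts = matrix(0, S, D),
      transCounts = matrix(0, S, S), initCounts = numeric(S)
    )
    ll <- 0
    for (i in idx) {
      fb <- forwardBackward(model, mats[[i]])
      agg$presentCounts <- agg$presentCounts + fb$presentCounts
      agg$absentCounts <- agg$absentCounts + fb$absentCounts
      agg$transCounts <- agg$transCounts + fb$transCounts
      agg$initCounts <- agg$initCounts + fb$initCounts
      ll <- ll + fb$logLik
    }
    trace <- c(trace, ll)
    model <- baumWelchUpdate(agg, config$pseudoCount, featureNames = feats)
    if (config$convergenceDelta >= 0 && iter > 1 &&
        (trace[iter] - trace[iter - 1]) < config$convergenceDelta) break
  }
  new("StackedHMMFit",
    emissions = emissionProbs(model),
    transitions = transitionProbs(model),
    initialProbs = initialProbs(model),
    featureNames = featureNames(model),
    logLikTrace = trace, config = config
  )
}

#' Total log-likelihood of observation chunks
#'
#' Sum of per-chunk forward log-likelihoods (chunks are independent
#' sequences).
#'
#' @param model a [StackedHMM-class].
#' @param chunks list of [ObservationChunk-class] or call matrices.
#' @return Scalar log-likelihood.
#' @export
logLikelihood <- function(model, chunks) {
  sum(vapply(chunks, function(ch) {
    m <- if (is(ch, "ObservationChunk")) binCalls(ch) else ch
    storage.mode(m) <- "integer"
    .cs_log_likelihood(initialProbs(model), transitionProbs(model),
                       emissionProbs(model), m)
  }, numeric(1)))
}

#' Information criteria for a fitted model
#'
#' `AIC = 2k - 2L` and `BIC = k log(n) - 2L`, with free-parameter count
#' `k = S*D + S*(S-1) + (S-1)` (one parameter per Bernoulli emission; each
#' transition row and the initial distribution lose one degree of freedom)
#' and `n` the number of bins in the evaluation subset. At genome scale these
#' are evaluated on the log-likelihood of a few hundred random 1-Mb regions.
#'
#' @param model a [StackedHMM-class].
#' @param logLik evaluated log-likelihood.
#' @param nBins number of bins the likelihood was evaluated on.
#' @return Named numeric vector `c(AIC = , BIC = , k = )`.
#' @export
aicBic <- function(model, logLik, nBins) {
  if (nBins <= 0) stop("nBins must be positive")
  S <- nStates(model); D <- nFeatures(model)
  k <- S * D + S * (S - 1) + (S - 1)
  c(AIC = 2 * k - 2 * logLik, BIC = k * log(nBins) - 2 * logLik, k = k)
}

#' Compare two models by emission correlation
#'
#' For every state of the reference model, the maximum Pearson correlation
#' between its emission vector and any state of the other model, with the
#' maximizing state index. States whose emission vector is constant have
#' undefined correlation and are reported as `NA`.
#'
#' @param reference,other [StackedHMM-class] objects over the same feature
#'   set (or the same restricted subset, in the same order).
#' @return `data.frame` with columns `state`, `maxCorrelation`,
#'   `bestMatch`.
#' @export
compareModels <- function(reference, other) {
  er <- emissionProbs(reference)
  eo <- emissionProbs(other)
  if (ncol(er) != ncol(eo)) stop("models have different feature sets")
  res <- t(vapply(seq_len(nrow(er)), function(s) {
    x <- er[s, ]
    if (sd(x) == 0) return(c(NA_real_, NA_real_))
    cors <- apply(eo, 1, function(y) {
      if (sd(y) == 0) NA_real_ else cor(x, y)
    })
    if (all(is.na(cors))) return(c(NA_real_, NA_real_))
    j <- which.max(cors)
    c(cors[j], j)
  }, numeric(2)))
  data.frame(
    state = seq_len(nrow(er)),
    maxCorrelation = res[, 1],
    bestMatch = as.integer(res[, 2])
  )
}

#' Correlate one mark's emissions with tissue-group membership
#'
#' Restricts the emission matrix to the features carrying one chromatin mark
#' (one feature per cell type), and for each tissue group correlates every
#' state's emission vector with the binary in-group indicator over cell
#' types. Reports, per group, the maximum correlation over states — a measure
#' of whether some state is specific to that group for that mark.
#'
#' @param model a [StackedHMM-class].
#' @param metadata `data.frame` with columns `feature`, `mark`, `group` (one
#'   row per feature of the model).
#' @param mark mark to restrict to (e.g. `"H3K4me1"`).
#' @return `data.frame` with columns `group`, `maxCorrelation`, `bestState`.
#' @export
markGroupCorrelation <- function(model, metadata, mark) {
  sel <- metadata$mark == mark
  if (!any(sel)) stop("no features carry mark ", mark)
  cols <- match(metadata$feature[sel], featureNames(model))
  e <- emissionProbs(model)[, cols, drop = FALSE]
  groups <- unique(metadata$group[sel])
  res <- t(vapply(groups, function(g) {
    ind <- as.numeric(metadata$group[sel] == g)
    if (sd(ind) == 0) return(c(NA_real_, NA_real_))
    cors <- apply(e, 1, function(x) if (sd(x) == 0) NA_real_ else cor(x, ind))
    if (all(is.na(cors))) return(c(NA_real_, NA_real_))
    j <- which.max(cors)
    c(cors[j], j)
  }, numeric(2)))
  data.frame(
    group = groups,
    maxCorrelation = res[, 1],
    bestState = as.integer(res[, 2])
  )
}
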