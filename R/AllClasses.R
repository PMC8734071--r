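#' @importFrom methods new validObject is setClass setGeneric setMethod setValidity show
#' @importFrom stats ppois runif rnorm rpois rbinom cor sd wilcox.test setNames aggregate
#' @importFrom utils head tail
#' @importFrom S4Vectors Rle runLength runValue
#' @useDynLib chromstack, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.datatable.aware <- TRUE

.PROB_TOL <- 1e-9

#' Stacked multivariate Bernoulli hidden Markov model
#'
#' A hidden Markov model whose observation at each genomic bin is a binary
#' vector over many epigenomic datasets ("features") stacked together: one
#' column per dataset regardless of which cell type it came from. Each state
#' emits each feature independently as a Bernoulli draw, so the model is
#' fully described by an S x D emission matrix of "present"-call
#' probabilities, an S x S transition matrix and an initial distribution.
#'
#' @slot emissions numeric S x D matrix; `emissions[s, d]` is the probability
#'   that dataset `d` shows a present (1) call in state `s`.
#' @slot transitions numeric S x S stochastic matrix of state transitions.
#' @slot initialProbs numeric length-S initial state distribution.
#' @slot featureNames character length-D dataset identifiers, conventionally
#'   of the form `"<EID>-<mark>"`.
#'
#' @seealso [StackedHMM()], [trainStackedHMM()], [decodeSegmentation()]
#' @export
setClass("StackedHMM",
  representation(
    emissions = "matrix",
    transitions = "matrix",
    initialProbs = "numeric",
    featureNames = "character"
  )
)

setValidity("StackedHMM", function(object) {
  e <- object@emissions
  a <- object@transitions
  p <- object@initialProbs
  S <- nrow(e)
  msg <- character()
  if (S < 1L) msg <- c(msg, "model must have at least one state")
  if (nrow(a) != S || ncol(a) != S)
    msg <- c(msg, "transition matrix must be S x S")
  if (length(p) != S)
    msg <- c(msg, "initial distribution must have one entry per state")
  if (length(object@featureNames) != ncol(e))
    msg <- c(msg, "featureNames must have one entry per emission column")
  if (anyDuplicated(object@featureNames))
    msg <- c(msg, "featureNames must be unique")
  if (any(e < 0 | e > 1)) msg <- c(msg, "emission probabilities must lie in [0, 1]")
  if (any(a < 0 | a > 1) || any(abs(rowSums(a) - 1) > .PROB_TOL))
    msg <- c(msg, "transition rows must be probability distributions")
  if (any(p < 0) || abs(sum(p) - 1) > .PROB_TOL)
    msg <- c(msg, "initial probabilities must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Construct a StackedHMM
#'
#' @param emissions S x D matrix of per-state Bernoulli "present" probabilities.
#' @param transitions S x S row-stochastic transition matrix.
#' @param initialProbs length-S initial state distribution.
#' @param featureNames optional dataset names (defaults to the emission
#'   column names, then `"F1"..."FD"`).
#' @return A [StackedHMM-class] object.
#' @examples
#' m <- StackedHMM(
#'   emissions = rbind(c(0.9, 0.1), c(0.1, 0.9)),
#'   transitions = rbind(c(0.95, 0.05), c(0.05, 0.95)),
#'   initialProbs = c(0.5, 0.5)
#' )
#' nStates(m)
#' @export
StackedHMM <- function(emissions, transitions, initialProbs,
                       featureNames = NULL) {
  emissions <- as.matrix(emissions)
  transitions <- as.matrix(transitions)
  if (is.null(featureNames)) {
    featureNames <- colnames(emissions)
    if (is.null(featureNames)) featureNames <- paste0("F", seq_len(ncol(emissions)))
  }
  colnames(emissions) <- featureNames
  if (is.null(rownames(emissions)))
    rownames(emissions) <- paste0("S", seq_len(nrow(emissions)))
  new("StackedHMM",
    emissions = emissions, transitions = transitions,
    initialProbs = as.numeric(initialProbs),
    featureNames = as.character(featureNames)
  )
}

#' Fitted stacked HMM with its training trace
#'
#' Extends [StackedHMM-class] with the per-iteration log-likelihood trace of
#' the sampled-chunk Baum-Welch run and the resolved training configuration,
#' so a fit is self-describing and reproducible.
#'
#' @slot logLikTrace numeric; sampled-data log-likelihood at each iteration.
#'   Because each iteration may evaluate a different random subset of chunks,
#'   the trace need not be monotone.
#' @slot config list; resolved [trainConfig()] used for the run.
#' @export
setClass("StackedHMMFit",
  contains = "StackedHMM",
  representation(logLikTrace = "numeric", config = "list")
)

#' Chunk of binarized observations
#'
#' A block of consecutive 200-bp bins on one chromosome, holding the binary
#' present/absent calls (0/1; 2 = missing) for every dataset. Chromosomes are
#' split into chunks of at most 1 Mb so that training can subsample genomic
#' regions; each chunk is modelled as an independent sequence.
#'
#' @slot calls integer T x D matrix over \{0, 1, 2\}.
#' @slot chrom chromosome name.
#' @slot startBin 0-based index of the chunk's first bin on the chromosome.
#' @slot tag chunk tag, `"chrN"` or `"chrN.k"` for the k-th split chunk.
#' @export
setClass("ObservationChunk",
  representation(
    calls = "matrix",
    chrom = "character",
    startBin = "integer",
    tag = "character"
  )
)

setValidity("ObservationChunk", function(object) {
  v <- object@calls
  msg <- character()
  if (!is.numeric(v) && !is.integer(v)) msg <- c(msg, "calls must be numeric")
  if (length(v) && !all(v %in% c(0L, 1L, 2L)))
    msg <- c(msg, "calls must be 0, 1 or 2")
  if (object@startBin < 0L) msg <- c(msg, "startBin must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname ObservationChunk-class
#' @param calls integer matrix of binary calls (bins x datasets).
#' @param chrom chromosome name.
#' @param startBin 0-based first bin index on the chromosome.
#' @param tag chunk tag; defaults to the chromosome name.
#' @export
ObservationChunk <- function(calls, chrom, startBin = 0L, tag = chrom) {
  storage.mode(calls) <- "integer"
  new("ObservationChunk",
    calls = calls, chrom = as.character(chrom),
    startBin = as.integer(startBin), tag = as.character(tag)
  )
}

#' Genome-wide chromatin-state segmentation
#'
#' Per-chromosome run-length encoded state assignments at a fixed bin size.
#' The last bin of a chromosome may be truncated at the chromosome end; all
#' base-pair computations account for that.
#'
#' @slot states list of [S4Vectors::Rle] objects (one per chromosome) of
#'   1-based state indices, one element per bin.
#' @slot chromSizes named integer vector of chromosome lengths in bases.
#' @slot binSize bin width in bases (200 by default throughout the package).
#' @slot stateLabels character vector of state labels, e.g. `"1_Prom"`.
#' @export
setClass("Segmentation",
  representation(
    states = "list",
    chromSizes = "integer",
    binSize = "integer",
    stateLabels = "character"
  )
)

setValidity("Segmentation", function(object) {
  msg <- character()
  if (!identical(sort(names(object@states)), sort(names(object@chromSizes))))
    msg <- c(msg, "states and chromSizes must cover the same chromosomes")
  if (object@binSize < 1L) msg <- c(msg, "binSize must be positive")
  for (chrom in names(object@states)) {
    r <- object@states[[chrom]]
    nb <- .nBins(object@chromSizes[[chrom]], object@binSize)
    if (length(r) != nb) {
      msg <- c(msg, sprintf(
        "chromosome %s has %d bins but %d state assignments", chrom, nb, length(r)
      ))
    }
    if (length(r) && (min(runValue(r)) < 1L ||
                      max(runValue(r)) > length(object@stateLabels)))
      msg <- c(msg, sprintf("state indices on %s outside the label set", chrom))
  }
  if (length(msg)) msg else TRUE
})

#' @rdname Segmentation-class
#' @param states named list (one entry per chromosome) of per-bin 1-based
#'   state indices, plain vectors or [S4Vectors::Rle].
#' @param chromSizes named vector of chromosome lengths in bases.
#' @param binSize bin width in bases.
#' @param stateLabels optional labels; default `"S1"..."SN"`.
#' @export
Segmentation <- function(states, chromSizes, binSize = 200L,
                         stateLabels = NULL) {
  states <- lapply(states, function(x) if (is(x, "Rle")) x else Rle(as.integer(x)))
  nstates <- max(vapply(states, function(r) {
    if (length(r)) max(runValue(r)) else 0L
  }, integer(1)))
  if (is.null(stateLabels)) stateLabels <- paste0("S", seq_len(nstates))
  new("Segmentation",
    states = states,
    chromSizes = setNames(as.integer(chromSizes), names(chromSizes)),
    binSize = as.integer(binSize),
    stateLabels = as.character(stateLabels)
  )
}

.nBins <- function(chromLength, binSize) as.integer(ceiling(chromLength / binSize))
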