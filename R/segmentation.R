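#' Decode a genome-wide segmentation by maximum posterior
#'
#' Runs [forwardBackward()] over every chunk and assigns each bin the state
#' with the highest posterior probability (ties broken by the lowest state
#' index), the assignment rule under which the published genome-scale
#' annotation was produced. The chunks must tile every chromosome exactly
#' once.
#'
#' @param model a [StackedHMM-class].
#' @param chunks list of [ObservationChunk-class] covering the genome.
#' @param chromSizes named chromosome lengths.
#' @param binSize bin width in bases.
#' @param stateLabels optional labels (default `"S1"..."SN"`).
#' @return A [Segmentation-class].
#' @export
decodeSegmentation <- function(model, chunks, chromSizes, binSize = 200L,
                               stateLabels = NULL) {
  chroms <- vapply(chunks, function(ch) ch@chrom, character(1))
  perChrom <- lapply(setNames(names(chromSizes), names(chromSizes)), function(cn) {
    nb <- .nBins(chromSizes[[cn]], binSize)
    sel <- which(chroms == cn)
    if (!length(sel)) stop("no chunks cover chromosome ", cn)
    sel <- sel[order(vapply(chunks[sel], function(ch) ch@startBin, integer(1)))]
    v <- integer(nb)
    seen <- logical(nb)
    for (i in sel) {
      ch <- chunks[[i]]
      fb <- forwardBackward(model, ch)
      rows <- (ch@startBin + 1L):(ch@startBin + nrow(binCalls(ch)))
      if (max(rows) > nb || any(seen[rows]))
        stop("chunks overlap or exceed chromosome ", cn)
      v[rows] <- max.col(fb$gamma, ties.method = "first")
      seen[rows] <- TRUE
    }
    if (!all(seen)) stop("chunks leave gaps on chromosome ", cn)
    Rle(v)
  })
  if (is.null(stateLabels)) stateLabels <- paste0("S", seq_len(nStates(model)))
  Segmentation(perChrom, chromSizes, binSize, stateLabels)
}

#' Per-state genome coverage
#'
#' Fraction of the genome, in bases, assigned to each state. The final bin of
#' each chromosome is weighted by its true (possibly truncated) length, so
#' the fractions sum to exactly 1.
#'
#' @param seg a [Segmentation-class].
#' @return Named numeric vector over the state labels.
#' @export
stateCoverage <- function(seg) {
  bs <- binSize(seg)
  bases <- numeric(nStates(seg))
  for (chrom in names(seg@states)) {
    v <- seg@states[[chrom]]
    L <- seg@chromSizes[[chrom]]
    nb <- length(v)
    w <- rep(as.numeric(bs), nb)
    if (nb) w[nb] <- L - (nb - 1) * bs
    agg <- tapply(w, as.integer(as.vector(v)), sum)
    bases[as.integer(names(agg))] <- bases[as.integer(names(agg))] + agg
  }
  setNames(bases / sum(as.numeric(seg@chromSizes)), stateLabels(seg))
}

#' Per-bin state indices of a segmentation
#'
#' @param seg a [Segmentation-class].
#' @param chrom chromosome name (all chromosomes, concatenated in
#'   `chromSizes` order, when `NULL`).
#' @return Integer vector of 1-based state indices, one per bin.
#' @export
stateIndices <- function(seg, chrom = NULL) {
  if (!is.null(chrom)) return(as.integer(as.vector(seg@states[[chrom]])))
  unlist(lapply(names(seg@chromSizes), function(cn)
    as.integer(as.vector(seg@states[[cn]]))), use.names = FALSE)
}
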