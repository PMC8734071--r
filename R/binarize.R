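#' Count shifted reads per genomic bin
#'
#' Each read contributes one count to the bin containing its shifted 5' end:
#' plus-strand reads at `start + shift`, minus-strand reads at
#' `end - 1 - shift` (coordinates 0-based; unstranded reads are treated as
#' plus-strand). The shift approximates the midpoint of the sequenced
#' fragment. Shifted positions are clipped into the chromosome, so the total
#' count equals the number of reads.
#'
#' @param reads `GRanges` of read alignments (see [readReads()]).
#' @param chromSizes named chromosome lengths in bases.
#' @param binSize bin width in bases (200 throughout the method).
#' @param shift 5'-to-3' shift in bases applied before binning.
#' @return Named list with one non-negative integer vector per chromosome of
#'   `ceiling(length / binSize)` bin counts.
#' @export
countReads <- function(reads, chromSizes, binSize = 200L, shift = 100L) {
  if (binSize <= 0) stop("binSize must be positive")
  if (shift < 0) stop("shift must be non-negative")
  chrom <- as.character(GenomicRanges::seqnames(reads))
  if (!all(chrom %in% names(chromSizes)))
    stop("reads on chromosomes absent from chromSizes; filter with readReads()")
  minus <- as.character(GenomicRanges::strand(reads)) == "-"
  pos0 <- ifelse(minus,
    GenomicRanges::end(reads) - 1L - shift,
    GenomicRanges::start(reads) - 1L + shift
  )
  lens <- chromSizes[chrom]
  pos0 <- pmax(0L, pmin(as.integer(pos0), lens - 1L))
  bin <- pos0 %/% binSize
  out <- lapply(names(chromSizes), function(cn) {
    nb <- .nBins(chromSizes[[cn]], binSize)
    sel <- chrom == cn
    if (!any(sel)) return(integer(nb))
    tabulate(bin[sel] + 1L, nbins = nb)
  })
  names(out) <- names(chromSizes)
  out
}

#' Binarize a signal track against a control
#'
#' A bin is called present (1) when the Poisson upper-tail probability
#' \eqn{P(X \ge c)} of its signal count `c` is at most `pThreshold`, under a
#' bin-specific expectation \eqn{\lambda}. With a control track,
#' \eqn{\lambda = \max(\mathrm{control} \times r, \bar{s})} where `r` is the
#' signal/control sequencing-depth ratio and \eqn{\bar{s}} the global mean
#' signal per bin; without a control, \eqn{\lambda = \bar{s}} uniformly. An
#' all-zero signal yields an all-zero track.
#'
#' @param signal per-chromosome bin counts from [countReads()].
#' @param control matching control counts, or `NULL`.
#' @param pThreshold Poisson tail probability threshold (default `1e-4`).
#' @return Named list of integer 0/1 vectors, one per chromosome.
#' @export
binarizeTrack <- function(signal, control = NULL, pThreshold = 1e-4) {
  stopifnot(pThreshold > 0, pThreshold < 1)
  sAll <- unlist(signal, use.names = FALSE)
  if (any(sAll < 0)) stop("negative signal counts")
  meanSig <- sum(as.numeric(sAll)) / length(sAll)
  ratio <- 0
  if (!is.null(control)) {
    if (!identical(lengths(control), lengths(signal)))
      stop("signal and control are not aligned on the same bins")
    cAll <- unlist(control, use.names = FALSE)
    if (any(cAll < 0)) stop("negative control counts")
    totC <- sum(as.numeric(cAll))
    if (totC > 0) ratio <- sum(as.numeric(sAll)) / totC
  }
  lapply(setNames(names(signal), names(signal)), function(cn) {
    s <- signal[[cn]]
    lambda <- if (is.null(control)) rep(meanSig, length(s)) else
      pmax(control[[cn]] * ratio, meanSig)
    p <- ppois(s - 1L, lambda, lower.tail = FALSE)
    as.integer(s > 0L & p <= pThreshold)
  })
}

#' Merge per-dataset binary tracks into chromosome-chunked observation matrices
#'
#' Stacks the binary tracks of all datasets column-wise (column order follows
#' `names(tracks)`, i.e. the descriptor-table order, independently of any
#' batched processing order) and splits each chromosome into consecutive
#' chunks of at most `chunkLimit` bases. Chunks never span chromosomes; the
#' final partial bin of a chromosome is kept.
#'
#' @param tracks named list (one element per dataset) of per-chromosome
#'   binary vectors, all over the same chromosomes and bin counts.
#' @param chromSizes named chromosome lengths.
#' @param chunkLimit maximum chunk extent in bases (default 1 Mb).
#' @param binSize bin width in bases.
#' @return List of [ObservationChunk-class]; attribute `featureNames` holds
#'   the dataset order.
#' @export
mergeBinaries <- function(tracks, chromSizes, chunkLimit = 1e6, binSize = 200L) {
  if (!length(tracks)) stop("no datasets to merge")
  datasetNames <- names(tracks)
  if (is.null(datasetNames)) stop("tracks must be a named list")
  chunkBins <- max(1L, as.integer(chunkLimit %/% binSize))
  chunks <- list()
  for (chrom in names(chromSizes)) {
    nb <- .nBins(chromSizes[[chrom]], binSize)
    cols <- lapply(datasetNames, function(d) {
      v <- tracks[[d]][[chrom]]
      if (length(v) != nb)
        stop("dataset ", d, " has ", length(v), " bins on ", chrom,
             " but ", nb, " expected")
      v
    })
    m <- do.call(cbind, cols)
    colnames(m) <- datasetNames
    starts <- seq.int(0L, nb - 1L, by = chunkBins)
    split <- length(starts) > 1L
    for (k in seq_along(starts)) {
      rows <- (starts[k] + 1L):min(starts[k] + chunkBins, nb)
      tag <- if (split) paste0(chrom, ".", k - 1L) else chrom
      chunks[[length(chunks) + 1L]] <-
        ObservationChunk(m[rows, , drop = FALSE], chrom, starts[k], tag)
    }
  }
  attr(chunks, "featureNames") <- datasetNames
  chunks
}

#' Split a descriptor table into processing batches
#'
#' Binarizing hundreds of datasets is memory-bound, so the descriptor table
#' is cut into consecutive batches of at most `batchSize` rows that can be
#' processed independently (1032 datasets at the default batch size give 104
#' batches). Merging afterwards restores the original column order, so
#' batching never changes the result.
#'
#' @param descriptors `data.frame` from [readDescriptorTable()].
#' @param batchSize maximum rows per batch (default 10).
#' @return List of `ceiling(nrow / batchSize)` data.frames.
#' @export
splitDescriptorTable <- function(descriptors, batchSize = 10L) {
  if (batchSize < 1) stop("batchSize must be >= 1")
  n <- nrow(descriptors)
  if (n == 0) return(list())
  grp <- (seq_len(n) - 1L) %/% batchSize
  lapply(split(seq_len(n), grp), function(i) descriptors[i, , drop = FALSE])
}

#' Binarize one dataset from read files
#'
#' Convenience wrapper: count signal and control reads and binarize.
#'
#' @param signalReads,controlReads `GRanges` of alignments (`controlReads`
#'   may be `NULL`).
#' @inheritParams countReads
#' @inheritParams binarizeTrack
#' @return Named list of 0/1 vectors per chromosome.
#' @export
binarizeDataset <- function(signalReads, controlReads, chromSizes,
                            binSize = 200L, shift = 100L, pThreshold = 1e-4) {
  sig <- countReads(signalReads, chromSizes, binSize, shift)
  ctl <- if (is.null(controlReads)) NULL else
    countReads(controlReads, chromSizes, binSize, shift)
  binarizeTrack(sig, ctl, pThreshold)
}
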