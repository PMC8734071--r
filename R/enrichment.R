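.clipToGenome <- function(gr, chromSizes) {
  gr <- gr[as.character(GenomicRanges::seqnames(gr)) %in% names(chromSizes)]
  if (!length(gr)) return(gr)
  lens <- chromSizes[as.character(GenomicRanges::seqnames(gr))]
  keep <- GenomicRanges::start(gr) <= lens
  gr <- gr[keep]
  if (!length(gr)) return(gr)
  lens <- lens[keep]
  GenomicRanges::end(gr) <- pmin(GenomicRanges::end(gr), lens)
  GenomicRanges::reduce(GenomicRanges::sort(gr))
}

.overlapBases <- function(a, b) {
  if (!length(a) || !length(b)) return(0)
  hits <- GenomicRanges::findOverlaps(a, b, ignore.strand = TRUE)
  if (!length(hits)) return(0)
  ov <- IRanges::pintersect(a[S4Vectors::queryHits(hits)],
                            b[S4Vectors::subjectHits(hits)])
  sum(as.numeric(GenomicRanges::width(ov)))
}

#' Fold enrichment of states in external annotations
#'
#' The overlap between each state and each annotation relative to a uniform
#' genome-wide background, counted at single-base resolution:
#' \deqn{FE_{x,s} = \frac{\#SX \cdot \#G}{\#S \cdot \#X}}
#' where \eqn{\#S} is the number of bases in state \eqn{s}, \eqn{\#X} the
#' bases covered by annotation \eqn{x}, \eqn{\#SX} their overlap and
#' \eqn{\#G} the total genome length. Annotations are merged per label before
#' counting and clipped to the segmentation's chromosomes. An annotation with
#' no bases on those chromosomes yields an `NA` column; a state covering no
#' bases yields an `NA` row.
#'
#' @param seg a [Segmentation-class].
#' @param annotations named list of `GRanges` (a bare `GRanges` is treated as
#'   one annotation).
#' @return Numeric matrix, states x annotations, with attributes
#'   `genomeFraction` (per-annotation \eqn{\#X/\#G}) and `stateCoverage`.
#' @export
foldEnrichment <- function(seg, annotations) {
  if (is(annotations, "GRanges")) annotations <- list(annotation = annotations)
  cs <- chromSizes(seg)
  G <- sum(as.numeric(cs))
  segGR <- segmentationToGRanges(seg)
  byState <- lapply(seq_len(nStates(seg)), function(s)
    segGR[segGR$state == s])
  stateBases <- stateCoverage(seg) * G
  fe <- matrix(NA_real_, nStates(seg), length(annotations),
               dimnames = list(stateLabels(seg), names(annotations)))
  xFrac <- setNames(numeric(length(annotations)), names(annotations))
  for (j in seq_along(annotations)) {
    x <- .clipToGenome(annotations[[j]], cs)
    X <- sum(as.numeric(GenomicRanges::width(x)))
    xFrac[j] <- X / G
    if (X == 0) next
    for (s in seq_len(nStates(seg))) {
      if (stateBases[s] == 0) next
      SX <- .overlapBases(byState[[s]], x)
      fe[s, j] <- SX * G / (stateBases[s] * X)
    }
  }
  attr(fe, "genomeFraction") <- xFrac
  attr(fe, "stateCoverage") <- stateCoverage(seg)
  fe
}

#' Relative enrichment of a foreground over a background set
#'
#' Per-state ratio of the foreground's genome-wide fold enrichment to the
#' background's, used e.g. to compare lead fine-mapped variants against all
#' tested variants, or prioritized non-coding bases against all non-coding
#' bases. `NA` where the background enrichment is 0 or undefined.
#'
#' @param seg a [Segmentation-class].
#' @param foreground,background `GRanges`.
#' @return Named numeric vector over states.
#' @export
relativeEnrichment <- function(seg, foreground, background) {
  if (!length(foreground)) stop("empty foreground set")
  if (!length(background)) stop("empty background set")
  fe <- foldEnrichment(seg, list(fg = foreground, bg = background))
  out <- fe[, "fg"] / fe[, "bg"]
  out[!is.finite(out)] <- NA_real_
  setNames(out, stateLabels(seg))
}

#' Positional enrichment around anchor points
#'
#' Fold enrichment of every state at fixed strand-oriented offsets around a
#' set of anchor bases (TSS, TES, binding-site summits, ...). Offset 0 is the
#' bin containing the anchor base; positive offsets are downstream in the 5'
#' to 3' direction of the anchor's strand. For each offset, the fraction of
#' anchors whose offset bin carries a state is divided by that state's
#' genome-wide bin fraction; anchors whose offset bin falls outside the
#' chromosome are skipped at that offset.
#'
#' @param seg a [Segmentation-class].
#' @param anchors `GRanges` of single-base anchors with strand (unstranded
#'   treated as `+`).
#' @param window half-window in bases (default 25000); must be a multiple of
#'   `step`.
#' @param step offset spacing in bases (default: the segmentation bin size).
#' @return Numeric matrix, states x offsets, column names the signed offsets.
#' @export
positionalEnrichment <- function(seg, anchors, window = 25000L, step = NULL) {
  if (!length(anchors)) stop("empty anchor set")
  if (is.null(step)) step <- binSize(seg)
  if (window %% step != 0) stop("window must be a multiple of step")
  offsets <- seq.int(-window, window, by = step)
  bs <- binSize(seg)
  S <- nStates(seg)
  binsPerState <- numeric(S)
  stateVec <- lapply(setNames(names(chromSizes(seg)), names(chromSizes(seg))),
                     function(cn) stateIndices(seg, cn))
  for (v in stateVec) binsPerState <- binsPerState + tabulate(v, nbins = S)
  binFrac <- binsPerState / sum(binsPerState)
  chrom <- as.character(GenomicRanges::seqnames(anchors))
  pos0 <- GenomicRanges::start(anchors) - 1L
  minus <- as.character(GenomicRanges::strand(anchors)) == "-"
  lens <- chromSizes(seg)[chrom]
  counts <- matrix(0, S, length(offsets))
  valid <- numeric(length(offsets))
  for (k in seq_along(offsets)) {
    tgt <- ifelse(minus, pos0 - offsets[k], pos0 + offsets[k])
    ok <- tgt >= 0 & tgt < lens
    if (!any(ok)) next
    valid[k] <- sum(ok)
    bin <- tgt[ok] %/% bs + 1L
    st <- mapply(function(cn, b) stateVec[[cn]][b], chrom[ok], bin)
    counts[, k] <- tabulate(st, nbins = S)
  }
  enr <- sweep(counts, 2, valid, "/")
  enr <- sweep(enr, 1, binFrac, "/")
  enr[, valid == 0] <- NA_real_
  enr[binFrac == 0, ] <- NA_real_
  dimnames(enr) <- list(stateLabels(seg), offsets)
  enr
}

#' Sampled overlap probabilities against per-sample segmentations
#'
#' Estimates, for each state of the stacked segmentation, the probability
#' that a genomic bin assigned to it carries each state of an external
#' per-sample segmentation (e.g. a concatenated-model annotation) in samples
#' of each group. For each stacked state, `nBins` assigned bins are sampled
#' uniformly (with replacement only when fewer exist); the per-sample
#' frequencies of external states among them are averaged over `repetitions`
#' samplings and then over the samples of each group.
#'
#' @param seg a [Segmentation-class].
#' @param externals named list of [Segmentation-class] objects on the same
#'   chromosomes and bin size, one per sample.
#' @param sampleGroups named character vector mapping sample name to group.
#' @param nBins bins sampled per repetition (default 100).
#' @param repetitions number of samplings (default 21).
#' @param seed integer seed.
#' @return `data.frame` with columns `state`, `group`, `externalState`,
#'   `probability`; per `(state, group)` the probabilities sum to 1. States
#'   with no assigned bins are omitted.
#' @export
sampledOverlapProbabilities <- function(seg, externals, sampleGroups,
                                        nBins = 100L, repetitions = 21L,
                                        seed = 1L) {
  stopifnot(length(externals) >= 1, !is.null(names(externals)))
  set.seed(seed)
  segBins <- stateIndices(seg)
  extBins <- lapply(externals, stateIndices)
  for (e in extBins) {
    if (length(e) != length(segBins))
      stop("external segmentations must align to the same bins")
  }
  extLabels <- stateLabels(externals[[1]])
  nes <- length(extLabels)
  groups <- sampleGroups[names(externals)]
  out <- list()
  for (s in seq_len(nStates(seg))) {
    idx <- which(segBins == s)
    if (!length(idx)) next
    freq <- matrix(0, length(externals), nes)
    for (r in seq_len(repetitions)) {
      samp <- if (length(idx) >= nBins) sample(idx, nBins) else
        sample(idx, nBins, replace = TRUE)
      for (ei in seq_along(extBins)) {
        freq[ei, ] <- freq[ei, ] +
          tabulate(extBins[[ei]][samp], nbins = nes) / nBins
      }
    }
    freq <- freq / repetitions
    for (g in unique(groups)) {
      gm <- colMeans(freq[groups == g, , drop = FALSE])
      out[[length(out) + 1L]] <- data.frame(
        state = stateLabels(seg)[s], group = g,
        externalState = extLabels, probability = gm,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Write a fold-enrichment table as TSV
#'
#' One row per state plus a final `Genome%` row giving each annotation's
#' genome coverage, and a leading `Genome%` column with each state's
#' coverage — the layout used for state-characterization figures.
#'
#' @param fe matrix from [foldEnrichment()].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
writeEnrichmentTable <- function(fe, path) {
  cov <- attr(fe, "stateCoverage")
  gf <- attr(fe, "genomeFraction")
  dt <- data.table::data.table(
    State = c(rownames(fe), "Genome%"),
    `Genome%` = c(round(cov * 100, 4), 100)
  )
  for (j in colnames(fe)) dt[[j]] <- c(fe[, j], gf[[j]] * 100)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
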