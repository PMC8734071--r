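#' Simulation configuration with desk-scale defaults
#'
#' Defines a complete synthetic study: a known ground-truth model, chromosome
#' sizes, read-simulation rates and a seed. The defaults describe a
#' well-separated small genome — two 1-Mb chromosomes (10,000 200-bp bins),
#' five states over ten datasets, sticky transitions — on which the whole
#' pipeline runs in seconds while exercising every input class the real
#' method consumes.
#'
#' @param chromSizes named chromosome lengths (default two 1-Mb chromosomes).
#' @param truth ground-truth [StackedHMM-class]; default
#'   [exampleTruthModel()].
#' @param binSize bin width in bases.
#' @param chunkLimit chunk extent in bases for the generated observation
#'   chunks.
#' @param signalRate mean signal reads per active bin (Poisson).
#' @param backgroundRate mean reads per inactive bin and mean control reads
#'   per bin.
#' @param seed integer master seed; fixes all randomness downstream.
#' @return Configuration list.
#' @export
simulationConfig <- function(chromSizes = c(chr1 = 1e6, chr2 = 1e6),
                             truth = exampleTruthModel(),
                             binSize = 200L, chunkLimit = 1e6,
                             signalRate = 20, backgroundRate = 0.5,
                             seed = 1L) {
  stopifnot(signalRate > 0, backgroundRate > 0)
  list(
    chromSizes = setNames(as.integer(chromSizes), names(chromSizes)),
    truth = truth, binSize = as.integer(binSize), chunkLimit = chunkLimit,
    signalRate = signalRate, backgroundRate = backgroundRate,
    seed = as.integer(seed)
  )
}

#' Well-separated ground-truth model
#'
#' Each dataset is strongly emitted (probability `hi`) by the states it is
#' assigned to cyclically and weakly (`lo`) elsewhere; transitions are sticky
#' with probability `stay` of remaining in a state. This is the default truth
#' used by the synthetic study.
#'
#' @param nStates,nFeatures model dimensions.
#' @param hi,lo emission probabilities for assigned/unassigned datasets.
#' @param stay self-transition probability.
#' @return A [StackedHMM-class].
#' @export
exampleTruthModel <- function(nStates = 5L, nFeatures = 10L,
                              hi = 0.9, lo = 0.05, stay = 0.9) {
  e <- matrix(lo, nStates, nFeatures)
  for (d in seq_len(nFeatures)) e[(d - 1L) %% nStates + 1L, d] <- hi
  a <- matrix((1 - stay) / (nStates - 1), nStates, nStates)
  diag(a) <- stay
  StackedHMM(e, a, rep(1 / nStates, nStates),
             featureNames = paste0("E", sprintf("%03d", seq_len(nFeatures)),
                                   "-mark", seq_len(nFeatures)))
}

#' Simulate a genome of binary calls from a known model
#'
#' Samples a state path per chromosome from the truth's initial and
#' transition probabilities and emits each dataset's call as an independent
#' Bernoulli draw from the state's emission probability, then chunks the
#' calls at the configured limit. Deterministic per seed.
#'
#' @param config a [simulationConfig()].
#' @return List with `truth` (the generating [Segmentation-class]) and
#'   `chunks` (list of [ObservationChunk-class]).
#' @export
simulateGenome <- function(config) {
  set.seed(config$seed)
  truth <- config$truth
  e <- emissionProbs(truth)
  D <- nFeatures(truth)
  states <- list()
  tracks <- lapply(featureNames(truth), function(d) list())
  names(tracks) <- featureNames(truth)
  for (chrom in names(config$chromSizes)) {
    nb <- .nBins(config$chromSizes[[chrom]], config$binSize)
    path <- .cs_simulate_path(initialProbs(truth), transitionProbs(truth), nb)
    states[[chrom]] <- Rle(path)
    calls <- matrix(
      as.integer(runif(nb * D) < e[path, ]), nb, D,
      dimnames = list(NULL, featureNames(truth))
    )
    for (d in featureNames(truth)) tracks[[d]][[chrom]] <- calls[, d]
  }
  chunks <- mergeBinaries(tracks, config$chromSizes,
                          chunkLimit = config$chunkLimit,
                          binSize = config$binSize)
  list(
    truth = Segmentation(states, config$chromSizes, config$binSize),
    chunks = chunks,
    tracks = tracks
  )
}

#' Simulate signal and control reads for one binary track
#'
#' Per bin, the signal read count is Poisson with mean `signalRate` where the
#' truth call is 1 and `backgroundRate` elsewhere; control counts are Poisson
#' with mean `backgroundRate` everywhere. Each read is placed so that its
#' shifted 5' end falls on a uniformly drawn base of the intended bin — so
#' [countReads()] with the same shift recovers the intended counts exactly —
#' with strand drawn uniformly except near chromosome edges, where the strand
#' keeping the read in bounds is used.
#'
#' @param binary named per-chromosome list of 0/1 vectors (one dataset).
#' @param chromSizes named chromosome lengths.
#' @param signalRate,backgroundRate Poisson means per bin.
#' @param binSize bin width in bases.
#' @param shift the 5' shift that [countReads()] will undo.
#' @param readLength simulated read length in bases.
#' @param seed integer seed.
#' @return List with `signal` and `control` `GRanges`.
#' @export
simulateReads <- function(binary, chromSizes, signalRate = 20,
                          backgroundRate = 0.5, binSize = 200L,
                          shift = 100L, readLength = 36L, seed = 1L) {
  stopifnot(signalRate > 0, backgroundRate > 0)
  set.seed(seed)
  mk <- function(rates) {
    chromv <- character(0); startv <- integer(0); endv <- integer(0)
    strandv <- character(0)
    for (chrom in names(chromSizes)) {
      L <- chromSizes[[chrom]]
      n <- rpois(length(rates[[chrom]]), rates[[chrom]])
      tot <- sum(n)
      if (!tot) next
      binIdx <- rep(seq_along(n) - 1L, n)
      lo <- binIdx * binSize
      hiEx <- pmin(lo + binSize, L)
      p <- lo + floor(runif(tot) * (hiEx - lo))
      plusOk <- p >= shift & (p - shift + readLength) <= L
      minusOk <- (p + shift + 1L) <= L & (p + shift + 1L - readLength) >= 0L
      pickPlus <- ifelse(plusOk & minusOk, runif(tot) < 0.5, plusOk)
      keep <- plusOk | minusOk
      p <- p[keep]; pickPlus <- pickPlus[keep]
      s0 <- ifelse(pickPlus, p - shift, p + shift + 1L - readLength)
      e0 <- s0 + readLength
      chromv <- c(chromv, rep(chrom, length(p)))
      startv <- c(startv, as.integer(s0)); endv <- c(endv, as.integer(e0))
      strandv <- c(strandv, ifelse(pickPlus, "+", "-"))
    }
    GenomicRanges::GRanges(
      seqnames = chromv,
      ranges = IRanges::IRanges(start = startv + 1L, end = endv),
      strand = strandv
    )
  }
  sigRates <- lapply(binary, function(v) ifelse(v == 1L, signalRate, backgroundRate))
  ctlRates <- lapply(binary, function(v) rep(backgroundRate, length(v)))
  names(sigRates) <- names(binary); names(ctlRates) <- names(binary)
  list(signal = mk(sigRates), control = mk(ctlRates))
}

#' Toy annotation set with analytically known enrichment
#'
#' Places `n` intervals so that each falls inside a run of one of the
#' `targetStates` with probability `hitRate` and inside a non-target run
#' otherwise (runs chosen with probability proportional to their length, the
#' interval clipped into the run). With `hitRate = 1` and a single target
#' state the fold enrichment is exactly `1 / coverage(target)`; more
#' generally the expected enrichment is computable in closed form from
#' `hitRate` and the state coverages.
#'
#' @param truthSeg generating [Segmentation-class].
#' @param targetStates integer state indices to enrich in.
#' @param hitRate probability an interval lands in a target run.
#' @param n number of intervals.
#' @param width interval width in bases (clipped to the chosen run).
#' @param seed integer seed.
#' @return `GRanges` of annotation intervals.
#' @export
makeToyAnnotations <- function(truthSeg, targetStates, hitRate, n = 200L,
                               width = 100L, seed = 1L) {
  stopifnot(hitRate >= 0, hitRate <= 1, n >= 1)
  set.seed(seed)
  segGR <- segmentationToGRanges(truthSeg)
  inTgt <- segGR$state %in% targetStates
  pick <- function(runs, m) {
    if (!length(runs) || m == 0) return(NULL)
    wts <- as.numeric(GenomicRanges::width(runs))
    i <- sample.int(length(runs), m, replace = TRUE, prob = wts)
    rw <- GenomicRanges::width(runs)[i]
    wlen <- pmin(width, rw)
    off <- floor(runif(m) * (rw - wlen + 1))
    GenomicRanges::GRanges(
      seqnames = factor(as.character(GenomicRanges::seqnames(runs)[i]),
                        levels = names(chromSizes(truthSeg))),
      ranges = IRanges::IRanges(
        start = GenomicRanges::start(runs)[i] + as.integer(off),
        width = wlen
      )
    )
  }
  hit <- runif(n) < hitRate
  out <- c(pick(segGR[inTgt], sum(hit)), pick(segGR[!inTgt], sum(!hit)))
  GenomicRanges::sort(out)
}

#' Toy gene set over a simulated genome
#'
#' Uniformly placed non-overlapping genes with random strand, for expression
#' analyses.
#'
#' @param chromSizes named chromosome lengths.
#' @param n number of genes.
#' @param minLength,maxLength gene length range in bases.
#' @param seed integer seed.
#' @return Stranded `GRanges` with `gene_id`.
#' @export
makeToyGenes <- function(chromSizes, n = 100L, minLength = 2000L,
                         maxLength = 20000L, seed = 1L) {
  set.seed(seed)
  chrom <- sample(names(chromSizes), n, replace = TRUE,
                  prob = chromSizes / sum(chromSizes))
  len <- as.integer(floor(runif(n, minLength, maxLength + 1)))
  maxStart <- chromSizes[chrom] - len
  start0 <- as.integer(floor(runif(n) * pmax(1, maxStart)))
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, width = len),
    strand = sample(c("+", "-"), n, replace = TRUE),
    gene_id = sprintf("gene%04d", seq_len(n))
  )
  GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
  GenomeInfoDb::seqlengths(gr) <- unname(chromSizes)
  GenomicRanges::sort(gr)
}

#' Toy expression matrix with state-linked effects
#'
#' Each gene's expression is drawn around the effect size of the state
#' covering the largest share of its bases, with Gaussian noise, truncated at
#' zero to stay on the log(RPKM+1) scale.
#'
#' @param genes `GRanges` with `gene_id`.
#' @param truthSeg [Segmentation-class] defining the majority states.
#' @param effectSizes numeric vector, one mean expression per state.
#' @param nSamples number of sample columns.
#' @param noiseSd Gaussian noise sd.
#' @param seed integer seed.
#' @return Numeric matrix, genes x samples, gene IDs as rownames.
#' @export
makeToyExpression <- function(genes, truthSeg, effectSizes, nSamples = 3L,
                              noiseSd = 0.1, seed = 1L) {
  stopifnot(length(effectSizes) == nStates(truthSeg))
  set.seed(seed)
  segGR <- segmentationToGRanges(truthSeg)
  hits <- GenomicRanges::findOverlaps(genes, segGR, ignore.strand = TRUE)
  ov <- IRanges::pintersect(genes[S4Vectors::queryHits(hits)],
                            segGR[S4Vectors::subjectHits(hits)])
  dt <- data.table::data.table(
    g = S4Vectors::queryHits(hits),
    s = segGR$state[S4Vectors::subjectHits(hits)],
    w = GenomicRanges::width(ov)
  )
  maj <- dt[, list(w = sum(w)), by = c("g", "s")]
  maj <- maj[order(maj$g, -maj$w, maj$s), ]
  majState <- maj[!duplicated(maj$g), ]
  mu <- effectSizes[majState$s[match(seq_along(genes), majState$g)]]
  m <- matrix(pmax(0, rnorm(length(genes) * nSamples, mean = mu, sd = noiseSd)),
              length(genes), nSamples,
              dimnames = list(genes$gene_id,
                              paste0("sample", seq_len(nSamples))))
  m
}

#' Toy dataset metadata table
#'
#' Assigns marks and tissue groups to feature names cyclically, emulating the
#' epigenome-ID / mark / tissue-group structure of real dataset collections.
#'
#' @param featureNames dataset names.
#' @param marks mark names to cycle over.
#' @param groups tissue-group names to cycle over.
#' @return `data.frame` with columns `feature`, `eid`, `mark`, `group`.
#' @export
makeToyMetadata <- function(featureNames,
                            marks = c("H3K4me1", "H3K4me3", "H3K27ac",
                                      "H3K36me3", "DNase"),
                            groups = c("Blood", "Brain", "ESC")) {
  n <- length(featureNames)
  data.frame(
    feature = featureNames,
    eid = sprintf("E%03d", seq_len(n)),
    mark = rep_len(marks, n),
    group = rep_len(groups, n),
    stringsAsFactors = FALSE
  )
}
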