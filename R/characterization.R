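.allBins <- function(chromSizes, binSize) {
  out <- lapply(names(chromSizes), function(cn) {
    nb <- .nBins(chromSizes[[cn]], binSize)
    starts <- seq.int(1L, by = binSize, length.out = nb)
    GenomicRanges::GRanges(
      seqnames = factor(cn, levels = names(chromSizes)),
      ranges = IRanges::IRanges(start = starts,
                                end = pmin(starts + binSize - 1L, chromSizes[[cn]]))
    )
  })
  do.call(c, out)
}

.outerTSS <- function(genes) {
  ids <- genes$gene_id
  minus <- as.character(GenomicRanges::strand(genes)) == "-"
  if (any(as.character(GenomicRanges::strand(genes)) == "*"))
    stop("genes must be stranded for TSS analyses")
  tss0 <- ifelse(minus, GenomicRanges::end(genes) - 1L,
                 GenomicRanges::start(genes) - 1L)
  # outer TSS: 5'-most annotated start per gene on its strand
  dt <- data.table::data.table(
    id = ids, chrom = as.character(GenomicRanges::seqnames(genes)),
    tss0 = tss0, minus = minus
  )
  agg <- dt[, list(
    chrom = chrom[1],
    tss0 = if (minus[1]) max(tss0) else min(tss0),
    minus = minus[1]
  ), by = "id"]
  agg
}

#' Base-pair-normalized average expression per state
#'
#' For each state, the expression of the genes overlapping its bins averaged
#' with inverse-gene-length weights, so long genes do not dominate:
#' \deqn{\frac{\sum_{i \in B_s}\sum_{g \in G_i} E_g/L_g}
#'            {\sum_{i \in B_s}\sum_{g \in G_i} 1/L_g}}
#' where \eqn{B_s} are the bins assigned to state \eqn{s} and \eqn{G_i} the
#' genes overlapping bin \eqn{i} by at least one base. Computed per sample,
#' with the per-state mean and coefficient of variation across samples.
#'
#' @param seg a [Segmentation-class].
#' @param genes `GRanges` with a `gene_id` metadata column.
#' @param expr numeric matrix, genes x samples (log(RPKM+1) scale), gene IDs
#'   as rownames.
#' @return List with `values` (states x samples matrix, `NA` where a state
#'   overlaps no gene), `mean` and `cv` (across samples, per state).
#' @export
expressionByState <- function(seg, genes, expr) {
  if (is.null(dim(expr))) expr <- cbind(sample1 = expr)
  gidx <- match(genes$gene_id, rownames(expr))
  if (anyNA(gidx)) stop("genes missing from the expression matrix")
  bins <- .allBins(chromSizes(seg), binSize(seg))
  st <- stateIndices(seg)
  hits <- GenomicRanges::findOverlaps(bins, genes, ignore.strand = TRUE)
  S <- nStates(seg)
  values <- matrix(NA_real_, S, ncol(expr),
                   dimnames = list(stateLabels(seg), colnames(expr)))
  if (length(hits)) {
    b <- S4Vectors::queryHits(hits)
    g <- S4Vectors::subjectHits(hits)
    L <- as.numeric(GenomicRanges::width(genes))[g]
    stateOf <- st[b]
    den <- tapply(1 / L, stateOf, sum)
    for (j in seq_len(ncol(expr))) {
      E <- expr[gidx[g], j]
      num <- tapply(E / L, stateOf, sum)
      values[as.integer(names(num)), j] <- num / den
    }
  }
  mu <- rowMeans(values)
  sdv <- apply(values, 1, sd)
  list(values = values, mean = mu, cv = ifelse(mu != 0, sdv / mu, NA_real_))
}

#' State-resolved expression around transcription start sites
#'
#' For every 200-bp bin within `window` bases of a gene's outer TSS
#' (strand-oriented offsets; the TSS-overlapping bin is offset 0), records
#' the bin's state and the gene's expression, averages expression per
#' (state, offset) cell, optionally smooths each state's profile with a
#' centered moving average of width `smoothWindow` and drops the
#' half-window's worth of edge offsets (251 columns before smoothing, 231
#' after with the defaults), then averages the per-sample tables.
#'
#' @param seg a [Segmentation-class].
#' @param genes stranded `GRanges` with `gene_id`.
#' @param expr genes x samples expression matrix.
#' @param window half-window in bases (default 25000).
#' @param step offset spacing (default: segmentation bin size).
#' @param smoothWindow odd moving-average width (default 21).
#' @param smooth set `FALSE` to return the raw per-offset averages.
#' @return states x offsets matrix averaged over samples (cells with no
#'   contributing gene are `NA`; missing cells are skipped by the smoother).
#' @export
positionalExpression <- function(seg, genes, expr, window = 25000L,
                                 step = NULL, smoothWindow = 21L,
                                 smooth = TRUE) {
  if (is.null(step)) step <- binSize(seg)
  if (smoothWindow %% 2 == 0) stop("smoothWindow must be odd")
  if (is.null(dim(expr))) expr <- cbind(sample1 = expr)
  offsets <- seq.int(-window, window, by = step)
  K <- length(offsets)
  tss <- .outerTSS(genes)
  gidx <- match(tss$id, rownames(expr))
  if (anyNA(gidx)) stop("genes missing from the expression matrix")
  bs <- binSize(seg)
  cs <- chromSizes(seg)
  stateVec <- lapply(setNames(names(cs), names(cs)),
                     function(cn) stateIndices(seg, cn))
  S <- nStates(seg)
  # (state, offset, gene) incidence shared by all samples
  cell <- integer(0); geneRow <- integer(0)
  for (i in seq_len(nrow(tss))) {
    tgt <- if (tss$minus[i]) tss$tss0[i] - offsets else tss$tss0[i] + offsets
    ok <- tgt >= 0 & tgt < cs[[tss$chrom[i]]]
    if (!any(ok)) next
    b <- tgt[ok] %/% bs + 1L
    stv <- stateVec[[tss$chrom[i]]][b]
    cell <- c(cell, (which(ok) - 1L) * S + stv)
    geneRow <- c(geneRow, rep(gidx[i], sum(ok)))
  }
  cnt <- tabulate(cell, nbins = S * K)
  acc <- matrix(NA_real_, S, K, dimnames = list(stateLabels(seg), offsets))
  tables <- lapply(seq_len(ncol(expr)), function(j) {
    sums <- numeric(S * K)
    agg <- tapply(expr[geneRow, j], cell, sum)
    sums[as.integer(names(agg))] <- agg
    m <- acc
    m[] <- ifelse(cnt > 0, sums / cnt, NA_real_)
    m
  })
  if (smooth) {
    half <- (smoothWindow - 1L) %/% 2L
    tables <- lapply(tables, function(m) {
      sm <- m
      for (k in seq_len(K)) {
        win <- max(1L, k - half):min(K, k + half)
        sm[, k] <- rowMeans(m[, win, drop = FALSE], na.rm = TRUE)
      }
      sm[is.nan(sm)] <- NA_real_
      sm[, (half + 1L):(K - half), drop = FALSE]
    })
  }
  out <- Reduce(`+`, lapply(tables, function(m) { m[is.na(m)] <- 0; m }))
  nOk <- Reduce(`+`, lapply(tables, function(m) !is.na(m)))
  out <- out / nOk
  out[nOk == 0] <- NA_real_
  out
}

#' Average per-base signal per state
#'
#' Unweighted mean over the non-missing single-base values falling in each
#' state — e.g. fractional DNA methylation at CpG sites.
#'
#' @param seg a [Segmentation-class].
#' @param positions `GRanges` of single bases with a numeric metadata column
#'   `value` (`NA` allowed).
#' @return Named numeric vector over states (`NA` where a state contains no
#'   non-missing position).
#' @export
meanSignalByState <- function(seg, positions) {
  vals <- positions$value
  keep <- !is.na(vals)
  positions <- positions[keep]; vals <- vals[keep]
  out <- setNames(rep(NA_real_, nStates(seg)), stateLabels(seg))
  if (!length(positions)) return(out)
  bs <- binSize(seg)
  chrom <- as.character(GenomicRanges::seqnames(positions))
  bin <- (GenomicRanges::start(positions) - 1L) %/% bs + 1L
  st <- mapply(function(cn, b) as.integer(seg@states[[cn]][b]), chrom, bin)
  agg <- tapply(vals, st, mean)
  out[as.integer(names(agg))] <- agg
  out
}

#' Coefficient of variation of emissions across tissue groups
#'
#' For marks strongly tied to promoter/enhancer activity, measures how
#' tissue-group-specific each state's emissions are: per state and mark, the
#' datasets carrying the mark are averaged within each tissue group, and the
#' coefficient of variation (sample sd / mean) is taken across the group
#' means; group/mark combinations with no dataset are excluded. The per-state
#' values are then averaged over the states of each state group.
#'
#' @param model a [StackedHMM-class].
#' @param metadata `data.frame` with columns `feature`, `mark`, `group`.
#' @param marks marks to analyse (default the six promoter/enhancer marks).
#' @param stateGroups optional integer/character vector of length
#'   `nStates(model)` assigning each state to a group; default one group per
#'   state.
#' @return Numeric matrix, state groups x marks (`NA` where undefined).
#' @export
emissionCV <- function(model, metadata,
                       marks = c("DNase", "H3K27ac", "H3K4me1", "H3K4me2",
                                 "H3K4me3", "H3K9ac"),
                       stateGroups = NULL) {
  S <- nStates(model)
  if (is.null(stateGroups)) {
    stateGroups <- rownames(emissionProbs(model))
    if (is.null(stateGroups)) stateGroups <- paste0("S", seq_len(S))
  }
  e <- emissionProbs(model)
  cvs <- matrix(NA_real_, S, length(marks), dimnames = list(NULL, marks))
  for (mi in seq_along(marks)) {
    sel <- which(metadata$mark == marks[mi])
    if (!length(sel)) next
    cols <- match(metadata$feature[sel], featureNames(model))
    if (anyNA(cols))
      stop("metadata features absent from the model: ",
           paste(metadata$feature[sel][is.na(cols)], collapse = ", "))
    grp <- metadata$group[sel]
    for (s in seq_len(S)) {
      gm <- tapply(e[s, cols], grp, mean)
      mu <- mean(gm)
      if (length(gm) >= 2 && mu > 0) cvs[s, mi] <- sd(gm) / mu
    }
  }
  out <- rowsum(cvs, group = stateGroups, na.rm = TRUE)
  nOk <- rowsum((!is.na(cvs)) * 1, group = stateGroups)
  res <- out / nOk
  res[nOk == 0] <- NA_real_
  res
}

#' Bonferroni-corrected significance threshold
#'
#' @param m family size (number of tests).
#' @param alpha family-wise significance level.
#' @return `alpha / m`.
#' @export
bonferroniThreshold <- function(m, alpha = 0.05) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Differential emission of a mark in one tissue group
#'
#' For every (state, mark, tissue group) with at least one dataset inside and
#' one outside the group, tests by one-sided Mann-Whitney whether the state's
#' emission probabilities for the mark's datasets in the group are greater
#' than those outside it. Significance is Bonferroni-corrected over the whole
#' constructed family.
#'
#' @param model a [StackedHMM-class].
#' @param metadata `data.frame` with columns `feature`, `mark`, `group`.
#' @param marks marks to test (default the eight most profiled).
#' @param alpha family-wise significance level.
#' @return `data.frame` with columns `state`, `mark`, `group`, `p`,
#'   `significant`; attributes `m` (family size) and `threshold`
#'   (`alpha / m`).
#' @export
differentialEmissionTests <- function(model, metadata,
                                      marks = c("H3K9me3", "H3K4me1", "H3K4me3",
                                                "H3K27me3", "H3K36me3",
                                                "H3K27ac", "H3K9ac", "DNase"),
                                      alpha = 0.05) {
  e <- emissionProbs(model)
  rows <- list()
  for (mk in marks) {
    sel <- which(metadata$mark == mk)
    if (!length(sel)) next
    cols <- match(metadata$feature[sel], featureNames(model))
    if (anyNA(cols))
      stop("metadata features absent from the model: ",
           paste(metadata$feature[sel][is.na(cols)], collapse = ", "))
    grp <- metadata$group[sel]
    for (g in unique(grp)) {
      inCols <- cols[grp == g]
      outCols <- cols[grp != g]
      if (!length(inCols) || !length(outCols)) next
      for (s in seq_len(nStates(model))) {
        p <- suppressWarnings(
          wilcox.test(e[s, inCols], e[s, outCols],
                      alternative = "greater")$p.value
        )
        rows[[length(rows) + 1L]] <- data.frame(
          state = s, mark = mk, group = g, p = p, stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, rows)
  m <- nrow(res)
  thr <- bonferroniThreshold(m, alpha)
  res$significant <- res$p < thr
  attr(res, "m") <- m
  attr(res, "threshold") <- thr
  res
}

#' Greedy Naive-Bayes selection of summary datasets
#'
#' Selects a small ordered subset of datasets whose Naive-Bayes state
#' predictions best agree with the full model's assignments on a sample of
#' bins, for compact visual summaries of the emission matrix. At each step
#' the feature maximizing the agreement between the full-model assignment and
#' \eqn{\arg\max_s \hat\pi_s \prod_{d \in F} \mathrm{Bern}(o_d; e_{s,d})}
#' (with \eqn{\hat\pi} the empirical state frequencies on the sample) is
#' added; ties break to the lower feature index.
#'
#' @param model a [StackedHMM-class].
#' @param calls integer bins x features matrix of binary calls for the
#'   sampled bins.
#' @param assignments full-model state index (1-based) per sampled bin.
#' @param k number of datasets to select.
#' @param nSample optional cap on the number of bins used (uniform subsample;
#'   default all provided bins, the genome-scale runs use 50k).
#' @param seed seed for the subsample.
#' @return Integer vector of `k` feature indices in selection order, with
#'   attribute `agreement` (the agreement after each addition, non-decreasing
#'   on the sample).
#' @export
greedySummarySelection <- function(model, calls, assignments, k,
                                   nSample = NULL, seed = 1L) {
  D <- nFeatures(model)
  if (k > D) stop("k must not exceed the number of features")
  if (k == 0) return(integer(0))
  stopifnot(nrow(calls) == length(assignments))
  if (!is.null(nSample) && nSample < nrow(calls)) {
    set.seed(seed)
    keep <- sample.int(nrow(calls), nSample)
    calls <- calls[keep, , drop = FALSE]
    assignments <- assignments[keep]
  }
  S <- nStates(model)
  e <- emissionProbs(model)
  piHat <- tabulate(assignments, nbins = S) / length(assignments)
  logE1 <- log(e); logE0 <- log(1 - e)
  contrib <- function(f) {
    o <- calls[, f]
    outer(o == 1L, logE1[, f]) + outer(o == 0L, logE0[, f])
  }
  base <- matrix(log(piHat), nrow(calls), S, byrow = TRUE)
  chosen <- integer(0)
  agreement <- numeric(0)
  for (step in seq_len(k)) {
    best <- NA_integer_; bestAcc <- -Inf
    for (f in setdiff(seq_len(D), chosen)) {
      sc <- base + contrib(f)
      pred <- max.col(sc, ties.method = "first")
      acc <- mean(pred == assignments)
      if (acc > bestAcc + 1e-12) { bestAcc <- acc; best <- f }
    }
    chosen <- c(chosen, best)
    agreement <- c(agreement, bestAcc)
    base <- base + contrib(best)
  }
  attr(chosen, "agreement") <- agreement
  chosen
}
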