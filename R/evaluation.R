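.binOverlapBases <- function(seg, target) {
  cs <- chromSizes(seg)
  bs <- binSize(seg)
  tgt <- .clipToGenome(target, cs)
  # rebuild on exactly the segmentation's chromosomes so coverage() accepts
  # the named width vector even when the clipped target is empty
  tgt <- GenomicRanges::GRanges(
    seqnames = factor(as.character(GenomicRanges::seqnames(tgt)),
                      levels = names(cs)),
    ranges = IRanges::ranges(tgt)
  )
  cov <- GenomicRanges::coverage(tgt,
    width = setNames(as.integer(cs), names(cs)))
  unlist(lapply(names(cs), function(cn) {
    nb <- .nBins(cs[[cn]], bs)
    starts <- seq.int(1L, by = bs, length.out = nb)
    ends <- pmin(starts + bs - 1L, cs[[cn]])
    as.numeric(IRanges::viewSums(IRanges::Views(cov[[cn]], starts, ends)))
  }), use.names = FALSE)
}

#' AUROC of a segmentation at predicting an annotation
#'
#' Evaluates how informative a state annotation is about the positions of an
#' external annotation. The genome's bins are randomly split in half into
#' training and test sets; per-state enrichment for the target is computed on
#' the training bins only (overlap bases per state base, relative to the
#' training-wide rate); states are ranked by decreasing enrichment (ties by
#' lower state index); and test bins are predicted positive state-by-state
#' along that ranking. A test bin is positive when it overlaps the target by
#' at least one base. The ROC is traced over ranking prefixes and summarized
#' by its trapezoidal area.
#'
#' @param seg a [Segmentation-class].
#' @param target `GRanges` annotation to predict.
#' @param split fraction of bins assigned to training (default 0.5).
#' @param seed integer seed for the split.
#' @return List with `auroc`, `roc` (`data.frame` of `FPR`, `TPR` including
#'   the (0,0) and (1,1) endpoints), `ranking` (state indices in prediction
#'   order), and `seed`. `auroc` is `NA` when the test bins contain no
#'   positives or no negatives.
#' @export
predictiveAUROC <- function(seg, target, split = 0.5, seed = 1L) {
  if (!length(target)) stop("empty target annotation")
  stopifnot(split > 0, split < 1)
  st <- stateIndices(seg)
  ovl <- .binOverlapBases(seg, target)
  bs <- binSize(seg)
  cs <- chromSizes(seg)
  w <- unlist(lapply(names(cs), function(cn) {
    nb <- .nBins(cs[[cn]], bs)
    wv <- rep(as.numeric(bs), nb)
    if (nb) wv[nb] <- cs[[cn]] - (nb - 1) * bs
    wv
  }), use.names = FALSE)
  n <- length(st)
  set.seed(seed)
  train <- sample.int(n, size = round(split * n))
  isTrain <- logical(n); isTrain[train] <- TRUE
  S <- nStates(seg)
  ovS <- vapply(seq_len(S), function(s)
    sum(ovl[isTrain & st == s]), numeric(1))
  wS <- vapply(seq_len(S), function(s)
    sum(w[isTrain & st == s]), numeric(1))
  rate <- sum(ovl[isTrain]) / sum(w[isTrain])
  enr <- ifelse(wS > 0 & rate > 0, (ovS / wS) / rate, NA_real_)
  key <- ifelse(is.na(enr), -Inf, enr)
  ranking <- order(-key, seq_len(S))
  pos <- !isTrain & ovl >= 1
  neg <- !isTrain & ovl < 1
  P <- sum(pos); N <- sum(neg)
  if (P == 0 || N == 0) {
    return(list(auroc = NA_real_, roc = NULL, ranking = ranking, seed = seed))
  }
  tp <- vapply(ranking, function(s) sum(pos & st == s), numeric(1))
  fp <- vapply(ranking, function(s) sum(neg & st == s), numeric(1))
  tpr <- c(0, cumsum(tp) / P, 1)
  fpr <- c(0, cumsum(fp) / N, 1)
  auroc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(
    auroc = auroc,
    roc = data.frame(FPR = fpr, TPR = tpr),
    ranking = ranking, seed = seed
  )
}
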