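#' Read a chrom.sizes table
#'
#' Two tab-delimited columns: chromosome name, length in bases. Order is
#' preserved and used everywhere downstream, so results are deterministic.
#'
#' @param path path to the file.
#' @return Named integer vector of chromosome lengths.
#' @export
readChromSizes <- function(path) {
  dt <- .freadTSV(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 2) stop("chrom.sizes must have two columns")
  len <- as.integer(dt[[2]])
  if (anyNA(len) || any(len <= 0)) stop("chromosome lengths must be positive integers")
  if (anyDuplicated(dt[[1]])) stop("duplicate chromosome names")
  setNames(len, dt[[1]])
}

#' Read aligned reads from a tagAlign or BED file
#'
#' tagAlign is BED-like: chrom, start, end, sequence, score, strand. Plain BED
#' is accepted with strand in column 6 when present. Coordinates on disk are
#' 0-based half-open; the returned [GenomicRanges::GRanges] uses the usual
#' 1-based closed convention. Gzipped files are read transparently. Reads on
#' chromosomes absent from `chromSizes` are dropped with a message giving the
#' count, since real alignment files routinely contain unplaced contigs.
#'
#' @param path tagAlign/BED file, optionally gzipped.
#' @param chromSizes optional named vector of chromosome lengths used to
#'   filter unknown chromosomes and attach `seqlengths`.
#' @return A `GRanges` of read alignments with strand.
#' @export
readReads <- function(path, chromSizes = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- .freadTSV(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (nrow(dt) == 0) {
    return(GenomicRanges::GRanges(seqlengths = chromSizes))
  }
  if (ncol(dt) < 3) stop("expected at least 3 tab-delimited columns")
  start0 <- suppressWarnings(as.integer(dt[[2]]))
  end0 <- suppressWarnings(as.integer(dt[[3]]))
  bad <- which(is.na(start0) | is.na(end0))
  if (length(bad)) stop("malformed coordinates at line ", bad[1])
  bad <- which(start0 >= end0)
  if (length(bad)) stop("start >= end at line ", bad[1])
  strand <- if (ncol(dt) >= 6) dt[[6]] else rep(".", nrow(dt))
  strand[!strand %in% c("+", "-")] <- "*"
  chrom <- dt[[1]]
  if (!is.null(chromSizes)) {
    keep <- chrom %in% names(chromSizes)
    if (!all(keep)) {
      message(sum(!keep), " read(s) on unknown chromosomes dropped")
    }
    chrom <- chrom[keep]; start0 <- start0[keep]; end0 <- end0[keep]
    strand <- strand[keep]
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = strand
  )
  if (!is.null(chromSizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
    GenomeInfoDb::seqlengths(gr) <- unname(chromSizes)
  }
  gr
}

.openWrite <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
}

# fread with transparent gzip support and a 0-row result for empty files.
.freadTSV <- function(path, ...) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "r")
    on.exit(close(con))
    lines <- readLines(con)
    if (!length(lines)) return(data.table::data.table())
    data.table::fread(text = lines, ...)
  } else {
    if (file.size(path) == 0) return(data.table::data.table())
    data.table::fread(path, ...)
  }
}

#' Write / read a merged binarized chunk file
#'
#' The on-disk dialect is two header lines followed by the call matrix: line 1
#' is `sample TAB chunkTag` (the tag is `"chrN"`, or `"chrN.k"` for the k-th
#' chunk of a split chromosome); line 2 is the tab-delimited dataset names;
#' each following line is one 200-bp bin's tab-delimited calls (0/1, or 2 for
#' missing). Files ending in `.gz` are compressed. `readBinarizedChunk` is the
#' exact inverse of `writeBinarizedChunk`.
#'
#' @param chunk an [ObservationChunk-class].
#' @param sample sample label for the first header field (the stacked design
#'   uses the constant `"genome"`).
#' @param featureNames dataset names for the header; must match the column
#'   count.
#' @param path output file; `.gz` suffix triggers gzip.
#' @return `writeBinarizedChunk` returns `path` invisibly;
#'   `readBinarizedChunk` returns the [ObservationChunk-class] (with
#'   `startBin` taken from the `startBin` argument) plus attributes `sample`
#'   and `featureNames`.
#' @export
writeBinarizedChunk <- function(chunk, sample, featureNames, path) {
  calls <- binCalls(chunk)
  if (length(featureNames) != ncol(calls))
    stop("featureNames length does not match the number of call columns")
  con <- .openWrite(path)
  on.exit(close(con))
  writeLines(paste(sample, chunk@tag, sep = "\t"), con)
  writeLines(paste(featureNames, collapse = "\t"), con)
  if (nrow(calls)) {
    writeLines(do.call(paste, c(asplit(calls, 2), list(sep = "\t"))), con)
  }
  invisible(path)
}

#' @rdname writeBinarizedChunk
#' @param startBin 0-based index of the chunk's first bin; the file itself
#'   stores only the chunk tag.
#' @export
readBinarizedChunk <- function(path, startBin = 0L) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("binarized file must have two header lines")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(hdr) != 2) stop("malformed header line 1")
  feats <- strsplit(lines[2], "\t", fixed = TRUE)[[1]]
  body <- lines[-(1:2)]
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    nc <- lengths(parts)
    if (any(nc != length(feats))) {
      stop("row ", which(nc != length(feats))[1],
           " has ", nc[nc != length(feats)][1], " columns, expected ",
           length(feats))
    }
    calls <- matrix(as.integer(unlist(parts)), ncol = length(feats), byrow = TRUE)
    if (anyNA(calls) || !all(calls %in% c(0L, 1L, 2L)))
      stop("binarized values must be 0, 1 or 2")
  } else {
    calls <- matrix(integer(), 0, length(feats))
  }
  colnames(calls) <- feats
  chrom <- sub("\\.[0-9]+$", "", hdr[2])
  chunk <- ObservationChunk(calls, chrom = chrom, startBin = startBin, tag = hdr[2])
  attr(chunk, "sample") <- hdr[1]
  attr(chunk, "featureNames") <- feats
  chunk
}

#' Read a directory of binarized chunk files
#'
#' Orders files by chromosome (chrom.sizes order) and chunk index, assigns
#' each chunk its cumulative `startBin`, and checks that the dataset header is
#' identical across files.
#'
#' @param dir directory holding files written by [writeBinarizedChunk()].
#' @param chromSizes named chromosome lengths fixing the chromosome order.
#' @param pattern filename regular expression.
#' @return List of [ObservationChunk-class] with attribute `featureNames`.
#' @export
readBinarizedDir <- function(dir, chromSizes, pattern = "\\.(txt|txt\\.gz)$") {
  paths <- list.files(dir, pattern = pattern, full.names = TRUE)
  if (!length(paths)) stop("no binarized files in ", dir)
  chunks <- lapply(paths, readBinarizedChunk)
  tags <- vapply(chunks, function(x) x@tag, character(1))
  chromOf <- sub("\\.[0-9]+$", "", tags)
  idx <- suppressWarnings(as.integer(sub("^.*\\.", "", tags)))
  idx[is.na(idx) | chromOf == tags] <- 0L
  ord <- order(match(chromOf, names(chromSizes)), idx)
  chunks <- chunks[ord]
  chromOf <- chromOf[ord]
  feats <- attr(chunks[[1]], "featureNames")
  for (ch in chunks) {
    if (!identical(attr(ch, "featureNames"), feats))
      stop("dataset headers differ across binarized files")
  }
  offset <- 0L
  lastChrom <- ""
  for (i in seq_along(chunks)) {
    if (!identical(chromOf[i], lastChrom)) { offset <- 0L; lastChrom <- chromOf[i] }
    chunks[[i]]@startBin <- offset
    offset <- offset + nrow(binCalls(chunks[[i]]))
  }
  attr(chunks, "featureNames") <- feats
  chunks
}

#' Convert a segmentation to genomic ranges
#'
#' One range per maximal run of a state, 1-based closed as usual for
#' `GRanges`; the final bin of a chromosome is truncated at the chromosome
#' end.
#'
#' @param seg a [Segmentation-class].
#' @return A `GRanges` with metadata columns `state` (integer index) and
#'   `label`.
#' @export
segmentationToGRanges <- function(seg) {
  bs <- binSize(seg)
  out <- lapply(names(seg@states), function(chrom) {
    r <- seg@states[[chrom]]
    if (!length(r)) return(NULL)
    ends <- cumsum(runLength(r))
    starts <- c(0L, head(ends, -1)) * bs
    endsBp <- pmin(ends * bs, seg@chromSizes[[chrom]])
    GenomicRanges::GRanges(
      seqnames = factor(chrom, levels = names(seg@chromSizes)),
      ranges = IRanges::IRanges(start = starts + 1L, end = endsBp),
      state = runValue(r),
      label = stateLabels(seg)[runValue(r)]
    )
  })
  gr <- do.call(c, out[!vapply(out, is.null, logical(1))])
  GenomeInfoDb::seqlevels(gr) <- names(seg@chromSizes)
  GenomeInfoDb::seqlengths(gr) <- unname(seg@chromSizes)
  gr
}

#' Write a segmentation as BED
#'
#' Minimal 4-column BED (chrom, start, end, state label) with 0-based
#' half-open coordinates and maximal state runs merged, or 9-column BED with
#' an RGB colour per state when `bed9 = TRUE`.
#'
#' @param seg a [Segmentation-class].
#' @param path output path (`.gz` supported).
#' @param bed9 write the 9-column variant.
#' @param colors character vector of `"r,g,b"` strings, one per state
#'   (recycled defaults otherwise).
#' @return `path`, invisibly.
#' @export
writeSegmentationBED <- function(seg, path, bed9 = FALSE, colors = NULL) {
  gr <- segmentationToGRanges(seg)
  dt <- data.table::data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = gr$label
  )
  if (bed9) {
    if (is.null(colors)) {
      pal <- grDevices::col2rgb(grDevices::rainbow(nStates(seg)))
      colors <- apply(pal, 2, paste, collapse = ",")
    }
    dt[, c("score", "strand", "thickStart", "thickEnd", "itemRgb") := list(
      0L, ".", dt$start, dt$end, colors[gr$state]
    )]
  }
  con <- .openWrite(path)
  on.exit(close(con))
  writeLines(do.call(paste, c(as.list(dt), list(sep = "\t"))), con)
  invisible(path)
}

#' Read an annotation BED file into labelled interval sets
#'
#' Intervals sharing a label are merged (book-ended and overlapping runs
#' collapsed) by default; under `strict = TRUE`, overlapping intervals within
#' one label raise an error instead.
#'
#' @param path BED file (3+ columns; column 4 is the label, a single constant
#'   label derived from the filename is used when absent).
#' @param chromSizes optional named lengths to attach as `seqlengths`.
#' @param strict error on within-label overlaps instead of merging.
#' @return Named list of `GRanges`, one per label, sorted and disjoint.
#' @export
readAnnotationBED <- function(path, chromSizes = NULL, strict = FALSE) {
  dt <- .freadTSV(path, header = FALSE, sep = "\t", fill = TRUE,
                          colClasses = list(character = 1))
  if (ncol(dt) < 3) stop("BED needs at least 3 columns")
  label <- if (ncol(dt) >= 4) as.character(dt[[4]]) else
    rep(sub("\\.bed(\\.gz)?$", "", basename(path)), nrow(dt))
  gr <- GenomicRanges::GRanges(
    seqnames = dt[[1]],
    ranges = IRanges::IRanges(start = as.integer(dt[[2]]) + 1L,
                              end = as.integer(dt[[3]]))
  )
  if (!is.null(chromSizes)) {
    GenomeInfoDb::seqlevels(gr) <- union(names(chromSizes),
                                         GenomeInfoDb::seqlevels(gr))
    GenomeInfoDb::seqlengths(gr)[names(chromSizes)] <- unname(chromSizes)
  }
  out <- lapply(split(gr, label), function(g) {
    red <- GenomicRanges::reduce(GenomicRanges::sort(g))
    if (strict && length(red) < length(g) &&
        sum(GenomicRanges::width(red)) < sum(GenomicRanges::width(g)))
      stop("overlapping intervals within one label under strict mode")
    red
  })
  out[unique(label)]
}

#' Read a segmentation back from a BED file
#'
#' Inverse of [writeSegmentationBED()] given the chromosome sizes and bin
#' size. State indices are recovered from numeric label prefixes
#' (`"12_Enh"` or `"S12"`), otherwise from the sorted label set.
#'
#' @param path 4+ column BED of state intervals covering whole bins.
#' @param chromSizes named chromosome lengths.
#' @param binSize bin width in bases.
#' @param stateLabels optional full label set fixing indices for states
#'   absent from the file.
#' @return A [Segmentation-class].
#' @export
readSegmentationBED <- function(path, chromSizes, binSize = 200L,
                                stateLabels = NULL) {
  dt <- .freadTSV(path, header = FALSE, sep = "\t",
                          colClasses = list(character = 1))
  if (ncol(dt) < 4) stop("segmentation BED needs 4 columns")
  labels <- as.character(dt[[4]])
  if (is.null(stateLabels)) {
    uniq <- unique(labels)
    pref <- suppressWarnings(as.integer(sub("^S?([0-9]+).*$", "\\1", uniq)))
    if (!anyNA(pref) && !anyDuplicated(pref)) {
      stateLabels <- character(max(pref))
      stateLabels[pref] <- uniq
      empty <- !nzchar(stateLabels)
      stateLabels[empty] <- paste0("S", which(empty))
    } else {
      stateLabels <- sort(uniq)
    }
  }
  idx <- match(labels, stateLabels)
  if (anyNA(idx)) stop("unknown state label: ", labels[which(is.na(idx))[1]])
  states <- lapply(names(chromSizes), function(chrom) {
    sel <- dt[[1]] == chrom
    nb <- .nBins(chromSizes[[chrom]], binSize)
    v <- integer(nb)
    if (any(sel)) {
      s0 <- as.integer(dt[[2]][sel]); e0 <- as.integer(dt[[3]][sel])
      b0 <- s0 %/% binSize + 1L
      b1 <- pmin(as.integer(ceiling(e0 / binSize)), nb)
      st <- idx[sel]
      for (i in seq_along(b0)) v[b0[i]:b1[i]] <- st[i]
    }
    if (any(v == 0L)) stop("segmentation does not cover chromosome ", chrom)
    Rle(v)
  })
  names(states) <- names(chromSizes)
  Segmentation(states, chromSizes, binSize, stateLabels)
}

#' Read the dataset descriptor table
#'
#' The stacked design's four tab-delimited columns: sample label (constant
#' `"genome"`), feature name `"<EID>-<mark>"`, signal read file, control read
#' file.
#'
#' @param path TSV path.
#' @return `data.frame` with columns `sample`, `feature`, `signal`,
#'   `control`.
#' @export
readDescriptorTable <- function(path) {
  dt <- .freadTSV(path, header = FALSE, sep = "\t")
  if (!ncol(dt) %in% 3:4) stop("descriptor table must have 3 or 4 columns")
  out <- data.frame(
    sample = as.character(dt[[1]]),
    feature = as.character(dt[[2]]),
    signal = as.character(dt[[3]]),
    control = if (ncol(dt) == 4) as.character(dt[[4]]) else NA_character_,
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$feature)) stop("feature names must be unique")
  out
}

#' Read a gene coordinate table
#'
#' Tab-delimited with header: gene ID, chrom, start (0-based), end
#' (exclusive), strand, type.
#'
#' @param path TSV path.
#' @param chromSizes optional named lengths.
#' @return `GRanges` with metadata columns `gene_id` and `type`.
#' @export
readGeneTable <- function(path, chromSizes = NULL) {
  dt <- .freadTSV(path, header = TRUE, sep = "\t")
  gr <- GenomicRanges::GRanges(
    seqnames = dt[[2]],
    ranges = IRanges::IRanges(start = as.integer(dt[[3]]) + 1L,
                              end = as.integer(dt[[4]])),
    strand = dt[[5]],
    gene_id = as.character(dt[[1]]),
    type = if (ncol(dt) >= 6) as.character(dt[[6]]) else NA_character_
  )
  if (!is.null(chromSizes)) {
    GenomeInfoDb::seqlevels(gr) <- names(chromSizes)
    GenomeInfoDb::seqlengths(gr) <- unname(chromSizes)
  }
  gr
}

#' Read an expression matrix
#'
#' Gene IDs in the first column, one column per sample; values are expected
#' on the log(RPKM + 1) scale.
#'
#' @param path TSV path with header.
#' @return Numeric matrix, genes x samples, gene IDs as rownames.
#' @export
readExpressionMatrix <- function(path) {
  dt <- .freadTSV(path, header = TRUE, sep = "\t")
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- as.character(dt[[1]])
  storage.mode(m) <- "double"
  m
}

#' Write / read a model directory
#'
#' Serializes a [StackedHMM-class] as three human-readable TSV tables —
#' `emissions.tsv` (states x datasets, feature names in the header),
#' `transitions.tsv` (states x states) and `initial.tsv` (state,
#' probability) — plus, for a [StackedHMMFit-class], `manifest.json` holding
#' the resolved training configuration and the per-iteration log-likelihood
#' trace. `readModelDir` is the inverse and returns a fit whenever a
#' manifest is present.
#'
#' @param model a [StackedHMM-class] or [StackedHMMFit-class].
#' @param dir directory to create/populate.
#' @return `writeModelDir` returns `dir` invisibly; `readModelDir` returns
#'   the reconstructed model.
#' @export
writeModelDir <- function(model, dir) {
  stopifnot(is(model, "StackedHMM"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  e <- emissionProbs(model)
  ed <- data.frame(state = rownames(e), e, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(ed, file.path(dir, "emissions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  a <- transitionProbs(model)
  ad <- data.frame(state = rownames(e), a, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(ad) <- c("state", rownames(e))
  utils::write.table(ad, file.path(dir, "transitions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  pd <- data.frame(state = rownames(e), probability = initialProbs(model),
                   stringsAsFactors = FALSE)
  utils::write.table(pd, file.path(dir, "initial.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (is(model, "StackedHMMFit")) {
    jsonlite::write_json(
      list(config = model@config, logLikTrace = logLikTrace(model)),
      file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}

#' @rdname writeModelDir
#' @export
readModelDir <- function(dir) {
  ep <- file.path(dir, "emissions.tsv")
  if (!file.exists(ep)) stop("no emissions.tsv in ", dir)
  ed <- utils::read.table(ep, header = TRUE, sep = "\t", check.names = FALSE)
  e <- as.matrix(ed[, -1, drop = FALSE])
  rownames(e) <- as.character(ed[[1]])
  ad <- utils::read.table(file.path(dir, "transitions.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  a <- as.matrix(ad[, -1, drop = FALSE])
  pd <- utils::read.table(file.path(dir, "initial.tsv"), header = TRUE,
                          sep = "\t", check.names = FALSE)
  m <- StackedHMM(e, a, pd$probability, featureNames = colnames(e))
  mp <- file.path(dir, "manifest.json")
  if (file.exists(mp)) {
    man <- jsonlite::read_json(mp, simplifyVector = TRUE)
    m <- new("StackedHMMFit", m,
             logLikTrace = as.numeric(man$logLikTrace),
             config = as.list(man$config))
  }
  m
}
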