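test_that("simulation is deterministic per seed and respects configured dimensions", {
  cfg <- simulationConfig(chromSizes = c(chr1 = 1e5, chr2 = 6e4), seed = 21)
  s1 <- simulateGenome(cfg)
  s2 <- simulateGenome(cfg)
  expect_identical(stateIndices(s1$truth), stateIndices(s2$truth))
  expect_identical(binCalls(s1$chunks[[1]]), binCalls(s2$chunks[[1]]))
  s3 <- simulateGenome(simulationConfig(chromSizes = c(chr1 = 1e5, chr2 = 6e4),
                                        seed = 22))
  expect_false(identical(stateIndices(s3$truth), stateIndices(s1$truth)))

  expect_length(stateIndices(s1$truth, "chr1"), 500L)
  expect_length(stateIndices(s1$truth, "chr2"), 300L)
  D <- nFeatures(cfg$truth)
  expect_true(all(vapply(s1$chunks, function(x) ncol(binCalls(x)) == D,
                         logical(1))))
  expect_true(all(unlist(lapply(s1$chunks, binCalls)) %in% c(0L, 1L)))
})

test_that("empirical transition frequencies match the generating matrix", {
  cfg <- simulationConfig(chromSizes = c(chr1 = 4e6), seed = 77)
  sim <- simulateGenome(cfg)
  path <- stateIndices(sim$truth, "chr1")
  a <- transitionProbs(cfg$truth)
  n <- length(path) - 1L
  emp <- table(factor(path[-length(path)], 1:5), factor(path[-1], 1:5))
  emp <- emp / rowSums(emp)
  for (i in 1:5) for (j in 1:5) {
    se <- sqrt(a[i, j] * (1 - a[i, j]) / sum(path[-length(path)] == i))
    expect_lt(abs(emp[i, j] - a[i, j]), 4 * se + 1e-9)
  }
  # per-dataset call frequencies conditioned on state match the emissions
  calls <- do.call(rbind, lapply(sim$chunks, binCalls))
  e <- emissionProbs(cfg$truth)
  stAll <- stateIndices(sim$truth)
  for (s in 1:5) {
    freq <- colMeans(calls[stAll == s, , drop = FALSE])
    expect_equal(unname(freq), unname(e[s, ]), tolerance = 0.03)
  }
})

test_that("binarization recovery of simulated reads improves with depth", {
  cfg <- simulationConfig(chromSizes = c(chr1 = 2e5), seed = 9)
  sim <- simulateGenome(cfg)
  truthTrack <- sim$tracks[[1]]
  # no-control limit (lambda = global mean) so the depth sweep has a clean
  # analytic target: recovery approaches 1 as the signal rate grows
  recovery <- vapply(c(3, 10, 40), function(rate) {
    rd <- simulateReads(truthTrack, cfg$chromSizes, signalRate = rate,
                        backgroundRate = 0.5, seed = 4)
    sig <- countReads(rd$signal, cfg$chromSizes)
    bin <- binarizeTrack(sig)
    mean(unlist(bin) == unlist(truthTrack))
  }, numeric(1))
  expect_gte(min(diff(recovery)), 0)
  expect_gte(recovery[3], 0.98)
})

test_that("toy annotations are calibrated against their closed-form enrichment", {
  study <- smallStudy()
  seg <- study$truth
  # hitRate 1, single target: FE = 1 / coverage(target) exactly
  for (s in c(1, 4)) {
    ann <- makeToyAnnotations(seg, targetStates = s, hitRate = 1,
                              n = 200, seed = 50 + s)
    fe <- foldEnrichment(seg, list(a = ann))
    expect_equal(unname(fe[s, "a"]),
                 1 / unname(stateCoverage(seg)[s]), tolerance = 1e-10)
    expect_equal(sum(fe[-s, "a"]), 0)
  }
  # intermediate hitRate: the fraction of intervals falling inside a
  # target-state run equals hitRate in expectation (each interval is placed
  # wholly within one run, so this is exact up to binomial noise)
  ann <- makeToyAnnotations(seg, targetStates = 2, hitRate = 0.7,
                            n = 2000, seed = 61)
  runs <- segmentationToGRanges(seg)
  inTarget <- GenomicRanges::countOverlaps(ann, runs[runs$state == 2],
                                           type = "within") > 0
  expect_equal(mean(inTarget), 0.7, tolerance = 0.03)
})

test_that("toy genes and expression are well-formed and state-linked", {
  study <- smallStudy()
  genes <- makeToyGenes(study$config$chromSizes, n = 60, seed = 2)
  expect_length(genes, 60)
  expect_true(all(GenomicRanges::end(genes) <=
                    study$config$chromSizes[
                      as.character(GenomicRanges::seqnames(genes))]))
  expect_true(all(GenomicRanges::start(genes) >= 1))
  expect_false(any(duplicated(genes$gene_id)))

  eff <- c(10, 8, 6, 4, 2)
  # run-scale genes sit mostly inside one state run, so the state means
  # track the generating effect sizes; multi-run genes would blur them
  short <- makeToyGenes(study$config$chromSizes, n = 120,
                        minLength = 400, maxLength = 1500, seed = 2)
  expr <- makeToyExpression(short, study$truth, effectSizes = eff,
                            nSamples = 3, noiseSd = 0.05, seed = 3)
  expect_equal(dim(expr), c(120L, 3L))
  res <- expressionByState(study$truth, short, expr)
  ok <- !is.na(res$mean)
  expect_gte(cor(res$mean[ok], eff[ok]), 0.9)
  expect_equal(unname(which.max(res$mean)), 1L)

  # null: flat effects give no state separation beyond noise
  exprN <- makeToyExpression(genes, study$truth, effectSizes = rep(5, 5),
                             nSamples = 3, noiseSd = 0.05, seed = 4)
  resN <- expressionByState(study$truth, genes, exprN)
  expect_lt(diff(range(resN$mean[!is.na(resN$mean)])), 0.2)
})

test_that("toy metadata cycles marks and groups over the feature names", {
  md <- makeToyMetadata(paste0("f", 1:7))
  expect_equal(nrow(md), 7L)
  expect_equal(md$mark[1:6], c("H3K4me1", "H3K4me3", "H3K27ac",
                               "H3K36me3", "DNase", "H3K4me1"))
  expect_equal(md$group[1:4], c("Blood", "Brain", "ESC", "Blood"))
  expect_equal(md$eid[1], "E001")
})

test_that("the full pipeline on fresh simulated data recovers the annotation", {
  cfg <- simulationConfig(chromSizes = c(chr1 = 6e5, chr2 = 4e5),
                          chunkLimit = 1e5, seed = 33)
  sim <- simulateGenome(cfg)
  # random restarts with likelihood-based selection, the standard guard
  # against EM local optima at this desk scale
  fits <- lapply(c(6, 7, 8), function(s) {
    trainStackedHMM(sim$chunks,
                    trainConfig(nStates = 5,
                                nSampledChunks = length(sim$chunks),
                                maxIterations = 60, seed = s))
  })
  lls <- vapply(fits, function(f) logLikelihood(f, sim$chunks), numeric(1))
  fit <- fits[[which.max(lls)]]
  seg <- decodeSegmentation(fit, sim$chunks, cfg$chromSizes)
  perm <- matchStates(cfg$truth, fit)
  relabeled <- match(stateIndices(seg), perm)
  expect_gte(mean(relabeled == stateIndices(sim$truth)), 0.95)
})
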