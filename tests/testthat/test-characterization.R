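test_that("bp-normalized expression collapses correctly on constructed fixtures", {
  # one gene fully inside one state: the state's value is the gene's expression
  seg <- Segmentation(list(chr1 = c(1, 1, 2, 2, 2)), c(chr1 = 1000L), 200L)
  g1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 300), strand = "+",
                               gene_id = "gA")
  e1 <- matrix(3.7, 1, 1, dimnames = list("gA", "s1"))
  res <- expressionByState(seg, g1, e1)
  expect_equal(unname(res$values["S1", 1]), 3.7)

  # two genes over one bin, E = (2, 4), L = (100, 200) -> 8/3
  seg2 <- Segmentation(list(chr1 = c(1, 2)), c(chr1 = 400L), 200L)
  genes <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(1, 1), c(100, 200)), strand = "+",
    gene_id = c("g1", "g2")
  )
  ex <- matrix(c(2, 4), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  res2 <- expressionByState(seg2, genes, ex)
  expect_equal(unname(res2$values["S1", 1]), 8 / 3)
  # state 2 overlaps no gene -> missing
  expect_true(is.na(res2$values["S2", 1]))

  # each gene contributes once per state it overlaps, so a state spanning
  # several bins scores the same as a single-bin state
  seg3 <- Segmentation(list(chr1 = c(1, 1)), c(chr1 = 400L), 200L)
  res3 <- expressionByState(seg3, genes, ex)
  expect_equal(unname(res3$values["S1", 1]), 8 / 3)
})

test_that("TSS-centred expression tables have the documented geometry and smoothing", {
  study <- smallStudy()
  seg <- study$truth
  genes <- makeToyGenes(study$config$chromSizes, n = 80, seed = 6)
  expr <- makeToyExpression(genes, seg, effectSizes = c(5, 4, 3, 2, 1),
                            nSamples = 2, seed = 7)
  raw <- positionalExpression(seg, genes, expr, smooth = FALSE)
  expect_equal(ncol(raw), 251L)
  expect_equal(colnames(raw)[1], "-25000")
  expect_equal(colnames(raw)[251], "25000")
  sm <- positionalExpression(seg, genes, expr)
  expect_equal(ncol(sm), 231L)
  expect_equal(colnames(sm)[1], "-23000")

  # constant expression is smoothing-invariant
  exprC <- expr; exprC[] <- 2.5
  smC <- positionalExpression(seg, genes, exprC)
  expect_true(all(abs(smC[!is.na(smC)] - 2.5) < 1e-12))

  # single gene, single state: smoothed values equal the raw value (the TSS
  # sits > 25 kb from both chromosome ends so every offset is on-genome)
  segU <- Segmentation(
    lapply(seg@states, function(r) rep(1L, length(r))),
    chromSizes(seg), binSize(seg)
  )
  g <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100001, 120000),
                              strand = "+", gene_id = "gX")
  ex1 <- matrix(1.25, 1, 1, dimnames = list(g$gene_id, "s"))
  smU <- positionalExpression(segU, g, ex1)
  expect_true(all(abs(smU[1, ] - 1.25) < 1e-12))
})

test_that("per-base signal averages match a direct loop", {
  seg <- Segmentation(list(chr1 = c(1, 2, 1, 2, 2)), c(chr1 = 1000L), 200L)
  pos <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(c(10, 250, 410, 999, 601), width = 1),
    value = c(0.2, 0.8, 0.8, NA, 0.5)
  )
  res <- meanSignalByState(seg, pos)
  expect_equal(unname(res["S1"]), mean(c(0.2, 0.8)))
  expect_equal(unname(res["S2"]), mean(c(0.8, 0.5)))

  allHalf <- pos
  allHalf$value <- 0.5
  expect_equal(unname(meanSignalByState(seg, allHalf)), c(0.5, 0.5))

  # random placement vs brute-force loop
  set.seed(13)
  rpos <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(sample.int(1000, 200), width = 1),
    value = runif(200)
  )
  got <- meanSignalByState(seg, rpos)
  st <- stateIndices(seg)[((GenomicRanges::start(rpos) - 1L) %/% 200L) + 1L]
  expect_equal(unname(got), as.numeric(tapply(rpos$value, st, mean)))
})

test_that("emission CV uses group means with sample standard deviation", {
  feats <- paste0("E", 1:4, "-H3K27ac")
  # state 1: group means 0.2 and 0.4 -> CV = sd(c(.2,.4))/0.3
  e <- rbind(c(0.1, 0.3, 0.3, 0.5), c(0.6, 0.6, 0.6, 0.6))
  m <- StackedHMM(e, matrix(0.5, 2, 2), c(0.5, 0.5), featureNames = feats)
  md <- data.frame(feature = feats, mark = "H3K27ac",
                   group = c("A", "B", "A", "B"))
  cv <- emissionCV(m, md, marks = "H3K27ac")
  expect_equal(unname(cv["S1", "H3K27ac"]), sd(c(0.2, 0.4)) / 0.3)
  expect_equal(unname(cv["S2", "H3K27ac"]), 0)

  # state groups average across member states; singleton group is identity
  cvg <- emissionCV(m, md, marks = "H3K27ac", stateGroups = c("g", "g"))
  expect_equal(unname(cvg["g", "H3K27ac"]),
               mean(c(sd(c(0.2, 0.4)) / 0.3, 0)))
})

test_that("differential-emission tests match exact Mann-Whitney enumeration and Bonferroni exactly", {
  feats <- paste0("E", 1:4, "-H3K4me3")
  e <- rbind(c(0.8, 0.9, 0.1, 0.2))
  m <- StackedHMM(e, matrix(1, 1, 1), 1, featureNames = feats)
  md <- data.frame(feature = feats, mark = "H3K4me3",
                   group = c("A", "A", "B", "B"))
  res <- differentialEmissionTests(m, md, marks = "H3K4me3")
  # untied 2-vs-2 all-greater arrangement: one-sided exact p = 1/choose(4,2)
  pa <- res$p[res$group == "A"]
  expect_equal(pa, 1 / 6)
  expect_equal(attr(res, "m"), 2L)
  expect_equal(attr(res, "threshold") * attr(res, "m"), 0.05)

  # identically distributed in/out groups: p near 0.5, not significant
  set.seed(20)
  featsBig <- paste0("E", 1:60, "-DNase")
  eb <- matrix(runif(60), 1, 60)
  mb <- StackedHMM(eb, matrix(1, 1, 1), 1, featureNames = featsBig)
  mdb <- data.frame(feature = featsBig, mark = "DNase",
                    group = rep(c("A", "B"), each = 30))
  resb <- differentialEmissionTests(mb, mdb, marks = "DNase")
  expect_true(all(resb$p > 0.01))
  expect_false(any(resb$significant))
})

test_that("the Bonferroni threshold reproduces the published family computation", {
  expect_equal(bonferroniThreshold(14200, 0.05) * 14200, 0.05)
  expect_equal(signif(bonferroniThreshold(14200, 0.05), 2), 3.5e-6)
})

test_that("greedy summary selection finds the separating feature first and improves monotonically", {
  study <- smallStudy()
  truth <- study$config$truth
  calls <- do.call(rbind, lapply(study$chunks, binCalls))
  assign <- stateIndices(study$truth)

  expect_identical(greedySummarySelection(truth, calls, assign, k = 0), integer(0))
  oneFeat <- StackedHMM(emissionProbs(truth)[, 1, drop = FALSE],
                        transitionProbs(truth), initialProbs(truth))
  expect_equal(as.integer(greedySummarySelection(
    oneFeat, calls[, 1, drop = FALSE], assign, k = 1)), 1L)
  expect_error(greedySummarySelection(truth, calls, assign, k = 99), "exceed")

  sel <- greedySummarySelection(truth, calls, assign, k = 5, nSample = 5000,
                                seed = 9)
  expect_length(sel, 5)
  expect_gte(min(diff(attr(sel, "agreement"))), 0)

  # constructed fixture: one feature separates two states perfectly, the
  # other is uninformative -> the separating feature is selected first
  e <- rbind(c(0.999, 0.5), c(0.001, 0.5))
  m2 <- StackedHMM(e, matrix(0.5, 2, 2), c(0.5, 0.5))
  set.seed(30)
  a2 <- sample(1:2, 2000, replace = TRUE)
  c2 <- cbind(as.integer(runif(2000) < e[a2, 1]),
              as.integer(runif(2000) < 0.5))
  expect_equal(as.integer(greedySummarySelection(m2, c2, a2, k = 1)), 1L)
})
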