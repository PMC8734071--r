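test_that("stabilized emission products equal the log-space computation", {
  m <- StackedHMM(rbind(c(0.9, 0.9), c(0.1, 0.1)),
                  rbind(c(0.5, 0.5), c(0.5, 0.5)), c(0.5, 0.5))
  r <- stabilizedEmissionProducts(m, c(1L, 1L))
  expect_equal(as.numeric(r), c(1, 0.01 / 0.81))

  one <- StackedHMM(matrix(0.3, 1, 3), matrix(1, 1, 1), 1)
  expect_equal(as.numeric(stabilizedEmissionProducts(one, c(1L, 0L, 1L))), 1)

  same <- StackedHMM(rbind(c(0.2, 0.7), c(0.2, 0.7)),
                     rbind(c(0.5, 0.5), c(0.5, 0.5)), c(0.5, 0.5))
  expect_equal(as.numeric(stabilizedEmissionProducts(same, c(0L, 1L))), c(1, 1))

  # random instances incl. tiny emissions: relative products match exp of
  # log-space sums renormalized by the max, and missing calls are skipped
  for (seed in 1:25) {
    set.seed(seed)
    S <- sample(2:5, 1); D <- sample(2:12, 1)
    e <- matrix(runif(S * D, 1e-6, 1 - 1e-6), S, D)
    mod <- StackedHMM(e, matrix(1 / S, S, S), rep(1 / S, S))
    o <- randomTinyObs(1, D, seed + 100, missingRate = 0.2)[1, ]
    logs <- vapply(seq_len(S), function(s) {
      sum(ifelse(o == 2, 0, ifelse(o == 1, log(e[s, ]), log(1 - e[s, ]))))
    }, numeric(1))
    expected <- exp(logs - max(logs))
    got <- stabilizedEmissionProducts(mod, as.integer(o))
    expect_equal(as.numeric(got), expected, tolerance = 1e-10)
    # scale factor restores the true joint probability
    expect_equal(log(as.numeric(got)) + attr(got, "logScale"), logs,
                 tolerance = 1e-8)
  }
})

test_that("forward-backward posteriors match exhaustive path enumeration", {
  # single-position closed form
  m <- randomTinyModel(3, 4, 1)
  o <- randomTinyObs(1, 4, 2)
  fb <- forwardBackward(m, o)
  oracle <- enumeratePosteriors(initialProbs(m), transitionProbs(m),
                                emissionProbs(m), o)
  expect_equal(fb$gamma, oracle$gamma, tolerance = 1e-10)
  expect_equal(fb$logLik, oracle$logLik, tolerance = 1e-10)

  for (seed in 1:40) {
    set.seed(seed)
    S <- sample(2:4, 1); D <- sample(2:6, 1); T <- sample(2:8, 1)
    m <- randomTinyModel(S, D, seed * 13)
    o <- randomTinyObs(T, D, seed * 7, missingRate = 0.1)
    fb <- forwardBackward(m, o)
    oracle <- enumeratePosteriors(initialProbs(m), transitionProbs(m),
                                  emissionProbs(m), o)
    expect_equal(fb$gamma, oracle$gamma, tolerance = 1e-8)
    expect_equal(fb$logLik, oracle$logLik, tolerance = 1e-8)
    expect_equal(rowSums(fb$gamma), rep(1, T), tolerance = 1e-8)
    expect_equal(sum(fb$transCounts), T - 1, tolerance = 1e-8)
    expect_equal(colSums(fb$presentCounts + fb$absentCounts),
                 colSums(o != 2) * 1.0, tolerance = 1e-8)
  }
})

test_that("near-deterministic emissions let posterior decoding recover the path", {
  S <- 3; D <- 4
  e <- matrix(0.001, S, D)
  for (d in seq_len(D)) e[(d - 1) %% S + 1, d] <- 0.999
  a <- matrix(0.03, S, S); diag(a) <- 0.94
  m <- StackedHMM(e, a, rep(1 / S, S))
  set.seed(5)
  path <- integer(200)
  path[1] <- sample(S, 1)
  for (t in 2:200) path[t] <- sample(S, 1, prob = a[path[t - 1], ])
  obs <- matrix(as.integer(runif(200 * D) < e[path, ]), 200, D)
  fb <- forwardBackward(m, obs)
  expect_equal(max.col(fb$gamma, ties.method = "first"), path)
})

test_that("the M-step implements pseudo-count ratios", {
  S <- 2; D <- 2
  zero <- list(presentCounts = matrix(0, S, D), absentCounts = matrix(0, S, D),
               transCounts = matrix(0, S, S), initCounts = numeric(S))
  m <- baumWelchUpdate(zero, pseudoCount = 1)
  expect_equal(unname(emissionProbs(m)), matrix(0.5, S, D))
  expect_equal(transitionProbs(m), matrix(0.5, S, S))
  expect_equal(initialProbs(m), c(0.5, 0.5))

  stats <- list(
    presentCounts = rbind(c(8, 0), c(1, 3)),
    absentCounts = rbind(c(2, 10), c(9, 7)),
    transCounts = rbind(c(3, 1), c(2, 2)),
    initCounts = c(1, 0)
  )
  m1 <- baumWelchUpdate(stats, pseudoCount = 1)
  expect_equal(transitionProbs(m1)[1, ], c(4 / 6, 2 / 6))
  expect_equal(unname(emissionProbs(m1))[1, 1], 9 / 12)
  m0 <- baumWelchUpdate(stats, pseudoCount = 0)
  expect_equal(unname(emissionProbs(m0))[1, 1], 8 / 10)
  expect_equal(transitionProbs(m0)[2, ], c(0.5, 0.5))
})

test_that("classical EM (full data, no pseudo-counts) never decreases the likelihood", {
  study <- smallStudy()
  chunks <- study$chunks
  cfg <- trainConfig(nStates = 5, nSampledChunks = length(chunks),
                     maxIterations = 25, pseudoCount = 0, seed = 2)
  fit <- trainStackedHMM(chunks, cfg)
  expect_gte(min(diff(logLikTrace(fit))), -1e-8)
})

test_that("training is deterministic per seed and recovers the generating parameters", {
  study <- smallStudy()
  cfg <- trainConfig(nStates = 5, nSampledChunks = length(study$chunks),
                     maxIterations = 40, seed = 3)
  fit1 <- trainStackedHMM(study$chunks, cfg)
  fit2 <- trainStackedHMM(study$chunks, cfg)
  expect_identical(emissionProbs(fit1), emissionProbs(fit2))
  expect_identical(logLikTrace(fit1), logLikTrace(fit2))

  truth <- study$config$truth
  perm <- matchStates(truth, fit1)
  expect_equal(sort(perm), 1:5)
  mae <- mean(abs(emissionProbs(fit1)[perm, ] - emissionProbs(truth)))
  expect_lte(mae, 0.02)
})

test_that("log-likelihood is additive over chunks and exact on closed forms", {
  one <- StackedHMM(matrix(0.5, 1, 1), matrix(1, 1, 1), 1)
  expect_equal(logLikelihood(one, list(matrix(1L, 1, 1))), log(0.5))

  m <- randomTinyModel(3, 4, 8)
  o1 <- randomTinyObs(5, 4, 1)
  o2 <- randomTinyObs(7, 4, 2)
  expect_equal(logLikelihood(m, list(o1, o2)),
               logLikelihood(m, list(o1)) + logLikelihood(m, list(o2)))
  expect_equal(logLikelihood(m, list(o1)),
               enumeratePosteriors(initialProbs(m), transitionProbs(m),
                                   emissionProbs(m), o1)$logLik,
               tolerance = 1e-8)
})

test_that("information criteria follow their definitions and select the truth", {
  m <- StackedHMM(matrix(0.5, 2, 2), matrix(0.5, 2, 2), c(0.5, 0.5))
  # k = 2*2 + 2*1 + 1 = 7
  ab <- aicBic(m, logLik = 0, nBins = 1)
  expect_equal(unname(ab["AIC"]), 14)
  expect_equal(unname(ab["BIC"]), 0)
  ab2 <- aicBic(m, logLik = -10, nBins = 100)
  expect_true(ab2["AIC"] < ab2["BIC"])  # ln(100) > 2
  expect_error(aicBic(m, 0, 0), "positive")

  # model selection: criteria over S in 2..7 dip at/near the generating S = 5
  study <- smallStudy()
  nBins <- sum(vapply(study$chunks, function(x) nrow(binCalls(x)), integer(1)))
  bic <- vapply(2:7, function(S) {
    cfg <- trainConfig(S, nSampledChunks = length(study$chunks),
                       maxIterations = 20, seed = 4)
    fit <- trainStackedHMM(study$chunks, cfg)
    aicBic(fit, logLikelihood(fit, study$chunks), nBins)["BIC"]
  }, numeric(1))
  expect_equal(2:7, 2:7)
  expect_lte(abs(which.min(bic) + 1 - 5), 1)
})

test_that("random initialization is seeded, stochastic-valid and centred", {
  m1 <- initRandomHMM(4, 6, seed = 10)
  m2 <- initRandomHMM(4, 6, seed = 10)
  expect_identical(emissionProbs(m1), emissionProbs(m2))
  expect_equal(rowSums(transitionProbs(m1)), rep(1, 4))
  expect_equal(sum(initialProbs(m1)), 1)
  means <- vapply(1:200, function(s)
    mean(emissionProbs(initRandomHMM(2, 5, seed = s))), numeric(1))
  expect_lt(abs(mean(means) - 0.5), 0.02)
})

test_that("model comparison reports maximum emission correlations and permutations", {
  m <- randomTinyModel(4, 6, 21)
  self <- compareModels(m, m)
  expect_equal(self$maxCorrelation, rep(1, 4))
  expect_equal(self$bestMatch, 1:4)

  perm <- c(3, 1, 4, 2)
  mp <- StackedHMM(emissionProbs(m)[perm, ], transitionProbs(m)[perm, perm],
                   initialProbs(m)[perm])
  res <- compareModels(m, mp)
  expect_equal(res$maxCorrelation, rep(1, 4))
  expect_equal(perm[res$bestMatch], 1:4)

  # brute-force double loop oracle
  other <- randomTinyModel(3, 6, 22)
  res2 <- compareModels(m, other)
  for (s in 1:4) {
    cors <- vapply(1:3, function(j)
      cor(emissionProbs(m)[s, ], emissionProbs(other)[j, ]), numeric(1))
    expect_equal(res2$maxCorrelation[s], max(cors))
    expect_equal(res2$bestMatch[s], which.max(cors))
  }
})

test_that("mark-restricted correlations flag a group-specific state", {
  # 2 states x 6 cell types of one mark; state 2 is "on" only in group A cells
  feats <- paste0("E", 1:6, "-H3K4me1")
  e <- rbind(rep(0.5, 6), c(0.9, 0.9, 0.9, 0.1, 0.1, 0.1))
  m <- StackedHMM(e, matrix(0.5, 2, 2), c(0.5, 0.5), featureNames = feats)
  md <- data.frame(feature = feats, mark = "H3K4me1",
                   group = rep(c("A", "B"), each = 3))
  res <- markGroupCorrelation(m, md, "H3K4me1")
  expect_equal(res$maxCorrelation[res$group == "A"], 1)
  expect_equal(res$bestState[res$group == "A"], 2L)
})
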