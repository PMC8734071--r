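# chromstack

Universal chromatin-state annotation from stacked epigenomic data.

## The scientific problem

Chromatin immunoprecipitation and accessibility assays (histone-modification
ChIP-seq, DNase-seq, ATAC-seq) describe the regulatory state of the genome,
but each individual track is noisy and assay-specific. The classical
"concatenated" approach learns one hidden Markov model per cell type over a
handful of marks, producing a different annotation per cell type. The
**stacked** approach taken here instead treats *every dataset from every cell
type* as one feature of a single multivariate observation per genomic bin,
and learns **one universal annotation** of the genome: each 200-bp bin is
assigned to one of S states, where a state is defined by its probability of
showing a signal call in each of the (possibly >1000) input datasets.

Because the state definitions span cell types, the resulting annotation
captures both constitutive elements (promoters and transcribed bodies active
everywhere) and cell-type-restricted elements (enhancers active only in one
tissue group), in a single coordinate system.

## The model

Each genomic bin `t` carries a binary vector `x_t ∈ {0,1}^D` (one bit per
dataset, from Poisson-background binarization of read counts). The model is a
hidden Markov chain with S states and **independent Bernoulli emissions**:

```
P(x_t | state s) = ∏_d  p_{s,d}^{x_{t,d}} (1 - p_{s,d})^{1 - x_{t,d}}
```

with an S×S transition matrix and an initial distribution per chromosome
chunk. Parameters are learned by Baum–Welch (EM) with:

* a numerically stabilized emission product (the `-many` scheme: per-bin
  rescaling with an accumulated log-scale, so products over thousands of
  datasets neither underflow nor bias the likelihood),
* optional per-iteration random chunk subsampling for scalability
  (`nSampledChunks`, default 300 chunks),
* a pseudo-count prior (default 1) and a log-likelihood convergence delta.

Decoding assigns each bin its posterior-maximal state. Downstream, states are
characterized by fold enrichment against external annotations
(`FE = (overlap · genome) / (stateSize · annotationSize)`), TSS-anchored
positional enrichment and expression curves (±25 kb at 200-bp resolution,
with window-21 smoothing), per-state expression summaries, emission
coefficients of variation across cell-type groups, Wilcoxon differential
emission tests with Bonferroni control, greedy selection of maximally
informative summary features, AUROC-based predictive evaluation, AIC/BIC
model selection, and emission-correlation matching between independently
learned models.

## Worked example

A small self-contained study: simulate a 1-Mb genome with a known 5-state
truth model and 10 binarized datasets, learn the model back, decode, and
characterize the states. (Numbers below are the actual output of this code.)

```r
library(chromstack)

cfg <- simulationConfig(chromSizes = c(chr1 = 6e5, chr2 = 4e5),
                        chunkLimit = 1e5, seed = 33)
sim <- simulateGenome(cfg)
sim$chunks[[1]]
#> ObservationChunk chr1.0: 500 bins x 10 datasets (startBin 0)

fit <- trainStackedHMM(sim$chunks,
         trainConfig(nStates = 5, nSampledChunks = length(sim$chunks),
                     maxIterations = 60, seed = 8))
fit
#> StackedHMMFit: 5 states x 10 features
#>   emission range: [0.04089, 0.9073]
#>   60 training iterations, final sampled logLik -13641.07

seg <- decodeSegmentation(fit, sim$chunks, cfg$chromSizes)
seg
#> Segmentation: 5 states over 2 chromosomes (5000 bins of 200 bp)

cmp <- compareModels(cfg$truth, fit)
cmp$bestMatch                       # learned state matching each truth state
#> [1] 5 3 2 1 4
round(cmp$maxCorrelation, 4)        # emission-vector correlations
#> [1] 0.9998 0.9997 0.9998 0.9998 0.9997
mean(match(stateIndices(seg), cmp$bestMatch) == stateIndices(sim$truth))
#> [1] 0.9948                        # per-bin decode accuracy vs truth
```

State characterization against a toy annotation born entirely from truth
state 2 (so the closed-form enrichment is 1/coverage of that state):

```r
ann <- makeToyAnnotations(sim$truth, targetStates = 2, hitRate = 1,
                          n = 200, seed = 5)
round(foldEnrichment(sim$truth, list(enhancerLike = ann)), 3)
#>    enhancerLike
#> S1        0.000
#> S2        5.187
#> S3        0.000
#> S4        0.000
#> S5        0.000
round(1 / stateCoverage(sim$truth)[2], 3)
#>    S2
#> 5.187
```

Linking states to expression (genes generated with per-state effect sizes
10, 8, 6, 4, 2):

```r
genes <- makeToyGenes(cfg$chromSizes, n = 120, minLength = 400,
                      maxLength = 1500, seed = 2)
expr <- makeToyExpression(genes, sim$truth, effectSizes = c(10, 8, 6, 4, 2),
                          nSamples = 3, noiseSd = 0.05, seed = 3)
expressionByState(sim$truth, genes, expr)$mean
#>       S1       S2       S3       S4       S5
#> 9.424771 7.689855 5.953493 4.534820 2.447592
```

## Command-line interface

`inst/scripts/stackstate` exposes the full pipeline as subcommands
(`simulate`, `binarize`, `merge`, `learn`, `segment`, `enrich`, `posenrich`,
`overlap-prob`, `auroc`, `characterize`, `compare`), each writing a JSON run
manifest next to its outputs:

```sh
STACKSTATE=$(Rscript -e 'cat(system.file("scripts","stackstate",package="chromstack"))')
Rscript "$STACKSTATE" simulate --chroms chr1:400000,chr2:200000 --seed 11 --reads --outdir study
Rscript "$STACKSTATE" learn --indir study/binarized --chrom-sizes study/chrom.sizes \
        --states 5 --outdir study/model
Rscript "$STACKSTATE" segment --model study/model --indir study/binarized \
        --chrom-sizes study/chrom.sizes --out study/segments.bed.gz
```

## Reproduction

* **Unit and integration tests** (requires the package to be installed):

  ```sh
  Rscript -e 'testthat::test_dir("tests/testthat", package = "chromstack",
                                  load_package = "installed")'
  ```

* **Acceptance run** — computes the package's headline quantities on seeded
  synthetic data and writes them as JSON:

  ```sh
  Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
  ```

  All randomness derives from `--seed`. With seed 1 the run reports, among
  others: forward–backward max posterior error `2.4e-15` against exhaustive
  path enumeration, minimum EM log-likelihood increment `-8.7e-11`
  (monotone to numerical precision), 200k-bin emission recovery MAE
  `0.00105` with decode accuracy `0.9954`, and the closed-form
  fold-enrichment identities satisfied to `2.2e-16`.
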