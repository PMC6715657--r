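test_that("the same configuration yields byte-identical bundles", {
  cfg <- syntheticConfig(seed = 5, nChromosomes = 1, chromLength = 200000,
                         nGenes = 20, nPeaks = 30,
                         expressionPlan = list(nExpressed = 8, noiseSd = 0),
                         orthologPlan = list(nPairs = 16, nConserved = 2))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateDataset(cfg, d1)
  generateDataset(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
})

test_that("motif planting mutates the genome and rejects overlaps", {
  set.seed(6)
  sg <- newSyntheticGenome(c(chr1 = randomDNA(500)))
  sg <- plantMotif(sg, "chr1", 101, "+", "AACAATG")
  p <- buildPWM("AACAATG")
  hits <- scanSequence(p, sg$seqs[["chr1"]], 75)
  expect_true(any(hits$offset == 101 & hits$strand == "+"))
  sg2 <- plantMotif(sg, "chr1", 301, "-", "AACAATG")
  expect_equal(substr(sg2$seqs[["chr1"]], 301, 307), "CATTGTT")
  hits2 <- scanSequence(p, sg2$seqs[["chr1"]], 75)
  expect_true(any(hits2$offset == 301 & hits2$strand == "-"))
  expect_error(plantMotif(sg, "chr1", 104, "+", "AACAATG"), "overlap")
  expect_error(plantMotif(sg, "chr1", 499, "+", "AACAATG"), "fit")
})

test_that("the expression plan is recovered exactly when noise is off", {
  set.seed(8)
  ids <- sprintf("g%04d", 1:300)
  plan <- list(nExpressed = 40L, noiseSd = 0)
  out <- realizeExpressionPlan(plan, ids)
  expect_length(out$expressed, 40L)
  expect_setequal(callHighlyExpressed(out$records), out$expressed)
  ## all genes planted null -> empty call
  out0 <- realizeExpressionPlan(list(nExpressed = 0L, noiseSd = 0), ids)
  expect_length(callHighlyExpressed(out0$records), 0L)
})

test_that("null q-values pass the q criterion alone at roughly the 5% rate", {
  set.seed(9)
  ids <- sprintf("g%04d", 1:3000)
  out <- realizeExpressionPlan(list(nExpressed = 0L, noiseSd = 0), ids)
  ## failure mode 1 draws q ~ Uniform(0,1); those rows have FPKM < 1
  mode1 <- out$records[out$records$fpkm_cell < 1, ]
  expect_gt(nrow(mode1), 500)
  rate <- mean(mode1$q_value < 0.05)
  expect_gt(rate, 0.02); expect_lt(rate, 0.08)   # binomial expectation ~5%
})

test_that("an all-OTHER category plan classifies everything as OTHER", {
  cfg <- syntheticConfig(seed = 10, nChromosomes = 1, chromLength = 200000,
                         nGenes = 20, nPeaks = 20,
                         categoryFractions = c(UPSTREAM_10KB = 0, UTR5 = 0,
                                               CODING_EXON = 0, INTRON = 0,
                                               UTR3 = 0, DOWNSTREAM_10KB = 0,
                                               OTHER = 1),
                         expressionPlan = list(nExpressed = 5, noiseSd = 0),
                         orthologPlan = list(nPairs = 10, nConserved = 0))
  d <- withr::local_tempdir()
  b <- generateDataset(cfg, d)
  genome <- readGenome(b$files$a[["genome"]])
  gm <- readGeneModels(b$files$a[["genes"]])
  pk <- readPeakTable(b$files$a[["peaks"]], "macs_tsv")
  idx <- buildAnnotationIndex(gm, chromSizes = setNames(width(genome),
                                                        names(genome)))
  cls <- classifyPeaks(pk, idx)
  expect_true(all(cls$category == "OTHER"))
})

test_that("infeasible plans error before writing anything", {
  ## more intron peaks than intron candidate sites on a single chromosome
  cfg <- syntheticConfig(seed = 11, nChromosomes = 1, chromLength = 200000,
                         nGenes = 20, nPeaks = 200,
                         categoryFractions = c(UPSTREAM_10KB = 0, UTR5 = 0,
                                               CODING_EXON = 0, INTRON = 1,
                                               UTR3 = 0, DOWNSTREAM_10KB = 0,
                                               OTHER = 0),
                         expressionPlan = list(nExpressed = 5, noiseSd = 0),
                         orthologPlan = list(nPairs = 10, nConserved = 0))
  d <- file.path(withr::local_tempdir(), "never")
  expect_error(generateDataset(cfg, d), "infeasible")
  expect_equal(length(list.files(d)), 0L)
  expect_error(syntheticConfig(nGenes = 10, nChromosomes = 3), "divisible")
  expect_error(syntheticConfig(expressionPlan = list(nExpressed = 999,
                                                     noiseSd = 0)),
               "infeasible")
})

test_that("generated files re-parse through the readers without warnings", {
  sb <- smallBundle()
  fl <- sb$bundle$files
  expect_no_warning({
    genome <- readGenome(fl$a[["genome"]])
    gm <- readGeneModels(fl$a[["genes"]])
    pk <- readPeakTable(fl$a[["peaks"]], "macs_tsv")
    bed <- readPeakTable(fl$a[["peaks_bed"]], "bed")
    tr <- readConservationTrack(fl$a[["conservation"]])
    ex <- readExpressionTable(fl$a[["expression"]])
    om <- readOrthologMap(fl$orthologs)
    go <- readGoMap(fl$go)
    mono <- readMemeMotif(fl$motif)
  })
  expect_equal(length(pk), sb$bundle$manifest$config$nPeaks)
  expect_equal(length(gm), sb$bundle$manifest$config$nGenes)
  expect_equal(pk$summit, bed$summit)   # BED midpoints equal planted summits
  expect_equal(pwmConsensus(mono), "AACAATG")
})

test_that("planted palindromes are recovered at the planted frequency", {
  sb <- smallBundle()
  fl <- sb$bundle$files
  m <- sb$bundle$manifest
  genome <- readGenome(fl$a[["genome"]])
  pk <- readPeakTable(fl$a[["peaks"]], "macs_tsv")
  mono <- readMemeMotif(fl$motif)
  pal <- buildPalindromePWM(mono, 4)
  freq <- motifPeakFrequency(pk, genome, pal, threshold = 75)
  expect_equal(freq, unname(m$species$a$motif_frequency["palindrome"]))
  ## monotonicity under the planted conditions: stricter threshold, fewer hits
  expect_lte(motifPeakFrequency(pk, genome, pal, threshold = 90), freq)
})
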