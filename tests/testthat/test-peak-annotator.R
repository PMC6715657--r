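test_that("flanks are strand-aware and clipped at chromosome bounds", {
  gm <- makeModels(data.frame(chrom = "chr1", start = 20001L, end = 25000L,
                              strand = "+", gene_id = "g1"))
  idx <- buildAnnotationIndex(gm, chromSizes = c(chr1 = 100000))
  up <- idx@ranges[idx@ranges$category == "UPSTREAM_10KB"]
  expect_equal(c(start(up), end(up)), c(10001L, 20000L))
  dn <- idx@ranges[idx@ranges$category == "DOWNSTREAM_10KB"]
  expect_equal(c(start(dn), end(dn)), c(25001L, 35000L))

  ## clamped at the chromosome start
  gm2 <- makeModels(data.frame(chrom = "chr1", start = 4001L, end = 9000L,
                               strand = "+", gene_id = "g1"))
  idx2 <- buildAnnotationIndex(gm2, chromSizes = c(chr1 = 100000))
  up2 <- idx2@ranges[idx2@ranges$category == "UPSTREAM_10KB"]
  expect_equal(c(start(up2), end(up2)), c(1L, 4000L))

  ## minus strand: upstream flank sits off the high-coordinate TSS
  gm3 <- makeModels(data.frame(chrom = "chr1", start = 20001L, end = 25000L,
                               strand = "-", gene_id = "g1"))
  idx3 <- buildAnnotationIndex(gm3, chromSizes = c(chr1 = 100000))
  up3 <- idx3@ranges[idx3@ranges$category == "UPSTREAM_10KB"]
  expect_equal(c(start(up3), end(up3)), c(25001L, 35000L))

  expect_error(buildAnnotationIndex(gm, chromSizes = c(chr2 = 1000)),
               "unknown chromosome")
})

test_that("summit classification follows the precedence and tie-break rules", {
  ## gene A intron overlapping gene B's upstream flank
  gm <- makeModels(
    data.frame(chrom = "chr1", start = c(10001L, 22001L), end = c(18000L, 30000L),
               strand = "+", gene_id = c("gA", "gB"),
               cds_start = c(10500L, 22500L), cds_end = c(17500L, 29500L)),
    list(cbind(c(10001L, 16001L), c(12000L, 18000L)), NULL))
  idx <- buildAnnotationIndex(gm, chromSizes = c(chr1 = 100000))
  pk <- makePeaks("chr1", c(14000L, 5000L, 60000L))
  cls <- classifyPeaks(pk, idx)
  expect_equal(as.character(cls$category),
               c("INTRON", "UPSTREAM_10KB", "OTHER"))
  expect_equal(cls$gene_id, c("gA", "gA", NA))

  ## nearest-TSS tie break between two upstream flanks, then gene id
  gm2 <- makeModels(data.frame(
    chrom = "chr1", start = c(30001L, 42000L), end = c(32000L, 44000L),
    strand = c("-", "+"), gene_id = c("gLeft", "gRight")))
  ## minus gene TSS = 32000 (upstream flank 32001..42000); plus gene TSS =
  ## 42000 (upstream flank 32000..41999): the flanks overlap almost fully
  idx2 <- buildAnnotationIndex(gm2, chromSizes = c(chr1 = 100000))
  near_left <- classifyPeaks(makePeaks("chr1", 33000L), idx2)
  expect_equal(near_left$gene_id, "gLeft")
  near_right <- classifyPeaks(makePeaks("chr1", 41500L), idx2)
  expect_equal(near_right$gene_id, "gRight")
  midpoint <- classifyPeaks(makePeaks("chr1", 37000L), idx2)  # 5000 bp to each
  expect_equal(midpoint$gene_id, "gLeft")   # smallest gene_id on exact tie
})

test_that("category fractions sum to one and match planted construction", {
  gm <- makeModels(data.frame(chrom = "chr1", start = 50001L, end = 55000L,
                              strand = "+", gene_id = "g1",
                              cds_start = 50001L, cds_end = 55000L))
  idx <- buildAnnotationIndex(gm, chromSizes = c(chr1 = 200000))
  pk <- makePeaks("chr1", c(rep(45000L, 5), rep(150000L, 5)), w = 100L)
  fr <- categoryFractions(pk, idx)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-9)
  expect_equal(fr$fraction[fr$category == "UPSTREAM_10KB"], 0.5)
  expect_equal(fr$fraction[fr$category == "OTHER"], 0.5)
  expect_equal(sum(fr$count), length(pk))
  expect_error(categoryFractions(pk[0], idx), "at least one")
})

test_that("classification agrees with the per-base painter oracle", {
  set.seed(101)
  for (rep in 1:10) {
    chromLen <- 50000L
    gm <- randomModels("chrO", chromLen, nGenes = 5L)
    sizes <- c(chrO = chromLen)
    idx <- buildAnnotationIndex(gm, chromSizes = sizes)
    paint <- paintCategories(gm, sizes)
    summits <- sample.int(chromLen - 600L, 80L) + 300L
    cls <- classifyPeaks(makePeaks("chrO", summits, w = 50L), idx)
    expect_identical(as.character(cls$category), paint$chrO[summits])
  }
})

test_that("mirroring strands and coordinates leaves categories unchanged", {
  set.seed(202)
  chromLen <- 40000L
  gm <- randomModels("chrM", chromLen, nGenes = 4L)
  g <- geneRanges(gm)
  flip <- function(pos) chromLen - pos + 1L
  ## reflect genes about the chromosome midpoint and flip strands
  gflip <- data.frame(chrom = "chrM", start = flip(end(g)), end = flip(start(g)),
                      strand = ifelse(as.character(strand(g)) == "+", "-", "+"),
                      gene_id = g$gene_id,
                      cds_start = flip(g$cds_end), cds_end = flip(g$cds_start))
  exflip <- lapply(seq_along(g), function(i) {
    ex <- modelExons(gm)[[i]]
    m <- cbind(flip(end(ex)), flip(start(ex)))
    m[order(m[, 1L]), , drop = FALSE]
  })
  gm2 <- makeModels(gflip, exflip)
  sizes <- c(chrM = chromLen)
  idx1 <- buildAnnotationIndex(gm, chromSizes = sizes)
  idx2 <- buildAnnotationIndex(gm2, chromSizes = sizes)
  summits <- seq(500L, chromLen - 500L, by = 177L)
  c1 <- classifyPeaks(makePeaks("chrM", summits, w = 50L), idx1)
  c2 <- classifyPeaks(makePeaks("chrM", flip(summits), w = 50L), idx2)
  expect_identical(as.character(c1$category), as.character(c2$category))
})

test_that("peak overlap counting respects half-open abutment and pairs", {
  A <- GRanges("chr1", IRanges(101, 200)); A$name <- "a1"
  A$summit <- 150L; A$fold_enrichment <- NA_real_
  B <- GRanges("chr1", IRanges(151, 250)); B$name <- "b1"
  B$summit <- 200L; B$fold_enrichment <- NA_real_
  expect_equal(countPeakOverlaps(A, B),
               list(n_a_overlapping = 1L, n_b_overlapping = 1L, n_pairs = 1L))
  ## BED half-open abutment: 0-based [100,200) and [200,300) do not overlap
  B2 <- GRanges("chr1", IRanges(201, 300))
  expect_equal(countPeakOverlaps(A, B2)$n_pairs, 0L)
  ## three A peaks over one B peak
  A3 <- GRanges("chr1", IRanges(c(101, 141, 181), c(140, 180, 220)))
  B1 <- GRanges("chr1", IRanges(101, 220))
  expect_equal(countPeakOverlaps(A3, B1),
               list(n_a_overlapping = 3L, n_b_overlapping = 1L, n_pairs = 3L))
})

test_that("fold-enrichment histogram and moments follow the bin convention", {
  pk <- makePeaks("chr1", seq(1000L, 5000L, by = 1000L),
                  fold = c(1, 2, 3, 4, 5))
  st <- enrichmentHistogramStats(pk, binWidth = 5)
  expect_equal(st$skewness, 0)             # symmetric values
  expect_equal(st$kurtosis, 1.7)           # m4/m2^2 for 1..5
  pk2 <- makePeaks("chr1", c(1000L, 2000L, 3000L), fold = c(12, 17, 17))
  h <- enrichmentHistogramStats(pk2, binWidth = 5)$histogram
  expect_equal(h$bin_start, c(10, 15))
  expect_equal(h$count, c(1L, 2L))
  const <- makePeaks("chr1", c(1000L, 2000L, 3000L), fold = 7)
  expect_error(enrichmentHistogramStats(const), "variance")
  expect_error(enrichmentHistogramStats(pk[1:2]), "at least 3")
})

test_that("every peak gets exactly one category", {
  set.seed(7)
  gm <- randomModels("chrU", 30000L, 3L)
  idx <- buildAnnotationIndex(gm, chromSizes = c(chrU = 30000L))
  pk <- makePeaks("chrU", sample.int(29000L, 200L) + 500L, w = 50L)
  cls <- classifyPeaks(pk, idx)
  expect_false(anyNA(cls$category))
  expect_equal(sum(table(cls$category)), length(pk))
})
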