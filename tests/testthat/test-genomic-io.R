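test_that("BED peaks parse with midpoint summits and validated coordinates", {
  f <- withr::local_tempfile(lines = c("track name=x",
                                       "chr1\t100\t200\tp1",
                                       "chr1\t300\t401\tp2\t8.5"))
  pk <- readPeakTable(f, "bed")
  expect_length(pk, 2L)                       # parser totality: one per line
  expect_equal(start(pk), c(101L, 301L))      # 0-based -> 1-based
  expect_equal(end(pk), c(200L, 401L))
  ## BED 100-200 midpoint = 0-based 150 = 1-based 151
  expect_equal(pk$summit, c(151L, 351L))
  expect_equal(pk$name, c("p1", "p2"))
  expect_equal(pk$fold_enrichment, c(NA, 8.5))

  bad <- withr::local_tempfile(lines = c("chr1\t10\t20\tok", "chr1\t50\t40\tbad"))
  expect_error(readPeakTable(bad, "bed"), "line 2")
  empty <- withr::local_tempfile(lines = character(0))
  expect_length(readPeakTable(empty, "bed"), 0L)
})

test_that("MACS-style summit-offset tables parse in both coordinate frames", {
  f <- withr::local_tempfile(lines = c(
    "chr\tstart\tend\tlength\tsummit\tfold_enrichment",
    "chr2\t100\t201\t101\t30\t12.5"))
  pk <- readPeakTable(f, "macs_tsv")
  ## summit = start + offset in the file frame: 0-based 130 = 1-based 131
  expect_equal(pk$summit, 131L)
  expect_equal(start(pk), 101L)
  pk1 <- readPeakTable(f, "macs_tsv", oneBased = TRUE)
  expect_equal(start(pk1), 100L)
  expect_equal(pk1$summit, 130L)

  miss <- withr::local_tempfile(lines = c("chr\tstart\tend", "chr1\t1\t10"))
  expect_error(readPeakTable(miss, "macs_tsv"), "summit")
  expect_error(readPeakTable(f, "unknown_dialect"), "arg")
})

test_that("peak tables round-trip through the macs_tsv dialect", {
  pk <- makePeaks("chr1", c(1000L, 5000L, 9000L), fold = c(3.5, 7.25, 10))
  f <- withr::local_tempfile()
  writePeakTable(pk, f, "macs_tsv")
  back <- readPeakTable(f, "macs_tsv")
  expect_equal(start(back), start(pk))
  expect_equal(end(back), end(pk))
  expect_equal(back$summit, pk$summit)
  expect_equal(back$name, pk$name)
  expect_equal(back$fold_enrichment, pk$fold_enrichment)
})

test_that("GTF gene models: UTR derivation, strand TSS, longest transcript", {
  gtf <- withr::local_tempfile(fileext = ".gtf", lines = c(
    ## gene gA, + strand, one exon [5001,8000] with CDS [5501,7500]
    paste("chr1\tsrc\ttranscript\t5001\t8000\t.\t+\t.",
          'gene_id "gA"; transcript_id "gA_t1";', sep = "\t"),
    paste("chr1\tsrc\texon\t5001\t8000\t.\t+\t.",
          'gene_id "gA"; transcript_id "gA_t1";', sep = "\t"),
    paste("chr1\tsrc\tCDS\t5501\t7500\t.\t+\t0",
          'gene_id "gA"; transcript_id "gA_t1";', sep = "\t"),
    ## gene gB, - strand, two transcripts (3000 bp and 2000 bp span)
    paste("chr1\tsrc\texon\t20001\t23000\t.\t-\t.",
          'gene_id "gB"; transcript_id "gB_t1";', sep = "\t"),
    paste("chr1\tsrc\tCDS\t20501\t22500\t.\t-\t0",
          'gene_id "gB"; transcript_id "gB_t1";', sep = "\t"),
    paste("chr1\tsrc\texon\t20001\t22000\t.\t-\t.",
          'gene_id "gB"; transcript_id "gB_t2";', sep = "\t")))
  gm <- readGeneModels(gtf, "gtf")
  g <- geneRanges(gm)
  expect_setequal(g$gene_id, c("gA", "gB"))
  gA <- g[g$gene_id == "gA"]
  expect_equal(gA$tss, 5001L)
  expect_equal(c(gA$cds_start, gA$cds_end), c(5501L, 7500L))
  gB <- g[g$gene_id == "gB"]
  expect_equal(gB$transcript_id, "gB_t1")      # longest span wins
  expect_equal(gB$tss, 23000L)                 # minus strand: high end
  ## UTRs via the annotation index (exonic parts outside the CDS)
  idx <- buildAnnotationIndex(gm, chromSizes = c(chr1 = 50000))
  r <- idx@ranges
  utr5A <- r[r$gene_id == "gA" & r$category == "UTR5"]
  expect_equal(c(start(utr5A), end(utr5A)), c(5001L, 5500L))
  utr3A <- r[r$gene_id == "gA" & r$category == "UTR3"]
  expect_equal(c(start(utr3A), end(utr3A)), c(7501L, 8000L))
})

test_that("exon outside declared transcript bounds is a validation error", {
  gtf <- withr::local_tempfile(fileext = ".gtf", lines = c(
    paste("chr1\tsrc\ttranscript\t1000\t2000\t.\t+\t.",
          'gene_id "gX"; transcript_id "gX_t1";', sep = "\t"),
    paste("chr1\tsrc\texon\t900\t2000\t.\t+\t.",
          'gene_id "gX"; transcript_id "gX_t1";', sep = "\t")))
  expect_error(readGeneModels(gtf, "gtf"), "gX")
})

test_that("gene models round-trip through GTF and parse from BED12/GFF3", {
  gm <- makeModels(
    data.frame(chrom = "chr1", start = c(1000L, 9000L), end = c(4000L, 12000L),
               strand = c("+", "-"), gene_id = c("g1", "g2"),
               cds_start = c(1400L, 9500L), cds_end = c(3500L, 11500L)),
    list(cbind(c(1000L, 2500L), c(2000L, 4000L)), NULL))
  f <- withr::local_tempfile(fileext = ".gtf")
  writeGeneModels(gm, f)
  back <- readGeneModels(f, "gtf")
  expect_equal(geneRanges(back)$gene_id, geneRanges(gm)$gene_id)
  expect_equal(start(geneRanges(back)), start(geneRanges(gm)))
  expect_equal(geneRanges(back)$tss, geneRanges(gm)$tss)
  expect_equal(geneRanges(back)$cds_start, geneRanges(gm)$cds_start)
  expect_identical(lapply(modelExons(back), ranges),
                   lapply(modelExons(gm), ranges))

  bed12 <- withr::local_tempfile(fileext = ".bed", lines = paste(
    "chr1", 999, 4000, "g1", 0, "+", 1399, 3500, "0", 2,
    "1001,1500,", "0,1500,", sep = "\t"))
  gb <- readGeneModels(bed12, "bed12")
  expect_equal(start(geneRanges(gb)), 1000L)
  expect_equal(geneRanges(gb)$cds_start, 1400L)
  expect_equal(start(modelExons(gb)[["g1"]]), c(1000L, 2500L))

  gff3 <- withr::local_tempfile(fileext = ".gff3", lines = c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t1000\t4000\t.\t+\t.\tID=g1",
    "chr1\tsrc\tmRNA\t1000\t4000\t.\t+\t.\tID=g1_t1;Parent=g1",
    "chr1\tsrc\texon\t1000\t2000\t.\t+\t.\tID=e1;Parent=g1_t1",
    "chr1\tsrc\texon\t2500\t4000\t.\t+\t.\tID=e2;Parent=g1_t1",
    "chr1\tsrc\tCDS\t1400\t2000\t.\t+\t0\tID=c1;Parent=g1_t1",
    "chr1\tsrc\tCDS\t2500\t3500\t.\t+\t0\tID=c2;Parent=g1_t1"))
  gg <- readGeneModels(gff3, "gff3")
  expect_equal(geneRanges(gg)$gene_id, "g1")
  expect_equal(geneRanges(gg)$cds_end, 3500L)
})

test_that("conservation tracks: wiggle and bedGraph dialects, sparse store", {
  wig <- withr::local_tempfile(fileext = ".wig", lines = c(
    "fixedStep chrom=chr1 start=11 step=1 span=1", "0.5", "0.6"))
  tr <- readConservationTrack(wig)
  ## wiggle is 1-based: values at 1-based 11,12 (0-based 10,11)
  expect_equal(trackScore(tr, "chr1", 11:12), c(0.5, 0.6))
  expect_true(is.na(trackScore(tr, "chr1", 10)))   # missing, distinct from 0
  expect_true(is.na(trackScore(tr, "chrX", 11)))

  bg <- withr::local_tempfile(fileext = ".bedgraph",
                              lines = "chr1\t0\t3\t1.0")
  tb <- readConservationTrack(bg)
  expect_equal(trackScore(tb, "chr1", 1:3), c(1, 1, 1))
  expect_true(is.na(trackScore(tb, "chr1", 4)))

  bad <- withr::local_tempfile(fileext = ".bedgraph",
                               lines = "chr1\t0\t3\t1.5")
  expect_error(readConservationTrack(bad), "\\[0,1\\]")
})

test_that("conservation tracks round-trip through fixedStep wiggle", {
  bg <- withr::local_tempfile(fileext = ".bedgraph", lines = c(
    "chr1\t10\t15\t0.25", "chr1\t100\t103\t0.8", "chr2\t0\t2\t1"))
  tr <- readConservationTrack(bg)
  f <- withr::local_tempfile(fileext = ".wig")
  writeConservationTrack(tr, f)
  back <- readConservationTrack(f)
  expect_equal(trackChroms(back), trackChroms(tr))
  expect_equal(trackScore(back, "chr1", 1:110), trackScore(tr, "chr1", 1:110))
  expect_equal(trackScore(back, "chr2", 1:2), c(1, 1))
})

test_that("expression, ortholog and GO tables validate and deduplicate", {
  f <- withr::local_tempfile(lines = c(
    "gene_id\tfpkm_cell\tfpkm_whole_embryo\tq_value", "g1\t2.0\t1.0\t0.01"))
  tab <- readExpressionTable(f)
  expect_equal(tab$fpkm_cell, 2.0)
  expect_equal(tab$q_value, 0.01)

  dup <- withr::local_tempfile(lines = c(
    "gene_id\tfpkm_cell\tfpkm_whole_embryo\tq_value",
    "g1\t2\t1\t0.01", "g1\t3\t1\t0.01"))
  expect_error(readExpressionTable(dup), "duplicate")
  badq <- withr::local_tempfile(lines = c(
    "gene_id\tfpkm_cell\tfpkm_whole_embryo\tq_value", "g1\t2\t1\t1.5"))
  expect_error(readExpressionTable(badq), "q_value")
  miss <- withr::local_tempfile(lines = c("gene_id\tfpkm_cell", "g1\t2"))
  expect_error(readExpressionTable(miss), "fpkm_whole_embryo")

  orth <- withr::local_tempfile(lines = c(
    "gene_a\tgene_b\thomology_type",
    "m1\tc1\tortholog_one2one", "m1\tc1\tortholog_one2one"))
  expect_equal(nrow(readOrthologMap(orth)), 1L)     # duplicate pair dropped

  go <- withr::local_tempfile(lines = c(
    "gene_id\tgo_term", "g1\tGO:0001501", "g1\tGO:0001501", "g2\tGO:0008150"))
  expect_equal(nrow(readGoMap(go)), 2L)
})

test_that("report tables are written deterministically", {
  report <- list(tables = list(demo = data.frame(gene_id = c("b", "a"),
                                                 n = c(2L, 1L)),
                               empty = data.frame(gene_id = character(),
                                                  n = integer())),
                 summary = list(n = 2L, note = "x"))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeReportTables(report, d1)
  writeReportTables(report, d2)
  expect_identical(readLines(file.path(d1, "demo.tsv")),
                   readLines(file.path(d2, "demo.tsv")))
  expect_identical(readLines(file.path(d1, "run_summary.json")),
                   readLines(file.path(d2, "run_summary.json")))
  ## stable order and headered empty table
  expect_equal(readLines(file.path(d1, "demo.tsv"))[2], "a\t1")
  expect_equal(readLines(file.path(d1, "empty.tsv")), "gene_id\tn")
})
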