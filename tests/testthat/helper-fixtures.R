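suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

## Build a GeneModels object from a compact spec:
## genes: data.frame(chrom, start, end, strand, gene_id, cds_start, cds_end)
## exons: list of 2-column matrices (start, end) parallel to genes; default
##        one exon spanning the gene
makeModels <- function(genes, exons = NULL) {
  gr <- GRanges(genes$chrom, IRanges(genes$start, genes$end),
                strand = genes$strand)
  gr$gene_id <- genes$gene_id
  gr$transcript_id <- paste0(genes$gene_id, "_t1")
  gr$tss <- ifelse(genes$strand == "-", genes$end, genes$start)
  gr$cds_start <- if ("cds_start" %in% names(genes)) genes$cds_start
                  else genes$start
  gr$cds_end <- if ("cds_end" %in% names(genes)) genes$cds_end else genes$end
  gr$biotype <- if ("biotype" %in% names(genes)) genes$biotype
                else "protein_coding"
  exl <- lapply(seq_len(nrow(genes)), function(i) {
    if (is.null(exons) || is.null(exons[[i]]))
      GRanges(genes$chrom[i], IRanges(genes$start[i], genes$end[i]),
              strand = genes$strand[i])
    else
      GRanges(genes$chrom[i], IRanges(exons[[i]][, 1L], exons[[i]][, 2L]),
              strand = genes$strand[i])
  })
  new("GeneModels", genes = gr,
      exons = GRangesList(setNames(exl, genes$gene_id)))
}

## GRanges peak set from summits (1-based), half-width w
makePeaks <- function(chrom, summits, w = 250L, fold = NA_real_) {
  gr <- GRanges(chrom, IRanges(summits - w, summits + w - 1L))
  gr$name <- paste0("p", seq_along(summits))
  gr$summit <- as.integer(summits)
  gr$fold_enrichment <- rep_len(fold, length(summits))
  gr
}

## Brute-force per-base category painter: paints every base of every
## chromosome with its best category (increasing precedence order, so later
## paints overwrite earlier ones), then a summit's category is its paint.
## Independent oracle for classifyPeaks.
paintCategories <- function(models, chromSizes, upstream = 10000,
                            downstream = 10000) {
  paint <- lapply(chromSizes, function(L) rep("OTHER", L))
  g <- geneRanges(models)
  exl <- modelExons(models)
  layer <- function(cat) {
    for (i in seq_along(g)) {
      chrom <- as.character(seqnames(g))[i]
      L <- chromSizes[[chrom]]
      st <- as.character(strand(g))[i]
      gs <- start(g)[i]; ge <- end(g)[i]
      ex <- ranges(exl[[i]])
      cs <- g$cds_start[i]; ce <- g$cds_end[i]
      segs <- switch(cat,
        DOWNSTREAM_10KB = if (st == "-") cbind(gs - downstream, gs - 1)
                          else cbind(ge + 1, ge + downstream),
        UPSTREAM_10KB = if (st == "-") cbind(ge + 1, ge + upstream)
                        else cbind(gs - upstream, gs - 1),
        INTRON = if (length(ex) > 1L)
          cbind(head(end(ex), -1) + 1, tail(start(ex), -1) - 1)
          else cbind(1, 0),
        CODING_EXON = {
          r <- if (is.na(cs)) ex else restrict(ex, cs, ce)
          r <- r[width(r) > 0]
          cbind(start(r), end(r))
        },
        UTR3 = {
          if (is.na(cs)) cbind(1, 0) else {
            r <- if (st == "-") restrict(ex, gs, cs - 1)
                 else restrict(ex, ce + 1, ge)
            r <- r[width(r) > 0]
            cbind(start(r), end(r))
          }
        },
        UTR5 = {
          if (is.na(cs)) cbind(1, 0) else {
            r <- if (st == "-") restrict(ex, ce + 1, ge)
                 else restrict(ex, gs, cs - 1)
            r <- r[width(r) > 0]
            cbind(start(r), end(r))
          }
        })
      for (k in seq_len(nrow(segs))) {
        s <- max(1, segs[k, 1]); e <- min(L, segs[k, 2])
        if (s <= e) paint[[chrom]][s:e] <<- cat
      }
    }
  }
  for (cat in c("DOWNSTREAM_10KB", "UPSTREAM_10KB", "INTRON", "CODING_EXON",
                "UTR3", "UTR5"))
    layer(cat)
  paint
}

## Random valid gene models on one chromosome: disjoint coding gene bodies
## with 1-3 exons (flanks may collide freely).
randomModels <- function(chrom, chromLen, nGenes) {
  pitch <- chromLen %/% nGenes
  genes <- NULL
  exons <- list()
  for (i in seq_len(nGenes)) {
    lo <- (i - 1L) * pitch + 1L
    w <- sample(1500:min(5000, pitch - 200L), 1L)
    gs <- lo + sample.int(pitch - w - 100L, 1L)
    ge <- gs + w - 1L
    nex <- sample(1:3, 1L)
    bounds <- sort(sample(seq(gs + 100L, ge - 100L, by = 50L), 2L * (nex - 1L)))
    exs <- matrix(c(gs, if (nex > 1L) bounds[seq(2, length(bounds), 2)] + 1L,
                    if (nex > 1L) bounds[seq(1, length(bounds), 2)], ge),
                  ncol = 2L)
    cds_lo <- gs + sample.int(min(200L, w %/% 4L), 1L)
    cds_hi <- ge - sample.int(min(200L, w %/% 4L), 1L)
    genes <- rbind(genes, data.frame(
      chrom = chrom, start = gs, end = ge,
      strand = sample(c("+", "-"), 1L),
      gene_id = sprintf("%s_g%02d", chrom, i),
      cds_start = cds_lo, cds_end = cds_hi))
    exons[[i]] <- exs
  }
  makeModels(genes, exons)
}

## Exhaustive per-offset PWM scan oracle: explicit window extraction and
## complementation, independent of the sliding-column implementation.
oracleScan <- function(pwm, seq, threshold = 75) {
  w <- pwmWeights(pwm)
  L <- ncol(w)
  maxsc <- sum(apply(w, 2, max))
  chars <- strsplit(toupper(seq), "")[[1]]
  code <- match(chars, c("A", "C", "G", "T"))
  compcode <- c(4L, 3L, 2L, 1L)  # A<->T, C<->G
  res <- list()
  for (o in seq_len(length(code) - L + 1L)) {
    win <- code[o:(o + L - 1L)]
    if (anyNA(win)) next
    sc <- 100 * sum(w[cbind(win, seq_len(L))]) / maxsc
    if (sc > threshold)
      res[[length(res) + 1L]] <- data.frame(offset = o, strand = "+", score = sc)
    rcwin <- rev(compcode[win])
    sc2 <- 100 * sum(w[cbind(rcwin, seq_len(L))]) / maxsc
    if (sc2 > threshold)
      res[[length(res) + 1L]] <- data.frame(offset = o, strand = "-", score = sc2)
  }
  if (!length(res))
    return(data.frame(offset = integer(), strand = character(),
                      score = numeric()))
  out <- do.call(rbind, res)
  out <- out[order(out$offset, out$strand), ]
  rownames(out) <- NULL
  out
}

randomDNA <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = "")

## small synthetic bundle shared across tests (built once per test run)
smallBundleEnv <- new.env()
smallBundle <- function() {
  if (is.null(smallBundleEnv$bundle)) {
    cfg <- syntheticConfig(seed = 42, nChromosomes = 2, chromLength = 200000,
                           nGenes = 40, nPeaks = 60,
                           expressionPlan = list(nExpressed = 12, noiseSd = 0),
                           orthologPlan = list(nPairs = 32, nConserved = 4))
    dir <- file.path(tempdir(), "regcons_small_bundle")
    smallBundleEnv$bundle <- generateDataset(cfg, dir)
    smallBundleEnv$config <- syntheticRunConfig(smallBundleEnv$bundle$files)
  }
  list(bundle = smallBundleEnv$bundle, config = smallBundleEnv$config)
}
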