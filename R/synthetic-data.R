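## Two-species synthetic dataset generator. Every analysis-relevant property
## (peak category, motif content, conservation level, expression status,
## target / regulated status, conserved pairs) is planted deterministically
## and recorded in a ground-truth manifest, so full-pipeline recovery can be
## tested exactly.

## Fixed chromosome layout constants: genes sit on a 9 kb pitch with a 5 kb
## body and alternating strands. Flanks of neighboring genes overlap, which
## the classification precedence resolves; planted summit positions are
## chosen so the intended category always wins (see the methods vignette).
## The 9 kb pitch makes the convergent gap between a + gene and the next -
## gene contain a zone more than 10 kb from every TSS-facing flank, so
## DOWNSTREAM plants are unambiguous.
.SLOT <- 9000L
.BODY_OFF <- 1500L   # body starts at slot + 1501
.BODY_LEN <- 5000L
## exon structure relative to the body (1-based): three exons, two introns
.EXONS_REL <- cbind(start = c(1L, 2401L, 3801L), end = c(1200L, 3000L, 5000L))
.CDS_REL <- c(601L, 4400L)

#' Synthetic dataset configuration
#'
#' Defaults describe the desk-scale study conditions: per species 5
#' chromosomes of 200 kb, 100 genes, 300 peaks of 500 bp; category fractions
#' with upstream and intron binding dominating; a motif plan planting SOX-like
#' palindromic dimers (4 bp spacer), extra single half-sites and CCAAT boxes;
#' a two-level conservation plan (window means 0.6 vs 0.3, sd 0.15); an
#' expression plan of 30 truly expressed genes per species with noise off;
#' and an ortholog plan of 80 one-to-one pairs with 10 conserved regulated
#' genes.
#'
#' @param seed Integer seed; the whole bundle is a deterministic function of
#'   the configuration.
#' @param nChromosomes,chromLength,nGenes,nPeaks Per-species sizes. `nGenes`
#'   must be divisible by `nChromosomes`.
#' @param peakWidth Peak interval width in bases.
#' @param gc Background GC content (PWM false-positive rates depend on it).
#' @param categoryFractions Named fractions over the seven categories,
#'   summing to 1.
#' @param motifPlan List: `palindrome`, `singleExtra`, `ccaat` (fractions of
#'   peaks planted), `monomerSites` (aligned half-site(s) the PWM is built
#'   from), `spacer`, `threshold`.
#' @param conservationPlan List: `highFraction`, `highMean`, `lowMean`, `sd`,
#'   `flank`.
#' @param expressionPlan List: `nExpressed`, `noiseSd`.
#' @param orthologPlan List: `nPairs`, `nConserved`.
#' @param cleanBackground Resample peak backgrounds until motif scans agree
#'   exactly with the planted flags (guarantees exact recovery).
#' @return A configuration list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(seed = 1L,
                            nChromosomes = 5L,
                            chromLength = 200000L,
                            nGenes = 100L,
                            nPeaks = 300L,
                            peakWidth = 500L,
                            gc = 0.5,
                            categoryFractions = c(UPSTREAM_10KB = 0.30,
                                                  UTR5 = 0.02,
                                                  CODING_EXON = 0.05,
                                                  INTRON = 0.25,
                                                  UTR3 = 0.03,
                                                  DOWNSTREAM_10KB = 0.10,
                                                  OTHER = 0.25),
                            motifPlan = list(palindrome = 0.20,
                                             singleExtra = 0.30,
                                             ccaat = 0.25,
                                             monomerSites = "AACAATG",
                                             spacer = 4L,
                                             threshold = 75),
                            conservationPlan = list(highFraction = 0.5,
                                                    highMean = 0.6,
                                                    lowMean = 0.3,
                                                    sd = 0.15,
                                                    flank = 100L),
                            expressionPlan = list(nExpressed = 30L, noiseSd = 0),
                            orthologPlan = list(nPairs = 80L, nConserved = 10L),
                            cleanBackground = TRUE) {
  cfg <- list(seed = as.integer(seed), nChromosomes = as.integer(nChromosomes),
              chromLength = as.integer(chromLength), nGenes = as.integer(nGenes),
              nPeaks = as.integer(nPeaks), peakWidth = as.integer(peakWidth),
              gc = gc, categoryFractions = categoryFractions,
              motifPlan = motifPlan, conservationPlan = conservationPlan,
              expressionPlan = expressionPlan, orthologPlan = orthologPlan,
              cleanBackground = cleanBackground)
  if (cfg$nGenes %% cfg$nChromosomes != 0L)
    stop("nGenes must be divisible by nChromosomes")
  if (abs(sum(categoryFractions) - 1) > 1e-9)
    stop("category fractions must sum to 1")
  if (!setequal(names(categoryFractions), .CATEGORIES))
    stop("category fractions must cover exactly the seven categories")
  if (cfg$expressionPlan$nExpressed > cfg$nGenes)
    stop("infeasible plan: nExpressed > nGenes")
  if (cfg$orthologPlan$nConserved > cfg$expressionPlan$nExpressed)
    stop("infeasible plan: nConserved > nExpressed")
  class(cfg) <- "syntheticConfig"
  cfg
}

## candidate summit positions per category on one chromosome with G genes;
## positions are >= 600 bp apart so 500 bp peak intervals never overlap
.categorySites <- function(G, chromLength) {
  bs <- function(i) i * .SLOT + .BODY_OFF + 1L          # body start, 1-based
  be <- function(i) i * .SLOT + .BODY_OFF + .BODY_LEN   # body end
  plus <- function(i) i %% 2L == 0L
  idx <- 0:(G - 1L)
  utr5 <- ifelse(plus(idx), bs(idx) + 299L, bs(idx) + 4699L)
  utr3 <- ifelse(plus(idx), bs(idx) + 4699L, bs(idx) + 299L)
  coding <- c(bs(idx) + 899L, bs(idx) + 4099L)
  intron <- c(bs(idx) + 1799L, bs(idx) + 3399L)
  ## divergent gaps (minus gene then plus gene) are upstream-only: covered by
  ## both neighbors' TSS-facing flanks, by no gene body
  odd <- idx[idx %% 2L == 1L & idx < G - 1L]
  up <- c(400L, 1000L, outer(odd * .SLOT, seq(6800L, 10200L, by = 600L), `+`))
  ## convergent gaps (plus gene then minus gene): the zone > 10 kb from the
  ## closest minus-gene end on the left and > 10 kb before the next plus TSS
  even <- idx[idx %% 2L == 0L & idx < G - 1L]
  down <- c(outer(even * .SLOT, c(7700L, 8300L, 8900L), `+`))
  otherMin <- be(G - 1L) + 10400L
  other <- if (otherMin <= chromLength - 300L)
    seq(otherMin, chromLength - 300L, by = 600L) else integer(0)
  list(UPSTREAM_10KB = sort(as.integer(up)),
       UTR5 = sort(as.integer(utr5)),
       CODING_EXON = sort(as.integer(coding)),
       INTRON = sort(as.integer(intron)),
       UTR3 = sort(as.integer(utr3)),
       DOWNSTREAM_10KB = sort(as.integer(down)),
       OTHER = sort(as.integer(other)))
}

## largest-remainder apportionment of nPeaks over the category fractions
.apportion <- function(fracs, n) {
  raw <- fracs * n
  k <- floor(raw)
  rem <- n - sum(k)
  if (rem > 0) {
    ord <- order(raw - k, decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1
  }
  as.integer(k)
}

## gene models for one synthetic species on the fixed grid
.speciesGeneModels <- function(cfg, chroms, prefix) {
  G <- cfg$nGenes %/% cfg$nChromosomes
  slot <- rep(0:(G - 1L), times = length(chroms))
  chrom <- rep(chroms, each = G)
  b0 <- slot * .SLOT + .BODY_OFF
  st <- ifelse(slot %% 2L == 0L, "+", "-")
  gid <- sprintf("%s%03d", prefix, seq_along(slot))
  genes <- GRanges(chrom, IRanges(b0 + 1L, b0 + .BODY_LEN), strand = st)
  genes$gene_id <- gid
  genes$transcript_id <- paste0(gid, "_t1")
  genes$tss <- ifelse(st == "-", b0 + .BODY_LEN, b0 + 1L)
  genes$cds_start <- b0 + .CDS_REL[1L]
  genes$cds_end <- b0 + .CDS_REL[2L]
  genes$biotype <- "protein_coding"
  exlist <- lapply(seq_along(slot), function(k)
    GRanges(chrom[k], IRanges(b0[k] + .EXONS_REL[, "start"],
                              b0[k] + .EXONS_REL[, "end"]), strand = st[k]))
  gm <- new("GeneModels", genes = genes,
            exons = GRangesList(setNames(exlist, gid)))
  validObject(gm)
  gm
}

#' Create a synthetic genome with a plant registry
#'
#' @param seqs Named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @return A `syntheticGenome` list with elements `seqs` (character, named)
#'   and `plants` (`GRanges` registry of planted instances).
#' @export
newSyntheticGenome <- function(seqs) {
  if (is(seqs, "DNAStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  structure(list(seqs = seqs, plants = GRanges()), class = "syntheticGenome")
}

#' Plant a motif instance into a synthetic genome
#'
#' Replaces the bases at `[position, position + nchar(instance) - 1]` with
#' the instance (reverse-complemented when `strand == "-"`). Planting over a
#' previously planted instance is an error.
#'
#' @param genome A `syntheticGenome` from [newSyntheticGenome()].
#' @param chrom Chromosome name.
#' @param position 1-based start of the plant.
#' @param strand `"+"` or `"-"`.
#' @param instance ACGT string to plant.
#' @return The mutated `syntheticGenome`.
#' @export
plantMotif <- function(genome, chrom, position, strand = "+", instance) {
  stopifnot(inherits(genome, "syntheticGenome"), chrom %in% names(genome$seqs))
  width <- nchar(instance)
  if (position < 1L || position + width - 1L > nchar(genome$seqs[[chrom]]))
    stop("plant does not fit within chromosome ", chrom)
  new_r <- GRanges(chrom, IRanges(position, position + width - 1L))
  if (length(genome$plants) && any(overlapsAny(new_r, genome$plants)))
    stop("plant overlaps a previously planted instance on ", chrom)
  if (strand == "-")
    instance <- as.character(reverseComplement(DNAString(instance)))
  substr(genome$seqs[[chrom]], position, position + width - 1L) <- instance
  genome$plants <- c(genome$plants, new_r)
  genome
}

#' Realize an expression plan
#'
#' Planted-expressed genes receive cell FPKM > 1, fold change > 1.5 and a
#' small q-value; every other gene deliberately violates at least one
#' criterion (low FPKM, low fold change, or large q, cycling through the
#' three failure modes). With `noiseSd = 0` the expression filter recovers
#' the planted set exactly.
#'
#' @param plan List with `nExpressed` and `noiseSd` (see [syntheticConfig()]).
#' @param geneIds All gene ids.
#' @param expressed Planted-expressed ids; sampled from `geneIds` when `NULL`.
#' @return List with `records` (expression data.frame) and `expressed`.
#' @export
realizeExpressionPlan <- function(plan, geneIds, expressed = NULL) {
  if (is.null(expressed)) {
    if (plan$nExpressed > length(geneIds)) stop("infeasible plan: nExpressed > genes")
    expressed <- sample(geneIds, plan$nExpressed)
  }
  n <- length(geneIds)
  isExpr <- geneIds %in% expressed
  fpkm <- whole <- q <- numeric(n)
  fpkm[isExpr] <- round(runif(sum(isExpr), 2, 8), 3)
  whole[isExpr] <- round(fpkm[isExpr] / runif(sum(isExpr), 2, 4), 3)
  q[isExpr] <- round(runif(sum(isExpr), 0.0005, 0.04), 4)
  nullIdx <- which(!isExpr)
  mode <- rep_len(1:3, length(nullIdx))
  for (k in seq_along(nullIdx)) {
    i <- nullIdx[k]
    if (mode[k] == 1L) {          # fails FPKM > 1
      fpkm[i] <- round(runif(1, 0, 0.9), 3)
      whole[i] <- round(runif(1, 0.1, 1), 3)
      q[i] <- round(runif(1, 0, 1), 4)
    } else if (mode[k] == 2L) {   # fails fold change > 1.5
      whole[i] <- round(runif(1, 1.5, 3), 3)
      fpkm[i] <- round(whole[i] * runif(1, 1.01, 1.4), 3)
      q[i] <- round(runif(1, 0.0005, 0.04), 4)
    } else {                      # fails q < 0.05
      fpkm[i] <- round(runif(1, 2, 6), 3)
      whole[i] <- round(fpkm[i] / runif(1, 2, 3), 3)
      q[i] <- round(runif(1, 0.07, 0.99), 4)
    }
  }
  if (!is.null(plan$noiseSd) && plan$noiseSd > 0)
    fpkm <- pmax(0, fpkm + rnorm(n, 0, plan$noiseSd))
  list(records = data.frame(gene_id = geneIds, fpkm_cell = fpkm,
                            fpkm_whole_embryo = whole, q_value = q),
       expressed = sort(expressed))
}

## sample() without the scalar-x surprise
.safeSample <- function(x, size) x[sample.int(length(x), size)]

## random background sequence
.randSeq <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

## Generate one species: genome, gene models, peaks with planted categories /
## motifs / conservation, plus the per-species slice of the manifest.
.generateSpecies <- function(cfg, prefix) {
  G <- cfg$nGenes %/% cfg$nChromosomes
  chroms <- paste0(prefix, "_chr", seq_len(cfg$nChromosomes))
  sites <- .categorySites(G, cfg$chromLength)
  counts <- .apportion(cfg$categoryFractions[.CATEGORIES], cfg$nPeaks)
  names(counts) <- .CATEGORIES
  ## candidate pool over all chromosomes
  chosen <- list()
  for (cat in .CATEGORIES) {
    pool <- expand.grid(chrom = chroms, pos = sites[[cat]],
                        stringsAsFactors = FALSE)
    if (nrow(pool) < counts[[cat]])
      stop("infeasible plan: ", counts[[cat]], " ", cat,
           " peaks requested but only ", nrow(pool), " candidate site(s)")
    take <- pool[sample(nrow(pool), counts[[cat]]), , drop = FALSE]
    take$category <- rep(cat, nrow(take))
    chosen[[cat]] <- take
  }
  peaks <- do.call(rbind, chosen)
  peaks <- peaks[order(peaks$chrom, peaks$pos), ]
  rownames(peaks) <- NULL
  peaks$name <- sprintf("%s_peak_%04d", prefix, seq_len(nrow(peaks)))
  half <- cfg$peakWidth %/% 2L
  peaks$start <- peaks$pos - half          # 1-based
  peaks$end <- peaks$pos + half - 1L
  ## motif flags: deterministic counts so manifest frequencies are crisp
  mp <- cfg$motifPlan
  n <- nrow(peaks)
  nPal <- round(mp$palindrome * n)
  nSingle <- round(mp$singleExtra * n)
  nCcaat <- round(mp$ccaat * n)
  if (nPal + nSingle > n) stop("infeasible plan: motif fractions exceed peak count")
  palIdx <- sample(n, nPal)
  singleIdx <- sample(setdiff(seq_len(n), palIdx), nSingle)
  ccaatIdx <- sample(n, nCcaat)
  peaks$planted_palindrome <- seq_len(n) %in% palIdx
  peaks$planted_single <- seq_len(n) %in% singleIdx
  peaks$has_ccaat <- seq_len(n) %in% ccaatIdx
  peaks$has_palindrome <- peaks$planted_palindrome
  ## a palindrome contains two half-sites, so it implies a single-site hit
  peaks$has_single <- peaks$planted_palindrome | peaks$planted_single
  peaks$motif_strand <- sample(c("+", "-"), n, replace = TRUE)
  ## conservation groups and window means
  cp <- cfg$conservationPlan
  nHigh <- round(cp$highFraction * n)
  highIdx <- sample(n, nHigh)
  peaks$cons_group <- ifelse(seq_len(n) %in% highIdx, "high", "low")
  mu <- ifelse(peaks$cons_group == "high", cp$highMean, cp$lowMean)
  peaks$cons_mean <- round(pmin(1, pmax(0, rnorm(n, mu, cp$sd))), 6)
  peaks$fold_enrichment <- round(5 + rgamma(n, shape = 3, scale = 3), 4)
  ## genome with planted motifs and (optionally) clean backgrounds
  mono <- buildPWM(mp$monomerSites, name = "half_site")
  pal <- buildPalindromePWM(mono, spacer = mp$spacer)
  cons <- pwmConsensus(mono)
  consRc <- as.character(reverseComplement(DNAString(cons)))
  L <- nchar(cons)
  seqs <- setNames(vapply(chroms, function(ch) .randSeq(cfg$chromLength, cfg$gc), ""),
                   chroms)
  maxTries <- 500L
  for (i in seq_len(n)) {
    s <- peaks$start[i]; e <- peaks$end[i]; pos <- peaks$pos[i]
    relSummit <- pos - s + 1L
    w <- e - s + 1L
    plants <- list()
    if (peaks$planted_palindrome[i]) {
      plants[[length(plants) + 1L]] <- list(rel = relSummit - (L + mp$spacer %/% 2L),
                                            kind = "pal")
    } else if (peaks$planted_single[i]) {
      inst <- if (peaks$motif_strand[i] == "-") consRc else cons
      plants[[length(plants) + 1L]] <- list(rel = relSummit - L %/% 2L,
                                            kind = "fixed", seq = inst)
    }
    if (peaks$has_ccaat[i]) {
      box <- if (peaks$motif_strand[i] == "-") "ATTGG" else "CCAAT"
      off <- if (length(plants)) 40L else -2L
      plants[[length(plants) + 1L]] <- list(rel = relSummit + off,
                                            kind = "fixed", seq = box)
    }
    ok <- FALSE
    for (try in seq_len(maxTries)) {
      bg <- .randSeq(w, cfg$gc)
      for (pl in plants) {
        inst <- if (pl$kind == "pal") {
          core <- paste0(cons, .randSeq(mp$spacer, cfg$gc), consRc)
          if (peaks$motif_strand[i] == "-")
            as.character(reverseComplement(DNAString(core))) else core
        } else pl$seq
        substr(bg, pl$rel, pl$rel + nchar(inst) - 1L) <- inst
      }
      if (!cfg$cleanBackground) { ok <- TRUE; break }
      palHit <- nrow(scanSequence(pal, bg, mp$threshold)) > 0L
      singleHit <- nrow(scanSequence(mono, bg, mp$threshold)) > 0L
      ccaatHit <- iupacMatchCount(bg, "CCAAT") > 0L
      if (palHit == peaks$has_palindrome[i] &&
          singleHit == peaks$has_single[i] &&
          ccaatHit == peaks$has_ccaat[i]) { ok <- TRUE; break }
    }
    if (!ok) stop("could not realize a clean background for peak ", peaks$name[i])
    substr(seqs[[peaks$chrom[i]]], s, e) <- bg
  }
  ## conservation track: constant drawn value over each summit window
  flank <- cp$flank
  trackGr <- GRanges(peaks$chrom,
                     IRanges(pmax(1L, peaks$pos - flank), peaks$pos + flank))
  track <- .trackFromRanges(trackGr, peaks$cons_mean)
  models <- .speciesGeneModels(cfg, chroms, prefix)
  ## target status by direct span arithmetic (independent of the annotator)
  g <- models@genes
  isTarget <- vapply(seq_along(g), function(k) {
    onChrom <- peaks$chrom == as.character(seqnames(g))[k]
    if (as.character(strand(g))[k] == "-") {
      lo <- start(g)[k]; hi <- min(end(g)[k] + 10000L, cfg$chromLength)
    } else {
      lo <- max(1L, start(g)[k] - 10000L); hi <- end(g)[k]
    }
    any(onChrom & peaks$pos >= lo & peaks$pos <= hi)
  }, logical(1))
  list(prefix = prefix, chroms = chroms, peaks = peaks, seqs = seqs,
       track = track, models = models,
       genes = data.frame(gene_id = g$gene_id, target = isTarget),
       pwm = list(monomer = mono, palindrome = pal),
       counts = counts)
}

#' Generate a complete two-species synthetic dataset
#'
#' Writes, per species: genome FASTA, gene models (GTF), peak tables
#' (MACS-style TSV and BED), a fixedStep conservation track and an expression
#' table; plus a cross-species ortholog map, a GO annotation map, the
#' half-site and palindrome PWMs (MEME format), and a ground-truth manifest
#' (JSON). The same configuration always yields byte-identical files.
#'
#' @param config A [syntheticConfig()].
#' @param outDir Output directory.
#' @return List with `files` (named paths) and `manifest` (the ground truth:
#'   per-peak planted categories, motif flags and conservation; per-gene
#'   target/expressed/regulated status; conserved pairs; planted summary
#'   statistics).
#' @export
generateDataset <- function(config, outDir) {
  stopifnot(inherits(config, "syntheticConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  set.seed(config$seed)
  spA <- .generateSpecies(config, "GA")
  spB <- .generateSpecies(config, "GB")
  op <- config$orthologPlan
  if (op$nPairs > config$nGenes) stop("infeasible plan: nPairs > nGenes")
  orthoIdx <- sort(sample(config$nGenes, op$nPairs))
  orthoMap <- data.frame(gene_a = spA$genes$gene_id[orthoIdx],
                         gene_b = spB$genes$gene_id[orthoIdx],
                         homology_type = "ortholog_one2one")
  ## genes that could become conserved regulated: target in both species and
  ## linked by the map
  candidate <- orthoIdx[spA$genes$target[orthoIdx] & spB$genes$target[orthoIdx]]
  if (length(candidate) < op$nConserved)
    stop("infeasible plan: only ", length(candidate),
         " ortholog-linked genes are targets in both species; nConserved = ",
         op$nConserved)
  conservedIdx <- sort(.safeSample(candidate, op$nConserved))
  ep <- config$expressionPlan
  fillPool <- setdiff(seq_len(config$nGenes), candidate)
  nFill <- ep$nExpressed - op$nConserved
  if (nFill > length(fillPool))
    stop("infeasible plan: not enough non-candidate genes to fill the expressed set")
  exprIdxA <- sort(c(conservedIdx, .safeSample(fillPool, nFill)))
  exprIdxB <- sort(c(conservedIdx, .safeSample(fillPool, nFill)))
  exprA <- realizeExpressionPlan(ep, spA$genes$gene_id,
                                 spA$genes$gene_id[exprIdxA])
  exprB <- realizeExpressionPlan(ep, spB$genes$gene_id,
                                 spB$genes$gene_id[exprIdxB])
  spA$genes$expressed <- spA$genes$gene_id %in% exprA$expressed
  spB$genes$expressed <- spB$genes$gene_id %in% exprB$expressed
  spA$genes$regulated <- spA$genes$target & spA$genes$expressed
  spB$genes$regulated <- spB$genes$target & spB$genes$expressed
  conservedPairs <- data.frame(gene_a = spA$genes$gene_id[conservedIdx],
                               gene_b = spB$genes$gene_id[conservedIdx])
  ## GO map (species A ids): annotate a subset of conserved genes with a
  ## development term plus background annotations on other genes
  nGo <- if (length(conservedIdx)) max(1L, round(op$nConserved * 0.3)) else 0L
  goConserved <- sort(.safeSample(conservedIdx, nGo))
  goOther <- .safeSample(setdiff(seq_len(config$nGenes), goConserved),
                         round(config$nGenes * 0.1))
  goMap <- rbind(data.frame(gene_id = spA$genes$gene_id[goConserved],
                            go_term = rep("GO:0001501", nGo)),
                 data.frame(gene_id = spA$genes$gene_id[sort(goOther)],
                            go_term = rep("GO:0008150", length(goOther))))
  writeSpecies <- function(sp, expr, tag) {
    peaksGr <- GRanges(sp$peaks$chrom, IRanges(sp$peaks$start, sp$peaks$end))
    peaksGr$name <- sp$peaks$name
    peaksGr$summit <- sp$peaks$pos
    peaksGr$fold_enrichment <- sp$peaks$fold_enrichment
    files <- c(genome = file.path(outDir, paste0("genome_", tag, ".fa")),
               genes = file.path(outDir, paste0("genes_", tag, ".gtf")),
               peaks = file.path(outDir, paste0("peaks_", tag, ".tsv")),
               peaks_bed = file.path(outDir, paste0("peaks_", tag, ".bed")),
               conservation = file.path(outDir, paste0("conservation_", tag, ".wig")),
               expression = file.path(outDir, paste0("expression_", tag, ".tsv")))
    writeGenome(DNAStringSet(sp$seqs), files[["genome"]])
    writeGeneModels(sp$models, files[["genes"]])
    writePeakTable(peaksGr, files[["peaks"]], "macs_tsv")
    writePeakTable(peaksGr, files[["peaks_bed"]], "bed")
    writeConservationTrack(sp$track, files[["conservation"]])
    write.table(expr$records, files[["expression"]], sep = "\t",
                quote = FALSE, row.names = FALSE)
    files
  }
  filesA <- writeSpecies(spA, exprA, "a")
  filesB <- writeSpecies(spB, exprB, "b")
  orthoPath <- file.path(outDir, "orthologs.tsv")
  write.table(orthoMap, orthoPath, sep = "\t", quote = FALSE, row.names = FALSE)
  goPath <- file.path(outDir, "go_a.tsv")
  write.table(goMap, goPath, sep = "\t", quote = FALSE, row.names = FALSE)
  memePath <- file.path(outDir, "half_site.meme")
  writeMemeMotif(spA$pwm$monomer, memePath)
  speciesManifest <- function(sp) {
    pk <- sp$peaks[c("name", "chrom", "pos", "category", "has_palindrome",
                     "has_single", "has_ccaat", "cons_group", "cons_mean")]
    names(pk)[names(pk) == "pos"] <- "summit"
    list(peaks = pk,
         genes = sp$genes,
         category_fractions = setNames(as.numeric(sp$counts) / nrow(sp$peaks),
                                       names(sp$counts)),
         motif_frequency = c(palindrome = 100 * mean(sp$peaks$has_palindrome),
                             single = 100 * mean(sp$peaks$has_single),
                             ccaat = 100 * mean(sp$peaks$has_ccaat)),
         targets = sort(sp$genes$gene_id[sp$genes$target]),
         expressed = sort(sp$genes$gene_id[sp$genes$expressed]),
         regulated = sort(sp$genes$gene_id[sp$genes$regulated]))
  }
  manifest <- list(config = unclass(config),
                   species = list(a = speciesManifest(spA),
                                  b = speciesManifest(spB)),
                   conserved_pairs = conservedPairs,
                   n_conserved = nrow(conservedPairs),
                   go_term = "GO:0001501",
                   n_go_conserved = nGo)
  manifestPath <- file.path(outDir, "manifest.json")
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  files <- list(a = filesA, b = filesB, orthologs = orthoPath, go = goPath,
                motif = memePath, manifest = manifestPath)
  list(files = files, manifest = manifest)
}
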