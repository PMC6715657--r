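## Seven-category genomic classification of peak summits, category fraction
## summaries, peak-set overlap counts and fold-enrichment histogram moments.

#' Build a genomic annotation index
#'
#' Derives labeled genomic ranges from gene models: a strand-aware upstream
#' flank off the TSS, 5'UTR, coding exons, introns, 3'UTR and a strand-aware
#' downstream flank off the transcript end. Flanks are clipped at chromosome
#' bounds. Exons of CDS-less genes count as the exon category by default
#' (with a warning); set `includeNoncoding = FALSE` to drop non-coding genes
#' entirely.
#'
#' @param models A [GeneModels-class].
#' @param upstreamBp,downstreamBp Flank sizes in bases (default 10 kb).
#' @param chromSizes Named vector of chromosome lengths covering all gene
#'   chromosomes.
#' @param includeNoncoding Keep CDS-less genes (their exons labeled as the
#'   exon category)?
#' @return An [AnnotationIndex-class].
#' @export
buildAnnotationIndex <- function(models, upstreamBp = 10000, downstreamBp = 10000,
                                 chromSizes, includeNoncoding = TRUE) {
  stopifnot(is(models, "GeneModels"), upstreamBp >= 0, downstreamBp >= 0)
  g <- models@genes
  unknown <- setdiff(unique(as.character(seqnames(g))), names(chromSizes))
  if (length(unknown))
    stop("gene on unknown chromosome: ", paste(unknown, collapse = ", "))
  noncoding <- is.na(g$cds_start)
  if (any(noncoding)) {
    if (!includeNoncoding) {
      keep <- which(!noncoding)
      g <- g[keep]
      models <- new("GeneModels", genes = g, exons = models@exons[keep])
      noncoding <- rep(FALSE, length(g))
    } else {
      warning(sum(noncoding), " non-coding gene(s): exons counted as the exon category")
    }
  }
  pieces <- list()
  add <- function(chrom, s, e, category, gene_id, tss, strand) {
    s <- pmax(s, 1); e <- pmin(e, chromSizes[[chrom]])
    keep <- s <= e
    if (!any(keep)) return()
    pieces[[length(pieces) + 1L]] <<- data.frame(
      chrom = chrom, start = s[keep], end = e[keep], category = category,
      gene_id = gene_id, tss = tss, stringsAsFactors = FALSE)
  }
  for (i in seq_along(g)) {
    chrom <- as.character(seqnames(g))[i]
    st <- as.character(strand(g))[i]
    gs <- start(g)[i]; ge <- end(g)[i]
    gid <- g$gene_id[i]; tss <- g$tss[i]
    ex <- models@exons[[i]]
    exr <- IRanges::ranges(ex)
    if (st == "-") {
      add(chrom, ge + 1, ge + upstreamBp, "UPSTREAM_10KB", gid, tss, st)
      add(chrom, gs - downstreamBp, gs - 1, "DOWNSTREAM_10KB", gid, tss, st)
    } else {
      add(chrom, gs - upstreamBp, gs - 1, "UPSTREAM_10KB", gid, tss, st)
      add(chrom, ge + 1, ge + downstreamBp, "DOWNSTREAM_10KB", gid, tss, st)
    }
    ## introns: gaps between exons inside the gene span
    if (length(exr) > 1L) {
      gap_s <- end(exr)[-length(exr)] + 1L
      gap_e <- start(exr)[-1L] - 1L
      add(chrom, gap_s, gap_e, "INTRON", gid, tss, st)
    }
    if (noncoding[i] || is.na(g$cds_start[i])) {
      add(chrom, start(exr), end(exr), "CODING_EXON", gid, tss, st)
    } else {
      cs <- g$cds_start[i]; ce <- g$cds_end[i]
      coding <- IRanges::restrict(exr, cs, ce)
      coding <- coding[width(coding) > 0L]
      add(chrom, start(coding), end(coding), "CODING_EXON", gid, tss, st)
      left <- IRanges::restrict(exr, gs, cs - 1L)
      left <- left[width(left) > 0L]
      right <- IRanges::restrict(exr, ce + 1L, ge)
      right <- right[width(right) > 0L]
      if (st == "-") {
        add(chrom, start(right), end(right), "UTR5", gid, tss, st)
        add(chrom, start(left), end(left), "UTR3", gid, tss, st)
      } else {
        add(chrom, start(left), end(left), "UTR5", gid, tss, st)
        add(chrom, start(right), end(right), "UTR3", gid, tss, st)
      }
    }
  }
  df <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               category = character(), gene_id = character(), tss = integer())
  gr <- GRanges(df$chrom, IRanges(df$start, df$end))
  gr$category <- df$category
  gr$gene_id <- df$gene_id
  gr$tss <- df$tss
  new("AnnotationIndex", ranges = gr,
      params = list(upstreamBp = upstreamBp, downstreamBp = downstreamBp,
                    includeNoncoding = includeNoncoding))
}

#' Classify peaks into the seven genomic categories
#'
#' Each peak is classified by its summit position into exactly one category.
#' When the summit lies in ranges of several categories or genes, precedence
#' is UTR5 > UTR3 > CODING_EXON > INTRON > UPSTREAM_10KB > DOWNSTREAM_10KB,
#' then nearest TSS, then smallest gene id. A summit in no labeled range is
#' OTHER with no gene.
#'
#' @param peaks `GRanges` with a `summit` metadata column (see
#'   [readPeakTable()]).
#' @param index An [AnnotationIndex-class].
#' @return The peaks with added metadata columns `category` (factor over the
#'   seven categories) and `gene_id` (`NA` for OTHER).
#' @export
classifyPeaks <- function(peaks, index) {
  stopifnot(is(index, "AnnotationIndex"))
  category <- rep("OTHER", length(peaks))
  gene_id <- rep(NA_character_, length(peaks))
  if (length(peaks)) {
    summits <- GRanges(seqnames(peaks), IRanges(peaks$summit, peaks$summit))
    hits <- findOverlaps(summits, index@ranges, ignore.strand = TRUE)
    if (length(hits)) {
      q <- queryHits(hits); s <- subjectHits(hits)
      prec <- .CATEGORY_PRECEDENCE[index@ranges$category[s]]
      tssdist <- abs(peaks$summit[q] - index@ranges$tss[s])
      gid <- index@ranges$gene_id[s]
      ord <- order(q, prec, tssdist, gid)
      first <- !duplicated(q[ord])
      qf <- q[ord][first]; sf <- s[ord][first]
      category[qf] <- index@ranges$category[sf]
      gene_id[qf] <- index@ranges$gene_id[sf]
    }
  }
  peaks$category <- factor(category, levels = .CATEGORIES)
  peaks$gene_id <- gene_id
  peaks
}

#' Category counts and fractions of a peak set
#'
#' @param peaks `GRanges` with `summit` column.
#' @param index An [AnnotationIndex-class].
#' @return A `data.frame` with one row per category (all seven, in display
#'   order): `category`, `count`, `fraction`. Fractions sum to 1.
#' @export
categoryFractions <- function(peaks, index) {
  if (!length(peaks)) stop("category fractions need at least one peak")
  cls <- classifyPeaks(peaks, index)
  counts <- table(cls$category)
  data.frame(category = .CATEGORIES,
             count = as.integer(counts[.CATEGORIES]),
             fraction = as.numeric(counts[.CATEGORIES]) / length(peaks))
}

#' Count overlaps between two peak sets
#'
#' @param peaksA,peaksB `GRanges` peak sets on the same assembly.
#' @param minOverlap Minimum overlap in bases (default 1; intervals are
#'   half-open in BED terms, so abutting peaks do not overlap).
#' @return A list with `n_a_overlapping` (A peaks overlapping any B peak),
#'   `n_b_overlapping`, and `n_pairs` (distinct overlapping pairs).
#' @export
countPeakOverlaps <- function(peaksA, peaksB, minOverlap = 1L) {
  hits <- findOverlaps(peaksA, peaksB, minoverlap = minOverlap,
                       ignore.strand = TRUE)
  list(n_a_overlapping = length(unique(queryHits(hits))),
       n_b_overlapping = length(unique(subjectHits(hits))),
       n_pairs = length(hits))
}

#' Fold-enrichment histogram and shape moments
#'
#' Bins peak fold-enrichment values into fixed-width bins `[k*w, (k+1)*w)`
#' and reports moment-based sample skewness `g1 = m3 / m2^1.5` and Pearson
#' kurtosis `g2 = m4 / m2^2` (a normal distribution gives 3).
#'
#' @param peaks `GRanges` with a `fold_enrichment` column.
#' @param binWidth Histogram bin width.
#' @return List with `histogram` (data.frame `bin_start`, `bin_end`,
#'   `count`), `skewness` and `kurtosis`.
#' @export
enrichmentHistogramStats <- function(peaks, binWidth = 5) {
  v <- peaks$fold_enrichment
  v <- v[!is.na(v)]
  if (length(v) < 3L) stop("need at least 3 peaks with fold_enrichment")
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 == 0) stop("fold_enrichment has zero variance")
  g1 <- mean((v - m)^3) / m2^1.5
  g2 <- mean((v - m)^4) / m2^2
  bin <- floor(v / binWidth)
  counts <- table(bin)
  bins <- as.integer(names(counts))
  hist <- data.frame(bin_start = bins * binWidth,
                     bin_end = (bins + 1) * binWidth,
                     count = as.integer(counts))
  list(histogram = hist[order(hist$bin_start), ], skewness = g1, kurtosis = g2)
}
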