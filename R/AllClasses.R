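#' @import methods
#' @importFrom S4Vectors mcols mcols<- Rle runValue queryHits subjectHits DataFrame metadata metadata<-
#' @importFrom IRanges IRanges RleList Views viewMeans findOverlaps overlapsAny width start end
#' @importFrom GenomicRanges GRanges GRangesList seqnames strand strand<- granges
#' @importFrom GenomeInfoDb seqlevels seqlengths
#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement vcountPattern subseq
#' @importFrom stats runif rnorm rgamma pnorm setNames
#' @importFrom utils read.delim write.table combn head tail
NULL

## Display order of the seven genomic categories (pie-chart order).
.CATEGORIES <- c("UPSTREAM_10KB", "UTR5", "CODING_EXON", "INTRON",
                 "UTR3", "DOWNSTREAM_10KB", "OTHER")

## Classification precedence (lower rank wins): UTRs outrank the exons that
## contain them, gene-internal categories outrank flanks.
.CATEGORY_PRECEDENCE <- c(UTR5 = 1L, UTR3 = 2L, CODING_EXON = 3L, INTRON = 4L,
                          UPSTREAM_10KB = 5L, DOWNSTREAM_10KB = 6L)

#' Region categories
#'
#' The seven genomic categories a binding region can be assigned to:
#' up to 10 kb upstream of the TSS, 5'UTR, coding exon, intron, 3'UTR,
#' up to 10 kb downstream of the transcript end, and everything else.
#'
#' @return Character vector of the seven category names, in display order.
#' @export
regionCategories <- function() .CATEGORIES

#' Gene models for one genome
#'
#' One transcript model per gene: the stranded genomic span, the TSS, the
#' ordered disjoint exons, and (for coding genes) the CDS bounds. Built by
#' [readGeneModels()] from GTF/GFF3/BED12 using the longest-transcript rule.
#'
#' @slot genes A [GenomicRanges::GRanges] with one range per gene and
#'   metadata columns `gene_id`, `transcript_id`, `tss` (1-based position of
#'   the transcription start site), `cds_start`, `cds_end` (1-based closed
#'   bounds, `NA` for non-coding genes) and `biotype`.
#' @slot exons A [GenomicRanges::GRangesList] parallel to `genes`, named by
#'   `gene_id`, holding the sorted, disjoint exons of the selected transcript.
#' @export
setClass("GeneModels",
         representation(genes = "GRanges", exons = "GRangesList"))

setValidity("GeneModels", function(object) {
  g <- object@genes
  need <- c("gene_id", "transcript_id", "tss", "cds_start", "cds_end", "biotype")
  if (!all(need %in% colnames(mcols(g))))
    return(paste("genes must carry metadata columns:", paste(need, collapse = ", ")))
  if (length(object@exons) != length(g))
    return("exons must be parallel to genes")
  if (anyDuplicated(g$gene_id))
    return("duplicate gene_id")
  for (i in seq_along(g)) {
    ex <- object@exons[[i]]
    if (length(ex) == 0L) return(paste0("gene ", g$gene_id[i], ": no exons"))
    if (is.unsorted(start(ex)))
      return(paste0("gene ", g$gene_id[i], ": exons not sorted"))
    if (length(ex) > 1L && any(start(ex)[-1L] <= end(ex)[-length(ex)]))
      return(paste0("gene ", g$gene_id[i], ": exons overlap"))
    if (min(start(ex)) < start(g)[i] || max(end(ex)) > end(g)[i])
      return(paste0("gene ", g$gene_id[i], ": exon outside transcript bounds"))
    tss_ok <- if (as.character(strand(g)[i]) == "-") end(g)[i] else start(g)[i]
    if (g$tss[i] != tss_ok)
      return(paste0("gene ", g$gene_id[i], ": tss does not match strand convention"))
    if (!is.na(g$cds_start[i])) {
      if (g$cds_start[i] > g$cds_end[i])
        return(paste0("gene ", g$gene_id[i], ": cds_start > cds_end"))
      if (g$cds_start[i] < start(g)[i] || g$cds_end[i] > end(g)[i])
        return(paste0("gene ", g$gene_id[i], ": CDS outside transcript bounds"))
    }
  }
  TRUE
})

setMethod("show", "GeneModels", function(object) {
  n <- length(object@genes)
  nc <- sum(!is.na(object@genes$cds_start))
  cat("GeneModels with", n, "genes (", nc, "coding ) on",
      length(unique(as.character(seqnames(object@genes)))), "chromosome(s)\n")
  if (n) {
    cat("  gene_ids:", paste(head(object@genes$gene_id, 4L), collapse = ", "),
        if (n > 4L) "..." else "", "\n")
  }
})

#' @describeIn GeneModels-class Number of genes.
#' @param x A `GeneModels` object.
#' @export
setMethod("length", "GeneModels", function(x) length(x@genes))

#' Accessors for GeneModels
#'
#' @param x A [GeneModels-class] object.
#' @return `geneIds()` the character vector of gene identifiers;
#'   `geneRanges()` the per-gene `GRanges` (with tss/CDS metadata);
#'   `modelExons()` the per-gene `GRangesList` of exons.
#' @name GeneModels-accessors
NULL

#' @rdname GeneModels-accessors
#' @export
geneIds <- function(x) {
  stopifnot(is(x, "GeneModels"))
  x@genes$gene_id
}

#' @rdname GeneModels-accessors
#' @export
geneRanges <- function(x) {
  stopifnot(is(x, "GeneModels"))
  x@genes
}

#' @rdname GeneModels-accessors
#' @export
modelExons <- function(x) {
  stopifnot(is(x, "GeneModels"))
  x@exons
}

#' Sparse per-base conservation scores
#'
#' Holds per-chromosome conservation scores in `[0, 1]` (phastCons-style) as
#' run-length encoded vectors with `NA` at unscored positions. Built by
#' [readConservationTrack()].
#'
#' @slot scores A [IRanges::RleList] of numeric Rle vectors, one per
#'   chromosome, 1-based; `NA` marks positions with no stored score.
#' @export
setClass("ConservationTrack", representation(scores = "RleList"))

setValidity("ConservationTrack", function(object) {
  for (nm in names(object@scores)) {
    v <- runValue(object@scores[[nm]])
    v <- v[!is.na(v)]
    if (length(v) && (min(v) < 0 || max(v) > 1))
      return(paste0("chromosome ", nm, ": score outside [0,1]"))
  }
  TRUE
})

setMethod("show", "ConservationTrack", function(object) {
  ns <- vapply(object@scores, function(r) sum(!is.na(r)), numeric(1))
  cat("ConservationTrack:", length(object@scores), "chromosome(s),",
      format(sum(ns), big.mark = ","), "scored base(s)\n")
})

#' Query stored conservation scores
#'
#' @param track A [ConservationTrack-class].
#' @param chrom Chromosome name.
#' @param pos 1-based positions.
#' @return Numeric scores; `NA` for unscored positions or unknown
#'   chromosomes (missing is distinct from 0 at this layer).
#' @export
trackScore <- function(track, chrom, pos) {
  stopifnot(is(track, "ConservationTrack"))
  if (!chrom %in% names(track@scores)) return(rep(NA_real_, length(pos)))
  r <- track@scores[[chrom]]
  out <- rep(NA_real_, length(pos))
  ok <- pos >= 1L & pos <= length(r)
  if (any(ok)) out[ok] <- as.numeric(r[pos[ok]])
  out
}

#' @describeIn ConservationTrack-class Chromosomes with stored scores.
#' @param object A `ConservationTrack`.
#' @export
setGeneric("trackChroms", function(object) standardGeneric("trackChroms"))

#' @rdname ConservationTrack-class
#' @export
setMethod("trackChroms", "ConservationTrack", function(object) names(object@scores))

#' Position-weight matrix with relative-score semantics
#'
#' A per-position nonnegative weight for each base, as produced from a set
#' of aligned binding sites by [buildPWM()] (weights are base counts, the
#' frequency-matrix convention of EMBOSS prophecy). A window's relative
#' score is `100 * raw / maxScore`, see [relativeScore()].
#'
#' @slot weights A 4 x L numeric matrix, rows named A, C, G, T.
#' @slot name Motif name (used in MEME-format files).
#' @export
setClass("MotifMatrix", representation(weights = "matrix", name = "character"))

setValidity("MotifMatrix", function(object) {
  w <- object@weights
  if (!is.numeric(w) || nrow(w) != 4L || is.null(rownames(w)) ||
      !identical(rownames(w), c("A", "C", "G", "T")))
    return("weights must be a numeric 4 x L matrix with rows A, C, G, T")
  if (ncol(w) < 1L) return("motif length must be >= 1")
  if (any(w < 0)) return("weights must be nonnegative")
  if (sum(apply(w, 2L, max)) <= sum(apply(w, 2L, min)))
    return("max_score must exceed min_score")
  TRUE
})

#' Palindromic dimer motif
#'
#' A composite PWM of two inverted copies of a monomer half-site separated
#' by a score-neutral spacer; see [buildPalindromePWM()].
#'
#' @slot monomer The half-site [MotifMatrix-class].
#' @slot spacer Spacer width in bases.
#' @export
setClass("PalindromeMotif", contains = "MotifMatrix",
         representation(monomer = "MotifMatrix", spacer = "integer"))

setMethod("show", "MotifMatrix", function(object) {
  cat(class(object), if (nzchar(object@name)) sQuote(object@name) else "",
      "length", ncol(object@weights),
      "max_score", pwmMaxScore(object), "\n")
  cat("  consensus:", pwmConsensus(object), "\n")
})

#' PWM accessors
#'
#' @param x A [MotifMatrix-class].
#' @return `pwmWeights()` the 4 x L weight matrix; `pwmMaxScore()` /
#'   `pwmMinScore()` the sum of per-position maxima / minima;
#'   `pwmLength()` the motif length; `pwmConsensus()` the string of
#'   per-position maximal bases (ties broken alphabetically).
#' @name MotifMatrix-accessors
NULL

#' @rdname MotifMatrix-accessors
#' @export
pwmWeights <- function(x) {
  stopifnot(is(x, "MotifMatrix"))
  x@weights
}

#' @rdname MotifMatrix-accessors
#' @export
pwmMaxScore <- function(x) sum(apply(pwmWeights(x), 2L, max))

#' @rdname MotifMatrix-accessors
#' @export
pwmMinScore <- function(x) sum(apply(pwmWeights(x), 2L, min))

#' @rdname MotifMatrix-accessors
#' @export
pwmLength <- function(x) ncol(pwmWeights(x))

#' @rdname MotifMatrix-accessors
#' @export
pwmConsensus <- function(x) {
  w <- pwmWeights(x)
  paste(rownames(w)[apply(w, 2L, which.max)], collapse = "")
}

#' Genomic annotation index
#'
#' Labeled genomic ranges (category, gene) derived from gene models plus
#' strand-aware upstream/downstream flanks, used to classify peak summits.
#' Built by [buildAnnotationIndex()].
#'
#' @slot ranges A `GRanges` with metadata columns `category`, `gene_id` and
#'   `tss` (the owning gene's TSS, for nearest-TSS tie breaking).
#' @slot params List of the flank sizes and options used.
#' @export
setClass("AnnotationIndex", representation(ranges = "GRanges", params = "list"))

setMethod("show", "AnnotationIndex", function(object) {
  cat("AnnotationIndex:", length(object@ranges), "labeled range(s);",
      "upstream", object@params$upstreamBp, "bp, downstream",
      object@params$downstreamBp, "bp\n")
  print(table(object@ranges$category))
})
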