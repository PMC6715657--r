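## Peak-to-gene target assignment over the cis-regulatory span, the
## FPKM / fold-change / q-value expression filter, and their intersection
## into regulated gene sets.

#' Cis-regulatory span of genes
#'
#' The span from 10 kb upstream of the TSS (strand-aware) through the end of
#' the transcript (i.e. through the 3'UTR), clipped at chromosome bounds.
#'
#' @param models A [GeneModels-class].
#' @param upstreamBp Upstream extension in bases (default 10 kb).
#' @param chromSizes Optional named chromosome lengths for clipping.
#' @return `GRanges` with a `gene_id` column, one span per gene.
#' @export
cisRegulatorySpan <- function(models, upstreamBp = 10000, chromSizes = NULL) {
  stopifnot(is(models, "GeneModels"))
  g <- models@genes
  minus <- as.character(strand(g)) == "-"
  s <- ifelse(minus, start(g), pmax(1, start(g) - upstreamBp))
  e <- ifelse(minus, end(g) + upstreamBp, end(g))
  if (!is.null(chromSizes)) {
    lim <- chromSizes[as.character(seqnames(g))]
    e <- pmin(e, ifelse(is.na(lim), e, lim))
  }
  span <- GRanges(seqnames(g), IRanges(s, e), strand = strand(g))
  span$gene_id <- g$gene_id
  span
}

#' Assign peaks to putative target genes
#'
#' A gene is a putative target if at least one peak summit lies within its
#' cis-regulatory span (10 kb upstream of the TSS through the transcript
#' end). A peak may support several overlapping genes. With
#' `mode = "overlap"` any base of peak overlap with the span qualifies
#' instead of the summit. Restricted to protein-coding genes by default when
#' biotypes are available.
#'
#' @param peaks `GRanges` with `name` and `summit` columns.
#' @param models A [GeneModels-class].
#' @param upstreamBp Upstream extension of the span.
#' @param mode `"summit"` (default) or `"overlap"`.
#' @param codingOnly Restrict to `biotype == "protein_coding"`?
#' @param chromSizes Optional chromosome lengths for span clipping.
#' @return `data.frame` with columns `gene_id`, `n_supporting_peaks`,
#'   `peak_names` (comma-separated), one row per putative target gene.
#' @export
assignPutativeTargets <- function(peaks, models, upstreamBp = 10000,
                                  mode = c("summit", "overlap"),
                                  codingOnly = TRUE, chromSizes = NULL) {
  mode <- match.arg(mode)
  span <- cisRegulatorySpan(models, upstreamBp, chromSizes)
  if (codingOnly) {
    coding <- models@genes$biotype == "protein_coding"
    if (any(coding)) span <- span[coding]
  }
  query <- if (mode == "summit")
    GRanges(seqnames(peaks), IRanges(peaks$summit, peaks$summit))
  else granges(peaks)
  hits <- findOverlaps(query, span, ignore.strand = TRUE)
  if (!length(hits))
    return(data.frame(gene_id = character(), n_supporting_peaks = integer(),
                      peak_names = character()))
  df <- data.frame(gene_id = span$gene_id[subjectHits(hits)],
                   peak = peaks$name[queryHits(hits)])
  df <- df[!duplicated(df), ]
  df <- df[order(df$gene_id, df$peak), ]
  agg <- split(df$peak, df$gene_id)
  data.frame(gene_id = names(agg),
             n_supporting_peaks = lengths(agg),
             peak_names = vapply(agg, paste, "", collapse = ","),
             row.names = NULL)
}

#' Call highly expressed genes
#'
#' A gene passes when all three criteria hold strictly: cell FPKM greater
#' than `fpkmMin`, fold change (cell / whole embryo) greater than `fcMin`,
#' and q-value smaller than `qMax`. A zero whole-embryo denominator with
#' positive cell FPKM counts as infinite fold change (pass).
#'
#' @param records Expression `data.frame` from [readExpressionTable()].
#' @param fpkmMin,fcMin,qMax Thresholds (defaults 1.0, 1.5, 0.05).
#' @return Character vector of passing gene ids.
#' @export
callHighlyExpressed <- function(records, fpkmMin = 1.0, fcMin = 1.5, qMax = 0.05) {
  fc <- ifelse(records$fpkm_whole_embryo == 0,
               ifelse(records$fpkm_cell > 0, Inf, 0),
               records$fpkm_cell / records$fpkm_whole_embryo)
  pass <- records$fpkm_cell > fpkmMin & fc > fcMin & records$q_value < qMax
  records$gene_id[pass]
}

#' Intersect targets with expressed genes into a regulated set
#'
#' @param targets Character vector of putative target gene ids (or the
#'   data.frame from [assignPutativeTargets()]).
#' @param expressed Character vector of highly expressed gene ids.
#' @param species Species label carried in the result.
#' @return List of class `regulatedGeneSet` with `species`, `genes` (sorted),
#'   `n_targets`, `n_expressed`, `n_regulated`.
#' @export
callRegulated <- function(targets, expressed, species = "") {
  if (is.data.frame(targets)) targets <- targets$gene_id
  targets <- unique(targets); expressed <- unique(expressed)
  genes <- sort(intersect(targets, expressed))
  structure(list(species = species, genes = genes,
                 n_targets = length(targets),
                 n_expressed = length(expressed),
                 n_regulated = length(genes)),
            class = "regulatedGeneSet")
}

#' @export
print.regulatedGeneSet <- function(x, ...) {
  cat("Regulated gene set", if (nzchar(x$species)) paste0("(", x$species, ")"),
      ":", x$n_regulated, "genes =", x$n_targets, "targets  /\\ ",
      x$n_expressed, "expressed\n")
  invisible(x)
}
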