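## Readers and writers for the standard formats the pipeline touches.
## Internal containers are GRanges (1-based, closed); 0-based sources (BED,
## bedGraph) and 1-based sources (GTF/GFF3, wiggle) are converted here at the
## boundary and converted back on write.

#' Read a peak table
#'
#' Reads ChIP-seq peaks from BED (0-based half-open) or from a MACS-style
#' summit-offset TSV. For BED input without a summit the summit defaults to
#' the interval midpoint. For the `macs_tsv` dialect the summit column is an
#' offset from the start column; set `oneBased = TRUE` for genuine MACS
#' `.xls` tables whose start column is 1-based.
#'
#' @param path File path.
#' @param dialect `"bed"` or `"macs_tsv"`.
#' @param oneBased For `macs_tsv`: whether the start column is 1-based.
#' @return A `GRanges` with metadata columns `name`, `summit` (1-based
#'   absolute position of the summit base) and `fold_enrichment` (`NA` when
#'   absent).
#' @export
readPeakTable <- function(path, dialect = c("bed", "macs_tsv"), oneBased = FALSE) {
  dialect <- match.arg(dialect)
  stopifnot(file.exists(path))
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (dialect == "bed") {
    if (!length(lines)) return(.emptyPeaks())
    fields <- strsplit(lines, "\t", fixed = TRUE)
    ncols <- lengths(fields)
    if (any(ncols < 3L))
      stop("BED line ", lineno[which(ncols < 3L)[1L]], ": fewer than 3 columns")
    chrom <- vapply(fields, `[`, "", 1L)
    start0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
    end0 <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
    bad <- is.na(start0) | is.na(end0) | start0 >= end0 | start0 < 0
    if (any(bad))
      stop("BED line ", lineno[which(bad)[1L]], ": malformed coordinates")
    name <- ifelse(ncols >= 4L, vapply(fields, function(f) f[4L][1L], ""),
                   paste0("peak_", seq_along(fields)))
    fe <- rep(NA_real_, length(fields))
    has5 <- ncols >= 5L
    fe[has5] <- suppressWarnings(as.numeric(vapply(fields[has5], `[`, "", 5L)))
    summit1 <- floor((start0 + end0) / 2) + 1
    gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  } else {
    if (!length(lines)) return(.emptyPeaks())
    header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
    need <- c("chr", "start", "end", "summit")
    miss <- setdiff(need, header)
    if (length(miss))
      stop("macs_tsv: missing required column(s): ", paste(miss, collapse = ", "))
    if (length(lines) < 2L) return(.emptyPeaks())
    tab <- read.delim(text = paste(lines, collapse = "\n"),
                      stringsAsFactors = FALSE, check.names = FALSE)
    start0 <- as.numeric(tab$start) - if (oneBased) 1 else 0
    end0 <- as.numeric(tab$end)
    bad <- is.na(start0) | is.na(end0) | start0 >= end0 | start0 < 0
    if (any(bad))
      stop("macs_tsv line ", lineno[1L + which(bad)[1L]], ": malformed coordinates")
    chrom <- as.character(tab$chr)
    name <- if ("name" %in% header) as.character(tab$name)
            else paste0("peak_", seq_len(nrow(tab)))
    fe <- if ("fold_enrichment" %in% header) as.numeric(tab$fold_enrichment)
          else rep(NA_real_, nrow(tab))
    offs <- as.numeric(tab$summit)
    if (any(!is.na(offs) & (offs < 0 | start0 + offs >= end0)))
      stop("macs_tsv: summit offset outside peak interval")
    summit1 <- start0 + offs + 1
    gr <- GRanges(chrom, IRanges(start0 + 1, end0))
  }
  if (any(!is.na(fe) & fe < 0)) stop("fold_enrichment must be >= 0")
  mcols(gr) <- DataFrame(name = name, summit = as.integer(summit1),
                         fold_enrichment = fe)
  gr
}

.emptyPeaks <- function() {
  gr <- GRanges()
  mcols(gr) <- DataFrame(name = character(), summit = integer(),
                         fold_enrichment = numeric())
  gr
}

#' Write a peak table
#'
#' Inverse of [readPeakTable()]; `macs_tsv` preserves summits exactly, BED
#' output drops them (they are recovered as midpoints on read).
#'
#' @param peaks `GRanges` with `name`, `summit`, `fold_enrichment` columns.
#' @param path Output path.
#' @param dialect `"bed"` or `"macs_tsv"`.
#' @export
writePeakTable <- function(peaks, path, dialect = c("bed", "macs_tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "bed") {
    df <- data.frame(chrom = as.character(seqnames(peaks)),
                     start = start(peaks) - 1L, end = end(peaks),
                     name = peaks$name,
                     fold_enrichment = ifelse(is.na(peaks$fold_enrichment), ".",
                                              as.character(peaks$fold_enrichment)))
    write.table(df, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else {
    df <- data.frame(chr = as.character(seqnames(peaks)),
                     start = start(peaks) - 1L, end = end(peaks),
                     length = width(peaks),
                     summit = peaks$summit - start(peaks),
                     name = peaks$name,
                     fold_enrichment = peaks$fold_enrichment)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read gene models
#'
#' Builds one transcript model per gene from GTF, GFF3 or BED12 input. When a
#' gene has several transcripts the one with the longest genomic span is kept
#' (ties broken by lexicographically smallest transcript id). Exons are
#' merged and sorted; genes without CDS are flagged non-coding.
#'
#' @param path File path.
#' @param format `"gtf"`, `"gff3"` or `"bed12"`. Defaults to the file
#'   extension.
#' @return A [GeneModels-class] object.
#' @export
readGeneModels <- function(path, format = c("auto", "gtf", "gff3", "bed12")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gtf = "gtf", gff3 = "gff3", gff = "gff3", bed = "bed12",
                     stop("cannot infer gene-model format from extension: ", ext))
  }
  if (format == "bed12") return(.readBed12Models(path))
  gr <- rtracklayer::import(path, format = if (format == "gtf") "gtf" else "gff3")
  if (format == "gtf") {
    if (!all(c("gene_id", "transcript_id") %in% colnames(mcols(gr))))
      stop("GTF lacks gene_id/transcript_id attributes")
    ex <- gr[gr$type == "exon"]
    cds <- gr[gr$type == "CDS"]
    txg <- gr[gr$type %in% c("transcript", "mRNA")]
    tx2gene <- setNames(as.character(ex$gene_id), as.character(ex$transcript_id))
    biot <- if ("gene_biotype" %in% colnames(mcols(gr)))
      setNames(as.character(gr$gene_biotype), as.character(gr$gene_id)) else NULL
  } else {
    typ <- as.character(gr$type)
    txmask <- typ %in% c("mRNA", "transcript")
    txid <- as.character(gr$ID)
    parent <- vapply(as.list(gr$Parent),
                     function(p) if (length(p)) p[[1L]] else NA_character_, "")
    tx2gene <- setNames(parent[txmask], txid[txmask])
    ex <- gr[typ == "exon"]
    ex$transcript_id <- vapply(as.list(ex$Parent), `[[`, "", 1L)
    ex$gene_id <- tx2gene[ex$transcript_id]
    cds <- gr[typ == "CDS"]
    if (length(cds)) {
      cds$transcript_id <- vapply(as.list(cds$Parent), `[[`, "", 1L)
      cds$gene_id <- tx2gene[cds$transcript_id]
    } else cds$transcript_id <- character(0)
    txg <- gr[txmask]
    txg$transcript_id <- txid[txmask]
    biot <- NULL
  }
  if (!length(ex)) stop("no exon features found")
  .assembleModels(ex, cds, txg, biot)
}

## Pick one transcript per gene, validate exon containment, merge exons.
.assembleModels <- function(ex, cds, txg, biotypes) {
  txid <- as.character(ex$transcript_id)
  gid <- as.character(ex$gene_id)
  ord <- order(gid, txid, as.character(seqnames(ex)), start(ex))
  ex <- ex[ord]; txid <- txid[ord]; gid <- gid[ord]
  spl <- split(seq_along(ex), txid)
  tx_gene <- vapply(spl, function(i) gid[i[1L]], "")
  tx_span <- vapply(spl, function(i) max(end(ex)[i]) - min(start(ex)[i]) + 1L, 0L)
  ## longest genomic span per gene; ties -> smallest transcript id
  sel <- tapply(seq_along(spl), tx_gene, function(k) {
    k <- k[order(-tx_span[k], names(spl)[k])]
    k[1L]
  })
  sel_tx <- names(spl)[unlist(sel)]
  ## validate exons against declared transcript bounds when present
  if (length(txg)) {
    tb <- setNames(seq_along(txg), as.character(txg$transcript_id))
    for (t in intersect(names(tb), names(spl))) {
      i <- spl[[t]]
      j <- tb[[t]]
      if (min(start(ex)[i]) < start(txg)[j] || max(end(ex)[i]) > end(txg)[j])
        stop("gene ", gid[i[1L]], ": exon outside transcript bounds")
    }
  }
  genes <- vector("list", length(sel_tx))
  exlist <- vector("list", length(sel_tx))
  cds_tx <- if (length(cds)) as.character(cds$transcript_id) else character(0)
  for (k in seq_along(sel_tx)) {
    t <- sel_tx[k]
    i <- spl[[t]]
    e <- GenomicRanges::reduce(granges(ex[i]))
    strand(e) <- strand(ex[i])[1L]
    gene_id <- gid[i[1L]]
    cs <- ce <- NA_integer_
    if (length(cds_tx)) {
      ci <- which(cds_tx == t)
      if (length(ci)) {
        cs <- min(start(cds)[ci]); ce <- max(end(cds)[ci])
      }
    }
    bt <- if (!is.null(biotypes) && gene_id %in% names(biotypes))
      biotypes[[gene_id]] else if (!is.na(cs)) "protein_coding" else "noncoding"
    st <- as.character(strand(e))[1L]
    g <- GRanges(seqnames(e)[1L], IRanges(min(start(e)), max(end(e))), strand = st)
    g$gene_id <- gene_id
    g$transcript_id <- t
    g$tss <- if (st == "-") end(g) else start(g)
    g$cds_start <- cs; g$cds_end <- ce
    g$biotype <- bt
    genes[[k]] <- g
    exlist[[k]] <- e
  }
  genes <- do.call(c, genes)
  ord <- order(as.character(seqnames(genes)), start(genes), genes$gene_id)
  gm <- new("GeneModels", genes = genes[ord],
            exons = GRangesList(setNames(exlist[ord], genes$gene_id[ord])))
  validObject(gm)
  gm
}

.readBed12Models <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 12L)) stop("BED12 requires 12 columns")
  genes <- vector("list", length(fields))
  exlist <- vector("list", length(fields))
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    chrom <- f[1L]; start0 <- as.integer(f[2L]); end0 <- as.integer(f[3L])
    name <- f[4L]; st <- f[6L]
    thick_s <- as.integer(f[7L]); thick_e <- as.integer(f[8L])
    nblk <- as.integer(f[10L])
    sizes <- as.integer(strsplit(f[11L], ",")[[1L]])[seq_len(nblk)]
    offs <- as.integer(strsplit(f[12L], ",")[[1L]])[seq_len(nblk)]
    e <- GRanges(chrom, IRanges(start0 + offs + 1L, start0 + offs + sizes),
                 strand = st)
    if (max(end(e)) > end0) stop("gene ", name, ": exon outside transcript bounds")
    g <- GRanges(chrom, IRanges(start0 + 1L, end0), strand = st)
    g$gene_id <- name; g$transcript_id <- name
    g$tss <- if (st == "-") end0 else start0 + 1L
    coding <- thick_e > thick_s
    g$cds_start <- if (coding) thick_s + 1L else NA_integer_
    g$cds_end <- if (coding) thick_e else NA_integer_
    g$biotype <- if (coding) "protein_coding" else "noncoding"
    genes[[k]] <- g
    exlist[[k]] <- GenomicRanges::reduce(e)
  }
  genes <- do.call(c, genes)
  ## BED12 name doubles as gene id; duplicates resolved by the span rule
  if (anyDuplicated(genes$gene_id)) {
    keep <- tapply(seq_along(genes), genes$gene_id, function(i) {
      i[order(-width(genes)[i], genes$transcript_id[i])][1L]
    })
    keep <- sort(unlist(keep))
    genes <- genes[keep]; exlist <- exlist[keep]
  }
  ord <- order(as.character(seqnames(genes)), start(genes), genes$gene_id)
  gm <- new("GeneModels", genes = genes[ord],
            exons = GRangesList(setNames(exlist[ord], genes$gene_id[ord])))
  validObject(gm)
  gm
}

#' Write gene models as GTF
#'
#' Emits transcript, exon and CDS features (1-based, closed) with `gene_id`,
#' `transcript_id` and `gene_biotype` attributes; the inverse of
#' [readGeneModels()] for single-transcript models.
#'
#' @param models A [GeneModels-class].
#' @param path Output path.
#' @export
writeGeneModels <- function(models, path) {
  stopifnot(is(models, "GeneModels"))
  g <- models@genes
  out <- character(0)
  attr9 <- function(i) sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
                               g$gene_id[i], g$transcript_id[i], g$biotype[i])
  for (i in seq_along(g)) {
    chrom <- as.character(seqnames(g))[i]
    st <- as.character(strand(g))[i]
    out <- c(out, paste(chrom, "regcons", "transcript", start(g)[i], end(g)[i],
                        ".", st, ".", attr9(i), sep = "\t"))
    ex <- models@exons[[i]]
    for (j in seq_along(ex))
      out <- c(out, paste(chrom, "regcons", "exon", start(ex)[j], end(ex)[j],
                          ".", st, ".", attr9(i), sep = "\t"))
    if (!is.na(g$cds_start[i])) {
      cdsr <- IRanges::restrict(IRanges::ranges(ex), g$cds_start[i], g$cds_end[i])
      cdsr <- cdsr[width(cdsr) > 0L]
      for (j in seq_along(cdsr))
        out <- c(out, paste(chrom, "regcons", "CDS", start(cdsr)[j], end(cdsr)[j],
                            ".", st, "0", attr9(i), sep = "\t"))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a conservation track
#'
#' Reads per-base conservation scores from wiggle (fixedStep/variableStep,
#' 1-based) or bedGraph (0-based half-open) into a sparse per-chromosome
#' store. Scores outside `[0, 1]` are a validation error. Positions absent
#' from the file have no stored score (`NA`), which is distinct from 0.
#'
#' @param path File path.
#' @param format `"wig"` or `"bedgraph"`; default from the file extension.
#' @return A [ConservationTrack-class].
#' @export
readConservationTrack <- function(path, format = c("auto", "wig", "bedgraph")) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, wig = "wig", bedgraph = "bedgraph", bg = "bedgraph",
                     stop("cannot infer track format from extension: ", ext))
  }
  gr <- rtracklayer::import(path, format = if (format == "wig") "wig" else "bedGraph")
  sc <- as.numeric(gr$score)
  if (any(sc < 0 | sc > 1))
    stop("conservation score outside [0,1]")
  .trackFromRanges(gr, sc)
}

.trackFromRanges <- function(gr, sc) {
  chroms <- sort(unique(as.character(seqnames(gr))))
  rles <- vector("list", length(chroms))
  names(rles) <- chroms
  for (ch in chroms) {
    i <- which(as.character(seqnames(gr)) == ch)
    i <- i[order(start(gr)[i])]
    s <- start(gr)[i]; e <- end(gr)[i]; v <- sc[i]
    vals <- lens <- numeric(0)
    cur <- 0L
    for (k in seq_along(i)) {
      if (s[k] > cur + 1L) { vals <- c(vals, NA_real_); lens <- c(lens, s[k] - cur - 1L) }
      vals <- c(vals, v[k]); lens <- c(lens, e[k] - s[k] + 1L)
      cur <- e[k]
    }
    rles[[ch]] <- Rle(vals, lens)
  }
  new("ConservationTrack", scores = RleList(rles, compress = FALSE))
}

#' Write a conservation track as fixedStep wiggle
#'
#' @param track A [ConservationTrack-class].
#' @param path Output path.
#' @export
writeConservationTrack <- function(track, path) {
  stopifnot(is(track, "ConservationTrack"))
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track@scores)) {
    r <- track@scores[[ch]]
    rl <- S4Vectors::runLength(r); rv <- runValue(r)
    pos <- cumsum(c(1, rl))[seq_along(rl)]
    for (k in seq_along(rv)) {
      if (is.na(rv[k])) next
      writeLines(sprintf("fixedStep chrom=%s start=%d step=1 span=1", ch, pos[k]), con)
      writeLines(rep(format(rv[k], digits = 15, scientific = FALSE), rl[k]), con)
    }
  }
  invisible(path)
}

#' Read / write a genome FASTA
#'
#' Thin wrappers over Biostrings; sequence names are truncated at the first
#' whitespace on read.
#'
#' @param path File path.
#' @return A `DNAStringSet`.
#' @export
readGenome <- function(path) {
  g <- readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' @rdname readGenome
#' @param genome A `DNAStringSet`.
#' @export
writeGenome <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

#' Read an expression table
#'
#' Headered TSV with columns `gene_id`, `fpkm_cell`, `fpkm_whole_embryo`
#' and `q_value`. Duplicate gene rows, negative FPKM or q outside `[0, 1]`
#' are errors.
#'
#' @param path File path.
#' @return A `data.frame` of validated expression records.
#' @export
readExpressionTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "fpkm_cell", "fpkm_whole_embryo", "q_value")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("expression table: missing required column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(tab$gene_id))
    stop("expression table: duplicate gene rows: ",
         paste(unique(tab$gene_id[duplicated(tab$gene_id)]), collapse = ", "))
  if (any(tab$fpkm_cell < 0) || any(tab$fpkm_whole_embryo < 0))
    stop("expression table: negative FPKM")
  if (any(tab$q_value < 0 | tab$q_value > 1))
    stop("expression table: q_value outside [0,1]")
  tab[need]
}

#' Read an ortholog map
#'
#' Headered TSV with columns `gene_a`, `gene_b` and optionally
#' `homology_type`. Duplicate pairs are deduplicated; many-to-many maps are
#' allowed.
#'
#' @param path File path.
#' @return A `data.frame` with columns `gene_a`, `gene_b`, `homology_type`.
#' @export
readOrthologMap <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_a", "gene_b"), colnames(tab))
  if (length(miss))
    stop("ortholog map: missing required column(s): ", paste(miss, collapse = ", "))
  if (!"homology_type" %in% colnames(tab)) tab$homology_type <- "ortholog"
  tab <- tab[!duplicated(tab[c("gene_a", "gene_b")]),
             c("gene_a", "gene_b", "homology_type")]
  rownames(tab) <- NULL
  tab
}

#' Read a GO annotation map
#'
#' Headered TSV with columns `gene_id` and `go_term`; flat annotations with
#' set semantics (duplicates dropped).
#'
#' @param path File path.
#' @return A `data.frame` with columns `gene_id`, `go_term`.
#' @export
readGoMap <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("gene_id", "go_term"), colnames(tab))
  if (length(miss))
    stop("GO map: missing required column(s): ", paste(miss, collapse = ", "))
  tab <- tab[!duplicated(tab[c("gene_id", "go_term")]), c("gene_id", "go_term")]
  rownames(tab) <- NULL
  tab
}

#' Write report tables
#'
#' Writes every table of a species or comparison report as a TSV with a
#' stable row order, plus a machine-readable JSON run summary. Deterministic:
#' the same report always produces byte-identical files.
#'
#' @param report A report list with elements `tables` (named list of
#'   data.frames) and `summary` (list).
#' @param outDir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
writeReportTables <- function(report, outDir) {
  if (!dir.exists(outDir) &&
      !dir.create(outDir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", outDir)
  paths <- character(0)
  for (nm in names(report$tables)) {
    df <- report$tables[[nm]]
    ord <- intersect(c("chrom", "start", "gene_id", "gene_a", "name", "peak"),
                     colnames(df))
    if (length(ord) && nrow(df))
      df <- df[do.call(order, df[ord]), , drop = FALSE]
    p <- file.path(outDir, paste0(nm, ".tsv"))
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(outDir, "run_summary.json")
  jsonlite::write_json(report$summary, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(c(paths, p))
}
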