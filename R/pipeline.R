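## Orchestration: a YAML run configuration, per-species analysis
## (annotate -> scan -> conserve -> targets), cross-species comparison, and
## deterministic TSV/JSON reports. Also usable stage by stage; the regcons
## command-line script under inst/scripts/ is a thin wrapper over these
## functions.

.DEFAULT_THRESHOLDS <- list(upstream_bp = 10000, downstream_bp = 10000,
                            flank_bp = 100, motif_threshold = 75,
                            fpkm_min = 1.0, fc_min = 1.5, q_max = 0.05)
.DEFAULT_MODES <- list(overlap_mode = "summit", motif_window = "peak",
                       bin_boundary = "left", ortholog_filter = NULL)

#' Read a run configuration
#'
#' YAML file with `species` input paths, `thresholds` and `modes` sections;
#' missing thresholds and modes take the standard defaults (10 kb flanks,
#' +/- 100 bp conservation window, motif threshold 75, FPKM > 1, fold change
#' > 1.5, q < 0.05, summit mode).
#'
#' @param path YAML file path.
#' @param checkPaths Verify that all referenced input files exist.
#' @return A validated `runConfig` list.
#' @export
readRunConfig <- function(path, checkPaths = TRUE) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$species) || !length(cfg$species))
    stop("run config: no species section")
  cfg$thresholds <- utils::modifyList(.DEFAULT_THRESHOLDS,
                                      if (is.null(cfg$thresholds)) list() else cfg$thresholds)
  cfg$modes <- utils::modifyList(.DEFAULT_MODES,
                                 if (is.null(cfg$modes)) list() else cfg$modes)
  if (any(unlist(cfg$thresholds[c("upstream_bp", "downstream_bp", "flank_bp")]) < 0))
    stop("run config: flank thresholds must be nonnegative")
  if (checkPaths) {
    for (sp in names(cfg$species)) {
      paths <- cfg$species[[sp]]
      pp <- unlist(paths[c("genome", "genes", "peaks", "conservation",
                           "expression", "motifs")])
      pp <- pp[!is.na(pp) & nzchar(pp)]
      missing <- pp[!file.exists(pp)]
      if (length(missing))
        stop("run config: species ", sp, ": missing input file(s): ",
             paste(missing, collapse = ", "))
    }
  }
  class(cfg) <- "runConfig"
  cfg
}

.stage <- function(name, expr) {
  message("[", name, "] ...")
  tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
}

#' Run the per-species analysis
#'
#' Executes annotate (seven-category classification and fractions), scan
#' (single, palindromic and CCAAT motif frequencies), conserve (per-peak
#' window means, bin distribution) and targets (cis-regulatory assignment,
#' expression filter, regulated set) for one species of a run configuration,
#' in order. Sections whose inputs are absent from the configuration are
#' marked `"skipped"` in the summary.
#'
#' @param config A `runConfig` (see [readRunConfig()]) or a plain list with
#'   the same structure.
#' @param species Species key within `config$species`.
#' @param outDir Optional directory: when given, tables and a JSON run
#'   summary are written via [writeReportTables()].
#' @param stages Subset of `c("annotate", "scan", "conserve", "targets")`.
#' @return A `speciesReport` list: `tables` (data.frames), `summary`
#'   (thresholds echoed, per-stage counts), `sets` (targets / expressed /
#'   regulated gene ids) and `objects` (classified peaks, index, models).
#' @export
runSpecies <- function(config, species, outDir = NULL,
                       stages = c("annotate", "scan", "conserve", "targets")) {
  stopifnot(species %in% names(config$species))
  sc <- config$species[[species]]
  th <- config$thresholds
  md <- config$modes
  genome <- .stage("load", readGenome(sc$genome))
  chromSizes <- setNames(width(genome), names(genome))
  models <- .stage("load", readGeneModels(sc$genes))
  dialect <- if (is.null(sc$peaks_dialect)) "macs_tsv" else sc$peaks_dialect
  peaks <- .stage("load", readPeakTable(sc$peaks, dialect))
  tables <- list(); summary <- list(species = species,
                                    thresholds = th, modes = md)
  sets <- list(); objects <- list(models = models)
  if ("annotate" %in% stages) {
    idx <- .stage("annotate", buildAnnotationIndex(models, th$upstream_bp,
                                                   th$downstream_bp, chromSizes))
    peaks <- .stage("annotate", classifyPeaks(peaks, idx))
    fr <- .stage("annotate", categoryFractions(peaks, idx))
    tables$annotated_peaks <- data.frame(
      chrom = as.character(seqnames(peaks)), start = start(peaks) - 1L,
      end = end(peaks), name = peaks$name, summit = peaks$summit,
      category = as.character(peaks$category), gene_id = peaks$gene_id)
    tables$category_fractions <- fr
    summary$n_peaks <- length(peaks)
    summary$category_counts <- setNames(as.list(fr$count), fr$category)
    objects$index <- idx
    stats <- tryCatch(enrichmentHistogramStats(peaks), error = function(e) NULL)
    if (!is.null(stats)) {
      tables$fold_enrichment_histogram <- stats$histogram
      summary$fold_enrichment <- list(skewness = stats$skewness,
                                      kurtosis = stats$kurtosis)
    }
  }
  if ("scan" %in% stages) {
    if (is.null(sc$motifs)) {
      summary$motif <- "skipped"
    } else {
      mono <- .stage("scan", readMemeMotif(sc$motifs))
      spacer <- if (is.null(sc$spacer)) 4L else sc$spacer
      pal <- buildPalindromePWM(mono, spacer)
      win <- md$motif_window
      freqSingle <- .stage("scan", motifPeakFrequency(peaks, genome, mono,
                                                      th$motif_threshold, win))
      freqPal <- .stage("scan", motifPeakFrequency(peaks, genome, pal,
                                                   th$motif_threshold, win))
      ccaatHits <- .stage("scan", vapply(seq_along(peaks), function(i) {
        seq <- subseq(genome[[as.character(seqnames(peaks))[i]]],
                      start(peaks)[i], end(peaks)[i])
        iupacMatchCount(seq, "CCAAT") > 0
      }, logical(1)))
      tables$motif_frequency <- data.frame(
        motif = c("single_site", "palindrome", "CCAAT"),
        percent_of_peaks = c(freqSingle, freqPal, 100 * mean(ccaatHits)))
      summary$motif <- list(threshold = th$motif_threshold, window = win,
                            palindrome_percent = freqPal,
                            single_percent = freqSingle,
                            ccaat_percent = 100 * mean(ccaatHits))
    }
  }
  if ("conserve" %in% stages) {
    if (is.null(sc$conservation)) {
      summary$conservation <- "skipped"
    } else {
      track <- .stage("conserve", readConservationTrack(sc$conservation))
      means <- .stage("conserve", peakConservation(track, peaks, th$flank_bp,
                                                   chromSizes))
      cs <- conservationSummary(means, boundary = md$bin_boundary)
      tables$peak_conservation <- data.frame(
        name = peaks$name, chrom = as.character(seqnames(peaks)),
        start = start(peaks) - 1L, summit = peaks$summit, mean_score = means)
      tables$conservation_bins <- cs$bins
      summary$conservation <- list(grand_mean = cs$grand_mean,
                                   flank_bp = th$flank_bp,
                                   bin_boundary = md$bin_boundary)
      objects$conservation_means <- means
    }
  }
  if ("targets" %in% stages) {
    if (is.null(sc$expression)) {
      summary$targets <- "skipped"
    } else {
      targets <- .stage("targets", assignPutativeTargets(
        peaks, models, th$upstream_bp, mode = md$overlap_mode,
        chromSizes = chromSizes))
      expr <- .stage("targets", readExpressionTable(sc$expression))
      expressed <- .stage("targets", callHighlyExpressed(expr, th$fpkm_min,
                                                         th$fc_min, th$q_max))
      reg <- callRegulated(targets, expressed, species)
      tables$putative_targets <- targets
      tables$regulated_genes <- data.frame(gene_id = reg$genes)
      summary$targets <- list(n_targets = reg$n_targets,
                              n_expressed = reg$n_expressed,
                              n_regulated = reg$n_regulated)
      sets <- list(targets = sort(unique(targets$gene_id)),
                   expressed = sort(unique(expressed)), regulated = reg$genes)
    }
  }
  report <- structure(list(species = species, tables = tables,
                           summary = summary, sets = sets, objects = objects),
                      class = "speciesReport")
  if (!is.null(outDir)) writeReportTables(report, outDir)
  report
}

#' @export
print.speciesReport <- function(x, ...) {
  cat("speciesReport for", x$species, "-", x$summary$n_peaks, "peaks\n")
  if (length(x$sets))
    cat("  targets:", length(x$sets$targets),
        " expressed:", length(x$sets$expressed),
        " regulated:", length(x$sets$regulated), "\n")
  invisible(x)
}

#' Cross-species comparison of two species reports
#'
#' Maps the two regulated gene sets through the ortholog table, reports the
#' conserved pairs and Venn counts, and tallies GO-term membership of the
#' conserved species-A genes.
#'
#' @param reportA,reportB `speciesReport` objects with regulated sets.
#' @param orthologMap Ortholog `data.frame` (see [readOrthologMap()]).
#' @param goMap Optional GO `data.frame` (see [readGoMap()]); species-A ids.
#' @param goTerms GO term ids to tally.
#' @param homologyType Optional homology-type filter.
#' @param outDir Optional output directory.
#' @return A `comparisonReport` list with `tables`, `summary` and the
#'   [conservedRegulated()] result under `conservation`.
#' @export
runCompare <- function(reportA, reportB, orthologMap, goMap = NULL,
                       goTerms = character(0), homologyType = NULL,
                       outDir = NULL) {
  if (!length(reportA$sets$regulated) && is.null(reportA$sets$regulated))
    stop("stage compare: report A has no regulated set")
  cmp <- .stage("compare", conservedRegulated(reportA$sets$regulated,
                                              reportB$sets$regulated,
                                              orthologMap, homologyType))
  tables <- list(conserved_pairs = cmp$pairs)
  goTally <- NULL
  if (!is.null(goMap) && length(goTerms)) {
    goTally <- data.frame(go_term = goTerms,
                          n_conserved_annotated = vapply(goTerms, function(t)
                            countGoAnnotated(unique(cmp$pairs$gene_a), goMap, t),
                            integer(1)))
    tables$go_tally <- goTally
  }
  summary <- list(species_a = reportA$species, species_b = reportB$species,
                  n_regulated_a = length(reportA$sets$regulated),
                  n_regulated_b = length(reportB$sets$regulated),
                  n_a_with_ortholog = cmp$n_a_with_ortholog,
                  n_b_with_ortholog = cmp$n_b_with_ortholog,
                  n_conserved_a = cmp$n_conserved_a,
                  n_conserved_b = cmp$n_conserved_b,
                  n_pairs = cmp$n_pairs,
                  venn = as.list(cmp$venn))
  report <- structure(list(tables = tables, summary = summary,
                           conservation = cmp, go_tally = goTally),
                      class = "comparisonReport")
  if (!is.null(outDir)) writeReportTables(report, outDir)
  report
}

#' Run both species and the comparison
#'
#' @param config A `runConfig` (or path to one).
#' @param outDir Optional output directory; per-species subdirectories and a
#'   `compare` subdirectory are written.
#' @return List with one `speciesReport` per species and `compare`.
#' @export
runAll <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  spn <- names(config$species)
  reports <- lapply(spn, function(sp)
    runSpecies(config, sp, outDir = if (is.null(outDir)) NULL
               else file.path(outDir, sp)))
  names(reports) <- spn
  out <- reports
  if (length(spn) >= 2L && !is.null(config$compare$orthologs)) {
    orth <- readOrthologMap(config$compare$orthologs)
    go <- if (!is.null(config$compare$go)) readGoMap(config$compare$go) else NULL
    terms <- if (!is.null(config$compare$go_terms))
      unlist(config$compare$go_terms) else character(0)
    out$compare <- runCompare(reports[[1L]], reports[[2L]], orth, go, terms,
                              homologyType = config$modes$ortholog_filter,
                              outDir = if (is.null(outDir)) NULL
                              else file.path(outDir, "compare"))
  }
  out
}

#' Write a run configuration for a synthetic bundle
#'
#' Convenience: points a `runConfig` at the files of a [generateDataset()]
#' bundle.
#'
#' @param files The `files` element returned by [generateDataset()].
#' @param path Optional YAML path to write.
#' @return The `runConfig` list (invisibly writes YAML when `path` given).
#' @export
syntheticRunConfig <- function(files, path = NULL) {
  cfg <- list(version = 1,
              thresholds = .DEFAULT_THRESHOLDS,
              modes = .DEFAULT_MODES,
              species = list(
                a = list(genome = files$a[["genome"]], genes = files$a[["genes"]],
                         peaks = files$a[["peaks"]], peaks_dialect = "macs_tsv",
                         conservation = files$a[["conservation"]],
                         expression = files$a[["expression"]],
                         motifs = files$motif, spacer = 4L),
                b = list(genome = files$b[["genome"]], genes = files$b[["genes"]],
                         peaks = files$b[["peaks"]], peaks_dialect = "macs_tsv",
                         conservation = files$b[["conservation"]],
                         expression = files$b[["expression"]],
                         motifs = files$motif, spacer = 4L)),
              compare = list(orthologs = files$orthologs, go = files$go,
                             go_terms = list("GO:0001501")))
  if (!is.null(path)) {
    yaml::write_yaml(cfg, path)
  }
  class(cfg) <- "runConfig"
  cfg
}
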