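## Cross-species comparison of regulated gene sets through an ortholog map:
## conserved pairs, Venn counts, and flat GO-term tallies.

#' Filter genes to those with an ortholog
#'
#' @param genes Character vector of gene ids.
#' @param map Ortholog `data.frame` from [readOrthologMap()].
#' @param side `"A"` (match against `gene_a`) or `"B"` (`gene_b`).
#' @param homologyType Optional filter on the `homology_type` column (e.g.
#'   `"ortholog_one2one"`); `NULL` keeps every pair.
#' @return The subset of `genes` having at least one ortholog pair.
#' @export
filterWithOrthologs <- function(genes, map, side = c("A", "B"),
                                homologyType = NULL) {
  side <- match.arg(side)
  if (!is.null(homologyType)) map <- map[map$homology_type %in% homologyType, ]
  col <- if (side == "A") map$gene_a else map$gene_b
  genes[genes %in% col]
}

#' Conserved regulated genes across two species
#'
#' A conserved pair `(a, b)` has `a` regulated in species A, `b` regulated in
#' species B, and `(a, b)` in the ortholog map. Conservation is counted as
#' distinct species-A genes (and, symmetrically, species-B genes); pair
#' counts are also reported for many-to-many maps. Venn counts follow the
#' with-ortholog universes: left-only = `n_a_with_ortholog - n_conserved_a`.
#'
#' @param setA,setB Regulated gene id vectors (or `regulatedGeneSet`
#'   objects) for species A and B.
#' @param map Ortholog `data.frame` from [readOrthologMap()].
#' @param homologyType Optional homology-type filter.
#' @return List with `n_a_with_ortholog`, `n_b_with_ortholog`, `pairs`
#'   (data.frame `gene_a`, `gene_b`, `homology_type`), `n_pairs`,
#'   `n_conserved_a`, `n_conserved_b`, and `venn` (left-only / shared-a /
#'   shared-b / right-only counts).
#' @export
conservedRegulated <- function(setA, setB, map, homologyType = NULL) {
  if (inherits(setA, "regulatedGeneSet")) setA <- setA$genes
  if (inherits(setB, "regulatedGeneSet")) setB <- setB$genes
  if (!is.null(homologyType)) map <- map[map$homology_type %in% homologyType, ]
  withA <- unique(filterWithOrthologs(setA, map, "A"))
  withB <- unique(filterWithOrthologs(setB, map, "B"))
  sel <- map$gene_a %in% setA & map$gene_b %in% setB
  pairs <- map[sel, , drop = FALSE]
  pairs <- pairs[order(pairs$gene_a, pairs$gene_b), , drop = FALSE]
  rownames(pairs) <- NULL
  ncA <- length(unique(pairs$gene_a))
  ncB <- length(unique(pairs$gene_b))
  list(n_a_with_ortholog = length(withA),
       n_b_with_ortholog = length(withB),
       pairs = pairs,
       n_pairs = nrow(pairs),
       n_conserved_a = ncA,
       n_conserved_b = ncB,
       venn = c(a_only = length(withA) - ncA,
                conserved_a = ncA,
                conserved_b = ncB,
                b_only = length(withB) - ncB))
}

#' Count genes annotated with a GO term
#'
#' Flat membership counting (no ontology-graph propagation): how many of the
#' given genes carry the term in the annotation map.
#'
#' @param genes Character vector of gene ids.
#' @param goMap `data.frame` from [readGoMap()].
#' @param term GO term id, e.g. `"GO:0001501"`.
#' @return Integer count.
#' @export
countGoAnnotated <- function(genes, goMap, term) {
  if (!grepl("^GO:\\d{7}$", term)) stop("malformed GO term id: ", term)
  annotated <- unique(goMap$gene_id[goMap$go_term == term])
  sum(unique(genes) %in% annotated)
}
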