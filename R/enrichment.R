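## Local gene-set over-representation analysis and the per-TAD term test.
## These replace web-service enrichment with the same hypergeometric
## statistics computed on user-supplied GMT collections.

#' Hypergeometric over-representation p-value for one term
#'
#' Upper-tail hypergeometric test of a query gene list against one term's
#' gene set within a universe: `N = |universe|`, `K = |term ∩ universe|`,
#' `n = |query ∩ universe|`, `k = |query ∩ term ∩ universe|`.
#'
#' @param queryGenes character vector of query gene ids.
#' @param termGenes character vector of the term's gene ids.
#' @param universeGenes character vector of the universe.
#' @return p-value in (0, 1\].
#' @export
oraTest <- function(queryGenes, termGenes, universeGenes) {
  universeGenes <- unique(universeGenes)
  if (!length(universeGenes)) stop("empty gene universe")
  query <- intersect(unique(queryGenes), universeGenes)
  term <- intersect(unique(termGenes), universeGenes)
  k <- length(intersect(query, term))
  tadHypergeomTest(length(universeGenes), length(term), length(query), k)
}

#' Over-representation analysis across a gene-set collection
#'
#' Runs [oraTest()] for every term of a GMT collection and adjusts across
#' terms with Benjamini-Hochberg.
#'
#' @param queryGenes query gene ids (e.g. genes of significant events).
#' @param geneSets named list of gene sets (see [readGMT()]).
#' @param universeGenes the gene universe (e.g. all genes in the aggregated
#'   table).
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return `data.frame` with `term_id`, `k`, `n_query`, `K`, `N`, `p`,
#'   `adj_p`, `significant`, sorted by `p`.
#' @export
oraRun <- function(queryGenes, geneSets, universeGenes, alpha = 0.05) {
  universe <- unique(universeGenes)
  if (!length(universe)) stop("empty gene universe")
  query <- intersect(unique(queryGenes), universe)
  rows <- lapply(names(geneSets), function(id) {
    term <- intersect(unique(geneSets[[id]]), universe)
    k <- length(intersect(query, term))
    data.frame(term_id = id, k = k, n_query = length(query),
               K = length(term), N = length(universe),
               p = tadHypergeomTest(length(universe), length(term),
                                    length(query), k),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- bhAdjust(res$p)
  res$significant <- res$adj_p < alpha
  res <- res[order(res$p, res$term_id), ]
  rownames(res) <- NULL
  res
}

#' Per-TAD significance of enriched terms
#'
#' For every (enriched term, TAD) pair, tests whether the term's genes
#' concentrate in that TAD: upper-tail hypergeometric with universe
#' `N` = genes present in the aggregated table, `K` = the term's genes in
#' the universe, `n` = genes in the TAD and `k` = the term's genes in the
#' TAD; BH adjustment within each term. With `outDir` set, writes
#' `over-represented enriched terms.csv` (grouped by TAD) and
#' `enriched terms in different TADs.csv` (grouped by term).
#'
#' @param enrichedTerms character vector of term ids to localise (typically
#'   the significant rows of [oraRun()]).
#' @param agg a [TADExperiment-class] (provides the gene -> TAD mapping).
#' @param geneSets named list of gene sets.
#' @param outDir optional output directory.
#' @return `data.frame` with `term_id`, `tad_id`, `k_term_tad`,
#'   `n_tad_genes`, `K_term`, `N_universe`, `p`, `adj_p`.
#' @export
perTadTermTest <- function(enrichedTerms, agg, geneSets, outDir = NULL) {
  rd <- SummarizedExperiment::rowData(agg)
  ## gene -> TADs mapping from the aggregated table (multi-gene events
  ## contribute every listed gene)
  hasGene <- nzchar(rd$gene_id)
  genes <- strsplit(rd$gene_id[hasGene], ";", fixed = TRUE)
  tadRep <- rep(rd$tad_id[hasGene], lengths(genes))
  genes <- unlist(genes, use.names = FALSE)
  universe <- unique(genes)
  N <- length(universe)
  if (!N) stop("aggregated table has no annotated genes")
  keep <- !is.na(tadRep)
  byTad <- lapply(split(genes[keep], tadRep[keep]), unique)

  rows <- list()
  for (term in enrichedTerms) {
    tg <- intersect(unique(geneSets[[term]]), universe)
    if (is.null(geneSets[[term]]))
      stop("term '", term, "' absent from the gene-set collection")
    sub <- lapply(names(byTad), function(td) {
      tadGenes <- byTad[[td]]
      k <- length(intersect(tg, tadGenes))
      data.frame(term_id = term, tad_id = td, k_term_tad = k,
                 n_tad_genes = length(tadGenes), K_term = length(tg),
                 N_universe = N,
                 p = tadHypergeomTest(N, length(tg), length(tadGenes), k),
                 stringsAsFactors = FALSE)
    })
    sub <- do.call(rbind, sub)
    sub$adj_p <- bhAdjust(sub$p)
    rows[[term]] <- sub
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  if (!is.null(outDir) && !is.null(res)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    byTadOut <- res[order(res$tad_id, res$p, res$term_id), ]
    byTermOut <- res[order(res$term_id, res$p, res$tad_id), ]
    utils::write.csv(byTadOut,
                     file.path(outDir, "over-represented enriched terms.csv"),
                     row.names = FALSE)
    utils::write.csv(byTermOut,
                     file.path(outDir, "enriched terms in different TADs.csv"),
                     row.names = FALSE)
  }
  res
}
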