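## Gene and TAD annotation of event coordinates.
## Overlap semantics: intervals are BED half-open on disk, 1-based closed as
## GRanges in memory; "overlap" means >= 1 shared base.

.FEATURE_PRECEDENCE <- c("cds", "exon", "threeUTR", "fiveUTR",
                         "intron", "promoter")

## normalize GTF type spellings to the feature vocabulary used in outputs
.gtfFeatureSets <- function(gtf, promoterUp = 1000L, promoterDown = 200L) {
  type <- as.character(gtf$type)
  gid <- as.character(gtf$gene_id)
  sets <- list()
  pick <- function(types) {
    sel <- type %in% types
    g <- GenomicRanges::granges(gtf[sel])
    S4Vectors::mcols(g)$gene_id <- gid[sel]
    g
  }
  sets$cds <- pick("CDS")
  sets$exon <- pick("exon")
  sets$threeUTR <- pick(c("three_prime_utr", "three_prime_UTR", "3UTR"))
  sets$fiveUTR <- pick(c("five_prime_utr", "five_prime_UTR", "5UTR"))

  ## gene extents: explicit "gene" rows when present, else per-gene range
  if (any(type == "gene")) {
    genes <- pick("gene")
  } else {
    spl <- split(GenomicRanges::granges(gtf), gid)
    genes <- unlist(range(spl))
    S4Vectors::mcols(genes)$gene_id <- names(genes)
    names(genes) <- NULL
  }
  sets$gene <- genes

  ## introns: gene extent minus its exons
  if (length(sets$exon) && length(genes)) {
    exByGene <- split(sets$exon, sets$exon$gene_id)
    idx <- match(genes$gene_id, names(exByGene))
    hasEx <- !is.na(idx)
    if (any(hasEx)) {
      intr <- IRanges::psetdiff(GenomicRanges::granges(genes[hasEx]),
                                exByGene[idx[hasEx]])
      gidRep <- rep(genes$gene_id[hasEx], lengths(intr))
      intr <- unlist(intr, use.names = FALSE)
      S4Vectors::mcols(intr)$gene_id <- gidRep
      sets$intron <- intr
    } else sets$intron <- GenomicRanges::GRanges()
  } else sets$intron <- GenomicRanges::GRanges()

  prom <- suppressWarnings(
    GenomicRanges::promoters(genes, upstream = promoterUp,
                             downstream = promoterDown))
  GenomicRanges::start(prom) <- pmax(GenomicRanges::start(prom), 1L)
  GenomicRanges::end(prom) <- pmax(GenomicRanges::end(prom),
                                   GenomicRanges::start(prom))
  S4Vectors::mcols(prom)$gene_id <- genes$gene_id
  sets$promoter <- prom
  sets
}

#' Annotate events with gene ids and gene features
#'
#' Each event is intersected with the gene features of a GTF annotation
#' (strand-insensitive). The reported feature is the highest-precedence one
#' overlapped anywhere (`cds > exon > threeUTR > fiveUTR > intron >
#' promoter`); an event overlapping no gene is `"intergenic"`. When several
#' genes overlap one event all their ids are joined with `";"` (sorted).
#'
#' @param events `GRanges` of event coordinates.
#' @param gtf path to a GTF file or an imported `GRanges` (1-based, with
#'   `type` and `gene_id` metadata columns).
#' @param promoterUp,promoterDown promoter window around the TSS, in bases.
#' @return `DataFrame` with columns `gene_id` (`""` when intergenic) and
#'   `gene_feature`, parallel to `events`.
#' @export
annotateGenes <- function(events, gtf, promoterUp = 1000L,
                          promoterDown = 200L) {
  if (is.character(gtf))
    gtf <- rtracklayer::import(gtf, format = "gtf")
  sets <- .gtfFeatureSets(gtf, promoterUp, promoterDown)
  n <- length(events)
  feature <- rep(NA_character_, n)
  geneHits <- vector("list", n)
  for (feat in rev(.FEATURE_PRECEDENCE)) {   # low precedence first, overwritten
    s <- sets[[feat]]
    if (!length(s)) next
    ov <- GenomicRanges::findOverlaps(events, s, ignore.strand = TRUE)
    q <- S4Vectors::queryHits(ov)
    feature[unique(q)] <- feat
    g <- split(s$gene_id[S4Vectors::subjectHits(ov)], q)
    for (i in names(g))
      geneHits[[as.integer(i)]] <- c(geneHits[[as.integer(i)]], g[[i]])
  }
  ## any overlap with the gene body contributes the gene id even if the
  ## feature label comes from another gene
  ovg <- GenomicRanges::findOverlaps(events, sets$gene, ignore.strand = TRUE)
  gg <- split(sets$gene$gene_id[S4Vectors::subjectHits(ovg)],
              S4Vectors::queryHits(ovg))
  for (i in names(gg))
    geneHits[[as.integer(i)]] <- c(geneHits[[as.integer(i)]], gg[[i]])
  gene_id <- vapply(geneHits, function(g)
    if (is.null(g)) "" else paste(sort(unique(g)), collapse = ";"), "")
  feature[is.na(feature)] <- "intergenic"
  S4Vectors::DataFrame(gene_id = gene_id, gene_feature = feature)
}

#' Assign events to TAD segments
#'
#' Every event gets the id of the segment it overlaps. An event overlapping
#' several segments (segments are not assumed disjoint) is assigned to the
#' one with the largest overlap length, ties broken by the lexicographically
#' smallest segment id. Events overlapping no segment get `NA` (they stay in
#' the table but are excluded from TAD-level statistics).
#'
#' @param events `GRanges` of event coordinates.
#' @param segments `GRanges` of segments with names = tad ids
#'   (see [readSegments()]).
#' @return Character vector of tad ids parallel to `events` (`NA` when
#'   unassigned).
#' @export
assignTads <- function(events, segments) {
  stopifnot(!is.null(names(segments)), !anyDuplicated(names(segments)))
  ov <- GenomicRanges::findOverlaps(events, segments, ignore.strand = TRUE)
  out <- rep(NA_character_, length(events))
  if (!length(ov)) return(out)
  q <- S4Vectors::queryHits(ov)
  s <- S4Vectors::subjectHits(ov)
  w <- GenomicRanges::width(GenomicRanges::pintersect(
    GenomicRanges::granges(events)[q], GenomicRanges::granges(segments)[s]))
  id <- names(segments)[s]
  ord <- order(q, -w, id, method = "radix")
  first <- !duplicated(q[ord])
  out[q[ord][first]] <- id[ord][first]
  out
}
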