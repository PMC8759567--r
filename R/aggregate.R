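#' Build the aggregated event x sample table
#'
#' Runs the whole data-aggregation phase: sample harmonisation across
#' layers, per-layer scaling to \[0,100\] ([scaleFreq()] / [scaleCounts()]),
#' gene annotation ([annotateGenes()]), TAD assignment ([assignTads()]) and
#' row-wise concatenation of all layers into one [TADExperiment-class].
#' When `outDir` is given the standard file suite is written:
#' `integrated-table.csv`, `integrated-tad-table.csv` and `summary.txt`
#' (which source provided which kind of data).
#'
#' @param layers list of [OmicsLayer-class] (see [loadOmicsDir()]).
#' @param segments TAD `GRanges` from [readSegments()], or `NULL` to skip
#'   TAD assignment.
#' @param gtf GTF path or imported `GRanges`, or `NULL` to skip gene
#'   annotation.
#' @param config list from [runConfig()].
#' @param outDir optional output directory for the file suite.
#' @param verbose emit progress messages.
#' @return A [TADExperiment-class].
#' @export
buildAggregatedTable <- function(layers, segments = NULL, gtf = NULL,
                                 config = runConfig(), outDir = NULL,
                                 verbose = TRUE) {
  stopifnot(length(layers) >= 1L)
  layers <- harmonizeSamples(layers, mode = config$sampleMode)

  scaled <- lapply(layers, function(layer) {
    v <- SummarizedExperiment::assay(layer, "values")
    if (omicsKind(layer) == "count") scaleCounts(v)
    else scaleFreq(v, betaAutoscale = config$betaAutoscale)
  })
  allIds <- unlist(lapply(scaled, rownames), use.names = FALSE)
  if (anyDuplicated(allIds))
    stop("event ids collide across layers: ",
         paste(utils::head(unique(allIds[duplicated(allIds)]), 3L),
               collapse = ", "))
  mat <- do.call(rbind, scaled)
  ranges <- do.call(c, unname(lapply(layers,
    function(l) GenomicRanges::granges(
      SummarizedExperiment::rowRanges(l)))))
  names(ranges) <- allIds
  source <- rep(vapply(layers, layerSource, ""),
                vapply(layers, nrow, 1L))
  kind <- rep(vapply(layers, omicsKind, ""),
              vapply(layers, nrow, 1L))

  if (!is.null(gtf)) {
    .msg("annotating genes...", verbose = verbose)
    ann <- annotateGenes(ranges, gtf,
                         promoterUp = config$promoterUp,
                         promoterDown = config$promoterDown)
  } else {
    ann <- S4Vectors::DataFrame(gene_id = rep("", length(ranges)),
                                gene_feature = rep("", length(ranges)))
  }
  tad_id <- if (!is.null(segments)) assignTads(ranges, segments)
            else rep(NA_character_, length(ranges))

  rowData <- S4Vectors::DataFrame(
    source = unname(source), kind = unname(kind),
    gene_id = ann$gene_id, gene_feature = ann$gene_feature,
    tad_id = tad_id)
  srcMap <- stats::setNames(vapply(layers, omicsKind, ""),
                            vapply(layers, layerSource, ""))
  agg <- TADExperiment(mat, ranges, rowData, sourceMap = srcMap,
                       segments = segments)
  if (!is.null(outDir)) writeAggregatedTable(agg, outDir)
  agg
}

## flat data.frame view used by the on-disk writers: chromosome, TAD name,
## TAD start/end, event id + coordinates, gene id/functionality, source,
## then one column per sample
.aggAsDataFrame <- function(agg, withTads = TRUE) {
  gr <- SummarizedExperiment::rowRanges(agg)
  rd <- SummarizedExperiment::rowData(agg)
  bed <- .grangesToBed(gr)
  base <- data.frame(
    chromosome = bed$chrom, stringsAsFactors = FALSE)
  if (withTads) {
    segs <- tadRegions(agg)
    idx <- if (is.null(segs)) rep(NA_integer_, nrow(agg))
           else match(rd$tad_id, names(segs))
    base$TAD <- ifelse(is.na(rd$tad_id), "", rd$tad_id)
    base$TAD_start <- ifelse(is.na(idx), NA,
                             GenomicRanges::start(segs)[idx] - 1L)
    base$TAD_end <- ifelse(is.na(idx), NA, GenomicRanges::end(segs)[idx])
  }
  cbind(base,
        data.frame(eventID = rownames(agg),
                   start = bed$start, end = bed$end,
                   GeneID = rd$gene_id, GeneFunction = rd$gene_feature,
                   source = rd$source, stringsAsFactors = FALSE),
        as.data.frame(SummarizedExperiment::assay(agg, "scaled"),
                      check.names = FALSE))
}

#' Write the aggregated-table file suite
#'
#' Writes `integrated-table.csv` (events without TAD columns),
#' `integrated-tad-table.csv` (with TAD name/start/end) and `summary.txt`
#' (source -> kind mapping) into `outDir`.
#'
#' @param agg a [TADExperiment-class].
#' @param outDir output directory (created if needed).
#' @export
writeAggregatedTable <- function(agg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(.aggAsDataFrame(agg, withTads = FALSE),
                   file.path(outDir, "integrated-table.csv"),
                   row.names = FALSE)
  utils::write.csv(.aggAsDataFrame(agg, withTads = TRUE),
                   file.path(outDir, "integrated-tad-table.csv"),
                   row.names = FALSE)
  sm <- sourceMap(agg)
  writeLines(c("source\tkind", paste(names(sm), sm, sep = "\t")),
             file.path(outDir, "summary.txt"))
  invisible(outDir)
}

#' Reverse methylation values in selected gene features
#'
#' For frequency-layer rows whose `source` is listed and whose
#' `gene_feature` is in `features`, the value is complemented
#' (`100 - value`) so that low methylation maps to high values — aligning
#' the direction of methylation with transcriptional activity before joint
#' analysis. Applying the operation twice restores the input. With `outDir`
#' set, `integrated-tad-table-methNorm.txt` is written.
#'
#' @param agg a [TADExperiment-class].
#' @param sources source labels to reverse (must be `freq` layers).
#' @param features gene features to reverse (e.g. `c("promoter",
#'   "intergenic")`).
#' @param outDir optional output directory.
#' @return The modified [TADExperiment-class].
#' @export
reverseMethylation <- function(agg, sources,
                               features = c("promoter", "intergenic"),
                               outDir = NULL) {
  sm <- sourceMap(agg)
  unknown <- setdiff(sources, names(sm))
  if (length(unknown))
    stop("unknown source(s): ", paste(unknown, collapse = ", "))
  notFreq <- sources[sm[sources] != "freq"]
  if (length(notFreq))
    stop("source(s) not of kind freq: ", paste(notFreq, collapse = ", "))
  rd <- SummarizedExperiment::rowData(agg)
  sel <- rd$source %in% sources & rd$gene_feature %in% features
  v <- SummarizedExperiment::assay(agg, "scaled")
  v[sel, ] <- 100 - v[sel, , drop = FALSE]
  SummarizedExperiment::assays(agg)$scaled <- v
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(.aggAsDataFrame(agg, withTads = TRUE),
                       file.path(outDir, "integrated-tad-table-methNorm.txt"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  agg
}
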