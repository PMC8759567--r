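#' OmicsLayer: one omics input table
#'
#' A `RangedSummarizedExperiment` holding one omics layer: event coordinates
#' as `rowRanges`, one `"values"` assay (events x samples) and the layer's
#' `kind` — `"freq"` for data already on a frequency scale (methylation beta
#' x100, mutation VAF x100) or `"count"` for expression counts that still
#' need [scaleCounts()].
#'
#' @slot kind `"freq"` or `"count"`.
#' @slot source name of the originating input file (used as the layer label
#'   in the aggregated table).
#' @aliases OmicsLayer
#' @seealso [loadOmicsDir()], [buildAggregatedTable()]
#' @export
setClass("OmicsLayer",
  contains = "RangedSummarizedExperiment",
  representation(kind = "character", source = "character"))

setValidity("OmicsLayer", function(object) {
  msg <- character()
  if (length(object@kind) != 1L || !object@kind %in% c("freq", "count"))
    msg <- c(msg, "kind must be \"freq\" or \"count\"")
  if (length(object@source) != 1L || !nzchar(object@source))
    msg <- c(msg, "source must be a non-empty string")
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay \"values\" is required")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate event ids")
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsLayer
#'
#' @param values numeric matrix, events x samples; rownames are event ids,
#'   colnames are sample ids.
#' @param ranges `GRanges` of event coordinates (1-based closed), same length
#'   and order as `nrow(values)`.
#' @param kind `"freq"` or `"count"`.
#' @param source label of the originating file.
#' @return An [OmicsLayer-class].
#' @export
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 501), width = 2))
#' m  <- matrix(c(0, 50, 100, 25), 2, 2,
#'              dimnames = list(c("cg1", "cg2"), c("S1", "S2")))
#' OmicsLayer(m, gr, kind = "freq", source = "meth.txt")
OmicsLayer <- function(values, ranges, kind, source) {
  stopifnot(is.matrix(values), length(ranges) == nrow(values))
  names(ranges) <- rownames(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values), rowRanges = ranges)
  new("OmicsLayer", se, kind = kind, source = source)
}

#' @describeIn OmicsLayer-class the layer kind (`"freq"` or `"count"`).
#' @param x,object an `OmicsLayer`.
#' @export
omicsKind <- function(x) x@kind

#' @describeIn OmicsLayer-class the originating source label.
#' @export
layerSource <- function(x) x@source

setMethod("show", "OmicsLayer", function(object) {
  cat(sprintf("OmicsLayer \"%s\" (%s): %d events x %d samples\n",
              object@source, object@kind, nrow(object), ncol(object)))
})

#' TADExperiment: the aggregated multi-omics event table
#'
#' A `RangedSummarizedExperiment` produced by [buildAggregatedTable()]. The
#' single `"scaled"` assay holds all events of all layers on the common
#' \[0,100\] scale (`NA` marks samples absent from a layer under union
#' harmonisation). `rowData` carries `source`, `kind`, `gene_id`,
#' `gene_feature` and `tad_id` per event; `metadata(x)$sourceMap` maps each
#' source file to its kind, and `metadata(x)$segments` stores the TAD
#' intervals used for the assignment.
#'
#' @aliases TADExperiment
#' @seealso [eventDiffRun()], [tadDiffRun()], [tadSampleMeans()]
#' @export
setClass("TADExperiment", contains = "RangedSummarizedExperiment")

setValidity("TADExperiment", function(object) {
  msg <- character()
  if (!"scaled" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay \"scaled\" is required")
  else {
    v <- SummarizedExperiment::assay(object, "scaled")
    vv <- v[!is.na(v)]
    if (length(vv) && (any(!is.finite(vv)) ||
                       min(vv) < -1e-8 || max(vv) > 100 + 1e-8))
      msg <- c(msg, "scaled values must lie in [0, 100] (or NA)")
  }
  need <- c("source", "kind", "gene_id", "gene_feature", "tad_id")
  miss <- setdiff(need, colnames(SummarizedExperiment::rowData(object)))
  if (length(miss))
    msg <- c(msg, paste0("rowData lacks column(s): ",
                         paste(miss, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "event ids must be unique across the aggregated table")
  if (length(msg)) msg else TRUE
})

#' Construct a TADExperiment
#'
#' Usually produced by [buildAggregatedTable()]; the constructor is exported
#' for programmatic assembly (tests, simulations).
#'
#' @param scaled numeric matrix on \[0,100\] (NA allowed), events x samples.
#' @param ranges `GRanges` of event coordinates.
#' @param rowData `DataFrame`/data.frame with columns `source`, `kind`,
#'   `gene_id`, `gene_feature`, `tad_id`.
#' @param sourceMap named character vector mapping source label -> kind.
#' @param segments `GRanges` of TAD intervals (names = tad ids) or `NULL`.
#' @return A [TADExperiment-class].
#' @export
TADExperiment <- function(scaled, ranges, rowData, sourceMap = character(),
                          segments = NULL) {
  stopifnot(is.matrix(scaled), length(ranges) == nrow(scaled))
  names(ranges) <- rownames(scaled)
  ranges <- GenomicRanges::granges(ranges)   # drop stray mcols
  S4Vectors::mcols(ranges) <- S4Vectors::DataFrame(rowData)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(scaled = scaled), rowRanges = ranges)
  obj <- new("TADExperiment", se)
  S4Vectors::metadata(obj)$sourceMap <- sourceMap
  S4Vectors::metadata(obj)$segments <- segments
  validObject(obj)
  obj
}

#' @describeIn TADExperiment-class source label -> kind mapping.
#' @param x,object a `TADExperiment`.
#' @export
sourceMap <- function(x) S4Vectors::metadata(x)$sourceMap

#' @describeIn TADExperiment-class the TAD segment `GRanges` used for
#'   assignment (names are tad ids), or `NULL`.
#' @export
tadRegions <- function(x) S4Vectors::metadata(x)$segments

#' @describeIn TADExperiment-class per-event TAD ids (`NA` when unassigned).
#' @export
tadIds <- function(x) SummarizedExperiment::rowData(x)$tad_id

#' @describeIn TADExperiment-class event identifiers.
#' @export
eventIds <- function(x) rownames(x)

setMethod("show", "TADExperiment", function(object) {
  rd <- SummarizedExperiment::rowData(object)
  cat(sprintf(
    "TADExperiment: %d events x %d samples\n  sources: %s\n  TAD-assigned events: %d / %d (%d TADs)\n",
    nrow(object), ncol(object),
    paste(sprintf("%s (%s)", names(sourceMap(object)), sourceMap(object)),
          collapse = ", "),
    sum(!is.na(rd$tad_id)), nrow(object),
    length(unique(rd$tad_id[!is.na(rd$tad_id)]))))
})
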