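## Visualisation helpers. Every figure writes a machine-readable sidecar
## CSV of the plotted values next to it; tests assert sidecars, not pixels.

.writeFigure <- function(p, file) {
  grDevices::pdf(file, width = 7, height = 5)
  print(p)
  grDevices::dev.off()
  invisible(file)
}

.sidecarPath <- function(file) paste0(tools::file_path_sans_ext(file),
                                      "_data.csv")

#' Dot plot of a TAD's event values by group
#'
#' `mode = "cases"` plots every sample's value for each event of the TAD,
#' coloured by group; `mode = "means"` plots per-event group means joined
#' by a line, with violins of the per-sample TAD means overlaid. The
#' sidecar CSV holds the long table of plotted values.
#'
#' @param agg a [TADExperiment-class].
#' @param tadId the TAD to plot.
#' @param groups named 0/1 vector (names = sample ids).
#' @param file output figure path (PDF).
#' @param mode `"cases"` or `"means"`.
#' @return list with `file`, `sidecar` and `data` (the sidecar contents).
#' @export
plotTadDots <- function(agg, tadId, groups, file,
                        mode = c("cases", "means")) {
  mode <- match.arg(mode)
  rd <- SummarizedExperiment::rowData(agg)
  sel <- !is.na(rd$tad_id) & rd$tad_id == tadId
  if (!any(sel)) stop("TAD '", tadId, "' has no events")
  groups <- groups[!is.na(groups)]
  v <- SummarizedExperiment::assay(agg, "scaled")[sel, names(groups),
                                                  drop = FALSE]
  long <- data.frame(
    event = rep(rownames(v), ncol(v)),
    sample = rep(colnames(v), each = nrow(v)),
    group = rep(unname(groups), each = nrow(v)),
    value = as.vector(v), stringsAsFactors = FALSE)
  long <- long[!is.na(long$value), ]
  if (mode == "cases") {
    data <- long
    p <- ggplot2::ggplot(data, ggplot2::aes(
      x = .data$event, y = .data$value,
      colour = factor(.data$group))) +
      ggplot2::geom_jitter(width = 0.15, size = 0.8) +
      ggplot2::labs(title = tadId, colour = "group", y = "scaled value") +
      ggplot2::theme_bw() +
      ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                         size = 5))
  } else {
    data <- stats::aggregate(value ~ event + group, long, mean)
    sampMeans <- stats::aggregate(value ~ sample + group, long, mean)
    p <- ggplot2::ggplot(data, ggplot2::aes(
      x = factor(.data$group), y = .data$value)) +
      ggplot2::geom_violin(data = sampMeans, alpha = 0.3) +
      ggplot2::geom_point() +
      ggplot2::geom_line(ggplot2::aes(group = .data$event), alpha = 0.4) +
      ggplot2::labs(title = tadId, x = "group",
                    y = "mean scaled value per event") +
      ggplot2::theme_bw()
  }
  .writeFigure(p, file)
  sidecar <- .sidecarPath(file)
  utils::write.csv(data, sidecar, row.names = FALSE)
  list(file = file, sidecar = sidecar, data = data)
}

#' Genomic-track plot of events in a region
#'
#' Plots event values against their chromosomal position within a region,
#' per case (`mode = "cases"`), as group means (`mode = "groups"`) or as
#' the group-1 minus group-0 difference (`mode = "difference"`). TAD
#' extents overlapping the region are drawn underneath. The sidecar CSV
#' holds the plotted values.
#'
#' @param agg a [TADExperiment-class].
#' @param region string `"chrom:start-end"` (BED convention).
#' @param groups named 0/1 vector.
#' @param file output figure path (PDF).
#' @param mode `"cases"`, `"groups"` or `"difference"`.
#' @return list with `file`, `sidecar` and `data`.
#' @export
plotTadTrack <- function(agg, region, groups, file,
                         mode = c("cases", "groups", "difference")) {
  mode <- match.arg(mode)
  m <- regmatches(region,
                  regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
  if (length(m) != 4L) stop("region must look like chr1:1000-50000")
  reg <- .bedToGRanges(m[2L], as.numeric(m[3L]), as.numeric(m[4L]))
  sel <- suppressWarnings(   # disjoint seqlevels just mean "no events"
    IRanges::overlapsAny(SummarizedExperiment::rowRanges(agg), reg,
                         ignore.strand = TRUE))
  groups <- groups[!is.na(groups)]
  if (!any(sel)) {
    warning("no events in region ", region)
    data <- data.frame(event = character(), position = numeric(),
                       series = character(), value = numeric())
  } else {
    v <- SummarizedExperiment::assay(agg, "scaled")[sel, names(groups),
                                                    drop = FALSE]
    pos <- GenomicRanges::start(SummarizedExperiment::rowRanges(agg))[sel] - 1L
    if (mode == "cases") {
      data <- data.frame(event = rep(rownames(v), ncol(v)),
                         position = rep(pos, ncol(v)),
                         series = rep(colnames(v), each = nrow(v)),
                         value = as.vector(v), stringsAsFactors = FALSE)
    } else {
      m0 <- rowMeans(v[, names(groups)[groups == 0], drop = FALSE],
                     na.rm = TRUE)
      m1 <- rowMeans(v[, names(groups)[groups == 1], drop = FALSE],
                     na.rm = TRUE)
      data <- if (mode == "groups")
        data.frame(event = rep(rownames(v), 2L),
                   position = rep(pos, 2L),
                   series = rep(c("group0", "group1"), each = nrow(v)),
                   value = c(m0, m1), stringsAsFactors = FALSE)
      else
        data.frame(event = rownames(v), position = pos,
                   series = "group1 - group0", value = m1 - m0,
                   stringsAsFactors = FALSE)
    }
    data <- data[!is.na(data$value), ]
  }
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = .data$position, y = .data$value, colour = .data$series)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(title = region, y = "scaled value") +
    ggplot2::theme_bw() +
    ggplot2::theme(legend.position = if (mode == "cases") "none"
                   else "right")
  segs <- tadRegions(agg)
  if (!is.null(segs)) {
    hit <- suppressWarnings(
      IRanges::overlapsAny(segs, reg, ignore.strand = TRUE))
    if (any(hit)) {
      tb <- data.frame(xmin = GenomicRanges::start(segs)[hit] - 1L,
                       xmax = GenomicRanges::end(segs)[hit],
                       id = names(segs)[hit])
      p <- p + ggplot2::geom_segment(
        data = tb, ggplot2::aes(x = .data$xmin, xend = .data$xmax),
        y = -4, yend = -4, linewidth = 2, colour = "grey40",
        inherit.aes = FALSE)
    }
  }
  .writeFigure(p, file)
  sidecar <- .sidecarPath(file)
  utils::write.csv(data, sidecar, row.names = FALSE)
  list(file = file, sidecar = sidecar, data = data)
}

#' Bar plot of enrichment results
#'
#' Bars of `-log10(adj_p)` for the top terms, sorted by adjusted p. Works
#' on the outputs of [oraRun()] and [motifEnrichment()]. The sidecar CSV
#' holds the plotted table.
#'
#' @param results data.frame with a term/motif id column and `adj_p`.
#' @param file output figure path (PDF).
#' @param top number of terms shown (default 20).
#' @return list with `file`, `sidecar` and `data`.
#' @export
plotEnrichmentBars <- function(results, file, top = 20L) {
  if (!nrow(results)) stop("empty enrichment results")
  idCol <- intersect(c("term_id", "motif_id"), colnames(results))[1L]
  if (is.na(idCol)) stop("results need a term_id or motif_id column")
  data <- results[order(results$adj_p), , drop = FALSE]
  data <- utils::head(data, top)
  data <- data.frame(id = data[[idCol]], adj_p = data$adj_p,
                     neg_log10_adj_p = -log10(pmax(data$adj_p, 1e-300)),
                     stringsAsFactors = FALSE)
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = stats::reorder(.data$id, .data$neg_log10_adj_p),
    y = .data$neg_log10_adj_p)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "-log10 adjusted p") +
    ggplot2::theme_bw()
  .writeFigure(p, file)
  sidecar <- .sidecarPath(file)
  utils::write.csv(data, sidecar, row.names = FALSE)
  list(file = file, sidecar = sidecar, data = data)
}
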