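## TAD-level aggregation of event significance: hypergeometric enrichment of
## significant events per TAD plus an expression-based activation score.

#' Upper-tail hypergeometric test
#'
#' Probability of observing at least `k` significant events in a TAD of
#' `n` events, when `K` of the `N` TAD-assigned events are significant
#' overall: `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`.
#'
#' @param N total number of events in the universe.
#' @param K number of "marked" (significant) events in the universe.
#' @param n number of events drawn (events in the TAD).
#' @param k number of marked events drawn.
#' @return the upper-tail p-value in (0, 1\].
#' @export
#' @examples
#' tadHypergeomTest(10, 5, 4, 4)  # 5/210
tadHypergeomTest <- function(N, K, n, k) {
  N <- .stopifnotScalarCount(N, "N"); K <- .stopifnotScalarCount(K, "K")
  n <- .stopifnotScalarCount(n, "n"); k <- .stopifnotScalarCount(k, "k")
  if (K > N || n > N || k > min(K, n))
    stop("inconsistent counts: need K <= N, n <= N, k <= min(K, n)")
  stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
}

#' TAD activation score
#'
#' Mean of |logFC| over the TAD's expression-source (`kind == "count"`)
#' events — the phenotypic-outcome criterion. A TAD without expression
#' events scores 0 and therefore can never pass the activation threshold.
#'
#' @param logFC per-event log fold changes.
#' @param kind per-event layer kinds (`"freq"`/`"count"`).
#' @return mean |logFC| of the expression events (0 when there are none).
#' @export
tadActivation <- function(logFC, kind) {
  sel <- kind == "count" & !is.na(logFC)
  if (!any(sel)) return(0)
  mean(abs(logFC[sel]))
}

#' TAD-level differential analysis for one contrast
#'
#' For every TAD with at least one assigned event: counts its events and
#' its significant events (from [eventDiffRun()]), tests the significant
#' count for enrichment with [tadHypergeomTest()] against the universe of
#' all TAD-assigned, testable events, and computes the activation score
#' ([tadActivation()]). A TAD is called significant when
#' `hyper_p < alphaTad` and `activation >= activationMin`. A BH-adjusted
#' hypergeometric p is reported for information but does not enter the
#' default call. With `outDir` set, writes `<contrast>_TADiff.txt` (TAD
#' statistics followed by their events with per-sample values) and appends
#' to `Summary_TADiff.txt`.
#'
#' @param agg a [TADExperiment-class].
#' @param eventStats result of [eventDiffRun()] for the same table.
#' @param contrast contrast name (used for output files).
#' @param alphaTad hypergeometric p threshold (default 0.01).
#' @param activationMin activation threshold (default 2).
#' @param outDir optional output directory.
#' @return `data.frame` with one row per TAD: `tad_id`, `chrom`, `start`,
#'   `end` (BED convention), `n_events`, `n_sig`, `hyper_p`, `hyper_adj_p`,
#'   `activation`, `significant`; sorted by `hyper_p`.
#' @export
tadDiffRun <- function(agg, eventStats, contrast = "contrast",
                       alphaTad = 0.01, activationMin = 2, outDir = NULL) {
  stopifnot(identical(rownames(eventStats), rownames(agg)))
  rd <- SummarizedExperiment::rowData(agg)
  inUniverse <- !is.na(rd$tad_id) & eventStats$included
  if (!any(inUniverse))
    stop("no TAD-assigned testable events; run the aggregation with segments")
  tad <- rd$tad_id[inUniverse]
  sig <- eventStats$significant[inUniverse]
  lfc <- eventStats$logFC[inUniverse]
  kind <- rd$kind[inUniverse]
  N <- sum(inUniverse)
  K <- sum(sig)

  tads <- sort(unique(tad))
  nEvents <- as.integer(table(factor(tad, levels = tads)))
  nSig <- as.integer(tapply(sig, factor(tad, levels = tads), sum))
  hyperP <- vapply(seq_along(tads), function(i)
    tadHypergeomTest(N, K, nEvents[i], nSig[i]), 0)
  act <- vapply(tads, function(td) {
    i <- tad == td
    tadActivation(lfc[i], kind[i])
  }, 0)

  segs <- tadRegions(agg)
  idx <- if (is.null(segs)) rep(NA_integer_, length(tads))
         else match(tads, names(segs))
  res <- data.frame(
    tad_id = tads,
    chrom = if (is.null(segs)) NA_character_
            else as.character(GenomicRanges::seqnames(segs))[idx],
    start = if (is.null(segs)) NA_integer_
            else GenomicRanges::start(segs)[idx] - 1L,
    end = if (is.null(segs)) NA_integer_
          else GenomicRanges::end(segs)[idx],
    n_events = nEvents, n_sig = nSig,
    hyper_p = hyperP, hyper_adj_p = bhAdjust(hyperP),
    activation = act,
    significant = hyperP < alphaTad & act >= activationMin,
    stringsAsFactors = FALSE)
  res <- res[order(res$hyper_p, res$tad_id), ]
  rownames(res) <- NULL

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    path <- file.path(outDir, paste0(contrast, "_TADiff.txt"))
    utils::write.table(res, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    ## nested event rows for the significant TADs
    if (any(res$significant)) {
      ev <- eventStats[inUniverse, , drop = FALSE]
      ev <- ev[ev$tad_id %in% res$tad_id[res$significant], , drop = FALSE]
      vals <- SummarizedExperiment::assay(agg, "scaled")[rownames(ev), ,
                                                         drop = FALSE]
      cat("\n# events of significant TADs\n", file = path, append = TRUE)
      suppressWarnings(utils::write.table(
        cbind(ev, as.data.frame(vals, check.names = FALSE)),
        path, sep = "\t", quote = FALSE, row.names = FALSE, append = TRUE))
    }
    sumPath <- file.path(outDir, "Summary_TADiff.txt")
    if (!file.exists(sumPath))
      writeLines("contrast\tn_TADs_tested\tn_significant", sumPath)
    cat(sprintf("%s\t%d\t%d\n", contrast, nrow(res), sum(res$significant)),
        file = sumPath, append = TRUE)
  }
  res
}

#' Per-TAD, per-sample mean event values
#'
#' Arithmetic mean over each TAD's events of the scaled values, per sample
#' (`NA` cells excluded pairwise); the TAD-level view used for clustering
#' and ordination.
#'
#' @param agg a [TADExperiment-class].
#' @return matrix TADs x samples, rownames = tad ids.
#' @export
tadSampleMeans <- function(agg) {
  rd <- SummarizedExperiment::rowData(agg)
  keep <- !is.na(rd$tad_id)
  if (!any(keep)) stop("no TAD-assigned events")
  v <- SummarizedExperiment::assay(agg, "scaled")[keep, , drop = FALSE]
  f <- factor(rd$tad_id[keep])
  num <- rowsum(ifelse(is.na(v), 0, v), f)
  den <- rowsum((!is.na(v)) * 1, f)
  out <- num / den
  out[den == 0] <- NA_real_
  out
}

#' Per-TAD mean absolute group difference
#'
#' For each TAD, the mean over its events of |group-1 mean - group-0 mean|;
#' the score behind the TAD-level clustering heatmaps.
#'
#' @param agg a [TADExperiment-class].
#' @param groups named 0/1 vector (names = sample ids).
#' @return named numeric vector, one score per TAD.
#' @export
tadAbsDiffMeans <- function(agg, groups) {
  groups <- groups[!is.na(groups)]
  rd <- SummarizedExperiment::rowData(agg)
  keep <- !is.na(rd$tad_id)
  if (!any(keep)) stop("no TAD-assigned events")
  v <- SummarizedExperiment::assay(agg, "scaled")[keep, , drop = FALSE]
  g0 <- intersect(colnames(v), names(groups)[groups == 0])
  g1 <- intersect(colnames(v), names(groups)[groups == 1])
  d <- abs(rowMeans(v[, g1, drop = FALSE], na.rm = TRUE) -
           rowMeans(v[, g0, drop = FALSE], na.rm = TRUE))
  out <- tapply(d, factor(rd$tad_id[keep]), mean, na.rm = TRUE)
  stats::setNames(as.numeric(out), names(out))
}
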