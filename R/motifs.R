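## Sequence extraction and PWM motif over-representation: a local,
## file-based equivalent of web-service motif enrichment (JASPAR-format
## PWMs + genome FASTA), using log-odds scanning on both strands and a
## one-sided Fisher test of hit frequencies.

#' Promoter windows of annotated genes
#'
#' `[TSS - upstream, TSS + downstream)` on each gene's annotated strand;
#' the regions scanned for expression events.
#'
#' @param gtf GTF path or imported `GRanges`.
#' @param upstream,downstream window extent in bases (defaults 1000 / 200).
#' @return `GRanges` with names = gene ids.
#' @export
promoterRanges <- function(gtf, upstream = 1000L, downstream = 200L) {
  if (is.character(gtf)) gtf <- rtracklayer::import(gtf, format = "gtf")
  sets <- .gtfFeatureSets(gtf, upstream, downstream)
  prom <- sets$promoter
  names(prom) <- prom$gene_id
  prom
}

#' Extract (merged) event sequences from a genome FASTA
#'
#' Point events are extended by `flank` bases on both sides; overlapping
#' extended intervals on one chromosome are merged (union) so each stretch
#' of sequence is extracted once. Intervals reaching past a contig end are
#' truncated with a warning. With `outDir` set, writes `seq_perTADs.fasta`
#' and `prepared sequences info.csv` (merged coordinates + constituent
#' event ids).
#'
#' Expression events should be passed as promoter windows
#' ([promoterRanges()]) rather than transcript bodies.
#'
#' @param events `GRanges` with names = event ids.
#' @param genome `DNAStringSet` or FASTA path.
#' @param flank extension in bases (default 50).
#' @param outDir optional output directory.
#' @return list with `sequences` (`DNAStringSet`, one per merged interval)
#'   and `info` (`data.frame`: `seq_id`, `chrom`, `start`, `end` in BED
#'   convention, `event_ids` joined with `";"`).
#' @export
extractSequences <- function(events, genome, flank = 50L, outDir = NULL) {
  stopifnot(flank >= 0, !is.null(names(events)))
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  ext <- GenomicRanges::granges(events)
  GenomicRanges::strand(ext) <- "*"
  ext <- GenomicRanges::resize(ext, GenomicRanges::width(ext) + 2L * flank,
                               fix = "center")
  GenomicRanges::start(ext) <- pmax(GenomicRanges::start(ext), 1L)
  merged <- GenomicRanges::reduce(ext)
  ov <- GenomicRanges::findOverlaps(merged, ext)
  members <- vapply(
    split(names(events)[S4Vectors::subjectHits(ov)],
          S4Vectors::queryHits(ov)),
    function(x) paste(sort(unique(x)), collapse = ";"), "")
  chrom <- as.character(GenomicRanges::seqnames(merged))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing))
    stop("chromosome(s) absent from the genome FASTA: ",
         paste(missing, collapse = ", "))
  ends <- GenomicRanges::end(merged)
  lens <- Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(ends > lens)) {
    warning(sum(ends > lens), " interval(s) truncated at contig end")
    ends <- pmin(ends, lens)
  }
  starts <- GenomicRanges::start(merged)
  seqs <- Biostrings::DNAStringSet(vapply(seq_along(merged), function(i)
    as.character(Biostrings::subseq(genome[[chrom[i]]],
                                    starts[i], ends[i])), ""))
  ids <- sprintf("%s:%d-%d", chrom, starts - 1L, ends)
  names(seqs) <- ids
  info <- data.frame(seq_id = ids, chrom = chrom, start = starts - 1L,
                     end = ends, event_ids = unname(members),
                     stringsAsFactors = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(seqs,
                                file.path(outDir, "seq_perTADs.fasta"))
    utils::write.csv(info,
                     file.path(outDir, "prepared sequences info.csv"),
                     row.names = FALSE)
  }
  list(sequences = seqs, info = info)
}

.BASES <- c("A", "C", "G", "T")

.pwmMatrix <- function(pwm) {
  m <- if (is.list(pwm)) pwm$matrix else pwm
  stopifnot(nrow(m) == 4L)
  if (is.null(rownames(m))) rownames(m) <- .BASES
  if (any(abs(colSums(m) - 1) > 1e-6))
    stop("PWM columns must sum to 1 (probabilities)")
  m[.BASES, , drop = FALSE]
}

#' Scan a sequence with a position weight matrix
#'
#' Computes the log2 odds score of the PWM against the background base
#' composition at every position of the sequence, on both strands (reverse
#' strand positions refer to the forward coordinate of the window start).
#' Windows containing `N` are skipped. Hits are positions whose score
#' reaches `thresholdFrac` of the motif's maximum achievable score.
#'
#' @param sequence a character string or `DNAString` over A/C/G/T/N.
#' @param pwm a PWM from [readJASPAR()] or a 4 x width probability matrix
#'   (rows A, C, G, T).
#' @param background base frequencies (A, C, G, T), default uniform.
#' @param thresholdFrac hit threshold as a fraction of the maximum score
#'   (default 0.8).
#' @return list with `max_score` (`NA` when the sequence is shorter than
#'   the motif), `threshold`, and `hits` (`data.frame`: `position`,
#'   `strand`, `score`).
#' @export
pwmScan <- function(sequence, pwm, background = rep(0.25, 4),
                    thresholdFrac = 0.8) {
  m <- .pwmMatrix(pwm)
  stopifnot(length(background) == 4L, all(background > 0),
            abs(sum(background) - 1) < 1e-6)
  lods <- log2(m / background)
  w <- ncol(m)
  s <- toupper(as.character(sequence))
  n <- nchar(s)
  maxScore <- sum(apply(lods, 2L, max))
  threshold <- thresholdFrac * maxScore
  if (n < w)
    return(list(max_score = NA_real_, threshold = threshold,
                hits = data.frame(position = integer(), strand = character(),
                                  score = numeric())))
  code <- match(strsplit(s, "", fixed = TRUE)[[1L]], .BASES)  # N -> NA
  scanStrand <- function(L) {
    npos <- n - w + 1L
    sc <- numeric(npos)
    for (j in seq_len(w))
      sc <- sc + L[cbind(code[seq_len(npos) + j - 1L], j)]
    sc                                             # NA where window has N
  }
  fwd <- scanStrand(lods)
  ## reverse strand: score the reverse complement motif on the forward text
  rcLods <- lods[4:1, rev(seq_len(w)), drop = FALSE]
  rev <- scanStrand(rcLods)
  pos <- seq_len(n - w + 1L)
  hits <- rbind(
    data.frame(position = pos, strand = "+", score = fwd),
    data.frame(position = pos, strand = "-", score = rev))
  hits <- hits[!is.na(hits$score), , drop = FALSE]
  maxObs <- if (nrow(hits)) max(hits$score) else NA_real_
  hits <- hits[hits$score >= threshold, , drop = FALSE]
  hits <- hits[order(hits$position, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  list(max_score = maxObs, threshold = threshold, hits = hits)
}

#' Motif over-representation between two sequence sets
#'
#' For each PWM, counts foreground and background sequences containing at
#' least one hit ([pwmScan()]) and tests foreground enrichment with a
#' one-sided Fisher exact test; BH adjustment across motifs.
#'
#' @param fgSeqs,bgSeqs `DNAStringSet` (or character vectors) of foreground
#'   and background sequences.
#' @param pwms named list of PWMs (see [readJASPAR()]).
#' @param thresholdFrac hit threshold, fraction of each motif's maximum
#'   score (default 0.8).
#' @param background base frequencies for the log-odds (default uniform).
#' @param outDir optional; writes `report MotifEA.txt`.
#' @return `data.frame` with `motif_id`, `fg_hits`, `fg_n`, `bg_hits`,
#'   `bg_n`, `p`, `adj_p`, sorted by `p`.
#' @export
motifEnrichment <- function(fgSeqs, bgSeqs, pwms, thresholdFrac = 0.8,
                            background = rep(0.25, 4), outDir = NULL) {
  stopifnot(length(fgSeqs) >= 1L, length(bgSeqs) >= 1L)
  hasHit <- function(seqs, pwm) vapply(as.character(seqs), function(s)
    nrow(pwmScan(s, pwm, background, thresholdFrac)$hits) > 0L, NA)
  rows <- lapply(names(pwms), function(id) {
    fg <- hasHit(fgSeqs, pwms[[id]])
    bg <- hasHit(bgSeqs, pwms[[id]])
    tab <- matrix(c(sum(fg), sum(!fg), sum(bg), sum(!bg)), 2L, 2L)
    data.frame(motif_id = id, fg_hits = sum(fg), fg_n = length(fg),
               bg_hits = sum(bg), bg_n = length(bg),
               p = stats::fisher.test(tab, alternative = "greater")$p.value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- bhAdjust(res$p)
  res <- res[order(res$p, res$motif_id), ]
  rownames(res) <- NULL
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(res, file.path(outDir, "report MotifEA.txt"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  res
}
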