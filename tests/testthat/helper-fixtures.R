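## In-code fixture builders (no stored data files).

## small OmicsLayer straight from vectors
makeLayer <- function(ids, chrom, start, end, values, kind = "freq",
                      source = "layer.txt") {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end))
  rownames(values) <- ids
  OmicsLayer(values, gr, kind = kind, source = source)
}

## write a tab-delimited omics table file
writeOmicsFile <- function(path, ids, chrom, start, end, values) {
  df <- data.frame(eventID = ids, chrom = chrom, start = start, end = end,
                   values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

## a TADExperiment built directly (bypasses files) from a scaled matrix
makeAgg <- function(values, tad_id,
                    kind = rep("freq", nrow(values)),
                    source = ifelse(kind == "freq", "meth.txt", "expr.txt"),
                    gene_id = rep("", nrow(values)),
                    gene_feature = rep("intergenic", nrow(values)),
                    chrom = rep("chr1", nrow(values)),
                    segments = NULL) {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("ev%04d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("S%03d", seq_len(ncol(values)))
  gr <- GenomicRanges::GRanges(chrom,
    IRanges::IRanges(seq_len(nrow(values)) * 10L, width = 2L))
  srcMap <- c("meth.txt" = "freq", "expr.txt" = "count")
  srcMap <- srcMap[unique(source)]
  TADExperiment(values, gr,
                S4Vectors::DataFrame(source = source, kind = kind,
                                     gene_id = gene_id,
                                     gene_feature = gene_feature,
                                     tad_id = tad_id),
                sourceMap = srcMap, segments = segments)
}

## a 10-gene toy annotation: explicit per-feature interval table (the
## oracle's view) plus the corresponding GTF file (the package's view)
toyAnnotation <- function(dir = withr::local_tempdir()) {
  set.seed(42)
  feats <- list(); gtf <- list()
  for (g in 1:10) {
    chrom <- if (g <= 6) "chr1" else "chr2"
    s <- g * 10000L
    e <- s + 4000L
    strand <- if (g %% 2) "+" else "-"
    gene <- sprintf("gene%02d", g)
    ex1 <- c(s, s + 1200L); ex2 <- c(e - 1000L, e)
    cds <- c(s + 200L, s + 900L)
    utr3 <- c(e - 300L, e)
    intron <- c(ex1[2L], ex2[1L])
    tss <- if (strand == "+") s else e
    prom <- if (strand == "+") c(tss - 1000L, tss + 200L)
            else c(tss - 200L, tss + 1000L)
    feats[[g]] <- data.frame(
      chrom = chrom,
      start = c(cds[1L], ex1[1L], ex2[1L], utr3[1L], intron[1L], prom[1L]),
      end   = c(cds[2L], ex1[2L], ex2[2L], utr3[2L], intron[2L], prom[2L]),
      gene = gene,
      feature = c("cds", "exon", "exon", "threeUTR", "intron", "promoter"),
      stringsAsFactors = FALSE)
    attrs <- sprintf('gene_id "%s"; transcript_id "%s.t";', gene, gene)
    gtf[[g]] <- data.frame(
      chrom = chrom, src = "toy",
      type = c("gene", "exon", "exon", "CDS", "three_prime_utr"),
      start = c(s, ex1[1L], ex2[1L], cds[1L], utr3[1L]) + 1L,
      end = c(e, ex1[2L], ex2[2L], cds[2L], utr3[2L]),
      score = ".", strand = strand, frame = ".", attrs = attrs,
      stringsAsFactors = FALSE)
  }
  gtfPath <- file.path(dir, "toy.gtf")
  write.table(do.call(rbind, gtf), gtfPath, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  list(features = do.call(rbind, feats), gtf = gtfPath)
}

## run the full pipeline on a generated bundle; returns everything
runPipeline <- function(bundle, outDir = NULL, config = runConfig()) {
  layers <- loadOmicsDir(bundle$freqDir, bundle$countsDir,
                         config$allowedChromosomes, verbose = FALSE)
  agg <- buildAggregatedTable(layers, readSegments(bundle$tads),
                              bundle$gtf, config, outDir = outDir,
                              verbose = FALSE)
  meta <- readSampleMeta(bundle$meta, config$minMarkerN, verbose = FALSE)
  ev <- eventDiffRun(agg, meta, "group", alpha = config$alphaEvent,
                     lfcMin = config$lfcMin, outDir = outDir)
  td <- tadDiffRun(agg, ev, "group", alphaTad = config$alphaTad,
                   activationMin = config$activationMin, outDir = outDir)
  list(agg = agg, meta = meta, events = ev, tads = td)
}
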