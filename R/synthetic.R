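## Synthetic multi-omics bundle generator with planted ground truth.
## Emulates the structure of a methylation + expression cohort clustered in
## TADs: non-overlapping domains of 0.2-1.5 Mb across chr1-chr22, events
## placed inside domains, a toy GTF with ~1 gene per 3 events, bimodal Beta
## methylation values and overdispersed negative-binomial counts, a binary
## contrast, and an optional mean shift planted in a subset of TADs
## (positive on the expression scale, sign-flipped for methylation to mimic
## the inverse coupling of promoter methylation and transcription).

#' Generate a complete synthetic input bundle
#'
#' Writes, under `outDir`: `freq/methylation.txt` (beta values x100),
#' `counts/expression.txt` (negative-binomial counts), `tads.bed`,
#' `genes.gtf`, `metadata.tsv` (one binary contrast `group`) and
#' `truth.json` (the planted TADs/events and the parameters). Planted TADs
#' shift all their events by `effect` units on the common \[0,100\] scale
#' in group-1 samples: counts are multiplied so the shift survives the
#' log scaling, methylation betas are shifted down (saturating at 0/1 as
#' real betas do). Everything derives from `seed`; the same seed
#' reproduces the bundle byte for byte.
#'
#' @param outDir directory to write the bundle into.
#' @param nTads number of TADs (default 200).
#' @param eventsPerTad events per TAD (default 20).
#' @param exprFraction fraction of events that are expression transcripts
#'   (default 0.2, the approximate transcript share of a joint
#'   methylation + RNA-seq cohort).
#' @param nSamplesPerGroup samples per group (default 20).
#' @param nPlantedTads TADs carrying the planted effect (default 5).
#' @param effect planted shift in \[0,100\]-scale units (default 30;
#'   0 gives a null bundle).
#' @param seed RNG seed.
#' @return Invisibly, a list with `dir`, the file paths, and `truth`
#'   (`planted_tads`, `planted_events`, `effect`, `n_samples_per_group`,
#'   `seed`).
#' @export
generateBundle <- function(outDir, nTads = 200L, eventsPerTad = 20L,
                           exprFraction = 0.2, nSamplesPerGroup = 20L,
                           nPlantedTads = 5L, effect = 30, seed = 1L) {
  stopifnot(nTads >= 1L, eventsPerTad >= 1L, exprFraction >= 0,
            exprFraction <= 1, nSamplesPerGroup >= 2L,
            nPlantedTads >= 0L, nPlantedTads <= nTads, effect >= 0)
  set.seed(seed)
  dir.create(file.path(outDir, "freq"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "counts"), recursive = TRUE,
             showWarnings = FALSE)

  nS <- 2L * nSamplesPerGroup
  samples <- sprintf("S%03d", seq_len(nS))
  group <- rep(0:1, each = nSamplesPerGroup)

  ## --- TADs: tile chromosomes with 0.2-1.5 Mb domains + 50 kb gaps
  chroms <- paste0("chr", rep(1:22, length.out = nTads))
  tadW <- as.integer(round(runif(nTads, 2e5, 1.5e6)))
  tadStart <- integer(nTads)
  offs <- stats::setNames(rep(1e5, 22), paste0("chr", 1:22))
  for (i in seq_len(nTads)) {
    tadStart[i] <- as.integer(offs[chroms[i]])
    offs[chroms[i]] <- offs[chroms[i]] + tadW[i] + 5e4
  }
  tadId <- sprintf("TAD%04d", seq_len(nTads))
  bed <- data.frame(chroms, tadStart, tadStart + tadW, tadId)
  tadBed <- file.path(outDir, "tads.bed")
  utils::write.table(bed, tadBed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  ## --- events: per TAD, exprFraction transcripts tied to genes, the rest
  ## CpG point events
  nExpr <- round(eventsPerTad * exprFraction)
  nMeth <- eventsPerTad - nExpr
  nGenes <- max(1L, ceiling(eventsPerTad / 3))
  ev <- list(); gtf <- list()
  for (i in seq_len(nTads)) {
    lo <- tadStart[i]; hi <- tadStart[i] + tadW[i]
    gStart <- sort(as.integer(round(runif(nGenes, lo + 2000,
                                          hi - 32000))))
    gW <- as.integer(round(runif(nGenes, 8000, 30000)))
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    gid <- sprintf("g%04d_%d", i, seq_len(nGenes))
    for (j in seq_len(nGenes)) {
      s <- gStart[j]; e <- s + gW[j]
      ex1 <- c(s, s + as.integer(gW[j] * 0.3))
      ex2 <- c(e - as.integer(gW[j] * 0.25), e)
      attrs <- sprintf(
        'gene_id "%s"; transcript_id "%s.t1"; gene_name "%s";',
        gid[j], gid[j], gid[j])
      gtf[[length(gtf) + 1L]] <- data.frame(
        chrom = chroms[i], src = "synthetic",
        type = c("gene", "exon", "exon", "CDS"),
        start = c(s, ex1[1L], ex2[1L], ex1[1L] + 10L) + 1L,
        end = c(e, ex1[2L], ex2[2L], ex1[2L]),
        score = ".", strand = strand[j], frame = ".",
        attrs = attrs, stringsAsFactors = FALSE)
    }
    if (nExpr > 0L) {
      ge <- sample(nGenes, nExpr, replace = nExpr > nGenes)
      ev[[length(ev) + 1L]] <- data.frame(
        eventID = sprintf("tx_%04d_%d", i, seq_len(nExpr)),
        chrom = chroms[i], start = gStart[ge],
        end = gStart[ge] + gW[ge], kind = "count", tad = tadId[i],
        stringsAsFactors = FALSE)
    }
    if (nMeth > 0L) {
      pos <- as.integer(round(runif(nMeth, lo, hi - 2)))
      ev[[length(ev) + 1L]] <- data.frame(
        eventID = sprintf("cg_%04d_%d", i, seq_len(nMeth)),
        chrom = chroms[i], start = pos, end = pos + 2L,
        kind = "freq", tad = tadId[i], stringsAsFactors = FALSE)
    }
  }
  ev <- do.call(rbind, ev)
  gtf <- do.call(rbind, gtf)
  gtfPath <- file.path(outDir, "genes.gtf")
  utils::write.table(gtf, gtfPath, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  planted <- sort(sample(tadId, nPlantedTads))
  isPlanted <- ev$tad %in% planted

  ## --- methylation: per-event bimodal Beta baseline, shared by all
  ## samples; planted events shift group-1 betas DOWN by effect/100
  meth <- ev[ev$kind == "freq", , drop = FALSE]
  mHigh <- sample(c(TRUE, FALSE), nrow(meth), replace = TRUE)
  a <- ifelse(mHigh, 5, 2); b <- ifelse(mHigh, 2, 5)
  mVals <- matrix(rbeta(nrow(meth) * nS, a, b), nrow(meth), nS)
  pm <- meth$eventID %in% ev$eventID[isPlanted]
  if (effect > 0 && any(pm)) {
    g1 <- which(group == 1L)
    mVals[pm, g1] <- pmin(pmax(mVals[pm, g1, drop = FALSE] -
                                 effect / 100, 0), 1)
  }
  methTab <- data.frame(meth[, c("eventID", "chrom", "start", "end")],
                        round(mVals * 100, 4), check.names = FALSE)
  colnames(methTab)[-(1:4)] <- samples
  methPath <- file.path(outDir, "freq", "methylation.txt")
  utils::write.table(methTab, methPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## --- expression: NB counts, dispersion 0.2 (size 5); planted events
  ## multiply the group-1 mean so the shift is ~`effect` after log scaling
  expr <- ev[ev$kind == "count", , drop = FALSE]
  cPath <- file.path(outDir, "counts", "expression.txt")
  if (nrow(expr)) {
    muMax <- 5000
    pe <- expr$eventID %in% ev$eventID[isPlanted]
    fct <- exp(effect * log1p(muMax) / 100)
    mu <- exp(runif(nrow(expr), log(5), log(muMax)))
    mu[pe] <- exp(runif(sum(pe), log(5), log(muMax) - log(fct)))
    muMat <- matrix(mu, nrow(expr), nS)
    if (effect > 0 && any(pe))
      muMat[pe, group == 1L] <- muMat[pe, group == 1L, drop = FALSE] * fct
    cVals <- matrix(rnbinom(nrow(expr) * nS, mu = muMat, size = 5),
                    nrow(expr), nS)
    cTab <- data.frame(expr[, c("eventID", "chrom", "start", "end")],
                       cVals, check.names = FALSE)
    colnames(cTab)[-(1:4)] <- samples
    utils::write.table(cTab, cPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }

  metaPath <- file.path(outDir, "metadata.tsv")
  utils::write.table(data.frame(sample_id = samples, group = group),
                     metaPath, sep = "\t", quote = FALSE, row.names = FALSE)

  truth <- list(planted_tads = planted,
                planted_events = sort(ev$eventID[isPlanted]),
                effect = effect,
                n_samples_per_group = nSamplesPerGroup,
                seed = seed)
  jsonlite::write_json(truth, file.path(outDir, "truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(dir = outDir, freqDir = file.path(outDir, "freq"),
                 countsDir = file.path(outDir, "counts"),
                 tads = tadBed, gtf = gtfPath, meta = metaPath,
                 truth = truth))
}

#' Score planted-truth recovery of TAD calls
#'
#' @param truth truth list from [generateBundle()] (or parsed
#'   `truth.json`).
#' @param tadStats result of [tadDiffRun()].
#' @return list with `sensitivity` (fraction of planted TADs called
#'   significant) and `false_calls` (significant TADs that were not
#'   planted).
#' @export
scoreRecovery <- function(truth, tadStats) {
  called <- tadStats$tad_id[tadStats$significant]
  planted <- unlist(truth$planted_tads)
  list(sensitivity = if (length(planted))
         mean(planted %in% called) else NA_real_,
       false_calls = length(setdiff(called, planted)))
}
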