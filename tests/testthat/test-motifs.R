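uniformPwm <- function(w) matrix(0.25, 4, w,
                                 dimnames = list(c("A", "C", "G", "T")))

test_that("sequence extraction merges overlapping flanks per chromosome", {
  genome <- Biostrings::DNAStringSet(c(
    chr1 = paste(rep("ACGT", 100), collapse = ""),
    chr2 = paste(rep("GGCC", 50), collapse = "")))
  ev <- GenomicRanges::GRanges(c("chr1", "chr1", "chr2"),
    IRanges::IRanges(c(101, 141, 21), c(101, 141, 21)))
  names(ev) <- c("cgA", "cgB", "cgC")
  out <- extractSequences(ev, genome, flank = 50)
  expect_equal(nrow(out$info), 2)              # chr1 events merged
  chr1row <- out$info[out$info$chrom == "chr1", ]
  expect_equal(chr1row$start, 50)              # [50, 141) BED convention
  expect_equal(chr1row$end, 191)
  expect_equal(chr1row$event_ids, "cgA;cgB")
  expect_equal(nchar(as.character(out$sequences[[which(
    out$info$chrom == "chr1")]])), 141)
  ## single event: one record of length 2*flank + event length
  single <- extractSequences(ev[1], genome, flank = 10)
  expect_equal(nchar(as.character(single$sequences[[1]])), 21)
  ## truncation at contig end warns
  evEnd <- GenomicRanges::GRanges("chr2", IRanges::IRanges(195, 195))
  names(evEnd) <- "cgZ"
  expect_warning(tr <- extractSequences(evEnd, genome, flank = 50),
                 "truncated")
  expect_equal(tr$info$end, 200)
})

test_that("promoter windows follow the annotated strand", {
  toy <- toyAnnotation(withr::local_tempdir())
  prom <- promoterRanges(toy$gtf, upstream = 1000, downstream = 200)
  expect_equal(length(prom), 10)
  ## gene01 is on +: promoter ends 200 bases into the gene
  g1 <- prom["gene01"]
  expect_equal(GenomicRanges::width(g1), 1200)
  expect_equal(GenomicRanges::end(g1), 10000 + 200)  # TSS at 10000 (BED)
})

test_that("PWM scanning gives zero log-odds for the uninformative motif", {
  scan <- pwmScan("ACGTACGT", uniformPwm(3), thresholdFrac = 0)
  expect_equal(scan$max_score, 0)
  expect_true(all(scan$hits$score == 0))
  expect_equal(nrow(scan$hits), 2 * (8 - 3 + 1))  # both strands
})

test_that("PWM scores match hand computation at every position", {
  ## width-2 motif on a 6-mer, uniform background
  m <- matrix(c(0.7, 0.1, 0.1, 0.1,
                0.1, 0.1, 0.7, 0.1), 4, 2,
              dimnames = list(c("A", "C", "G", "T")))
  s <- "AGCAGT"
  scan <- pwmScan(s, m, thresholdFrac = -Inf)
  base <- strsplit(s, "")[[1]]
  fwd <- vapply(1:5, function(i)
    log2(m[base[i], 1] / 0.25) + log2(m[base[i + 1], 2] / 0.25), 0)
  got <- scan$hits
  expect_equal(got$score[got$strand == "+"], fwd)
  ## reverse strand equals scoring the reverse complement text forward
  rc <- c(A = "T", C = "G", G = "C", T = "A")
  rcs <- paste(rev(rc[base]), collapse = "")
  rcBase <- strsplit(rcs, "")[[1]]
  rev <- vapply(1:5, function(i)
    log2(m[rcBase[i], 1] / 0.25) + log2(m[rcBase[i + 1], 2] / 0.25), 0)
  expect_equal(sort(got$score[got$strand == "-"]), sort(rev))
})

test_that("scan scores are strand-symmetric and robust to N padding", {
  set.seed(31)
  m <- matrix(rgamma(4 * 5, 1), 4, 5,
              dimnames = list(c("A", "C", "G", "T")))
  m <- sweep(m, 2, colSums(m), "/")
  s <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
             collapse = "")
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(s)))
  expect_equal(pwmScan(s, m)$max_score, pwmScan(rc, m)$max_score)
  padded <- paste0("NNN", s, "NN")
  expect_equal(pwmScan(padded, m)$max_score, pwmScan(s, m)$max_score)
  ## too-short sequence flagged as undefined
  expect_true(is.na(pwmScan("AC", m)$max_score))
})

test_that("motif enrichment reproduces the exact Fisher tail", {
  ## foreground all carry a sharp AAAA motif, background never:
  ## p = 1/C(10,5)
  m <- matrix(0.01 / 3, 4, 4, dimnames = list(c("A", "C", "G", "T")))
  m["A", ] <- 0.99
  pwms <- list(M = m)
  fg <- rep("GGAAAAGG", 5)
  bg <- rep("GGGGGGGG", 5)
  res <- motifEnrichment(fg, bg, pwms, thresholdFrac = 0.8)
  expect_equal(res$fg_hits, 5)
  expect_equal(res$bg_hits, 0)
  expect_equal(res$p, 1 / choose(10, 5), tolerance = 1e-12)
  expect_equal(res$p, hyperUpperEnum(10, 5, 5, 5), tolerance = 1e-12)
  ## identical sets: one-sided p >= 0.5
  res2 <- motifEnrichment(fg, fg, pwms)
  expect_gte(res2$p, 0.5)
  ## unattainable threshold: no hits anywhere, p = 1
  res3 <- motifEnrichment(fg, bg, pwms, thresholdFrac = 1e9)
  expect_equal(res3$fg_hits, 0)
  expect_equal(res3$p, 1)
})

test_that("enrichment p-values are super-uniform under a null background", {
  set.seed(41)
  m <- matrix(rgamma(4 * 6, 1), 4, 6,
              dimnames = list(c("A", "C", "G", "T")))
  m <- sweep(m, 2, colSums(m), "/")
  rseq <- function(n, len) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
  ps <- vapply(1:30, function(i)
    motifEnrichment(rseq(8, 40), rseq(8, 40), list(M = m))$p, 0)
  ## super-uniform: P(p <= a) <= a; allow Monte-Carlo slack
  expect_lte(mean(ps <= 0.1), 0.25)
  expect_gte(mean(ps), 0.35)
})
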