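## Independent reference implementations used to check the package's
## statistics: plain enumeration / loop code, no shared internals.

## upper-tail hypergeometric by direct pmf enumeration with choose()
hyperUpperEnum <- function(N, K, n, k) {
  hi <- min(K, n)
  if (k > hi) return(0)
  i <- k:hi
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

## Benjamini-Hochberg by sort / cummin / unsort
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

## naive all-pairs interval assignment on BED half-open coordinates:
## largest overlap wins, ties to the lexicographically smallest id
naiveAssign <- function(ev, seg) {
  vapply(seq_len(nrow(ev)), function(i) {
    ovl <- pmin(ev$end[i], seg$end) - pmax(ev$start[i], seg$start)
    ovl[seg$chrom != ev$chrom[i]] <- 0
    hit <- which(ovl > 0)
    if (!length(hit)) return(NA_character_)
    hit <- hit[ovl[hit] == max(ovl[hit])]
    sort(seg$id[hit])[1L]
  }, "")
}

## naive gene annotation against an explicit feature table
## (columns chrom, start, end, gene, feature; BED half-open)
naiveAnnotate <- function(ev, feat,
                          precedence = c("cds", "exon", "threeUTR",
                                         "fiveUTR", "intron", "promoter")) {
  lapply(seq_len(nrow(ev)), function(i) {
    ovl <- pmin(ev$end[i], feat$end) - pmax(ev$start[i], feat$start)
    hit <- which(ovl > 0 & feat$chrom == ev$chrom[i])
    if (!length(hit))
      return(list(gene_id = "", gene_feature = "intergenic"))
    feats <- feat$feature[hit]
    best <- precedence[min(match(feats, precedence))]
    list(gene_id = paste(sort(unique(feat$gene[hit])), collapse = ";"),
         gene_feature = best)
  })
}

## ordinary (unmoderated) two-sample pooled t, straight loop
pooledTLoop <- function(x, g0, g1) {
  t(vapply(seq_len(nrow(x)), function(i) {
    a <- x[i, g0]; b <- x[i, g1]
    a <- a[!is.na(a)]; b <- b[!is.na(b)]
    s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
      (length(a) + length(b) - 2)
    tt <- (mean(b) - mean(a)) /
      sqrt(s2 * (1 / length(a) + 1 / length(b)))
    c(logFC = mean(b) - mean(a), s2 = s2, t = tt)
  }, c(logFC = 0, s2 = 0, t = 0)))
}
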