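## Per-event two-group differential analysis with empirical-Bayes variance
## shrinkage (moderated t), written for the two-group special case on the
## common [0,100] scale.

#' Two-group summary statistics per event
#'
#' For every event (row) computes the difference of group means
#' (`logFC = mean(group1) - mean(group0)` on the \[0,100\] scale), the
#' overall mean (`AveExpr`), the pooled within-group variance `s2` with
#' `df = n0 + n1 - 2` residual degrees of freedom, and the per-group counts
#' of non-missing samples. `NA` cells are excluded pairwise; events with
#' fewer than two usable samples in either group are flagged
#' (`included = FALSE`, statistics `NA`).
#'
#' @param values numeric matrix, events x samples.
#' @param groups named 0/1 vector (names = sample ids); samples not named
#'   are ignored.
#' @return `data.frame` with columns `logFC`, `AveExpr`, `s2`, `df`, `n0`,
#'   `n1`, `included`, rownames = event ids.
#' @export
fitTwoGroup <- function(values, groups) {
  groups <- groups[!is.na(groups)]
  if (!all(groups %in% c(0, 1)))
    stop("groups must be coded 0/1")
  g0 <- intersect(colnames(values), names(groups)[groups == 0])
  g1 <- intersect(colnames(values), names(groups)[groups == 1])
  if (length(g0) < 2L || length(g1) < 2L)
    stop("need >= 2 samples per group (got ",
         length(g0), " and ", length(g1), ")")
  grpStats <- function(cols) {
    x <- values[, cols, drop = FALSE]
    n <- rowSums(!is.na(x))
    m <- rowMeans(x, na.rm = TRUE)
    ss <- rowSums((x - m)^2, na.rm = TRUE)
    list(n = n, mean = m, ss = ss)
  }
  a <- grpStats(g0)
  b <- grpStats(g1)
  df <- a$n + b$n - 2L
  included <- a$n >= 2L & b$n >= 2L
  s2 <- ifelse(included, (a$ss + b$ss) / pmax(df, 1L), NA_real_)
  logFC <- ifelse(included, b$mean - a$mean, NA_real_)
  ave <- rowMeans(values[, c(g0, g1), drop = FALSE], na.rm = TRUE)
  data.frame(logFC = logFC, AveExpr = ave, s2 = s2,
             df = ifelse(included, df, NA_integer_),
             n0 = a$n, n1 = b$n, included = included,
             row.names = rownames(values))
}

## inverse of the trigamma function by Newton iteration
.trigammaInverse <- function(y, tol = 1e-8, maxIter = 50L) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))       # trigamma(x) ~ 1/x^2 for small x
  if (y < 1e-6) return(1 / y)            # trigamma(x) ~ 1/x for large x
  x <- 0.5 + 1 / y
  for (i in seq_len(maxIter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2L)
    x <- x + dif
    if (abs(dif) / x < tol) break
  }
  x
}

#' Estimate the empirical-Bayes variance prior
#'
#' Moment estimator of the scaled-inverse-chi-squared prior
#' (`d0` prior degrees of freedom, `s0_2` prior variance) from per-event
#' sample variances, using the log-variance representation:
#' `e_g = ln(s2_g) - digamma(df_g/2) + ln(df_g/2)` has mean
#' `ln(s0^2) - digamma(d0/2) + ln(d0/2)` and excess variance
#' `trigamma(d0/2)` beyond `trigamma(df_g/2)`; `d0` is recovered through the
#' inverse trigamma (Newton iteration, tolerance 1e-8). A non-positive
#' excess yields `d0 = Inf` (no event-to-event variance heterogeneity
#' beyond sampling noise) with `s0_2 = mean(s2)`.
#'
#' @param s2 per-event pooled variances.
#' @param df per-event residual degrees of freedom.
#' @return list with `d0` and `s0_2`.
#' @export
estimateModeration <- function(s2, df) {
  ok <- !is.na(s2) & !is.na(df) & df >= 1L
  s2 <- s2[ok]; df <- df[ok]
  if (all(s2 == 0))
    stop("all residual variances are zero; filter constant events first")
  pos <- s2 > 0
  s2 <- s2[pos]; df <- df[pos]
  if (length(s2) < 10L)
    stop("need >= 10 events with positive variance and df >= 1")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  G <- length(e)
  excess <- mean((e - ebar)^2 * G / (G - 1) - trigamma(df / 2))
  if (excess <= 0) {
    ## no excess dispersion: the infinite-prior limit; the prior variance
    ## is then the plain mean of the observed variances (the bias term
    ## digamma(d0/2) - log(d0/2) vanishes as d0 grows)
    list(d0 = Inf, s0_2 = mean(s2))
  } else {
    d0 <- 2 * .trigammaInverse(excess)
    list(d0 = d0, s0_2 = exp(ebar + digamma(d0 / 2) - log(d0 / 2)))
  }
}

#' Moderated t statistics from fitted group statistics
#'
#' Shrinks each event's variance toward the prior,
#' `s~2 = (d0 * s0^2 + df * s2) / (d0 + df)` (equal to `s0^2` when
#' `d0 = Inf`), forms `t = logFC / sqrt(s~2 * (1/n0 + 1/n1))` and a
#' two-sided p-value on `d0 + df` degrees of freedom (standard normal when
#' infinite). As `d0 -> 0` the ordinary pooled two-sample t is recovered.
#'
#' @param fit `data.frame` from [fitTwoGroup()].
#' @param params list with `d0`, `s0_2` (see [estimateModeration()]).
#' @return `fit` with added columns `s2_post`, `t`, `P.Value`, `df_total`.
#' @export
moderateStats <- function(fit, params) {
  stopifnot(params$d0 >= 0, params$s0_2 > 0)
  d0 <- params$d0
  s2p <- if (is.infinite(d0)) rep(params$s0_2, nrow(fit))
         else (d0 * params$s0_2 + fit$df * fit$s2) / (d0 + fit$df)
  se <- sqrt(s2p * (1 / fit$n0 + 1 / fit$n1))
  t <- fit$logFC / se
  dfTot <- d0 + fit$df
  p <- 2 * stats::pt(-abs(t), df = dfTot)
  fit$s2_post <- ifelse(fit$included, s2p, NA_real_)
  fit$t <- ifelse(fit$included, t, NA_real_)
  fit$df_total <- ifelse(fit$included, dfTot, NA_real_)
  fit$P.Value <- ifelse(fit$included, p, NA_real_)
  fit
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment; output is aligned with the
#' input order. `NA` entries propagate as `NA` and do not count toward the
#' number of tests.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return adjusted p-values, same length and order.
#' @export
bhAdjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0,1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Per-event differential analysis for one contrast
#'
#' Runs [fitTwoGroup()], [estimateModeration()], [moderateStats()] and
#' [bhAdjust()] on the aggregated table for one binary metadata contrast,
#' and flags events significant when `adj.P.Val < alpha` and
#' `|logFC| >= lfcMin`. With `outDir` set, writes
#' `<contrast>_evenDiff.txt` (annotation + statistics + per-sample values)
#' and appends a line to `Summary_evenDiff.txt`.
#'
#' @param agg a [TADExperiment-class].
#' @param meta metadata data.frame from [readSampleMeta()].
#' @param contrast name of the metadata column to test.
#' @param alpha adjusted-p threshold (default 0.01).
#' @param lfcMin minimum |logFC| on the \[0,100\] scale (default 2).
#' @param outDir optional output directory.
#' @return `data.frame` of per-event statistics (annotation columns,
#'   `logFC`, `AveExpr`, `t`, `P.Value`, `adj.P.Val`, `significant`),
#'   rownames = event ids. Events with too few usable samples carry `NA`
#'   statistics and `significant = FALSE`.
#' @export
eventDiffRun <- function(agg, meta, contrast, alpha = 0.01, lfcMin = 2,
                         outDir = NULL) {
  if (!contrast %in% colnames(meta))
    stop("contrast '", contrast, "' not present in the metadata")
  groups <- stats::setNames(meta[[contrast]], rownames(meta))
  values <- SummarizedExperiment::assay(agg, "scaled")
  fit <- fitTwoGroup(values, groups)
  params <- estimateModeration(fit$s2[fit$included], fit$df[fit$included])
  fit <- moderateStats(fit, params)
  fit$adj.P.Val <- bhAdjust(fit$P.Value)
  fit$significant <- !is.na(fit$adj.P.Val) &
    fit$adj.P.Val < alpha & abs(fit$logFC) >= lfcMin
  rd <- SummarizedExperiment::rowData(agg)
  bed <- .grangesToBed(SummarizedExperiment::rowRanges(agg))
  res <- cbind(
    data.frame(eventID = rownames(agg), chromosome = bed$chrom,
               start = bed$start, end = bed$end,
               GeneID = rd$gene_id, GeneFunction = rd$gene_feature,
               tad_id = ifelse(is.na(rd$tad_id), "", rd$tad_id),
               source = rd$source, kind = rd$kind,
               stringsAsFactors = FALSE),
    fit[, c("logFC", "AveExpr", "t", "P.Value", "adj.P.Val",
            "s2", "df", "n0", "n1", "included", "significant")])
  rownames(res) <- rownames(agg)
  attr(res, "moderation") <- params
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    full <- cbind(res, as.data.frame(values, check.names = FALSE))
    utils::write.table(full,
                       file.path(outDir, paste0(contrast, "_evenDiff.txt")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    sumPath <- file.path(outDir, "Summary_evenDiff.txt")
    if (!file.exists(sumPath))
      writeLines("contrast\tn_events_tested\tn_significant", sumPath)
    cat(sprintf("%s\t%d\t%d\n", contrast, sum(fit$included),
                sum(res$significant)),
        file = sumPath, append = TRUE)
  }
  res
}
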