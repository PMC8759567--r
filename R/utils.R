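## internal helpers shared across modules

.msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(...)
  invisible(NULL)
}

#' Default run configuration
#'
#' Returns the configuration list used across the pipeline. Any entry can be
#' overridden via `...`; unknown keys are rejected so typos fail loudly. The
#' list round-trips through YAML ([readRunConfig()] / [writeRunConfig()]).
#'
#' @param ... named overrides of the defaults.
#' @return A named list with entries:
#' \describe{
#'   \item{allowedChromosomes}{chromosomes retained on load (default chr1-chr22).}
#'   \item{sampleMode}{`"intersect"` (samples present in every layer) or
#'     `"union"` (all samples; absent cells become `NA` and are excluded
#'     pairwise from statistics).}
#'   \item{minMarkerN}{binary metadata markers present in fewer samples than
#'     this are dropped (default 5).}
#'   \item{betaAutoscale}{multiply a frequency layer by 100 when its maximum
#'     is <= 1 (methylation beta dialect).}
#'   \item{reverseFeatures}{gene features whose methylation values are
#'     complemented by [reverseMethylation()].}
#'   \item{alphaEvent, lfcMin}{event significance: BH-adjusted p < alphaEvent
#'     and |logFC| >= lfcMin (defaults 0.01 and 2).}
#'   \item{alphaTad, activationMin}{TAD significance: hypergeometric
#'     p < alphaTad and activation >= activationMin (defaults 0.01 and 2).}
#'   \item{flank}{bases added on both sides of point events before sequence
#'     extraction (default 50).}
#'   \item{promoterUp, promoterDown}{promoter window around the TSS used for
#'     expression events (defaults 1000 and 200).}
#'   \item{pwmThreshold}{fraction of a motif's maximum log-odds score that
#'     counts as a hit (default 0.8).}
#'   \item{seed}{RNG seed echoed into logs.}
#' }
#' @export
#' @examples
#' cfg <- runConfig(sampleMode = "union")
#' cfg$minMarkerN
runConfig <- function(...) {
  cfg <- list(
    allowedChromosomes = paste0("chr", 1:22),
    sampleMode         = "intersect",
    minMarkerN         = 5L,
    betaAutoscale      = TRUE,
    reverseFeatures    = c("promoter", "intergenic"),
    alphaEvent         = 0.01,
    lfcMin             = 2,
    alphaTad           = 0.01,
    activationMin      = 2,
    flank              = 50L,
    promoterUp         = 1000L,
    promoterDown       = 200L,
    pwmThreshold       = 0.8,
    seed               = 1L
  )
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad))
      stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
    cfg[names(dots)] <- dots
  }
  cfg
}

#' @rdname runConfig
#' @param path YAML file path.
#' @export
readRunConfig <- function(path) {
  do.call(runConfig, yaml::read_yaml(path))
}

#' @rdname runConfig
#' @param config a configuration list from [runConfig()].
#' @export
writeRunConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

## BED half-open [start, end) -> GRanges (1-based closed) and back
.bedToGRanges <- function(chrom, start, end, names = NULL) {
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  if (!is.null(names)) names(gr) <- names
  gr
}

.grangesToBed <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end   = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

.stopifnotScalarCount <- function(x, nm) {
  if (length(x) != 1L || is.na(x) || x < 0 || x != round(x))
    stop(nm, " must be a single non-negative integer")
  invisible(as.integer(x))
}
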