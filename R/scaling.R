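#' Scale expression counts to the common \[0,100\] range
#'
#' Per sample (column) j the transform is
#' \deqn{x_{ij} = \ln(1 + c_{ij}) \cdot 100 / \max_i \ln(1 + c_{ij}),}
#' i.e. a log transform followed by division by the column maximum so the
#' most expressed event in each sample sits at 100. A column whose maximum
#' is 0 (all zero counts) stays all-zero. `NA` cells (samples absent from
#' the layer) are ignored in the maximum and preserved.
#'
#' The `log1p` offset makes the transform defined at zero counts, which are
#' pervasive in real expression data; it is the package's one deliberate
#' change to the plain log scaling.
#'
#' @param values non-negative numeric matrix (events x samples); NA allowed.
#' @return Matrix of the same shape with all finite values in \[0,100\].
#' @export
#' @examples
#' scaleCounts(cbind(c(exp(1) - 1, exp(2) - 1, exp(4) - 1)))  # 25, 50, 100
scaleCounts <- function(values) {
  values <- as.matrix(values)
  vv <- values[!is.na(values)]
  if (any(!is.finite(vv)) || any(vv < 0))
    stop("counts must be finite and non-negative")
  lg <- log1p(values)
  mx <- suppressWarnings(apply(lg, 2L, max, na.rm = TRUE))
  mx[!is.finite(mx) | mx <= 0] <- 1       # all-zero / all-NA column -> stays 0
  sweep(lg, 2L, mx, "/") * 100
}

#' Clamp / rescale frequency values to \[0,100\]
#'
#' Frequency layers (methylation beta x100, mutation VAF x100) are expected
#' on \[0,100\] already. When `betaAutoscale` is on and the whole matrix
#' maximum is <= 1 the layer is treated as raw beta values and multiplied
#' by 100. Values outside \[0,100\] are clamped, with one warning giving
#' the count.
#'
#' @param values numeric matrix; NA allowed.
#' @param betaAutoscale detect the \[0,1\] beta dialect and rescale.
#' @return Matrix with all finite values in \[0,100\].
#' @export
scaleFreq <- function(values, betaAutoscale = TRUE) {
  values <- as.matrix(values)
  if (any(!is.finite(values[!is.na(values)])))
    stop("frequency values must be finite")
  if (isTRUE(betaAutoscale) &&
      all(is.na(values) | values <= 1) && any(values > 0, na.rm = TRUE))
    values <- values * 100
  nClamp <- sum(values < 0 | values > 100, na.rm = TRUE)
  if (nClamp > 0L)
    warning(nClamp, " frequency value(s) outside [0,100] were clamped")
  values[values < 0] <- 0
  values[values > 100] <- 100
  values
}

#' Harmonise the sample sets of several omics layers
#'
#' `mode = "intersect"` keeps only samples present in every layer (samples
#' with missing data are excluded); `mode = "union"` keeps every sample seen
#' in any layer and fills absent cells with `NA`, which downstream
#' statistics exclude pairwise per event. Either way all layers end up with
#' identical sample columns in identical order.
#'
#' @param layers list of [OmicsLayer-class].
#' @param mode `"intersect"` or `"union"`.
#' @return List of layers with aligned columns.
#' @export
harmonizeSamples <- function(layers, mode = c("intersect", "union")) {
  mode <- match.arg(mode)
  stopifnot(length(layers) >= 1L)
  sampleSets <- lapply(layers, colnames)
  keep <- if (mode == "intersect") Reduce(intersect, sampleSets)
          else Reduce(union, sampleSets)
  if (!length(keep))
    stop("no samples shared by all layers under intersect mode")
  keep <- sort(keep)
  lapply(layers, function(layer) {
    have <- intersect(keep, colnames(layer))
    out <- layer[, have]
    if (length(have) < length(keep)) {
      v <- SummarizedExperiment::assay(out, "values")
      full <- matrix(NA_real_, nrow(v), length(keep),
                     dimnames = list(rownames(v), keep))
      full[, have] <- v
      out <- OmicsLayer(full, SummarizedExperiment::rowRanges(out),
                        kind = layer@kind, source = layer@source)
    } else {
      out <- out[, keep]
    }
    out
  })
}
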