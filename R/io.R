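#' Read one omics table
#'
#' Input tables are tab-delimited with a header line: column 1 the unique
#' event id, columns 2-4 chromosome / start / end in BED convention (0-based
#' half-open), and every remaining column one sample. Events on chromosomes
#' outside `allowedChromosomes` are dropped (the count is reported).
#'
#' @param path file path.
#' @param kind `"freq"` or `"count"`.
#' @param allowedChromosomes chromosomes to retain.
#' @param verbose emit progress messages.
#' @return An [OmicsLayer-class]; the number of rows dropped by the
#'   chromosome filter is available as `metadata(x)$droppedChrom`.
#' @export
readOmicsTable <- function(path, kind,
                           allowedChromosomes = paste0("chr", 1:22),
                           verbose = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 5L)
    stop("'", path, "': expected >= 5 tab-delimited columns ",
         "(id, chrom, start, end, >=1 sample)")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("'", path, "': duplicate event id(s): ",
         paste(utils::head(dup, 3L), collapse = ", "))
  }
  start <- suppressWarnings(as.numeric(tab[[3L]]))
  end   <- suppressWarnings(as.numeric(tab[[4L]]))
  bad <- which(is.na(start) | is.na(end) | start > end)
  if (length(bad))
    stop("'", path, "', line ", bad[1L] + 1L,
         ": unparseable or inverted coordinates")
  chrom <- as.character(tab[[2L]])
  keep <- chrom %in% allowedChromosomes
  dropped <- sum(!keep)
  if (dropped > 0L)
    .msg(sprintf("%s: dropped %d event(s) outside allowed chromosomes",
                 basename(path), dropped), verbose = verbose)
  vals <- as.matrix(tab[keep, -(1:4), drop = FALSE])
  if (!is.numeric(vals))
    stop("'", path, "': non-numeric sample values")
  rownames(vals) <- ids[keep]
  gr <- .bedToGRanges(chrom[keep], start[keep], end[keep], ids[keep])
  layer <- OmicsLayer(vals, gr, kind = kind, source = basename(path))
  S4Vectors::metadata(layer)$droppedChrom <- dropped
  layer
}

#' Load all omics tables from freq/ and counts/ directories
#'
#' Every file in `freqDir` becomes a `freq` layer (values already on a
#' frequency scale) and every file in `countsDir` a `count` layer
#' (expression counts).
#'
#' @param freqDir,countsDir directories of tab-delimited tables; either may
#'   be `NULL` or empty.
#' @inheritParams readOmicsTable
#' @return A list of [OmicsLayer-class] objects.
#' @export
loadOmicsDir <- function(freqDir = NULL, countsDir = NULL,
                         allowedChromosomes = paste0("chr", 1:22),
                         verbose = TRUE) {
  files <- c()
  kinds <- c()
  for (spec in list(list(freqDir, "freq"), list(countsDir, "count"))) {
    d <- spec[[1L]]
    if (!is.null(d) && dir.exists(d)) {
      f <- sort(list.files(d, full.names = TRUE))
      files <- c(files, f)
      kinds <- c(kinds, rep(spec[[2L]], length(f)))
    }
  }
  if (!length(files))
    stop("no omics tables found under the given directories")
  layers <- mapply(function(f, k)
    readOmicsTable(f, k, allowedChromosomes, verbose = verbose),
    files, kinds, SIMPLIFY = FALSE)
  names(layers) <- basename(files)
  layers
}

#' Write an omics layer back to its on-disk dialect
#'
#' Inverse of [readOmicsTable()] (coordinates returned to 0-based half-open).
#'
#' @param layer an [OmicsLayer-class].
#' @param path output file.
#' @export
writeOmicsTable <- function(layer, path) {
  bed <- .grangesToBed(SummarizedExperiment::rowRanges(layer))
  out <- data.frame(eventID = rownames(layer), bed,
                    SummarizedExperiment::assay(layer, "values"),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read TAD segments from a BED file
#'
#' BED3+ with the segment name in column 4 (names are generated when the
#' column is absent). Coordinates are 0-based half-open on disk.
#'
#' @param path BED file.
#' @return A `GRanges` with names = tad ids.
#' @export
readSegments <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3L) stop("'", path, "': BED needs >= 3 columns")
  ids <- if (ncol(tab) >= 4L) as.character(tab[[4L]]) else
    sprintf("TAD%04d", seq_len(nrow(tab)))
  if (anyDuplicated(ids))
    stop("'", path, "': duplicate segment ids")
  if (any(tab[[2L]] >= tab[[3L]]))
    stop("'", path, "': segment start must be < end")
  .bedToGRanges(as.character(tab[[1L]]), tab[[2L]], tab[[3L]], ids)
}

#' Read the sample metadata table
#'
#' Tab-delimited; first column sample ids, each remaining column one
#' contrast. Contrast columns are binarised: values already in \{0,1\} (or
#' NA) are kept; a multi-level column is expanded into one-vs-rest binary
#' contrasts named `<column>.<level>` with a warning. Binary markers present
#' (value 1) in fewer than `minMarkerN` samples are dropped, as are
#' contrasts with fewer than two samples in either group.
#'
#' @param path TSV file.
#' @param minMarkerN minimum number of positive samples for a marker.
#' @param verbose emit messages about dropped markers.
#' @return A data.frame with rownames = sample ids and one 0/1/NA column per
#'   retained contrast.
#' @export
readSampleMeta <- function(path, minMarkerN = 5L, verbose = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("'", path, "': metadata needs >= 2 columns")
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) stop("'", path, "': duplicate sample ids")
  out <- list()
  for (nm in colnames(tab)[-1L]) {
    col <- tab[[nm]]
    lev <- sort(unique(col[!is.na(col)]))
    if (all(lev %in% c(0, 1))) {
      out[[nm]] <- as.integer(col)
    } else if (length(lev) == 2L) {
      out[[nm]] <- as.integer(col == lev[2L])
    } else {
      warning("contrast '", nm, "' has ", length(lev),
              " levels; expanding to one-vs-rest contrasts")
      for (l in lev)
        out[[paste(nm, l, sep = ".")]] <- as.integer(col == l)
    }
  }
  meta <- data.frame(out, row.names = ids, check.names = FALSE)
  keep <- vapply(meta, function(col) {
    n1 <- sum(col == 1L, na.rm = TRUE)
    n0 <- sum(col == 0L, na.rm = TRUE)
    n1 >= minMarkerN && n1 >= 2L && n0 >= 2L
  }, logical(1))
  if (any(!keep))
    .msg("dropped marker(s) below the sample-count filter: ",
         paste(colnames(meta)[!keep], collapse = ", "), verbose = verbose)
  meta[, keep, drop = FALSE]
}

#' Read gene sets from a GMT file
#'
#' One term per line: term id, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return A named list of character vectors (names = term ids); the
#'   descriptions are in `attr(x, "description")`.
#' @export
readGMT <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(parts, length, 1L) < 3L
  if (any(short)) stop("'", path, "': GMT line with fewer than 3 fields")
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(names(sets))) stop("'", path, "': duplicate term ids")
  attr(sets, "description") <- vapply(parts, `[[`, "", 2L)
  sets
}

#' Read position weight matrices in JASPAR PFM format
#'
#' Parses the JASPAR text dialect (`>ID name` header, then four lines
#' `A [ counts ]` ... `T [ counts ]`; the brackets are optional). Counts are
#' converted to per-column probabilities after adding `pseudocount`.
#'
#' @param path PFM file containing one or more motifs.
#' @param pseudocount added to every count before normalisation.
#' @return A named list of PWMs; each element is a list with `id`, `name`,
#'   `matrix` (4 x width probability matrix, rows A/C/G/T) and
#'   `pseudocount`.
#' @export
readJASPAR <- function(path, pseudocount = 0.25) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("'", path, "': no '>' motif headers found")
  pwms <- list()
  for (i in seq_along(hdr)) {
    from <- hdr[i] + 1L
    to <- if (i < length(hdr)) hdr[i + 1L] - 1L else length(lines)
    block <- lines[from:to]
    if (length(block) != 4L)
      stop("'", path, "': motif block must have 4 base lines")
    toks <- strsplit(sub("^>", "", lines[hdr[i]]), "\\s+")[[1L]]
    id <- toks[1L]
    nm <- if (length(toks) > 1L) paste(toks[-1L], collapse = " ") else id
    rows <- lapply(block, function(l) {
      l <- gsub("[][]", " ", l)
      f <- strsplit(trimws(l), "\\s+")[[1L]]
      list(base = f[1L], counts = as.numeric(f[-1L]))
    })
    bases <- vapply(rows, `[[`, "", "base")
    if (!setequal(bases, c("A", "C", "G", "T")))
      stop("'", path, "': motif ", id, " lacks A/C/G/T rows")
    m <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(m) <- bases
    m <- m[c("A", "C", "G", "T"), , drop = FALSE]
    if (any(is.na(m))) stop("'", path, "': non-numeric counts in ", id)
    m <- m + pseudocount
    m <- sweep(m, 2L, colSums(m), "/")
    pwms[[id]] <- list(id = id, name = nm, matrix = m,
                       pseudocount = pseudocount)
  }
  pwms
}
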