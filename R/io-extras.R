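#' Read a 4-column reads TSV
#'
#' Columns chrom, pos (1-based 5' end), strand, fraglen — the input format
#' for [shiftedFivePrimeCounts]. A header line is optional.
#'
#' @param path Path to the TSV.
#' @return A data.frame with those four columns.
#' @export
readReadsTsv <- function(path) {
  first <- readLines(path, n = 1L)
  hasHeader <- grepl("chrom", first, fixed = TRUE)
  tb <- read.table(path, sep = "\t", header = hasHeader,
                   stringsAsFactors = FALSE)
  if (!hasHeader) {
    if (ncol(tb) != 4L) stop("expected 4 columns: chrom pos strand fraglen")
    names(tb) <- c("chrom", "pos", "strand", "fraglen")
  }
  stopifnot(all(c("chrom", "pos", "strand", "fraglen") %in% names(tb)))
  if (any(!tb$strand %in% c("+", "-"))) stop("strand must be + or -")
  tb
}

#' Read a precomputed counts TSV
#'
#' First column `peak_id`, one column per sample.
#'
#' @param path Path to the TSV (header required).
#' @return An integer matrix with peak ids as rownames.
#' @export
readCountsTsv <- function(path) {
  tb <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tb)[1L] != "peak_id") stop("first column must be peak_id")
  m <- as.matrix(tb[, -1L, drop = FALSE])
  if (!is.numeric(m) || any(m < 0)) stop("counts must be non-negative")
  rownames(m) <- tb$peak_id
  storage.mode(m) <- "integer"
  m
}

#' Write / read a background model in Markov-background format
#'
#' The plain-text format used by first-order Markov background files:
#' one line per k-mer (`A 0.29000`, then `AA 0.08500`, ...), order 0
#' always present and order 1 when available.
#'
#' @param bg A background list (see [backgroundFromSequences]).
#' @param path File path.
#' @return `path`, invisibly (writer); a background list (reader).
#' @export
writeBackground <- function(bg, path) {
  p0 <- .bg0(bg)
  lines <- sprintf("%s %.5f", DNA_BASES, p0)
  if (is.list(bg) && !is.null(bg$transition)) {
    joint <- sweep(bg$transition, 1L, p0, "*")
    for (a in DNA_BASES) for (b in DNA_BASES)
      lines <- c(lines, sprintf("%s%s %.5f", a, b, joint[a, b]))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname writeBackground
#' @export
readBackground <- function(path) {
  lines <- grep("^\\s*#", readLines(path), value = TRUE, invert = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "\\s+")
  kmer <- vapply(parts, `[`, "", 1L)
  freq <- as.numeric(vapply(parts, `[`, "", 2L))
  o0 <- freq[match(DNA_BASES, kmer)]
  if (anyNA(o0)) stop("missing order-0 frequencies")
  names(o0) <- DNA_BASES
  o0 <- o0 / sum(o0)
  out <- list(order0 = o0)
  dinucs <- as.vector(outer(DNA_BASES, DNA_BASES, paste0))
  if (all(dinucs %in% kmer)) {
    joint <- matrix(freq[match(dinucs, kmer)], 4L, 4L,
                    dimnames = list(DNA_BASES, DNA_BASES))
    out$transition <- joint / rowSums(joint)
  }
  out
}

#' Save / load a trained ConvNet
#'
#' The weights go into an RDS archive next to a human-readable JSON of
#' the architecture configuration.
#'
#' @param model A [ConvNet-class].
#' @param path Path for the weights archive (`.rds`); the config is
#'   written alongside as `<path>.json`.
#' @return `path` invisibly (saver); the restored `ConvNet` (loader).
#' @export
saveConvNet <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params,
               trained = model@trained, log = model@log), path)
  jsonlite::write_json(model@config, paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname saveConvNet
#' @export
loadConvNet <- function(path) {
  x <- readRDS(path)
  new("ConvNet", config = x$config, params = x$params,
      trained = x$trained, log = x$log)
}

#' Write per-position attribution as bedGraph
#'
#' Sums contributions over the four bases at each window position and
#' writes one bedGraph line per position, using the peak windows to place
#' the values genomically.
#'
#' @param tracks List of attribution tracks (each with a `contrib`
#'   matrix), one per peak.
#' @param windows A `GRanges` of the corresponding peak windows (same
#'   order and lengths).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeAttributionBedGraph <- function(tracks, windows, path) {
  stopifnot(length(tracks) == length(windows))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("track type=bedGraph name=attribution", con)
  for (i in seq_along(tracks)) {
    v <- colSums(tracks[[i]]$contrib)
    start0 <- GenomicRanges::start(windows)[i] - 1L
    chrom <- as.character(GenomicRanges::seqnames(windows))[i]
    writeLines(sprintf("%s\t%d\t%d\t%.6g", chrom,
                       start0 + seq_along(v) - 1L,
                       start0 + seq_along(v), v), con)
  }
  invisible(path)
}
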