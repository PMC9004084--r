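#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib dbdmotif, .registration = TRUE
#' @importFrom stats median pnorm rnorm runif rbinom rnbinom sd var cor
#'   p.adjust wilcox.test quantile setNames binomial coef
#' @importFrom utils read.table write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Read a genome FASTA file
#'
#' Reads a multi-record FASTA into a named [Biostrings::DNAStringSet].
#' Sequences are uppercased and any character outside A/C/G/T/N is replaced
#' with N (with a warning giving the replacement count). Chromosome names are
#' taken as the first whitespace-delimited word of each header and must be
#' unique.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet], one entry per chromosome.
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1L]) stop("not a FASTA file (no leading '>'): ", path)
  idx <- cumsum(hdr)
  nms <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  if (anyDuplicated(nms)) {
    stop("duplicate chromosome name(s): ",
         paste(unique(nms[duplicated(nms)]), collapse = ", "))
  }
  seqs <- vapply(split(lines[!hdr], idx[!hdr]), paste0, "", collapse = "")
  # records with no sequence lines vanish from split(); restore as empty
  full <- setNames(character(length(nms)), as.character(seq_along(nms)))
  full[names(seqs)] <- seqs
  full <- toupper(full)
  nbad <- sum(vapply(gregexpr("[^ACGTN]", full), function(m)
    sum(m > 0L), 0L))
  if (nbad > 0L) {
    warning(nbad, " non-ACGTN character(s) replaced with N")
    full <- gsub("[^ACGTN]", "N", full)
  }
  names(full) <- nms
  Biostrings::DNAStringSet(full)
}

#' Write a DNAStringSet to FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet] or named character vector.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeGenome <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Read narrowPeak / BED6 peak files
#'
#' Accepts the ENCODE 10-column narrowPeak dialect or plain 6-column BED.
#' File coordinates are BED-style (0-based half-open); the returned
#' [GenomicRanges::GRanges] uses the usual 1-based closed convention.
#' Metadata columns: `name`, `score`, `signal` (narrowPeak column 7),
#' `pNeglog10`, `qNeglog10`, `peakOffset` (column 10, -1 if absent) and
#' `summit`, the absolute 1-based summit position (NA when no summit offset
#' is present). Six-column input gets signal 0 and p = q = -1.
#'
#' @param path Path to a tab-separated peak file.
#' @return A `GRanges` in file order (possibly empty).
#' @export
readNarrowPeak <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  emptyGR <- GenomicRanges::GRanges(
    seqnames = character(), ranges = IRanges::IRanges(),
    name = character(), score = integer(), signal = numeric(),
    pNeglog10 = numeric(), qNeglog10 = numeric(),
    peakOffset = integer(), summit = integer())
  info <- file.info(path)
  if (info$size == 0L) return(emptyGR)
  tb <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = "character", quote = "",
                   comment.char = "#")
  if (nrow(tb) == 0L) return(emptyGR)
  if (!(ncol(tb) %in% c(6L, 10L)))
    stop("expected 6 or 10 tab-separated columns, got ", ncol(tb))
  start0 <- suppressWarnings(as.numeric(tb[[2L]]))
  end0 <- suppressWarnings(as.numeric(tb[[3L]]))
  if (anyNA(start0) || anyNA(end0) ||
      any(start0 != floor(start0)) || any(end0 != floor(end0)))
    stop("non-integer coordinates in ", path)
  if (any(start0 >= end0)) stop("start >= end in ", path)
  if (ncol(tb) == 10L) {
    signal <- as.numeric(tb[[7L]])
    p10 <- as.numeric(tb[[8L]])
    q10 <- as.numeric(tb[[9L]])
    offs <- as.integer(tb[[10L]])
  } else {
    signal <- rep(0, nrow(tb))
    p10 <- rep(-1, nrow(tb))
    q10 <- rep(-1, nrow(tb))
    offs <- rep(-1L, nrow(tb))
  }
  if (any(offs >= end0 - start0)) stop("summit offset beyond peak end")
  if (any(signal < 0)) stop("negative signal value")
  summit <- ifelse(offs >= 0L, start0 + offs + 1L, NA_integer_)
  GenomicRanges::GRanges(
    seqnames = tb[[1L]],
    ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = "*",
    name = tb[[4L]],
    score = suppressWarnings(as.integer(tb[[5L]])),
    signal = signal, pNeglog10 = p10, qNeglog10 = q10,
    peakOffset = as.integer(offs), summit = as.integer(summit))
}

#' Write intervals as BED
#'
#' Writes a `GRanges` as BED (0-based half-open), using the `name` metadata
#' column when present.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeBed <- function(gr, path) {
  nm <- if (!is.null(gr$name)) gr$name else rep(".", length(gr))
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr),
                   name = nm)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Extract a fixed-width window around a summit
#'
#' Returns the sequence covering `[summit - flank, summit + flank)` in
#' 0-based terms, i.e. `2 * flank` bases with the summit base at position
#' `flank + 1` of the window. Windows extending past either chromosome edge
#' raise an error; callers drop such peaks.
#'
#' @param genome A named `DNAStringSet` (or named character vector).
#' @param chrom Chromosome name.
#' @param summit 1-based summit position.
#' @param flank Half-width in bp (window length is `2 * flank`).
#' @return A character string of length `2 * flank`.
#' @export
extractWindow <- function(genome, chrom, summit, flank) {
  stopifnot(flank > 0)
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- if (is.character(genome)) nchar(genome[[chrom]])
         else length(genome[[chrom]])
  from <- summit - flank
  to <- summit + flank - 1L
  if (from < 1L || to > len)
    stop("window [", from, ",", to, "] out of bounds for ", chrom,
         " (length ", len, ")")
  as.character(Biostrings::subseq(Biostrings::DNAStringSet(genome)[[chrom]],
                                  from, to))
}

#' One-hot encode a DNA sequence
#'
#' Encodes a sequence over A/C/G/T/N as a 4 x L indicator matrix with rows
#' A, C, G, T. N becomes an all-zero column, so column sums are 1 for called
#' bases and 0 for N.
#'
#' @param seq A DNA string (character scalar) over A/C/G/T/N.
#' @return A 4 x nchar(seq) numeric matrix with rownames A, C, G, T.
#' @export
oneHot <- function(seq) {
  chars <- strsplit(toupper(as.character(seq)), "", fixed = TRUE)[[1L]]
  bad <- !(chars %in% c(DNA_BASES, "N"))
  if (any(bad)) stop("invalid character(s): ",
                     paste(unique(chars[bad]), collapse = ", "))
  m <- matrix(0, nrow = 4L, ncol = length(chars),
              dimnames = list(DNA_BASES, NULL))
  ridx <- match(chars, DNA_BASES)
  keep <- !is.na(ridx)
  m[cbind(ridx[keep], which(keep))] <- 1
  m
}

#' Reverse complement a one-hot matrix
#'
#' Reverses column order and swaps rows A-T and C-G. Involution; all-zero
#' (N) columns stay zero. Fractional entries (PFMs) are handled the same way.
#'
#' @param m A 4 x L matrix with rows A, C, G, T.
#' @return The reverse-complemented matrix.
#' @export
revcompOneHot <- function(m) {
  stopifnot(nrow(m) == 4L)
  out <- m[4:1, rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

#' Decode a one-hot (or PFM) matrix to its consensus string
#'
#' All-zero columns decode to N; otherwise the row with maximal weight wins
#' (ties broken by A < C < G < T order).
#'
#' @param m A 4 x L matrix with rows A, C, G, T.
#' @return A character string of length `ncol(m)`.
#' @export
consensusOfMatrix <- function(m) {
  stopifnot(nrow(m) == 4L)
  if (ncol(m) == 0L) return("")
  idx <- apply(m, 2L, which.max)
  out <- DNA_BASES[idx]
  out[colSums(m != 0) == 0] <- "N"
  paste0(out, collapse = "")
}

#' Reverse complement a DNA string
#' @param seq A DNA character scalar.
#' @return The reverse complement string.
#' @export
revcompSeq <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
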