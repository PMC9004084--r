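#' Exact background score distribution for a PWM
#'
#' FIMO-style dynamic programming: every PWM entry is discretised onto an
#' integer grid (`bins` bins across the total score range), and the exact
#' distribution of the integer score of a random k-mer under the order-0
#' background is built column by column. Scanning queries k-mer scores
#' through the same discretisation, so reported p-values are exact for the
#' discretised score; the discretisation error of the score itself is
#' bounded by `width * range / (2 * bins)`. When an order-1 background is
#' supplied only its order-0 (stationary) component is used.
#'
#' @param pwm A 4 x W log2-odds matrix (see [pfmToPwm]).
#' @param bg Background model (list with `order0` or a length-4 vector).
#' @param bins Number of discretisation bins (default 1000).
#' @return An object of class `pwmPtable` with the integerised matrix, the
#'   tail-probability vector and the grid metadata.
#' @export
pwmScoreDistribution <- function(pwm, bg, bins = 1000L) {
  stopifnot(nrow(pwm) == 4L, all(is.finite(pwm)))
  p0 <- .bg0(bg)
  stopifnot(all(p0 > 0), abs(sum(p0) - 1) < 1e-6)
  W <- ncol(pwm)
  colMin <- apply(pwm, 2L, min)
  colMax <- apply(pwm, 2L, max)
  range <- sum(colMax - colMin)
  scale <- if (range > 0) bins / range else 1
  E <- round(sweep(pwm, 2L, colMin, "-") * scale)
  storage.mode(E) <- "integer"
  maxInt <- sum(apply(E, 2L, max))
  dist <- numeric(maxInt + 1L)
  dist[1L] <- 1
  for (j in seq_len(W)) {
    nxt <- numeric(maxInt + 1L)
    for (b in 1:4) {
      e <- E[b, j]
      n <- length(dist) - e
      nxt[(e + 1L):(e + n)] <- nxt[(e + 1L):(e + n)] + p0[b] * dist[1:n]
    }
    dist <- nxt
  }
  pTail <- rev(cumsum(rev(dist)))
  pTail <- pmin(pTail, 1)
  structure(list(E = E, pTail = pTail, scale = scale, colMin = colMin,
                 maxInt = maxInt, width = W, bg = p0),
            class = "pwmPtable")
}

#' P-value of a k-mer (or integer score) under a score distribution
#'
#' @param tab A `pwmPtable` from [pwmScoreDistribution].
#' @param kmer A DNA string of the PWM's width, or an integer score already
#'   on the table's grid.
#' @return `Pr(score >= s)` under the background.
#' @export
pwmPvalue <- function(tab, kmer) {
  if (is.character(kmer)) {
    code <- match(strsplit(toupper(kmer), "")[[1L]], DNA_BASES)
    stopifnot(length(code) == tab$width, !anyNA(code))
    s <- sum(tab$E[cbind(code, seq_len(tab$width))])
  } else {
    s <- as.integer(kmer)
  }
  s <- max(0L, min(s, tab$maxInt))
  tab$pTail[s + 1L]
}

#' Scan sequences with a PWM
#'
#' Scores every offset of every sequence on both strands against a motif
#' (the minus strand scores the reverse-complement k-mer against the same
#' PWM), attaches exact background p-values from [pwmScoreDistribution],
#' retains hits with `p <= pThreshold` (or every offset when
#' `emitAll = TRUE`), and computes BH q-values jointly across all retained
#' hits of the scan. Offsets whose window contains N are skipped.
#' Sequences shorter than the motif yield no hits. Hits are ordered by
#' (sequence, offset, strand with "+" first).
#'
#' @param seqs Named character vector or `DNAStringSet` of sequences.
#' @param x A PFM or `megaMotif` (converted with [pfmToPwm]).
#' @param bg Background model used for both the log-odds conversion and
#'   the p-value DP.
#' @param pThreshold Retention threshold on p (default 1e-4, the usual
#'   scanning default).
#' @param emitAll Retain every scored offset regardless of p.
#' @param bins Discretisation bins for the p-value DP.
#' @return A data.frame with columns `seqname`, `start` (1-based), `strand`,
#'   `score` (log2-odds), `pvalue`, `qvalue`, `matched`.
#' @export
scanPwm <- function(seqs, x, bg, pThreshold = 1e-4, emitAll = FALSE,
                    bins = 1000L) {
  if (inherits(x, "megaMotif")) x <- x$pfm
  pwm <- pfmToPwm(x, bg)
  tab <- pwmScoreDistribution(pwm, bg, bins = bins)
  W <- ncol(pwm)
  nms <- names(seqs)
  seqs <- as.character(seqs)
  names(seqs) <- if (is.null(nms)) paste0("seq", seq_along(seqs)) else nms
  Erc <- tab$E[4:1, rev(seq_len(W)), drop = FALSE]
  pwmRc <- pwm[4:1, rev(seq_len(W)), drop = FALSE]
  accName <- list(); accStart <- list(); accStrand <- list()
  accScore <- list(); accP <- list(); accMatch <- list()
  k <- 0L
  for (si in seq_along(seqs)) {
    sq <- toupper(seqs[[si]])
    chars <- strsplit(sq, "")[[1L]]
    L <- length(chars)
    if (L < W) next
    code <- match(chars, DNA_BASES)
    nOff <- L - W + 1L
    intF <- integer(nOff); intR <- integer(nOff)
    scF <- numeric(nOff); scR <- numeric(nOff)
    valid <- rep(TRUE, nOff)
    for (j in seq_len(W)) {
      cj <- code[j:(j + nOff - 1L)]
      bad <- is.na(cj)
      valid <- valid & !bad
      cj[bad] <- 1L
      intF <- intF + tab$E[cbind(cj, j)]
      intR <- intR + Erc[cbind(cj, j)]
      scF <- scF + pwm[cbind(cj, j)]
      scR <- scR + pwmRc[cbind(cj, j)]
    }
    off <- which(valid)
    if (!length(off)) next
    pF <- tab$pTail[pmin(intF[off], tab$maxInt) + 1L]
    pR <- tab$pTail[pmin(intR[off], tab$maxInt) + 1L]
    # minus-strand matched sequences are mirrored substrings of the
    # reverse-complemented sequence (one revcomp per sequence)
    rcsq <- revcompSeq(sq)
    k <- k + 1L
    accName[[k]] <- rep(names(seqs)[si], 2L * length(off))
    accStart[[k]] <- c(off, off)
    accStrand[[k]] <- rep(c("+", "-"), each = length(off))
    accScore[[k]] <- c(scF[off], scR[off])
    accP[[k]] <- c(pF, pR)
    accMatch[[k]] <- c(substring(sq, off, off + W - 1L),
                       substring(rcsq, L - off - W + 2L, L - off + 1L))
  }
  hits <- if (k > 0L) {
    data.frame(seqname = unlist(accName), start = unlist(accStart),
               strand = unlist(accStrand), score = unlist(accScore),
               pvalue = unlist(accP), matched = unlist(accMatch))
  } else NULL
  if (is.null(hits) || nrow(hits) == 0L) {
    return(data.frame(seqname = character(), start = integer(),
                      strand = character(), score = numeric(),
                      pvalue = numeric(), qvalue = numeric(),
                      matched = character()))
  }
  if (!emitAll) hits <- hits[hits$pvalue <= pThreshold, , drop = FALSE]
  if (nrow(hits) == 0L) {
    hits$qvalue <- numeric(0)
    return(hits[, c("seqname", "start", "strand", "score", "pvalue",
                    "qvalue", "matched")])
  }
  hits$qvalue <- bhAdjust(hits$pvalue)
  ord <- order(match(hits$seqname, names(seqs)), hits$start,
               hits$strand != "+")
  hits <- hits[ord, c("seqname", "start", "strand", "score", "pvalue",
                      "qvalue", "matched")]
  rownames(hits) <- NULL
  hits
}

#' Per-sequence best-hit feature
#'
#' Collapses a scan to one number per sequence. Mode `"neglog10_q_cap"`:
#' `-log10` of the smallest hit q-value if it is below `qCap` (default
#' 0.5), else 0. Mode `"neglog10_p_or_one"`: `-log10` of the smallest hit
#' p-value, with p set to 1 (feature 0) for sequences without any hit.
#' Ties are broken by (offset, "+" strand first), though the feature value
#' does not depend on the tie-break.
#'
#' @param hits A scan result from [scanPwm].
#' @param seqnames The full universe of sequence names (so hit-less
#'   sequences get a feature).
#' @param mode Feature mode; see above.
#' @param qCap q-value cap for the q mode.
#' @return Named numeric vector, one feature per sequence.
#' @export
bestHitFeature <- function(hits, seqnames,
                           mode = c("neglog10_q_cap", "neglog10_p_or_one"),
                           qCap = 0.5) {
  mode <- match.arg(mode)
  feat <- setNames(numeric(length(seqnames)), seqnames)
  if (nrow(hits) > 0L) {
    if (mode == "neglog10_q_cap") {
      best <- tapply(hits$qvalue, hits$seqname, min)
      v <- ifelse(best < qCap, -log10(pmax(best, 1e-300)), 0)
    } else {
      best <- tapply(hits$pvalue, hits$seqname, min)
      v <- -log10(pmax(best, 1e-300))
    }
    ok <- intersect(names(v), seqnames)
    feat[ok] <- v[ok]
  }
  feat
}

#' Write scan hits as a FIMO-style TSV
#'
#' Columns motif_id, sequence_name, start, stop, strand, score, p-value,
#' q-value, matched_sequence with 1-based inclusive coordinates.
#'
#' @param hits A scan result from [scanPwm].
#' @param path Output path.
#' @param motifId Motif identifier for the first column.
#' @param width Motif width (used for the stop coordinate).
#' @return `path`, invisibly.
#' @export
writeFimoTsv <- function(hits, path, motifId = "motif",
                         width = NULL) {
  if (is.null(width))
    width <- if (nrow(hits)) nchar(hits$matched[1L]) else 0L
  df <- data.frame(motif_id = motifId, sequence_name = hits$seqname,
                   start = hits$start, stop = hits$start + width - 1L,
                   strand = hits$strand, score = hits$score,
                   `p.value` = hits$pvalue, `q.value` = hits$qvalue,
                   matched_sequence = hits$matched)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
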