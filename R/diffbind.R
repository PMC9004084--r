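#' Merge summit peaks across datasets
#'
#' Single-linkage merging of peak summits within each chromosome: peaks whose
#' summits are within `radius` bp of each other (chained transitively) become
#' one merged peak whose summit is the arithmetic mean of the member summits,
#' rounded half-up. Matches the 50 bp summit-merging rule used when pooling
#' reproducible peaks across replicates and datasets.
#'
#' @param summits A data.frame with columns `chrom` and `summit` (1-based
#'   positions; an optional `source` column is carried along), or a
#'   width-1 `GRanges`.
#' @param radius Maximum summit distance (bp) for merging, default 50.
#' @return A width-1 `GRanges` at the merged summits, sorted by
#'   (chrom, summit), with metadata columns `nMembers` and `summit`.
#' @export
mergeSummitPeaks <- function(summits, radius = 50) {
  stopifnot(radius > 0)
  if (is(summits, "GRanges")) {
    summits <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(summits)),
      summit = GenomicRanges::start(summits))
  }
  stopifnot(all(c("chrom", "summit") %in% names(summits)))
  if (nrow(summits) == 0L) {
    return(GenomicRanges::GRanges(seqnames = character(),
                                  ranges = IRanges::IRanges(),
                                  nMembers = integer(), summit = integer()))
  }
  parts <- split(summits$summit, summits$chrom)
  res <- lapply(sort(names(parts)), function(chr) {
    s <- sort(parts[[chr]])
    grp <- cumsum(c(1L, as.integer(diff(s) > radius)))
    mg <- vapply(split(s, grp), function(v) floor(mean(v) + 0.5), 0)
    data.frame(chrom = chr, summit = unname(mg),
               nMembers = as.integer(table(grp)))
  })
  res <- do.call(rbind, res)
  GenomicRanges::GRanges(
    seqnames = res$chrom,
    ranges = IRanges::IRanges(start = res$summit, width = 1L),
    nMembers = res$nMembers, summit = as.integer(res$summit))
}

#' Summit-centred windows for merged peaks
#'
#' @param merged A width-1 `GRanges` of merged summits (from
#'   [mergeSummitPeaks]).
#' @param flank Half-width in bp; windows are `[summit - flank,
#'   summit + flank)` in 0-based terms (width `2 * flank`).
#' @return A `GRanges` of fixed-width windows carrying the `summit` column.
#' @export
peakWindows <- function(merged, flank) {
  stopifnot(flank > 0)
  s <- GenomicRanges::start(merged)
  GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(merged),
    ranges = IRanges::IRanges(start = s - flank, end = s + flank - 1L),
    summit = s)
}

#' Count shifted read 5' ends in peaks
#'
#' Each read's 5' end is shifted by half its fragment length (floor), and a
#' peak counts the read if the shifted position falls inside the peak
#' interval. In the default strand-aware mode plus-strand reads shift right
#' and minus-strand reads shift left; `mode = "literal-right"` shifts every
#' read to the right regardless of strand. Shifted positions below 1 are
#' clipped to 1 with a warning; reads on chromosomes absent from `peaks`
#' simply never overlap.
#'
#' @param reads A data.frame with columns `chrom`, `pos` (1-based 5'-end
#'   position), `strand` ("+"/"-"), `fraglen` (> 0).
#' @param peaks A `GRanges` of peak intervals.
#' @param mode "strand" (default) or "literal-right".
#' @return Integer vector of counts, one per peak.
#' @export
shiftedFivePrimeCounts <- function(reads, peaks,
                                   mode = c("strand", "literal-right")) {
  mode <- match.arg(mode)
  stopifnot(all(c("chrom", "pos", "strand", "fraglen") %in% names(reads)))
  if (nrow(reads) > 0L && any(reads$fraglen <= 0))
    stop("fragment lengths must be positive")
  if (nrow(reads) == 0L) return(integer(length(peaks)))
  half <- floor(reads$fraglen / 2)
  shift <- ifelse(mode == "strand" & reads$strand == "-", -half, half)
  pos <- reads$pos + shift
  if (any(pos < 1L)) {
    warning(sum(pos < 1L), " shifted position(s) clipped to 1")
    pos <- pmax(pos, 1L)
  }
  rg <- GenomicRanges::GRanges(
    seqnames = reads$chrom,
    ranges = IRanges::IRanges(start = pos, width = 1L))
  suppressWarnings(GenomicRanges::countOverlaps(peaks, rg))
}

#' Assemble a peak-by-sample count matrix
#'
#' @param peaks A `GRanges` of merged peak windows.
#' @param counts Integer matrix (peaks x samples) or a list of per-sample
#'   count vectors.
#' @param condition Character/factor per sample, e.g. "WT" / "mut".
#' @param replicate Optional replicate ids (default seq along samples).
#' @return A [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, `rowRanges = peaks` and colData `condition`, `replicate`.
#' @export
makeCountMatrix <- function(peaks, counts, condition, replicate = NULL) {
  if (is.list(counts) && !is.matrix(counts)) counts <- do.call(cbind, counts)
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == length(peaks),
            ncol(counts) == length(condition),
            all(counts >= 0))
  if (is.null(replicate)) replicate <- seq_len(ncol(counts))
  colnames(counts) <- paste0(condition, "_", replicate)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = peaks,
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   replicate = replicate))
}

.countsOf <- function(x) {
  if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "counts")
  else as.matrix(x)
}

#' Median-of-ratios size factors
#'
#' The DESeq-style depth normaliser: for each sample, the median across peaks
#' of the ratio between its count and the row geometric mean, using only
#' peaks with all-positive counts.
#'
#' @param counts Count matrix or `SummarizedExperiment` with a `counts`
#'   assay.
#' @return Positive numeric vector, one size factor per sample.
#' @export
estimateSizeFactors <- function(counts) {
  k <- .countsOf(counts)
  allpos <- rowSums(k == 0) == 0L
  if (!any(allpos)) stop("no peak has all-positive counts")
  kk <- k[allpos, , drop = FALSE]
  geo <- exp(rowMeans(log(kk)))
  apply(kk, 2L, function(col) median(col / geo))
}

#' Simplified negative-binomial Wald test for differential binding
#'
#' A self-contained stand-in for a full differential-count analysis:
#' counts are normalised by median-of-ratios size factors; per-peak
#' fold-change is `log2FC = log2((mu_mut + 0.5) / (mu_WT + 0.5))` so that
#' peaks stronger in the wild type get negative log2FC; dispersion is
#' estimated per peak by method of moments and pooled across peaks within 20
#' bins of base mean (floored at 1e-8); a Wald z-score on log2FC with a
#' delta-method standard error gives two-sided normal p-values and BH
#' q-values. All-zero peaks get log2FC 0, p 1 and are excluded from the BH
#' universe.
#'
#' @param counts Count matrix or `SummarizedExperiment` (assay `counts`).
#' @param condition Per-sample condition labels; see `wt`/`mut`.
#' @param wt,mut Condition values identifying the wild-type and mutant
#'   groups (defaults "WT", "mut"). If `counts` is a `SummarizedExperiment`
#'   with a `condition` colData column, `condition` may be omitted.
#' @param sizeFactors Optional precomputed size factors.
#' @param nBins Number of base-mean bins for dispersion pooling.
#' @return A data.frame with columns `baseMean`, `log2FC`, `se`, `stat`,
#'   `pvalue`, `qvalue`, `dispersion`.
#' @export
nbWaldTest <- function(counts, condition = NULL, wt = "WT", mut = "mut",
                       sizeFactors = NULL, nBins = 20L) {
  k <- .countsOf(counts)
  if (is.null(condition) && is(counts, "SummarizedExperiment"))
    condition <- SummarizedExperiment::colData(counts)$condition
  stopifnot(!is.null(condition), length(condition) == ncol(k))
  iw <- which(condition == wt)
  im <- which(condition == mut)
  if (length(iw) < 1L || length(im) < 1L)
    stop("need at least one sample per condition")
  if (is.null(sizeFactors)) sizeFactors <- estimateSizeFactors(k)
  norm <- sweep(k, 2L, sizeFactors, "/")
  muW <- rowMeans(norm[, iw, drop = FALSE])
  muM <- rowMeans(norm[, im, drop = FALSE])
  baseMean <- rowMeans(norm)
  lfc <- log2((muM + 0.5) / (muW + 0.5))

  # method-of-moments dispersion, pooled within condition then across peaks
  momAlpha <- function(idx) {
    n <- length(idx)
    if (n < 2L) return(rep(NA_real_, nrow(k)))
    m <- rowMeans(norm[, idx, drop = FALSE])
    v <- apply(norm[, idx, drop = FALSE], 1L, var)
    sinv <- mean(1 / sizeFactors[idx])
    ifelse(m > 0, (v - m * sinv) / m^2, NA_real_)
  }
  aW <- momAlpha(iw)
  aM <- momAlpha(im)
  dfW <- max(length(iw) - 1L, 0L)
  dfM <- max(length(im) - 1L, 0L)
  alpha <- rep(NA_real_, nrow(k))
  w <- cbind(ifelse(is.na(aW), 0, dfW), ifelse(is.na(aM), 0, dfM))
  tot <- rowSums(w)
  ok <- tot > 0
  alpha[ok] <- (ifelse(is.na(aW), 0, aW) * w[, 1L] +
                ifelse(is.na(aM), 0, aM) * w[, 2L])[ok] / tot[ok]

  # pool across peaks in bins of baseMean
  tested <- baseMean > 0
  pooled <- rep(NA_real_, nrow(k))
  if (any(tested)) {
    br <- quantile(baseMean[tested], probs = seq(0, 1, length.out = nBins + 1L),
                   names = FALSE)
    br <- unique(br)
    bin <- cut(baseMean[tested], breaks = br, include.lowest = TRUE)
    binMean <- tapply(alpha[tested], bin, mean, na.rm = TRUE)
    binMean[is.nan(binMean)] <- 0
    pooled[tested] <- binMean[as.integer(bin)]
  }
  disp <- pmax(pooled, 1e-8)

  # delta-method SE of log2 ratio of normalised group means
  varMean <- function(mu, idx, a) {
    (1 / length(idx)^2) * sum(mu / sizeFactors[idx] + a * mu^2)
  }
  se <- vapply(seq_len(nrow(k)), function(i) {
    if (!tested[i]) return(NA_real_)
    vW <- varMean(muW[i], iw, disp[i])
    vM <- varMean(muM[i], im, disp[i])
    sqrt(vM / (muM[i] + 0.5)^2 + vW / (muW[i] + 0.5)^2) / log(2)
  }, 0)
  stat <- lfc / se
  p <- 2 * pnorm(-abs(stat))
  p[!tested] <- 1
  lfc[!tested] <- 0
  stat[!tested] <- 0
  q <- rep(1, nrow(k))
  q[tested] <- bhAdjust(p[tested])
  data.frame(baseMean = baseMean, log2FC = lfc, se = se, stat = stat,
             pvalue = p, qvalue = q, dispersion = disp)
}

#' Label peaks as positive / negative / excluded
#'
#' A peak is positive (significantly stronger in the wild type) when
#' `q < 0.05` and `log2FC < -1`; negative (preserved or stronger in the
#' mutant) when `log2FC >= 0`; otherwise excluded. The three labels are
#' exhaustive and mutually exclusive.
#'
#' @param results A data.frame with columns `log2FC` and `qvalue` (as
#'   returned by [nbWaldTest] or [readExternalDiff]).
#' @param qThreshold,lfcThreshold Positive-set thresholds (defaults 0.05
#'   and -1).
#' @return A factor with levels positive, negative, excluded.
#' @export
labelDifferential <- function(results, qThreshold = 0.05,
                              lfcThreshold = -1) {
  stopifnot(all(c("log2FC", "qvalue") %in% names(results)))
  lab <- rep("excluded", nrow(results))
  lab[results$qvalue < qThreshold & results$log2FC < lfcThreshold] <-
    "positive"
  lab[results$log2FC >= 0] <- "negative"
  factor(lab, levels = c("positive", "negative", "excluded"))
}

#' Ingest an externally computed differential table
#'
#' Reads a TSV with header columns `peak_id`, `log2FC`, `pvalue`, `qvalue`
#' (e.g. a DESeq2 export) so published differential results can drive the
#' labelling and downstream modelling.
#'
#' @param path Path to the TSV.
#' @return A data.frame with those four columns.
#' @export
readExternalDiff <- function(path) {
  tb <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("peak_id", "log2FC", "pvalue", "qvalue")
  if (!all(need %in% names(tb)))
    stop("differential table must have columns: ",
         paste(need, collapse = ", "))
  tb[, need]
}
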