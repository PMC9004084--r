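#' Maximum dot-product motif score of a short read
#'
#' One-hot encodes the read and its reverse complement and computes the dot
#' product with the query PFM at every full-overlap alignment (the query
#' sliding within the read, or the read within the query when the query is
#' wider), returning the maximum over alignments and orientations. By
#' construction the score is invariant to reverse-complementing the read.
#'
#' @param read A DNA string.
#' @param query A PFM (e.g. the 16 bp SELEX query from [buildSelexQuery]).
#' @return The maximum dot product.
#' @export
selexReadScore <- function(read, query) {
  ohF <- oneHot(read)
  ohR <- revcompOneHot(ohF)
  W <- ncol(query)
  L <- ncol(ohF)
  best <- -Inf
  for (oh in list(ohF, ohR)) {
    if (L >= W) {
      for (o in 0:(L - W))
        best <- max(best, sum(oh[, (o + 1L):(o + W)] * query))
    } else {
      for (o in 0:(W - L))
        best <- max(best, sum(oh * query[, (o + 1L):(o + L)]))
    }
  }
  best
}

# Vectorised max-dot-product scoring of a fixed-length pool; identical to
# selexReadScore read by read, but one matrix-indexing pass per alignment.
.selexPoolScores <- function(reads, query) {
  n <- length(reads)
  L <- unique(nchar(reads))
  if (length(L) != 1L) {
    return(vapply(reads, selexReadScore, 0, query = query,
                  USE.NAMES = FALSE))
  }
  W <- ncol(query)
  codes <- matrix(match(unlist(strsplit(toupper(reads), "")), DNA_BASES),
                  nrow = n, byrow = TRUE)
  if (anyNA(codes)) {
    return(vapply(reads, selexReadScore, 0, query = query,
                  USE.NAMES = FALSE))
  }
  rcCodes <- matrix(5L - codes[, rev(seq_len(L)), drop = FALSE], nrow = n)
  best <- rep(-Inf, n)
  for (cod in list(codes, rcCodes)) {
    if (L >= W) {
      for (o in 0:(L - W)) {
        s <- numeric(n)
        for (j in seq_len(W)) s <- s + query[cbind(cod[, o + j], j)]
        best <- pmax(best, s)
      }
    } else {
      for (o in 0:(W - L)) {
        s <- numeric(n)
        for (j in seq_len(L)) s <- s + query[cbind(cod[, j], o + j)]
        best <- pmax(best, s)
      }
    }
  }
  best
}

#' SELEX cycle enrichment test
#'
#' Scores every read of the control pool (cycle 0) and the selected pool
#' (cycle K) by the maximum dot product against the query (see
#' [selexReadScore]) and compares the two score distributions with a
#' one-sided Wilcoxon rank-sum test (selected pool greater).
#'
#' @param cycle0,cycleK Character vectors of reads.
#' @param query A query PFM.
#' @return A test result list (see [wilcoxonRankSum]) with the per-pool
#'   scores attached as `scores0`, `scoresK`.
#' @export
selexEnrichmentTest <- function(cycle0, cycleK, query) {
  if (!length(cycle0) || !length(cycleK)) stop("empty read pool")
  s0 <- .selexPoolScores(cycle0, query)
  sK <- .selexPoolScores(cycleK, query)
  res <- wilcoxonRankSum(sK, s0, alternative = "greater")
  res$scores0 <- s0
  res$scoresK <- sK
  res
}

#' Aggregate motif-hit logos at q-value cutoffs
#'
#' Scans the reads with the query motif (all offsets, joint BH), and for
#' each q cutoff averages the one-hot encoded read segments at hit
#' positions (minus-strand hits reverse-complemented first) into a PFM of
#' the query width. Cutoffs without hits yield `NULL` entries.
#'
#' @param reads Character vector of reads.
#' @param query A query PFM.
#' @param bg Background model for the scan.
#' @param qCutoffs q-value cutoffs (default 0.05, 0.01, 0.005, 0.001).
#' @return Named list of PFMs (or `NULL` where a cutoff had no hits).
#' @export
aggregateHitLogo <- function(reads, query, bg,
                             qCutoffs = c(0.05, 0.01, 0.005, 0.001)) {
  names(reads) <- paste0("read", seq_along(reads))
  hits <- scanPwm(reads, query, bg, emitAll = TRUE)
  W <- ncol(query)
  out <- setNames(vector("list", length(qCutoffs)),
                  paste0("q", qCutoffs))
  for (ci in seq_along(qCutoffs)) {
    hh <- hits[hits$qvalue < qCutoffs[ci], , drop = FALSE]
    if (nrow(hh) == 0L) next
    acc <- matrix(0, 4L, W, dimnames = list(DNA_BASES, NULL))
    for (r in seq_len(nrow(hh))) {
      oh <- oneHot(substring(reads[[hh$seqname[r]]], hh$start[r],
                             hh$start[r] + W - 1L))
      if (hh$strand[r] == "-") oh <- revcompOneHot(oh)
      acc <- acc + oh
    }
    out[[ci]] <- pfm(acc / nrow(hh), name = paste0("hits_q", qCutoffs[ci]))
  }
  out
}

#' Partition peaks by overlap with strict and relaxed reference sets
#'
#' `overlapping` holds the query peaks with at least 1 bp overlap with any
#' strict reference peak; `non_overlapping` holds the query peaks with no
#' overlap with any relaxed reference peak. Peaks overlapping a relaxed but
#' not a strict reference peak fall in neither subset.
#'
#' @param peaksA Query `GRanges`.
#' @param strictB Strict reference `GRanges` (e.g. reproducible peaks).
#' @param relaxedB Relaxed reference `GRanges` (superset of strictB).
#' @return A list with `overlapping` and `non_overlapping` `GRanges`.
#' @export
partitionByOverlap <- function(peaksA, strictB, relaxedB) {
  ovStrict <- GenomicRanges::countOverlaps(peaksA, strictB,
                                           ignore.strand = TRUE) > 0
  ovRelaxed <- GenomicRanges::countOverlaps(peaksA, relaxedB,
                                            ignore.strand = TRUE) > 0
  list(overlapping = peaksA[ovStrict],
       non_overlapping = peaksA[!ovRelaxed])
}

#' Compare best-hit p-values between two peak subsets
#'
#' Computes the per-peak best motif-hit `-log10` p-value (p set to 1, i.e.
#' feature 0, for peaks without a hit) for the sequences of each subset
#' with an all-offsets scan, and compares the two distributions with a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param seqsOverlap,seqsNonOverlap Character vectors of peak sequences.
#' @param x PFM or `megaMotif` to scan for.
#' @param bg Background model.
#' @return A test result list with the per-subset features attached.
#' @export
comparePartitionPvalues <- function(seqsOverlap, seqsNonOverlap, x, bg) {
  if (!length(seqsOverlap) || !length(seqsNonOverlap))
    stop("both partition sides must be nonempty")
  featOf <- function(seqs, prefix) {
    names(seqs) <- paste0(prefix, seq_along(seqs))
    hits <- scanPwm(seqs, x, bg, emitAll = TRUE)
    bestHitFeature(hits, names(seqs), mode = "neglog10_p_or_one")
  }
  fo <- featOf(seqsOverlap, "ov")
  fn <- featOf(seqsNonOverlap, "no")
  res <- wilcoxonRankSum(fo, fn, alternative = "two.sided")
  res$featOverlap <- fo
  res$featNonOverlap <- fn
  res
}

#' Build a peak-strength table
#'
#' For each peak: the natural log of the narrowPeak signal (column 7) and,
#' for each supplied motif, the best-hit p-value, q-value and hit flags at
#' the standard (p < 1e-4) and strict (q < 0.05) cutoffs, from an
#' all-offsets scan.
#'
#' @param seqs Named character vector of peak sequences.
#' @param signal Per-peak narrowPeak signal values (> 0).
#' @param motifs Named list of PFMs / `megaMotif`s to scan.
#' @param bg Background model.
#' @return A data.frame with `lnSignal` and per-motif columns
#'   `<name>_minP`, `<name>_minQ`, `<name>_hit_p` (p < 1e-4),
#'   `<name>_hit_q` (q < 0.05), `<name>_neglog10q`.
#' @export
buildStrengthTable <- function(seqs, signal, motifs, bg) {
  stopifnot(length(seqs) == length(signal), all(signal > 0))
  if (is.null(names(seqs))) names(seqs) <- paste0("peak", seq_along(seqs))
  out <- data.frame(lnSignal = log(signal), row.names = names(seqs))
  for (nm in names(motifs)) {
    hits <- scanPwm(seqs, motifs[[nm]], bg, emitAll = TRUE)
    minP <- setNames(rep(1, length(seqs)), names(seqs))
    minQ <- setNames(rep(1, length(seqs)), names(seqs))
    if (nrow(hits)) {
      bp <- tapply(hits$pvalue, hits$seqname, min)
      bq <- tapply(hits$qvalue, hits$seqname, min)
      minP[names(bp)] <- bp
      minQ[names(bq)] <- bq
    }
    out[[paste0(nm, "_minP")]] <- minP
    out[[paste0(nm, "_minQ")]] <- minQ
    out[[paste0(nm, "_hit_p")]] <- minP < 1e-4
    out[[paste0(nm, "_hit_q")]] <- minQ < 0.05
    out[[paste0(nm, "_neglog10q")]] <- -log10(pmax(minQ, 1e-300))
  }
  out
}

#' Peak-strength association with the downstream motif
#'
#' Compares the peak strength (ln signal) of peaks carrying the core motif
#' but no downstream motif against peaks carrying the core-followed-by-
#' downstream mega-motif, with a two-sided Wilcoxon rank-sum test and a
#' six-fold Bonferroni correction.
#'
#' @param strength A table from [buildStrengthTable] containing motifs
#'   named `core`, `downstream` and `core_downstream`.
#' @param cutoffMode "p1e-4" (hit = p < 1e-4, the scan default) or
#'   "q0.05" (hit = q < 0.05, the strict cutoff).
#' @param m Bonferroni factor (default 6).
#' @return A test result list with `pAdjusted`, group sizes and medians.
#' @export
strengthAssociation <- function(strength, cutoffMode = c("p1e-4", "q0.05"),
                                m = 6) {
  cutoffMode <- match.arg(cutoffMode)
  suf <- if (cutoffMode == "p1e-4") "_hit_p" else "_hit_q"
  groupA <- strength[[paste0("core", suf)]] &
    !strength[[paste0("downstream", suf)]]
  groupB <- strength[[paste0("core_downstream", suf)]]
  if (!any(groupA) || !any(groupB))
    return(list(p = NA_real_, pAdjusted = NA_real_, nA = sum(groupA),
                nB = sum(groupB), flagged = "empty group"))
  res <- wilcoxonRankSum(strength$lnSignal[groupA],
                         strength$lnSignal[groupB],
                         alternative = "two.sided")
  res$pAdjusted <- bonferroniAdjust(res$p, m)
  res$nA <- sum(groupA)
  res$nB <- sum(groupB)
  res$medianA <- median(strength$lnSignal[groupA])
  res$medianB <- median(strength$lnSignal[groupB])
  res
}

#' Compare strength/motif-score correlations between two motifs
#'
#' Pearson correlation between peak strength (ln signal) and the
#' `-log10` best-hit q-value for each motif over all peaks (no-hit peaks
#' get feature 0), compared with a one-sided Fisher r-to-z test
#' (`motifY`'s correlation greater) and a six-fold Bonferroni correction.
#'
#' @param strength A table from [buildStrengthTable].
#' @param motifX,motifY Motif names in the table (reference and
#'   comparison).
#' @param m Bonferroni factor (default 6).
#' @return A test result list with `rX`, `rY` and `pAdjusted`.
#' @export
strengthCorrelationComparison <- function(strength, motifX, motifY, m = 6) {
  fx <- strength[[paste0(motifX, "_neglog10q")]]
  fy <- strength[[paste0(motifY, "_neglog10q")]]
  n <- nrow(strength)
  if (n < 4L) stop("need at least 4 peaks")
  if (sd(fx) == 0 || sd(fy) == 0 || sd(strength$lnSignal) == 0)
    stop("constant feature or strength vector")
  rX <- cor(strength$lnSignal, fx)
  rY <- cor(strength$lnSignal, fy)
  res <- fisherRtoZCompare(rY, n, rX, n, alternative = "greater")
  res$rX <- rX
  res$rY <- rY
  res$pAdjusted <- bonferroniAdjust(res$p, m)
  res
}

#' L2-regularised logistic-regression baseline
#'
#' Fits a ridge-penalised logistic regression (via glmnet, penalty
#' strength matching an sklearn-style C = 1, intercept unpenalised) on the
#' training + validation chromosomes and reports the test-chromosome AUPRC
#' -- the motif-hit-score baseline against which the network is compared.
#'
#' @param features Numeric matrix (peaks x features) of motif hit scores.
#' @param labels 0/1 labels per peak.
#' @param chroms Chromosome per peak.
#' @param split A [splitSpec].
#' @param C Inverse regularisation strength (default 1).
#' @return A list with `coef`, `testScores`, `testLabels`, `testAuprc`.
#' @export
logisticBaseline <- function(features, labels, chroms, split = splitSpec(),
                             C = 1) {
  features <- as.matrix(features)
  tr <- chroms %in% c(split$train, split$val)
  te <- chroms %in% split$test
  if (length(unique(labels[tr])) < 2L)
    stop("both classes required in train+validation")
  n <- sum(tr)
  # glmnet needs >= 2 columns; pad single features with a zero column
  Xtr <- features[tr, , drop = FALSE]
  Xte <- features[te, , drop = FALSE]
  pad <- ncol(Xtr) == 1L
  if (pad) {
    Xtr <- cbind(Xtr, 0)
    Xte <- cbind(Xte, 0)
  }
  fit <- glmnet::glmnet(Xtr, labels[tr], family = "binomial", alpha = 0,
                        lambda = 1 / (C * n), standardize = FALSE,
                        thresh = 1e-10)
  sc <- as.vector(stats::predict(fit, Xte, type = "response"))
  list(coef = as.vector(coef(fit)),
       testScores = sc, testLabels = labels[te],
       testAuprc = auprc(sc, labels[te]))
}
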