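#' Synthetic-data configuration
#'
#' Defines the generative conditions the test bench emulates: a
#' multi-chromosome i.i.d. background genome at a given GC content,
#' summit-centred peaks whose windows never leave a chromosome, a core
#' motif present in (almost) every peak, a downstream motif present only
#' in "stronger in wild-type" peaks at a fixed spacer downstream of the
#' core, negative-binomial replicate counts with sample-specific size
#' factors and a planted log2 fold-change on the positive peaks, and 20 bp
#' SELEX-style read pools with or without query-motif enrichment.
#'
#' @param nChroms Number of chromosomes (named chr1..chrN so the
#'   chromosome-based split applies).
#' @param nPeaks Total number of peaks.
#' @param flank Window half-width in bp (windows are `2 * flank`).
#' @param gc Background GC fraction (default 0.42, mouse-like).
#' @param corePfm Core motif PFM (default a sharpened 19 bp consensus).
#' @param downstreamPfm Downstream motif PFM (default sharpened GAGCCA).
#' @param spacerMin,spacerMax Spacer between core and downstream motif in
#'   positive peaks (default fixed 2 bp; widen for variable-spacing data).
#' @param fractionPositive Fraction of peaks carrying the downstream motif
#'   and the planted fold-change.
#' @param plantedLfc Planted log2 fold-change (mutant over wild type) for
#'   positive peaks (default -2).
#' @param nbMean Median peak read-count level (per-peak means are
#'   log-normal around this).
#' @param nbDispersion NB dispersion (default 0.05).
#' @param replicates Replicates per condition (default 3).
#' @param selexReadLen SELEX read length (default 20).
#' @param selexEnrichment Fraction of selected-pool reads carrying the
#'   query motif (default 0.3).
#' @param motifJitter Maximum absolute summit-relative jitter of the motif
#'   cassette (default 10 bp).
#' @return A config list.
#' @export
simConfig <- function(nChroms = 10L, nPeaks = 4000L, flank = 100L,
                      gc = 0.42,
                      corePfm = consensusPfm("TGGCCACCAGGGGGCGCTA",
                                             p = 0.85, name = "core"),
                      downstreamPfm = consensusPfm("GAGCCA", p = 0.9,
                                                   name = "downstream"),
                      spacerMin = 2L, spacerMax = 2L,
                      fractionPositive = 0.35, plantedLfc = -2,
                      nbMean = 200, nbDispersion = 0.05,
                      replicates = 3L, selexReadLen = 20L,
                      selexEnrichment = 0.3, motifJitter = 10L) {
  stopifnot(nPeaks >= 10L, gc > 0, gc < 1, spacerMin <= spacerMax,
            fractionPositive > 0, fractionPositive < 1, flank > 0)
  list(nChroms = nChroms, nPeaks = nPeaks, flank = flank, gc = gc,
       corePfm = corePfm, downstreamPfm = downstreamPfm,
       spacerMin = spacerMin, spacerMax = spacerMax,
       fractionPositive = fractionPositive, plantedLfc = plantedLfc,
       nbMean = nbMean, nbDispersion = nbDispersion,
       replicates = replicates, selexReadLen = selexReadLen,
       selexEnrichment = selexEnrichment, motifJitter = motifJitter)
}

.sampleBg <- function(n, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

.samplePfm <- function(x) {
  paste0(apply(x, 2L, function(col) sample(DNA_BASES, 1L, prob = col)),
         collapse = "")
}

#' Simulate a genome with planted peaks
#'
#' Generates an i.i.d. background genome, places non-overlapping
#' summit-centred peaks, and writes a motif cassette into each peak window
#' near the summit (jitter up to `motifJitter` bp, random strand):
#' positive peaks get core + spacer + downstream motif, negative peaks the
#' core motif only. Peak strengths (narrowPeak-style signal) are drawn
#' log-normal with positives boosted, for the strength-association
#' analyses.
#'
#' @param cfg A [simConfig].
#' @param seed RNG seed.
#' @return A list with `genome` (DNAStringSet), `peaks` (width-1 summit
#'   `GRanges` with `signal`), and `manifest` (a data.frame of ground
#'   truth: label, insert coordinates, strand, spacer, true log2FC).
#' @export
simulateGenomeAndPeaks <- function(cfg, seed = 1L) {
  set.seed(seed)
  perChrom <- ceiling(cfg$nPeaks / cfg$nChroms)
  spacing <- max(2L * cfg$flank + 60L, 250L)
  chromLen <- spacing * (perChrom + 1L)
  genome <- character(cfg$nChroms)
  names(genome) <- paste0("chr", seq_len(cfg$nChroms))
  manifest <- list()
  peakId <- 0L
  coreW <- ncol(cfg$corePfm)
  downW <- ncol(cfg$downstreamPfm)
  labels <- sample(rep(c("positive", "negative"),
                       c(round(cfg$nPeaks * cfg$fractionPositive),
                         cfg$nPeaks - round(cfg$nPeaks *
                                            cfg$fractionPositive))))
  for (ci in seq_len(cfg$nChroms)) {
    chars <- .sampleBg(chromLen, cfg$gc)
    nHere <- min(perChrom, cfg$nPeaks - peakId)
    if (nHere <= 0L) { genome[ci] <- paste0(chars, collapse = ""); next }
    summits <- spacing * seq_len(nHere)
    for (k in seq_len(nHere)) {
      peakId <- peakId + 1L
      lab <- labels[peakId]
      spacer <- sample(cfg$spacerMin:cfg$spacerMax, 1L)
      cassette <- if (lab == "positive") {
        paste0(.samplePfm(cfg$corePfm),
               paste0(.sampleBg(spacer, cfg$gc), collapse = ""),
               .samplePfm(cfg$downstreamPfm))
      } else {
        .samplePfm(cfg$corePfm)
      }
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") cassette <- revcompSeq(cassette)
      cw <- nchar(cassette)
      jit <- sample(-cfg$motifJitter:cfg$motifJitter, 1L)
      insertStart <- summits[k] - cw %/% 2L + jit   # 1-based
      chars[insertStart:(insertStart + cw - 1L)] <-
        strsplit(cassette, "")[[1L]]
      manifest[[peakId]] <- data.frame(
        peak = peakId, chrom = names(genome)[ci], summit = summits[k],
        label = lab, insertStart = insertStart,
        insertEnd = insertStart + cw - 1L, strand = strand,
        spacer = if (lab == "positive") spacer else NA_integer_,
        trueLfc = if (lab == "positive") cfg$plantedLfc else 0)
    }
    genome[ci] <- paste0(chars, collapse = "")
  }
  manifest <- do.call(rbind, manifest)
  signal <- exp(rnorm(nrow(manifest), mean = 3, sd = 0.7) +
                ifelse(manifest$label == "positive", 0.5, 0))
  peaks <- GenomicRanges::GRanges(
    seqnames = manifest$chrom,
    ranges = IRanges::IRanges(start = manifest$summit, width = 1L),
    summit = manifest$summit, label = manifest$label, signal = signal)
  list(genome = Biostrings::DNAStringSet(genome), peaks = peaks,
       manifest = manifest)
}

#' Simulate replicate counts for the planted peaks
#'
#' Negative-binomial counts with per-sample size factors drawn log-uniform
#' in \[0.5, 2\]: per-peak baseline means are log-normal around `nbMean`;
#' mutant means of positive peaks are multiplied by `2^trueLfc`; negative
#' peaks share means across conditions.
#'
#' @param cfg A [simConfig].
#' @param manifest Manifest from [simulateGenomeAndPeaks] (columns `peak`,
#'   `trueLfc`; any data.frame with those columns works).
#' @param seed RNG seed.
#' @param peaks Optional `GRanges` to attach as rowRanges.
#' @return A `SummarizedExperiment` (assay `counts`, colData `condition`,
#'   `replicate`) with the true size factors in `metadata()`.
#' @export
simulateCounts <- function(cfg, manifest, seed = 1L, peaks = NULL) {
  set.seed(seed)
  n <- nrow(manifest)
  nrep <- cfg$replicates
  sf <- exp(runif(2L * nrep, log(0.5), log(2)))
  baseMu <- exp(rnorm(n, mean = log(cfg$nbMean), sd = 0.5))
  muW <- baseMu
  muM <- baseMu * 2^manifest$trueLfc
  size <- 1 / cfg$nbDispersion
  counts <- matrix(0L, n, 2L * nrep)
  for (j in seq_len(nrep)) {
    counts[, j] <- rnbinom(n, mu = muW * sf[j], size = size)
    counts[, nrep + j] <- rnbinom(n, mu = muM * sf[nrep + j], size = size)
  }
  condition <- rep(c("WT", "mut"), each = nrep)
  if (is.null(peaks)) {
    peaks <- GenomicRanges::GRanges(
      seqnames = manifest$chrom,
      ranges = IRanges::IRanges(start = manifest$summit, width = 1L))
  }
  se <- makeCountMatrix(peaks, counts, condition,
                        replicate = rep(seq_len(nrep), 2L))
  S4Vectors::metadata(se)$sizeFactors <- sf
  S4Vectors::metadata(se)$trueLfc <- manifest$trueLfc
  se
}

#' Simulate SELEX-style read pools
#'
#' The control pool (cycle 0) is pure background; the selected pool adds,
#' in an `selexEnrichment` fraction of reads, a sequence sampled from the
#' query PFM at a uniform offset and random orientation.
#'
#' @param cfg A [simConfig].
#' @param query Query PFM (width <= read length).
#' @param n Reads per pool.
#' @param seed RNG seed.
#' @return A list with `cycle0`, `cycleK` (character vectors) and
#'   `planted` (indices of enriched reads in `cycleK`).
#' @export
simulateSelexPools <- function(cfg, query, n = 5000L, seed = 1L) {
  set.seed(seed)
  L <- cfg$selexReadLen
  W <- ncol(query)
  if (W > L) stop("query wider than the read length")
  mkRead <- function() paste0(.sampleBg(L, cfg$gc), collapse = "")
  cycle0 <- vapply(seq_len(n), function(i) mkRead(), "")
  cycleK <- vapply(seq_len(n), function(i) mkRead(), "")
  planted <- which(runif(n) < cfg$selexEnrichment)
  for (i in planted) {
    ins <- .samplePfm(query)
    if (runif(1) < 0.5) ins <- revcompSeq(ins)
    o <- sample.int(L - W + 1L, 1L)
    r <- strsplit(cycleK[i], "")[[1L]]
    r[o:(o + W - 1L)] <- strsplit(ins, "")[[1L]]
    cycleK[i] <- paste0(r, collapse = "")
  }
  list(cycle0 = cycle0, cycleK = cycleK, planted = planted)
}
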