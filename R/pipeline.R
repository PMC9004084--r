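#' Run the full differential-motif-discovery pipeline on synthetic data
#'
#' The end-to-end chain: simulate a genome with planted peaks and replicate
#' counts; run the negative-binomial differential test and label peaks
#' positive (significantly stronger in the wild type) or negative; extract
#' summit-centred windows and train the convolutional network on the
#' chromosome split; compute Rescale-rule attributions for the true
#' positive validation examples; extract, cluster and aggregate seqlets
#' into discovered motifs; and trim the top motif to its informative span.
#'
#' @param cfg A [simConfig].
#' @param seed Master seed; stage seeds are derived from it.
#' @param tc A [trainConfig] (its seed is overridden from `seed`).
#' @param split A [splitSpec]; chromosomes absent from the simulated
#'   genome are ignored.
#' @param minSeqlets Minimum seqlet support per discovered motif (default
#'   20, the desk-scale setting; 200 matches full-scale data).
#' @param seqletWidth,seqletFdr Seqlet extraction settings. The default
#'   width 31 covers the full core + spacer + downstream cassette so
#'   same-site seqlets align well.
#' @param simThreshold Leader-similarity threshold for clustering. The
#'   pipeline default 0.45 accounts for the overlap-fraction weighting of
#'   the similarity under up to ~10 bp of site jitter.
#' @param attributionTarget Readout to attribute: "logit" (default; the
#'   classifier's pre-sigmoid output, so scores reflect the decision) or
#'   "conv3" (sum of final convolutional layer activations).
#' @param outDir Optional directory; when given, the genome FASTA, peak
#'   BED, count TSV, label BED, motif MEME file, training log and a JSON
#'   summary are written there.
#' @return A list with the simulation, differential results, labels,
#'   trained model, per-split AUPRCs, discovered motifs, the trimmed
#'   top-motif consensus and `flagshipRecovered` (does it contain the
#'   planted downstream consensus).
#' @export
runPipeline <- function(cfg = simConfig(), seed = 1L,
                        tc = trainConfig(), split = splitSpec(),
                        minSeqlets = 20L, seqletWidth = 31L,
                        seqletFdr = 0.2, simThreshold = 0.45,
                        attributionTarget = c("logit", "conv3"),
                        outDir = NULL) {
  attributionTarget <- match.arg(attributionTarget)
  sim <- simulateGenomeAndPeaks(cfg, seed = seed)
  se <- simulateCounts(cfg, sim$manifest, seed = seed + 1L,
                       peaks = sim$peaks)
  diffRes <- nbWaldTest(se)
  labels <- labelDifferential(diffRes)

  keep <- labels != "excluded"
  man <- sim$manifest[keep, , drop = FALSE]
  lab01 <- as.integer(labels[keep] == "positive")
  seqs <- vapply(seq_len(nrow(man)), function(i)
    extractWindow(sim$genome, man$chrom[i], man$summit[i], cfg$flank), "")
  ex <- makeExampleSet(seqs, lab01, man$chrom, peakIds = man$peak)

  tc$seed <- seed + 2L
  model <- buildConvNet(convNetConfig(inputLen = 2L * cfg$flank),
                        seed = seed + 2L)
  model <- trainConvNet(model, ex, split = split, tc = tc)

  metrics <- list()
  for (part in c("val", "test")) {
    sel <- ex$chrom %in% split[[part]]
    sc <- predictConvNet(model, ex$X[, , sel, drop = FALSE],
                         peakIds = ex$peakId[sel])
    yl <- tapply(ex$y[sel], ex$peakId[sel], max)[names(sc)]
    metrics[[paste0(part, "Auprc")]] <- auprc(sc, yl)
    metrics[[paste0(part, "Recall80")]] <- recallAtPrecision(sc, yl)
  }

  # attribution on true positive validation examples
  valIdx <- which(ex$chrom %in% split$val & ex$y == 1)
  valScores <- predictConvNet(model, ex$X[, , valIdx, drop = FALSE])
  tpIdx <- valIdx[valScores > 0.5]
  tracks <- list()
  if (length(tpIdx)) {
    att <- rescaleContributions(model, ex$X[, , tpIdx, drop = FALSE],
                                target = attributionTarget)
    tracks <- lapply(seq_along(tpIdx), function(i)
      list(contrib = att$contrib[, , i], hyp = att$hyp[, , i],
           onehot = ex$X[, , tpIdx[i]]))
  }
  motifs <- discoverMotifs(tracks, width = seqletWidth, fdr = seqletFdr,
                           simThreshold = simThreshold,
                           minSeqlets = minSeqlets, seed = seed + 3L)

  # dissect the top motif with the core-style and downstream-end trims
  trimmedConsensus <- NA_character_
  trimmedDownstreamConsensus <- NA_character_
  flagship <- FALSE
  if (length(motifs)) {
    top <- motifs[[1L]]
    # dissect only the well-supported span: sparse flank columns are
    # averages of a handful of members and carry no motif signal
    ok <- top@coverage >= 0.5 * max(top@coverage)
    runs <- rle(ok)
    ends <- cumsum(runs$lengths)
    big <- which(runs$values)[which.max(runs$lengths[runs$values])]
    cov <- seq.int(ends[big] - runs$lengths[big] + 1L, ends[big])
    topPfm <- pfm(top@pfm[, cov, drop = FALSE], name = "top")
    trimOrNA <- function(rule) {
      tryCatch(consensusOfMatrix(trimPfm(topPfm, rule)),
               error = function(e) NA_character_)
    }
    trimmedConsensus <- trimOrNA(coreTrimRule())
    trimmedDownstreamConsensus <- trimOrNA(downstreamTrimRule())
    downCons <- consensusOfMatrix(cfg$downstreamPfm)
    hasDown <- function(s) {
      !is.na(s) && (grepl(downCons, s, fixed = TRUE) ||
                    grepl(revcompSeq(downCons), s, fixed = TRUE))
    }
    flagship <- hasDown(trimmedConsensus) ||
      hasDown(trimmedDownstreamConsensus)
  }

  out <- list(sim = sim, counts = se, diff = diffRes, labels = labels,
              model = model, metrics = metrics, motifs = motifs,
              trimmedConsensus = trimmedConsensus,
              trimmedDownstreamConsensus = trimmedDownstreamConsensus,
              flagshipRecovered = flagship, nTracks = length(tracks))
  if (!is.null(outDir)) .writePipelineOutputs(out, cfg, outDir)
  out
}

.writePipelineOutputs <- function(out, cfg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  writeGenome(out$sim$genome, file.path(outDir, "genome.fa"))
  pk <- out$sim$peaks
  pk$name <- paste0("peak", seq_along(pk))
  writeBed(peakWindows(pk, cfg$flank), file.path(outDir, "peaks.bed"))
  lb <- pk
  lb$name <- as.character(out$labels)
  writeBed(peakWindows(lb, cfg$flank), file.path(outDir, "labels.bed"))
  cnt <- SummarizedExperiment::assay(out$counts, "counts")
  write.table(data.frame(peak_id = paste0("peak", seq_len(nrow(cnt))), cnt),
              file.path(outDir, "counts.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cbind(peak_id = paste0("peak", seq_len(nrow(out$diff))),
                    out$diff),
              file.path(outDir, "differential.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(out$sim$manifest, file.path(outDir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (length(out$motifs)) {
    pfms <- lapply(seq_along(out$motifs), function(i) {
      m <- out$motifs[[i]]@pfm
      cov <- colSums(m) > 0
      pfm(m[, cov, drop = FALSE], name = paste0("discovered_", i))
    })
    writeMeme(pfms, file.path(outDir, "motifs.meme"))
    imp <- do.call(rbind, lapply(seq_along(out$motifs), function(i) {
      m <- out$motifs[[i]]@importance
      data.frame(motif = paste0("discovered_", i),
                 base = rep(DNA_BASES, ncol(m)),
                 position = rep(seq_len(ncol(m)), each = 4L),
                 importance = as.vector(m))
    }))
    write.table(imp, file.path(outDir, "motif_importance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(out$model@log, file.path(outDir, "training_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(metrics = out$metrics,
                  nMotifs = length(out$motifs),
                  trimmedConsensus = out$trimmedConsensus,
                  trimmedDownstreamConsensus =
                    out$trimmedDownstreamConsensus,
                  flagshipRecovered = out$flagshipRecovered,
                  labelCounts = as.list(table(out$labels)))
  jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outDir)
}
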