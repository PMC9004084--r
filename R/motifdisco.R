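#' @title DiscoveredMotif: an aggregate of attributed seqlets
#'
#' @description The result of clustering high-attribution seqlets: a
#' fixed-width position frequency matrix (the mean of the aligned one-hot
#' sequences), a matching importance matrix (the mean of the aligned
#' hypothetical scores), the number of supporting seqlets and the rank by
#' support.
#'
#' @slot pfm 4 x width PFM (columns sum to 1 where covered, 0 elsewhere).
#' @slot importance 4 x width mean hypothetical-score matrix.
#' @slot coverage Number of seqlets covering each column.
#' @slot nSeqlets Number of supporting seqlets.
#' @slot rank Rank by seqlet support (1 = most supported).
#' @export
setClass("DiscoveredMotif",
         representation(pfm = "matrix", importance = "matrix",
                        coverage = "numeric", nSeqlets = "integer",
                        rank = "integer"))

setMethod("show", "DiscoveredMotif", function(object) {
  cat("DiscoveredMotif rank", object@rank, "(", object@nSeqlets,
      "seqlets )\n")
  cov <- colSums(object@pfm) > 0
  cat("  consensus:",
      consensusOfMatrix(object@pfm[, cov, drop = FALSE]), "\n")
})

#' Extract high-attribution seqlets
#'
#' Slides a window of `width` bp over each attribution track, scoring
#' windows by the sum of absolute contributions. A null distribution is
#' built from the same window sums on tracks whose per-position attribution
#' values are shuffled within each peak in non-overlapping 2 bp blocks; the
#' extraction threshold is the smallest window score at which the empirical
#' false discovery rate (null exceedances over real exceedances) is at most
#' `fdr`. Overlapping passing windows are resolved per track by greedy
#' non-maximum suppression: windows are accepted in decreasing score order
#' and any window overlapping an accepted one is suppressed, so an
#' isolated high-scoring site yields exactly one seqlet.
#'
#' @param tracks A list, one element per peak, each a list with `contrib`
#'   and `hyp` 4 x L matrices (from [rescaleContributions]) and `onehot`
#'   (the 4 x L input).
#' @param width Seqlet width in bp (default 21).
#' @param fdr Seqlet FDR threshold (default 0.2).
#' @param seed Seed for the null shuffle.
#' @return A list of seqlets, each a list with `peak`, `start` (1-based
#'   offset within the window), `width`, `onehot`, `scores`, `hyp`,
#'   `total` (summed absolute contribution) and `orientation` ("fwd").
#' @export
extractSeqlets <- function(tracks, width = 21L, fdr = 0.2, seed = 1L) {
  stopifnot(length(tracks) > 0L)
  set.seed(seed)
  winSums <- function(v) {
    cs <- cumsum(c(0, v))
    cs[(width + 1L):length(cs)] - cs[seq_len(length(cs) - width)]
  }
  posImp <- lapply(tracks, function(tr) colSums(abs(tr$contrib)))
  real <- lapply(posImp, winSums)
  shuffled <- lapply(posImp, function(v) {
    nb <- ceiling(length(v) / 2L)
    blocks <- split(v, rep(seq_len(nb), each = 2L)[seq_along(v)])
    unlist(blocks[sample.int(nb)], use.names = FALSE)
  })
  null <- lapply(shuffled, winSums)
  allReal <- unlist(real, use.names = FALSE)
  allNull <- unlist(null, use.names = FALSE)
  if (all(allReal == 0)) return(list())
  cand <- sort(unique(allReal), decreasing = TRUE)
  thr <- NA_real_
  nullSorted <- sort(allNull)
  realSorted <- sort(allReal)
  for (t in rev(cand)) {   # ascending: smallest threshold passing FDR
    nNull <- length(allNull) - findInterval(t - 1e-12, nullSorted)
    nReal <- length(allReal) - findInterval(t - 1e-12, realSorted)
    if (nReal > 0L && nNull / nReal <= fdr) { thr <- t; break }
  }
  if (is.na(thr)) return(list())
  out <- list()
  for (i in seq_along(tracks)) {
    sc <- real[[i]]
    pass <- which(sc >= thr)
    if (!length(pass)) next
    # ties (flat plateaus) resolved towards the window whose importance
    # peak sits closest to the window centre
    centring <- vapply(pass, function(p) {
      seg <- posImp[[i]][p:(p + width - 1L)]
      abs(which.max(seg) - (width + 1) / 2)
    }, 0)
    pass <- pass[order(-sc[pass], centring)]
    kept <- integer(0)
    for (p in pass) {
      if (!length(kept) || all(abs(kept - p) >= width)) kept <- c(kept, p)
    }
    for (p in sort(kept)) {
      cols <- p:(p + width - 1L)
      out[[length(out) + 1L]] <- list(
        peak = i, start = p, width = width,
        onehot = tracks[[i]]$onehot[, cols, drop = FALSE],
        scores = tracks[[i]]$contrib[, cols, drop = FALSE],
        hyp = tracks[[i]]$hyp[, cols, drop = FALSE],
        total = sc[p], orientation = "fwd")
    }
  }
  out
}

#' Similarity between two seqlets
#'
#' The maximum, over relative offsets up to half the seqlet width in either
#' direction and over both orientations, of the cosine similarity between
#' the hypothetical-score matrices on the overlapping columns, weighted by
#' the overlap fraction. The best offset and orientation are returned as
#' attributes (`offset`, `orientation`), recording how `b` aligns to `a`.
#'
#' @param a,b Seqlets (equal widths).
#' @return Similarity in \[-1, 1\] with alignment attributes.
#' @export
seqletSimilarity <- function(a, b) {
  w <- ncol(a$hyp)
  stopifnot(ncol(b$hyp) == w)
  maxOff <- floor(w / 2)
  best <- -Inf; bestOff <- 0L; bestOri <- "fwd"
  for (ori in c("fwd", "rev")) {
    hb <- if (ori == "rev") revcompOneHot(b$hyp) else b$hyp
    for (off in (-maxOff):maxOff) {
      ja <- max(1L, 1L + off):min(w, w + off)
      jb <- ja - off
      va <- as.vector(a$hyp[, ja, drop = FALSE])
      vb <- as.vector(hb[, jb, drop = FALSE])
      na <- sqrt(sum(va^2)); nb <- sqrt(sum(vb^2))
      if (na == 0 || nb == 0) next
      s <- sum(va * vb) / (na * nb) * (length(ja) / w)
      if (s > best) { best <- s; bestOff <- off; bestOri <- ori }
    }
  }
  structure(best, offset = bestOff, orientation = bestOri)
}

#' Greedy leader clustering of seqlets
#'
#' Seqlets are visited in decreasing order of total absolute contribution.
#' Each seqlet joins the first existing cluster whose leader it matches
#' with similarity at least `simThreshold` (recording the best offset and
#' orientation), otherwise it founds a new cluster. Clusters with fewer
#' than `minSeqlets` members are discarded; survivors are sorted by size.
#'
#' @param seqlets List of seqlets from [extractSeqlets].
#' @param simThreshold Leader-similarity threshold (default 0.8).
#' @param minSeqlets Minimum cluster size (default 200, lowered for
#'   desk-scale data).
#' @return A list of clusters; each is a list of members, every member a
#'   seqlet with `offset` and `orientation` fields relative to the leader.
#' @export
clusterSeqlets <- function(seqlets, simThreshold = 0.8, minSeqlets = 200L) {
  if (!length(seqlets)) return(list())
  ord <- order(vapply(seqlets, function(s) s$total, 0), decreasing = TRUE)
  clusters <- list()
  for (i in ord) {
    s <- seqlets[[i]]
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      leader <- clusters[[ci]][[1L]]
      sim <- seqletSimilarity(leader, s)
      if (as.numeric(sim) >= simThreshold) {
        s$offset <- attr(sim, "offset")
        s$orientation <- attr(sim, "orientation")
        clusters[[ci]][[length(clusters[[ci]]) + 1L]] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      s$offset <- 0L
      s$orientation <- "fwd"
      clusters[[length(clusters) + 1L]] <- list(s)
    }
  }
  sizes <- vapply(clusters, length, 0L)
  clusters <- clusters[sizes >= minSeqlets]
  clusters[order(vapply(clusters, length, 0L), decreasing = TRUE)]
}

#' Aggregate a seqlet cluster into a motif
#'
#' Members are mapped onto a common frame using their stored offsets and
#' orientations (reverse-orientation members are reverse-complemented
#' first), the leader is centred in a window of `outWidth` columns, and the
#' PFM and importance matrix are the per-column means of the one-hot
#' sequences and hypothetical scores over the members covering each column.
#' Uncovered columns are zero.
#'
#' @param cluster One cluster from [clusterSeqlets].
#' @param outWidth Output motif width (default 50).
#' @param rank Rank to record (default 1).
#' @return A [DiscoveredMotif-class].
#' @export
aggregateCluster <- function(cluster, outWidth = 50L, rank = 1L) {
  stopifnot(length(cluster) > 0L)
  w <- cluster[[1L]]$width
  centre <- (outWidth - w) %/% 2L  # leader columns at centre + 1 .. centre + w
  pfmSum <- matrix(0, 4L, outWidth, dimnames = list(DNA_BASES, NULL))
  impSum <- matrix(0, 4L, outWidth)
  cover <- numeric(outWidth)
  for (m in cluster) {
    oh <- m$onehot
    hy <- m$hyp
    if (!is.null(m$orientation) && m$orientation == "rev") {
      oh <- revcompOneHot(oh)
      hy <- revcompOneHot(hy)
    }
    off <- if (is.null(m$offset)) 0L else m$offset
    cols <- centre + off + seq_len(w)   # member column j sits at leader j+off
    keep <- cols >= 1L & cols <= outWidth
    pfmSum[, cols[keep]] <- pfmSum[, cols[keep]] + oh[, keep, drop = FALSE]
    impSum[, cols[keep]] <- impSum[, cols[keep]] + hy[, keep, drop = FALSE]
    cover[cols[keep]] <- cover[cols[keep]] + 1L
  }
  covered <- cover > 0
  pfmOut <- pfmSum
  pfmOut[, covered] <- sweep(pfmSum[, covered, drop = FALSE], 2L,
                             cover[covered], "/")
  impOut <- impSum
  impOut[, covered] <- sweep(impSum[, covered, drop = FALSE], 2L,
                             cover[covered], "/")
  new("DiscoveredMotif", pfm = pfmOut, importance = impOut,
      coverage = cover, nSeqlets = length(cluster),
      rank = as.integer(rank))
}

# Realign cluster members against the cluster's aggregate importance
# matrix: a leader is one noisy seqlet, but the aggregate averages the
# noise away, so one or two realignment passes sharpen blurred columns.
.refineClusterAlignment <- function(cluster, outWidth, iterations = 2L) {
  w <- cluster[[1L]]$width
  centre <- (outWidth - w) %/% 2L
  for (it in seq_len(iterations)) {
    agg <- aggregateCluster(cluster, outWidth = outWidth)
    imp <- agg@importance
    W <- ncol(imp)
    for (mi in seq_along(cluster)) {
      hyF <- cluster[[mi]]$hyp
      best <- -Inf; bestP <- centre + 1L; bestOri <- "fwd"
      for (ori in c("fwd", "rev")) {
        hy <- if (ori == "rev") revcompOneHot(hyF) else hyF
        nh <- sqrt(sum(hy^2))
        if (nh == 0) next
        for (p in seq_len(W - w + 1L)) {
          seg <- imp[, p:(p + w - 1L), drop = FALSE]
          ns <- sqrt(sum(seg^2))
          if (ns == 0) next
          s <- sum(hy * seg) / (nh * ns)
          if (s > best) { best <- s; bestP <- p; bestOri <- ori }
        }
      }
      cluster[[mi]]$offset <- bestP - 1L - centre
      cluster[[mi]]$orientation <- bestOri
    }
  }
  cluster
}

#' Discover motifs from attribution tracks
#'
#' The simplified seqlet-aggregation pipeline: extract high-attribution
#' seqlets, cluster them by hypothetical-score similarity, refine member
#' alignments against each cluster's aggregate, aggregate each surviving
#' cluster, and rank motifs by seqlet support.
#'
#' @inheritParams extractSeqlets
#' @inheritParams clusterSeqlets
#' @inheritParams aggregateCluster
#' @param refine Alignment-refinement passes against the cluster
#'   aggregate (default 4; 0 disables).
#' @return A list of [DiscoveredMotif-class] objects sorted by support.
#' @export
discoverMotifs <- function(tracks, width = 21L, fdr = 0.2,
                           simThreshold = 0.8, minSeqlets = 200L,
                           outWidth = 50L, refine = 4L, seed = 1L) {
  seqlets <- extractSeqlets(tracks, width = width, fdr = fdr, seed = seed)
  clusters <- clusterSeqlets(seqlets, simThreshold = simThreshold,
                             minSeqlets = minSeqlets)
  lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    if (refine > 0L)
      cl <- .refineClusterAlignment(cl, outWidth, iterations = refine)
    aggregateCluster(cl, outWidth = outWidth, rank = i)
  })
}
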