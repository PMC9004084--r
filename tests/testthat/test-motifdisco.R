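# Build an attribution-track fixture with spikes of importance at known
# sites; hypothetical scores carry a motif pattern at the spike.
spikeTrack <- function(L = 120, sites = integer(0), pattern = NULL,
                       noise = 0) {
  contrib <- matrix(0, 4, L)
  hyp <- matrix(noise * rnorm(4 * L), 4, L)
  onehot <- oneHot(randomDna(L))
  for (s in sites) {
    w <- ncol(pattern)
    cols <- s:(s + w - 1)
    hyp[, cols] <- hyp[, cols] + pattern
    contrib[, cols] <- pattern * onehot[, cols]
    # put the observed-base contribution mass at the site
    contrib[, cols] <- contrib[, cols] + onehot[, cols]
  }
  list(contrib = contrib, hyp = hyp, onehot = onehot)
}

test_that("an isolated contribution spike yields exactly one seqlet centred on it", {
  set.seed(41)
  pat <- pfmToPwm(consensusPfm("GAGCCA", 0.9), gcBackground(0.5))
  tracks <- lapply(1:30, function(i) spikeTrack(sites = 50, pattern = pat))
  seqlets <- extractSeqlets(tracks, width = 21, fdr = 0.2)
  perTrack <- table(vapply(seqlets, function(s) s$peak, 0))
  # full-overlap non-maximum suppression: one seqlet per isolated site
  expect_true(all(perTrack == 1))
  centres <- vapply(seqlets, function(s) s$start + (s$width - 1) / 2, 0)
  expect_true(all(abs(centres - 52.5) <= 3.5))
})

test_that("all-zero tracks yield no seqlets", {
  tracks <- lapply(1:5, function(i)
    list(contrib = matrix(0, 4, 60), hyp = matrix(0, 4, 60),
         onehot = oneHot(randomDna(60))))
  expect_length(extractSeqlets(tracks), 0)
})

test_that("planted high-scoring sites are recovered within 3 bp at high rate", {
  set.seed(43)
  pat <- pfmToPwm(consensusPfm("GAGCCA", 0.9), gcBackground(0.5))
  sites <- sample(30:90, 300, replace = TRUE)
  tracks <- lapply(sites, function(s)
    spikeTrack(L = 150, sites = s, pattern = pat, noise = 0.02))
  seqlets <- extractSeqlets(tracks, width = 21, fdr = 0.2)
  hit <- logical(length(sites))
  for (sq in seqlets) {
    ctr <- sq$start + (sq$width - 1) / 2
    if (abs(ctr - (sites[sq$peak] + 2.5)) <= 3 + (21 - 6) / 2)
      hit[sq$peak] <- TRUE
  }
  expect_gt(mean(hit), 0.95)
})

test_that("seqlet similarity is maximal for identical seqlets and matches a brute-force scan", {
  set.seed(44)
  mk <- function(hyp) list(hyp = hyp, width = ncol(hyp))
  h <- matrix(rnorm(4 * 21), 4, 21, dimnames = list(c("A","C","G","T"), NULL))
  a <- mk(h)
  expect_equal(as.numeric(seqletSimilarity(a, a)), 1)
  # sign flip: at width 1 the only alignment is offset 0, so the
  # similarity of a seqlet against its negation is exactly -1 (a
  # row-palindromic column keeps the reverse orientation at -1 too)
  hp <- matrix(c(1, 2, 2, 1), 4, 1, dimnames = list(rownames(h), NULL))
  expect_equal(as.numeric(seqletSimilarity(mk(hp), mk(-hp))), -1)

  # shifted copy: compare against an independent exhaustive oracle
  bruteSim <- function(ha, hb) {
    w <- ncol(ha)
    best <- -Inf
    for (ori in 1:2) {
      hh <- if (ori == 2) hb[4:1, w:1] else hb
      for (off in -floor(w / 2):floor(w / 2)) {
        ja <- max(1, 1 + off):min(w, w + off)
        va <- as.vector(ha[, ja]); vb <- as.vector(hh[, ja - off])
        if (sum(va^2) == 0 || sum(vb^2) == 0) next
        s <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2)) * length(ja) / w
        best <- max(best, s)
      }
    }
    best
  }
  for (i in 1:10) {
    h1 <- matrix(rnorm(84), 4, 21, dimnames = list(c("A","C","G","T"), NULL))
    h2 <- cbind(h1[, 4:21], matrix(rnorm(12), 4, 3))
    dimnames(h2) <- dimnames(h1)
    expect_equal(as.numeric(seqletSimilarity(mk(h1), mk(h2))),
                 bruteSim(h1, h2), tolerance = 1e-12)
  }
})

test_that("similarity recognises a reverse-complemented seqlet", {
  h <- matrix(rnorm(84), 4, 21, dimnames = list(c("A","C","G","T"), NULL))
  a <- list(hyp = h, width = 21)
  b <- list(hyp = revcompOneHot(h), width = 21)
  s <- seqletSimilarity(a, b)
  expect_equal(as.numeric(s), 1)
  expect_equal(attr(s, "orientation"), "rev")
})

test_that("leader clustering groups copies, separates dissimilar motifs, applies the size floor", {
  set.seed(46)
  mkSeqlet <- function(hyp, total) {
    oh <- oneHot(randomDna(ncol(hyp)))
    list(hyp = hyp, onehot = oh, scores = hyp * oh, total = total,
         width = ncol(hyp), peak = 1, start = 1, orientation = "fwd")
  }
  h <- matrix(rnorm(84), 4, 21)
  copies <- lapply(1:10, function(i) mkSeqlet(h, 10 - i * 0.1))
  cl <- clusterSeqlets(copies, minSeqlets = 2)
  expect_length(cl, 1)
  expect_length(cl[[1]], 10)

  h2 <- matrix(rnorm(84), 4, 21)  # independent pattern, similarity << 0.8
  mixed <- c(lapply(1:8, function(i) mkSeqlet(h, 5)),
             lapply(1:8, function(i) mkSeqlet(h2, 4)))
  cl2 <- clusterSeqlets(mixed, minSeqlets = 2)
  expect_length(cl2, 2)
  expect_equal(vapply(cl2, length, 0L), c(8L, 8L))

  expect_length(clusterSeqlets(copies, minSeqlets = 11), 0)
  # cluster sizes never exceed the seqlet count
  expect_lte(sum(vapply(cl2, length, 0L)), length(mixed))
})

test_that("aggregation averages aligned one-hot and hypothetical matrices", {
  seqA <- "GAGCCAGAGCCAGAGCCAGAG"
  ohA <- oneHot(seqA)
  base <- list(hyp = matrix(1, 4, 21), onehot = ohA, scores = ohA,
               total = 5, width = 21L, peak = 1, start = 1,
               orientation = "fwd", offset = 0L)
  cl <- list(base, base)
  mot <- aggregateCluster(cl, outWidth = 50, rank = 1)
  cov <- colSums(mot@pfm) > 0
  expect_equal(sum(cov), 21)
  expect_equal(consensusOfMatrix(mot@pfm[, cov]), seqA)
  expect_true(all(abs(colSums(mot@pfm[, cov]) - 1) < 1e-9))

  # two members differing at one base (G in one, C in the other)
  # average to a half/half column
  ohB <- ohA
  ohB[, 1] <- c(0, 1, 0, 0)  # G -> C at the first column
  memberB <- base
  memberB$onehot <- ohB
  mot2 <- aggregateCluster(list(base, memberB), outWidth = 50)
  covCols <- which(colSums(mot2@pfm) > 0)
  expect_equal(unname(mot2@pfm[c("C", "G"), covCols[1]]), c(0.5, 0.5))

  # offsets shift members within the frame
  memberC <- base
  memberC$offset <- 3L
  mot3 <- aggregateCluster(list(base, memberC), outWidth = 50)
  expect_equal(sum(colSums(mot3@pfm) > 0), 24)
})
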