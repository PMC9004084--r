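test_that("SELEX read scoring matches an exhaustive-alignment oracle and strand symmetry", {
  bruteScore <- function(read, query) {
    ohs <- list(oneHot(read), revcompOneHot(oneHot(read)))
    W <- ncol(query); L <- nchar(read)
    best <- -Inf
    for (oh in ohs) {
      if (L >= W) {
        for (o in 0:(L - W))
          best <- max(best, sum(oh[, (o + 1):(o + W)] * query))
      } else {
        for (o in 0:(W - L))
          best <- max(best, sum(oh * query[, (o + 1):(o + L)]))
      }
    }
    best
  }
  set.seed(51)
  bg <- gcBackground()
  query <- buildSelexQuery(consensusPfm(randomDna(19)),
                           consensusPfm("GAGCCA"), bg)
  reads <- vapply(1:200, function(i) randomDna(20), "")
  pool <- dbdmotif:::.selexPoolScores(reads, query)
  for (i in seq_along(reads)) {
    s <- selexReadScore(reads[i], query)
    expect_equal(s, bruteScore(reads[i], query))
    expect_equal(s, selexReadScore(revcompSeq(reads[i]), query))
    expect_equal(s, pool[i])   # vectorised pool path agrees
  }
  # consensus of a 0/1 query scores its width
  oneq <- pfm(oneHot("GATTACA"))
  expect_equal(selexReadScore("GATTACA", oneq), 7)
  # read shorter than query: read slides within the query
  expect_equal(selexReadScore("GAT", oneq), 3)
})

test_that("SELEX enrichment test is powered under planting and calm under the null", {
  cfgS <- simConfig(nPeaks = 10)
  bg <- gcBackground(cfgS$gc)
  query <- buildSelexQuery(cfgS$corePfm, cfgS$downstreamPfm, bg)

  pools <- simulateSelexPools(cfgS, query, n = 800, seed = 52)
  res <- selexEnrichmentTest(pools$cycle0, pools$cycleK, query)
  expect_lt(res$p, 1e-6)

  cfg0 <- simConfig(nPeaks = 10, selexEnrichment = 0)
  p0 <- vapply(1:10, function(i) {
    pl <- simulateSelexPools(cfg0, query, n = 150, seed = 100 + i)
    selexEnrichmentTest(pl$cycle0, pl$cycleK, query)$p
  }, 0)
  expect_gt(median(p0), 0.15)
  expect_lt(median(p0), 0.85)
  expect_error(selexEnrichmentTest(character(0), "ACGT", query), "empty")
})

test_that("aggregate hit logos recover the planted consensus", {
  set.seed(53)
  bg <- gcBackground(0.5)
  query <- consensusPfm("GAGCCATT", p = 0.95)
  reads <- vapply(1:300, function(i) {
    r <- randomDna(20)
    if (i <= 225) {
      ins <- paste0(vapply(1:8, function(j)
        if (runif(1) < 0.9) substr("GAGCCATT", j, j)
        else sample(c("A", "C", "G", "T"), 1), ""), collapse = "")
      o <- sample(1:13, 1)
      substr(r, o, o + 7) <- ins
    }
    r
  }, "")
  logos <- aggregateHitLogo(reads, query, bg)
  expect_named(logos, c("q0.05", "q0.01", "q0.005", "q0.001"))
  lg <- logos[["q0.05"]]
  expect_false(is.null(lg))
  expect_equal(colSums(lg), rep(1, 8))
  expect_true(all(apply(lg, 2, max) >= 0.8))
})

test_that("overlap partitioning uses strict and relaxed references asymmetrically", {
  gr <- function(...) GenomicRanges::GRanges("chr1", IRanges::IRanges(...))
  a <- gr(start = c(1, 1, 200), end = c(100, 100, 250))[1]
  strict <- gr(start = 100, end = 150)
  expect_length(partitionByOverlap(a, strict, strict)$overlapping, 1)

  # touching is not overlap: a peak ending where the relaxed set begins
  # still counts as non-overlapping
  relaxed <- gr(start = 101, end = 200)   # 0-based [100,200)
  expect_length(partitionByOverlap(a, strict[0], relaxed)$non_overlapping,
                1)
  relaxed2 <- gr(start = 50, end = 200)
  # overlaps relaxed but not strict: excluded from both subsets
  part <- partitionByOverlap(a, gr(start = 300, end = 400), relaxed2)
  expect_length(part$overlapping, 0)
  expect_length(part$non_overlapping, 0)
  # disjoint sides whenever strict is contained in relaxed
  set.seed(54)
  peaks <- gr(start = seq(1, 5000, by = 50), width = 40)
  strictR <- gr(start = sample(1:5000, 20), width = 30)
  relaxedR <- c(strictR, gr(start = sample(1:5000, 40), width = 30))
  p2 <- partitionByOverlap(peaks, strictR, relaxedR)
  expect_length(GenomicRanges::intersect(p2$overlapping,
                                         p2$non_overlapping), 0)
})

test_that("partition p-value comparison separates planted from background sides", {
  set.seed(55)
  bg <- gcBackground(0.5)
  mm <- buildMegaMotif(list(consensusPfm("TGACGTCA", 0.95)), integer(0), bg)
  withM <- vapply(1:60, function(i) {
    s <- randomDna(120)
    o <- sample(20:90, 1)
    substr(s, o, o + 7) <- "TGACGTCA"
    s
  }, "")
  without <- vapply(1:60, function(i) randomDna(120), "")
  res <- comparePartitionPvalues(withM, without, mm, bg)
  expect_lt(res$p, 1e-10)
  # same content on both sides: no signal
  res0 <- comparePartitionPvalues(without[1:30], without[31:60], mm, bg)
  expect_gt(res0$p, 0.01)
})

test_that("strength association and correlation comparison respond to planted structure", {
  set.seed(56)
  bg <- gcBackground(0.5)
  # variable-quality instances (sampled from the PFMs) so motif-hit flags
  # actually partition the peaks
  core <- consensusPfm("TGGCCACCAGGGGGCGCTA", 0.7, name = "core")
  down <- consensusPfm("GAGCCA", 0.9, name = "downstream")
  pres <- megaMotifPresets(core, consensusPfm(randomDna(10)), down, bg)
  n <- 250
  hasDown <- rep(c(TRUE, FALSE), length.out = n)
  samp <- function(x) paste0(apply(x, 2, function(col)
    sample(c("A", "C", "G", "T"), 1, prob = col)), collapse = "")
  seqs <- vapply(seq_len(n), function(i) {
    s <- randomDna(160)
    ins <- if (hasDown[i]) paste0(samp(core), "CA", samp(down))
           else samp(core)
    o <- sample(30:100, 1)
    substr(s, o, o + nchar(ins) - 1) <- ins
    s
  }, "")
  signal <- exp(rnorm(n, 3, 0.3) + ifelse(hasDown, 0.6, 0))
  st <- buildStrengthTable(seqs, signal,
                           motifs = list(core = pres$core,
                                         downstream = pres$downstream,
                                         core_downstream =
                                           pres$core_downstream),
                           bg)
  # the composite flag is enriched in the peaks that carry the cassette
  expect_gt(mean(st$core_downstream_hit_p[hasDown]),
            mean(st$core_downstream_hit_p[!hasDown]) + 0.2)
  res <- strengthAssociation(st)
  expect_lt(res$pAdjusted, 0.05)
  expect_gt(res$medianB, res$medianA)
  res2 <- strengthAssociation(st, cutoffMode = "q0.05")
  expect_true(is.finite(res2$pAdjusted))

  cc <- strengthCorrelationComparison(st, "core", "core_downstream")
  expect_gt(cc$rY, cc$rX)
  expect_lt(cc$pAdjusted, 1e-6)
  # identical motif: centred null
  cc0 <- strengthCorrelationComparison(st, "core", "core")
  expect_equal(cc0$statistic, 0)
  expect_equal(cc0$p, 0.5)
})

test_that("the group comparison itself is powered at the documented sizes", {
  set.seed(57)
  mkTable <- function(shift) {
    n <- 1000
    grpB <- rep(c(FALSE, TRUE), each = n / 2)
    data.frame(lnSignal = rnorm(n, 3, 0.5) + ifelse(grpB, shift, 0),
               core_hit_p = TRUE,
               downstream_hit_p = grpB,   # group A = core & !downstream
               core_downstream_hit_p = grpB)
  }
  shifted <- strengthAssociation(mkTable(0.5))
  expect_lt(shifted$pAdjusted, 1e-6)
  expect_equal(shifted$nA, 500)
  expect_equal(shifted$nB, 500)
  null <- strengthAssociation(mkTable(0))
  expect_gt(null$pAdjusted, 0.05)
})

test_that("the logistic baseline is sane on perfect and null features", {
  set.seed(57)
  n <- 400
  chroms <- rep(c("chr3", "chr8", "chr1"), length.out = n)
  y <- rbinom(n, 1, 0.4)
  perfect <- logisticBaseline(matrix(y + rnorm(n, sd = 0.01)), y, chroms)
  expect_gt(perfect$testAuprc, 0.99)
  null <- logisticBaseline(matrix(rnorm(n)), y, chroms)
  prev <- mean(null$testLabels)
  expect_lt(abs(null$testAuprc - prev), 0.2)
  expect_error(logisticBaseline(matrix(rnorm(10)), rep(1, 10),
                                rep("chr3", 10)),
               "both classes")
})
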