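test_that("summit merging chains within the radius and averages summits", {
  df <- function(s) data.frame(chrom = "chr1", summit = s)
  m1 <- mergeSummitPeaks(df(c(100, 140)))
  expect_length(m1, 1)
  expect_equal(m1$summit, 120L)

  m2 <- mergeSummitPeaks(df(c(100, 160)))
  expect_length(m2, 2)

  # transitive chain 0-40-80 collapses even though 0 and 80 are 80 apart
  m3 <- mergeSummitPeaks(df(c(1, 41, 81)))
  expect_length(m3, 1)
  expect_equal(m3$summit, 41L)

  # half-up rounding of the mean
  m4 <- mergeSummitPeaks(df(c(10, 15)))
  expect_equal(m4$summit, 13L)
})

test_that("summit merging is idempotent and chromosome-aware", {
  set.seed(3)
  df <- data.frame(chrom = sample(c("chr1", "chr2"), 200, TRUE),
                   summit = sample.int(5000, 200, TRUE))
  m <- mergeSummitPeaks(df)
  m2 <- mergeSummitPeaks(data.frame(
    chrom = as.character(GenomicRanges::seqnames(m)), summit = m$summit))
  expect_equal(m2$summit, m$summit)
  expect_equal(as.character(GenomicRanges::seqnames(m2)),
               as.character(GenomicRanges::seqnames(m)))
  # merged summits on one chromosome are > radius apart
  for (ch in c("chr1", "chr2")) {
    s <- sort(m$summit[as.character(GenomicRanges::seqnames(m)) == ch])
    if (length(s) > 1) expect_true(all(diff(s) > 50))
  }
})

test_that("shifted 5'-end counting follows the strand-aware and literal rules", {
  pk <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(start = 151, end = 250))
  reads <- data.frame(chrom = "chr1", pos = 100, strand = "+",
                      fraglen = 200)
  expect_equal(shiftedFivePrimeCounts(reads, pk), 1L)  # 100+100=200 in peak

  pk2 <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(start = 301, end = 400))
  expect_equal(shiftedFivePrimeCounts(reads, pk2), 0L)

  # minus-strand read shifts left in strand mode, right in literal mode
  rm <- data.frame(chrom = "chr1", pos = 300, strand = "-", fraglen = 200)
  expect_equal(shiftedFivePrimeCounts(rm, pk, mode = "strand"), 1L)   # 200
  expect_equal(shiftedFivePrimeCounts(rm, pk2, mode = "literal-right"), 1L)
  # unknown chromosome reads never count; negative shifts clip with warning
  ro <- data.frame(chrom = "chrUn", pos = 100, strand = "+", fraglen = 10)
  expect_equal(shiftedFivePrimeCounts(ro, pk), 0L)
  rneg <- data.frame(chrom = "chr1", pos = 1, strand = "-", fraglen = 500)
  expect_warning(shiftedFivePrimeCounts(rneg, pk), "clipped")
})

test_that("median-of-ratios size factors recover depth ratios", {
  k <- matrix(rpois(600, 100), ncol = 2)
  expect_equal(estimateSizeFactors(cbind(k[, 1], k[, 1])), c(1, 1))
  sf <- estimateSizeFactors(cbind(k[, 1], 2 * k[, 1]))
  expect_equal(sf[2] / sf[1], 2)
  # per-sample depth scaling is absorbed into the relative size factors
  sf1 <- estimateSizeFactors(k)
  k2 <- k
  k2[, 2] <- 3 * k[, 2]
  sf2 <- estimateSizeFactors(k2)
  expect_equal(sf2[2] / sf2[1], 3 * sf1[2] / sf1[1])
  # uniform depth scaling leaves the ratios untouched
  expect_equal(estimateSizeFactors(3 * k), sf1)
  expect_error(estimateSizeFactors(matrix(c(0, 1, 1, 0), 2)),
               "all-positive")
})

test_that("NB Wald test is null-centred and finds planted fold-changes", {
  pc <- plantedCounts(n = 600, nPlanted = 60, seed = 21)
  dr <- nbWaldTest(pc$counts, pc$condition)
  planted <- pc$truth < 0
  expect_gt(mean(dr$qvalue[planted] < 0.05 & dr$log2FC[planted] < -1), 0.9)
  expect_lt(mean(dr$pvalue[!planted] < 0.05), 0.12)
  expect_equal(mean(dr$log2FC[planted]), -2, tolerance = 0.2)
  # identical groups: flat fold-change, near-1 p
  kk <- matrix(rpois(300, 200), ncol = 6)
  kk[, 4:6] <- kk[, 1:3]
  dr2 <- nbWaldTest(kk, pc$condition)
  expect_true(all(abs(dr2$log2FC) < 1e-8))
  expect_true(all(dr2$pvalue > 0.99))
  # all-zero row is reported as untested
  kz <- rbind(matrix(rpois(60, 100), ncol = 6), 0)
  drz <- nbWaldTest(kz, pc$condition)
  expect_equal(drz$pvalue[11], 1)
  expect_equal(drz$log2FC[11], 0)
})

test_that("NB Wald test agrees with DESeq2 on a planted fixture", {
  skip_if_not_installed("DESeq2")
  pc <- plantedCounts(n = 300, nPlanted = 30, seed = 5)
  dr <- nbWaldTest(pc$counts, pc$condition)
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      countData = pc$counts,
      colData = data.frame(condition = factor(pc$condition,
                                              levels = c("WT", "mut"))),
      design = ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    dres <- DESeq2::results(dds, contrast = c("condition", "mut", "WT"))
  })
  ok <- !is.na(dres$padj)
  expect_gt(cor(dr$log2FC[ok], dres$log2FoldChange[ok]), 0.95)
  # the two tests call (essentially) the same planted peaks
  mine <- dr$qvalue < 0.05 & dr$log2FC < -1
  theirs <- !is.na(dres$padj) & dres$padj < 0.05 &
    dres$log2FoldChange < -1
  expect_gt(mean(mine == theirs), 0.95)
})

test_that("labelling reproduces the positive/negative thresholds exactly", {
  tb <- data.frame(
    log2FC = c(-1.5, 0.5, -1.5, -0.5, 0.0, -2.0),
    qvalue = c(0.01, 0.01, 0.20, 0.01, 0.80, 0.049))
  lab <- labelDifferential(tb)
  expect_equal(as.character(lab),
               c("positive",   # q<0.05 & lfc<-1
                 "negative",   # lfc >= 0
                 "excluded",   # q too large
                 "excluded",   # lfc in (-1, 0)
                 "negative",   # lfc == 0 boundary
                 "positive"))
  # exhaustive and exclusive partition
  expect_false(anyNA(lab))
  expect_equal(nlevels(lab), 3L)
})

test_that("external differential tables are ingested and labelable", {
  f <- tempfile()
  write.table(data.frame(peak_id = c("p1", "p2"), log2FC = c(-2, 1),
                         pvalue = c(1e-5, 0.5), qvalue = c(1e-4, 0.7)),
              f, sep = "\t", quote = FALSE, row.names = FALSE)
  tb <- readExternalDiff(f)
  expect_equal(as.character(labelDifferential(tb)),
               c("positive", "negative"))
  bad <- tempfile()
  write.table(data.frame(x = 1), bad, sep = "\t", row.names = FALSE)
  expect_error(readExternalDiff(bad), "columns")
})
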