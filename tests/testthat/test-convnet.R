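test_that("architecture arithmetic: valid convolutions and dropped partial pool window", {
  cfg <- convNetConfig(inputLen = 1000)
  expect_equal(cfg$convOut, 958L)
  expect_equal(cfg$pooledWidth, 27L)
  expect_error(convNetConfig(inputLen = 40), "too short")
  expect_error(convNetConfig(inputLen = 60), "pooling window")

  # parameter count is a pure function of config and input length
  m <- buildConvNet(cfg, seed = 1)
  expected <- 60 * 4 * 15 + 60 +      # conv1
    60 * 60 * 15 + 60 +               # conv2
    15 * 60 * 15 + 15 +               # conv3
    15 * 27 + 1                       # dense
  expect_equal(nParams(m), expected)
})

test_that("all-zero weights give sigmoid(0) = 0.5 and outputs always lie in (0, 1)", {
  m <- tinyConvNet()
  zero <- m
  zero@params <- lapply(m@params, function(p) p * 0)
  X <- array(0, c(4, 80, 3))
  for (i in 1:3) X[, , i] <- oneHot(randomDna(80))
  expect_equal(unname(predictConvNet(zero, X)), rep(0.5, 3))
  sc <- predictConvNet(m, X)
  expect_true(all(sc > 0 & sc < 1))
})

test_that("prediction is deterministic and symmetric over strand example order", {
  m <- tinyConvNet(seed = 4)
  s <- randomDna(80)
  X <- array(0, c(4, 80, 4))
  X[, , 1] <- oneHot(s); X[, , 2] <- revcompOneHot(oneHot(s))
  X[, , 3] <- X[, , 2]; X[, , 4] <- X[, , 1]    # swapped pair
  p1 <- predictConvNet(m, X[, , 1:2, drop = FALSE], peakIds = c(1, 1))
  p2 <- predictConvNet(m, X[, , 3:4, drop = FALSE], peakIds = c(1, 1))
  expect_equal(p1, p2)
  expect_equal(predictConvNet(m, X), predictConvNet(m, X))
  expect_error(predictConvNet(m, array(0, c(4, 79, 1))), "input length")
})

test_that("the fused training step reproduces the reference double-precision pass", {
  set.seed(8)
  m <- tinyConvNet(seed = 2)
  cfg <- m@config
  B <- 16
  X <- array(0, c(4, 80, B))
  for (i in seq_len(B)) X[, , i] <- oneHot(randomDna(80))
  y <- rbinom(B, 1, 0.5)
  w <- rep(0.5, B)
  st <- dbdmotif:::.cnnStepC(m@params, X, y, w, 0, cfg$poolWidth,
                             cfg$poolStride, 1L)
  acts <- dbdmotif:::.fwdActs(m@params, cfg, X)
  expect_equal(as.vector(st$yhat), acts$yhat, tolerance = 1e-5)
  gr <- dbdmotif:::.bwd(m@params, cfg, X, acts, 0.5 * (acts$yhat - y) / B)
  for (nm in names(gr)) {
    scale <- max(1e-6, max(abs(gr[[nm]])))
    expect_lt(max(abs(gr[[nm]] - st$grads[[nm]])) / scale, 1e-3)
  }
})

test_that("reference backward pass matches finite differences", {
  set.seed(12)
  m <- tinyConvNet(seed = 3)
  cfg <- m@config
  X <- array(0, c(4, 80, 2))
  for (i in 1:2) X[, , i] <- oneHot(randomDna(80))
  y <- c(1, 0)
  lossOf <- function(params) {
    a <- dbdmotif:::.fwdActs(params, cfg, X)
    -mean(y * log(a$yhat) + (1 - y) * log(1 - a$yhat))
  }
  acts <- dbdmotif:::.fwdActs(m@params, cfg, X)
  gr <- dbdmotif:::.bwd(m@params, cfg, X, acts, (acts$yhat - y) / 2)
  for (nm in names(m@params)) {
    for (r in 1:3) {
      i <- sample(length(m@params[[nm]]), 1)
      p2 <- m@params
      p2[[nm]][i] <- p2[[nm]][i] + 1e-6
      num <- (lossOf(p2) - lossOf(m@params)) / 1e-6
      expect_equal(gr[[nm]][i], num, tolerance = 1e-3)
    }
  }
})

test_that("class weights equal the fraction of peaks in the other class", {
  # 3000 positives / 9000 negatives -> weights 0.75 / 0.25
  nPos <- 3000; nNeg <- 9000
  expect_equal(nNeg / (nPos + nNeg), 0.75)
  # wiring check inside training on a tiny run: training errors without
  # both classes
  m <- tinyConvNet()
  ex <- makeExampleSet(vapply(1:10, function(i) randomDna(80), ""),
                       rep(1, 10), rep("chr3", 10))
  expect_error(trainConvNet(m, ex), "both classes")
})

test_that("training learns a planted motif and early-stops on the validation metric", {
  set.seed(99)
  n <- 500
  chroms <- rep(c("chr3", "chr4", "chr3", "chr8", "chr1"),
                length.out = n)
  y <- rbinom(n, 1, 0.5)
  seqs <- vapply(seq_len(n), function(i) {
    s <- randomDna(80)
    if (y[i] == 1) substr(s, 30, 41) <- "GAGCCAGAGGTT"
    s
  }, "")
  ex <- makeExampleSet(seqs, y, chroms)
  m <- buildConvNet(convNetConfig(inputLen = 80, nFilters = c(10, 10, 5),
                                  filterWidth = 15, poolWidth = 35,
                                  poolStride = 35), seed = 5)
  tc <- trainConfig(maxEpochs = 40, minEpochs = 30, seed = 6,
                    batchSize = 50)
  fit <- trainConvNet(m, ex, tc = tc)
  expect_true(fit@trained)
  sel <- ex$chrom %in% "chr1"
  sc <- predictConvNet(fit, ex$X[, , sel, drop = FALSE],
                       peakIds = ex$peakId[sel])
  yl <- tapply(ex$y[sel], ex$peakId[sel], max)[names(sc)]
  expect_gt(auprc(sc, yl), 0.9)
  # log carries both phases and the metric per epoch
  expect_true(all(c("pretrain", "main") %in% fit@log$phase))
  expect_true(all(fit@log$valRecall80 >= 0 & fit@log$valRecall80 <= 1))
})

test_that("training is reproducible for a fixed seed", {
  set.seed(1)
  n <- 80
  chroms <- rep(c("chr3", "chr8"), length.out = n)
  y <- rbinom(n, 1, 0.5)
  seqs <- vapply(seq_len(n), function(i) {
    s <- randomDna(80)
    if (y[i] == 1) substr(s, 35, 40) <- "GAGCCA"
    s
  }, "")
  ex <- makeExampleSet(seqs, y, chroms)
  mk <- function() {
    m <- buildConvNet(convNetConfig(inputLen = 80, nFilters = c(4, 4, 2),
                                    filterWidth = 15, poolWidth = 35,
                                    poolStride = 35), seed = 2)
    trainConvNet(m, ex, split = splitSpec(train = "chr3", val = "chr8"),
                 tc = trainConfig(maxEpochs = 2, seed = 3, batchSize = 40))
  }
  f1 <- mk(); f2 <- mk()
  expect_identical(f1@params, f2@params)
  expect_identical(f1@log, f2@log)
})

test_that("recall at a precision floor enumerates thresholds with tie grouping", {
  expect_equal(recallAtPrecision(c(0.9, 0.8, 0.7, 0.6), c(1, 1, 0, 1)),
               2 / 3)
  expect_equal(recallAtPrecision(c(0.9, 0.8, 0.1, 0.2), c(1, 1, 0, 0)), 1)
  expect_equal(recallAtPrecision(rep(0.5, 4), c(1, 1, 0, 0)), 0)
})

test_that("AUPRC matches a brute-force per-threshold oracle including ties", {
  bruteAuprc <- function(scores, labels) {
    th <- sort(unique(scores), decreasing = TRUE)
    P <- sum(labels == 1)
    prevR <- 0
    area <- 0
    for (t in th) {
      sel <- scores >= t
      prec <- sum(labels[sel] == 1) / sum(sel)
      rec <- sum(labels[sel] == 1) / P
      area <- area + (rec - prevR) * prec
      prevR <- rec
    }
    area
  }
  expect_equal(auprc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(auprc(rep(0.3, 10), rep(c(1, 0), 5)), 0.5)
  set.seed(13)
  for (i in 1:20) {
    n <- 100
    scores <- round(runif(n), sample(c(1, 2, 6), 1))  # force ties sometimes
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(auprc(scores, labels), bruteAuprc(scores, labels),
                 tolerance = 1e-9)
  }
  expect_error(auprc(c(0.1, 0.2), c(1, 1)), "both classes")
})
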