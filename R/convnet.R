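#' @title ConvNet: the fixed differential-peak prediction network
#'
#' @description An S4 container for the small convolutional network used to
#' predict, from one-hot sequence, whether a peak is significantly stronger
#' in the wild type. The architecture is fixed: three valid (unpadded)
#' convolutions (60 filters of 4 x 15, then 60 of 1 x 15 over 60 channels,
#' then 15 of 1 x 15 over 60 channels, all stride 1), each followed by a
#' rectified linear unit and train-time dropout (rate 0.2), a 1 x 35
#' max-pool with stride 35 (final partial window dropped), and a single
#' sigmoid output unit.
#'
#' @slot config List of architecture hyperparameters (see [convNetConfig]).
#' @slot params List of weight/bias arrays.
#' @slot trained Logical; whether [trainConvNet] has been run.
#' @slot log Training log (epoch, phase, loss, validation metrics).
#' @export
setClass("ConvNet",
         representation(config = "list", params = "list",
                        trained = "logical", log = "data.frame"))

setMethod("show", "ConvNet", function(object) {
  cfg <- object@config
  cat("ConvNet (3 conv + ReLU + maxpool + dense sigmoid)\n")
  cat("  input: 4 x", cfg$inputLen, "one-hot\n")
  cat("  filters:", paste(cfg$nFilters, collapse = "/"),
      " width", cfg$filterWidth, " pool", cfg$poolWidth, "\n")
  cat("  parameters:", nParams(object),
      if (object@trained) " (trained)\n" else " (untrained)\n")
})

#' Architecture configuration
#'
#' @param inputLen Input sequence length (>= 43 so all three valid
#'   convolutions fit; must additionally leave at least one complete
#'   pooling window, i.e. `inputLen - 42 >= poolWidth`).
#' @param nFilters Filters per convolutional layer.
#' @param filterWidth Width of every convolutional filter.
#' @param poolWidth,poolStride Max-pooling window and stride.
#' @param dropout Dropout rate applied after each conv + ReLU at train time.
#' @return A config list.
#' @export
convNetConfig <- function(inputLen = 1000, nFilters = c(60, 60, 15),
                          filterWidth = 15, poolWidth = 35,
                          poolStride = 35, dropout = 0.2) {
  convOut <- inputLen - 3 * (filterWidth - 1)
  if (convOut < 1) stop("input too short for the convolution stack")
  if (convOut < poolWidth)
    stop("input too short: no complete pooling window")
  list(inputLen = inputLen, nFilters = nFilters, filterWidth = filterWidth,
       poolWidth = poolWidth, poolStride = poolStride, dropout = dropout,
       convOut = convOut, pooledWidth = convOut %/% poolStride)
}

#' Build (He-normal initialise) a ConvNet
#'
#' @param cfg Config from [convNetConfig].
#' @param seed Integer RNG seed for the initialisation.
#' @return An untrained [ConvNet-class] object.
#' @export
buildConvNet <- function(cfg, seed = 1L) {
  set.seed(seed)
  K <- cfg$filterWidth
  nf <- cfg$nFilters
  he <- function(outC, inC, k) {
    array(rnorm(outC * inC * k, sd = sqrt(2 / (inC * k))),
          dim = c(outC, inC, k))
  }
  D <- nf[3L] * cfg$pooledWidth
  params <- list(
    W1 = he(nf[1L], 4L, K), b1 = numeric(nf[1L]),
    W2 = he(nf[2L], nf[1L], K), b2 = numeric(nf[2L]),
    W3 = he(nf[3L], nf[2L], K), b3 = numeric(nf[3L]),
    wd = rnorm(D, sd = sqrt(2 / D)), bd = 0)
  new("ConvNet", config = cfg, params = params, trained = FALSE,
      log = data.frame())
}

#' Number of free parameters
#' @param model A `ConvNet`.
#' @return Integer parameter count.
#' @export
nParams <- function(model) {
  sum(vapply(model@params, length, 0L))
}

## ---- low-level forward / backward (tap-loop convolutions on BLAS) ----

.convFwd <- function(W, b, X) .convFwdC(W, as.numeric(b), X)

.convBwdX <- function(W, dY) .convBwdXC(W, dY)

.convBwdW <- function(W, X, dY) .convBwdWC(W, X, dY)

.poolFwd <- function(A, width, stride) {
  d <- dim(A)
  nw <- d[2L] %/% stride
  out <- array(-Inf, dim = c(d[1L], nw, d[3L]))
  arg <- array(0L, dim = c(d[1L], nw, d[3L]))
  for (t in seq_len(width)) {
    idx <- (seq_len(nw) - 1L) * stride + t
    slice <- A[, idx, , drop = FALSE]
    upd <- slice > out
    out[upd] <- slice[upd]
    arg[upd] <- t
  }
  list(out = out, arg = arg)
}

.poolBwd <- function(dOut, arg, Tlen, stride) {
  d <- dim(dOut)
  dA <- array(0, dim = c(d[1L], Tlen, d[3L]))
  for (t in seq_len(stride)) {
    idx <- (seq_len(d[2L]) - 1L) * stride + t
    sel <- arg == t
    if (any(sel)) {
      tmp <- array(0, dim = d)
      tmp[sel] <- dOut[sel]
      dA[, idx, ] <- dA[, idx, , drop = FALSE] + tmp
    }
  }
  dA
}

# Full forward pass. dropoutMasks NULL => inference (no dropout). Returns
# activations needed for backprop and attribution.
.fwdActs <- function(params, cfg, X, dropoutMasks = NULL) {
  Z1 <- .convFwd(params$W1, params$b1, X)
  A1 <- pmax(Z1, 0)
  if (!is.null(dropoutMasks)) A1 <- A1 * dropoutMasks[[1L]]
  Z2 <- .convFwd(params$W2, params$b2, A1)
  A2 <- pmax(Z2, 0)
  if (!is.null(dropoutMasks)) A2 <- A2 * dropoutMasks[[2L]]
  Z3 <- .convFwd(params$W3, params$b3, A2)
  A3 <- pmax(Z3, 0)
  if (!is.null(dropoutMasks)) A3 <- A3 * dropoutMasks[[3L]]
  pl <- .poolFwd(A3, cfg$poolWidth, cfg$poolStride)
  B <- dim(X)[3L]
  P <- matrix(pl$out, ncol = B)
  z <- as.vector(crossprod(P, params$wd)) + params$bd
  yhat <- 1 / (1 + exp(-z))
  list(Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, Z3 = Z3, A3 = A3,
       pool = pl$out, arg = pl$arg, P = P, z = z, yhat = yhat)
}

.bwd <- function(params, cfg, X, acts, dz, dropoutMasks = NULL) {
  B <- dim(X)[3L]
  dwd <- as.vector(acts$P %*% dz)
  dbd <- sum(dz)
  dP <- outer(params$wd, dz)
  dPool <- array(dP, dim = dim(acts$pool))
  dA3 <- .poolBwd(dPool, acts$arg, dim(acts$A3)[2L], cfg$poolStride)
  if (!is.null(dropoutMasks)) dA3 <- dA3 * dropoutMasks[[3L]]
  dZ3 <- dA3 * (acts$Z3 > 0)
  g3 <- .convBwdW(params$W3, acts$A2, dZ3)
  dA2 <- .convBwdX(params$W3, dZ3)
  if (!is.null(dropoutMasks)) dA2 <- dA2 * dropoutMasks[[2L]]
  dZ2 <- dA2 * (acts$Z2 > 0)
  g2 <- .convBwdW(params$W2, acts$A1, dZ2)
  dA1 <- .convBwdX(params$W2, dZ2)
  if (!is.null(dropoutMasks)) dA1 <- dA1 * dropoutMasks[[1L]]
  dZ1 <- dA1 * (acts$Z1 > 0)
  g1 <- .convBwdW(params$W1, X, dZ1)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db,
       W3 = g3$dW, b3 = g3$db, wd = dwd, bd = dbd)
}

## ---- example sets ----

#' Build a strand-paired example set from peak windows
#'
#' For each labelled peak two examples are created: the one-hot of the
#' forward window and of its reverse complement, sharing the peak's label,
#' chromosome and id.
#'
#' @param seqs Character vector of fixed-width window sequences.
#' @param labels 0/1 labels per peak.
#' @param chroms Chromosome per peak.
#' @param peakIds Peak identifiers (default seq along peaks).
#' @return A list with `X` (4 x L x 2n array), `y`, `chrom`, `peakId`,
#'   `strand`.
#' @export
makeExampleSet <- function(seqs, labels, chroms, peakIds = NULL) {
  n <- length(seqs)
  stopifnot(length(labels) == n, length(chroms) == n)
  if (is.null(peakIds)) peakIds <- seq_len(n)
  L <- nchar(seqs[1L])
  X <- array(0, dim = c(4L, L, 2L * n))
  for (i in seq_len(n)) {
    oh <- oneHot(seqs[i])
    X[, , 2L * i - 1L] <- oh
    X[, , 2L * i] <- revcompOneHot(oh)
  }
  list(X = X,
       y = rep(as.numeric(labels), each = 2L),
       chrom = rep(chroms, each = 2L),
       peakId = rep(peakIds, each = 2L),
       strand = rep(c("fwd", "rev"), n))
}

#' Chromosome-based train/validation/test split
#'
#' Defaults follow the held-out-chromosome scheme: training on chr3-chr7,
#' chr10-chr19 and chrX, validation on chr8-chr9, testing on chr1-chr2.
#'
#' @param train,val,test Character vectors of chromosome names (pairwise
#'   disjoint).
#' @return A list of the three sets.
#' @export
splitSpec <- function(train = c(paste0("chr", c(3:7, 10:19)), "chrX"),
                      val = c("chr8", "chr9"),
                      test = c("chr1", "chr2")) {
  if (length(intersect(train, val)) || length(intersect(train, test)) ||
      length(intersect(val, test)))
    stop("split chromosome sets must be pairwise disjoint")
  list(train = train, val = val, test = test)
}

.subsetExamples <- function(ex, idx) {
  list(X = ex$X[, , idx, drop = FALSE], y = ex$y[idx],
       chrom = ex$chrom[idx], peakId = ex$peakId[idx],
       strand = ex$strand[idx])
}

## ---- training ----

#' Training configuration
#'
#' SGD with Nesterov momentum 0.85 and learning rate 0.01, batch size 200,
#' class weights equal to the fraction of peaks in the other class, early
#' stopping after three consecutive epochs without improvement in recall at
#' 80% precision on the validation set, and a balanced pre-training phase
#' in which the negative set is down-sampled to the size of the positive
#' set.
#'
#' @param learningRate,momentum,batchSize SGD hyperparameters.
#' @param patience Early-stopping patience in epochs.
#' @param precisionFloor Precision floor for the validation metric.
#' @param minEpochs Warm-up epochs per phase before the patience rule is
#'   armed (the metric is 0 until precision first reaches the floor, which
#'   on small data can take several epochs).
#' @param maxEpochs Hard cap for the main training phase.
#' @param pretrain Whether to run the balanced pre-training phase.
#' @param pretrainMaxEpochs Hard cap for the pre-training phase (default
#'   12: pre-training supplies an initialisation for the main phase and
#'   does not need to run to convergence).
#' @param seed RNG seed for shuffling, down-sampling and dropout.
#' @return A config list.
#' @export
trainConfig <- function(learningRate = 0.01, momentum = 0.85,
                        batchSize = 200L, patience = 3L,
                        precisionFloor = 0.8, minEpochs = 8L,
                        maxEpochs = 18L, pretrain = TRUE,
                        pretrainMaxEpochs = 12L, seed = 1L) {
  list(learningRate = learningRate, momentum = momentum,
       batchSize = batchSize, patience = patience,
       precisionFloor = precisionFloor, minEpochs = minEpochs,
       maxEpochs = maxEpochs, pretrain = pretrain,
       pretrainMaxEpochs = pretrainMaxEpochs, seed = seed)
}

.trainPhase <- function(model, exTrain, exVal, tc, phase, classWeights) {
  cfg <- model@config
  params <- model@params
  vel <- lapply(params, function(p) p * 0)
  nEx <- length(exTrain$y)
  bestMetric <- -Inf
  bestParams <- params
  badEpochs <- 0L
  log <- list()
  cap <- if (phase == "pretrain" && !is.null(tc$pretrainMaxEpochs))
    tc$pretrainMaxEpochs else tc$maxEpochs
  for (epoch in seq_len(cap)) {
    ord <- sample.int(nEx)
    lossSum <- 0
    for (bs in split(ord, ceiling(seq_along(ord) / tc$batchSize))) {
      Xb <- exTrain$X[, , bs, drop = FALSE]
      yb <- exTrain$y[bs]
      wb <- ifelse(yb == 1, classWeights["pos"], classWeights["neg"])
      dropSeed <- sample.int(.Machine$integer.max, 1L)
      step <- .cnnStepC(params, Xb, yb, wb, cfg$dropout,
                        cfg$poolWidth, cfg$poolStride, dropSeed)
      lossSum <- lossSum + step$loss
      grads <- step$grads
      for (nm in names(params)) {
        vel[[nm]] <- tc$momentum * vel[[nm]] - tc$learningRate * grads[[nm]]
        params[[nm]] <- params[[nm]] + tc$momentum * vel[[nm]] -
          tc$learningRate * grads[[nm]]
      }
    }
    tmp <- model
    tmp@params <- params
    valScores <- predictConvNet(tmp, exVal$X, peakIds = exVal$peakId)
    valLabels <- tapply(exVal$y, exVal$peakId, max)[names(valScores)]
    metric <- recallAtPrecision(valScores, valLabels, tc$precisionFloor)
    ap <- auprc(valScores, valLabels)
    log[[epoch]] <- data.frame(phase = phase, epoch = epoch,
                               loss = lossSum / nEx,
                               valRecall80 = metric, valAuprc = ap)
    if (metric > bestMetric) {
      bestMetric <- metric
      bestParams <- params
      badEpochs <- 0L
    } else {
      badEpochs <- badEpochs + 1L
      if (epoch > tc$minEpochs && badEpochs >= tc$patience) break
    }
  }
  model@params <- bestParams
  list(model = model, log = do.call(rbind, log))
}

#' Train the ConvNet
#'
#' Two phases: pre-training from the He-normal initialisation on
#' class-balanced data (negative peaks down-sampled to the number of
#' positive peaks), then training from the pre-trained weights on the full
#' training data with class weights set to the fraction of peaks in the
#' other class. Both phases use the early-stopping rule; the
#' best-validation weights are kept.
#'
#' @param model An untrained (or trained) `ConvNet`.
#' @param examples An example set from [makeExampleSet].
#' @param split A [splitSpec].
#' @param tc A [trainConfig].
#' @return The trained `ConvNet` with a filled `log` slot.
#' @export
trainConvNet <- function(model, examples, split = splitSpec(),
                         tc = trainConfig()) {
  set.seed(tc$seed)
  exTrain <- .subsetExamples(examples, examples$chrom %in% split$train)
  exVal <- .subsetExamples(examples, examples$chrom %in% split$val)
  if (length(unique(exTrain$y)) < 2L || length(unique(exVal$y)) < 2L)
    stop("both classes must be present in the train and validation splits")
  logs <- list()
  if (tc$pretrain) {
    posPeaks <- unique(exTrain$peakId[exTrain$y == 1])
    negPeaks <- unique(exTrain$peakId[exTrain$y == 0])
    keepNeg <- sample(negPeaks, min(length(posPeaks), length(negPeaks)))
    exBal <- .subsetExamples(
      exTrain, exTrain$peakId %in% c(posPeaks, keepNeg))
    r <- .trainPhase(model, exBal, exVal, tc, "pretrain",
                     c(pos = 0.5, neg = 0.5))
    model <- r$model
    logs <- c(logs, list(r$log))
  }
  nPosPk <- length(unique(exTrain$peakId[exTrain$y == 1]))
  nNegPk <- length(unique(exTrain$peakId[exTrain$y == 0]))
  cw <- c(pos = nNegPk / (nPosPk + nNegPk), neg = nPosPk / (nPosPk + nNegPk))
  r <- .trainPhase(model, exTrain, exVal, tc, "main", cw)
  model <- r$model
  logs <- c(logs, list(r$log))
  model@trained <- TRUE
  model@log <- do.call(rbind, logs)
  model
}

#' Predict with a ConvNet
#'
#' Deterministic forward pass (dropout off). When `peakIds` is given, the
#' per-peak score is the mean of the forward and reverse-complement example
#' scores; otherwise per-example scores are returned.
#'
#' @param model A `ConvNet`.
#' @param X A 4 x L x N one-hot array (L must match the trained input
#'   length).
#' @param peakIds Optional peak id per example for strand averaging.
#' @param batchSize Forward batch size.
#' @return Numeric scores in \[0, 1\] (named by peak id when aggregated).
#' @export
predictConvNet <- function(model, X, peakIds = NULL, batchSize = 500L) {
  cfg <- model@config
  if (dim(X)[2L] != cfg$inputLen)
    stop("input length ", dim(X)[2L], " != trained input length ",
         cfg$inputLen)
  N <- dim(X)[3L]
  scores <- numeric(N)
  for (bs in split(seq_len(N), ceiling(seq_len(N) / batchSize))) {
    scores[bs] <- .cnnPredictC(model@params, X[, , bs, drop = FALSE],
                               cfg$poolWidth, cfg$poolStride)
  }
  if (is.null(peakIds)) return(scores)
  agg <- tapply(scores, peakIds, mean)
  agg[as.character(unique(peakIds))]
}

## ---- metrics ----

.prCurve <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  P <- sum(labels == 1)
  Nn <- sum(labels == 0)
  if (P == 0L || Nn == 0L) stop("both classes required")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y == 1)
  fp <- cumsum(y == 0)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(threshold = s[last], tp = tp[last], fp = fp[last], P = P)
}

#' Maximum recall at a precision floor
#'
#' Maximum recall over score thresholds whose precision is at least
#' `floor`; 0 when no threshold reaches the floor. Tied scores are grouped
#' into a single threshold.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param floor Precision floor (default 0.8).
#' @return Recall in \[0, 1\].
#' @export
recallAtPrecision <- function(scores, labels, floor = 0.8) {
  pc <- .prCurve(scores, labels)
  prec <- pc$tp / (pc$tp + pc$fp)
  rec <- pc$tp / pc$P
  ok <- prec >= floor
  if (!any(ok)) 0 else max(rec[ok])
}

#' Area under the precision-recall curve
#'
#' Step-curve area over all distinct score thresholds (equal scores grouped
#' into one step): the sum over steps of the recall increment times the
#' precision after including the step.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(scores, labels) {
  pc <- .prCurve(scores, labels)
  prec <- pc$tp / (pc$tp + pc$fp)
  rec <- pc$tp / pc$P
  dRec <- diff(c(0, rec))
  sum(dRec * prec)
}
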