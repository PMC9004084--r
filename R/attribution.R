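#' Rescale-rule contribution scores
#'
#' Computes, for each observed base of each input, its contribution to a
#' scalar readout of the network relative to a reference input, using the
#' Rescale rule: at every ReLU the multiplier is the ratio of the output
#' difference to the input difference (falling back to the gradient where
#' the input difference is below `1e-7` in magnitude), and linear layers
#' back-propagate multipliers through their weights. The default readout
#' ("conv3") is the sum over all units of the third convolutional layer's
#' post-ReLU output, for which completeness holds exactly:
#' the contributions of one input sum to `target(x) - target(reference)`.
#' The alternative readout "logit" attributes the pre-sigmoid dense output,
#' routing multipliers through the max-pool to the argmax unit of the
#' actual input (completeness then holds only when the actual and reference
#' pooling argmaxes agree).
#'
#' The default reference is a sequence of Ns, i.e. the all-zero one-hot
#' matrix.
#'
#' @param model A trained [ConvNet-class].
#' @param x A 4 x L one-hot matrix, or a 4 x L x N array of inputs.
#' @param reference Reference input of the same 4 x L shape (default
#'   all zeros).
#' @param target "conv3" (default) or "logit".
#' @return A list with `contrib` (same shape as `x`; zero on rows where the
#'   input is zero), `hyp` (hypothetical scores, see
#'   [hypotheticalContributions]), `targetX`, `targetRef` (per-input scalar
#'   readouts) and `target`.
#' @export
rescaleContributions <- function(model, x, reference = NULL,
                                 target = c("conv3", "logit")) {
  target <- match.arg(target)
  cfg <- model@config
  params <- model@params
  if (any(vapply(params, function(p) anyNA(p), TRUE)))
    stop("NaN/NA in model weights")
  single <- length(dim(x)) == 2L
  if (single) x <- array(x, dim = c(dim(x), 1L))
  if (dim(x)[1L] != 4L || dim(x)[2L] != cfg$inputLen)
    stop("input shape must be 4 x ", cfg$inputLen)
  B <- dim(x)[3L]
  if (is.null(reference))
    reference <- matrix(0, 4L, cfg$inputLen)
  if (!all(dim(reference) == c(4L, cfg$inputLen)))
    stop("reference shape must match the input")
  ax <- .fwdActs(params, cfg, x)
  ar <- .fwdActs(params, cfg, array(reference, dim = c(4L, cfg$inputLen, 1L)))
  # broadcast reference activations across the batch
  bc <- function(a) array(a, dim = c(dim(a)[1:2], B))
  reluMult <- function(Zx, Zr, Ax, Ar) {
    dZ <- Zx - bc(Zr)
    m <- (Ax - bc(Ar)) / dZ
    fb <- abs(dZ) < 1e-7
    m[fb] <- (Zx > 0)[fb]
    m
  }
  if (target == "conv3") {
    M3post <- array(1, dim = dim(ax$A3))
    tX <- apply(ax$A3, 3L, sum)
    tR <- sum(ar$A3)
  } else {
    nw <- cfg$pooledWidth
    nf3 <- cfg$nFilters[3L]
    Mp <- array(matrix(params$wd, nf3, nw), dim = c(nf3, nw, B))
    M3post <- array(0, dim = dim(ax$A3))
    for (t in seq_len(cfg$poolWidth)) {
      idx <- (seq_len(nw) - 1L) * cfg$poolStride + t
      sel <- ax$arg == t
      if (any(sel)) {
        tmp <- array(0, dim = dim(Mp))
        tmp[sel] <- Mp[sel]
        M3post[, idx, ] <- M3post[, idx, , drop = FALSE] + tmp
      }
    }
    tX <- ax$z
    tR <- ar$z
  }
  M3pre <- M3post * reluMult(ax$Z3, ar$Z3, ax$A3, ar$A3)
  M_A2 <- .convBwdX(params$W3, M3pre)
  M2pre <- M_A2 * reluMult(ax$Z2, ar$Z2, ax$A2, ar$A2)
  M_A1 <- .convBwdX(params$W2, M2pre)
  M1pre <- M_A1 * reluMult(ax$Z1, ar$Z1, ax$A1, ar$A1)
  Min <- .convBwdX(params$W1, M1pre)
  refArr <- array(reference, dim = c(4L, cfg$inputLen, B))
  contrib <- Min * (x - refArr)
  # hypothetical: substitute each base at each position into the reference
  refDot <- colSums(Min * refArr)          # L x B
  hyp <- Min - rep(refDot, each = 4L)
  if (single) {
    contrib <- contrib[, , 1L]
    hyp <- hyp[, , 1L]
  }
  list(contrib = contrib, hyp = hyp, targetX = tX, targetRef = tR,
       target = target)
}

#' Hypothetical contribution scores
#'
#' The per-position score of every possible base: the Rescale multipliers
#' from the actual pass applied to the one-hot difference obtained by
#' substituting each base at each position into the reference. The row of
#' the observed base equals its actual contribution; the other rows answer
#' "what would the readout credit this base here". These are the inputs to
#' seqlet aggregation.
#'
#' @inheritParams rescaleContributions
#' @return A 4 x L matrix (or 4 x L x N array) of hypothetical scores.
#' @export
hypotheticalContributions <- function(model, x, reference = NULL,
                                      target = c("conv3", "logit")) {
  rescaleContributions(model, x, reference, target)$hyp
}
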