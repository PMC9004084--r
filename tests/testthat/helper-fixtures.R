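# Shared fixtures: everything is generated in code at test time.

randomDna <- function(n, gc = 0.5) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}

# A small network whose shapes keep unit tests fast.
tinyConvNet <- function(inputLen = 80, seed = 1) {
  buildConvNet(convNetConfig(inputLen = inputLen, nFilters = c(5, 6, 3),
                             filterWidth = 15, poolWidth = 35,
                             poolStride = 35), seed = seed)
}

# NB count matrix with planted fold-changes on the first `nPlanted` rows.
plantedCounts <- function(n = 500, nPlanted = 50, lfc = -2, mu = 200,
                          disp = 0.05, reps = 3, seed = 1) {
  set.seed(seed)
  base <- exp(rnorm(n, log(mu), 0.5))
  sf <- exp(runif(2 * reps, log(0.5), log(2)))
  truth <- rep(c(lfc, 0), c(nPlanted, n - nPlanted))
  k <- sapply(seq_len(2 * reps), function(j) {
    m <- if (j <= reps) base else base * 2^truth
    rnbinom(n, mu = m * sf[j], size = 1 / disp)
  })
  list(counts = k, condition = rep(c("WT", "mut"), each = reps),
       truth = truth, sf = sf)
}
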