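#' Construct a position frequency matrix
#'
#' @param m A 4 x W matrix of column-stochastic probabilities (rows
#'   A, C, G, T).
#' @param name Motif name.
#' @return The validated PFM (a plain matrix with a `name` attribute).
#' @export
pfm <- function(m, name = "motif") {
  m <- as.matrix(m)
  stopifnot(nrow(m) == 4L, ncol(m) >= 1L)
  if (any(abs(colSums(m) - 1) > 1e-6))
    stop("PFM columns must sum to 1")
  rownames(m) <- DNA_BASES
  attr(m, "name") <- name
  m
}

#' Build a sharpened-consensus PFM from a DNA string
#'
#' Each column puts probability `p` on the consensus base and
#' `(1 - p) / 3` elsewhere; handy for constructing synthetic motifs.
#'
#' @param consensus Consensus string over A/C/G/T.
#' @param p Probability of the consensus base per column.
#' @param name Motif name.
#' @return A PFM.
#' @export
consensusPfm <- function(consensus, p = 0.85, name = consensus) {
  oh <- oneHot(consensus)
  if (any(colSums(oh) == 0)) stop("consensus must be over A/C/G/T")
  pfm(oh * p + (1 - oh) * (1 - p) / 3, name = name)
}

#' A motif-trimming rule
#'
#' Parameterises the degenerate-flank trimming procedures used to cut
#' aggregate motifs down to their informative span. Scanning proceeds in
#' `direction`; extraction starts at the first position (or first of two
#' consecutive positions, `startRequirement = "two_consecutive"`) whose
#' maximal base probability exceeds `cutoff`. With
#' `stopMode = "second_degenerate"` one interior degenerate position
#' (max probability <= cutoff) is tolerated and extraction ends before the
#' second; with `stopMode = "max_prob_drop"` extraction ends before the
#' first position whose maximal probability falls by more than `drop`
#' relative to the previously kept position.
#'
#' @param cutoff Probability threshold in (0, 1); comparison is strict.
#' @param startRequirement "one_position" or "two_consecutive".
#' @param direction "forward" (upstream to downstream) or "reverse".
#' @param stopMode "second_degenerate" or "max_prob_drop".
#' @param drop Drop threshold for `stopMode = "max_prob_drop"`.
#' @return A list of class `trimRule`.
#' @export
trimRule <- function(cutoff,
                     startRequirement = c("one_position", "two_consecutive"),
                     direction = c("forward", "reverse"),
                     stopMode = c("second_degenerate", "max_prob_drop"),
                     drop = 0.35) {
  stopifnot(cutoff > 0, cutoff < 1, drop > 0, drop < 1)
  structure(list(cutoff = cutoff,
                 startRequirement = match.arg(startRequirement),
                 direction = match.arg(direction),
                 stopMode = match.arg(stopMode),
                 drop = drop),
            class = "trimRule")
}

#' Preset trimming rules
#'
#' `upstreamTrimRule()`: cutoff 0.60, single-position start, forward scan,
#' stop before the second degenerate position. `coreTrimRule()`: cutoff
#' 0.40 with two consecutive passing positions required to start.
#' `downstreamTrimRule()`: cutoff 0.35, scanning from the downstream end
#' towards the start, stopping when the maximal base probability drops by
#' more than 0.35 between consecutive positions.
#'
#' @return A `trimRule`.
#' @export
upstreamTrimRule <- function() trimRule(0.60, "one_position", "forward",
                                        "second_degenerate")

#' @rdname upstreamTrimRule
#' @export
coreTrimRule <- function() trimRule(0.40, "two_consecutive", "forward",
                                    "second_degenerate")

#' @rdname upstreamTrimRule
#' @export
downstreamTrimRule <- function() trimRule(0.35, "one_position", "reverse",
                                          "max_prob_drop", drop = 0.35)

#' Trim degenerate flanks off a PFM
#'
#' Applies a [trimRule]; the result is always a contiguous slice of the
#' input with orientation preserved.
#'
#' @param x A PFM.
#' @param rule A `trimRule`.
#' @return The trimmed PFM.
#' @export
trimPfm <- function(x, rule) {
  stopifnot(inherits(rule, "trimRule"))
  W <- ncol(x)
  ord <- if (rule$direction == "reverse") rev(seq_len(W)) else seq_len(W)
  mx <- apply(x, 2L, max)[ord]
  pass <- mx > rule$cutoff
  start <- if (rule$startRequirement == "two_consecutive") {
    cand <- which(pass & c(pass[-1L], FALSE))
    if (length(cand)) cand[1L] else NA_integer_
  } else {
    if (any(pass)) which(pass)[1L] else NA_integer_
  }
  if (is.na(start)) stop("motif empty after trim")
  end <- length(mx)
  if (rule$stopMode == "second_degenerate") {
    degen <- which(!pass & seq_along(pass) > start)
    if (length(degen) >= 2L) end <- degen[2L] - 1L
  } else {
    i <- start
    while (i < length(mx)) {
      if (mx[i] - mx[i + 1L] > rule$drop) { end <- i; break }
      i <- i + 1L
    }
  }
  keep <- ord[start:end]
  keep <- sort(keep)
  out <- x[, keep, drop = FALSE]
  attr(out, "name") <- attr(x, "name")
  out
}

#' Estimate a background model from sequences
#'
#' Order-0 base probabilities and an order-1 (dinucleotide transition)
#' matrix from counts pooled over both strands with an add-0.1 pseudocount;
#' k-mers containing N are skipped. Mirrors the output of a first-order
#' Markov background estimator run on peak sequences.
#'
#' @param seqs Character vector or `DNAStringSet` of sequences.
#' @param pseudocount Added to every count (default 0.1).
#' @return A list with `order0` (named length-4 probabilities) and
#'   `transition` (4 x 4 row-stochastic matrix, from-base x to-base).
#' @export
backgroundFromSequences <- function(seqs, pseudocount = 0.1) {
  seqs <- toupper(as.character(seqs))
  if (length(seqs) == 0L || all(nchar(seqs) == 0L)) stop("no sequences")
  both <- c(seqs, vapply(seqs, revcompSeq, ""))
  ss <- Biostrings::DNAStringSet(both)
  c1 <- colSums(Biostrings::oligonucleotideFrequency(ss, 1L))[DNA_BASES]
  c2 <- colSums(Biostrings::oligonucleotideFrequency(ss, 2L))
  if (sum(c1) == 0) stop("no countable bases")
  c1 <- c1 + pseudocount
  order0 <- c1 / sum(c1)
  tr <- matrix(pseudocount, 4L, 4L, dimnames = list(DNA_BASES, DNA_BASES))
  for (a in DNA_BASES) for (b in DNA_BASES)
    tr[a, b] <- tr[a, b] + c2[[paste0(a, b)]]
  tr <- tr / rowSums(tr)
  list(order0 = order0, transition = tr)
}

#' Uniform-GC background
#'
#' Order-0 background with `A = T = (1 - gc) / 2` and `C = G = gc / 2`;
#' the default GC fraction 0.42 approximates the mouse genome.
#'
#' @param gc GC fraction.
#' @return A background list as from [backgroundFromSequences].
#' @export
gcBackground <- function(gc = 0.42) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  list(order0 = p, transition = matrix(rep(p, each = 4L), 4L, 4L,
       byrow = TRUE, dimnames = list(DNA_BASES, DNA_BASES)))
}

.bg0 <- function(bg) {
  p <- if (is.list(bg)) bg$order0 else bg
  if (!is.null(names(p))) p <- p[DNA_BASES]
  stopifnot(length(p) == 4L, !anyNA(p))
  setNames(as.numeric(p), DNA_BASES)
}

#' Convert a PFM to a log2-odds PWM
#'
#' `pwm[b, j] = log2((pfm[b, j] + pseudocount * bg[b]) /
#' ((1 + pseudocount) * bg[b]))`, the standard background-pseudocounted
#' log-odds conversion.
#'
#' @param x A PFM.
#' @param bg Background (list with `order0`, or a length-4 vector).
#' @param pseudocount Pseudocount fraction (default 0.001).
#' @return A 4 x W log2-odds matrix.
#' @export
pfmToPwm <- function(x, bg, pseudocount = 0.001) {
  p0 <- .bg0(bg)
  stopifnot(all(p0 > 0))
  out <- log2((x + pseudocount * p0) / ((1 + pseudocount) * p0))
  attr(out, "name") <- attr(x, "name")
  out
}

#' Assemble a mega-motif from parts and background spacers
#'
#' Concatenates PFM parts separated by spacer columns whose probabilities
#' equal the order-0 background (the "G/C-content" spacer columns).
#'
#' @param parts List of PFMs, in order.
#' @param spacers Integer vector of spacer widths, one fewer than parts.
#' @param bg Background model.
#' @param name Motif name.
#' @return A list of class `megaMotif` with elements `pfm`, `parts`,
#'   `spacers`.
#' @export
buildMegaMotif <- function(parts, spacers, bg, name = "mega") {
  stopifnot(length(spacers) == length(parts) - 1L, all(spacers >= 0))
  p0 <- .bg0(bg)
  pieces <- list(parts[[1L]])
  for (i in seq_along(spacers)) {
    if (spacers[i] > 0L)
      pieces <- c(pieces, list(matrix(p0, 4L, spacers[i],
                                      dimnames = list(DNA_BASES, NULL))))
    pieces <- c(pieces, list(parts[[i + 1L]]))
  }
  assembled <- pfm(do.call(cbind, pieces), name = name)
  structure(list(pfm = assembled, parts = parts, spacers = spacers,
                 name = name), class = "megaMotif")
}

#' The six mega-motif presets
#'
#' Given trimmed core, upstream and downstream motifs, returns the six
#' standard combinations: core; upstream; downstream; upstream + 7 bp
#' spacer + core; core + 2 bp spacer + downstream; and upstream + 7 bp +
#' core + 2 bp + downstream. Spacer columns carry the order-0 background.
#'
#' @param core,upstream,downstream PFMs.
#' @param bg Background model.
#' @return Named list of six `megaMotif` objects.
#' @export
megaMotifPresets <- function(core, upstream, downstream, bg) {
  list(
    core = buildMegaMotif(list(core), integer(0), bg, "core"),
    upstream = buildMegaMotif(list(upstream), integer(0), bg, "upstream"),
    downstream = buildMegaMotif(list(downstream), integer(0), bg,
                                "downstream"),
    upstream_core = buildMegaMotif(list(upstream, core), 7L, bg,
                                   "upstream_core"),
    core_downstream = buildMegaMotif(list(core, downstream), 2L, bg,
                                     "core_downstream"),
    upstream_core_downstream = buildMegaMotif(
      list(upstream, core, downstream), c(7L, 2L), bg,
      "upstream_core_downstream"))
}

#' Build the 16 bp SELEX query motif
#'
#' For 20 bp SELEX reads the full core + downstream combination does not
#' fit, so the query is the downstream-most 10 bp of the core motif, 2
#' background spacer columns, then the upstream-most 4 bp of the downstream
#' motif: width exactly 16.
#'
#' @param core Core PFM (width >= 10).
#' @param downstream Downstream PFM (width >= 4).
#' @param bg Background model.
#' @return A width-16 PFM.
#' @export
buildSelexQuery <- function(core, downstream, bg) {
  if (ncol(core) < 10L) stop("core motif must be at least 10 bp")
  if (ncol(downstream) < 4L) stop("downstream motif must be at least 4 bp")
  w <- ncol(core)
  mm <- buildMegaMotif(
    list(core[, (w - 9L):w, drop = FALSE],
         downstream[, 1:4, drop = FALSE]),
    2L, bg, "selex_query")
  mm$pfm
}

#' Write motifs in MEME minimal format
#'
#' @param motifs A PFM, `megaMotif`, or list of them.
#' @param path Output path.
#' @param bg Optional background for the header frequencies (default
#'   uniform).
#' @return `path`, invisibly.
#' @export
writeMeme <- function(motifs, path, bg = NULL) {
  if (is.matrix(motifs) || inherits(motifs, "megaMotif"))
    motifs <- list(motifs)
  p0 <- if (is.null(bg)) rep(0.25, 4L) else .bg0(bg)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "strands: + -", "",
               "Background letter frequencies",
               paste(sprintf("%s %.5f", DNA_BASES, p0), collapse = " "),
               ""), con)
  for (m in motifs) {
    x <- if (inherits(m, "megaMotif")) m$pfm else m
    nm <- attr(x, "name")
    if (is.null(nm)) nm <- "motif"
    writeLines(sprintf("MOTIF %s", nm), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
      ncol(x)), con)
    for (j in seq_len(ncol(x)))
      writeLines(paste(sprintf("%.6f", x[, j]), collapse = "  "), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from MEME minimal format
#'
#' @param path Path to a MEME-format motif file.
#' @return Named list of PFMs.
#' @export
readMeme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  if (length(starts) == 0L) stop("no MOTIF blocks in ", path)
  out <- list()
  for (s in starts) {
    nm <- strsplit(trimws(lines[s]), "\\s+")[[1L]][2L]
    h <- s + grep("^letter-probability matrix",
                  lines[(s + 1L):length(lines)])[1L]
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[h]))
    rows <- lines[(h + 1L):(h + w)]
    vals <- t(vapply(strsplit(trimws(rows), "\\s+"),
                     function(v) as.numeric(v[1:4]), numeric(4L)))
    out[[nm]] <- pfm(t(vals), name = nm)
  }
  out
}
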