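---
title: "Dissecting DNA-binding-domain motifs from differential ChIP-seq"
author: "dbdmotif maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting DNA-binding-domain motifs from differential ChIP-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Many transcription factors carry several DNA-binding domains — most
prominently the tandem C2H2 zinc fingers, of which CTCF has eleven — and
the sequence preference of an individual domain is hard to read off from
the factor's overall motif. When ChIP-seq is available for both the
wild-type factor and a variant with a single domain disabled, the peaks
that *weaken* in the mutant carry the signature of that domain's DNA
contact. `dbdmotif` implements a pipeline that turns this contrast into a
motif:

1. **Differential labelling.** Peaks from all datasets are merged by
   summit proximity, read 5′ ends (shifted by half the fragment length)
   are counted per merged peak, and a negative-binomial Wald test labels
   each peak *positive* (significantly stronger in the wild type:
   q < 0.05 and log2 fold-change < −1, with the fold-change oriented
   mutant-over-wild-type) or *negative* (fold-change ≥ 0). Other peaks
   are excluded.
2. **Sequence model.** A small convolutional network — three valid
   convolutions (60 filters of 4×15, 60 of 1×15, 15 of 1×15, stride 1,
   ReLU, dropout 0.2), a 1×35 max-pool with stride 35, and a dense
   sigmoid unit — is trained to predict the label from the one-hot
   encoded summit-centred window (rows A, C, G, T; N encoded as an
   all-zero column). Each peak contributes a forward and a
   reverse-complement example.
3. **Attribution.** Rescale-rule contribution scores are computed per
   nucleotide against an all-zero ("all-N") reference, together with
   *hypothetical* scores — the credit each of the four bases would
   receive at each position.
4. **Motif aggregation.** High-attribution windows ("seqlets") are
   extracted under an empirical-FDR threshold, clustered greedily by
   offset- and orientation-maximised cosine similarity of their
   hypothetical scores, and each cluster is averaged (one-hot → position
   frequency matrix, hypothetical scores → importance matrix) into a
   fixed-width discovered motif ranked by seqlet support.
5. **Dissection and downstream analyses.** Degenerate flanks are trimmed
   with parameterised rules; trimmed parts are recombined into
   "mega-motifs" with background-probability spacer columns; peaks and
   read pools are scanned with an exact-p-value PWM scanner; SELEX-style
   pools, peak-overlap partitions and peak-strength associations supply
   orthogonal evidence.

A seeded synthetic-data module generates every input the pipeline
consumes, so the full chain is testable offline.

## The synthetic bench

`simConfig()` fixes the study conditions the test bench emulates:

* a 10-chromosome i.i.d. background genome at GC 0.42 (a mouse-like
  value, also used for all "G/C-content" spacer columns);
* 4000 summit-centred peaks, each carrying a sharpened 19 bp core motif;
  35% of peaks additionally carry a 6 bp downstream motif (consensus
  GAGCCA) exactly 2 bp downstream of the core, the cassette jittered up
  to ±10 bp around the summit and inserted on a random strand;
* negative-binomial replicate counts (3 wild-type vs 3 mutant samples,
  log-normal per-peak means around 200, dispersion 0.05, per-sample size
  factors log-uniform in [0.5, 2]), with the mutant mean of
  downstream-carrying peaks multiplied by 2^−2;
* 20 bp SELEX-style read pools in which the selected cycle carries the
  16 bp query (the downstream 10 bp of the core, 2 background columns,
  the upstream 4 bp of the downstream motif) in 30% of reads.

Windows are summit ± 100 bp. This is a deliberate desk-scale choice: the
generator emulates the *statistical structure* of differential binding —
a discriminative sub-motif at fixed spacing inside a shared core context
— not genomic scale. For real data the network's default input length is
1000 (summit ± 500 bp; the architecture requires only ≥ 77 bp). What
passing on this bench demonstrates is that the chain of
labelling → learning → attribution → aggregation → trimming can recover a
planted discriminative element; it does not demonstrate robustness to
repeat structure, chromatin-driven covariates, or motif families absent
from the generator.

## The differential test

The NB Wald test is a transparent stand-in for a full differential-count
framework: median-of-ratios size factors; per-peak method-of-moments
dispersion pooled within 20 bins of base mean and floored at 10⁻⁸;
`log2FC = log2((μ_mut + 0.5) / (μ_WT + 0.5))`; a delta-method standard
error; two-sided normal p-values; BH q-values over the tested (non-zero)
peaks. Under its own generative null (2000 peaks, 3 vs 3) the fraction of
p < 0.05 sits within 0.05 ± 0.02, and planted log2FC = −2 peaks at mean
200 are recovered as positives at ≥ 90% sensitivity. Like any
median-based normaliser, the size factors acquire a small bias when a
third of peaks change in one direction; the planted-vs-null fold-change
*contrast* stays unbiased, which is what the labels consume.
`readExternalDiff()` ingests an externally computed (peak, log2FC, p, q)
table whenever a full differential framework is preferred.

## Training choices

The optimiser follows the fixed recipe: SGD with Nesterov momentum 0.85,
learning rate 0.01, batch size 200, weighted binary cross-entropy with
class weights equal to the fraction of peaks in the other class, a
balanced pre-training phase (negatives down-sampled to the positive
count, He-normal initialisation), and early stopping after three
consecutive epochs without improvement in validation recall at 80%
precision (defined as 0 when no threshold reaches the floor). Two
additions are ours:

* **Warm-up before early stopping** (`minEpochs`, default 8). On
  desk-scale data an epoch is only a handful of parameter updates and the
  validation metric stays exactly 0 for the first several epochs; the
  bare patience rule would abort training before the model leaves its
  initialisation. The stopping rule itself is unchanged once armed.
* **Epoch caps** (`maxEpochs`, default 18, for the main phase;
  `pretrainMaxEpochs`, default 12, for the balanced pre-training phase —
  pre-training supplies an initialisation and does not need to run to
  convergence).

Convolutions run as im2col + BLAS matrix products with single-precision
internals in the training step (the double-precision reference path in R
is retained and the two are cross-checked in the tests to float
tolerance). Training is deterministic given the seed. Splits are by
chromosome: train chr3–chr7 and chr10–chr19 plus chrX, validation
chr8–chr9, test chr1–chr2. Per-peak predictions average the forward and
reverse-complement example scores.

## Attribution choices

The Rescale rule assigns each ReLU a multiplier Δoutput/Δinput (gradient
fallback below 10⁻⁷) and back-propagates multipliers linearly; the
reference is the all-zero matrix, consistent with the N encoding.
Completeness (contributions summing to the readout difference) holds
exactly for the default "conv3" readout — the summed post-ReLU output of
the last convolutional layer. The pipeline, however, attributes the
**classifier logit** by default: the conv3 readout credits everything the
convolutional stack represents, and on data where a strong, shared core
motif is present in *both* classes the attribution mass lands on the
core rather than on the discriminative element; attributing the logit
(multipliers routed through the max-pool to the argmax of the actual
input) concentrates credit on what moves the decision. Both readouts are
exposed on `rescaleContributions()`.

## Seqlet aggregation choices

Seqlet extraction scores sliding windows by summed absolute contribution
and thresholds them at the smallest value with empirical FDR ≤ 0.2,
where the null re-computes the same windows after shuffling the
per-position attribution values of each peak in non-overlapping 2 bp
blocks (attribution values are not a nucleotide sequence, so this is our
reading of a "dinucleotide-preserving" shuffle: it keeps immediate local
correlation while destroying longer-range placement). Overlapping
windows are resolved by greedy non-maximum suppression that suppresses
*any* overlap with an accepted window — so an isolated site yields
exactly one seqlet — with score ties broken towards the window whose
importance peak is central. (A laxer rule that only suppressed > 50%
overlap left two to three shifted copies of every site; the copies then
formed their own large, blurred cluster that could outrank the properly
centred one.)

Similarity between seqlets is the maximum over relative offsets (up to
half a width) and both orientations of the cosine between hypothetical
score matrices on the overlap, *weighted by the overlap fraction*.
Because of that weighting, two identical seqlets displaced by d bp can
score at most (w − d)/w; with sites jittered up to ±10 bp the pipeline
therefore clusters with a leader-similarity threshold of 0.45 and uses a
seqlet width of 31 bp (wide enough to span the whole
core + spacer + downstream cassette), while the bare operations keep the
stricter defaults (0.8, 21 bp) appropriate for pre-aligned inputs.
Clusters below `minSeqlets` (20 on the desk-scale bench; 200 is the
full-scale setting) are discarded. Before averaging, member alignments
are refined for a few passes against the running cluster aggregate (a
single leader is one noisy seqlet; the aggregate averages that noise
away, and realignment sharpens columns blurred by one-off offsets).
Survivors are averaged into width-50 motifs, and only the well-covered
span (columns covered by at least half the maximum coverage) is passed
to trimming — sparse flank columns are averages of a handful of members
and carry no signal.

## Trimming and dissection

`trimRule()` parameterises the three flank-trimming procedures: a 0.60
cutoff with single-position start (upstream-style), a 0.40 cutoff
requiring two consecutive passing positions (core-style), both tolerating
exactly one interior degenerate position and stopping before the second;
and a 0.35 cutoff scanning from the downstream end that stops when the
maximal base probability drops by more than 0.35 between consecutive
positions (downstream-style). All comparisons are strict, and the result
is always a contiguous slice. The pipeline reports the top discovered
motif dissected under both the core-style and downstream-style rules; on
the synthetic bench the downstream-style trim is the one that isolates
the planted GAGCCA element, exactly because two background spacer columns
separate it from the core (the core-style rule, scanning forward, ends at
that second degenerate column).

The six mega-motif presets are: core; upstream; downstream;
upstream + 7 bp + core; core + 2 bp + downstream; and
upstream + 7 bp + core + 2 bp + downstream, with spacer columns set to
the order-0 background.

## Scanning

`pwmScoreDistribution()` builds the exact distribution of the
integer-discretised PWM score under the order-0 background (1000 bins by
default over the total score range); scans query k-mer scores through the
same discretisation, so reported p-values are exact for the discretised
score and monotone in it. Both strands are scored (the minus strand via
the reverse-complemented matrix), offsets containing N are skipped, and
BH q-values are computed jointly across all retained hits of a scan.
When an order-1 background is supplied, only its stationary order-0
component enters the scoring — a documented simplification. Note that a
short or two-valued PWM attains few distinct scores, so its p-values are
coarse by construction; a 6 bp motif cannot reach p < 10⁻⁴ at all, which
is why presence/absence analyses should use the mega-motifs rather than
the short downstream element alone.

## Statistics

Rank comparisons use `stats::wilcox.test` (exact for small untied
samples, otherwise the tie-corrected normal approximation with continuity
correction); BH is `stats::p.adjust`; the fixed-factor Bonferroni
multiplies by 6 (two comparisons in each of three cell types/tissues) and
clips at 1. Correlation comparisons use the independent-samples Fisher
r-to-z formula even though the two correlations share the peak-strength
variable; this makes the test conservative in the common positive-
dependence case and is recorded as a simplification. The logistic
baseline is a ridge-penalised logistic regression (glmnet, α = 0) with
λ = 1/n matching an sklearn-style C = 1 penalty, the intercept
unpenalised, fit on the training + validation chromosomes and evaluated
by AUPRC on the test chromosomes. AUPRC is the tie-grouped step-curve
area (the recall increment times the precision after each distinct
threshold).

## Degenerate inputs and numerical edges

All-zero count rows are reported untested (p = 1, log2FC = 0) and stay
out of the BH universe. Sequences shorter than a motif scan to zero hits
without error. Empty partitions or motif-hit groups are flagged rather
than tested. The attribution multiplier falls back to the gradient when
|Δinput| < 10⁻⁷. Merged-summit means round half-up. Windows that would
leave a chromosome raise an error at extraction and are dropped by the
caller with a count.

## Problem sizes used by the checks

The packaged checks run the full chain at 4000 peaks (the default
bench), the model-vs-baseline comparison at 2000 peaks with the
core–downstream spacer varied 0–8 bp in 150 bp windows and a raised
epoch budget (variable spacing is a harder composition task than the
fixed-spacing bench, and the early-stopping metric is uninformative for
longer), differential calibration at 2000 peaks, SELEX power at
5000 reads per pool, and scanner uniformity at ≥ 10⁵ scored positions —
sizes at which every stage's behaviour is already asymptotic enough to be
informative while a complete run stays comfortably on a laptop core.

## Known limitations

* The seqlet clustering is a transparent greedy stand-in for a full
  seqlet-aggregation framework; it does not claim output compatibility
  with any published implementation, and its leader alignment can blur
  motif flanks when leaders are noisy.
* The NB test omits shrinkage, GLM covariates and independent filtering.
* Order-1 background scoring and partial-overlap SELEX alignments are
  not implemented (the latter is unnecessary at the default 16 bp query
  against 20 bp reads).
* The generator's i.i.d. background lacks repeats and compositional
  heterogeneity; recovery results on it bound what the method can do on
  real genomes only from above.
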