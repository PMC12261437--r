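---
title: "Coverage-aware quantification of long-read RNA-seq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coverage-aware quantification of long-read RNA-seq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrquant)
library(dplyr)
```

## The model

`lrquant` estimates relative transcript abundances `θ` from long-read
alignments to a transcriptome by maximising a fragment-level marginal
likelihood

$$
L(\theta) \;=\; \prod_{n=1}^{N} \sum_{j \in A(r_n)}
  \theta_j \,
  \Pr(A_n \mid T_n = j)\,
  \Pr(SE_n \mid T_n = j, CD_j),
$$

where $A(r_n)$ is the set of transcripts to which read $n$ aligns. Two
modelling assumptions distinguish it from short-read quantifiers:

1. **No length dependence.** Long-read library preparations do not fragment
   molecules, so the sampling rate of a transcript is proportional to its
   copy number only. There is no effective-length correction anywhere; the
   output `frac` is `θ` itself, and `num_reads = θ · N` is the expected
   read count. A consequence is that the model loses the implicit penalty
   that short-read models place on transcripts with long uncovered
   stretches; the coverage factor below restores that evidence explicitly.

2. **Alignment scores instead of mapping quality.** The conditional
   probability of an alignment is
   $\exp\!\big((AS_{nj} - AS_n^{\max})/s\big)$ with scale $s = 10$: the
   read's best alignment always receives probability exactly 1, slightly
   suboptimal alignments retain some mass, and strongly suboptimal ones are
   effectively discarded. MAPQ is deliberately not used — aligner MAPQ
   estimates are unreliable for this purpose — and the probability is
   invariant to shifting all of a read's scores by a constant.

The remaining factor of the per-read likelihood term, the probability of
the read itself given its alignment, carries no free formula and is
constant per read; any such constant cancels when responsibilities are
normalised in the E-step, so it is fixed at 1.

## The coverage factor

For each transcript, once per run and before inference:

1. the transcript is tiled into disjoint segments of `bin_width` (default
   100 nt; the final segment is truncated at the transcript end and keeps
   its true length as denominator);
2. every retained alignment — including multimapped ones, each with weight
   1 — adds to each overlapped segment the fraction of the *segment* it
   covers, giving fractional counts $c_i$ whose sum times segment length
   equals total aligned bases;
3. a pseudocount of 1% of the transcript's aligned reads is added to every
   segment to stabilise probabilities on sparse transcripts;
4. with mean count $E(c)$ and relative deviation
   $\delta_i = (E(c) - c_i)/E(c)$, the segment's assignment probability is
   the logistic $p_i = 1/(1 + e^{-a\delta_i})$ with growth rate $a = 2$:
   over-covered segments fall below $1/2$, under-covered ones above.

The span probability $\Pr(SE_n \mid T_n = j, CD_j)$ of an alignment is the
mean of the $p_i$ over the segments it touches, weighted by the covered
fraction of each segment and normalised to sum to one. Normalising makes
the result a convex combination in $(0,1)$ — a probability-like score
independent of read length — which we prefer over the un-normalised
weighted sum because partial end segments would otherwise deflate long
reads systematically. A transcript with no coverage gets flat
$p_i = 1/2$, and $a = 0$ turns the whole factor into a constant $1/2$
that cancels in the E-step, recovering the score-only (`nocov`) model
exactly — a property the test suite asserts.

Profiles are computed once from the input alignments and held fixed during
EM; re-estimating them dynamically as assignments sharpen is out of scope.

## Inference

EM runs from a deterministic uniform start (`θ_j = 1/M`; there is no
randomness anywhere in inference):

* **E-step** — responsibilities
  $r_{nj} = \theta_j q_{nj} / \sum_{j'} \theta_{j'} q_{nj'}$ with
  $q_{nj}$ the fixed conditional above; a read whose denominator is zero
  (all of its targets at zero abundance) is assigned uniformly over its
  entries;
* **M-step** — $\theta_j = \sum_n r_{nj} / N$.

Iteration stops when the maximum absolute change in expected counts falls
below `tol` (default $10^{-3}$ reads — a resolution well below anything
biologically interpretable) or at `max_iters` (default 1000). The marginal
log-likelihood is recorded each iteration and is non-decreasing; the test
suite checks both this and, on small instances, agreement of the final
log-likelihood with an exhaustive simplex grid search at resolution
$10^{-3}$ (those tests run EM at `tol = 1e-10` so that corner optima are
resolved to comparable precision). Because expected counts, not `θ`, drive
convergence, the criterion scales sensibly with library size.

Numerical notes: per-read normalisation keeps conditionals in $(0,1]$ with
the best alignment at exactly 1, so underflow can only arise from extreme
score gaps; reads whose conditionals all underflow carry no information
and are dropped with a message. Read totals are conserved exactly
($\sum_j \text{counts}_j = N$ to floating-point accuracy) at every
iteration.

## Input handling

Input is name-collated SAM/BAM (all records of a read contiguous — the
default output order of minimap2). Text SAM is converted to a temporary
BAM and all access goes through `Rsamtools`. Per record: unmapped records
are dropped; reverse-strand alignments are dropped by default since
transcriptome references are sense-stranded (`keep_reverse = TRUE` for
protocols where antisense hits are meaningful); secondary and
supplementary records are eligible like primaries; duplicate
(read, transcript) pairs collapse to the best-scoring record so a
transcript appears at most once in $A(r_n)$; a missing `AS` tag on a
mapped record is an error, as is a non-collated file. Spans are converted
to 0-based half-open transcript coordinates with the end derived from the
CIGAR reference width, since coverage lives in transcript coordinates. No
hard score filter is applied by default — the exponential falloff already
marginalises bad alignments — but `min_score_fraction` offers an optional
per-read filter (applied only when the read's best score is positive,
since a fraction of a negative score is not meaningful).

## The synthetic-data generator

`simulate_reads()` emulates the features of long-read data that the model
actually consumes, without modelling base-level errors:

* transcripts are random sequences of configurable length (default
  500–3000 nt) with abundances drawn from a Dirichlet (default
  concentration 0.5, giving realistically skewed expression) or supplied
  directly;
* reads are drawn i.i.d. proportionally to `θ` — **no length
  weighting** — full-length with probability `p_full = 0.25`, otherwise
  3'-anchored truncated (start moves, end stays at the transcript 3' end,
  mimicking degradation and pore-exit artifacts) with truncated-lognormal
  aligned length (`meanlog = log(1000)`, `sdlog = 0.6`, minimum 50 nt);
  with the default length range this reproduces the commonly observed
  ~1.5:1 ratio of isoform length to aligned length;
* ambiguity comes from exact-prefix pairs: the short member's sequence is
  an exact prefix of the long member's, so any read contained in the
  shared prefix is emitted as alignments to both, at identical coordinates,
  with `AS = 2·span ± 2` integer jitter so exact ties and near-ties both
  occur;
* output is a valid name-collated SAM (plus transcript FASTA and a truth
  TSV), byte-reproducible under a fixed seed.

What the generator does **not** emulate — sequencing errors, alignment
soft-clipping, internal truncation, strand errors, realistic score
distributions — bounds what green tests mean: they validate the estimator
under its own generative assumptions, not performance on real nanopore
data.

`make_prefix_fixture()` builds the canonical hard case: T2 an exact prefix
(60%) of T1, every read from T2, tied scores. Score-only inference has a
flat likelihood there and the deterministic uniform start leaves the split
at exactly 500/500; the coverage model assigns all reads to T2, whose
explanation leaves no uncovered tail.

## Design choices and known limitations

* **Problem sizes.** The shipped tests run the full pipeline at up to 50
  transcripts × 50,000 reads and the oracle comparisons at ≤ 2 kb
  transcripts and ≤ 6-read EM instances — sizes chosen so the whole suite
  exercises every code path in well under a minute while keeping the grid
  and per-base oracles exhaustive.
* **Corner collapse on prefix pairs.** When a transcript is an exact
  prefix of a partner that has many unique reads, the likelihood optimum
  can sit at zero abundance for the short member even with the coverage
  term: the coverage odds in its favour (bounded by the logistic at
  roughly $e^{a}$ per read) must outweigh the partner's unique-read mass.
  This is a property of the length-free likelihood itself, visible in the
  parameter-recovery tests, and is the main respect in which estimates on
  heavily prefix-ambiguous catalogs remain biased toward longer isoforms.
  Distinguishable alignments (score differences) or dynamic coverage
  updates would mitigate it; both are out of scope here.
* **MARD convention.** The absolute relative difference is
  $|x-y|/(x+y)$, defined as 0 at $(0,0)$, hence bounded in $[0,1]$ —
  the convention of the quantification-benchmark literature. Pearson and
  CCC are computed on the $\log(1+x)$ scale by default (raw scale by
  flag); Spearman uses average ranks and Kendall is τ-b.
* **InfRV** is provided for stratifying transcripts by short-read
  quantification uncertainty: $\max(\sigma^2-\mu, 0)/(\mu+5) + 0.01$,
  hence always ≥ 0.01. Generating the inferential replicates themselves is
  out of scope.
* **Ties.** Duplicate (read, transcript) records with tied scores keep the
  first in file order; EM ties (zero denominators) resolve uniformly.

## Session

```{r}
sessionInfo()
```
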