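---
title: "Motif enrichment of somatic mutations: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motif enrichment of somatic mutations: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifexcess)
```

`motifexcess` asks whether somatic single-base substitutions
preferentially hit degenerate DNA motifs — deaminase targets such as
the AID motif `WRC/GYW`, the APOBEC motif `TCW/WGA`, the CpG
dinucleotide, and above all the hybrid `WRCG/CGYW`, an AID target whose
cytosine begins a CpG. This vignette explains the statistical model
behind each stage, the parameters that matter, what the synthetic data
do and do not emulate, and the design decisions that were genuinely
open.

## The excess statistic

Motifs are patterns over the IUPAC alphabet with one designated
*mutable* position (the deaminated C for the C-centred motifs, the A of
the polymerase-eta target `WA`). Matching is strand-symmetric: a genomic
position is a *motif position* if it sits at the mutable slot of an
occurrence of the pattern or of its reverse complement, counted once
even if both orientations match. For the palindromic `CG` the convention
"mutable position = the C" makes both bases of every CpG motif
positions, which is the intended semantics for CpG mutability. `N`
bases (masking) match nothing and are excluded from all totals.

For every mutation the 120 bp *neighborhood* (60 bp per side, truncated
at contig ends) centered on the mutated base is the local composition
control: mutation rates vary enormously along a genome, and comparing
against the immediately surrounding sequence conditions the statistic on
that variation. The excess of mutations in a motif is

$$\mathrm{excess} = F_m / F_n,$$

where $F_m$ is the fraction of mutations whose mutated base is a motif
position and $F_n$ the frequency of motif positions among the
*un-mutated* neighborhood bases (each window's own center is excluded
from the totals). Two significance assessments accompany it:

* **Fisher exact, two-sided**, on the 2×2 table (mutations in/out of
  the motif) × (un-mutated neighborhood positions in/out of the motif),
  via `stats::fisher.test`.
* **Monte Carlo, one-sided**: each replicate reassigns every mutation
  independently to a uniformly random un-mutated position *within its
  own neighborhood* whose reference base equals the mutation's
  reference base, preserving per-window base composition and the
  mutation count, then recounts mutations at motif positions. The
  p-value uses the add-one estimator $(1 + \#\{k^\* \ge k\})/(R+1)$, so
  its floor at $R = 1000$ replicates is just below $10^{-3}$. Drawing
  one uniform candidate per mutation is realized as an independent
  Bernoulli draw with that mutation's motif-candidate fraction — a
  distributional identity, not an approximation. A variant ignoring
  base identity is available (`match_ref_base = FALSE`) but is not the
  default: conditioning on the base parallels what $F_m/F_n$
  conditions on.

One numerical subtlety: positions too close to a window edge to host a
full occurrence in both orientations would be scored "non-motif" by
construction. Candidates for the Monte Carlo reassignment are therefore
restricted to positions whose motif status is fully evaluable inside
the window; without this restriction the test is measurably
anti-conservative (its type-I error at $\alpha = 0.05$ drifts above the
binomial band in null calibrations). $F_n$ itself keeps the whole
window, following the statistic's published definition — at 121 nt
windows the difference is below one percent.

CpG masking (`mask_cpg = TRUE`) replaces both bases of every CG
dinucleotide with `N` before any counting and drops mutations whose own
center is masked. It answers: does an AID-motif signal survive once
every CpG is removed from both numerator and denominator?

Multiple testing across a motif catalog (or across cohorts or patients)
uses Bonferroni at family level $\alpha = 0.05$: flagged iff
$p \le \alpha/m$.

## The hybrid-versus-CpG contrast

A strong `WRCG` excess could in principle be ordinary CpG
hypermutability. The contrast stage therefore classifies every CpG
occurrence in scope — by default the union of the mutation
neighborhoods, deduplicated by genomic coordinate; alternatively
explicit regions over a reference — by the two bases upstream of the C
on each strand: `WRCG` when they lie in W×R, otherwise control (the
union of `YCG` and `SNCG`). The two classes provably partition all
classifiable `NNCG` contexts (an exhaustive test enumerates all 16
prefixes); CpGs lacking two defined upstream bases are excluded from
both classes. An occurrence is *mutated* if at least one mutation hits
its mutable position — occurrences, not mutations, are counted, so a
recurrently hit CpG counts once. The mutated fractions of the two
classes meet in a two-sided Fisher test.

## Subsampling power analysis

Small cohorts (normal tissues, single patients) may show no enrichment
simply for lack of mutations. The power procedure compares the small
cohort's *effect size* $F_m - F_n$ with the effect sizes of 1000
size-matched subsamples, drawn without replacement, of a positive
(enriched) cohort, recomputing $F_n$ from each subsample's own
neighborhoods. Reported is the fraction of subsample effects strictly
greater than the reference effect (ties do not exceed). A fraction near
1 says even this few mutations drawn from the positive process would
almost always show a larger effect — the small cohort's null result is
then evidence about biology, not about sample size. Mutations, not
patients, are resampled: the procedure's unit of information is the
mutation, and patient-level resampling would require per-patient
metadata the mutation tables need not carry.

## Methylation association

Per-CpG methylation records (methylated reads, total reads, ratio
$= 100\,m/t$) are depth-filtered to strictly more than nine reads,
classified by motif context exactly as in the contrast stage, and
optionally flagged *mutated* when a mutation coincides with either base
of the CpG. The group comparison is a resampling test: with $M_1$ the
mean ratio of the WRCG-context group, each of 10,000 replicates draws,
without replacement, as many values from the larger group as the
smaller holds and computes its mean; reported is the probability that
$M_1$ is at least the sampled mean (ties count toward it, which only
matters in degenerate constant-ratio cases). When group 1 is the larger
the orientation is preserved by comparing sampled group-1 means against
$M_2$.

This p-value is *calibrated* — approximately uniform under no group
difference — only when the sampled pool is much larger than the fixed
group, because sampling without replacement shrinks the sampled-mean
variance by the finite-population factor $1 - n_{small}/n_{large}$;
with comparable group sizes the statistic concentrates toward 0 and 1
(in the equal-size limit it degenerates to a plain mean comparison).
The calibration experiments therefore run in the small-group/large-pool
regime (a mutated-WRCG group of tens of sites against a control pool of
hundreds), which is also the regime of the analysis the test is
designed for. For detecting a planted 5-point mean difference at
roughly 3,000 sites per group the concentration works in the test's
favor and the p-value sits at its floor.

Histograms use five half-open bins of width 20 over the 0–100 ratio
scale, the last bin closed so a ratio of exactly 100 is counted.

## The synthetic generator

`synthetic_truth()` fixes the simulated study conditions; all defaults
were chosen once, on domain grounds:

| parameter | default | why |
|---|---|---|
| `genome_length` | 450 kb | yields ≈6,200 CpGs, hence ≈3,000 depth-passing sites per motif-context group |
| `gc_content` | 0.42 | mammalian-like base composition |
| `cpg_enrichment` | 0.25 | human-like CpG depletion (observed/expected); also keeps the WRCG mutable-position density below 0.02 |
| `n_mutations` | 10,000 | the scale of a pooled exome cohort; ~2% of positions mutated |
| `theta` | empty (null) | per-motif rate multipliers; overlapping motifs compose multiplicatively |
| `transition_bias` | 1/3 | uniform alternate alleles |
| methylation means | 75 (WRCG) vs 80 (control), sd 20 | high-methylation regime with a 5-point planted contrast |
| `meth_depth_mean` | 30 | typical bisulfite coverage; nearly all sites pass the >9-read filter |

The reference is a first-order Markov chain whose C→G transition is
scaled by `cpg_enrichment`; its expected CpG count has a closed form
(stationary distribution × transition probability) used as the
independent oracle in the generator's tests. Mutation positions are
drawn without replacement with weights equal to the product of the
multipliers of the motifs whose mutable position they occupy (so a
`WRCG` cytosine under `theta = c(WRCG = 3, CG = 2)` carries weight 6);
the weighted draw uses exponential sort keys, which is equivalent to
successive weighted sampling. Methylation levels are Beta-distributed
per site around the context mean with binomial read noise on top.

What the generator does *not* emulate: real mutational spectra (the
default alternate-allele draw is uniform, whereas real cohorts can
show strong G:C/A:T asymmetry and transition/transversion imbalance —
`transition_bias` adjusts only part of that), clustered hypermutation
(kataegis),
selection, regional mutation-rate variation beyond what windowing
absorbs, multi-contig genomes, and bimodal methylation landscapes.
Passing tests on synthetic data therefore demonstrate correctness of
the statistics and recovery of planted context effects — not that any
particular biological dataset will show them.

## Problem sizes and numerical choices

The test suite and the acceptance script scale their experiments to
run comfortably on one CPU: null calibrations use 500 datasets of 200
mutations on a 100 kb reference with 199 Monte Carlo replicates;
recovery experiments use the full 10,000-mutation defaults; power
experiments use positive cohorts of 1,000–1,200 mutations against
50-mutation references; methylation null calibrations use 200 trials
of 200 sampling replicates. The null-calibration motif is `WA/TW`, the
densest in the catalog (≈0.3 of positions): exact tests are discrete,
and for sparse motifs (`WRCG` hits ≈25 of 200 mutations) the Fisher
p-value's atoms are large enough that no sample size of *datasets*
makes its distribution pass a uniformity test — a property of exact
tests on small counts, not an implementation artifact. Type-I error
stays inside the binomial band for sparse motifs regardless.

Other numerical conventions: no Haldane correction (the exact test
handles zero cells); `Fn = 0` flags a result non-computable rather than
dividing by zero; an empty mutation set after CpG masking is an error;
coordinates are 1-based throughout (file formats and internals alike),
matching R/Bioconductor convention; lower-case (soft-masked) reference
bases are uppercased; windows overlapping several mutations are
extracted independently per mutation, and each window excludes only its
own center from the un-mutated totals.

## Open choices and their resolutions

* **Mutable position of `WRCG`**: the C only. Deaminases act on the C;
  whether the G should also count is exposed by supplying a custom
  catalog entry (`motif_pair("WRCG", mutable_index = 4)`) rather than a
  default.
* **Recurrent mutations** shared across samples are kept by default
  (`dedup = TRUE` available): recurrence at hypermutable sites is part
  of the signal under study.
* **Pooling**: $F_n$ pools neighborhoods across samples; per-sample
  analysis is available (`per_sample` in the pipeline) with Bonferroni
  across samples.
* **Contrast scope**: the union of mutation neighborhoods by default —
  the same conditioning as the excess statistic; whole-region scans are
  available via `enumerate_cpg_occurrences(reference =, regions =)`.
* **Methylation records** are used as given, one row per position per
  dataset; no cross-patient pooling of read counts happens before the
  depth filter.
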