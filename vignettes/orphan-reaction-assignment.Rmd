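---
title: "Assigning genes to orphan reactions from fitness screens: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assigning genes to orphan reactions from fitness screens: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orphanfit)
```

## The problem

A genome-scale metabolic model couples reactions to genes through boolean
GPR rules, yet many reactions — 128 of 2251 in the *E. coli* model
iJO1366, for instance — are orphans with no known catalysing gene.
Genome-wide fitness screens measure the growth cost of disrupting each
gene across many media conditions; genes acting in the same pathway tend
to show correlated fitness profiles. `orphanfit` exploits this to
propose genes for orphan reactions: a good candidate should correlate
with the fitness behaviour of the orphan's metabolic neighborhood.

## From gene scores to reaction vectors

GPR rules are held in disjunctive normal form: an OR over protein
clauses, each clause an AND over the genes of one catalysing protein.
`parse_gpr()` distributes AND over OR, so arbitrary nesting reduces to
this form. Gene fitness collapses to reaction fitness by the max–min
rule (`reaction_score()`): a complex is only as fit as its weakest
subunit (min within a clause), while isozymes substitute for each other
(max over clauses).

Two deliberate choices here:

* **Missing data drop clauses, not values.** A clause containing a gene
  with no measurement is not evaluable and is excluded; a reaction whose
  clauses all drop is missing for that condition. Imputing zeros inside
  a min/max would bias scores toward zero systematically. Per-reaction
  coverage (fraction of GPR genes with data) is reported so callers can
  filter.
* **Normalization order.** For fitness, raw gene scores feed the
  collapse and only the reaction matrix is Z-normalized per condition;
  gene-level vectors used as candidates are Z-normalized over the gene
  set. For expression, whose per-gene scales are arbitrary, samples are
  Z-normalized per condition *before* the collapse and the reaction
  matrix re-normalized after. Z-normalization uses the population
  standard deviation (divide by N), since each condition's full
  considered set is observed, not sampled.

## Neighborhoods and currency pruning

Reactions sharing a metabolite are neighbors, but metabolites such as
water, protons or ATP appear in so many reactions that they connect
essentially everything. Species referenced by more than `cutoff = 11`
reactions are pruning candidates, visited from the highest frequency down
(ties broken by species id for reproducibility). A removal is committed
unless it would leave *any* reaction that currently has at least two
profiled non-orphan neighbors with fewer than two — the minimum needed to
bridge a one-reaction gap in a linear pathway — in which case it is
reverted. Frequencies are computed once on the unpruned model: removing a
species does not change any other species' membership counts. Reactions
retaining two or more profiled non-orphan neighbors are *adequate*;
only they can be scored. Boundary and exchange reactions are treated like
any other reaction.

## The Association Likelihood Score

For an adequate orphan reaction, every gene with a fitness vector is a
candidate (the model's own genes included). The ALS is the mean Spearman
correlation with the two most-correlated neighbor reaction vectors.
Spearman (average ranks for ties) makes the score invariant to monotone
distortions of the fitness scale; correlations use pairwise-complete
conditions with a minimum overlap of 3 (below that a neighbor is
skipped, and a candidate with fewer than two usable neighbors is not
scored). Taking the top two neighbors, rather than all, keeps the score
meaningful for reactions embedded in long linear pathways where only the
adjacent steps are informative.

Tunable parameters, with defaults:

| parameter | default | meaning |
|---|---|---|
| `cutoff` | 11 | metabolite frequency above which pruning is attempted |
| `alpha` | 0.21 | weight of the summed promoter ALS added to a gene's ALS |
| `top_k` | 20 | candidates reported per reaction |
| `min_overlap` | 3 | minimum shared conditions per correlation |

`alpha` and `cutoff` follow the constants established for the 48-condition
*E. coli* screen and iJO1366; on other datasets a small grid scan over
`alpha` via repeated `loo_validate()` calls is the intended recalibration
route. Promoter vectors are built with the same averaging scheme as other
non-coding regions (mean raw insertion fitness over the half-open
interval, both strands pooled). Expression-based scores are computed per
dataset and averaged — averaging keeps datasets with different sample
counts from dominating one another, which concatenation would not — and
the fitness/expression combination is their equal-weight mean, falling
back (flagged) to the available source when one is missing.

## Confidence

Leave-one-out over the non-orphan adequate reactions yields empirical
score distributions for true pairs and spurious pairs. For an observed
score σ, with inclusive survival fractions `P(≥σ | true)` and
`P(≥σ | false)`:

* Bayesian confidence: `P(≥σ|true)·p_true / P(≥σ)`, with the marginal
  formed from the prior mixture of the two empirical tails — the mixture
  is our choice, as no marginal estimator is canonical here;
* unbiased confidence: `P(≥σ|true) / (P(≥σ|true) + P(≥σ|false))`.

`p_true` defaults to (#true gene–reaction pairs) / (#candidates ×
#non-orphan reactions) computed from the loaded model, and is
overridable. When σ exceeds every observed score both tails are zero and
the confidence is returned missing rather than extrapolated. At genome
scale the spurious-pair pool is capped by a seeded subsample
(`max_false`); at the scales used in this package's tests the full pool
is kept.

## Validation and baselines

`loo_validate()` casts each adequate non-orphan reaction as an orphan in
turn; its vector never serves as its own neighbor. The reported curve is
the fraction of reactions whose best true-gene rank is at most k, for
k = 1..20; `second_gene` mode removes the best-ranked true gene and asks
for another among reactions with two or more genes. Two uniform
baselines anchor the curves: the weak one assumes candidates are drawn
uniformly from the pool (`G·R/total`), the strong one assumes every pick
is a true gene of some reaction (`G·avg genes per reaction`). The hidden
reaction's row stays in the per-condition Z-normalization of the
reaction matrix — one row among dozens shifts column moments negligibly,
and rebuilding the matrix per holdout would multiply runtime for no
measurable change in ranks.

## The synthetic screen generator

`fixture_spec()` defines the study conditions used throughout the tests:
60 reactions, 80 genes and 48 conditions (the screen size of the
motivating *E. coli* dataset), with two planted currency metabolites of
frequency 12 and a 10% orphan share. The model is built from
three-reaction pathway motifs `flank_a → mid → flank_b` joined by shared
intermediates. Latent condition profiles are drawn per motif: flank
latents are independent standard normals and the middle latent is their
normalized sum. Each true gene's vector is its reaction's latent scaled
by `signal_strength` plus independent noise (`noise_sd`); decoys are
pure noise; expression datasets (11 and 36 samples, mirroring typical
microarray and RNA-seq compendia) redraw latents of the same structure.

The motif geometry is deliberate. If neighboring latents simply decayed
in correlation along a chain (correlation c per step), the flanking
reaction's own gene would always outrank the planted middle gene: the
flank gene correlates perfectly with its own reaction and with the
opposite flank at c², giving (1 + c²)/2, which exceeds the middle
gene's c for every c < 1. With the sum construction, the middle gene
correlates with *both* flanks at 1/√2 while each flank gene reaches only
(1 + ρ(a,b))/2 ≈ 1/2, so the planted gene is the unique best correlate
and noise-free recovery is achievable — which is what makes the
generator usable as a positive control. Middle reactions are the
adequate ones; flanks, with a single neighbor each, are deliberately
inadequate.

What the generator does **not** emulate: real metabolic topology (hub
metabolites with graded frequencies, cycles, compartments), correlated
measurement error across conditions, the long-tailed GPR size
distribution, operon structure in the genomic coordinates, and real
promoter sequence composition. Passing tests on these fixtures
demonstrate correctness of the machinery and recoverability under the
planted signal model, not expected accuracy on real screens, where
top-20 accuracy far below 1 is the norm.

## Companion genome statistics

* `binom_tail()` is the inclusive upper tail `P(X ≥ k)`; the
  region-effect test counts the conditions in which the focal region
  kind has the most negative location statistic and evaluates that count
  against `Binomial(n, 1/n_kinds)` — with 7 promoter sigma classes the
  null is the exact 1/7, not a decimal rounding of it.
* `class_enrichment()` is a one-tailed rank-sum test of a pair class
  against background; exact by enumeration up to n₁+n₂ = 10 (and, with
  a warning, whenever the class has under 3 values), normal
  approximation with tie and continuity correction above.
* `mhg()`/`mmhg_pair()` score label concentration at the top of ranked
  lists; the mmHG thresholds the first list, scores along the second,
  and takes empirical p-values from seeded shuffles of the first list's
  ordering. The threshold-on-one-list convention is ours and is
  oracle-tested; implementations differing in tie conventions may not
  match bit-for-bit.
* `pssm_enrichment()` scans promoters with a log-odds PSSM against a
  uniform background on both strands; the hit threshold is a free
  parameter since discovery tools rarely publish their internal cutoff.

## Numerical conventions and degenerate inputs

Genomic intervals are 0-based half-open; insertion membership is
`start ≤ position < end`. Ranking ties anywhere (candidates, promoters)
break lexicographically by id, making every ordering a reproducible
total order. Z-normalization rejects columns with fewer than two finite
values or zero spread by naming the offending condition. Empty candidate
sets, inadequate reactions, and orphan reactions passed to the collapse
raise errors rather than returning silent missings; survival-ratio
curves flag undefined points instead of emitting infinities.

## Problem sizes

The test suite and acceptance script run entirely on generated data:
single screens of 60 reactions × 48 conditions for recovery checks,
50 and 20 screens for the zero-signal calibration, 10 screens × four
condition subsets {6, 12, 24, 48} for the condition-count trend, and
exhaustive enumeration oracles up to N = 12 (mHG), 2⁴ assignments (GPR
truth tables) and n₁+n₂ = 10 (rank-sum). These sizes keep any single
check in the seconds range while leaving the statistics well away from
their small-sample edge cases.
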