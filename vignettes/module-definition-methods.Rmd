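---
title: "Defining regulatory modules: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining regulatory modules: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgrnet)
```

pgrnet implements a chain of analyses that turns knockout screens, factor
binding profiles, chromatin interactions and expression matrices into
*regulatory modules* — clusters of co-binding factors together with their
refined target genes — and then scores the activity of those modules
across samples. This vignette documents the statistical models behind
each stage, the parameters that matter, and the design decisions taken
where the procedure was genuinely open.

## Screen integration

Per-screen gene tables carry a normalized log2 fold change and a
negative-selection p-value (MAGeCK-style; `read_gene_summary()` maps
columns). Significance is `p_neg < 0.05`, strict and uncorrected — the
partition is deliberately defined on raw per-screen calls, because the
common set is itself an intersection over screens and further correction
would change its meaning. The *common* set is the intersection of all
per-screen significant sets; everything else significant anywhere is
*context-specific*. A gene absent from a screen counts as non-significant
there, which is conservative for the common set: a gene can only be
common if it was testable and significant everywhere.

sgRNA-level fold changes use counts-per-million normalization and a
pseudocount of 0.5 inside the log (`log2(cpm_to + 0.5) − log2(cpm_from +
0.5)`), the standard stabilizer for count ratios; 0 → 0 transitions give
exactly LFC 0. Gene-set comparisons use the Wilcoxon tests
(signed-rank against zero shift, or rank-sum between sets), exact for
n ≤ 25 without ties and normal-approximated with continuity correction
otherwise.

## Co-occupancy sub-classes

Peaks are binarized over fixed genome bins (default 1 kb): a factor
occupies a bin if a peak overlaps it by ≥ 1 bp. All coordinates are
0-based half-open (BED convention) throughout the package. For factors
$a, b$ occupying $m_a, m_b$ of $N$ bins with $O$ shared bins,

$$Z(a,b) = \frac{O - E}{\sigma}, \quad E = \frac{m_a m_b}{N}, \quad
\sigma^2 = E\left(1 - \frac{m_a}{N}\right)\frac{N - m_b}{N - 1},$$

the exact mean and variance of $O$ when one factor's bins are assigned
uniformly at random — a hypergeometric null. The literature on
co-occupancy scores does not pin down a single formulation; this null was
chosen because it is parameter-free, symmetric in $a, b$, and directly
testable against a permutation of bin labels (the test-suite checks
agreement within 0.1 on a 20-bin toy against 20,000 draws). The diagonal
is computed by the same formula and is the row maximum; a factor
occupying every bin has $\sigma = 0$ and its scores are defined as 0 with
a warning.

Factors are clustered by average-linkage hierarchical clustering on
$d(a,b) = 1 - \mathrm{cor}(Z_a, Z_b)$ over Z-matrix rows, and the tree is
cut at a user-chosen number of sub-classes. The cut count is a scientific
input, not an automatic criterion: in real data the number of sub-classes
emerges from inspection of the dendrogram and prior knowledge (nine in
the motivating setting). Constant Z rows make the correlation undefined
and raise an error naming the offending factors.

## High-degree co-occupancy binding sites

`hdbs_extract()` union-merges all member peaks (book-ended intervals
merge, gap 0 — the BEDTools merge default), counts for every merged
interval the number of distinct member factors overlapping it by ≥ 1 bp,
and keeps intervals with degree ≥ k. The k-of-n thresholds are per-class
configuration (mirroring published choices such as 25-of-32 or 11-of-12);
the pipeline default is k = n − 1 for an n-member class. Site count is
non-increasing in k, which the suite checks on fuzzed inputs against a
per-base counting oracle.

## Target assignment and positive-unlabeled refinement

*Proximal*: a gene is a putative target when an HDBS interval overlaps
TSS ± 5 kb (strand-independent; the window is closed at both ends in base
coordinates, so an interval starting exactly at TSS + 5000 still
qualifies). *Distal*: an interaction pair must have one anchor on an HDBS
interval and the **other** anchor on the gene's promoter window; both
anchor orderings count, but HDBS and promoter on the same anchor do not.

The putative set is noisy — promoter windows of bystander genes near a
loop anchor are pulled in, and interaction decoys add false links. The
refinement treats candidates as *positives of unknown purity* and
everything else as negatives: each round draws a balanced training set
(positives ∝ current weight, negatives ∝ 1 − weight), fits a
probabilistic classifier, and resets every gene's weight to its predicted
positive probability (5 rounds). This is repeated over a 10-member
ensemble alternating a k-nearest-neighbour estimator (k = 5) and a
ridge-regularized logistic model (λ = 0.01) — two learners with very
different biases, which is what makes the unanimity rule informative.

Each member votes positive when its final probability is ≥ 0.5, and a
candidate is retained when the ensemble positive fraction reaches the
threshold. The default threshold 1 demands unanimity (evaluated at
1 − 1e-9 to avoid floating-point false negatives). The vote-fraction
formulation was chosen deliberately over thresholding the mean
probability: a regularized logistic learner essentially never outputs a
probability of exactly 1, so mean-probability unanimity would make
threshold 1 empty by construction, while vote unanimity preserves its
intent — minimizing false positives. Non-candidates are never promoted:
refinement filters the putative set, it does not extend it.

Features are per-gene histone-mark quantifications (RPKM in a window
around the TSS — read as TSS ± 2.5 kb, i.e. 5 kb total, distinct from the
±5 kb proximal-target window; both are configurable because the two
windows serve different purposes) concatenated with expression
time-course values, each z-scored over the gene universe; genes missing a
source are imputed to the feature mean and flagged, zero-variance
features are dropped.

## Module activity, rank-AUC and survival

For expression $G$ (CPM/RPKM-like, genes × samples):

$$S(i,j) = \log_2\frac{G(i,j) + pc}{\bar G(i) + pc}, \qquad
C(i,j) = S(i,j) - \bar S(i), \qquad
E(x,y) = \frac{1}{g_x s_y}\sum_{i \in x,\; j \in y} C(i,j).$$

$\bar G(i)$ and $\bar S(i)$ are arithmetic means over **all** samples in
the matrix, not per group — activity is always relative to the whole
cohort. The pseudocount defaults to 1 (the matrices are CPM-scale;
without it a zero breaks the log) and is set to 0 in the closed-form
tests, where the chain reproduces E = ±0.5 exactly on the noiseless
one-sample-per-group scenario with a log2 effect of +1.

The per-sample rank-AUC score ranks genes by descending expression (ties
broken by gene label, for determinism), and measures the area under the
recovery curve of module genes within the top 5% of ranks, normalized to
[0, 1]. It is invariant to any monotone transform of the expression
column, so it can be compared across normalizations. Survival cohorts are
split at the activity median (ties at the cut go to the low stratum) and
compared by the log-rank test with Kaplan–Meier summaries, both via the
survival package.

## Enrichment patterns

Per sample, genes at least 2-fold above (below) their cross-sample
average are over-(under-)expressed; both boundaries are inclusive, and
"2-fold under" is read as ≤ mean/2 (equivalent to 2-fold on the log
scale). Genes with zero average are excluded from the universe. Module
enrichment is the hypergeometric upper tail $P[X \ge k]$ for both
directions, the universe being the genes present in the expression
matrix. When both directions pass α = 0.05 the smaller p wins (exact ties
go to over); the signed score is $-\log_2 p$ for over and $+\log_2 p$ for
under. No multiplicity correction is applied to the direction calls —
the raw α = 0.05 rule is part of the procedure being implemented — but
the p-values are returned so a BH report can be layered on.

The group-level pattern asks whether direction-enriched samples
concentrate in a group, again by a hypergeometric upper tail. One
consequence worth knowing: if an effect's mirror image is split evenly
across *two* equal-sized inactive groups, neither group can individually
reach significance (the best attainable p with 5-sample groups among 15
samples is 0.084). The detection tests therefore contrast the pluripotent
group against the pooled differentiated samples — an analysis choice, not
a generator change.

## What the generator emulates — and what it does not

`simulate_study()` plants: essential genes shared by all screens plus
per-screen specific ones (negative-binomial sgRNA counts, dispersion 0.1,
4 guides/gene, log-normal library factors, sdlog 0.1); factor classes
sharing binding sites (shared-site width 600 bp with uniform jitter
≤ bin/4 — width exceeds twice the jitter so planted co-binding always
survives overlap counting); true targets that are proximal or
loop-connected distal with decoy pairs; expression groups with log2 ±2
module shifts (a 4-fold activation places active-group samples exactly at
the 2-fold-over-mean boundary in the noiseless limit, so the inclusive
boundary rule matters) under multiplicative log-normal noise (sdlog 0.4);
separable histone/time-course features with a planted 20% contamination
among putative targets; and exponential survival with hazard ratio 3
between high- and low-activity patients under uniform censoring.

Deliberately absent: read-level data (no FASTQ/BAM), peak-calling noise,
overlapping classes, batch effects, correlated features, non-proportional
hazards, and the long-tailed gene-length and mappability artifacts of
real RPKM. Passing tests therefore demonstrate that the implementation
computes its statistics correctly and recovers structure the generative
model can express — not that the defaults match any particular real
dataset.

The standard study sizes (2,000 genes, 5 screens, 3 classes × 4 factors +
3 noise factors, 50 sites/class on a 4 Mb two-chromosome genome, 3 × 10
samples, 200 patients) keep every planted structure estimable while the
full suite, including 1,000-case brute-force oracles and 200-replicate
survival simulations, completes in minutes.

## Numerical conventions and degenerate inputs

* Coordinates 0-based half-open everywhere; "central peak" = interval
  midpoint (integer division).
* Peak-annotation distance is midpoint to nearest TSS, signed by gene
  strand (upstream negative); equidistant ties go to the
  lower-coordinate TSS. Category priority: promoter (|d| ≤ 3 kb) >
  gene body > distal intergenic.
* Coverage profile windows extending past a chromosome end are
  zero-filled and still count in the denominator.
* All-zero samples, empty annotations, empty modules, zero-variance
  features, all-tied paired comparisons and empty survival strata raise
  errors or warnings rather than silently producing numbers; p = 1 is
  returned only where it is the honest answer (empty module, all-zero
  differences).
* Every generator routes randomness through `withr::with_seed` on
  offsets of the configuration seed, so a fixed `sim_config()` yields
  byte-identical studies and pipeline outputs.

## Known limitations

The Z-score null assumes bins are exchangeable, ignoring mappability and
chromatin-accessibility structure; real co-occupancy matrices are
computed over highly non-uniform backgrounds. The PU ensemble's unanimity
rule is aggressive by design — with weakly separable features it will
sacrifice recall long before precision, and the threshold should be
lowered knowingly. The rank-AUC top fraction (5%) follows the convention
of the regulon-activity literature; small modules in large universes are
noisy at any top fraction. Group-level enrichment inherits the
granularity limits of small per-group sample counts described above.
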