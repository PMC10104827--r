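# pgrnet

Integrative definition of pluripotency regulatory modules from CRISPR
screens, binding co-occupancy, chromatin interactions and expression data.

## The problem

The gene regulatory network that maintains embryonic stem cell (ESC)
self-renewal is organized in *sub-classes*: groups of transcription
factors and co-factors that bind the same genomic sites (CORE, MYC, PRC,
PAF, PCGF, TBX, ...). A sub-class together with its target genes forms a
*module* whose expression activity tracks the pluripotent state — in ESCs,
in early embryos, and (re-activated) in cancers. Defining such modules
requires stitching together several analyses that are usually run ad hoc:

1. **Screen integration** — per-screen negative-selection hits
   (MAGeCK-style gene tables, p < 0.05) are partitioned into a *common*
   set (significant in every screen) and a *context-specific* set (the
   union minus the common set); screens are compared by Pearson
   correlation of normalized log2 fold changes.
2. **Co-occupancy sub-classes** — binding peaks are binarized over genome
   bins; for factors a, b occupying m_a, m_b of N bins with O shared
   bins, the co-occupancy Z-score is

       Z(a,b) = (O − E) / σ,  E = m_a·m_b / N,
       σ² = E · (1 − m_a/N) · (N − m_b) / (N − 1)

   (hypergeometric null of independent placement). Factors are clustered
   by average-linkage on 1 − cor(Z rows).
3. **High-degree co-occupancy binding sites (HDBS)** — member peaks are
   union-merged; each merged interval's degree is the number of member
   factors overlapping it; intervals with degree ≥ k are retained
   (the k-of-n rule, e.g. 25-of-32 for a CORE-like class).
4. **Target assignment** — proximal targets: an HDBS interval within
   TSS ± 5 kb; distal targets: a chromatin interaction pair with one
   anchor on an HDBS interval and the other on the promoter window. The
   putative set is then refined by positive-unlabeled adaptive sampling
   (an ensemble of kNN and ridge-logistic learners; at prediction
   threshold 1 a candidate must be retained unanimously), purging false
   positives by their histone-mark and expression time-course features.
5. **Module activity** — expression G(i,j) is standardized against the
   per-gene mean and centered,

       S(i,j) = log2( G(i,j) / Ḡ(i) ),   C(i,j) = S(i,j) − S̄(i),

   and module activity is the plain mean E(x,y) of C over module-x genes
   and group-y samples. A rank-AUC score gives per-sample activity, and
   a median split on activity feeds Kaplan–Meier / log-rank survival
   analysis.
6. **Enrichment patterns** — per sample, genes ≥ 2-fold above (below)
   their cross-sample average form over-(under-)expressed sets; module
   enrichment is a hypergeometric upper-tail test, with the direction of
   smaller p reported as a signed −log2(p) score, per sample and per
   sample group.

Every input can be generated synthetically with planted ground truth
(`sim_config()` / `simulate_study()`), so each stage is verifiable without
any external download.

## Worked example

```r
library(pgrnet)
cfg <- sim_config(seed = 1)       # 5 screens, 3 planted classes + 3 noise
res <- run_pipeline(cfg)          # simulate + full analysis chain

table(res$classes$clustering$membership)
#> 1 2 3 4 5 6
#> 4 4 4 1 1 1
```

The three planted 4-factor classes are recovered exactly; the three noise
factors fall into singletons.

```r
round(res$activity$E, 3)
#>               ESC    EB6   EB12
#> subclass01  1.167 -0.575 -0.592
#> subclass02  1.137 -0.563 -0.574
#> subclass03 -1.064  0.522  0.542
```

Modules 1–2 (activated classes) show positive centered activity in the
pluripotent group and negative activity after differentiation; module 3
(the repressed class) shows the mirror pattern — the planted log2 ±2
shifts survive the whole chain of screen → class → HDBS → target → E(x,y).

```r
length(res$screens$partition$common)   # planted all-screen essentials
#> 60
signif(res$survival$p, 3)              # log-rank on activity median split
#> 1.36e-07
```

The survival cohort, generated with hazard ratio 3 between high- and
low-activity patients, is cleanly separated by the activity median split.

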