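---
title: "Methods: injury time-course transcriptome analysis with injurytx"
author: "injurytx authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: injury time-course transcriptome analysis with injurytx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(injurytx)
```

# The analysis problem

Contusive injury of neural tissue triggers a cascade of transcriptional
programs — inflammation, cell death, tissue remodeling — that unfold over
days. A bulk RNA-seq time course of such an injury typically contrasts a
sham control against an acute and a subacute stage (here labeled CTR, D2,
D7) with very few biological replicates (two controls, three per injured
stage). `injurytx` implements the full downstream analysis of such a
design: deciding which expression estimates are trustworthy at all,
calling differential expression, grouping genes by trajectory, ranking
candidate genes on an interaction network, detecting isoform switches,
testing marker signatures for enrichment, and checking concordance with
qPCR. Every stage is exercised against a synthetic-data generator with
known ground truth, so the package's claims about its own behavior are
measurable.

# Detection thresholding from confidence bounds

Transcript-assembly pipelines report, for every gene and sample, an FPKM
estimate together with a 95% confidence interval. The package calls an
estimate **reliable** when its CI lower bound is strictly above zero — the
data can distinguish the gene from silence — and **unreliable** otherwise
(`label_reliability()`). Pooling the calls of all samples, a reliability
curve over a threshold grid is built (`detection_curve()`): at each
threshold $t$,

* reliability$(t)$ = reliable fraction among calls with FPKM $\ge t$,
* FP$(t) = 1 -$ reliability$(t)$ (estimates kept by the threshold that may
  be zero),
* FN$(t)$ = fraction of all reliable calls falling below $t$ (real signal
  discarded).

`select_threshold()` returns the smallest grid threshold whose reliability
reaches a target (default 0.99). `floor_fpkm()` then replaces every value
below the chosen threshold by the threshold itself before fold changes are
formed, the classic guard against ratio inflation by near-zero
denominators.

**Design choice.** FP and FN have no canonical algebraic definition in
this setting; the operationalization above was chosen because it makes
"the probability that a transcript can be reliably detected" exactly the
reliability curve the selection works on. Calls are pooled over samples
and one study-wide threshold is chosen (not per sample or per replicate) —
with 2–3 replicates per stage, per-sample curves are noisy and a single
floor keeps every downstream ratio on one scale. The default grid is
logarithmic with 50 points from 0.001 to 10 FPKM, covering the range where
bulk FPKM detection limits realistically live.

# Differential expression

For a contrast (treated vs control stage), `fold_change()` is the ratio of
replicate means of floored FPKM; `de_t_test()` is the classic two-sided
unpaired Student's *t*-test with pooled variance; `call_de()` marks a gene
significant iff its fold change exceeds the cutoff in either direction
(default 2) **and** the raw p-value is below the cutoff (default 0.05).
`venn_partition()` intersects the up/down sets of two contrasts, and
`select_top_fraction()` takes the strongest `fraction` (default 10%) of
each direction — the focus genes of the network stage.

Design choices worth stating explicitly:

* **Pooled-variance Student, not Welch.** With $n = 2$ vs $3$, Welch's
  degrees-of-freedom estimate is extremely unstable; the pooled test is
  the textbook "unpaired t-test" at these sizes. Welch remains available
  (`var_equal = FALSE`).
* **Testing on raw FPKM.** The rule tests the values whose ratio is being
  reported. A log2-scale option (`log_scale = TRUE`) exists; it is usually
  better powered under multiplicative noise but changes which genes pass,
  so the raw scale is the default and the log variant is opt-in.
* **No multiple-testing correction in the call.** The selection rule is a
  joint fold-and-p filter at raw $p < 0.05$; BH q-values are reported in
  the output for transparency but do not enter the call.
* **Degenerate genes.** Zero variance in both groups yields $p = 1$ when
  the means agree and $p = 0$ with a warning when they differ; NaNs never
  propagate.
* **Top-fraction denominator** is the count of significant genes in that
  direction, with ties broken by gene id so selections are reproducible.

# Trajectory clustering

Genes whose floored stage means change more than 2-fold between at least
two stages (`select_varying_genes()`) are standardized gene-wise
(`standardize_profiles()`; population-*n* standard deviation, so tests
can assert exact values) and clustered with fuzzy c-means
(`fuzzy_cmeans()`, default $k = 9$, fuzzifier $m = 1.25$). The optimizer
is the classic alternating scheme on the objective
$J = \sum_{ij} u_{ij}^m \lVert x_i - c_j \rVert^2$ with k-means++-style
seeding; by default three restarts are run from seeds derived from the
given seed and the lowest-objective run is returned, which removes the
occasional local optimum a single seeding produces. $m = 1.25$ is a common
choice for z-scored expression trajectories: with only three stages,
larger fuzzifiers wash the memberships toward uniformity.

Sample-level QC uses `hierarchical_samples()` (complete linkage on
$1 - r$, Pearson, over the 3000 most variable genes) and
`replicate_correlation()`. Clustering operates on stage means (3-point
profiles), which is what a 3-stage trajectory design supports.

# Network-based candidate prioritization

The framework mirrors how hub genes are prioritized from knowledge-base
interaction networks:

1. focus genes = top fraction of up/down-regulated genes;
2. `build_network()` induces the edge-list subgraph over focus genes plus
   (optionally) their first neighbors, dropping isolated nodes;
3. `filter_candidates()` keeps genes on the plasma membrane or in
   extracellular space with a fold change beyond the cutoff — the
   drug-accessible compartments — plus any gene with drug information
   regardless of location;
4. `relevance_index()` scores RI $= |\log \mathrm{FC}| \times$ connection
   number, and `rank_candidates()` sorts by RI with degree and gene-id
   tie-breaks.

The log base (default 2) only rescales RI by a positive constant, so
rankings are base-invariant; absolute RI values printed by other tools may
assume a different base. Interactions are treated as undirected and
multi-edges are collapsed, so "connection number" means distinct
interaction partners. When one direction dominates a stage, separate
networks per direction are available (`separate_directions = TRUE`).
Genes missing from the annotation default to location "other" without
drug information — permissive enough that prioritization still runs on
partially annotated networks.

# Isoform analysis

On an isoform-level study with an isoform-to-gene map,
`count_expressed_isoforms()` counts isoforms whose stage-mean FPKM clears
the detection threshold (the same global threshold as the gene level, for
consistency), `major_isoform()` takes the stage-wise argmax (exact ties go
to the lexicographically smallest id and are flagged), and
`detect_switch()` reports the earliest stage pair whose major isoforms
differ. An optional margin (e.g. 1.5×) additionally requires the incoming
major isoform to beat the displaced one by that ratio; the margin defaults
to 1 (the literal rule) and is a robustness option against noise-driven
flips. `anova_across_stages()` is classic one-way fixed-effects ANOVA with
the same degenerate-input conventions as the t-test.

The published per-stage counts of multi-isoform genes are ambiguous
between per-stage and all-stages counting; `count_expressed_isoforms()`
reports both (`multi_isoform` carries one entry per stage plus an
`all_stages` entry).

# Enrichment

Two engines cover the two enrichment idioms:

* `fisher_enrichment()` — one-sided hypergeometric over-representation of
  a query set against a collection, BH-corrected. The universe should be
  the genes passing the detection threshold, not the whole annotation.
* `enrichment_score()` / `gsea_permutation()` — the weighted
  Kolmogorov–Smirnov running-sum statistic over a fold-change-ranked list:
  hits advance the sum by their $|\mathrm{metric}|^p$ share, misses
  retreat it by $1/(N - N_{set})$, and ES is the signed maximum deviation.
  The null is built by **gene-label permutation** (random same-size sets):
  with 2–3 replicates per stage, phenotype permutation admits too few
  distinct relabelings to be meaningful. NES divides ES by the mean
  |null ES| of the same sign; nominal p uses the $(k+1)/(m+1)$ estimator,
  so it is floored and never exactly zero; FDR is BH across queried sets.

A property worth knowing: "a randomly placed set scores zero" holds
exactly in expectation for the unweighted statistic ($p = 0$), while the
weighted form ($p = 1$, the default) carries a small set-size-dependent
bias (of order ±0.02–0.1 depending on the metric's asymmetry) because
hit increments concentrate where $|\mathrm{metric}|$ is large. The
package's null checks therefore assert the zero-mean property at $p = 0$
and on equal-metric lists, where it is exact.

# qPCR concordance

`delta_delta_ct()` implements relative quantification: technical
replicates are averaged per gene and sample; $\Delta Ct$ = gene minus
housekeeping per sample; biological replicates are averaged on the
$\Delta Ct$ (cycle) scale; $\Delta\Delta Ct$ is the treated-minus-control
difference and the fold change is $2^{-\Delta\Delta Ct}$ with
amplification efficiency fixed at 2. Averaging biological replicates on
the cycle scale (rather than on the fold scale) keeps the estimator
unbiased under Gaussian cycle noise; the sd of per-replicate
$2^{-\Delta\Delta Ct}$ values is reported as a simple error estimate.
`qpcr_concordance()` summarizes agreement with expression-derived fold
changes as Pearson/Spearman correlations of log2 folds plus a
sign-agreement fraction.

# The synthetic-data generator

`sim_config()` / `simulate_all()` emit a complete ground-truthed input
bundle. What it emulates, and the defaults:

* **Design**: stages CTR/D2/D7 with 2/3/3 biological replicates.
* **Baseline expression**: log-normal, log2 mean 3 and sd 2 for the
  well-expressed component, plus a weakly expressed component (25% of
  expressed genes, log2 mean −3, sd 1.5) that populates the detection
  boundary — without it the reliability curve would be flat and threshold
  selection trivial. 15% of genes are silent (truth 0).
* **Differential expression**: 8% of expressed genes up and 8% down per
  injured stage, $|\log_2 \mathrm{FC}| \sim N(2, 0.5)$ truncated at 1;
  half of a stage's DE genes persist (same direction) into the next stage,
  emulating responses spanning the acute and subacute phases.
* **Noise**: multiplicative log-normal on FPKM (additive Gaussian on log2,
  sd 0.25) — the standard bulk-expression assumption.
* **Confidence intervals**: symmetric on the log2 scale with half-width
  $h = a + (1-a)\sqrt{d/(v + \varepsilon)}\,J$, where $d$ is the planted
  detection limit (default 0.1 FPKM), $a = 0.1$, and $J$ is log-normal
  jitter (sd 0.5); the lower bound reaches 0 once $h \ge 1$. The
  constants were calibrated once so that reliability at 0.1 FPKM is ≈ 0.99
  under the defaults; they describe the emulation, not any particular
  upstream estimator.
* **Network**: preferential attachment (2 edges per node) over the DE
  genes plus a random background fill, with 3 planted hubs wired to at
  least degree 40. The first hub is the DE gene with the largest planted
  |log2 FC| among well-expressed genes (baseline ≥ 1 FPKM) — the
  framework's ideal candidate; a change at the detection boundary would be
  erased by flooring and is not a fair recovery target. Planted hubs are
  annotated to drug-accessible compartments.
* **Isoforms**: 1–12 isoforms per gene with 99% of genes at 1–5;
  per-stage true proportions are constant except for planted switch genes
  (5% of well-expressed multi-isoform genes), whose leading isoform hands
  over linearly from 70% to 20% across the course while another rises
  symmetrically. Observed gene values are split among isoforms with mild
  Dirichlet jitter (concentration 200), so isoform values sum exactly to
  the gene value in every sample.
* **qPCR**: housekeeping Ct 20, one cycle per 2-fold of true change,
  Gaussian cycle noise sd 0.1, triplicate reactions.
* **Determinism**: one global seed; every sub-generator derives its own
  stream by a fixed offset, so any component can be regenerated
  independently and all emitted tables are bitwise reproducible.

What the generator does **not** emulate: sequencing-depth and coverage
effects, batch effects, correlated genes, annotation errors, directed or
typed interactions, and amplification-efficiency variation in qPCR.
Passing tests therefore demonstrate that the implementations recover the
structure they claim to recover under the stated noise model — not that
the pipeline is robust to every artifact of real tissue RNA-seq.

# Numerical conventions

* Ratios are never formed on unfloored values inside the pipeline.
* Fuzzy c-means stops when the objective decreases by < 1e-9 or after 500
  sweeps; profiles coinciding with a center receive crisp membership.
* Ties are always broken deterministically (gene or isoform id,
  then-degree for candidate ranks), so every table is reproducible.
* Degenerate statistical inputs (zero variances) resolve to the boundary
  p-values stated above rather than NaN.

# Problem sizes used by the test suite

The packaged checks run at sizes a laptop handles in a few minutes, chosen
as the smallest designs at which the measured properties are stable:
2,000-gene studies (20 seeds per planted detection limit) for threshold
recovery; 10,000 null genes for test size; 2,000 genes at planted
$|\log_2 \mathrm{FC}| = 2$ for power and FDR; 900 genes in 9 archetypes
for clustering recovery; 10,000 random sets for the enrichment null; 10
seeds of 800-gene studies for switch recovery; 100 seeds of 200-gene
studies for qPCR recovery; and a 500-gene end-to-end determinism run.
`scripts/acceptance.R` re-runs exactly these computations from an
installed copy of the package and writes the measured quantities as JSON.

# Known limitations

* The t-test on 2 vs 3 replicates has little power for fold changes below
  ~4 at realistic noise; the planted-effect conditions reflect this.
* The detection-curve FP/FN operationalization is one defensible reading;
  alternative definitions can be computed from the `label_reliability()`
  table directly.
* RI values depend on the log base (rankings do not).
* Gene-label permutation tests a different null than phenotype
  permutation; its p-values describe set position, not between-group
  variability.
* The isoform switch call uses stage means; replicate-level switch
  uncertainty is only addressed through the optional margin.
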