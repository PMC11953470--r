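---
title: "Context-aware DNA methylation subtyping: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Context-aware DNA methylation subtyping: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epityper)
library(dplyr)
```

# The problem

Bulk tumor methylation arrays measure, at each CpG, the fraction of
methylated signal (the beta value) in a mixture of malignant and
non-malignant cells. Two features dominate what such data look like:

* **Tumor purity.** If a fraction $p_s$ of sample $s$'s cells are malignant,
  the observed beta at probe $i$ is approximately
  $\beta_{is} = p_s\, t_{is} + (1 - p_s)\, n_{is} + \varepsilon$, where
  $t$ and $n$ are the (unobserved) tumor and normal methylation states.
  Because individual cells are essentially methylated or not, $t$ and $n$
  sit near 0 or 1; the intermediate values seen in bulk data are largely a
  purity artifact, and unsupervised analyses of unadjusted data partly
  cluster samples by tumor cell content rather than tumor biology.
* **Genomic context.** The expected methylation level and its biological
  meaning depend on where a CpG sits: promoter CpG islands are usually
  unmethylated, low-density "ocean" regions are methylated by default, and
  variable methylation of distal regulatory elements in open chromatin
  carries subtype information.

`epityper` implements a workflow that addresses both: per-CpG linear purity
adjustment with an inferred in-silico normal, context annotation of every
probe, NMF clustering of context-restricted high-variance CpGs into
*epitypes*, rank-test differential methylation, CpG-gene expression linkage
with an outlier-robust jackknife correlation against an empirical
randomized null, and co-expression network extraction — plus a synthetic
cohort generator that produces all of these inputs with known ground truth.

# Per-CpG purity models

For each probe the samples are partitioned into at most three *methylation
populations* (groups of tumors sharing a methylation state at that CpG) by
one-dimensional k-means on beta with $k \in \{1,2,3\}$ chosen by mean
silhouette width; if no split reaches a mean silhouette of 0.60 the probe is
treated as one population. The k-means centers are initialised at the
$(j - \tfrac12)/k$ quantiles of the beta values, which makes the procedure
fully deterministic; the Lloyd iterations then run on the line until the
assignment stabilises.

Each population gets a least-squares line $\beta \sim \text{purity}$. The
slope is confined to $[-1, 1]$: beta is a fraction of a two-component
mixture, so no population can change faster than the mixture itself; when
the slope is clipped the intercept is refit through the population centroid.
Probes with fewer than 10 usable samples are flagged unfit and adjustment
returns its input unchanged.

Adjustment extrapolates each sample's population line to purity 1 while
preserving the sample's residual,
$$\hat\beta = (a + b) + \left(\beta_{\text{obs}} - (a + b\,p)\right),$$
clamped to $[0,1]$. Preserving the residual (rather than reporting the line
value) keeps inter-tumor heterogeneity visible after adjustment; at
$p = 1$ the adjustment is exactly the identity. The *inferred normal* is the
population line at purity 0 (the intercept, clamped): the methylation state
the admixed non-malignant cells are estimated to carry.

Samples not seen at fit time (or unassignable) are attached to the nearest
line by absolute residual.

# Context annotation

Gene models are consensus transcripts: exons of all of a gene's transcripts
are pooled, the 5'-most base becomes the TSS and the 3'-most the TES (on the
minus strand the 5'-most base is the larger coordinate, so `tss > tes`).
Probes are then assigned:

* a **genic context** from the distance $d$ to the nearest consensus TSS:
  promoter ($|d| \le 500$ bp), proximal ($500 < |d| \le 5000$ bp), distal
  ($|d| > 5000$ bp). Both boundaries are inclusive; equidistant ties break
  by lexical gene id so annotation is deterministic. The signed distance is
  positive downstream of transcription.
* a **CpG-density context**: island if inside a (merged) CpG island, shore
  within 2,000 bp of an island edge (inclusive), ocean otherwise. The 2 kb
  shore width is the island/shore/ocean convention.
* an **open-chromatin flag**: containment of the 1 bp probe position in any
  ATAC peak. Probe coordinates are 1-based (array manifest convention);
  BED-derived intervals are 0-based half-open and converted at ingest.
* optional **local density metrics** from a probe-centred sequence window
  (1,001 bp by convention): the observed/expected CpG ratio
  $\text{O/E} = \#\text{CpG} \cdot L / (\#C \cdot \#G)$ and GC fraction,
  a two-class split (HCG at O/E $\ge 0.48$), and a three-class promoter
  scheme over sliding 500 bp subwindows (HCP when some subwindow has
  O/E $\ge 0.75$ and GC $\ge 0.55$; LCP when every subwindow has
  O/E $< 0.48$; ICP otherwise). O/E is invariant under reverse
  complementation, which the tests exploit.

Per-context variability is summarised as the distribution of per-probe beta
SDs, and transcription-factor overlap enrichment of a probe cluster uses a
one-sided Fisher exact test per TF with FDR adjustment across TFs.

# Epityping by NMF

Clustering runs on the $n_{\text{top}}$ most variable probes within a
context filter — canonically distal probes overlapping ATAC peaks, the
context where subtype information concentrates. Ranking is by SD across
samples with lexical tie-breaks; probes with missing values are excluded
from ranking so SDs are comparable.

The sample clustering is non-negative matrix factorization with the
Kullback-Leibler objective and multiplicative updates, restarted `nrun`
times from random initialisations whose seeds derive deterministically from
the master seed (`seed + run`); the best run by objective is kept and each
sample is assigned to the factor with its largest mixture coefficient.
Convergence is declared when the relative objective change falls below
1e-6 (checked every 10 iterations) or after 2,000 iterations. The update
loop is compiled (RcppArmadillo) because the restarts dominate the
workflow's runtime. Concordance between a two-group NMF split and an
external binary label (e.g. Basal vs non-Basal expression subtype) is the
accuracy maximised over the two cluster-label mappings, so it is invariant
to relabeling; note this statistic is $\ge 0.5$ by construction and its
chance level at $n$ samples sits near $0.5 + O(1/\sqrt n)$, which is why
the no-signal controls below use larger cohorts. CpG row structure for
heatmaps uses Euclidean Ward (`ward.D`) clustering.

# Differential methylation and expression

Per probe, a two-sided Wilcoxon rank-sum test (two groups) or
Kruskal-Wallis test (more). A probe whose pooled SD across all samples in
the comparison is zero gets $p = 1$ — a constant probe carries no evidence,
and the pooled interpretation keeps group-wise-constant probes with unequal
means testable. P-values are Bonferroni- (or FDR-) adjusted across probes,
and significance additionally requires a maximum pairwise group-mean beta
difference above `delta_cut` (0.25 by default; the p filter can be disabled
for pure effect-size screens). For group sizes up to 6 per group the
Wilcoxon p-value is computed by exact enumeration of
$\binom{n}{n_1}$ rank assignments (two-sided: probability of a rank sum at
least as far from its null expectation as observed — valid under ties);
above that, the tie-corrected normal approximation with continuity
correction, matching the classical large-sample formula. The tests are
evaluated row-wise in vectorised form so cohort-scale simulations (tens of
thousands of probes) stay fast; the classical single-vector implementations
serve as oracles in the test suite. Exact enumeration is limited to the
two-group case: full enumeration of three-way arrangements is
combinatorially infeasible and the Kruskal-Wallis branch always uses its
chi-square approximation. Probes with less than 80% sample coverage are
flagged and skipped (configurable).

Tumor-vs-normal contrasts attach, per probe, the difference between a tumor
group's mean beta and the mean inferred normal beta of the same samples,
plus the normal background state (hypo when mean beta $\le 0.5$).

Differential expression follows the same rank-test pattern on
$\log_2(\text{FPKM} + 0.1)$ with FDR across genes, and requires a raw-scale
difference above 1 FPKM between the highest and lowest group median — an
effect-size guard against large-cohort significance of negligible changes.
The three-group group-specific scheme restricts to overall-significant
genes, FDR-adjusts each pairwise Wilcoxon family separately over that
restricted set, and calls a gene group-specific when both pairwise tests
involving the group are significant and the third is not; assignments are
mutually exclusive by construction and permute correctly under group
relabeling.

# Methylation-expression linkage

Each CpG maps to all genes whose consensus TSS falls within a 500 kb window
centred on the probe (inclusive at exactly 250 kb). To damp spurious
correlations, probes need a beta range above 0.25, genes an FPKM range
above 1 and a cohort mean FPKM of at least 0.5; expression is then
log-transformed.

The association measure is a **jackknife Pearson correlation**: Pearson r
on the full data and on each leave-one-out subsample, returning the signed
value of smallest absolute magnitude among them. This conservative
definition directly honours the estimator's purpose — a single influential
sample can manufacture a large full-data r, but the subsample excluding it
will not follow. A bias-corrected jackknife estimate
($n r - (n-1)\bar r_{(-i)}$) is available as an option. The estimator is
computed from downdated sums (exact to floating point against the
brute-force oracle) and always lies within the span of
$\{r_{\text{full}}, r_{(-1)}, \dots, r_{(-n)}\}$; note
$|r_{\text{jack}}| \le |r_{\text{full}}|$ is *not* guaranteed in general.
Pairs that are constant in any leave-one-out subsample are flagged
degenerate and dropped.

Significance cutoffs come from an **empirical null**: a seeded uniform draw
of probes (50,000 by default; analyses here scale it down), paired with all
window genes through the same filters and the same correlation, pooled, and
summarised by the 2.5th and 97.5th percentiles (linear interpolation
between order statistics). One pooled null is computed per cohort analysed.
Calls are strict: a pair is significant only when its correlation falls
strictly outside the cutoffs, so about 5% of truly null pairs are flagged
by construction — a calibration the acceptance suite checks with a binomial
confidence band. Whether the null pools every window gene per probe or one
gene per probe is a free choice; pooling all is used, which matches how the
real pairs are formed.

Candidate epigenetically regulated genes are filtered by: at least 3
significant *negative* pairs within 7 kb of the TSS, membership in the
differentially expressed set, an absolute between-group median FPKM
difference above 5, and optionally a median fold change above 10 (medians
offset by 0.1 so zero medians stay finite). All thresholds are parameters.

# Metagenes and networks

A metagene rank score is, per sample, the mean ascending rank (average
ranks on ties) of the member genes divided by the total gene count — a
value in (0, 1] invariant under any monotone transform of that sample's
expression vector, so no cross-sample normalisation is required.
Co-expression networks are connected components of the graph whose edges
join gene pairs with Spearman correlation $\ge 0.7$ (positive correlations
only), keeping components with at least 8 genes; each network's per-sample
score is the median raw FPKM of its members. Correlations are computed on
raw FPKM — Spearman is rank-based, so the log transform would change
nothing but ties. Edges can be exported as a SIF file for external viewers.

# The synthetic cohort generator

`simulate_cohort()` produces every input the pipeline ingests, with truth.
Its default configuration *is* the reference study condition of the
acceptance suite and stays fixed:

* 120 samples in two epitypes (75/25), with 3 + 2 nested subgroups;
  tumor purity uniform on (0.3, 0.9); noise SD 0.03 (truncated-normal on
  the mixture via clipping to $[0,1]$ — simple and clip-safe; logit-normal
  noise would be the obvious alternative).
* One synthetic chromosome with 400 genes on 50 kb tiles (alternating
  strands), so a 500 kb window holds roughly ten TSSs. Gene tiles cycle
  through three promoter archetypes (island promoter, no promoter CGI,
  shore promoter) and every tile carries a distal island, which makes every
  genic x density context combination realisable with *exact* intended
  annotations; probes are placed in per-stratum zones at fractions chosen
  to echo an array's context proportions (promoters enriched for islands,
  distal regions dominated by oceans). ATAC peaks are 151 bp intervals over
  probes drawn with context-dependent probabilities (promoters 0.50,
  proximal 0.35, distal 0.30).
* Tumor states sit near 0.06/0.94, islands mostly unmethylated and oceans
  mostly methylated; 80% of probes keep the normal state
  (`concordant_frac`), the rest are somatically shifted. A planted block of
  200 distal-ATAC CpGs separates the epitypes at $\Delta\beta = 0.4$ (half
  gaining, half losing methylation in the minor epitype, with the normal
  state matching the major epitype); 30 CpGs per subgroup separate
  subgroups at $\Delta\beta = 0.3$. Ten percent of probes are *variably
  methylated*: continuous tumor variation (scaled Beta(8,8)) unrelated to
  epitype or expression — the pool of variable-but-unlinked CpGs real
  methylomes carry, without which an empirical null has no eligible
  probes after adjustment.
* Expression is log-normal FPKM; 60 genes shift by 1.5 log2 units between
  epitypes; 50 genes near planted pair probes are coupled to their probe's
  tumor beta at correlation 0.7 (negative by default; pair probes vary as
  scaled Beta(2,2) and are kept out of ATAC peaks so they do not enter the
  clustering context); latent-factor blocks of 10 and 7 genes provide one
  recoverable network and one that the 8-gene rule must reject.
* Everything is deterministic given the seed (default 221027, echoing the
  workflow's clustering seed), and the caller's RNG state is untouched.

What the generator does **not** emulate: array chemistry and probe-type
effects, copy-number-driven methylation artifacts, spatially correlated
(region-level) methylation, heavy-tailed expression noise, batch effects.
Passing tests therefore demonstrate correctness of the algorithms under the
stated generative assumptions, not robustness to those real-data features.

# Validation design and problem sizes

The acceptance suite (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) recomputes, from scratch:
purity recovery (100-sample, 2,000-probe cohorts; MAE of adjusted beta
against true tumor beta and of inferred against true normal, both under
0.05); epityping recovery (120 samples, 200 planted distal-ATAC DMCs,
NMF $k=2$, nrun 30, seed 221027, concordance $\ge 0.95$) with no-signal
controls at $n = 500$ where the chance level of the max-mapped accuracy
statistic concentrates tightly around 0.5; exact rank-test fidelity against
a permutation-enumeration oracle; type-I error (50 null cohorts of 10,000
probes under Bonferroni, mean false positives $\le 1$) and power (100
planted $\Delta\beta = 0.4$ instances inside a 10,000-probe cohort,
detection $\ge 95\%$); the jackknife against its brute-force oracle on
1,000 vectors; empirical-null calibration at 5,000 null probes (the 50,000
of a full array scaled to the synthetic cohort) with seed-stable cutoffs;
the three-group scheme on 1,000 planted genes; network recovery; boundary
cases of the context windows; and one end-to-end run on the default cohort
from simulation through networks. Cohort sizes were chosen as the smallest
that make these properties statistically crisp.

# Known limitations

* The purity model is linear per population; focal copy-number events or
  allele-specific methylation that bend the beta-purity relation are not
  modelled, and probes with fewer than 10 usable samples pass through
  unadjusted.
* Population discovery uses 1-D k-means with a silhouette threshold; very
  close populations (separation under roughly twice the noise SD) merge,
  which is conservative for adjustment but blurs the inferred normal for
  those probes.
* The empirical null assumes the sampled probes are predominantly
  unlinked to expression; in a cohort where a large fraction of variable
  CpGs carries true signal the cutoffs widen and calls become conservative.
* NMF assignments use the dominant mixture coefficient; samples loading
  almost equally on two factors are still assigned hard labels.
* Region-level (DMR) merging, beta-binomial models, probe-chemistry
  normalisation and genome-build liftover are out of scope.
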