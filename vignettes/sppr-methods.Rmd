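---
title: "Methods: correlating expression and proteome with specific protein production rate"
author: "spprOmics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: correlating expression and proteome with specific protein production rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spprOmics)
```

# Scope

`spprOmics` implements a system-wide analysis of chemostat cultivations of a
protein-secreting filamentous fungus: per-sample physiology, per-gene
correlation of expression with the specific extracellular protein production
rate (SPPR), chromosomal-cluster detection with permutation support,
cross-genome cluster conservation, metabolic-network scoring (reporter
metabolites, enriched molecular paths), transcript–protein integration, and
cross-platform calibration. Because the full analysis needs a deposited
microarray data set, a genome annotation and proteomics spot tables, the
package ships a first-class synthetic-data module that generates all inputs
with planted, recoverable structure; every statistical property of the
pipeline is tested against those plants or against closed-form oracles.

# Physiology

At chemostat steady state the dilution rate $D$ (h$^{-1}$) equals the
specific growth rate, and mass balances give

$$\mathrm{SPPR} = 1000\,\frac{D\,P}{X}, \qquad
  q_s = \frac{D\,(S_{feed}-S_{res})}{X}, \qquad
  Y_{xs} = \frac{X}{S_{feed}-S_{res}}, \qquad
  Y_{ps} = \frac{P}{S_{feed}-S_{res}},$$

with $X$ the biomass dry weight (g/L), $P$ extracellular protein (g/L) and
$S$ the limiting substrate (g/L). SPPR is reported in mg protein · g
biomass$^{-1}$ · h$^{-1}$, hence the factor 1000. The source study does not
print its SPPR formula; the standard steady-state balance above is assumed,
and a precomputed `SPPR` column in the cultivation table is accepted
unchanged by the readers for users who compute it differently. Residual
substrate below detection is coded 0. Condition contrasts
(`conditionContrast()`) use the pooled-variance Student t by default — the
test named in this literature — with Welch available via `welch = TRUE`.

# Correlation with SPPR and FDR control

For each gene, `correlateToSppr()` computes the Pearson correlation $r$
between its log2 expression profile and the per-sample SPPR, with the exact
p-value from $t = r\sqrt{n-2}/\sqrt{1-r^2}$ on $n-2$ df. Pearson (rather
than Spearman) is the default because the downstream machinery — q-values on
t p-values, linear models, probit-transformed scores — assumes it; Spearman
is available via `method = "spearman"`. SPPR enters on its raw scale;
`log_sppr = TRUE` switches to the log scale. Genes with zero expression
variance have no defined correlation: they are excluded from the q-value
input and reported as `NA` rather than being assigned $r = 0$.

FDR is controlled with Storey q-values (`estimateQvalues()`):
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on the grid
$\lambda \in \{0.05, \dots, 0.95\}$, smoothed with a cubic smoothing spline
(3 df) and evaluated at the largest $\lambda$, clipped to $(0,1]$; then
$q_{(i)} = \min_{j\ge i} \hat\pi_0\, m\, p_{(j)}/j$, capped at 1. Gene
selection (`selectSignificant()`) thresholds $|r|$ (default 0.8) and reports
the achieved FDR as the largest q among the selected genes. The
single-sample sensitivity check (`exclusionSensitivity()`) recomputes all
correlations without one cultivation and reports the change in the count of
genes above the cut — the screen used to decide whether an outlying
cultivation should be retained.

Differential expression between conditions uses a moderated per-gene linear
model: the pooled within-group variance $s^2$ (on $d$ df) is shrunk towards
a prior $s_0^2$ with prior df $d_0$, both estimated across genes by the
method of moments under a scaled inverse chi-square prior (marginally,
$s^2/s_0^2 \sim F(d, d_0)$, so $d_0$ and $s_0^2$ solve the sample mean and
variance of $s^2$). The moderated t is referred to $d + d_0$ df,
Benjamini–Hochberg adjusted per contrast, and a gene is called at
`p_adj < 0.05` and `|log2FC| > 0.5`. This reproduces the intent of the
standard moderated-t tools without depending on their internals; the test
suite cross-checks fold changes and rankings against limma.

# Chromosomal structure

`adjacentQualifyingPairs()` finds chromosomally consecutive gene pairs with
both $|r|$ above a cut (default 0.7) and equal sign; adjacency never crosses
scaffold boundaries. The permutation test keeps gene positions fixed and
shuffles the correlation values over positions (scaffold gene counts are
preserved by construction); the statistic is the number of genes in at least
one qualifying pair, per sign (a pair-count statistic is available), and the
empirical p uses the add-one estimator $(1 + \#\{perm \ge obs\})/(1 +
n_{perm})$ so p is never zero.

`detectClusters()` seeds a cluster with three consecutive genes all above
the cut with equal sign, then extends over flanking genes while the *sign*
of their correlation matches — a literal reading of extension "until the
direction of correlation changes". Extension therefore imposes no magnitude
requirement by default; `extend_r_cut` restores one. Genes with $r$ exactly
0 (or missing) terminate extension and never seed. Promoter-sharing
potential requires divergent transcription — upstream gene on the minus
strand, downstream on the plus strand — and the separation is measured
between the annotated transcription start positions (for a minus-strand
gene, its end coordinate); the default gap cut is 1000 bases.

Cluster conservation in other genomes slides windows of 16 (step 2) or 30
(step 5) consecutive genes along each scaffold, compares InterPro domain
content as *sets* (duplicates count once), and by default requires all the
cluster's distinct domains in a window — the strictest reading of domain
"overlap". `min_shared` relaxes this, since partial (four-of-five-gene)
conservation is biologically meaningful. Because a domain match can come
from an unrelated family, `verifyHomology()` confirms a match only when
every shared domain is carried by a window gene sharing an orthology group
with a query-cluster gene.

# Metabolic network

The bipartite network (genes ↔ metabolites) is transferred across species by
bidirectional best blastp hits: each gene must be the other's unique best
hit, with bit score above 50 in *either* direction (the literal reading of
the rule; a strict both-directions mode is a flag). Ties for a best hit are
skipped with a warning, which keeps the mapping an injective partial
matching.

Reporter metabolites score each metabolite by its neighbouring genes'
one-sided correlation p-values:
$Z_{raw} = \sum_{i} \Phi^{-1}(1-p_i)/\sqrt{k}$ over the $k$ adjacent genes,
corrected by the mean and SD of the same statistic over `n_background`
(default 1000) random size-$k$ gene draws, with $p = 1 - \Phi(Z_{corr})$.
Metabolites pass at $p < 0.05$ with more than one adjacent gene. The
analysis runs once per tail (H1: $r > 0$ and H1: $r < 0$), matching a search
for the highest correlations of either sign. P-values are clamped to
$[10^{-15}, 1-10^{-15}]$ before the probit so scores stay finite.

Path detection projects the network onto genes (edge when two genes share a
metabolite; edge weight the product of the two genes' bidirectional-hit
score products, rescaled by the maximum to $(0,1]$) and searches for the
maximum-score simple path of each length $k = 3..12$ by color coding:
random $k$-colorings plus dynamic programming over colorful paths (exact
over the colored instance; a path is found with probability
$\ge 1-\delta$ once the number of colorings reaches $\ln(1/\delta)e^k$,
the package default with $\delta = 0.05$). The path score is the sum of
probit-transformed node p-values; the edge term
$\lambda \sum \ln w_e$ is available but defaults to $\lambda = 0$ because no
mixing rule between node and edge evidence is established — the edge weights
still shape the graph through the projection. Significance comes from
shuffling node weights over nodes (and edge weights over edges when
$\lambda \neq 0$), recomputing the best score per shuffle (default 10,000
shuffles), add-one empirical p, cut 0.025; significant paths with
overlapping gene sets are merged by union, the simplest resolution of
"overlapping paths combined". The dynamic program is implemented in C++
(`src/colorcoding.cpp`) since the shuffle null multiplies its cost by the
shuffle count.

# Transcript–protein integration

Pairs of protein and transcript log2 fold changes are classified with two
cut-offs: 0.6 log2 (1.5-fold) marks differential expression and 0.3 log2
(1.2-fold) marks "not differentially expressed". Q1–Q4 are the concordant
and discordant quadrants; T0/T-0 are protein-changed, transcript-flat
classes. A pair whose transcript sits between 0.3 and 0.6 alongside a
changed protein is deliberately `unclassified`: the flat classes require the
transcript to clear the stricter "not changed" bar. The translational
control efficiency ratio is
$\mathrm{TCEr} = 2^{(\Delta_{protein} - \Delta_{transcript})}$ — the linear
fold-change ratio — flagged beyond 3 and 1/3, and inverts exactly under
swapping the comparison direction. Protein spots are classified
independently even when several isoforms map to one gene, since isoform
abundance can move independently.

# Cross-platform calibration and enrichment

Three nested OLS models relate microarray to affinity-capture (TRAC)
signals: shared intercept and slope (m0), gene-specific intercepts with a
shared slope (m1), gene-specific slopes (m2). Comparison uses the
least-squares AIC, $n\ln(RSS/n) + 2 n_{par}$, with the same constant
convention across models; ties go to fewer parameters. Intercepts are fixed
effects — the mixed-model variant would alter the likelihood but not the
selection logic at these sizes. Enrichment uses one-sided
over-representation p from the hypergeometric tail (computational
annotations) or Fisher's exact test (manual annotations); for a 2×2 table
the two coincide, which the tests check to 10 significant digits. Raw
p-values are thresholded at 0.05 without multiplicity adjustment, matching
the convention of the tables this reproduces; `adjust = TRUE` adds BH.
"% of expressed" is the category's share of the query set and
"% of annotated" the query set's share of the category — the interpretation
consistent with the magnitudes in the published tables, exposed as such.

# Synthetic data: what it emulates, and what not

The generator reproduces the study design: 9 samples, triplicate chemostats
in three conditions (growth rate 0.03 h$^{-1}$ low density, 0.06 h$^{-1}$
low density, 0.03 h$^{-1}$ high density with 4× feed substrate). Default
SPPR values (3.0, 2.6, 3.4; 1.5, 1.4, 1.6; 0.8, 0.7, 0.9 mg/g/h) follow the
observed ordering — highest at the low growth rate, lowest at high density —
at magnitudes realistic for lactose-limited chemostats of a hypersecreting
strain; the spread within the first condition mimics the one outlying
cultivation. Default genome: 10 scaffolds × 100 genes; gene lengths
log-normal around 1.3 kb; GC% drawn per gene from taxonomy-class means
(58/58/55.5, SD 3) — GC is a number, not a sequence property, because the
gene-characteristic statistics need nothing more. Planted structure: 50 + 50
genes at target correlation ±0.9 (slope chosen as
$b = \rho\sigma/(sd(x)\sqrt{1-\rho^2})$ so the expected Pearson correlation
equals the target), three adjacent-gene clusters (5+, 4+, 3−), expression
noise Gaussian on the log2 scale with SD 0.25 — Gaussian because the
analyses assume post-normalisation log-scale data. The network generator
plants a metabolite chain through a chosen gene path and wires planted
reporter metabolites to genes of one correlation tail; calibration signals
are generated from the m1 model itself.

Not emulated: probe-level microarray structure, normalisation artefacts,
expression-level-dependent variance, correlated noise between adjacent
genes, gel-image or spot-quantification noise, and real genome gene-order
statistics. Passing tests therefore demonstrate that the *methods* recover
planted truth under their own assumptions, not that those assumptions hold
for any particular real data set.

# Numerical choices and degenerate inputs

* P-values are clamped away from 0 and 1 before probit transforms.
* Degenerate reporter backgrounds (all pooled scores equal) give corrected
  score 0 rather than 0/0.
* With a single gene, m1 and m2 collapse to m0 and m0 wins the AIC tie.
* Empirical p-values always use add-one estimators.
* The variance-prior moment estimator falls back to complete shrinkage
  ($d_0 = \infty$) when the across-gene variance of $s^2$ is at or below
  its sampling floor.
* All generators and analyses are deterministic given their seed; the
  pipeline derives all stage seeds from one configuration seed.

# Problem sizes in the test suite

The suite exercises the pipeline at sizes chosen to make Monte-Carlo
tolerances tight while keeping a full run in minutes: 1000-gene genomes
with 20 replicate seeds for FDR calibration, exact enumeration of all 720
assignments for the 6-gene permutation oracle, 20 ten-node graphs against
exhaustive path enumeration, 150–200 replicates for shuffle-null
calibration, and 50 replicates for calibration-parameter recovery. The
shuffle count for path significance defaults to 10,000 in the pipeline but
tests run at 400–500 with correspondingly widened tolerances.

# Known limitations

* The color-coding search cost grows as $2^k$ per coloring and $e^k$ in the
  coloring count; lengths beyond ~8 on large graphs need patience or a
  smaller `n_colorings` with a correspondingly weaker guarantee.
* The shuffle null for paths conditions on topology; it does not model
  uncertainty in the network reconstruction itself.
* The moment-based variance prior is coarser than profile-likelihood
  estimation; with few genes the prior df estimate is noisy (the moderated
  and unmoderated calls then differ little).
* The permutation scheme shuffles correlation values genome-wide; if gene
  density varies systematically between scaffolds in ways correlated with
  expression, a stratified scheme would be preferable.
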