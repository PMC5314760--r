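---
title: "Methods: comparing epigenetic and genetic cancer alterations on a signaling-domain interactome"
author: "sigdomnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing epigenetic and genetic cancer alterations on a signaling-domain interactome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific question

Tumors accumulate somatic mutations, copy-number alterations (SCNAs) and
DNA-methylation (DNAm) changes, and all three can drive expression
changes. `sigdomnet` implements a systems-level comparison of these
alteration classes: do *functional* DNAm alterations (methylation
changes accompanied by the opposite expression change) occupy different
positions in the protein-interaction network, and different layers of
the cell's signaling hierarchy, than functional SCNAs and frequent
mutations?

The workflow has five computational layers:

1. **Preprocessing** — probe filtering/imputation for 450k-style beta
   matrices, expression normalization, promoter-level methylation.
2. **Driver calling** — moderated-t differential statistics, the
   HyperM/HypoM classification, integrative ranking, a multivariate
   regression gate, a copy-number call matrix with joint
   SCNA-plus-expression rankings, and mutation-frequency ranking.
3. **Interactome** — signaling-domain annotation, hierarchy pruning,
   degree and shortest-path comparisons between alteration classes.
4. **Enrichment and meta-analysis** — domain enrichment per class,
   pathway-level differential-domain tests, Fisher's combined
   meta-analysis across cancer types.
5. **Co-expression consistency** — deregulation categories across
   cancer types, a permutation consistency test, and tumor-only
   correlation with epigenetic-enzyme expression.

A sixth module, the synthetic-data generator, produces matched
multi-omic cohorts and annotated interactomes with planted ground truth
so that every layer can be verified end to end.

# Preprocessing

**Beta cleaning.** Probes with missing values in more than 30% of
samples (`max_na_fraction = 0.3`) are removed. Remaining missing
entries are imputed by the mean of the `k = 5` nearest probes. The
imputation is *probe-wise*: probes are points, samples are coordinates,
and distances are mean squared differences over pairwise-complete
samples (so probes with different missingness patterns remain
comparable). Only probes observed at the target sample are eligible
neighbors; when fewer than `k` exist, all available are used with a
warning. The operation is idempotent. Probe-wise (rather than
sample-wise) imputation was chosen because nearest-neighbor structure
is far stronger across CpGs of the same locus class than across
patients; the direction is switchable by transposing the input.

**Expression normalization.** Zeros are replaced by the dataset-wide
minimum positive value (so `log2` is finite and the floor is
data-driven rather than an arbitrary pseudo-count), values are
log2-transformed, and columns are quantile normalized
(`limma::normalizeQuantiles`, tie values receiving the mean of the
quantile targets they span).

**Promoter methylation.** A gene's methylation is the mean beta of its
TSS200 probes; if none exist, of its first-exon probes; if none, of its
TSS1500 probes. Gene-body probes never contribute, and genes with only
body probes are absent from the output. The output is therefore always
a convex combination of probe values, and adding body probes can never
change a gene's row.

# Driver calling

**Moderated t.** Per-gene two-sample t-statistics with an empirical
Bayes variance: the posterior variance is
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ with
$(d_0, s_0^2)$ fitted by method of moments to the observed pooled
variances, using the fact that marginally
$s_g^2 \sim s_0^2 F_{d_g, d_0}$ under a scaled inverse-chi-square
prior. Matching the squared coefficient of variation $r$ of the
observed $s_g^2$ gives
$d_0 = (4 r d_g + 2 d_g - 4)/(r d_g - 2)$, which lies in $(4, \infty)$
whenever the observed dispersion exceeds the pure chi-square value
$2/d_g$; when it does not, the prior weight is effectively infinite
and the fit collapses to full pooling (implemented as $d_0 = 10^6$).
P-values use a t distribution on $d_g + d_0$ degrees of freedom.
Setting `d0 = 0` recovers the ordinary two-sample t exactly, which the
tests exploit as an oracle; the estimated fit is cross-checked against
`limma::eBayes` (whose `fitFDist` estimator differs slightly — the two
agree to correlation above 0.999 on simulated data but are not
identical, which is why the package carries its own implementation
with an explicit, controllable prior).

**Significance and classification.** A gene is called when
methylation FDR < 0.05 *and* |Δβ| > 0.1 *and* expression FDR < 0.05
*and* |log2FC| > 1 (FDR by Benjamini–Hochberg within each data type).
Genes whose two t-statistics share a sign are discarded — only
anti-correlated promoter-methylation/expression pairs are candidate
epigenetic drivers. HyperM means methylation up, expression down;
HypoM the mirror image. Within each class genes are ranked by
$S = (|t_{meth}| + |t_{expr}|)/2$, non-increasing, ties broken by
larger $|t_{expr}|$ then gene identifier. $S$ was chosen because it is
symmetric in the two evidence streams and monotone in each; any
strictly monotone combination gives the same top-k behavior in the
planted-signal regime the generator produces.

**Multivariate gate.** Expression is regressed on promoter methylation
and numeric copy-number state ({−2,…,2}, normals 0) over *all* samples.
Methylation-driven lists keep genes with a negative, significant
(p < 0.05) methylation coefficient; copy-number lists keep genes with
a positive, significant CNV coefficient. A constant covariate of
interest is a degenerate design: the gene is dropped with a warning. A
constant *nuisance* covariate is simply omitted — a gene with no
copy-number variation can still be methylation-driven. The p < 0.05
cut is ordinary least squares with no robustness modification; the
gate is a confounding filter, not an inference claim.

**Copy-number calling.** Per sample, the center $m$ is the
probe-weighted median of segment log2 ratios and the noise scale
$\sigma$ is the standard deviation of the 50% of (probe-weighted)
segment values nearest $m$ — the "noise half", which a genuine CNA
cannot contaminate. Gains/losses are beyond $m \pm 2\sigma$,
amplifications/deletions beyond $m \pm 4\sigma$ (strict inequalities).
Per (sample, gene), all overlapping segments (1-based inclusive
intervals, any ≥ 1 bp intersection) vote; the maximal-severity state
wins (Neutral < Gain/Loss < Amplification/Deletion) and severity ties
between gain-type and loss-type states go to the larger |segmented
mean|. $\sigma = 0$ collapses every call to Neutral, with a warning.

**Joint SCNA rankings.** Per gene, a Gaussian is fitted by maximum
likelihood to the log2 expression over the cohort's tumor samples;
values beyond $\hat\mu \pm 1.6449\,\hat\sigma$ (the 5% tails) are
flagged over-/underexpressed. The Amplification list ranks genes by
the number of samples that are simultaneously amplified and
overexpressed; Deletion mirrors it; both then pass the multivariate
gate with the CNV coefficient. Mutation ranking counts distinct
samples with at least one non-silent record.

# Interactome

**Domains.** Genes are mapped to coarse signaling domains from
cellular-localization terms by case-insensitive substring matching
against three keyword lists (intracellular, membrane-receptor,
extracellular); the shipped lists are the package defaults in
`default_domain_keywords()`. Multi-domain genes resolve by hierarchy:
any extracellular evidence gives EC (this covers EC+MR, EC+IC and
EC+MR+IC); otherwise MR+IC gives IC; otherwise the single match
stands. EC evidence dominating is deliberate: extracellular
annotations are rarer and more specific than the ubiquitous
intracellular terms. Fine classes then follow from membrane-receptor
adjacency in the network: EC genes touching an MR are secreted factors
(SF), otherwise growth modulators (GM); IC genes touching an MR are
receptor substrates (ICRS), otherwise non-receptor substrates (ICNRS).

**Pruning.** After dropping self-loops and duplicates and taking the
largest connected component, edges whose endpoint pair is not one of
EC-EC, EC-MR, MR-IC, IC-IC are removed (MR-MR and EC-IC in
particular), and the largest component is extracted *again* — pruning
can disconnect the graph, and downstream shortest-path analysis
requires connectivity, so prune-then-re-extract is the only order that
satisfies both the edge contract and the connectivity contract.

**Topology comparisons.** The top-100 genes of each class are mapped
onto the pruned network (absences are counted and dropped, never
imputed). Degree distributions are compared pairwise by one-tailed
Mann–Whitney rank-sum tests — `p_matrix[row, col]` tests whether the
column class has smaller degrees — plus a pooled DNAm
(HyperM + HypoM) versus CNV (Amplification + Deletion) comparison.
Within-class inter-connectivity uses all pairwise unweighted
shortest-path lengths, compared along the hierarchy HyperM > HypoM >
Mutation > Amplification > Deletion (each earlier class tested for
*longer* paths). The distance vectors of two classes have unequal
lengths, so no pairing between them exists and the unpaired
Mann–Whitney test is the coherent choice. Classes with fewer than
`min_genes = 5` mapped members give a missing p with a warning. Ties
are ubiquitous with integer degrees, so the normal approximation is
used whenever R's exact path is unavailable; the tie warning is
muted deliberately.

# Enrichment and meta-analysis

Each class's 2×2 table is (in list vs rest of annotated network) ×
(EC+MR vs IC). One-tailed Fisher's exact tests run in the direction
the biology under test predicts: EC+MR *enrichment* for the
methylation classes and mutations, EC+MR *depletion* for the
copy-number classes. The odds ratio is the sample cross-product
$ad/bc$ (reported NA for 0/0), not the conditional MLE. The background
is the full annotated network; a pathway-restricted background is a
one-line switch. The *equalized* mode truncates all five lists to the
shortest one before testing, removing list-size artifacts.

Pathway-level tests restrict to pathway members with an EC or IC
two-domain label (genes whose only annotation is membrane-receptor
carry no two-domain label and are excluded). The differential test
compares methylation-altered against SCNA-altered pathway genes over
EC/IC, one-tailed for methylation excess in EC; the within-pathway
variant compares altered against unaltered pathway genes. Degenerate
tables (no altered genes, single-domain pathways) give p = 1 by
convention and are flagged, so Fisher's combined test skips nothing
silently. The meta-analysis statistic is $X = -2\sum_i \ln p_i$
against a chi-square with $2k$ degrees of freedom; missing cancer
types reduce $k$, and p = 0 inputs are clamped to the smallest
positive double with a warning. Raw meta p-values are reported with a
0.05 working cutoff; a Benjamini–Hochberg-adjusted column is emitted
alongside, clearly labeled as an extension.

**A calibration caveat worth stating plainly.** The exact conditional
Fisher test is discrete and conservative: at nominal 0.05 its attained
per-table level is roughly 0.005–0.015 for the table sizes this
workflow produces, and $E[-2\ln p] \approx 1.4$–1.6 rather than 2.
Fisher's combined statistic inherits and *compounds* this deficit, so
under a global null the fraction of pathways reaching meta p < 0.05 is
near zero, not near 0.05. The acceptance suite measures this fraction
and documents it; rankings and planted-signal detection are unaffected
(the planted pathway still attains the best meta p in ≥ 18/20
replicates), but absolute meta p-values should be read as
conservative.

# Co-expression consistency

Per cancer type, every gene is HyperM_F (significant hypermethylation
with significant underexpression, at the driver thresholds), HyperM_NF
(hypermethylation only), HypoM_F, HypoM_NF, or NC. The cross-type
consistency statistic is the mean, over type pairs, of the fraction of
genes with identical category; the null permutes gene labels
independently within each type, preserving per-type category
frequencies, with $p = (1 + \#\{perm \ge obs\})/(n_{perm}+1)$. Columns
are put in canonical (sorted) order before permuting so the result
cannot depend on how the types were supplied. When no permutation
reaches the observed value the reported p is the attainable floor and
is flagged as such.

Enzyme co-expression uses tumor samples only: Pearson r and two-sided
p per (target, enzyme, cancer type). A target is labeled *positive*
for an enzyme when r > 0 with p < 0.05 in at least half of the types
with data and no type shows a significant negative correlation
(*negative* mirrored; otherwise *none*). The paper-style phrase
"significantly consistent" is not a defined statistic anywhere, so
this majority-with-no-contradiction rule is the package's
operationalization; both the majority fraction and the per-type
threshold are arguments. Correlation p-values are raw and two-sided.

# The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with planted, exportable ground truth:

* **Interactome** — label-aware preferential attachment: each new node
  draws a fine domain from `domain_fractions` (defaults GM 0.1, SF
  0.1, MR 0.2, ICRS 0.3, ICNRS 0.3, i.e. 40% EC+MR background) and
  attaches `m = 3` edges to existing nodes with probability
  proportional to $(degree+1)^{power}$ *among hierarchy-compatible
  nodes*, falling back to all nodes only when no compatible target
  exists (so degenerate label mixes, e.g. all-MR, still produce a
  connected graph whose edges all violate the hierarchy — exactly what
  a pruning test needs). The graph is connected by construction.
* **Methylation** — logit-normal beta values (bounded support,
  realistic heteroscedastic dispersion; logit-scale s.d. 0.5) around
  per-gene promoter baselines; planted HyperM genes gain
  `delta_beta = 0.3` in tumors (HypoM mirrored), with baselines drawn
  so the shift stays inside [0, 1] (extreme configurations clip with a
  warning). Probes carry TSS200/first-exon/TSS1500/body structure,
  including genes that exercise every fallback; body probes carry
  independent drift so that using them would corrupt promoter calls.
  Light missingness (0.5%) plus a few mostly-missing probes exercise
  the cleaning stage.
* **Expression** — Gaussian on the log2 scale (s.d. 1) around per-gene
  baselines, emitted on the raw scale so the normalizer sees realistic
  input; planted methylation classes shift by `log2fc = 2` in all
  tumors, planted copy-number classes only in the tumors carrying the
  event.
* **Copy number** — one linear pseudo-chromosome with genes tiled
  every 10 kb (1-based inclusive, the simplest geometry that
  exercises segment–gene overlap); ~21 background segments per tumor
  with log2-ratio noise s.d. 0.1, plus event segments at
  `cn_shift = 1` covering planted genes in a 40% tumor fraction.
* **Mutations** — 1% background per gene-sample with a mix of variant
  classes; planted genes add non-silent records at
  `mutation_rate = 0.15`.
* **Planting** — 60 genes per class (all five classes disjoint), with
  3:1 odds toward EC/MR for the methylation classes and toward IC for
  the copy-number classes; an optional degree bias places methylation
  drivers on low-degree and copy-number drivers on high-degree nodes,
  reproducing the topology contrast the analysis is designed to
  detect.

Defaults are the package's standard study conditions: 1000 genes,
50 normal + 50 tumor samples. Fixed seeds give byte-identical outputs,
including the written files.

What the generator does **not** emulate: Illumina type-I/type-II probe
chemistry (hence no BMIQ correction step), tumor purity and
clonality, read-count noise, germline CNVs, linkage between
neighboring genes beyond shared segments, and realistic pathway
co-membership structure. Passing tests therefore demonstrate that the
machinery recovers planted effects of the stated sizes under clean
noise models — not that the thresholds are optimal for any real
cohort.

# Problem sizes used by the test and acceptance suites

These are the package's verification conditions, chosen once:
planted-recovery runs use the full standard conditions (1000 genes,
50+50 samples, Δβ 0.3, 2-fold expression effects, degree bias 1.5);
null-calibration runs use 20 cohorts of 400 genes at 50+50 with all
effect sizes zero; moderated-t calibration uses 2000 simulated null
genes; the tail-call check uses 10 000 draws; pathway-null and
planted-pathway checks use a 2000-gene universe with 20–40 pathways of
100–200 genes over 5–10 synthetic cancer types, 20 replicates; oracle
checks use 1000 random call-matrix instances, 1000 random 2×2 tables
with margins ≤ 30, 200 random graphs of ≤ 50 nodes, and a closed-form
grid for the combined test.

# Known limitations

* The exact-test conservativeness described above: absolute pathway
  meta p-values run well below nominal under the null.
* The integrative ranking statistic $S$ is one reasonable choice among
  monotone combinations; rank orders near the tail of a list can
  differ under other choices.
* The interactome is undirected and unweighted; directionality of
  signaling is only encoded through the domain-hierarchy edge filter.
* Gene-level methylation ignores probe-level heterogeneity within a
  region class; a single aberrant TSS200 probe moves the gene mean.
* The multivariate gate is ordinary least squares; heavy-tailed
  expression outliers can flip marginal coefficients.
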