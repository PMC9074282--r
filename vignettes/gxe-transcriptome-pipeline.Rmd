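---
title: "Dissecting genotype-by-environment interaction in expression: models and methods"
author: "gxetrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting genotype-by-environment interaction in expression: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxetrans)
```

## The scientific setting

Panels of fully inbred, sequenced lines — the *Drosophila melanogaster*
Genetic Reference Panel (DGRP) being the canonical example — allow many
genetically identical individuals to be reared under controlled
environments. Rearing each line under a developmental exposure (here,
ethanol-supplemented medium) and under control conditions, with both sexes
and replicate RNA-seq samples per cell, turns the transcriptome into a
quantitative-genetic experiment: for every transcript one can ask how much
expression variation is genetic, how much is sex- or treatment-dependent,
and — the quantity of central interest — whether the *response* to the
exposure itself varies genetically (a line-by-treatment, L×T, interaction).

`gxetrans` implements that analysis end to end: normalization, factorial
variance partitioning with broad-sense heritability, per-line
delta-expression and its correlation networks, response-eQTL mapping with a
permutation-based empirical FDR and forward conditional selection,
integration with known-interaction databases and GO overrepresentation, and
an activity/sleep behavioural read-out from Drosophila Activity Monitor
(DAM) files. A synthetic-data generator with complete ground truth makes
every stage testable by parameter recovery.

## The factorial model and its F tests

Per transcript, the full model on log2 normalized expression is

Y = S + W + T + L + W×S + L×S + L×T + T×S + T×S×L + ε,

with sex S, treatment T and Wolbachia infection status W fixed, and line L
and all its interactions random. The per-sex reduced model is
Y = W + L + T + L×T + ε, and the per-condition model Y = W + L + ε.

The design is balanced (every line × sex × treatment cell has the same
number of replicates; the fits refuse unbalanced input), so sequential sums
of squares equal the Type III decomposition and every term has a
closed-form expected mean square. F tests follow the expected-mean-squares
ladder for the balanced mixed factorial:

* L, L×S and L×T are tested over the T×S×L mean square;
* T×S×L over the residual;
* fixed S, T and T×S over their interaction-with-line mean squares
  (L×S, L×T and T×S×L respectively);
* W and W×S over the residual.

We use closed-form method-of-moments estimation rather than REML because
for balanced data it is exact, fast enough to vectorise across tens of
thousands of transcripts through a single QR factorisation of the shared
design matrix, and checkable against a brute-force hat-matrix oracle — the
test suite verifies every SS, F and p against explicit cumulative
projection matrices to 1e-8 relative error.

Wolbachia is a line-level covariate and therefore confounded with line: it
is entered before the line terms, so its one degree of freedom (and its
W×S interaction) is absorbed first and the line terms are adjusted for it.
When the panel is entirely infected or uninfected the W terms drop out with
zero df.

### Variance components and heritability

With r replicates, 2 sexes, 2 treatments and the mean squares MS_·,
method-of-moments gives

* σ²_ε = MS_resid
* σ²_TSL = (MS_TSL − MS_resid) / r
* σ²_TL = (MS_TL − MS_TSL) / 2r, σ²_SL analogous
* σ²_L = (MS_L − MS_SL − MS_TL + MS_TSL) / 4r,

each truncated at zero (a negative moment estimate is sampling noise; the
truncation keeps H² in [0, 1] and is the only source of bias, measurably
small at 96 lines). Broad-sense heritability is

H² = (σ²_L + σ²_SL + σ²_TL + σ²_STL) / (σ²_L + σ²_SL + σ²_TL + σ²_STL + σ²_ε),

defined as 0 when every component is 0. This is the only reading of the
ratio that is bounded in [0, 1]; the variance components named are exactly
the line-associated ones, so H² is the fraction of within-sex,
within-treatment phenotypic variance attributable to genetic differences
among lines.

Multiple testing is controlled per model term across transcripts with
Benjamini–Hochberg adjustment (`bh_fdr()`, a validating wrapper over
`stats::p.adjust`); each term is its own correction family.

### Normalization

`normalize_counts()` reimplements TMM (trimmed mean of M-values):
reference sample = the one whose upper-quartile count fraction is closest
to the mean; genewise log-ratios trimmed 30% on M and 5% on A by rank;
inverse-variance weighted mean with the binomial delta-method weights;
factors rescaled to geometric mean one; output is log2(CPM + 0.5). The test
suite checks a two-sample toy against a hand computation and the factors
against `edgeR::calcNormFactors` on clean data. The pseudocount of 0.5 on
the CPM scale bounds the log for zero counts; its exact value only shifts
low-expression transcripts and cancels in delta-expression differences.

## Delta-expression and correlation networks

For the transcripts with a significant L×T term (per sex), delta-expression
is the per-line difference of condition means, ethanol minus control
(`Line.ETOH − Line.Baseline`). Under the model its between-line variance is
2σ²_TL + 2σ²_ε/r (verified by simulation in the tests), so it isolates the
genetically variable part of the response.

`correlation_network()` computes all pairwise Pearson correlations across
lines, with two-sided p-values from the t transform
t = r√((n−2)/(1−r²)) — the alternative (permutation p-values) is
computationally heavier and, at 50+ lines, practically identical for the
edge set retained downstream. Edges pass the dual filter
(`filter_edges()`): BH-FDR q < 0.05 **and** |r| at or above the 90th
percentile of |r| over *all* pairs (type-7 quantile; boundary ties all
retained). The quantile is computed over all pairs, not only significant
ones — the decile is a property of the whole correlation landscape, not of
the significant subset. Note a
scale coupling worth knowing: the decile budget grows with the square of
the transcript count, so when the analyte set is small relative to the
module structure, the decile can exceed the number of truly correlated
pairs and admit weak bridges. The bundled recovery checks therefore plant
three 10-transcript modules among 50 transcripts at 50 lines, where the
decile (122 pairs) sits inside the 135 true within-module pairs — the
regime the filter is designed for, in which module edges dominate the
retained decile.

`bicluster()` agglomerates the correlation matrix with complete linkage on
d = 1 − r; the same leaf order serves rows and columns of the symmetric
matrix.

### MCODE

Modules are extracted with a reimplementation of the MCODE
(molecular-complex-detection) algorithm. The vertex weight of v is
k × density of the highest k-core of its closed neighborhood; seeds are
taken in decreasing weight, each growing by breadth-first expansion to
unvisited neighbors with weight ≥ seed weight × (1 − vwp), vwp = 0.2.
"Fluff" (on by default) appends peripheral
neighbors whose closed-neighborhood density exceeds 0.1 without marking
them visited; "haircut" is off. The module score is density × size of the
grown core (fluff does not change the score), and modules with cumulative
score > 4 are retained. Two readings of "cumulative score" are possible —
per-module score, or a sum over sub-seeds; we implement the per-module
reading, which is the quantity Cytoscape's implementation reports per
cluster. Scoring before fluff keeps the retention rule independent of the
fluff density parameter.

## Response-eQTL mapping

The phenotype is covariate-adjusted delta-expression, one value per line.
Adjustment (`adjust_covariates()`) is fixed-effect residualization on
Wolbachia status, caller-supplied inversion indicators and top genotype
principal components: with one observation per line, best-linear-unbiased
prediction with these line-level covariates reduces to linear adjustment.
Genotype PCs (`genotype_pca()`, deterministic sign convention) guard
against population structure in real panels; in the package's own synthetic
panels there is none — the simulator draws variants independently — so the
bundled recovery benchmarks adjust for Wolbachia only, since structureless
PCs merely project planted signal out of the phenotype.

`eqtl_scan()` regresses the phenotype on genotype dosage per variant
(homozygous 0/2 calls halved to 0/1, so the slope is the effect of the
full substitution), skipping variants with fewer than 3 lines in a
genotype class. Significance is assessed against a permutation-based
empirical FDR (`permutation_fdr()`): line labels of the phenotype are
shuffled jointly across variants (preserving LD) 100 times; for candidate
thresholds at the observed p-values, empirical FDR(t) = mean permutation
count at or below t divided by the observed count; the threshold is the
largest t with empirical FDR ≤ 0.05, and 0 (no discoveries) when none
qualifies. Thresholds are per transcript; the number of permutations trades
resolution of the null tail against runtime and 100 matches the source
procedure.

Discoveries are pruned to independent signals by forward conditional
selection (`forward_select()`): candidates enter in order of marginal
p-value (ties by variant id) and are kept iff their conditional p-value in
the growing additive model is ≤ 1e-5; exact duplicates of kept genotype
columns are skipped. Selected variants are labelled *cis* to a gene when
they lie within 1,000 bp of the gene body (1-based inclusive: position in
[start − 1000, end + 1000] on the same chromosome) and *trans* otherwise;
`annotate_cis_genes()` lists every gene a variant is cis to, with an empty
list reported as intergenic.

## Interaction-network integration and GO overrepresentation

`build_network()` unions one eQTL-association edge per (L×T gene, cis
gene) pair with a known-interaction edge list (genetic / physical, typed
parallel edges retained, deduplicated per unordered pair and type).
`filter_network()` keeps all eQTL-association genes plus known interactors
with at least 5 *distinct* eQTL-gene neighbors one edge away (parallel
typed edges count once; the distinct-neighbor reading of the rule is
asserted per retained node in the tests, and the filter is idempotent).
`modularize()` runs MCODE on the simple-graph projection, and
`go_enrichment()` tests each module for term overrepresentation with the
one-sided hypergeometric tail against the background universe (annotation
genes ∩ background; terms with < 2 universe genes skipped), BH-corrected
across terms within a module.

## Activity and sleep phenotyping

`parse_dam()` reads TriKinetics-style monitor files (42 tab-separated
columns: index, date, time, status fields, then 32 channel counts),
rejecting malformed rows, non-contiguous or duplicated minutes and negative
counts with specific messages. Sleep is at least 5 consecutive minutes
without beam crossings (`call_sleep()`); day is the 12 h after lights-on
(06:00 by default, configurable). Per fly and phase: sleep proportion =
sleeping minutes / 720 averaged over whole days; bout count averaged over
days; activity = total counts per day. A bout spanning the day/night
boundary is split at the boundary and each fragment counts as a bout in its
phase — the 5-minute criterion was met by the whole bout, so fragments are
not re-thresholded. This choice (flagged prominently because it changes
bout counts) keeps day + night sleep minutes equal to total sleep minutes.

`survival_filter()` restricts analysis to lifespan days 2–9 (recording is
assumed to start on day 2; offset configurable) and drops flies whose
counts end in a terminal zero run of ≥ 24 h beginning inside the window —
the monitor-data convention for a death call, since monitors keep recording
dead channels as zeros. The threshold is configurable; 24 h cleanly
separates death from even extreme sleep under realistic activity
parameters.

`sleep_anova()` fits, per phenotype, the balanced factorial
Y = μ + T + L + S + T×L + T×S + L×S + T×L×S + Rep(T×L×S) + ε with
replicate-within-cell random: fixed effects are tested over the Rep mean
square and Rep over the residual (flies within replicate), using the same
QR engine and EMS logic as the expression models; a per-sex reduced model
Y = μ + T + L + T×L + Rep(T×L) + ε is available. Because the engine
requires balance, `rebalance_phenotypes()` trims each cell to its minimum
fly count after the survival filter.

## The synthetic-data generator

`simulate_expression()` draws the factorial model directly on the log2
scale — baseline U(3, 9), fixed sex/treatment/Wolbachia shifts, independent
Gaussian line-level draws for each random term, i.i.d. residuals — so the
variance-component ground truth is exact on the modelled scale; a
count-scale export (2^Y, rounded, with a library-size multiplier) exercises
normalization. Only a configurable fraction of transcripts gets nonzero
L×T variance, giving labelled null and alternative sets. Wolbachia is a
line-level binary with an additive shift, matching its nuisance role.
`plant_eqtls()` adds β × dosage to ethanol-condition samples only, so the
delta-expression carries the genetic signal; `plant_modules()` adds a
loading times a shared per-line latent factor to ethanol samples of the
member transcripts, inducing positive delta correlation within modules.
`simulate_genotypes()` draws independent biallelic variants (0/2, MAF
uniform in range, positions uniform over a genome) — deliberately without
linkage disequilibrium, so eQTL recovery tests are not confounded by LD.
`simulate_dam()` uses a two-state Markov chain per fly (mean sleep-bout
length and phase-dependent stationary activity set the transitions; awake
minutes emit 1 + Poisson(1) crossings), with deaths landing at least a day
before recording ends so the 24 h rule can always see them.

What the generator does **not** emulate — count overdispersion and
mean-variance coupling, LD structure, shared factors between sexes beyond
the planted ones, circadian activity shape beyond the 12:12 square wave —
bounds what passing tests show: recovery and calibration hold under the
model's own assumptions, not necessarily under every pathology of real
data. Residuals are assumed Gaussian on the log2 scale; this is an
assumption of the simulator, not an assertion about any real dataset.

## Numerical choices and degenerate inputs

* All per-transcript sums of squares come from one QR factorisation of the
  shared design matrix; rank deficiencies (e.g. Wolbachia within line) are
  resolved by the QR pivot exactly as in `stats::lm`.
* A term whose SS falls below a noise floor of n·(1e-7·(1 + max|Y|))² is
  treated as exactly zero and assigned p = 1 (the constant-transcript
  convention); a zero residual mean square with positive signal gives
  p = 0.
* Correlation p-values for |r| = 1 are set to 0; zero-variance transcripts
  are excluded from networks with a warning; networks need ≥ 3 lines.
* The top-|r| quantile is type 7 with boundary ties retained; the cut value
  is recorded on the filtered network.
* Forward selection breaks marginal-p ties lexicographically by variant id,
  making the selected set order-independent.
* Every generator and the pipeline driver take explicit seeds; the pipeline
  derives per-stage seeds from the global seed by a stage-name hash
  (`stage_seed()`), so stages are independently reproducible and a rerun
  with the same config is byte-identical.

## Problem sizes used by the bundled checks

The demo configuration (`default_config()`) runs 30 lines × 2 sexes × 2
treatments × 2 replicates over 500 transcripts, 800 variants on a compact
5 Mb two-chromosome genome (gene density comparable to a real fly genome,
so planted eQTLs have cis neighbors), three planted 10-transcript modules,
10 planted eQTLs and a 6-line DAM experiment — it completes in well under a
minute. Recovery benchmarks use 96 lines for variance components and eQTLs
(500 and 125 transcripts respectively, 400 variants) and 2,500 transcripts
for FDR calibration. These sizes were chosen so each check is sensitive to
the failure mode it guards while the whole suite stays interactive.

## Known limitations

* Balanced designs only; unbalanced data must be subsampled
  (`rebalance_phenotypes()` does this for DAM phenotypes).
* Method-of-moments components are truncated at zero, so individual
  estimates are biased upward near zero even though the untruncated
  moments are exact.
* The empirical-FDR thresholds are per transcript by default (a pooled
  variant across transcripts is not currently exposed).
* The interaction-network stage consumes a caller-supplied edge list; no
  database retrieval is performed, and curation steps (e.g. manually adding
  gene-family members to a module) are intentionally out of scope.
* MCODE here fixes one parameterization (vwp 0.2, fluff
  0.1, haircut off, score > 4); other implementations' "defaults" differ,
  which is why the parameters are recorded in every `module_set`.
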