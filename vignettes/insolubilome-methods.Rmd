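---
title: "Methods: differential protein insolubility and its downstream statistics"
author: "insolubilome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential protein insolubility and its downstream statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(insolubilome)
```

# Scope and model

`insolubilome` analyses protein-level quantification matrices from
SDS-insoluble fraction proteomics with a paired case/control design, the
design used to ask whether amyloid-beta expression drives the same
proteins into insolubility as normal aging does in *C. elegans*. The
pipeline starts at the protein quantification matrix (peak areas of
extracted ion chromatograms, as exported by DIA software); peptide-level
signal processing, protein inference and normalization are upstream and
out of scope.

The chain is:

1. **Differential insolubility.** Per-pair log2 ratios
   $d_i = \log_2(\text{case}_i) - \log_2(\text{control}_i)$ over
   biological replicate pairs; fold-change $\bar d$; two-sided paired
   $t = \bar d / (s_d / \sqrt n)$ on $n-1$ df. Multiple testing uses
   Storey q-values; a protein is called significantly increased when it
   has at least 2 unique peptides, $q < 0.01$ and $\log_2\mathrm{FC} >
   0.58$ (a 1.5-fold change). Those thresholds are the analysis defaults
   throughout.
2. **Core insoluble proteome (CIP).** Two published aging insoluble
   proteomes are intersected into an "aging core"; its intersection with
   the amyloid-driven significant set is the CIP. Both overlaps are
   assessed with the one-sided exact hypergeometric (Fisher) tail
   against an explicit universe.
3. **Over-representation.** Hypergeometric tests per gene-set term,
   Benjamini-Hochberg FDR within one namespace, and the reporting score
   `gene count x FDR`.
4. **Disease sharing.** For each protein, the number of diseases in a
   disease-to-GO-BP catalog (38 age-related diseases in 5 broad
   categories plus 12 non-age-related controls) whose term set shares at
   least one GO biological process with the protein's
   orthologue-expanded annotation profile; group comparisons by
   Kruskal-Wallis with Dunn's post hoc z tests.
5. **Biophysical scores.** Distribution comparisons (CamSol,
   Zyggregator, catGRANULE, supersaturation $\sigma_f$) between protein
   sets with the same Kruskal-Wallis/Dunn core, and the
   supersaturation fold-ratio of mean $\sigma_f$.
6. **Aging expression trends.** Per-gene Spearman correlation of
   expression with adult age over days 2-10, BH adjustment, and an
   up/down/unchanged call at p.adj < 0.05.

# Statistical choices

**Paired t degeneracies.** With only a handful of replicate pairs the
per-protein variance estimate can collapse. Identical nonzero
differences across pairs give $s_d = 0$ and an infinite t; we floor the
p-value at `1e-15` rather than propagate NaN. Identically-zero
differences mean no evidence of change: p = 1. Proteins with fewer than
two complete pairs are reported but flagged untested; zero intensities
are treated as missing because their logarithm is undefined. No
imputation is performed.

**Storey q-values.** The null proportion is estimated as
$\hat\pi_0(\lambda) = \#\{p > \lambda\}/(m(1-\lambda))$ on the grid
$\lambda = 0, 0.05, \ldots, 0.90$, smoothed with a cubic spline (3 df)
and evaluated at $\lambda = 0.90$, then clipped to $(0, 1]$. q-values
are the monotone step-up quantity $\hat\pi_0\min_{k \ge i}(m
p_{(k)}/k)$; with $\pi_0 = 1$ this is exactly Benjamini-Hochberg, which
the tests assert. A bootstrap $\pi_0$ (MSE-minimising $\lambda$) is
available behind an argument. The tuning is a convention: the grid and
smoother follow Storey & Tibshirani (2003).

**Overlap universe.** The universe for Fisher tests must be stated; the
default is a configurable reference-proteome size of 19,985 coding
genes, and every `OverlapTest` records the N it used. Whether to use
the detected proteome or the whole proteome as universe is a genuine
modelling choice; both are supported and neither is asserted as "the"
correct one, since the stronger claims of the analysis (set sizes,
fractions) do not depend on N.

**Enrichment score.** The reporting score is the product of the overlap
gene count and the FDR-corrected p-value. Taken literally this ranks
smaller values as *less* enriched, which clashes with barplot intuition;
a `neglog` display variant (`k * -log10(fdr)`) is therefore computed
alongside, and neither is asserted as the published figures' axis.

**Disease sharing.** "Shares a biological process" means exact GO term
id equality after orthologue expansion; no ontology-graph ancestor
closure is applied because the catalog is consumed as published. A worm
protein's annotation profile is the union over all of its human
orthologues (expand-all), the policy most consistent with comparing
protein sets against disease term sets; first-only is available. Dunn's
post hoc p-values are Bonferroni-corrected over all unordered pairs
(Holm available). The random "whole proteome" background (default
n = 1600) is drawn with an explicit, recorded seed.

**Spearman trends.** Midranks throughout; for $n \ge 10$ the
t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$, for $n < 10$ an
exact permutation p over all $n!$ orderings, which stays valid under
ties. A constant expression vector is classified "unchanged" ($\rho =
0$, p = 1) rather than untested: all ranks tied is evidence of no
trend. Datasets are pooled before correlation (values are assumed
pre-normalized); per-dataset analysis can be run by filtering the input
table.

**Supersaturation fold.** "Average supersaturation" is ambiguous
between the linear $\sigma_f$ scale and the log10 display scale. The
primary output is the ratio of arithmetic means on the linear scale —
a fold of averages reads most naturally there — with the geometric-mean
variant reported alongside.

# The synthetic data generator

Every stage is testable without downloads because the generators plant
known ground truth:

* `simulateQuantExperiment()` emulates the paired design: 4 biological
  replicate pairs of case vs control insoluble-fraction intensities.
  Intensities are lognormal (baseline log2 intensity
  $\mathcal N(17, 2^2)$, i.e. peak areas around $10^5$), spiked
  proteins have case intensities multiplied by $2^{\text{log2fc}}$
  before noise, and `noiseSd` (default 0.25 log2 units) is the sd of a
  per-pair case/control log2 ratio — the quantity replicate CVs are
  quoted on — implemented as per-sample noise of `noiseSd/sqrt(2)`.
  Missingness is completely at random (default 1%; protein-level DIA
  matrices after q-value sparse filtering are largely complete, and
  intensity-dependent dropout is deliberately not modelled).
  Unique-peptide counts are a unit-shifted Poisson with mean 5.5,
  matching the study system's spectral library (about 5.5 peptides per
  protein group), independent of intensity since only the >= 2 filter
  consumes them.
* `simulateAnnotationCatalog()` builds the disease catalog (38
  age-related diseases across the 5 broad categories, 12
  non-age-related), a 1-to-k (k <= 3) worm-to-human orthology map, and
  per-gene GO-BP annotations in which a planted protein subset draws
  terms from the age-related disease pools with a boosted weight, so
  that boost = 1 is an exchangeable null.
* `simulateScoreTable()` draws scores from location families (normal;
  lognormal for $\sigma_f$, shifts on log10). A planted log10 shift
  $s$ forces the linear-scale mean ratio towards $10^s$ as noise
  vanishes — the calibration case for the fold-ratio.
* `simulateExpressionSeries()` plants monotone linear trends (half up,
  half down) over days 2-10 in a configurable gene fraction.

All generators are pure functions of their parameters including the
seed, and they restore the caller's RNG state.

**What passing tests do and do not show.** The generators are
deliberately idealized: lognormal noise, MCAR missingness,
intensity-independent peptide counts, linear trends, exchangeable null
annotations. Recovery and calibration results on these inputs validate
the *statistics and plumbing* — they do not certify performance on real
insoluble-fraction data, where dropout is intensity-dependent, variance
is protein-dependent, and annotation catalogs are strongly structured.

# Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen as
the smallest sizes at which the asymptotic checks are stable: 2000
proteins with 200 spikes for recovery, 50 seeds x 250-300 proteins for
null calibration, 100 seeds for the Kruskal-Wallis type-I check,
catalogs of 400 proteins for the sharing statistic, 500 genes for
trends. Exact-arithmetic checks (hypergeometric vs enumeration,
BH vs the step-up formula, Mann-Whitney vs full enumeration) use
complete small grids (N <= 60; arms <= 6). End-to-end runs are
reproducible: `runPipeline()` writes a JSON manifest with input
checksums, thresholds and the seed, and a rerun with the same config is
byte-identical.

# Known limitations

* Identifier matching is by normalized string equality
  (`normalizeIds()`); no fuzzy matching across identifier systems.
* No GO graph propagation; annotation catalogs are taken as given.
* No peptide-level modelling, batch correction, or normalization; the
  pipeline assumes its input matrix is analysis-ready.
* The Mann-Whitney total-insoluble comparison is exact only without
  ties; complete ties fall back to the midrank normal approximation
  (and the fully degenerate case is reported as p = 1 directly).

# A minimal run

```{r example, eval = FALSE}
dir <- tempfile("insol")
cfg <- writeSyntheticInputs(dir, nProteins = 400, seed = 11)
res <- runPipeline(cfg)
unlist(res$manifest$stages)
length(res$significant)            # proteins passing the filters
res$cip$cipFraction                # CIP as a fraction of the aging core
res$share$test$p                   # sharing omnibus p
res$scores$supersaturationFold$fold
res$trends$summary
```
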