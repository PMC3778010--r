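---
title: "Proliferation expression signatures: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proliferation expression signatures: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prolifsig)
```

## The scientific question

Rapidly proliferating cells remodel their transcriptome. Given a panel of
cell lines with both expression profiles and growth measurements, every gene
can be scored by how strongly its expression tracks proliferation. Doing
this separately on a *cancer* panel and on a *non-cancerous* (lymphoblastoid)
panel exposes genes whose proliferation association is specific to cancer —
candidate selective anti-proliferative targets — and yields predictive
signatures for growth rate and patient outcome.

`prolifsig` implements that full chain: per-gene indices, a differential
index, enrichment statistics, penalized growth-rate predictors with
resampling nulls, and an expression-based survival classifier, together with
a synthetic-study generator that makes every stage testable offline.

## The proliferation index (PI)

For gene $g$ with log2 expression $x_g$ and per-sample growth rates $r$
(doubling times $d$ are first mapped to rates $r = \ln 2 / d$), the package
offers two variants:

* **Correlation PI** (default): the Spearman correlation
  $\rho(x_g, r)$, with average ranks under ties and a two-sided p-value
  from the $t$ approximation on $n-2$ degrees of freedom. Rank-based
  scoring makes the index invariant under any strictly increasing
  transform of either side — in particular, scoring against doubling times
  directly gives the exact negation of scoring against rates.
* **Slope PI**: the OLS slope of $x_g$ on $r$ (expression is the response),
  with the regression F-test p-value, then divided by the median absolute
  slope of the panel so that the median $|PI|$ is exactly 1. The
  normalization makes slope indices comparable across panels whose growth
  rates live on different scales (per-hour rates versus per-day rates).

Genes with zero expression variance get a missing index, p-value 1, and a
flag — a zero would otherwise silently enter medians and signatures.

`cPI` denotes the index on the cancer panel, `nPI` on the non-cancerous
panel. The subgroup operation (`compute_pi_groups()`) recomputes indices per
tumor type or growth-rate stratum; groups under `min_group = 4` samples are
skipped, the same rationale under which a 2-sample tumor type cannot be
scored.

## The differential index dPI

On the subset of genes with $cPI > 0$ and $nPI < 0$,

$$ dPI_g = \frac{cPI_g}{\,nPI_g - nPI_{\min} + \varepsilon\,}, $$

with $nPI_{\min}$ the minimum nPI over the *full* shared universe (not just
the subset) and $\varepsilon = 0.01$ keeping the denominator positive. The
score grows with cPI and grows as nPI becomes more negative; the gene at the
global nPI minimum has denominator exactly $\varepsilon$. Because dPI is a
combination of two measures, each gene inherits its cPI p-value; signatures
built from dPI therefore threshold those inherited p-values.

## Enrichment machinery

* `set_shift_test()` compares a set's (optionally absolute) PI values to the
  remaining genes with a two-sided Wilcoxon rank-sum test. On universes
  small enough to enumerate, the p-value is computed exactly over all
  $\binom{n}{k}$ label assignments, which stays exact under ties; otherwise
  the tie-corrected normal approximation with continuity correction is used.
  The default background *excludes* the set members; comparing members
  against a background that contains them is available via
  `include_members_in_background = TRUE`, since the inclusive reading of
  "all genes in the panel" is also defensible. The default avoids
  self-comparison.
* `run_collection()` filters sets by in-universe size with per-category
  thresholds (the convention of ignoring ontology terms under 25 genes and
  metabolic pathways under 5 maps to
  `min_size = c(default = 25, metabolic = 5)`) and applies Bonferroni
  correction *within* each category, mirroring per-ontology analysis.
  Bonferroni (not FDR) is the default deliberately; FDR can be computed from
  `p_raw` downstream if wanted.
* `empirical_set_test()` compares a set's mean PI against `n_perm` random
  equal-size sets, with the add-one estimator $(r+1)/(n_\text{perm}+1)$ so an
  empirical p-value is never zero.
* `bin_genes()` sorts genes ascending by PI (or |PI|) into fixed-size bins
  (200 by default); a remainder shorter than one bin is merged into the last
  bin, a choice the binning convention leaves open. `bin_enrichment()`
  reports per-bin fold enrichment of a "special" class against a reference
  universe with an upper-tail hypergeometric p-value, and
  `bin_covariate_means()`/`covariate_correlation()` attach per-bin covariate
  means plus gene-level and bin-level Spearman correlations.
* `top_k()` breaks boundary ties by gene identifier, so selections are
  deterministic across runs.

## Growth-rate prediction

A measure's **signature** is the set of genes surviving Bonferroni
correction at level `alpha = 0.05` over the genes carrying p-values.
`leave_pairs_out()` implements the resampled cross-validation: each
repetition randomly partitions the panel into disjoint two-sample test sets
(one three-sample set if the panel is odd, so every sample is predicted
exactly once per repetition), fits a lasso at fixed $\lambda$ on the
remaining samples restricted to the signature, and scores the repetition by
the Spearman correlation between predicted and measured rates.

The penalty default is $\lambda = 10^{-3}$, reading the protocol's
"e-3" as engineering notation; it is a configurable argument, and the
natural-log reading ($e^{-3} \approx 0.0498$) can be passed instead. The
lasso itself is glmnet's: $(1/2n)\sum(y-\hat y)^2 + \lambda \|w\|_1$ on
internally standardized predictors, coefficients returned on the original
scale. Single-predictor problems use the closed-form soft threshold under
the same conventions.

`compare_to_random()` runs the identical protocol on equal-size uniform
random gene sets and compares the signature's repetition correlations
against the pooled random correlations with a one-sided rank-sum test
(signature greater). Pooling all random R values is the default granularity;
`per_set_mean` is available. Both one-sided p-values are reported because a
signature can also significantly *underperform* random sets — the expected
behaviour of a differential signature applied to the non-cancerous panel.

For this stage $\lambda$ is fixed and only partitions are re-randomized
across the 100 repetitions; cross-validated $\lambda$ selection is reserved
for the survival stage, where the protocol states it explicitly.

## Survival stratification

`train_panel_model()` chooses $\lambda$ on the source panel by 5-fold
cross-validated mean squared error over a grid (default: 50 log-spaced
values from the smallest all-zero penalty down to $10^{-4}$), refits on the
full panel, and `apply_model()` scores a clinical cohort after intersecting
the model genes with the cohort's genes (absent genes are dropped and
counted). Cohort expression is used as provided apart from the same log2
ingest policy as panels; no cross-platform calibration is attempted, which
is a documented caveat for real multi-platform use.

The two-group split of predicted growth is an **exact** 1-D two-means:
all thresholds in sorted order are scanned for the minimal within-cluster
sum of squares. In one dimension this is provably the optimum that k-means
with $k=2$ converges to at best, and it removes initialization
nondeterminism. Separation is tested by the standard two-group logrank
(simultaneous risk sets at tied event times; 1-df chi-square), via
`survival::survdiff`, with Kaplan-Meier step tables exported per group.

## The synthetic study generator

`generate_study()` draws, from one seed: a cancer panel with lognormal
doubling times (hours), a larger normal panel with truncated-normal growth
rates (per hour), a gene-set collection, a clinical cohort, and a
ground-truth ledger.

The expression model is a single-factor linear model in log2 units:
$x_{gj} = a_g + \beta_g u_j + \varepsilon_{gj}$, with $u_j$ the sample's
latent proliferation factor, $\varepsilon \sim N(0, \sigma^2)$
(`noise_sd`, default 1) and baselines $a_g \sim N(7, 1.5^2)$ (a typical
log2 microarray range). The *measured* growth value is a noisy monotone
readout of the factor: on the log scale its correlation with $u$ is
`reliability` (default 0.85). This measurement-error channel is essential:
if measured growth itself drove expression, averaging the informative genes
of any moderately sized random set would reconstruct measured growth almost
perfectly, and no signature could outperform random sets — a structure
under which the growth-prediction comparisons the package implements would
be meaningless. It also reflects how doubling-time assays behave: the assay
has its own error relative to the biological proliferation state that
shapes expression.

Gene classes plant the cross-panel structure. Defaults: 15% cancer-positive,
5% cancer-negative, 5% normal-positive, 15% normal-negative, 5%
differential (cancer-positive *and* normal-negative), 55% null. The
differential class is deliberately a minority of each tail so that
selections by cPI alone dilute it — the property that makes the differential
index informative. Differential genes get a weaker normal-panel target
(|Spearman| 0.3 versus 0.5): genes picked for cancer significance carry
real but modest non-cancerous signal, which is also why the differential
signature fails to beat random sets when predicting *normal* growth.

`effect_size` is the target |Spearman| between a planted gene's expression
and measured growth, calibrated in closed form through the bivariate-normal
rank-correlation identity $\rho_S = (6/\pi)\arcsin(\rho_P/2)$ at the
reference noise level; per-gene effects are spread by a
Uniform$(1-h, 1+h)$ multiplier (`effect_heterogeneity`, default 0.4),
because real association scans produce a range of effect sizes rather than
one common value. The spread also matters statistically: signatures select
the strong tail of planted genes, so they outperform random sets even
though random sets contain some informative genes.

Survival times are exponential with hazard
$h_0 \exp(\gamma s_i)$, where $s_i$ is the standardized weighted sum of the
differential genes' cohort expression (recorded exactly in
`cohort_latent_score`) and $\gamma$ is set so the hazard ratio between the
top and bottom halves of $s$ equals `survival$hazard_ratio` (default 2.5,
using the half-normal mean gap $2\sqrt{2/\pi}$). Censoring is independent
exponential with its rate solved numerically so the expected censored
fraction matches `censoring_rate` (default 30%). The cohort expression
reuses the cancer-panel loadings for cancer-associated classes and gives
normal-only classes no loading — tumor tissue is modeled as expressing the
cancer program — which is why nPI-based stratification carries little
planted signal.

### What the generator does *not* emulate

No batch or platform effects, no tumor-type substructure, no correlated
gene-gene noise beyond the shared factor, no missing values, and a single
global proliferation axis. Passing tests on this generator therefore
demonstrates correctness of the statistical machinery and qualitative
reproduction of the cross-panel structure — not robustness to the noise
pathologies of real microarray compendia.

## Numerical choices and problem sizes

* Default synthetic universe: 800 genes (the real analysis used 12690;
  the generator scales down so the full pipeline runs at desk scale), with
  panels of 60 cancer and 224 normal samples and a 250-patient cohort.
* Exact rank-sum enumeration is used up to $\binom{n}{k} \le 10^5$;
  beyond that, the tie-corrected normal approximation.
* glmnet convergence: `thresh = 1e-9` for single fits; the resampling loops
  use `1e-5` (and the bundled acceptance checks `1e-4`), where thousands of
  small fixed-penalty fits are needed and looser tolerances change
  predictions negligibly relative to resampling noise.
* The acceptance-style checks run the growth-prediction null comparison at
  20 repetitions and 20 random sets over 10 seeds, and the survival power
  check over 20 seeds — reduced from the 100x100 protocol of a full
  analysis, sized for a single-CPU run. The normal-panel arm of that check
  predicts on a 112-sample subset of the 224-sample panel: the claim there
  is directional (the differential signature does *not* beat random sets)
  and the leave-pairs-out protocol's cost grows with the panel's fold
  count.
* The pooled signature-vs-random rank-sum comparison treats repetition
  correlations as exchangeable units, but repetitions within one gene set
  share that set, so pooled p-values are anticonservative at the set level
  (pseudoreplication) — they order signatures correctly but overstate
  certainty. The null-calibration check therefore uses one repetition per
  set, where exchangeability across the signature and the random sets is
  exact.
* Ties: average ranks everywhere; `top_k` boundary ties resolve by gene id;
  the exact 1-D two-means picks the first-minimum threshold.
* All randomness flows through explicit seeds (`with_seed` restores global
  RNG state), so every artifact is reproducible from its manifest.

## Known limitations

* Correlation is not causation: a high index flags association with
  proliferation, possibly indirect.
* The dPI denominator depends on the global nPI minimum, hence on outliers
  of the nPI distribution; a single extreme gene rescales all dPI values
  (the ordering within fixed cPI is unaffected).
* Clinical cohorts are scored without renormalization to the training
  panel's scale; on real cross-platform data the split, being
  rank-preserving under monotone shifts of the score, is more trustworthy
  than the absolute predicted growth rates.
* With `effect_size = 0.5` at 60 samples, planted genes sit near the
  Bonferroni detection boundary (two-sided p at $\rho = 0.5$, $n = 60$ is
  about $5\times10^{-5}$ versus a threshold of $2.5\times10^{-5}$ at 2000
  genes), so a signature recovers roughly half of the planted genes. Whole-
  signature recall substantially above that requires stronger effects; the
  ranking (AUC), by contrast, separates planted from null genes almost
  perfectly.
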