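# prolifsig

Genome-wide proliferation expression signatures from growth-annotated cell
panels: score every gene for how its expression tracks proliferation in
cancerous versus non-cancerous cells, then carry those scores through
enrichment analysis, growth-rate prediction and expression-based survival
stratification.

## Who this is for

Computational biologists working with panels that pair expression profiles
with growth measurements — a cancer cell-line panel with doubling times, a
lymphoblastoid panel with growth rates — and with clinical expression
cohorts carrying time-to-event outcomes. The package also bundles a
synthetic-study generator with a ground-truth ledger, so the entire pipeline
is testable without any external data.

## The statistics at the core

For gene $g$ with log2 expression $x_g$ and growth rates $r$ (doubling
times $d$ map to $r = \ln 2/d$):

* **cPI / nPI** — the proliferation index on the cancer / normal panel:
  Spearman $\rho(x_g, r)$ (default), or the normalized OLS slope of
  $x_g$ on $r$ (divided by the panel's median absolute slope, so median
  $|PI| = 1$). Two-sided p-values from the $t$ / F tests.
* **dPI** — for genes with $cPI>0$ and $nPI<0$:
  $dPI_g = cPI_g \,/\, (nPI_g - nPI_{\min} + \varepsilon)$,
  $\varepsilon = 0.01$, $nPI_{\min}$ the global minimum; p-values inherited
  from cPI.
* **Enrichment** — Wilcoxon rank-sum shift tests of a set's PI values
  against the rest (exact by enumeration on small universes), per-category
  Bonferroni; empirical random-set tests with $(r+1)/(n+1)$ p-values;
  200-gene bins with hypergeometric fold enrichment and covariate means.
* **Signatures and growth prediction** — Bonferroni-significant gene sets
  feed a lasso ($\lambda = 10^{-3}$) under leave-pairs-out resampling;
  performance is the Spearman correlation of predicted vs measured rates,
  benchmarked against equal-size random gene sets by rank-sum test.
* **Survival** — a panel-trained lasso (5-fold CV penalty) scores clinical
  samples; an exact 1-D two-means split labels low/high proliferation;
  separation is tested by logrank with Kaplan-Meier curves exported.

## Worked example

```r
library(prolifsig)

study <- generate_study(generator_config(seed = 7))
cpi <- compute_pi(study$cancer_panel, study$cancer_growth)
npi <- compute_pi(study$normal_panel, study$normal_growth)
dpi <- compute_dpi(cpi, npi, epsilon = 0.01)
nrow(dpi)
#> [1] 262

sig <- build_signature(cpi, alpha = 0.05)
sig
#> signature (spearman): 89 genes at alpha 0.05 / 800 tests

run <- leave_pairs_out(study$cancer_panel, study$cancer_growth, sig,
                       n_reps = 5, seed = 1)
run
#> prediction_run: 5 reps, 89 genes, mean R = 0.785

surv <- run_survival_pipeline(study$cancer_panel, study$cancer_growth,
                              study$normal_panel, study$normal_growth,
                              list(cpi = cpi, npi = npi, dpi = dpi),
                              study$cohort, seed = 3)
surv$summary[, c("measure", "n_signature", "chi_square", "p_value")]
#>   measure n_signature chi_square      p_value
#> 1     cpi          89 27.9664603 1.234365e-07
#> 2     npi         178  0.9299457 3.348770e-01
#> 3     dpi          48 16.1152128 5.960333e-05
```

Read it as: the cancer-derived signatures (cPI, dPI) stratify the synthetic
cohort sharply (logrank p ≤ 6e-5) while the non-cancerous signature (nPI)
does not (p = 0.33) — the planted cross-panel structure coming through the
whole pipeline. Mean R ≈ 0.79 is the leave-pairs-out Spearman correlation
between predicted and measured growth rates.

A one-shot driver writes every artifact of a run (score tables, enrichment,
bins, growth-prediction report, survival summary, KM tables) plus a JSON
manifest with the resolved config, seed and file hashes:

```r
run_full_study(list(seed = 1, out_dir = "run1"))
```

A thin command-line wrapper over the same functions is installed at
`exec/prolifsig` (subcommands: simulate, pi, dpi, enrich, bins,
predict-growth, survival, full-run).

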