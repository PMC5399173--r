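# reosig

Rank-based gene-pair prognostic signatures from within-sample relative
expression orderings (REOs), for drug-treated cancer cohorts.

## The problem and the model

Most transcriptional prognostic signatures summarize expression levels
into a risk score and compare it against a threshold learned on the
training cohort. That makes every classification depend on data
normalization — and therefore on which other samples happen to be
processed alongside. A REO signature avoids this entirely: each rule is a
boolean comparison of two genes *inside one sample*,

> rule *(a, b)*: does gene *a* sit above gene *b* in this sample?

so calls are invariant to any strictly monotone per-sample transform of
the data (quantile normalization, log scaling, rank transforms) and
robust to batch effects. A signature is an ordered set of such rules,
each tagged with the Cox log-hazard coefficient β of its indicator
I(G<sub>a</sub> > G<sub>b</sub>) against relapse-free survival (β > 0:
the ordering is a risk factor). A sample is called **high risk** when at
least half of its non-abstaining rules vote for high risk (a tie goes to
high risk).

The discovery procedure, given a candidate gene list:

1. **Pair screen (Set1).** Fit a univariate Cox model of relapse-free
   survival on I(G<sub>a</sub> > G<sub>b</sub>) for every unordered
   candidate pair; keep pairs with Benjamini–Hochberg FDR < 5%.
2. **Rank (Set2).** Sort the surviving rules by the Harrell C-index of
   their solo binary vote.
3. **Forward selection (Set3).** Seed with the top rule; walk down the
   list, keeping each rule only if the C-index of the majority-vote
   classification strictly increases.

Upstream of this, candidate genes are chosen for *drug relevance*:
genes whose expression correlates with GI50 drug sensitivity across a
cell-line panel (Spearman, p < 0.05), filtered to those associated with
relapse-free survival in treated patients (univariate Cox, FDR < 20%),
with the sign agreement of the two screens scored as *s/k* and tested
against an upper-tail Binomial(k, ½) null.

The package also bundles the published six-pair colorectal 5-FU
signature (`six_gps()`, 11 genes, all rules risky orderings) as a
ready-to-use classifier, and a multi-omics characterization battery for
the resulting risk groups: Wilcoxon differential expression with
cross-cohort direction concordance, Fisher contrasts of copy-number and
mutation frequencies, mutation direction-bias binomial test, pathway
alteration prevalence, copy-number– and methylation–expression Spearman
screens, MSI-High contrast, and PPI direct-link enrichment.

## Worked example

Everything is testable without downloads via the synthetic-data
generator, which plants reversal gene pairs driving a two-population
proportional-hazards relapse process:

```r
library(reosig)
cfg <- sim_config(seed = 42)            # 300 patients, 6 planted pairs, 400 noise genes
sim <- simulate_cohort(cfg)
fit <- reo_gps(sim$expr, sim$surv, genes = sim$truth$candidate_genes)
fit
```

```
REO gene-pair signature fit
filter cascade: candidate_genes = 30, pairs_enumerated = 435, pairs_tested = 358, set1_pairs = 13, signature_pairs = 6
training C-index: 0.748

Gene-pair REO signature: 6 rule(s), 11 distinct genes
provenance: forward-selected from 13 ranked pairs (policy skip-and-continue) 
                         rule   beta  p_value      fdr c_index
1      g0146 > g0400  (risky)  1.472 1.25e-16 2.23e-14   0.694
2 g0007 > g0284  (protective) -1.314 6.39e-14 5.72e-12   0.654
3      g0148 > g0370  (risky)  1.171 1.82e-11 1.09e-09   0.651
4      g0026 > g0190  (risky)  1.160 1.56e-11 1.09e-09   0.645
5 g0203 > g0213  (protective) -0.786 9.28e-06 4.75e-04   0.601
6 g0007 > g0081  (protective) -0.550 1.74e-03 4.79e-02   0.574
vote rule: high risk iff >= half of the non-abstaining rules vote high
```

The cascade line mirrors the discovery funnel (candidate genes →
enumerated pairs → Cox-tested pairs → FDR-surviving rules → selected
signature); here all six planted pairs were recovered. `summary()`
evaluates the training stratification and `predict()` classifies new
samples one at a time:

```r
summary(fit)
```

```
Risk stratification: 117 high-risk, 183 low-risk
log-rank: chi-square = 154.86, p = 1.5e-35
high vs low: HR = 7.93 (95% CI 5.45-11.55), p = 3.48e-27
C-index = 0.748
```

```r
lab <- predict(fit, sim$holdout_expr)   # factor low/high, one call per sample
c_index(sim$holdout_surv, as.numeric(lab == "high"))
#> 0.708
```

The hazard ratio ~8 and hold-out C-index ~0.71 say the binary vote
separates the planted risk populations cleanly out of sample. Applying
the bundled clinical signature to your own matrix is one line:
`predict(six_gps(), my_expr)` — no normalization against other samples
required.

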