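---
title: "Rank-based gene-pair signatures: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based gene-pair signatures: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reosig)
options(reosig.verbose = FALSE)
```

## The model

A relative-expression-ordering (REO) rule for a gene pair $(a, b)$ is the
within-sample indicator $I(G_a > G_b)$. Because it compares two
measurements made on the *same* sample, it is invariant to every strictly
monotone per-sample transform of the data and unaffected by additive
distortions shared by all genes of a sample. This is the core modelling
assumption: prognostic information is carried by which of two genes sits
higher, not by how much, so a classifier built from such rules needs no
normalization against other samples and is robust to experimental batch
effects. The price is a deliberate loss of magnitude information.

A *gene-pair signature* is an ordered set of rules, each carrying the
log-hazard coefficient $\beta$ of its indicator in a univariate Cox
proportional-hazards model of relapse-free survival (RFS, months from
surgery to relapse or last contact, right-censored). $\beta > 0$ marks
the ordering $G_a > G_b$ as a *risky* ordering, $\beta < 0$ as
protective. Classification is by majority vote: a sample is **high
risk** when its high-risk votes are at least half of the non-abstaining
votes. The tie therefore goes to high risk — with six rules, three risky
orderings suffice — matching the clinical asymmetry that a missed
high-risk call is the costlier error. A rule abstains when either gene
is missing from the sample; a sample abstaining on more than half of the
rules is reported unclassifiable rather than guessed.

## The discovery procedure

Given a training cohort and a candidate gene list, `reo_gps()` runs:

1. **Pair screen.** All $\binom{n}{2}$ unordered candidate pairs
   (canonical lexicographic orientation — testing both orientations
   would duplicate every test with a mirrored $\beta$ and double the
   multiple-testing burden for no information) are fitted by univariate
   Cox on their indicator. Benjamini–Hochberg control at FDR < 5% over
   all tested pairs yields *Set1*. Pairs with a constant indicator
   (including always-tied expression) are excluded with a warning;
   monotone-likelihood separation is flagged non-converged and excluded.
2. **Ranking.** *Set1* is sorted by the Harrell C-index of each rule's
   solo binary vote — the same score the composite is judged by — with
   ties broken by smaller p-value, then lexicographic pair id, so the
   ordering is a deterministic function of the data (*Set2*).
3. **Forward selection.** The top rule seeds the signature; walking down
   *Set2*, each rule is tentatively added, every sample re-classified by
   majority vote, and the rule kept only when the training C-index of
   the binary labels *strictly* increases (*Set3*).

Two selection policies are provided. `"stop-first-failure"` halts the
walk at the first non-improving rule — the most literal reading of "add
pairs until the C-index does not increase". The default is
`"skip-and-continue"`, which skips a non-improving rule and keeps
scanning. The choice matters: the true per-step C-index gain of a
majority-vote composite is small (the vote threshold $\lceil k/2 \rceil$
shifts only at odd sizes, so even-sized steps loosen and odd-sized steps
tighten the classifier), and in cohorts of a few hundred samples those
gains are comparable to the sampling noise of the C-index itself. Under
the stop policy a single downward fluctuation discards every remaining
candidate, so the selection truncates at one or two rules in a large
fraction of replicates even when the planted signal continues; the skip
policy loses only the fluctuating rule. We therefore treat the tolerant
scan as the default and keep the strict policy behind the flag.

### Upstream: drug-relevant candidate genes

Candidates are pre-selected for drug relevance in two screens.
`screen_gi50_genes()` correlates each gene with GI50 drug sensitivity
across a cell-line panel (Spearman, two-sided p < 0.05; a higher GI50
means a more resistant line, and inputs on the $-\log_{10}$ scale are
sign-flipped so records always carry GI50-scale signs).
`screen_rfs_genes()` keeps candidates whose expression is associated
with RFS in treated patients (univariate Cox, BH within the candidate
list only, FDR < 20%). The *concordance score* of the two screens is
$s/k$ — the fraction of genes passing both whose GI50 sign equals their
hazard sign — with significance from the upper tail of
$\mathrm{Binomial}(k, 1/2)$. A perfectly concordant overlap supports
reading the genes as clinically relevant drug-resistance genes.

## Statistical kernel

Standard tests are delegated to base R and the survival package behind a
thin uniform interface: Cox fits use `coxph` machinery
(Newton–Raphson on the partial likelihood, Efron tie handling by
default with Breslow behind a flag, convergence tolerance $10^{-9}$,
50 iterations), Kaplan–Meier uses `survfit`, the log-rank test
`survdiff`, the Wilcoxon rank-sum test `wilcox.test` (exact when both
groups have at most 12 observations, otherwise normal approximation with
tie and continuity correction), the Fisher test `fisher.test` (two-sided
by summing hypergeometric probabilities no larger than the observed —
the R convention), and Spearman's $\rho$ uses average ranks with the
two-sided t-approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$, adequate at
the panel sizes involved (tens of lines) and checked against permutation
in the test-suite.

The **Harrell C-index is implemented in the package** because its
permissible-pair convention must match the forward-selection scoring
exactly, and that convention is otherwise underdetermined: a pair of
patients is usable iff the member with the shorter time has an event;
for equal times with exactly one event the event member counts as
earlier; equal times with two events are excluded; tied risk scores
contribute 0.5. One consequence worth spelling out: with binary
high/low scores and two patients per group, all uncensored, the C-index
of a perfect split is $5/6$, not 1 — the two within-group pairs are
score ties. The implementation is verified against an $O(n^2)$
enumeration oracle on random instances. It materializes $n \times n$
comparison matrices, so memory grows quadratically; cohorts up to a few
thousand samples are comfortable.

## The synthetic study

The generator produces every input the pipeline consumes, with planted
truth, so each stage and the end-to-end build are testable without
downloads. Its defaults define the reference study conditions used by
the test-suite.

**Cohort** (`simulate_cohort`, defaults: 300 training + 150 hold-out
samples, 412 genes of which 12 belong to 6 planted pairs, per-ordering
log-hazard $\log 3$). Background expression is i.i.d. normal on the
log2 scale (log-normal abundance), mean 7, sd 2. Each sample carries a
latent binary risk state (fair coin); each planted pair shows its risky
ordering with probability 0.60 in high-state and 0.15 in low-state
samples. Three structural choices deserve explanation:

* *Narrow, spaced pair bands.* The two genes of a pair swap within a
  band of width ~1 log2 unit around a pair-specific center, and
  consecutive pair centers are spaced 2 units apart. Comparisons between
  genes of different pairs are then constant (two separated bands never
  overlap), and comparisons of a pair gene against a background gene are
  strongly attenuated (the background gene rarely falls inside the
  band). Without this, cross-pair comparisons aggregate two latent
  states and would dominate the screen — the planted pairs themselves
  must be the strongest signal for recovery to be a meaningful test.
* *A shared latent state with asymmetric vote errors.* With independent
  per-pair states, no single rule predicts the composite outcome much
  worse than the majority vote does, so forward selection has nothing to
  gain after the seed. Making all pairs noisy reporters of one
  two-population state — risky orderings frequent in high-state, rare in
  low-state samples, as heterogeneous resistance mechanisms would
  produce — gives the majority vote a genuine, strictly increasing
  population-level C-index path over the first several additions. The
  asymmetry is essential: with symmetric errors the OR-leaning even
  steps add false positives faster than sensitivity.
* *Survival process.* Relapse times are exponential proportional-hazards
  with linear predictor $\log 3 \times$ (risky-ordering count, centered),
  baseline hazard 0.02/month; censoring is independent exponential at
  0.01/month truncated at a 120-month horizon, giving a realistic ~55%
  censoring fraction.

**Cell panel** (`simulate_cell_panel`, 58 lines). A latent resistance
score generates GI50 (plus noise, sd 0.5) and, via a signed linear
coupling (slope 1.2), the expression of 50 coupled genes over the same
gene universe as the cohort. The planted pair genes are among them —
first gene of each pair positively, second negatively — so the two
screens overlap on sign-concordant genes and a cohort-fitted signature
calls high-GI50 lines resistant.

**Omics** (`simulate_omics`). Copy-number regions, mutations and
MSI-High status are Bernoulli draws with group-specific frequencies; the
differential settings mirror published colorectal contrasts (region
alteration 95.6% vs 43.5%, MSI-High 12.1% high-risk vs 27.7% low-risk,
mutations concentrated in the low-risk group). Methylation beta values
for coupled genes follow
$\mathrm{logit}^{-1}(-1.5\, z(\mathrm{expression}) + \varepsilon)$, so
the negative methylation–expression screen has planted truth alongside
an equal-sized null gene set.

**What the generator does not emulate** — and hence what passing tests
do *not* establish about real data: gene–gene correlation structure
beyond the planted pairs, platform- or probe-specific noise, informative
censoring, non-proportional hazards, subtype structure richer than two
populations, and any coupling between the omics layers beyond the
planted ones. Tests on this generator validate the *algorithms*, not the
biology of any particular cohort.

## Numerical choices and degenerate inputs

* Expression ties $G_a = G_b$: the strict indicator is false; ties are
  counted and logged. A rule with a protective direction consequently
  votes high on a tie.
* Missing values: a pair's vote is computed only where both genes are
  present; readers record missing cells as missing and reject
  non-numeric cells with their address, duplicated ids by name.
* BH adjustment validates its inputs against $[0,1]$; Fisher p-values
  are clamped at 1 to absorb floating-point overshoot from summing
  hypergeometric masses.
* All screens log in/out counts, mirroring the discovery funnel
  (candidates → survival-associated genes → Set1 pairs → signature), and
  every generator embeds its seed in the returned truth object;
  per-component substreams are fixed offsets of the global seed.
* The rank-difference diagnostic uses average within-sample ranks over
  the full supplied gene universe and reports the universe size, because
  the gap only has meaning relative to it.

## Test-suite problem sizes

The suite exercises the pipeline at deliberately modest sizes — cohorts
of 40–300 samples, candidate lists of 8–30 genes, 1000–2000-gene DEG
scans, 20–100 replicate seeds per property — chosen so each property is
measured with useful power while the whole suite stays quick to run.
Exact-test implementations are compared with full-enumeration oracles
only on instances with at most a few thousand outcomes, where the oracle
itself is exact.

## Known limitations

* The forward selection optimizes training C-index without internal
  cross-validation (by design, matching the published procedure);
  hold-out evaluation is reported only when a validation split is
  supplied, and training C-indexes carry optimistic selection bias.
* Recovery of a planted six-pair signature at effect $\log 3$ and
  $n = 300$ is intrinsically marginal: the later forward-selection steps
  improve the population C-index by about one sampling standard
  deviation, so in a substantial minority of replicates the fitted
  signature carries four of the six planted pairs rather than five or
  six. The hold-out discrimination of those signatures is nonetheless
  essentially as good — the missing rules are largely redundant with the
  accepted ones.
* The classifier is strictly vote-based; no probabilistic risk score or
  calibration is offered, and weighted-sum signatures are out of scope.
* The methylation screen consumes gene-level betas;
  `summarize_methylation()` offers a mean-beta CpG-to-gene pre-step given
  an explicit promoter map, but no probe annotation of its own.
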