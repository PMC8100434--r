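---
title: "Pathway co-occurrence stratification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway co-occurrence stratification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copath)
```

## The scientific problem

Only a minority of advanced NSCLC patients respond durably to immune
checkpoint inhibition, and single-gene markers have proven weak. copath
implements a pathway-level stratification: a tumor is scored against a
catalog of ten canonical oncogenic signaling pathways and eight DNA damage
response (DDR) pathways (MMR, BER, CPF, FA, HRR, NER, NHEJ, TLS). A
pathway is *altered* in a sample when at least one of its genes carries a
non-synonymous somatic mutation. *co-DDR* means two or more DDR pathways
altered in the same tumor, and the predictive stratum — NOTCH+/co-DDR+,
labeled **GoodBenefit** — is the co-occurrence of NOTCH pathway alteration
with co-DDR status. The package quantifies what that stratum buys:
progression-free survival (Kaplan–Meier, log-rank, Cox proportional
hazards), mutational burden contrasts, and immune-infiltration correlates
(ssGSEA, pre-ranked GSEA).

## The stratification rule

`assign_strata()` is a pure function of the boolean sample × pathway
matrix:

* `co_ddr` ⟺ number of altered DDR pathways ≥ 2;
* `GoodBenefit` ⟺ NOTCH altered ∧ co_ddr, everything else `BadBenefit`;
* the three-group view splits BadBenefit into `SinglePath` (exactly one of
  the two conditions holds) and `WildType` (neither).

Because the rule is so small it is tested by exhaustive enumeration over
all (NOTCH, n\_DDR) combinations, and the alteration matrix itself against
a brute-force triple loop.

Alteration is a *state*, not a burden: repeated hits in one gene alter a
pathway once, while every non-synonymous mutation counts toward TMB
(`compute_tmb()`). The non-synonymous class set defaults to the standard
whole-exome convention (missense, nonsense, nonstop, frameshift and
in-frame indels, splice site, translation start); which indel classes a
given cohort's pipeline counted is genuinely cohort-dependent, so the set
is a configurable argument rather than a constant. TMB is reported as a
raw count by default, with an optional per-megabase rescale, since cohort
capture sizes differ.

## The gene-set catalog is configuration, not code

The exact gene membership of each pathway belongs to the curated
literature, not to this package. `default_catalog()` ships a GMT fixture
with core genes per pathway drawn from the public pathway curations, and
its provenance string labels it a curated stand-in. Every entry point
accepts a user GMT plus a `pathway → category` sidecar, so a site's own
supplementary lists drop in without code changes. `restrict_catalog()`
intersects the catalog with a targeted panel and *drops* emptied sets —
on a panel with no TLS genes the co-DDR denominator becomes 7 pathways,
mirroring how targeted-sequencing cohorts must be analyzed. Gene matching
is case-insensitive uppercase with no alias resolution; identifier
conversion is out of scope and a documented limitation.

## Survival machinery

Kaplan–Meier, log-rank and Cox fits are delegated to the survival package
behind thin, typed surfaces (`km_fit()`, `logrank_test()`, `cox_fit()`):
these are standard estimators and reimplementing them would only add risk.
The package's own tests keep the delegation honest with independent
oracles — the hand product-limit formula, a hand observed-minus-expected
log-rank summation, and a golden-section maximization of the explicit
partial likelihood that must agree with the Newton fit to 1e−4.

Choices that matter:

* **Ties**: Efron correction by default (the R default), Breslow
  available.
* **Medians**: smallest time with survival ≤ 0.5, `NA` when the curve
  never crosses it — never extrapolated, because long-surviving strata in
  small cohorts routinely do not reach 0.5.
* **CIs**: `exp(coef ± 1.96·se)` from the inverse observed information.
* **Separation**: monotone likelihood is detected (runaway coefficient or
  SE, or the fitter's own diagnostics) and flagged on the result rather
  than silently returned.
* **Multivariable adjustment**: the adjustment set is not canonical, so
  `pathway_forest(adjust =)` takes any clinical columns; the analysis
  scripts use TMB (log1p-scaled), histology, smoking and PD-L1 — the
  plausible confounders available in a standard clinical table.
* **Exact tests**: `fisher_exact_2x2()` uses the point-probability
  two-sided convention (verified against full hypergeometric enumeration
  for every margin configuration up to n = 40); the Wilcoxon branch is
  exact for tie-free samples up to n = 8 per group and a midrank normal
  approximation with continuity correction beyond.
* **Summary tables**: within-column percentages with one-decimal
  half-away-from-zero rounding; Fisher for 2×2 associations, Pearson
  chi-square without continuity correction for larger tables; "Unknown"
  levels are displayed but excluded from tests.
* **Multiplicity**: prevalence and enrichment tables carry both raw p and
  Benjamini–Hochberg q across pathways, because headline pathway-level
  p-values in this literature are conventionally quoted unadjusted.

## Co-occurrence enrichment

The enrichment scan asks, for each pathway P other than the anchor,
whether *joint* alteration (NOTCH ∧ P) separates DCB from NDB: the 2×2
table is joint-altered yes/no × DCB/NDB, with a two-sided Fisher p and a
log2 odds ratio. When any cell is zero the Haldane–Anscombe +0.5
correction is applied to all four cells so the log-odds stay finite. The
contingency construction is genuinely ambiguous in this design — one can
also ask whether P is altered among NOTCH-altered tumors only — so the
alternative construction ships behind
`construction = "within_anchor"`; the default matches the
selection-for-benefit question the scan is meant to answer.

## Immune arm

`ssgsea_score()` implements the single-sample enrichment score as the sum
over the ranked gene list of the difference between the weighted in-set
cumulative (weights `rank^alpha`, normalized over in-set genes) and the
uniform out-of-set cumulative. Only within-sample ranks enter, so the
score is invariant under any strictly monotone transform of one sample's
values — asserted directly in the tests. `alpha = 0.25` follows the
method's convention; `alpha = 0` degrades to the unweighted KS running
sum. A signature covering every gene has no out-of-set mass and scores 0
by convention; signatures with fewer than two matrix genes are skipped
with a warning. Ties rank by stable gene name so scoring is
deterministic. Min-max rescaling across samples is off by default (it
changes nothing downstream of clustering and hides scale information).

Clustering uses Euclidean distances with the `ward.D` linkage — the
Lance–Williams Ward update applied to *unsquared* distances. That variant
(rather than textbook Ward/`ward.D2`) is deliberate: it reproduces the
behavior of the named option in the R clustering stack that this style of
immune subclassification conventionally uses. Clusters are labeled
immune-high/intermediate/low by descending cluster-mean score, which
makes labels invariant to sample order.

The group contrast ranks genes by the mean within-stratum z-score
(population-n denominator, another determinism choice; zero-variance
genes get z = 0 with a warning), focal stratum GoodBenefit, descending —
so "enriched" always means enriched in GoodBenefit. `preranked_gsea()`
is the classic weighted-KS maximum deviation with weight `|metric|`, a
*gene-label* permutation null (the list is fixed; which positions are
in-set is permuted), NES = ES over the mean magnitude of same-sign null
scores, and GSEA-style FDR over the pooled normalized null (BH on
permutation p-values by config). Calls follow the q < 10% rule: enriched
if NES > 0, depleted if NES < 0. The packaged 28 immune-cell signature
GMT is, like the pathway catalog, a curated stand-in keyed to the
standard 28-cell-type taxonomy and fully overridable. fgsea — which
estimates the same ES — serves as an independent cross-check in the test
suite, never as the implementation.

## What the synthetic cohorts emulate

`generate_cohort()` produces cohorts with the statistical structure the
analysis assumes, so every stage is testable without any external data:

* **Mutations**: each pathway gene mutates independently (baseline
  per-gene probability 0.01); a latent "responder-like" subgroup (45% of
  patients) mutates pathway genes at 5× and carries 1.6× the Poisson-80
  background burden, coupling TMB to the stratum. These rates were chosen
  once so that roughly 35–40% of patients land in GoodBenefit and TMB
  sits at whole-exome scale — the proportions a merged ICI-treated NSCLC
  cohort exhibits.
* **Strata**: derived by calling the public `assign_strata()` on the
  generated mutations, never sampled directly — generator and pipeline
  cannot drift apart.
* **Survival**: exponential PFS with baseline hazard log(2)/3.6 per month
  (BadBenefit median 3.6 months) and planted hazard ratio 0.34 for
  GoodBenefit, under which the Cox model is exactly specified; an
  independent exponential censoring process (rate 0.02/month) plus a
  40-month administrative cutoff give light, realistic censoring.
* **Response**: DCB drawn per stratum (0.70 GoodBenefit / 0.35
  BadBenefit), echoing the headline contrast such a cohort shows.
* **TNB**: Binomial(TMB, 0.1) — neoantigen burden proportional to
  mutation burden, consumed as a number, never computed from sequence.
* **Expression**: Normal(0, 1) baseline; activated CD4/CD8 T-cell
  signature genes shifted +1.5 SD in GoodBenefit samples, IL4 and TNFSF15
  shifted −1.5 SD.

One uniform per (sample, pathway gene) is drawn up front, so under a
fixed seed the mutation hit sets are *nested* in the per-gene rate and
stratum counts respond monotonically to it — a property the tests assert
deterministically. The whole bundle is a pure function of the config: the
same seed reproduces byte-identical files, checksummed in the manifest.

What the generator does **not** emulate: mutational signatures and
trinucleotide context, copy number, clonality, gene–gene correlation
within pathways, panel-specific capture bias, non-proportional hazards,
and informative censoring. Passing tests therefore demonstrate that the
machinery recovers planted effects under the model's own assumptions —
not that real cohorts satisfy those assumptions.

## Problem sizes and calibration bands

The test suite sizes its simulations to be informative yet quick: the
log-rank and Cox-Wald null calibrations use 2000 replicates at 50 per arm
(rejection at α = 0.05 expected in [0.04, 0.06]); hazard-ratio recovery
runs the full mutation→stratum→survival chain 200 times at n = 500 and
requires ≥ 90% CI coverage of the planted 0.34; permutation GSEA uses
1000 permutations, with null signatures required to stay under a 15%
false-call rate at the q < 10% threshold. The analysis scripts run the
default 106-patient scenario end to end.

## Known limitations

* Gene membership of the shipped catalogs is a curated stand-in; results
  on real cohorts depend on the supplied lists.
* No gene-alias or identifier resolution.
* Attrition semantics differ from some published analyses: samples with
  zero pathway hits are kept as all-false rows (they become WildType),
  never dropped.
* Proportional-hazards diagnostics, competing risks and time-varying
  covariates are out of scope.
* The GSEA FDR is permutation-based and therefore has Monte-Carlo noise
  at small `n_perm`; seeds make it reproducible, not exact.
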