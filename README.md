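# copath

Pathway-level biomarker analysis for immunotherapy-treated tumor cohorts.

Durable benefit from immune checkpoint inhibition (ICI) in advanced NSCLC
is hard to predict from single genes. `copath` stratifies a cohort by the
**co-occurrence of NOTCH pathway alteration with multi-DDR pathway
alteration** and quantifies what that stratum implies for survival,
mutational burden and immune infiltration. It is written for
translational genomics analysts who have a somatic mutation table (MAF),
a clinical table, and optionally an expression matrix, and want the whole
stratification-to-survival-to-immune chain as auditable, testable code.

## The model

For a catalog of gene sets P₁…P₁₈ (10 oncogenic signaling pathways, 8 DNA
damage response pathways: MMR, BER, CPF, FA, HRR, NER, NHEJ, TLS), sample
*s* is altered in pathway P iff at least one gene of P carries a
non-synonymous mutation in *s*. Define

* **co-DDR**: ≥ 2 DDR pathways altered;
* **GoodBenefit (NOTCH+/co-DDR+)**: NOTCH altered ∧ co-DDR;
  everything else **BadBenefit** (subdivided into SinglePath / WildType).

The stratum effect on progression-free survival is estimated by the Cox
proportional-hazards model λ(t|Z) = λ₀(t)·exp(βZ), Z the GoodBenefit
indicator, HR = exp(β) (Efron ties, Newton iterations); groups are
compared by Kaplan–Meier curves and the log-rank test. Pathway prevalence
and co-occurrence enrichment use two-sided Fisher exact tests with
Haldane–Anscombe-corrected odds ratios; TMB/TNB contrasts use the
Wilcoxon rank-sum test. The immune arm scores 28 immune-cell signatures
per sample by ssGSEA (rank-weighted running sum, α = 0.25), clusters
samples with Euclidean/ward.D linkage, and calls signatures enriched or
depleted in GoodBenefit by pre-ranked permutation GSEA (q < 10%, sign of
NES).

A seeded synthetic-cohort generator with a planted hazard ratio,
TMB-coupled latent structure and planted immune-signature shifts makes
every stage testable without external data. See
`vignettes/pathway-cooccurrence.Rmd` for the full methods account.

## Worked example

The `analysis/` scripts run the whole study on the packaged default
scenario (106 patients, planted GoodBenefit hazard ratio 0.34, seed 42):

```sh
Rscript analysis/01_simulate.R   # synthetic cohort -> results/synthetic_cohort/
Rscript analysis/02_stratify.R   # alteration matrix, strata, enrichment
Rscript analysis/03_survival.R   # KM / log-rank / Cox forest / TMB
Rscript analysis/04_immune.R     # ssGSEA, clustering, pre-ranked GSEA
Rscript analysis/05_report.R     # consolidated report -> results/report/
```

`analysis/03_survival.R` prints, for that seed:

```
Median PFS 12.5 (GoodBenefit) vs 3.5 (BadBenefit) months,
log-rank p = 6.71e-09. Univariate HR 0.26 (95% CI 0.16-0.42);
adjusted HR 0.12 (95% CI 0.05-0.28). TMB rank-sum p = 8.73e-15,
TNB p = 1.5e-06.
```

meaning: the 52 NOTCH+/co-DDR+ patients progress at roughly a quarter of
the hazard of the 54 others (the planted 0.34 sits inside the CI), their
median PFS is ~9 months longer, and their mutational burden is sharply
higher — the pattern the stratification is designed to surface. The
immune step then reports the planted activated CD4/CD8 T-cell signatures
as enriched in GoodBenefit (q < 0.10, NES > 0).

The same chain is available programmatically:

```r
library(copath)
cfg <- read_scenario(system.file("extdata", "default_scenario.yaml",
                                 package = "copath"))
b   <- generate_cohort(cfg, dir = "cohort")
run <- run_pipeline(b$paths$maf, b$paths$clinical, out_dir = "run")
render_report(run)
```

Real cohorts enter through `read_maf()` / `read_clinical()` /
`read_expression()`; a site's own pathway lists through `read_gmt()` plus
a category sidecar; targeted panels through `restrict_catalog()` (a panel
without TLS genes leaves 7 assayable DDR pathways, and co-DDR counts
against 7).

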