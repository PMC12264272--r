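# resistm

Scoring and survival stratification of colorectal cancer (CRC) cohorts
with the nine-gene, two-arm **RESIST-M** signature of oxaliplatin
resistance, for bioinformaticians and biostatisticians working with
bulk-expression cohorts that carry survival and molecular-subtype
annotations (CMS1–4, iCMS2/3, MSI, fibrosis).

Oxaliplatin-resistant CRC cells up-regulate *SERPINE1* (PAI-1) and
*SMARCD3* (the **RESIST-M1** arm) while suppressing seven
cholesterol-biosynthesis genes — *SC5D, FDPS, MVD, HMGCS1, HMGCR, CYP51A1,
ACAT2* (the **RESIST-M2** arm). Because the arms point in opposite
directions, the risk-up genes are first *reflected* per gene across the
cohort,

> x ↦ min + (max − min)(max − x)/(max − min) = min + max − x,

which inverts their ranking, and the combined per-sample score is the
median of the nine transformed values (lower score = higher-risk
pattern). Samples are split at the cohort-median score ("high" iff
strictly above the median), and the groups are compared with
Kaplan–Meier curves (log-log confidence intervals), the Mantel–Haenszel
log-rank test, and a Cox proportional-hazards hazard ratio (Breslow
ties, Wald intervals). The package also ships four published comparator
signatures (Yin, Lin, the 7-gene recurrence-score subset RCC7, and the
DNA-repair score RPS), Wilcoxon rank-sum score comparisons across CMS
subtypes, a Fisher exact test for enrichment of the signature-high group
in the CMS4/iCMS3-fibrotic subtype, a z-scored annotation-ordered
heatmap table, GMT import/export, and a seeded synthetic
expression–survival cohort generator standing in for real cohorts.

## Worked example

Simulate a 400-patient cohort in which the CMS4-and-fibrotic subgroup
(here 50% of patients) carries the RESIST-M expression pattern and a
planted hazard ratio of 2.5, then stratify survival with the combined
signature:

```r
library(resistm)

balanced <- cohort_config(
  n_samples = 400,
  subtype_proportions = c(CMS1 = 0.10, CMS2 = 0.25, CMS3 = 0.15, CMS4 = 0.50),
  fibrotic_fraction_in_cms4 = 1, seed = 1)
cohort <- simulate_cohort(balanced)

rep <- stratified_km_report(cohort$expression, cohort$clinical, "RESIST-M")
rep
#> <stratification_report> RESIST-M (reflected_median)
#>   groups: 200 high-risk / 200 low-risk
#>   log-rank chi-square = 65.100, p = 7.12e-16
#> <resistm_cox> HR = 2.868 (95% CI 2.199-3.742), p = 7.71e-15, 256 events / 400 subjects

enrichment_test(rep$status, cohort$clinical)
#> <enrichment_result> target: cms = CMS4 & fibrosis = fibrotic
#>            target
#> risk        in-target out
#>   risk-high       190  10
#>   risk-low          4 196
#>   odds ratio = 870, Fisher p = 3.38e-95
```

The median split recovers the planted separation: the signature-defined
high-risk half dies ~2.9× faster (the planted 2.5 plus sampling noise),
the log-rank test is decisive, and 190 of the 194 CMS4-fibrotic patients
land in the high-risk group (Fisher odds ratio 870). `autoplot(rep)`
draws the two Kaplan–Meier curves with confidence bands;
`run_pipeline(pipeline_config(...))` runs every signature, the subtype
comparisons, the enrichment test and the heatmap table in one call and
can write a JSON + TSV report.

Real data enter the same way via `read_expression()` (genes × samples
TSV/CSV, log2(TPM+1) recommended) and `read_clinical()`
(`sample_id`, `time`, `event`, plus `cms`/`icms`/`msi`/`fibrosis`
labels).

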