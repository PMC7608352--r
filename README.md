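# cnvcohort

An R package implementing a reproducible case–control association
pipeline for a recurrent copy-number deletion in a biobank-style cohort,
built around the 15q11.2 BP1–BP2 microdeletion (the ~500 kb region
between Prader–Willi/Angelman breakpoints 1 and 2, spanning *NIPA1*,
*NIPA2*, *CYFIP1* and *TUBGCP5*) and its association with congenital
cardiovascular malformation (CVM) and neuropsychiatric phenotypes.

It is intended for statistical geneticists and genetic epidemiologists
who need the full chain — CNV call ingestion, sample QC, locus
genotyping, rule-based electronic-health-record phenotyping, and the
association/regression battery — as tested, reusable code rather than a
one-off analysis script. Because the real cohort data are
access-controlled, the package ships a fully parameterised synthetic
cohort generator with ground-truth labels, so every stage is exercisable
and testable end to end.

## What it computes

**Locus genotyping.** From PennCNV-style `rawcnv` calls (1-based
inclusive coordinates), a sample is a deletion carrier when the union of
its heterozygous (CN = 1) calls covers at least 95% of the probe-bounded
locus chr15:22,819,338–23,093,090 (GRCh37). Samples with waviness factor
strictly outside [−0.03, 0.03] or more than 40 genome-wide calls are
excluded beforehand.

**Phenotyping.** A deterministic, codebook-driven cascade assigns
CASE / CONTROL / EXCLUDED per phenotype with machine-readable reasons:
syndromic samples are removed first; ICD-10 Q211 (ambiguous between
atrial septal defect and patent foramen ovale) is voided when a
PFO-specific operation (K165) or an AF-free stroke preceding the Q211
diagnosis indicates PFO; aortic-valve disease first diagnosed before 65
(and free of endocarditis-type exclusions) is taken as congenital
bicuspid aortic valve; self-reported heart surgery counts only under
age 18.

**Association.** For a 2×2 table with `a/b` carriers/non-carriers among
cases and `c/d` among controls:

- odds ratio `OR = ad / bc`, with the Woolf 95% interval
  `exp(log OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`;
- Yates-corrected chi-squared
  `N·(max(|ad − bc| − N/2, 0))² / ((a+b)(c+d)(a+c)(b+d))` on 1 df.

Cognitive and reproductive outcomes use covariate-adjusted models chosen
by distribution: linear for reaction time (5-SD outlier rule), Poisson
for fluid intelligence, logistic for binarised numeric memory (>6) and
pairs matching (>0), multinomial log-linear for highest qualification
(combined "other" group as baseline), and sex-stratified Poisson for
fecundity with a deletion×sex interaction test.

## Worked example

```r
library(cnvcohort)

# published 2x2: 18/2,774 carriers among CVM cases, 1,769/470,611 among controls
or_ci_chi2(18, 2774, 1769, 470611)
#> 2x2 association (a=18 carriers / 2792 cases vs c=1769 / 472380 controls)
#>   prevalence: cases 0.64%, controls 0.37%
#>   OR = 1.73 [95% CI 1.08-2.75]
#>   Yates chi-squared = 4.712, p = 0.03

# a synthetic cohort through the whole pipeline
rep <- run_pipeline(list(simulate = list(n_participants = 100000), seed = 7))
print(rep)
#> CNV association pipeline run
#>   participants: 100000; QC pass: 99620; deletion carriers (QC pass): 385
#>   CVM: CASE 582 / CONTROL 98862 / EXCLUDED 556
#>   NEUROPSYCH: CASE 718 / CONTROL 98513 / EXCLUDED 769
#>
#> CVM association:
#> 2x2 association (a=3 carriers / 581 cases vs c=379 / 98484 controls)
#>   prevalence: cases 0.52%, controls 0.38%
#>   OR = 1.34 [95% CI 0.43-4.20]
#>   Yates chi-squared = 0.030, p = 0.862
#> ...
#> Carrier effects (adjusted):
#>   reaction_time      beta =  19.9139 (se 5.6486), p = 0.000423
#>   fluid_intelligence beta =  -0.1187 (se 0.0222), p = 8.58e-08
#>   numeric_memory     beta =  -0.4880 (se 0.1037), p = 2.55e-06
#>   pairs_matching     beta =   0.1591 (se 0.1054), p = 0.131
#>   fecundity interaction p = 0.994
```

The first block reproduces the published CVM association exactly from
the printed counts. In the simulated run, carriers are drawn at 0.38%
prevalence and phenotypes at a true population OR of 1.73 — at a single
n = 100,000 replicate the point estimate is noisy (here 1.34 with a wide
CI, as expected with ~4 carrier-cases), while the adjusted regression
battery recovers the configured carrier effects (+17.8 ms reaction time,
log-rate −0.104 for fluid intelligence, log-odds −0.35 for numeric
memory). `emit_report(rep, "out/")` writes JSON and Markdown reports
plus the intermediate tables every printed count can be rebuilt from.

A command-line wrapper with `simulate` / `genotype` / `phenotype` /
`associate` / `run` subcommands is installed at
`system.file("scripts", "cnvcohort.R", package = "cnvcohort")`.

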