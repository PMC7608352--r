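---
title: "Methods: deletion genotyping, rule-based phenotyping and the association battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: deletion genotyping, rule-based phenotyping and the association battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvcohort)
```

`cnvcohort` implements a case–control association pipeline for the
15q11.2 BP1–BP2 microdeletion in a biobank-style cohort. This vignette
is the package's own account of the science: the models and decision
rules, the tunable parameters and why their defaults are what they are,
what the synthetic cohort does and does not emulate, and the numerical
choices made where the design was genuinely open.

## The deletion and the question

The BP1–BP2 deletion is a ~500 kb heterozygous loss between breakpoints
1 and 2 of the Prader–Willi/Angelman region, covering four non-imprinted
genes (*NIPA1*, *NIPA2*, *CYFIP1*, *TUBGCP5*). Its penetrance for any
phenotype is low (~10–12%), so meaningful effect estimates require
population-scale cohorts rather than clinic-ascertained series. The
pipeline estimates the deletion's association with congenital
cardiovascular malformation (CVM) and with neuropsychiatric diagnoses,
and its effects on cognitive scores, educational attainment and
fecundity.

## Locus genotyping by overlap fraction

CNV calls are ingested from PennCNV `rawcnv` text or an equivalent TSV;
coordinates are 1-based inclusive throughout, so an interval's length is
`end − start + 1`. Copy-number-2 lines are rejected at parse: a CN = 2
record is not a variant call, and accepting one silently would corrupt
call counts used in QC.

Sample-level QC mirrors array practice: a sample is excluded when its
waviness factor (a per-sample artifact metric) lies strictly outside
[−0.03, 0.03], or when it carries strictly more than 40 genome-wide
calls. Both boundaries are retained (a waviness of exactly ±0.03, or
exactly 40 calls, passes) — the count threshold deliberately keeps
high-burden samples because global CNV burden is itself a CVM risk
factor.

A sample is a deletion carrier when

```
overlap_fraction = |union(CN=1 calls) ∩ locus| / |locus| ≥ 0.95
```

with the locus fixed at the outermost probes covering the four genes,
chr15:22,819,338–23,093,090 (GRCh37, length 273,753 bp). Multiple CN = 1
calls are unioned with no gap-merging heuristic — the simplest rule
consistent with "spanning" the region. Since 0.95·273,753 = 260,065.35,
an intersection of 260,065 bp fails and 260,066 bp qualifies; this
integer boundary is pinned by tests. The 95% rule is applied to the
single probe-bounded interval rather than per gene: the four genes tile
the interval, and only the outer-probe interval is defined
unambiguously. Any CN = 0 call overlapping the locus is flagged as
anomalous and the sample is not called a carrier — homozygous loss of
this region is not expected in a living cohort, so it is surfaced
rather than absorbed.

The interval union is a ten-line sort-and-merge; the test suite checks
it against both a per-base-pair counting oracle and an independent
`IRanges` computation, and verifies monotonicity (extending or adding
calls never decreases the fraction) and order invariance.

## The phenotyping cascade

Phenotypes are assigned from coded clinical events (ICD-9/ICD-10
diagnoses, OPCS-4 procedures, self-reported illnesses and operations,
and death-register causes) by a deterministic cascade over named code
sets. The codebook is external configuration because curated code lists
are study-specific; the shipped default (Q20–Q28 congenital block, K165
PFO operation, I63/I64 stroke, I48 atrial fibrillation, I35/aortic-valve
procedures for the bicuspid-aortic-valve pattern, endocarditis
exclusions, F-chapter neuropsychiatric subsets) is a documented
stand-in, and analyses of real data should pin their own codebook.

For CVM, in order:

1. **Syndrome exclusion dominates everything.** Samples with syndromic
   codes linked to cardiovascular defects leave the cohort, keeping the
   case group non-syndromic.
2. **Congenital circulatory codes** make a case, except Q211, which is
   ambiguous between atrial septal defect (ASD) and patent foramen
   ovale (PFO) — a normal variant present in up to a quarter of the
   population that must not inflate the case group. Q211 evidence is
   voided when the history shows a PFO-specific closure operation
   (K165), or a stroke with no atrial-fibrillation code at or before it
   occurring strictly before the earliest Q211 (PFO is commonly found
   during a stroke workup; ASD, unlike PFO, predisposes to AF, so an
   AF-explained stroke does not point to PFO). A voided Q211 with no
   other case evidence excludes the sample from both groups.
3. **Congenital-heart operations and self-report** make a case;
   self-reported heart surgery counts only when performed before 18,
   since adult heart surgery is overwhelmingly acquired disease.
4. **Aortic-valve disease before 65** (stenosis, insufficiency, valve
   replacement; hospital-coded or self-reported) is taken as congenital
   bicuspid aortic valve, unless an exclusion such as endocarditis
   explains the valve damage; at 65 or older the far more likely
   explanation is age-related degeneration, so the sample leaves the
   control pool instead of becoming a case.
5. **Death-register causes** participate through the same sets (they
   are diagnosis codes; ICD-9 and ICD-10 code spaces cannot collide, so
   both pattern systems match them).
6. Remaining samples with acquired-defect codes are excluded from
   controls; a clean history is a control.

The neuropsychiatric axis is simpler: a code in the case subset
(schizophrenia spectrum, bipolar disorder, autism, intellectual
disability, developmental disorders) makes a case; any other
mental-and-behavioural code removes the sample from controls.
Cognitive analyses additionally drop anyone carrying a diagnosis
previously associated with the deletion.

Tie-breaking where the design was open: events are ordered by
`(age_at_event, tiebreak)`; a stroke and a Q211 at the same age with no
tiebreak information counts as "stroke prior" (conservative toward
purging PFO from the case group), while an AF code at the same age as a
stroke counts as "at or before" it (AF discovered during the stroke
admission is exactly the confounder the rule exists for). Age
thresholds (<65, <18) are strict, evaluated at the earliest qualifying
event. EXCLUDED reasons are a closed enumeration so downstream counts
are auditable, and excluded samples appear in neither margin of any
association table.

## The association battery

The 2×2 analysis uses the odds ratio `ad/bc`, the Woolf interval
`exp(log OR ± z·SE)` with `SE = √(1/a + 1/b + 1/c + 1/d)`, and the
Yates continuity-corrected chi-squared
`N·(max(|ad − bc| − N/2, 0))²/((a+b)(c+d)(a+c)(b+d))` on 1 df. The
clamp at zero is the conventional form of the correction (and what
`chisq.test()` computes); without it a table with identical rows would
not give p = 1. The continuity correction is the default because, at
these cell sizes (tens of carrier-cases against hundreds of thousands
of controls), the uncorrected statistic is anticonservative. If any
single cell is zero the Haldane–Anscombe correction (+0.5 to every
cell) is applied to the odds ratio and interval only, and flagged; a
zero case or control margin is an error, not a number.

Outcome models follow each outcome's distribution, adjusting for age
and sex with deletion carriage coded 0/1:

| outcome | preprocessing | family |
|---|---|---|
| reaction time (ms) | drop values > 5 SD from the mean | linear |
| fluid intelligence | none | Poisson (log link) |
| numeric memory | binarise ≤6 → 0, >6 → 1 | logistic |
| pairs matching (errors) | binarise 0 → 0, >0 → 1 | logistic |
| highest qualification | none | multinomial log-linear |
| fecundity (offspring count) | 5-SD rule + caps (>8 male, >7 female) | Poisson, sex-stratified |

The 5-SD rule is applied once, with mean and SD computed on the full
input — not iterated. Iterating would make the removal set depend on
its own output; the single pass is the minimal reading and is pinned by
a test constructing a value that only a second pass would remove. The
multinomial model pools all qualification categories other than
college/university degree and A/AS levels into a single baseline group
and reports per-category effects against it. Fecundity is fitted
per-sex as `count ~ deletion`, with a pooled
`count ~ deletion + sex + deletion:sex` model supplying the Wald
interaction p-value; age is omitted here deliberately, matching the
sex-stratified design. No multiple-testing adjustment is applied
anywhere: the battery reports per-outcome tests as-is.

## The synthetic cohort generator

The generator exists so the whole pipeline is testable without
access-controlled data, and its defaults are the study conditions, not
dials: deletion prevalence 0.38%; CVM and neuropsychiatric case
fractions of 0.59% and 0.72%; population odds ratios 1.73 and 1.84;
carrier effects of +17.8 ms on reaction time, log(5.40/5.99) ≈ −0.104
on the fluid-intelligence rate; per-sex fecundity means 1.66/1.80
(male carrier/non-carrier) and 1.88/1.82 (female); qualification
probabilities matching the observed carrier and non-carrier attainment
tables (implying a carrier degree log-odds of about −0.54 versus the
baseline group); QC failure rates 301/488,366 (waviness) and
1,401/488,366 (call-count excess). Where the source tables print no
value, a single realistic choice was made and kept: baseline
probabilities of 0.55 for numeric memory >6 and 0.35 for any
pairs-matching error with carrier log-odds −0.35 and +0.15
(directionally consistent with the observed score differences), mild
age and sex effects on each cognitive outcome so the covariate
adjustment is exercised, a background autosomal CNV mean of 3 calls per
sample, and 5 kb of per-boundary jitter on carriers' locus calls.

Two structural choices matter for interpretation:

- **The configured OR is the true population parameter.** Given overall
  prevalence `p`, carrier fraction `q` and target OR, the non-carrier
  risk `p0` solves `p = q·p1 + (1−q)·p0` with
  `odds(p1) = OR·odds(p0)` by 1-D root finding, and case status is
  drawn from the resulting per-group risks. Decoy labels are drawn
  among true controls independently of carrier status, so thinning the
  control pool leaves the OR untouched.
- **Decoys realise exactly the patterns the cascade must reject:**
  Q211+K165; an AF-free stroke dated before Q211; aortic stenosis at
  65+; a valve code plus endocarditis; a syndrome code alongside a
  congenital code. One case path adds a stroke explained by prior AF,
  so the disambiguation rule's *negative* branch is also exercised. The
  round-trip property — cascade output equals ground truth exactly, and
  genotyping recovers carrier status exactly for QC-passing samples —
  is asserted at n = 200,000 across seeds.

Carrier locus calls are jittered per boundary by at most ±J bp; the
validator rejects J large enough that a worst-case inward shrink could
break the 95% rule (for the default locus, J ≤ 6,843), so designated
carriers are carriers by construction. No CN = 0 call is ever emitted
at the locus. CVM and neuropsychiatric status are drawn independently
given carrier status: the source data report only that the two case
groups overlap in a handful of individuals, which is insufficient to
pin a dependence structure, so independence is the documented choice.

Dates are encoded as age-at-event (integer years, with an optional
fractional tiebreak for same-age ordering) rather than calendar dates:
the classifier needs only age thresholds and event order, and ages
avoid calendar edge cases. The generator draws from a single seeded
stream, fully vectorised; output is deterministic (byte-identical)
given the seed. Per-participant counter-derived substreams were
considered and dropped — base R exposes no cheap counter-based RNG API,
and the determinism invariant the pipeline relies on is the seeded one.

What the generator does **not** emulate: array intensities, B-allele
frequencies or probe-level data; informative missingness in cognitive
tests (outcomes are complete); correlated comorbidity structure beyond
the configured rates; calling-batch effects or ethnicity structure;
parent-of-origin effects. Passing tests therefore demonstrate that the
pipeline's logic and estimators are correct under the stated
generative model — not that the shipped default codebook reproduces any
specific real cohort's case counts.

## Problem sizes and numerical choices

Test and acceptance runs use sizes chosen to make the statistical
assertions sharp: ground-truth recovery and CI coverage of the true OR
at n = 200,000 over 20 seeds (coverage required in ≥18/20, the 3σ-style
scaled version of a ≥90/100 criterion); regression-battery recovery
within 3 SE at n = 100,000; the null fecundity-interaction uniformity
check over 200 replicates of n = 20,000 with carrier prevalence raised
to 2% (~400 carriers per replicate) so each replicate's Wald statistic
is in its asymptotic regime; Woolf CI coverage over 2,000 simulated
tables within ±2% of nominal. Root finding for `p0` uses `uniroot` at
tolerance 1e-14 on (0, 1); GLM fits are standard `stats::glm`/`lm` and
`nnet::multinom` maximum likelihood, with non-convergence and
degenerate inputs (single-carrier-class data, all-zero counts) raised
as classed fit errors rather than silent `NaN`s.

## Known limitations

- The default codebook is a structural stand-in; real analyses must
  supply curated code lists, and case counts from the default are not
  comparable to any published cohort.
- Only deletions are genotyped at the locus; duplication (CN ≥ 3)
  carriers are not identified, and no GRCh38 liftover is provided.
- The engine consumes hospital, self-report and death-register codes;
  primary-care records are out of scope.
- Adjusted multinomial odds from real data are not exactly reproducible
  from published frequency tables (the published estimates are
  age/sex-adjusted on individual-level data); the package asserts only
  that raw odds computed from such tables are consistent with the
  published adjusted intervals.
- The Woolf interval and Yates test are the defaults because they are
  the estimators the reported quantities use; exact conditional
  methods are not implemented.
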