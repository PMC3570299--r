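---
title: "Methods: weighted glycaemic risk scores in mother–offspring duos"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted glycaemic risk scores in mother-offspring duos}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(duoscore)
```

## The design

Mendelian randomization uses genetic variants as instruments for a
modifiable exposure: alleles are assorted at conception, so — absent
population stratification — genotype–outcome associations are protected
from the lifestyle confounding and reverse causation that afflict
observational contrasts. The mother–offspring *duo* design adds a second
lever: a maternal score affects the child both through the intrauterine
environment and through the ~50% of alleles the child inherits. Mutually
adjusting the maternal and offspring scores separates the two paths — the
coefficient on the maternal score, adjusted for the child's own score,
isolates the intrauterine (maternal genotype) effect.

`duoscore` implements this design around two published weighted scores for
glycaemic traits: a 16-variant fasting-glucose score (FGGRS, per-allele
weights in mmol/l) and a 22-variant type 2 diabetes score (T2DGRS, weights
on the log-odds scale), eight variants being shared. Each score is

$$S = \frac{\sum_i w_i g_i}{W}\,K,$$

with $g_i$ the risk-allele count, $W$ the total-effect denominator and $K$
the SNP count, so that one unit of $S$ is one "weighted allele" and
complete-data scores lie in $[0, 2K]$.

## The variant catalogue

The packaged catalogue (`inst/extdata/variant_catalog.tsv`) records, for 38
child-typed SNPs (35 also typed in mothers; the three ADIPOQ variants are
child-only), the major/minor alleles, minor-allele frequencies in mothers,
children and the CEU reference panel, the risk-allele orientation, trait
tags, and score weights. Orientation matters: genotypes are stored as
minor-allele dosages, but for many variants the trait-raising allele is the
*major* allele, so scoring complements the count (`2 − g`). Two catalogue
rows are LD proxies genotyped in place of the SNP whose published weight
they carry (GCK rs1799884 for rs4607517 at r² = 1.0; ADCY5 rs2877716 for
rs11708067 at r² = 0.8); `resolve_proxies()` records the substitutions and
warns below a configurable r² floor (default 0.5) while still applying the
substitution, as published practice did at r² = 0.8. One source table lists
the IGF2BP2 variant as rs4402690 where the score formula uses rs4402960; the
catalogue stores rs4402960 as canonical with rs4402690 as an alias, since
the formula governs computation.

Validation notes:

* Cohort minor-allele frequencies must lie in (0, 0.5]. The CEU column is
  the frequency *of the cohort's minor allele* in the reference panel, where
  that allele is sometimes the commoner one (printed values up to 0.54), so
  it is validated in (0, 1) and stored as printed.
* Exactly 16 records carry a fasting-glucose weight, 22 a diabetes weight,
  8 both; violations are load-time errors naming the offending row.

## Score construction choices

* **Denominator.** The published T2DGRS formula divides by 2.86, but its 22
  printed weights sum to 2.89. The package defaults to the published
  constant for fidelity and reports both in the build audit;
  `consistent_denominator = TRUE` substitutes the true sum. The discrepancy
  rescales scores by ~1%, well below sampling noise at realistic n.
* **Missing genotypes.** Three policies are implemented: `zero_fill`
  (missing terms contribute nothing; the default), `complete_case`, and
  `renormalize` (per-individual denominator from observed weights). All
  three coincide on complete data and all keep scores in $[0, 2K]$. The
  source study does not state its handling; notably, the analytic
  Hardy–Weinberg mean computed from the catalogued children's frequencies
  (17.1 weighted alleles for the FGGRS, 22.6 for the T2DGRS — see
  `analytic_score_moments()`) already matches the observed cohort means, so
  no missingness mechanism needs to be invoked to reconcile them.
* Scores are kept at full precision; only display layers round.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without
access to individual-level cohort data. It emulates the *statistical
structure the analysis assumes*, not the cohort itself:

* **Founders** (mothers) are drawn per SNP from Hardy–Weinberg proportions
  at the catalogued frequencies, independently across SNPs. With
  `n_subpops > 1`, subpopulations get frequencies shifted by
  ±`maf_divergence` (clipped to (0.01, 0.5]), producing the Wahlund
  heterozygote deficit in pooled samples and a recoverable PCA axis.
* **Transmission** passes one uniformly chosen maternal allele plus one
  paternal allele drawn from the (subpopulation-matched) population
  frequency; fathers are not represented as individuals because the design
  has no paternal genotypes. This yields the exact Mendelian constraints
  (a mother without an allele cannot transmit it) and the additive
  parent–offspring genotype correlation of 1/2 on which the duo adjustment
  rests.
* **LD proxies** are built by a haplotype copy scheme — each proxy allele
  copies the index allele with probability √r², else is an independent draw
  at the same frequency — the simplest construction achieving a target r²
  for an equal-frequency pair.
* **Phenotypes.** Fasting glucose and HbA1c are linear in the child's
  centred FGGRS with Gaussian residuals; IQ is linear in the centred
  maternal and offspring scores (T2DGRS by default), an optional maternal
  diabetes/glycosuria shift, and optional confounder terms; maternal
  diabetes/glycosuria is Bernoulli-logistic in the mother's centred T2DGRS
  with the intercept solved numerically (uniroot on the sample mean of the
  linked probabilities) so the marginal prevalence matches the
  configuration. Scores are centred at their *analytic* Hardy–Weinberg
  means so configured intercepts are interpretable as population means.
* **Missingness** is completely at random at a per-call rate (no mechanism
  is documented for the source data). After transmission, maternal columns
  for the three child-only variants are blanked, reproducing the 35/38
  typed-panel asymmetry.

Default calibration (units as stated, chosen once from the study's printed
summary statistics): fasting glucose intercept 4.88 mmol/l (female
baseline) with a +0.13 mmol/l male effect and residual SD 0.39, matching
the reported overall 4.95 ± 0.39 and the reported sex contrast; HbA1c
4.91 ± 0.31%; IQ 104.4 ± 16.4 with 49.9% boys and child age 8.58 ± 0.27
years; glucose and HbA1c effects of the child FGGRS 0.02 per weighted
allele (the fitted instrument-validation values); maternal
diabetes/glycosuria prevalence 0.05 (not printed in the source; a
plausible obstetric figure, configurable); all IQ effects (scores,
diabetes, confounders) default to zero so the base generator is a null
model, with scenario knobs for recovery studies. Exposed mothers are split
among pre-existing diabetes / gestational diabetes / glycosuria at fixed
0.2/0.4/0.4 proportions — only the combined binary enters any analysis, so
this split is cosmetic. The background panel for stratification PCA
defaults to 200 unlinked markers with frequencies uniform on (0.05, 0.5):
enough for clean subpopulation recovery at simulation scale, while the
source study's genomewide panel is out of scope.

What the generator does **not** emulate: linkage disequilibrium between
panel SNPs (beyond explicit proxy columns), assortative mating, parental
phenotype effects on confounders, informative missingness, measurement
error in phenotypes, and real ancestry gradients (structure is a discrete
mixture). Passing recovery tests therefore demonstrates the *estimators*
are correct under the assumed data-generating process, not that the source
cohort's estimates are reproduced — individual-level cohort data are not
deposited, and the cohort-specific estimates are deliberately not
acceptance quantities.

## Quality control and stratification

* **Hardy–Weinberg testing** uses the classical 1-df goodness-of-fit
  chi-square against expected counts at the sample allele frequency, the
  test the era's Stata tooling implemented; exact tests are out of scope.
  SNPs are *flagged* at p ≤ 0.02 — a reporting convention, not an exclusion
  rule (the source study kept its flagged SNPs, noting chance
  compatibility) — and a monomorphic SNP reports p = 1 with a degeneracy
  note rather than erroring, for robustness on small simulations.
* **Bonferroni thresholds** are α/n with a display value rounded to one
  significant figure (0.05/38 → 0.001), mirroring how such cut-offs are
  quoted.
* **PCA** follows the standard genotype-PCA recipe: mean-impute missing
  calls, centre each SNP and scale by √(p̂(1−p̂)), then take the top-k
  singular vectors. Monomorphic columns are dropped. Sign indeterminacy is
  resolved by making each component's largest-magnitude loading positive,
  so results are byte-reproducible. The smartpca outlier-removal loop is
  not reimplemented. Analyses adjust for the top 10 components by default,
  reduced with a warning when the background panel cannot support 10.

## Association machinery

* **OLS** (`ols_fit`) uses conventional standard errors and listwise
  deletion, reporting the n actually used; rank deficiency is an error
  naming the collinear columns. Nothing in the source indicates robust
  errors. 95% CIs are beta ± 1.96·se.
* **Confounder scans** test every exposure × covariable pair —
  categorical↔categorical by uncorrected chi-square (no Yates correction
  is mentioned in the source), anything else by the linear-regression slope
  test — and report the expected nominal count `round_half_away(α·n)`.
  Half-away rounding is the only rule consistent with both published
  expected counts (28.5 → 29 for 570 tests, 26.25 → 26 for 525).
  Untestable pairs (constant columns) are excluded from the denominator.
  The default covariable preset has 15 entries: thirteen confounder columns
  (with alcohol before and during pregnancy as two variables) plus child
  sex and age, matching the published "15 confounders" count.
* **Clinical rules.** Diabetes classification fires at fasting glucose
  ≥ 7.0 mmol/l *or* HbA1c ≥ 6.5% (missing measurements never qualify; both
  missing → missing). Glycosuria requires ≥ 2 occasions at ≥ 13.9 mmol/l;
  mg/dl inputs are converted at 18.016 mg/dl per mmol/l and compared at
  one-decimal precision, the precision at which the two published
  thresholds (13.9 mmol/l, 250 mg/dl) are equivalent. The combined
  maternal exposure uses precedence pre-existing > gestational > glycosuria.

## Pipeline and reproducibility

`run_study()` executes QC → PCA → scores → instrument validation →
offspring-IQ models → maternal-vs-offspring models → diabetes contrast →
confounder scan, each stage optional, with a participant-flow ledger so
every reported n traces to an inclusion step or listwise deletion. Reports
serialise to JSON (validated structurally against the shipped schema) and
plain text. Everything is deterministic given the configuration seed; the
only RNG consumer is the generator.

`replicate_study()` re-runs the pipeline across consecutive seeds and
summarises recovery (mean estimate, Monte-Carlo SE, empirical 95% CI
coverage). The shipped acceptance script uses it at the study's own sample
sizes — 573 (glucose arm), 1037 (HbA1c arm), 1102 duos (adjusted maternal
model), 6000 (diabetes contrast), 6272 (null IQ calibration) — with 200
replicates per quantity, sizes chosen to match the study while keeping a
full run in the minutes range on one core. The package's test suite uses
the same machinery at mostly smaller n, plus large single draws (10⁵
individuals) for law-of-large-numbers checks of frequencies, correlations
and analytic moments.

## Known limitations

* No formal instrumental-variable (Wald/two-stage) causal estimator: the
  design reports score–outcome regressions, as the source analysis did.
* No logistic or survival outcome models; the diabetes/glycosuria outcome
  is analysed only as an exposure contrast on IQ.
* The LD-proxy construction assumes equal allele frequencies for index and
  proxy; unequal-frequency LD simulation would need a haplotype-frequency
  parameterisation.
* The confounder generator draws independent marginals; it cannot by
  default reproduce the confounder–confounder and exposure–confounder
  correlations a real cohort shows (these are available as opt-in effect
  knobs, not defaults, because the source reports contrasts rather than
  usable generative parameters).
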