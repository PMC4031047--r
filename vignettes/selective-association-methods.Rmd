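---
title: "Methods: penalized-likelihood selection of subtype-selective association models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: penalized-likelihood selection of subtype-selective association models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(migselect)
```

## The question and the data reduction

Given hard-call genotypes for a SNP panel and a phenotype table in which
active migraineurs carry ten binary attack characteristics (aura, pulsating
pain, unilateral pain, phonophobia, photophobia, 4–72 h duration, nausea,
aggravation by physical activity, inhibition of daily activities, ≥6
attacks/year), `migselect` asks whether each SNP's association with migraine
is *selective* for each characteristic. Every SNP × characteristic analysis
reduces to six numbers: the minor-allele count and allele total in (a) cases
with the characteristic, (b) cases without it, and (c) non-cases
(`tabulate_trigroup()`). Former migraineurs, who are not sub-classified,
are excluded from these analyses; they form group (b) of the separate
`active_vs_former` partition, which asks whether associations differ between
current and remitted migraine. Individuals with a missing call at a SNP are
dropped from all three groups for that SNP only (complete case per SNP) —
the inputs are hard calls and the likelihood is defined on allele counts, so
dosage data must be rounded upstream.

## The likelihood and the six models

Within each group the two alleles of an individual are treated as
independent Bernoulli draws (Hardy–Weinberg within group), so
k_g ~ Binomial(n_g, p_g) with n_g twice the retained individuals. The six
inheritance models are equality constraints on (p_a, p_b, p_c): `null` (one
frequency, 1 df), `basic` (cases vs non-cases, 2 df), `subset` (free
frequency in cases-with, 2 df), `inverse_subset` (free in cases-without,
2 df), `modifier` (free case sub-group frequencies with the non-case
frequency pinned to their weighted mean, 2 df), and `general` (all free,
3 df). The modifier expresses association with the characteristic
*conditional on* having migraine — the pooled case pool looks like the
controls, but the two sub-groups differ.

All log-likelihoods drop the binomial coefficient, which is common to every
model at fixed data and cancels in all comparisons; boundary MLEs use the
0·log 0 = 0 convention. Every model except the modifier has closed-form
MLEs: each free parameter is the pooled sample frequency of the groups it
spans. The modifier is maximized numerically: the constrained likelihood is
concave in (p_a, p_b), and we run BFGS on the logit scale with analytic
gradients (relative tolerance 1e-12, started at the sample frequencies, a
short-circuit when the unconstrained optimum already satisfies the
constraint). The weight is w = n_a/(n_a + n_b) by default — the source
method says only "weighted mean", and allele-total weighting is the natural
sample-size reading; `modifier_weight = "equal"` is available.

## Selection, penalties and the LLR test

`select_inheritance_model()` minimizes BIC = −2ℓ + k·log(n) (default) or
AIC = −2ℓ + 2k. The BIC sample size n is the number of *individuals* in the
three groups, the usual convention; `bic_n = "alleles"` switches to allele
counts. Ties go to fewer degrees of freedom, then to the fixed order null,
basic, subset, inverse_subset, modifier, general — so exact ties always
resolve toward the simpler, earlier-listed model and selection is
deterministic. The selected model is scored by Λ = 2(ℓ_selected − ℓ_null)
with an analytic upper-tail chi-square p on df_selected − 1. The source
description of this test reads "twice the difference in the degrees of
freedom"; we use the plain difference, which is what standard asymptotics
give. The choice is immaterial downstream: the analytic p serves only to
*rank* observed data against permutation replicates, and any monotone
transformation yields identical empirical p-values. A null selection is
reported with Λ = 0 and p = 1 exactly.

## Permutation calibration and the two-stage correction

Because the selection procedure itself (not just one test) must be
calibrated, `permutation_significance()` reassigns genotypes to individuals
at random — one permutation of individual labels per replicate, applied
jointly to all SNPs, preserving the inter-SNP genotype correlation and the
phenotype structure — and repeats the whole selection. Per cell it reports
the non-null selection fraction and the empirical p: the fraction of
replicates whose analytic p is at or below the observed one, where a
null-selecting replicate contributes p = 1. Stage 1 corrects across the ten
characteristics per SNP by rank statistics (the observed r-th smallest p is
compared with the permutation distribution of r-th smallest values); stage
2 applies Šidák, 1 − (1 − p)^m, across SNPs (m defaults to the number of
SNPs in the panel).

Three conventions are exposed because the source wording fixes none of
them. (1) Fractions are plain r/B by default ("the fraction of"); the
(r+1)/(B+1) convention, which is a strictly valid p-value where r/B is
anti-conservative by ~1/B, is available via `convention = "add_one"`.
(2) Null-selecting replicates are pooled with p = 1 by default;
`condition_on_nonnull = TRUE` restricts the comparison to non-null
replicates. (3) Ties: the default counts a whole tied block as "≤
observed". Since most null replicates select the null model and tie at
p = 1 exactly, the default empirical p carries a point mass at 1 — it is
conservative there, not uniform. `ties = "random"` places the observed
value uniformly within its tied block (the standard randomized-p device for
discrete permutation tests), making the empirical p exactly discrete-uniform
under exchangeability; this is the form used when checking calibration, while
the default remains the faithful reporting convention.

One master seed spawns a per-replicate seed stream, so results are
reproducible and independent of execution order.

## Stratified effects, the coded allele, and clustering

For presentation and clustering, per-stratum effects come from unadjusted
logistic regression of case status on allele dose (0/1/2, additive), cases
being active migraineurs with (or without) the characteristic and controls
never-migraineurs, plus an overall active-vs-never column. Under within-group
HWE the genotype logit is exactly linear in dose, and because each fit
depends on the data only through the 3 × 2 dose-by-status table, fits use the
aggregated counts (identical estimates, far cheaper). The coded allele is
the one associated with increased odds of *any* migraine (active ∪ former vs
never); all betas are re-signed to it, so the overall any-migraine effect is
non-negative by construction. Separation or non-convergence is flagged in a
`converged` column with a warning rather than returned as silent NaN. A
guard (default ≥10 cases and ≥10 controls) rejects degenerate strata.

Selectivity profiles are t_c = (β_with,c − β_without,c)/√(SE²_with + SE²_without)
per characteristic, a 10-vector per SNP. Their null covariance — the
correlation induced by overlapping strata (a case with photophobia is often
also a case with nausea) — is estimated as the sample covariance of
t-vectors over a panel of SNPs with no migraine association. The original
analysis took such a panel from an external catalog; since that panel is not
distributed, the shipped pipeline simulates the null panel against the same
cohort (`simulate_null_tstats()`, default 1,222 SNPs with MAF uniform on
0.2–0.4), which reproduces the stratum-overlap correlation exactly because
it is a property of the phenotype structure, not of the SNPs. Pairs of SNPs
are compared by the Mahalanobis distance √((x−y)ᵀΣ⁻¹(x−y)) — Euclidean
distance after whitening by the Cholesky factor of Σ⁻¹ — with a
Moore–Penrose fallback and warning if Σ is singular. Hierarchical
clustering uses complete linkage by default (the default of the classical
agglomerative routine the original analysis called; single/average are
options), on unsquared distances; the leaf order sorts the effect-matrix
report and the dendrogram exports as Newick with merge heights as branch
lengths.

## The synthetic cohort

`simulation_scenario()` defaults encode the reference study conditions:
3,003 active, 2,119 former and 18,108 never-migraineur women, and the ten
characteristic prevalences taken from the reference counts (aura 1,177/3,003
= 0.39, photophobia 0.66, 4–72 h duration 0.78, ...). Characteristics are
drawn independently per active case by default; real features co-occur, so
an exchangeable latent-normal correlation `rho` is available, but no
published co-occurrence rates exist to set it from, and the default stays 0.
Genotypes are Binomial(2, p_g) per individual with p_g set by the SNP's
generating model and anchoring characteristic; SNP MAF defaults lie in
0.2–0.4, a typical common-variant range, since the true panel MAFs are not
printed. Modifier scenarios compute the control frequency from the realized
case sub-group sizes, so the generating constraint holds exactly in
expectation. Former migraineurs are assigned the prevalence-weighted mean of
the case sub-group frequencies — consistent with the empirical finding that
former and active migraineurs show similar overall association — and are
group (b) under the `active_vs_former` anchoring. `simulate_trigroup_counts()`
draws the sufficient statistics directly (k_g ~ Binomial(n_g, p_g)), which
is what calibration and recovery studies use at full and tenfold scale.

What the generator deliberately omits: linkage disequilibrium between SNPs,
population structure, imputation-dosage noise, covariate-phenotype
confounding, and characteristic co-occurrence beyond exchangeable
correlation. Passing tests therefore demonstrate correctness of the
machinery under the model's own assumptions, not robustness to stratified
or relatedness-confounded cohorts.

## Numerical choices and problem sizes

Tests and calibration runs use sizes chosen to exercise the asymptotics the
method relies on while staying desk-sized: the null calibration and AIC
chance-rate checks run 1,000–2,000 count-level replicates at the full
reference group sizes; model recovery runs 100 replicates per generating
model at tenfold scale with frequency separations of 0.02–0.08 (the
`general` scenario is placed well off the modifier's constraint surface —
with a control frequency near the weighted case mean, the 2-df modifier is
the correct BIC choice over the 3-df general, a genuine identifiability
boundary rather than a defect); permutation uniformity uses 20 null SNPs ×
10 characteristics at B = 200 with a cohort of 1,600. The pipeline's
end-to-end examples use cohorts of 1,200–5,300 with 60–500 permutations.

Other numerical details: minor-allele orientation ties at frequency 0.5
break alphabetically; selection ties break toward fewer df then fixed model
order; modifier optimization tolerance 1e-12 on the logit scale; empty
groups and monomorphic SNPs raise errors rather than producing degenerate
fits; the chi-square cohort-summary test uses no continuity correction,
which reproduces the reference demographic table's printed p-values from
its own counts; the t-test is pooled-variance by default with a Welch
option.

## Known limitations

The likelihood is allele-based; a genotype-level multinomial (robust to HWE
violations within groups) is out of scope, as are covariate-adjusted
likelihoods, X-chromosome handling, and mixed-model relatedness correction.
The analytic LLR p is a ranking device — model-selection pretesting makes
its chi-square reference nominal, which is precisely why the permutation
layer exists. The plain r/B empirical fractions are anti-conservative by
~1/B (use `convention = "add_one"` for strict validity at small B). With
B permutations the smallest attainable corrected p is 0; reporting at
B = 10,000 matches the source procedure, but conclusions at p near 1/B
deserve a larger B.
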