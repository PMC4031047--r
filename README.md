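# migselect

Migraine is clinically heterogeneous: beyond the classic with-aura (MA) /
without-aura (MO) dichotomy, attacks differ in photophobia, phonophobia,
nausea, pain character, duration and frequency. `migselect` asks, for each
candidate SNP, whether its association with migraine is **selective** for one
of these characteristics — stronger among migraineurs who report the feature
than among those who do not — rather than an undifferentiated case-control
signal. It is aimed at statistical geneticists and headache epidemiologists
working with case-control cohorts in which active migraineurs carry binary
attack-feature indicators.

## The model

For a SNP and a characteristic, individuals fall into three groups: (a)
cases with the characteristic, (b) cases without it, (c) non-cases. Under
Hardy-Weinberg equilibrium within group, the minor-allele count k_g out of
n_g = 2 m_g alleles in group g is Binomial(n_g, p_g), and six nested
constraints on (p_a, p_b, p_c) define the inheritance models:

| model          | constraint                            | free parameters |
|----------------|---------------------------------------|-----------------|
| null           | p_a = p_b = p_c                       | 1 |
| basic          | p_a = p_b, p_c free                   | 2 |
| subset         | p_a free, p_b = p_c                   | 2 |
| inverse subset | p_b free, p_a = p_c                   | 2 |
| modifier       | p_c = w·p_a + (1−w)·p_b               | 2 |
| general        | all free                              | 3 |

Each model is fit by maximum likelihood (closed-form pooled frequencies,
except the modifier, which is maximized numerically) and the model minimizing
BIC = −2ℓ + k·log(n) or AIC = −2ℓ + 2k is selected. The selected model is
scored by the log-likelihood-ratio statistic against the null with an
analytic chi-square p-value, which is then calibrated empirically: genotypes
are randomly reassigned to individuals (10,000 times by default), the entire
selection procedure is repeated, and per cell the non-null selection
fraction and the empirical p are reported. Multiple testing is corrected in
two stages — per-SNP rank statistics across the 10 characteristics, then a
Šidák correction 1 − (1 − p)^m across SNPs.

To interpret selected models, per-stratum effects are estimated by logistic
regression of case status on allele dose (coded allele = the allele that
increases the odds of any migraine), and SNPs are clustered by the
10-vector of normalized with/without effect differences
t_c = (β_with − β_without)/√(SE²_with + SE²_without) under a Mahalanobis
metric whose covariance comes from a panel of non-associated SNPs.

A synthetic-cohort generator reproduces the structure this analysis assumes
(default group sizes 3,003 active / 2,119 former / 18,108 never-migraineur;
the ten characteristic prevalences; HWE genotypes under any of the six
generating models), so every stage is testable without private cohort data.

## Worked example

```r
library(migselect)
library(dplyr)

sc <- simulation_scenario(
  n_active = 1000, n_former = 300, n_never = 4000,
  snps = bind_rows(
    scenario_snp("rs_null",  "null",   maf = 0.30),
    scenario_snp("rs_basic", "basic",  p_case = 0.33, p_ctrl = 0.28),
    scenario_snp("rs_aura",  "subset", characteristic = "aura",
                 p_with = 0.38, p_ctrl = 0.28)
  )
)
dat <- simulate_cohort(sc, seed = 42)

sel <- analyze_selection(dat$genotypes, dat$phenotypes, criteria = "bic")
selection_model_matrix(sel)
#>   snp_id   aura  pulsation unipain sound     light ...
#> 1 rs_null  -     -         -       -         -
#> 2 rs_basic basic basic     basic   inv. sub. basic
#> 3 rs_aura  sub.  basic     basic   basic     sub.
```

The null SNP draws `-` everywhere; the overall-association SNP draws
`basic`-type models; the aura-selective SNP is called `sub.` in its
generating cell. Permutation calibration of that cell:

```r
pm <- permutation_significance(dat$genotypes, dat$phenotypes,
                               n_permutations = 500, seed = 42,
                               criterion = "bic")
pm |> filter(snp_id == "rs_aura") |> arrange(sidak_p) |> head(3)
#>   snp_id  characteristic selected llr_stat llr_p_analytic frac_nonnull empirical_p rank_adjusted_p sidak_p
#> 1 rs_aura aura           subset      55.80       8.04e-14        0.022       0.000           0.000 0.00000
#> 2 rs_aura light          subset      10.26       1.36e-03        0.016       0.004           0.002 0.00599
#> 3 rs_aura pulsation      basic        9.24       2.37e-03        0.014       0.008           0.006 0.01789
```

The aura cell beats all 500 permutations (`empirical_p = 0`) and survives
both correction stages (`sidak_p = 0`). The stratified effects show why —
the minor allele raises the odds of migraine-with-aura (β = 0.56) but not
migraine-without-aura (β = −0.13, n.s.):

```r
estimate_stratified_effects(dat$genotypes, dat$phenotypes) |>
  filter(snp_id == "rs_aura", characteristic == "aura")
#>   snp_id  characteristic stratum    beta     se        p n_cases n_controls
#> 1 rs_aura aura           with     0.558 0.0766 3.14e-13     404       4000
#> 2 rs_aura aura           without -0.135 0.0714 5.90e-02     596       4000
```

`run_full_analysis(run_config(scenario = sc, seed = 42), out_dir = "out")`
writes the full report bundle (model matrices with significance stars,
permutation summaries, stratified effects, the cluster-ordered effect
matrix, a Newick dendrogram, cohort summary tables and a JSON manifest);
`inst/scripts/migselect` wraps the same call for shell use with a YAML
config.

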