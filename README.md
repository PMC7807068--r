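# riskforest

Post-GWAS gene–lifestyle risk profiling for right-censored cohort
studies. `riskforest` implements, as a tested and reusable pipeline, the
three analytic layers used to build breast-cancer risk profiles from a
candidate SNP panel plus lifestyle exposures in large postmenopausal
cohorts:

1. **Random survival forest (RSF) variable selection**, written from
   scratch (C++ core): bootstrap trees split by the standardized two-sample
   log-rank statistic, Nelson–Aalen terminal cumulative hazards, out-of-bag
   (OOB) Harrell concordance, minimal depth (MD), permutation importance
   (VIMP), and the *two-stage multimodal* screen — stage 1 filters SNPs and
   lifestyles in separate forests by MD/VIMP agreement; stage 2 ranks the
   survivors by MD, fits the nested sequence of forests, and keeps
   variables whose **drop error** `d_k = e_{k-1} − e_k` (null-model error
   fixed at 0.5) reaches a threshold δ = 0.005.
2. **Generalized multifactor dimensionality reduction (GMDR)** for
   gene–gene interaction search: covariate-adjusted score residuals,
   high/low multilocus cell classification, 10-fold testing balanced
   accuracy (TBA), cross-validation consistency (CVC), permutation
   p-values, and the best-model rule (highest TBA with CVC 10/10 and
   p < 0.05, with a CVC-first fallback).
3. **Cox risk profiling**: risk-genotype and risk-lifestyle coding, the
   combined 0/1/2 gene–lifestyle score `C = G + B`, dose–response and
   joint-effect tables with Benjamini–Hochberg correction, trend tests,
   multiplicative (product-term HR) and additive (RERI) interaction, and
   Schoenfeld proportional-hazards diagnostics.

Because the motivating cohort data are access-restricted, the package
includes a calibrated synthetic-cohort generator (Hardy–Weinberg
genotypes, realistic lifestyle margins, exponential survival with
plantable main and interaction effects, administrative censoring with a
mean 16-year follow-up and a 5.28% event fraction) so the entire pipeline
is testable end to end. Utilities for cohort I/O, genotype QC
(missing-call rate < 2%, exact Hardy–Weinberg p ≥ 1e-4) and the five
standard obesity strata (BMI 30 kg/m², waist 88 cm, waist-to-hip ratio
0.85, 10 MET-h/week, 9% calories from saturated fat) round out the
toolkit.

## Worked example

```r
library(riskforest)

spec <- sim_spec(n = 3000, n_snps = 30,
                 log_hr = c(SNP_010 = log(2), SNP_020 = log(1.8),
                            bmi = 0.05))
coh <- qc_filter(simulate_cohort(spec, seed = 1))
coh
#> <cohort> 3000 subjects, 160 events, 30 SNPs, 23 covariates

frame <- as_analysis_frame(coh)
sel <- select_variables(frame,
                        snps = colnames(coh$genotypes),
                        lifestyles = c("bmi", "alcohol_g_day", "oc_years",
                                       "ep_years", "age"),
                        forest = forest_config(n_trees = 200,
                                               vimp_reps = 3, seed = 1))
head(tidy(sel$stage2), 5)
#> # A tibble: 5 × 9
#>   variable minimal_depth     vimp md_rank vimp_rank cindex error drop_error
#>   <chr>            <dbl>    <dbl>   <int>     <int>  <dbl> <dbl>      <dbl>
#> 1 SNP_020          0.765  0.0425        1         1  0.511 0.489    0.0114
#> 2 bmi              1.04   0.00945       2         3  0.596 0.404    0.0844
#> 3 SNP_010          1.27   0.0285        3         2  0.644 0.356    0.0480
#> 4 SNP_028          1.91  -0.00437       4         5  0.648 0.352    0.00390
#> 5 SNP_025          2.26   0.00433       5         4  0.659 0.341    0.0113
sel$stage2$selected
#> SNP_020, bmi, SNP_010, SNP_025
```

Both planted SNPs and the planted BMI effect survive the two-stage
screen (one noise SNP slips in — at 200 trees the drop-error noise floor
is near δ; see the vignette). The nested c-index climbs from 0.511 with
one variable to 0.66 with five; each variable's `drop_error` is the OOB
error reduction it contributes on entry.

```r
scores <- gmdr_scores(frame, covariates = "bmi")
pool <- intersect(sel$stage2$selected, colnames(coh$genotypes))
gm <- gmdr_search(scores, frame[pool], pool, max_order = 2,
                  n_perm = 199, strata = frame$event, seed = 1)
gmdr_select_best(gm)
#>   order model               tba   cvc p_value significant
#> 1     2 SNP_020 + SNP_010 0.609    10   0.005 TRUE
```

The order-2 model pairing the two planted SNPs wins every
cross-validation fold (CVC 10/10) with testing balanced accuracy 0.609
and permutation p = 0.005 (the floor of 199 permutations).

```r
coding <- derive_risk_coding(frame, pool)
frame$G <- assign_risk_genotype(frame, coding)$G
frame$B <- assign_risk_lifestyle(frame)$B      # alcohol >= 18 g/d, E+P >= 10 y,
frame$C <- combine_gene_lifestyle(frame$G, frame$B)  # OC < 5 y, BMI >= 30
frame$heavy_alcohol <- as.integer(frame$alcohol_g_day >= 18)
jt <- joint_effect_table(frame, "C", "heavy_alcohol", covariates = "age")
dplyr::filter(jt, stratum == "total")
#>   stratum level     n    hr conf.low  p.value p.adjusted
#> 1 total       0   838 1        NA    NA       NA
#> 2 total       1  1914 0.964    0.664  0.846    0.909
#> 3 total       2   248 2.70     1.69   3.35e-5  6.71e-5
attr(jt, "p_trend")
#> 0.00147
```

Subjects at high risk for *both* genotypes and lifestyles (`C = 2`) carry
2.7 times the hazard of the low-risk reference, with a significant
dose–response trend — the gene–lifestyle synergy pattern the pipeline is
designed to surface.

`autoplot()` methods cover the MD-vs-VIMP agreement plot, the nested
c-index curve, cumulative-incidence curves by group
(`plot_cumulative_incidence()`), and a forest plot of the joint-effect
table. `run_pipeline(pipeline_config(...), out_dir)` orchestrates the
whole analysis (simulate/read → QC → strata → selection → GMDR →
profiling) with deterministic stage seeds and a JSON manifest;
`inst/scripts/run_pipeline.R` is a thin command-line wrapper.

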