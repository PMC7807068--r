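---
title: "Gene-lifestyle risk profiling with survival forests, GMDR and Cox models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-lifestyle risk profiling with survival forests, GMDR and Cox models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riskforest)
```

## The problem this package addresses

Post-GWAS risk profiling asks how a panel of candidate SNPs and a set of
lifestyle exposures jointly predict a right-censored disease outcome — here
modelled on incident invasive breast cancer in a large postmenopausal
cohort (on the order of 10,000 women followed for a mean of 16 years, with
an event fraction of roughly 5%). The pipeline has three analytic layers:

1. **Two-stage multimodal variable selection** with random survival
   forests (RSF): stage 1 screens SNPs and lifestyles in separate forests;
   stage 2 combines the survivors, orders them by minimal depth, and keeps
   variables that demonstrably improve out-of-bag (OOB) prediction in a
   nested-model error sequence.
2. **Generalized multifactor dimensionality reduction (GMDR)** over the
   selected SNPs to find the best gene–gene interaction model, judged by
   testing balanced accuracy (TBA), cross-validation consistency (CVC) and
   a permutation p-value.
3. **Risk-profile Cox models**: SNPs and lifestyles are dichotomized into
   risk categories, combined into a 0/1/2 gene–lifestyle score, and
   dose–response, joint and interaction effects are estimated with
   proportional-hazards regression, Benjamini–Hochberg adjustment and
   Schoenfeld diagnostics.

Because cohorts of this kind are access-restricted, the package ships a
calibrated synthetic-cohort generator; every stage is exercised and tested
against it.

## The random survival forest

Each of `n_trees` trees is grown on a bootstrap sample (on average
$1-e^{-1} \approx 63.2\%$ distinct subjects; the remaining ~36.8% are that
tree's OOB set). A node is split by the candidate (variable, value) pair
maximizing the absolute standardized two-sample log-rank statistic

$$ S = \frac{\sum_k \left(d_{k1} - d_k Y_{k1}/Y_k\right)}
{\sqrt{\sum_k d_k \frac{Y_{k1}}{Y_k}\left(1-\frac{Y_{k1}}{Y_k}\right)
\frac{Y_k-d_k}{Y_k-1}}}, $$

summed over distinct event times $k$, with `mtry` (default
$\lceil\sqrt p\rceil$) candidate variables per node and up to `nsplit`
(default 10, deduplicated) random candidate split values per variable —
the randomized-split strategy standard for survival forests. A split must
leave at least `min_node_events` (default 3) events in each daughter;
otherwise the node becomes terminal and stores the Nelson–Aalen cumulative
hazard of its in-bag members, evaluated on the pooled grid of event times.
Genotype dosages (0/1/2 minor-allele counts) are split as ordered numeric
values; categorical covariates are one-hot expanded.

Predictions average the terminal cumulative hazards over trees; the
cumulative incidence is $1-\exp(-\mathrm{CHF})$, and the *ensemble
mortality* (the CHF summed over the grid) is the risk score used for
Harrell's concordance. The OOB concordance restricts each subject's
average to trees where the subject was out of bag; OOB error is
$1-c$. Two rankings drive selection:

* **Minimal depth (MD)** — per tree, the depth of the first node split on
  a variable (root = 0); a variable unused by a tree is assigned that
  tree's maximum depth plus one, giving a total order. MD is the mean
  over trees; smaller is more predictive.
* **Permutation importance (VIMP)** — the drop in OOB concordance when a
  variable is permuted among each tree's OOB subjects, averaged over
  `vimp_reps` replicates with a fixed per-variable sub-seed. A constant
  column scores exactly zero.

## The two-stage selection and its thresholds

Stage 1 keeps variables whose MD is *distinctly* low — more than one
standard deviation below the group mean MD — with strictly positive VIMP.
The one-SD margin is the operational reading of "distinct": requiring only
MD below the mean admits roughly a quarter of pure-noise variables
(about half sit below the mean and about half of those draw a positive
VIMP by chance), while the margin holds the null admission rate near 9%
without losing planted signals in recovery simulations (three SNPs with
hazard ratio 1.8 among 100 noise SNPs at $n = 5000$ are recovered in
every probe seed). The margin is configurable (`md_margin`; 0 recovers
the plain below-the-mean rule).

Stage 2 grows a forest on the pooled survivors, orders them by MD, and
fits the nested sequence of forests on the top-$k$ variables. With the
null model's error fixed at 0.5, the drop error of the $k$-th variable is
$d_k = e_{k-1}-e_k$, and the telescoping identity
$0.5 - e_k = \sum_{j\le k} d_j$ holds exactly. The final set keeps
variables with $d_k \ge \delta$; the default $\delta = 0.005$ is chosen
to reproduce the published example ranking's 8-variable selection exactly
(it keeps a drop of 0.0073 and discards one of 0.0033) — see
`example_ranking_table()` and `select_by_drop_error()`.

A scale caveat worth stating plainly: nested OOB errors are themselves
estimates. At reduced scale (hundreds of trees, a few thousand subjects,
~5% events) consecutive drops fluctuate by more than $\delta$, and the
single-variable null forest's OOB concordance falls *below* 0.5 (the
classic bootstrap-overfit reversal), so on pure-noise inputs the
$\delta$ rule admits spurious variables. The rule's false-positive
control is only meaningful at the cohort scale it was designed for
(thousands of trees, several hundred events); the package implements the
rule as specified and leaves the forest size to the analyst.

## GMDR

GMDR reduces a multilocus genotype to one dimension through
covariate-adjusted score residuals: by default the residuals
$y - \hat y$ of a null logistic model of the event indicator on the
adjustment covariates (martingale residuals from a null Cox model are
available via `type = "martingale"` to use the time axis). Each
multilocus cell (up to $3^5$ cells at order 5) is labelled high-risk when
its summed residuals are positive; ties are conservatively low-risk, and
cells unseen in training predict low-risk (the majority class under rare
events). Ten-fold cross-validation — stratified by event status and fixed
by seed — yields the testing balanced accuracy
$(\mathrm{sens}+\mathrm{spec})/2$ averaged over folds; the per-fold top
training-accuracy combination defines CVC; the exhaustive search reports
the plurality winner per order (ties broken by mean training accuracy).
Significance comes from permuting scores against genotypes with the
add-one estimator $p = (1+\#\{TBA^\ast \ge TBA\})/(B+1)$. The best model
has the highest TBA among models with full CVC and $p<0.05$; when none
qualifies, full CVC takes precedence and the winner is flagged
non-significant.

## Risk profiles and Cox models

Risk genotypes may be declared per SNP as a set of dosages (so either
homozygote, or carrier status, can be the risk category) or derived from
the data as the dosage levels whose Nelson–Aalen cumulative incidence
exceeds the pooled incidence. The genotype indicator $G$ is 1 when a
subject carries the full risk panel (configurable threshold); lifestyle
rules default to alcohol ≥ 18 g/day, estrogen-plus-progestin use ≥ 10
years, past oral-contraceptive use < 5 years, and BMI ≥ 30 kg/m²; the
behavioral code $B$ is binary or three-level; and the combined score is
$C = G + \min(B,1) \in \{0,1,2\}$.

Cox models use the Efron tie correction by default (better behaved at the
event rates simulated here; Breslow is available). `joint_effect_table()`
reports HRs per score level overall and within a binary exposure stratum
with one BH family per table; `trend_test()` enters $C$ with exact linear
coding; `interaction_test()` reports both the multiplicative product-term
HR and the additive-scale RERI
($HR_{11}-HR_{10}-HR_{01}+1$, delta-method CI). Proportional hazards is
checked by the correlation of scaled Schoenfeld residuals with event-time
rank (Grambsch–Therneau, rank transform).

## The synthetic cohort

`sim_spec()` defaults emulate the study conditions end to end: 10,179
subjects; 156 SNPs with i.i.d. Hardy–Weinberg genotypes on a 0.05–0.5
allele-frequency ladder; covariates matching the cohort's first moments
(age ~ truncated normal with mean 66 and SD 6.65 on the 50–79 enrolment
window, solved so the truncated mean is 66; alcohol ~ zero-inflated gamma
with 30% non-drinkers, overall mean 6.1 g/day, calibrated so ~9.6% of
women are at or above 18 g/day; hormone-use durations as
never/short/medium/long mixtures at the reported category frequencies);
and an exponential baseline hazard with administrative censoring uniform
on 12–20 years (mean 16). When the baseline hazard is not fixed it is
calibrated by the closed-form relation
$P(\text{event}) = 1-(e^{-ra}-e^{-rb})/(r(b-a))$, $r = \lambda e^{\eta}$,
to the target event fraction 537/10179 = 5.28%. Effects are planted as
additive-dosage log hazard ratios, declared risk-genotype indicators, or
pairwise product terms.

What the generator does *not* emulate — linkage disequilibrium between
SNPs, population structure, covariate correlation (an independence
default; the descriptors are marginal), genotyping error and informative
censoring — bounds what passing tests can say about real cohorts: they
validate the estimators and the pipeline logic, not robustness to those
real-data features.

## Numerical choices and degenerate inputs

* Split ties (equal |log-rank|) resolve to the first candidate examined;
  forests are byte-reproducible under a fixed seed because all sampling
  runs through R's RNG.
* A node with fewer than twice `min_node_events` events, or no admissible
  split, becomes terminal; a cohort with fewer than 2 events refuses to
  fit.
* Concordance treats a pair as usable when one subject is observed to
  fail first (tied times count only event-vs-censored); tied risk scores
  count 1/2. The implementation is $O(n\log n)$ and is tested against
  brute-force pair enumeration.
* The exact Hardy–Weinberg test enumerates the conditional heterozygote
  distribution; its p-values are discrete, so uniformity under the null
  is only approximate at small samples.
* Missing genotypes are excluded pairwise for allele-frequency and HWE
  computations and mode-imputed for modelling; missing covariates are
  complete-case by default.
* Stage seeds are derived deterministically from the master seed and the
  stage name, so any stage can be reproduced in isolation.

## Problem sizes used in the tests

The shipped test-suite and acceptance script run the simulations at
deliberately modest sizes chosen as the smallest at which each property
is statistically clean: forests of 25–500 trees; selection-recovery runs
at $n = 5000$ with 100 trees and 3 VIMP replicates; GMDR recovery at
$n = 3000$ with a 15% event fraction (a pure interaction needs that much
power at this size); type-I-error and coverage loops at 200 replicates;
and null-calibration forests at a 25% event fraction so the concordance
noise floor (~$1/\sqrt{\text{events}}$) sits well inside the assertion
band. The full-cohort defaults (5000 trees, $n = 10179$) remain the
package defaults.

## A worked example

```{r example, eval = FALSE}
library(riskforest)

# a cohort with three planted SNP effects
spec <- sim_spec(n = 5000, n_snps = 50,
                 log_hr = c(SNP_010 = log(1.8), SNP_020 = log(1.8),
                            bmi = 0.04))
coh <- simulate_cohort(spec, seed = 1) |> qc_filter()
frame <- as_analysis_frame(coh)

sel <- select_variables(frame,
                        snps = colnames(coh$genotypes),
                        lifestyles = c("bmi", "alcohol_g_day", "oc_years",
                                       "ep_years", "age"),
                        forest = forest_config(n_trees = 300, seed = 1))
tidy(sel$stage2)
autoplot(sel$stage2)

scores <- gmdr_scores(frame, covariates = "bmi")
gm <- gmdr_search(scores, frame[sel$stage2$selected], sel$stage2$selected,
                  max_order = 2, n_perm = 199, strata = frame$event)
gmdr_select_best(gm)

coding <- derive_risk_coding(frame, intersect(sel$stage2$selected,
                                              colnames(coh$genotypes)))
frame$G <- assign_risk_genotype(frame, coding)$G
frame$B <- assign_risk_lifestyle(frame)$B
frame$C <- combine_gene_lifestyle(frame$G, frame$B)
frame$heavy_alcohol <- as.integer(frame$alcohol_g_day >= 18)
joint_effect_table(frame, "C", "heavy_alcohol", covariates = "age")
```

## Known limitations

* The nested-model drop-error rule inherits the noise of OOB error
  estimates; at small forest sizes it over-selects (discussed above).
* GMDR's exhaustive search is capped (default pool 25) — beyond that the
  combination count at order 5 is impractical by design.
* VIMP for one-hot expanded categorical variables sums the per-indicator
  importances rather than permuting the levels jointly; for the binary
  and dosage-coded variables this pipeline targets, the two coincide.
* The permutation p-value applies to a prespecified combination; applied
  to the search winner it inherits selection optimism, which is why CVC
  and TBA, not the p-value alone, drive best-model choice.
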