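# sustainms

Subtype-and-stage inference for multiple sclerosis from combined MRI and
serum neurofilament (sNfL) biomarkers.

Multiple sclerosis is clinically heterogeneous: patients with the same
clinical phenotype can follow very different biological trajectories.
`sustainms` implements a z-score event-based subtype-and-stage model
(SuStaIn) that clusters patients by the *order* in which their
biomarkers become abnormal (the subtype) while simultaneously placing
each patient along that ordering (the stage). It is aimed at
neuroimaging and biomarker researchers who have per-visit tables of
MRI-derived measures (regional volumes, T1/T2 ratios, lesion volume)
plus a pre-standardized sNfL z-score, and who want data-derived disease
subtypes that predict disability, radiological activity and treatment
response.

## The model

Each biomarker `b` carries ordered abnormality thresholds
`z_1 < z_2 < ... < z_R` (defaults 1, 2, 3 reference standard
deviations) and a ceiling `z_max`. An *event* is a (biomarker,
threshold) pair; with 6 biomarkers and 3 thresholds the model has
`N = 18` events and stages `0..18`. A subtype `c` is an admissible
permutation `S_c` of all events (level `j` precedes level `j+1` within
a biomarker). The expected value of biomarker `b` at stage `k` is the
piecewise-linear trajectory through `(0, 0)`, each of the biomarker's
event positions at its thresholds, and `(N, z_max)`. Observed profiles
are independent Gaussians around the stage-`k` expectations
(`sigma = 1` on the z scale), the stage has a uniform prior over
`0..N`, and subjects mix over subtypes with fractions `f_c`:

    P(x) = sum_c f_c * (N+1)^-1 * sum_k prod_b Normal(x_b; E_b(k, S_c), sigma_b)

Fitting maximizes the total log-likelihood by greedy coordinate ascent
over sequences (seeded random restarts) and, for several subtypes, a
hierarchical split followed by expectation-maximisation. Ordering
uncertainty is quantified by Metropolis-Hastings sampling over
sequences (the positional-variance matrix); the number of subtypes is
selected by 5-fold cross-validation with the cross-validation
information criterion, `CVIC = -2 x` out-of-fold log-likelihood
(posterior-averaged over MCMC sequence samples), with a parsimony
margin that prefers fewer subtypes on near-ties.

Around the core model the package provides: reference-cohort z-scoring
with signed abnormality directions (volumes and T1/T2 decrease, lesion
volume and sNfL increase), empirical-Bayes location/scale batch
harmonization with a reference batch, EDSS-anchored two-stage feature
selection (rank by |Spearman rho| with EDSS, then recursive elimination
against the stage-EDSS correlation), per-visit labelling with
subtype-switching stability analysis, and a validation layer
(Spearman correlations with strength labels, Fisher z comparison,
random-intercept mixed-model slopes, annualized brain-volume-change
contrasts, time-to-new-lesion Kaplan-Meier and Cox models). A
synthetic longitudinal cohort generator with planted subtypes, stages
and outcome linkages makes the whole pipeline testable end to end.

## Worked example

```r
library(sustainms)

cc      <- cohort_config(n_subjects = 200, seed = 42)  # synthetic trial
cohort  <- generate_cohort(cc)
baseline <- subset(cohort$visits, month == 0)

cfg <- event_config(ms_biomarker_panel())   # 6 biomarkers x 3 levels
fit <- sustain_fit(baseline, cfg, n_subtypes = 2, restarts = 8, seed = 1)
fit
#> Subtype-and-stage model: 2 subtype(s), 18 events, log-likelihood -2058.662
#>   subtype 1 (f = 0.513): snfl:1 > snfl:2 > cc_t1t2:1 > lesion_volume:1 > ...
#>   subtype 2 (f = 0.487): limbic_volume:1 > dgm_volume:1 > parietal_volume:1 > ...
```

Subtype 1 raises sNfL, corpus-callosum T1/T2 and lesion volume first
(an "early-sNfL" pattern); subtype 2 leads with limbic and deep-grey
volume loss and raises sNfL late. Each visit then gets a subtype
probability, a maximum a posteriori stage and a confidence:

```r
post <- sustain_assign(baseline, fit)
head(post[, c("subject", "p1", "p2", "ml_subtype", "ml_stage", "confidence")], 4)
#>    subject           p1          p2 ml_subtype ml_stage confidence
#> 1    S0001 9.348178e-01 0.065182187          1        2  0.9348178
#> 7    S0002 9.934610e-01 0.006539012          1       11  0.9934610
#> 13   S0003 7.339448e-05 0.999926606          2        9  0.9999266
#> 19   S0004 9.992123e-01 0.000787744          1        8  0.9992123

spearman_with_p(post$ml_stage, baseline$edss)
#> Spearman rho = 0.470 (moderate), p = 2.237e-12, n = 200
```

The fitted stage correlates moderately with disability (EDSS), which
is exactly the property the feature-selection step optimizes. Applying
the model longitudinally quantifies how stable subtype labels are as
the confidence threshold rises:

```r
lab <- label_visits(sustain_assign(cohort$visits, fit))
switching_analysis(lab)
#>   threshold n_retained n_switched switch_fraction
#> 1      0.80        155         55       0.3548387
#> 2      0.85        150         50       0.3333333
#> 3      0.90        135         44       0.3259259
```

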