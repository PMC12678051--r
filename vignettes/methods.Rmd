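---
title: "Subtype-and-stage modelling of MS from MRI and sNfL: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Subtype-and-stage modelling of MS from MRI and sNfL: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sustainms)
```

## The model

`sustainms` implements a z-score event-based subtype-and-stage model
for longitudinal multiple sclerosis biomarker data. The data are
per-visit abnormality z-scores for a biomarker panel — by default three
regional volumes (limbic cortex, deep grey matter, parietal cortex),
total T2 lesion volume, the corpus-callosum T1/T2 ratio, and the serum
neurofilament light chain (sNfL) z-score, which arrives
pre-standardized against a control population and passes through the
preprocessing untouched.

Each biomarker $b$ carries ordered abnormality thresholds
$z_1 < \dots < z_{R_b}$ and a ceiling $z_{max,b}$. An *event* is a
(biomarker, threshold) pair; the model's stage space has
$N = \sum_b R_b$ stages beyond stage 0, so the default six-biomarker,
three-level panel yields 18 stages. A *subtype* is an admissible
ordering $S$ of all events (within a biomarker, level $j$ precedes
level $j+1$). The expected value of biomarker $b$ at integer stage $k$
is the piecewise-linear trajectory through $(0, 0)$, the biomarker's
event positions at their thresholds, and $(N, z_{max,b})$; observed
profiles are independent Gaussians around these expectations with
noise $\sigma_b$ (default 1 — the inputs are z-scores); the stage
carries a uniform prior over $0..N$ and subtypes mix with fractions
$f_c$.

One degenerate corner deserves a note: when a biomarker's final event
occupies position $N$, the control points $(N, z_R)$ and
$(N, z_{max})$ collide. The event threshold wins — stage $k$ means
"$k$ events have occurred", so the value at an event's position is
always exactly its threshold — and the ceiling is only attained by
biomarkers whose last event precedes $N$.

### Thresholds

Two threshold conventions circulate for this model family:
mild/intermediate/severe at 1, 2 and 3 reference standard deviations,
and a coarser grid at z-scores of 4, 6 and 8. Rather than silently
picking a side, thresholds are fully configurable per biomarker;
`event_config()` defaults to `c(1, 2, 3)` with ceiling 5, and
`event_config_z468()` provides the 4/6/8 preset with ceiling 10. All
fitting, staging and uncertainty machinery is agnostic to the choice.

### Fitting

`sustain_fit()` maximizes the total log-likelihood. For one subtype it
runs seeded random restarts (default 25) of greedy coordinate ascent:
every event in turn is relocated to its likelihood-maximizing
admissible position until a sweep makes no improvement; ties keep the
incumbent position. For $C > 1$ the largest-membership subtype of the
$C-1$ solution is split (several random splits are tried, each briefly
polished, the best kept) and the mixture is refined by
expectation-maximisation: responsibilities update the fractions
(closed form, always a simplex point) and drive responsibility-weighted
greedy refits of each sequence. Because the M-step only ever accepts
strict improvements starting from the incumbent, the EM log-likelihood
is monotone non-decreasing; the implementation asserts this at every
iteration. EM stops when the gain falls below `tol` ($10^{-6}$ by
default). All randomness flows from one `seed` via a documented
splitting scheme (restart $r$ uses `seed + r - 1`; split attempt $t$
at level $c$ uses `seed + 1000c + 10t`).

The likelihood kernel exploits the Gaussian quadratic form: scoring a
candidate sequence against the whole cohort reduces to a single matrix
multiply plus a row-wise log-mean-exp (compiled), which is what makes
greedy ascent over thousands of candidate relocations practical in R.

### Uncertainty

`mcmc_positional_variance()` runs Metropolis–Hastings over sequences
per subtype (proposal: relocate a uniformly chosen event to a
uniformly chosen admissible position — symmetric, because an event's
admissible window length is invariant to its own relocation), holding
the other subtypes and the fractions at their fitted values. The
positional-variance matrix gives, per event, the posterior probability
of each position; rows sum to one and the support respects the
within-biomarker ordering. The package default of 10,000 iterations is
deliberately desk-scale — production analyses of this model family
typically use considerably longer chains.

### Model selection

`sustain_cv()` performs subject-level $K$-fold cross-validation
(default 5) and reports
$\mathrm{CVIC}(C) = -2 \sum \text{out-of-fold log-likelihood}$.
By default the out-of-fold log-likelihood is *posterior-predictive*:
the held-out likelihood is averaged over thinned MCMC samples of the
per-fold sequence posterior (about 50 samples from a 400-iteration
chain), following the criterion's original definition. This choice is
not cosmetic. With a maximum-likelihood plug-in evaluation, a
redundant extra subtype acts as a free model average over near-optimal
sequences and systematically flatters larger $C$ even on data
generated from a single subtype — in our simulations the plug-in
comparison on one-subtype cohorts was close to a coin flip, while the
posterior-averaged evaluation (which gives every candidate the same
hedge) restores the expected preference for the generating $C$. The
plug-in evaluation remains available via `mcmc_iters = 0`.

Selection applies a parsimony margin: the smallest $C$ whose CVIC is
within 6 of the minimum wins. The margin mirrors the practice of
preferring a simpler subtype model whose criterion is only trivially
worse; it is overridable per analysis.

### Assignment

`sustain_assign()` treats every subject-visit independently: subtype
probabilities $p_c \propto f_c (N+1)^{-1} \sum_k P(x \mid k, S_c)$,
and the reported stage is the maximum a posteriori stage under the
maximum-probability subtype. Ties resolve to the lower stage and the
lower subtype index — a deliberate, deterministic convention. Stage
assignment is MAP rather than posterior-mean; the full stage posterior
is attached for users who prefer other summaries.

## Preprocessing and harmonization

`fit_reference_stats()` / `to_abnormality_z()` normalize raw biomarker
values against a reference (healthy-control-like) cohort using sample
($n-1$) standard deviations, then flip signs for `direction =
"decrease"` biomarkers (volumes, T1/T2 ratios) so that larger z always
means more abnormal. Lesion volume is right-skewed and zero-inflated,
so it is `log1p`-transformed before z-scoring (`direction =
"increase"`); the transform is a config choice (`lesion_transform =
"log1p"` or `"none"`) because no canonical standardization exists for
it. The mapping is affine and invertible per biomarker;
`from_abnormality_z()` undoes it.

`fit_harmonization()` / `apply_harmonization()` implement the
parametric empirical-Bayes location/scale batch adjustment with a
reference batch: features are standardized against the reference
batch's mean and variance (after removing any designated covariate
effects, which are estimated batch-aware and restored afterwards),
per-batch locations and scales are shrunk towards moment-matched
pooled priors (normal for locations, inverse-gamma for scales, the
standard iterative solution), and the reference batch maps to the
identity — so harmonizing an external test set "towards" the training
set leaves the training data untouched. sNfL is never harmonized, and
lesion volume only on request, matching the convention that only
intensity-derived MRI features need scanner harmonization. The
implementation agrees with the reference-batch mode of the widely used
ComBat implementation to $10^{-6}$ on shared cases (cross-checked in
the test suite); it exists as its own code because the fit/apply split
with a serializable model is a hard requirement here. Covariates
default to none.

## Feature selection

The variable-selection procedure is two-stage and EDSS-anchored.
`rank_by_edss_correlation()` ranks candidates by $|\rho|$ (Spearman)
with EDSS — absolute value, because a strongly negative correlate is
as useful as a positive one — with alphabetical tie-breaks for
determinism, and keeps the top 10 by default.
`recursive_eliminate()` then drops one feature per round: for every
remaining feature it refits a reduced-restart single-subtype model
without it, stages all subjects, and removes the feature whose removal
maximizes the stage–EDSS Spearman correlation, down to 5 features.
Refits use $C = 1$ with 5 restarts for speed (stage ordering is
primarily sequence-driven; the final model is refit at full settings),
every round's objective and seed are logged in the trace, and the
whole procedure is deterministic given the table and seed. EDSS enters
only through this objective — never through the event model itself —
which is precisely why the pipeline should be described as "not
entirely unsupervised". The sizes 10 and 5 are config defaults, not
principled constants.

## Stability analysis

`label_visits()` reduces posteriors to per-visit labels;
`switching_analysis()` reports, per confidence threshold $\tau \in
\{0.80, 0.85, 0.90\}$, how many subjects have baseline confidence
$\geq \tau$ (inclusive, a documented choice between the two printed
conventions) and what fraction of them ever change their
maximum-probability subtype relative to baseline (a consecutive-visit
anchor is available via `anchor = "consecutive"`). Retention is gated
on the baseline visit's confidence.

A caution on monotonicity: because the switch fraction is computed
over the retained subjects only, and the retained set itself shrinks
with $\tau$, the fraction is *not* mathematically guaranteed to be
non-increasing in $\tau$; on synthetic cohorts at the default noise it
occasionally ticks up at the middle threshold by under a percentage
point. The robust, reproducible pattern — and the one the stability
analysis is meant to probe — is that switching at the 90% threshold
does not exceed switching at the 80% threshold, with retention
monotone by construction. The tests assert exactly that.

## Outcome statistics

The validation layer wraps the field's standard estimators behind
typed results: Spearman correlations with midrank ties, asymptotic
two-tailed p-values and strength labels (weak 0.10–0.39, moderate
0.40–0.69, strong 0.70–0.89, very strong 0.90–1.00 on $|\rho|$, with
$|\rho| < 0.10$ labelled "negligible" as a documented extension);
Fisher's z for comparing two independent correlations; per-group
random-intercept mixed models (`outcome ~ years + (1 | subject)`,
REML, Wald 95% CI, Satterthwaite p) fitted separately per subtype and
per subtype-by-arm, as the analyses they emulate did; time to new
gadolinium-enhancing lesion (event at the first follow-up visit whose
count exceeds the previous visit's; censoring at the last visit); Cox
proportional hazards with the Efron tie correction (visit-grid times
guarantee heavy ties); Kaplan–Meier step functions; and annualized
percentage-brain-volume-change contrasts via Welch t-tests (the
unequal-variance default is deliberate where only "t-tests" is
specified). Lesion-count trends are modelled on the raw count scale
with an identity link by default — matching how such slopes are
conventionally reported — with a `log1p` option off by default. No
multiplicity correction is applied ($\alpha = 0.05$ two-tailed
throughout), and `truncate_control_crossover()` implements the
control-arm truncation at month 24 used when a trial's control group
crosses over to treatment in an extension phase.

## The synthetic cohort generator

`cohort_config()` / `generate_cohort()` emulate the structure of the
clinical-trial cohorts this pipeline targets, with every link planted
so that downstream estimates have a known truth:

* **Design.** 200 subjects by default, visits at months 0, 3, 4, 5, 6
  and 12 (a phase-2 schedule), a treatment arm assigned with
  probability 0.5, subtype prevalences 0.44/0.56.
* **Subtypes and stages.** Two planted orderings over the default
  panel: an "early-sNfL" sequence (sNfL, corpus-callosum T1/T2 and
  lesion events first) and a "late-sNfL" sequence (limbic and
  deep-grey volume loss first, sNfL late). Baseline stages are uniform
  over 0..18; stages progress deterministically at 1.2 (early) and 0.8
  (late) stages/year with rounding, and never regress. sNfL needs no
  separate trajectory process: it is one of the six modelled
  biomarkers, and its early-versus-late character comes entirely from
  its position in each planted sequence.
* **Biomarkers.** z-values equal the planted trajectory's expectation
  at the true stage plus Gaussian noise (default $\sigma = 1$;
  $\sigma = 0$ admitted for noiseless trajectory checks). Batch
  effects (additive shift, multiplicative scale per biomarker) are
  applied last, for harmonization testing.
* **Outcome links.** No generative magnitudes exist in the source
  material for these links, so they are fixed once to reproduce the
  qualitative published patterns and flagged as arbitrary: EDSS
  $= \mathrm{clip}(\mathrm{round}_{0.5}(1.5 + 0.15 \cdot
  \text{stage} + \mathcal{N}(0, 1.5)), 0, 10)$, which yields a
  moderate stage–EDSS rank correlation (~0.45), the strength typically
  seen between imaging-derived stages and disability in relapse-onset
  MS cohorts; lesion counts are Poisson with log-rate
  linear in subtype (0.8 vs 0.4 events/visit), treatment (rate ratio
  0.3) and time, giving the low counts typical of established MS;
  annualized brain-volume change is normal with subtype means −0.46
  and −0.31 %/year and SD 0.42, an early-MS-scale atrophy contrast in
  which the more inflammatory subtype loses volume faster.
* **Survival truth.** `generate_survival_truth()` plants exponential
  first-event times under proportional hazards (default subtype hazard
  ratio 2.44 for early- versus late-sNfL new-lesion risk, treatment
  hazard ratio 0.5) and discretizes them onto the visit grid.

What the generator does **not** emulate: relapses (excluded from the
emulated analyses as too rare), missing data (the model requires
complete profiles; no imputation), MRI image processing (the pipeline
consumes feature tables), visit-level correlation beyond the shared
stage trajectory, and any real-data artefacts such as floor effects or
assay drift. Passing tests on these cohorts therefore demonstrate
correctness of the algorithms under the stated generative model, not
clinical performance on trial data.

## Problem sizes and numerical choices

The test-suite and acceptance-script workloads are sized for a single
CPU: sequence/subtype/stage recovery uses one 400-subject cohort at
$\sigma = 1$ with 8 greedy restarts; CVIC selection uses 250–300
subject cohorts over seeded replicates with 2 restarts, 8 EM
iterations and 400-iteration MCMC chains per fold; the brute-force
oracle comparisons enumerate all admissible sequences for event sets
up to $N \le 5$. Tolerances: oracle agreement to $10^{-10}$;
reference z-scoring to $10^{-12}$; the harmonization cross-check to
$10^{-6}$; EM monotonicity to $10^{-8}$ (floating-point slack).
Degenerate inputs error early and explicitly: incomplete biomarker
profiles, zero-variance reference columns, single batches, batches
with fewer than three rows, zero-event survival tables and
constant-covariate Cox fits all have dedicated messages.

## Known limitations

* Stage trajectories are monotone by assumption; fluctuating or
  remitting biomarker courses are outside the model class.
* The greedy + EM optimizer is a local method; well-separated
  orderings are recovered reliably at the tested sizes, but heavily
  overlapping subtypes can require more restarts and split attempts
  than the desk-scale defaults.
* MCMC here quantifies *ordering* uncertainty at fixed fractions; it
  is not a full joint posterior over sequences, fractions and stages.
* The Fisher z comparison assumes independent samples; comparing
  correlations computed on overlapping subjects inherits that
  approximation.
* The synthetic EDSS/lesion/PBVC link magnitudes are plausible
  inventions, and conclusions about real cohorts should not be read
  off them.
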