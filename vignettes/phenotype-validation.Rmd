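---
title: "Validating claims-code case definitions against a probabilistic gold standard"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating claims-code case definitions against a probabilistic gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoval)
```

## The estimand and the estimator

A case definition $D$ is a monotone boolean rule over claims codes. Its
operating characteristics against true disease status $Y$ — sensitivity,
specificity, PPV, NPV — are the estimands. Chart review can estimate PPV
only; `phenoval` instead trains a phenotype model on a gold-standard
cohort and carries its predicted case probabilities $p_i = \hat P(Y_i = 1
\mid \text{claims history})$ into a real-valued confusion matrix over an
independent test population:

$$\mathrm{TPs} = \sum_{i \in D^+} p_i, \quad
  \mathrm{FPs} = \sum_{i \in D^+} (1-p_i), \quad
  \mathrm{FNs} = \sum_{i \in D^-} p_i, \quad
  \mathrm{TNs} = \sum_{i \in D^-} (1-p_i),$$

with sensitivity $\mathrm{TPs}/(\mathrm{TPs}+\mathrm{FNs})$, specificity
$\mathrm{TNs}/(\mathrm{FPs}+\mathrm{TNs})$, PPV
$\mathrm{TPs}/(\mathrm{TPs}+\mathrm{FPs})$, NPV
$\mathrm{TNs}/(\mathrm{FNs}+\mathrm{TNs})$ and F-score
$2sp/(s+p)$ computed from proportion-scale sensitivity and PPV.

The key assumption is **calibration**: if $p_i$ equals the true posterior
probability of disease given the observables that $D$ depends on, then
conditionally on the data $Y_i \sim \mathrm{Bernoulli}(p_i)$, every cell
above is an unbiased estimate of its classical counterpart, and each index
converges to the classical index as the test population grows. Ranking
ability (AUC) is *not* sufficient — a model can order patients perfectly
and still produce badly biased indexes. `calibration_check()` therefore
estimates a weighted reliability-curve slope (observed event rate
regressed on mean prediction over prediction deciles) and
`evaluate_definitions()` flags the report whenever the slope leaves
[0.8, 1.2]. No recalibration is applied by default; the flag is a
warning, not a correction.

For degenerate $p_i \in \{0,1\}$ the probabilistic matrix reduces exactly
to the classical 2×2 — the test suite asserts this equivalence against an
independently written brute-force implementation on a thousand random
datasets.

Zero denominators (e.g. PPV of a definition matching nobody) are reported
as missing with the index named, never silently propagated as `NaN`.

## Study design encoded in the pipeline

**Periods.** Calendar windows are half-open: training 2009-01-01 to
2015-01-01, test 2015-01-01 to 2020-01-01. The test group contains only
patients *never seen* in the training window; patients visiting both
windows belong to training only (`split_by_period()`). Age is computed as
window-start year minus birth year, since the data model carries no finer
anchor.

**Gold standard.** Possible cases are screened by five criteria: (1)
confirmed T1D / insulin-dependent-diabetes diagnosis (prefix set, default
E10); (2) insulin prescription AND minimum serum CPR < 0.6 ng/ml AND a
ketoacidosis diagnosis; (3) GAD or IA-2 autoantibody positivity; (4)
diabetologist referral; (5) minimum serum CPR < 0.2 ng/ml. Both CPR
thresholds are strict inequalities, as clinical cut-offs are printed. The
temporal order of ketoacidosis diagnosis and CPR measurement is ignored —
the data model is presence-based within a period. Screened patients are
adjudicated (in the synthetic setting, by an oracle that can be given a
configurable error rate; default 0, treating adjudication as truth).
Adjudicated cases lose patients with a pancreas-transplant procedure code
or any confirmed/suspected type 2 diabetes code (3-digit E11); the T2D
exclusion is applied to cases only, as stated for the design this package
follows. Controls are sampled (without replacement, seeded) from patients
whose charts were never reviewed and who carry no confirmed or suspected
T1D code, at a default ratio of 233 controls per case — the labeled-cohort
ratio implied by a 296-case / 69,023-control training cohort. At the
default desk-scale population the eligible pool is smaller than the
target, so the whole pool is used; the ratio matters at larger scales.

**Features.** Dummy variables encode *presence during the period*, never
counts. Diagnosis codes are truncated to their 3-character ICD-10
category and namespaced by certainty (`confirmed:`/`suspected:` — claims
distinguish established diagnoses from codes entered to justify tests);
medications map to generic names (`med:`), procedures stay verbatim
(`proc:`). Everything used to assemble the gold standard is excluded as
leakage: confirmed T1D/T2D/ketoacidosis, suspected E10/E11/E13/E14, the
CPR and insulin-receptor-autoantibody test claims, and all insulin
medications (`default_leakage()`). Leakage is re-asserted *after* feature
screening. Features are screened to the top 500 by relative risk of case
status,

$$RR = \frac{(a+\varepsilon)/(a+b+2\varepsilon)}
            {(c+\varepsilon)/(c+d+2\varepsilon)},$$

with $\varepsilon = 0.5$ on all four cells whenever any cell is zero, and
$RR \equiv 1$ for constant features (an empty margin carries no
discrimination; the corrected ratio would otherwise return an arbitrary
prior-dependent value). Ties break lexicographically for determinism.
Protective features (RR < 1) rank low — there is no absolute-value
ranking. Age and sex bypass screening and are always appended: they are
listed as explanatory variables in their own right, outside the coded
dummies.

**Model.** Gradient-boosted trees (binary logistic objective), defaults:
500 rounds maximum, depth 4, learning rate 0.05, early stopping after 25
stalled rounds on a stratified 10% validation split, no subsampling,
single-threaded for bit-for-bit reproducibility given the seed. One
non-obvious default matters greatly: `min_child_weight = 1e-3`. At a
1:233 class imbalance the logistic hessians of a small, nearly pure code
group (e.g. the ~20 carriers of the needle code among 8,000 cohort
patients) sum to far less than xgboost's default threshold of 1, which
silently forbids exactly the splits this problem needs; with the
threshold effectively removed, the needle code takes its expected place
at the top of the gain-based importance table (importances are normalized
to sum to 1). Cross-validated AUC comes from seeded, label-stratified
tenfold CV, each fold refit for the early-stopped round count.

**Definitions.** The 11 built-in candidates combine four predicates: ①
confirmed E10 (prefix match, so 4-digit subcodes count), ② injector-needle
procedure 114010970, ③ any basal-insulin medication code, ④ CSII
syringe-pump procedure 114004810 or 114022010 — singly and as ①∧②, ①∧③,
①∧④, ①∧(③∨④), ①∧(②∨④), ①∧(②∨③), ①∧(②∨③∨④). The basal-insulin list is a
required, user-editable configuration (the shipped default is a named
placeholder catalogue of generic basal insulins, not a site formulary).
Matching uses the whole evaluation period; negation and temporal logic
are deliberately unsupported.

**Uncertainty.** Percentile bootstrap, default 1000 replicates at the 95%
level, resampling *patients* of the test population with replacement
(score and definition status stay paired). Replicates with an undefined
index are dropped for that index with a reported count. All definitions
share the same resamples within one `evaluate_definitions()` call, so
rows are paired. Resampling is implemented as multinomial weights, which
makes 1000 replicates over tens of thousands of patients a few seconds of
matrix arithmetic.

## What the generator emulates — and what it does not

`simulate_claims()` draws latent T1D and hemophilia status independently
per patient (defaults 0.5% and 0.2%), assigns each patient a visit
pattern (training only / both / test only with probabilities 0.25 / 0.15
/ 0.60, making the test population ~1.5× the training population), and
emits every code as an independent Bernoulli per patient per visited
period. Emission probabilities live in a table with class precedence
t1d > hemophilia > background (`NA` inherits). The default rates are
chosen so the single-code definitions land in the regime reported for
this phenotype at 0.5% prevalence: E10 carried by a third of true cases
(background 0.0033, putting E10-alone PPV near one third), needle code at
0.33 for T1D and 0.35 for hemophilia (the shared-code confounder) over a
2×10⁻⁴ background, basal insulins combining to ~0.40 presence, CSII pump
~0.04 with a 3×10⁻⁵ background. CPR values are lognormal (true cases
centred at 0.25 ng/ml, background at 1.8 ng/ml), autoantibody testing and
positivity, diabetologist referral, and age structure (cases 8-40 at
window start, background 0-90) are class-conditional. A catalogue of
1000 class-independent noise codes across all four namespaces exercises
feature screening. Chart-review error is 0 by default and configurable
for sensitivity analyses.

Because everything is generated, an *exactly calibrated scorer* exists:
`oracle_scores()` computes the Bayes posterior of latent T1D from the
generative parameters over the four latent-class combinations, using the
signal codes, lab occurrence and values, and the referral flag (noise
codes cancel; age is omitted — definitions depend only on codes, so
calibration with respect to every definition is preserved). This scorer
separates two questions the trained model would conflate: *is the
probabilistic estimator right when its assumption holds?* (yes — at
n = 50,000 it recovers latent-truth sensitivity and PPV of all 11
definitions within 0.03, per the acceptance suite) and *is a model
trained at desk scale calibrated?* (at 32 training cases, no — the
reliability slope is ~1.4 and the report says so).

The generator deliberately omits features of real claims data:
longitudinal disease trajectories and code dates carry no information
beyond period presence; emissions are independent across codes given
class (real comorbidity and billing-bundle correlations are absent);
care-site mixture is not modelled — which is why the generator cannot
simultaneously reproduce a low *test-period* needle sensitivity and the
near-universal needle coverage among *in-cohort* treated patients that a
single hospital's data would show. Passing tests therefore demonstrate
correctness of the estimator and pipeline mechanics under the stated
assumptions, not fidelity of any particular rate to a real population.

## Numerical and design choices

- Windows half-open; all stage randomness is seeded, with pipeline stage
  seeds derived from the master seed by fixed offsets (+1 simulation, +2
  cohort, +3 model, +4 bootstrap), recorded in the manifest.
- Column order of the feature matrix is deterministic (namespace blocks,
  lexicographic inside); RR ties break lexicographically; bootstrap
  quantiles use R's default type-7.
- Medication codes missing from the generic map are used verbatim with a
  warning rather than dropped — losing a signal silently would bias the
  model, while a raw code is merely an unmapped feature name.
- Scoring aligns columns by name: features the model never saw are
  dropped with a warning; training features absent at scoring time are
  zero-filled (absence of a code is a valid observation, not
  missingness); no overlap at all is an error.
- The probabilistic indexes are reported on proportion scale in the
  results table; the printed report follows the field's convention of
  percentages at 1 decimal for sensitivity/PPV/specificity/NPV and a
  3-decimal proportion for the F-score.
- Degenerate inputs: empty datasets yield age/sex-only feature matrices
  and zero prevalences; an all-empty confusion matrix is an error; a
  definition matching nobody yields an N = 0 row with its undefined
  indexes named.

Problem sizes used by the shipped checks were chosen to keep a full run
at desk scale: the default population is 20,000 patients; the
parameter-recovery and ordering checks run once at 50,000; bootstrap
coverage uses 200 replications at n = 5,000 with closed-form targets
under a Beta-score generating process.

## Known limitations

- The probabilistic indexes inherit any miscalibration of the scorer;
  with rare phenotypes and small gold-standard cohorts the trained
  model's slope can sit well outside [0.8, 1.2], and the package flags
  but does not fix this (an isotonic or Platt recalibration layer is a
  natural extension).
- At realistic prevalence, definitions matching few patients (the CSII
  pump rules) have PPV estimates resting on a dozen positives;
  neighbouring definitions' sensitivity intervals (basal insulin vs
  needle, ~0.40 vs ~0.33) overlap at 95% confidence with only ~140 latent
  cases in a 30,000-patient test population. These are sample-size facts,
  not estimator defects.
- Boolean definitions only: no negation, visit-count thresholds or
  temporal separation constraints.
- One simulated site; no care-site mixture or cross-site transport of
  definitions.
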