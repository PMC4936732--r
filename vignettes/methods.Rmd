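---
title: "Methods: ROC-index importance ranking, model skeletonization, and Bayesian network analysis of TBI outcome predictors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ROC-index importance ranking, model skeletonization, and Bayesian network analysis of TBI outcome predictors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbirank)
```

## The problem

After traumatic brain injury (TBI), clinicians want to know which admission
findings matter most for predicting six-month outcome, dichotomized as
*poor* (death or severe disability) versus *favorable* (moderate disability
or good recovery).  `tbirank` implements a complete analysis chain for this
question on cohorts following the CRASH-trial admission schema: 13
categorical predictors spanning patient/injury characteristics (sex, age
band, injury cause, major extracranial injury), clinical assessment
(pupillary response and the eye/verbal/motor components of the Glasgow Coma
Scale), and five CT findings (petechial hemorrhage, subarachnoid bleed,
obliterated third ventricle/basal cisterns, midline shift, hematoma).

The chain is: complete-case filtering → dummy-coded logistic outcome models
with repeated cross-validation → variable importance by *drop-one* changes
in ROC indices → stepwise model simplification with a paired significance
stopping rule → constrained Bayesian-network analysis of how the retained
"key predictors" relate to the discarded variables.

## Outcome models and cross-validation

Each predictor enters as an indicator block with its first listed category
as reference (29 columns for the full model).  Age is treated as
categorical bands, not as a linear score.  Fits are maximum-likelihood
logistic regressions via iteratively reweighted least squares
(`stats::glm.fit`); non-convergence (e.g. separation) is flagged on the
fitted object and the selection routines refuse flagged fits rather than
proceeding silently.

Out-of-sample predicted probabilities come from repeated K-fold
cross-validation, by default K = 5 folds and 6 independent cycles, pooling
all (record, cycle) predictions.  Two design choices matter:

* **Pairing.**  Fold memberships are a function of only the record count
  and `split_seed`, never of the predictor subset.  Any two models
  evaluated under the same seed therefore share identical splits, which is
  what makes the paired model comparisons below valid.  Averaging per
  record before ROC construction is possible by aggregating the returned
  table, but pooling is the default.
* **Degenerate folds.**  A category absent from a training fold yields an
  unidentified coefficient; it is treated as zero for prediction and the
  event is logged on the `cv_predictions` object.

## ROC indices

The empirical ROC curve is built from all distinct score thresholds with
ties grouped, so the trapezoidal area equals the Mann–Whitney statistic
with half credit for ties.  The *partial* AUC restricts the integral to a
sub-interval of the specificity axis (pAUC~SP~) or, via the
curve-transposition identity, the sensitivity axis (pAUC~SE~); interval
boundaries are linearly interpolated between adjacent operating points.
The default region is 90–100%, the clinically interesting regime.  Raw
partial areas are standardized after McClish,

$$\mathrm{spAUC} = \frac{1}{2}\left(1 + \frac{A - A_{\min}}{A_{\max} - A_{\min}}\right),$$

where $A_{\max}$ is the interval width and $A_{\min}$ the chance-diagonal
area inside the interval, so 0.5 is chance and 1 is perfection regardless
of region; below-chance areas map below 0.5 and carry a flag.

Model comparisons use:

* **DeLong's test** for full-AUC comparisons on paired scores, via
  placement values (structural components) and their covariance.
* A **stratified paired bootstrap** for partial-area comparisons, because
  the classical DeLong covariance is derived for the full area.  Positives
  and negatives are resampled separately (so no resample is degenerate),
  the statistic is the difference in standardized pAUC, and the p-value is
  two-sided normal on the bootstrap standard error.  Confidence intervals
  for a single standardized pAUC are percentile bootstrap.  Both pathways
  are labeled on their results; which estimator a given published analysis
  used for partial areas is often ambiguous, so making the method explicit
  is part of the contract.

## Importance ranking and skeletonization

Importance of predictor $v$ is the percent drop
$100\,(M_{\text{all}} - M_{\text{all}\setminus v})/M_{\text{all}}$
of a metric $M$ (full AUC, standardized pAUC~SP~, or standardized
pAUC~SE~) computed from pooled cross-validated predictions, with identical
splits for every subset.  Greater drop = more important.  Drops can be
negative — removing a noise variable can improve out-of-sample accuracy —
and are reported as such.  Ties break alphabetically.  A fourth ranking by
the drop in Nagelkerke R² uses full-data fits (no cross-validation),
mirroring the goodness-of-fit ranking tradition; here
$R^2 = (1 - e^{2(\ell_0-\ell_1)/n})/(1 - e^{2\ell_0/n})$.

Skeletonization fixes the ranking once, from the complete model, and then
drops the lowest-ranked remaining variable one step at a time.  Each
reduced model's pooled predictions are compared against the *complete*
model (paired splits; DeLong for full AUC, bootstrap for pAUC targets).
The selected model is the last one before the comparison first reaches
significance at α (default 0.05); its retained variables are the **key
predictors**.  If the very first reduction is already significant the
complete model is kept and flagged.  As a conventional baseline the
package also provides whole-block backward elimination under AIC.

## Bayesian network analysis

Associations among the variables are modeled as a discrete Bayesian
network.  Structure search is greedy hill-climbing over single-edge
additions, deletions and reversals, scored by BIC
($\sum_v \hat\ell_v - \tfrac{1}{2}\,df_v \log n$, decomposable per
family), accepting only strictly improving moves, with randomized restarts.
The network-analysis stage pre-fixes edges from each key predictor to the
outcome via a whitelist; direction is a configurable choice (the
key→outcome orientation is the package default) since a pre-fixed
association does not itself carry a causal direction.  BIC is the score
because the hill-climbing literature the approach descends from defaults
to it; score-equivalent DAGs are indistinguishable, so recovery claims in
the test-suite are made at the level of Markov equivalence classes
(skeleton + v-structures), not raw edge sets.

CPTs are conditional frequencies with optional Laplace smoothing; unseen
parent configurations get the uniform distribution and are flagged.
Queries (e.g. the probability of extracranial injury given injury cause)
are exact, by sum-product variable elimination, and are verified against
brute-force joint enumeration in the tests.

## The synthetic cohort generator

The generator exists so every downstream stage has a testable ground
truth without the trial data.  It is a forest-structured discrete network
over the 13 predictors plus a logistic outcome mechanism:

* `sex` and `age` are roots; `age → cause → ec` captures the age-driven
  shift from road-traffic accidents toward falls, and the higher
  extracranial-injury rates of high-energy mechanisms (defaults 27.2% /
  22.2% / 10.4% for RTA / falls / other, chosen to echo the conditional
  frequencies reported for the real cohort; they are defaults, not
  calibration targets).
* The nine severity-linked variables (GCS components, pupils, CT
  findings) are driven by a latent four-level ordinal injury-severity
  variable: each conditional $P(v\mid s)$ tilts the variable's marginal by
  a severity score, and the latent is then collapsed through first-order
  conditioning into a chain
  eye → motor → verbal → pupils → phm → sah → oblt → mdls → hmt, so all
  CPTs are over observed variables, exact marginalization stays
  closed-form, and clinically co-occurring findings are positively
  associated.  The cost of the collapse is that long-range dependence
  decays along the chain faster than a genuine shared latent would imply —
  a known, documented simplification.
* The outcome is Bernoulli with log-odds additive in per-category
  coefficients: monotone in GCS ordering, positive for pupil abnormality,
  mass-effect CT signs, older age and extracranial injury; magnitudes sit
  in `default_truth()` and give the importance machinery a known answer.

**Calibration.**  Target marginals are the published complete-case
frequencies.  Because the source table's within-variable percentages sum
to slightly under 100 (its complete-data percentages were evidently
computed over a marginally different denominator), each non-reference
category is pinned at exactly its printed value and the ~0.4% shortfall is
absorbed by the last listed category.  Calibration proceeds in topological
order by per-category log-odds tilts (iterative proportional fitting
against the exactly marginalized distribution, default tolerance 1e-6
absolute per category), then root-finds the outcome intercept against the
target poor-outcome rate using the exact linear-predictor distribution
(component-wise enumeration and convolution — no Monte Carlo).

**Missingness** is missing-completely-at-random, with rates pinned to the
published entire-dataset frequencies: "scan not done" (p = 0.2061) applies
jointly to all five CT variables, a joint CT "no data" event (p = 0.0128)
covers findings missing despite a scan, and independent rates cover
injury-cause and extracranial-injury "no data", unassessable pupils, and
the two unknown-outcome codes.  Because these sources are independent in
the generator but overlapped in the real cohort, the expected complete-case
retention is 67.9% rather than the real cohort's 69.4% — a deliberate
consequence of keeping the mechanism simple and the marginal rates exact.
The generator does not model informative missingness, continuous
covariates, or longitudinal outcomes, so passing tests say nothing about
robustness to those features of real data.

## Numerical and testing choices

* All stochastic operations take explicit integer seeds; pipelines derive
  per-stage seeds from one master seed, so stages are independently
  reproducible and identical configurations give byte-identical numeric
  output.
* Logistic convergence: IRLS tolerance 1e-10, 100 iterations;
  probabilities for log-likelihoods are clamped away from 0/1 at 1e-15.
* Tie handling is trapezoidal/half-credit everywhere, so the AUC equals
  the normalized Mann–Whitney statistic exactly (asserted to 1e-12).
* Bootstrap comparisons and CIs default to 2000 replicates; the
  test-suite's replicated recovery study uses 5-fold single-cycle CV,
  120 bootstrap replicates, 50 cohorts of n = 5000 with two informative
  predictors among ten — sizes chosen as the smallest at which recovery
  claims are stable.
* The hill-climber caches family scores; tie-breaking among equal-score
  moves is deterministic (first in a fixed lexicographic sweep).
* Degenerate inputs: single-class label vectors, single-category
  predictor blocks, cyclic whitelists, and zero-probability evidence all
  raise immediate, labeled errors.

## Known limitations

Complete-case filtering is the only missing-data strategy (by design — the
analysis this package operationalizes did not impute), so results inherit
whatever selection the missingness mechanism induces.  The bootstrap
pathway for partial-area comparisons is approximate at extreme operating
points where the empirical curve is flat.  The generator's chain collapse
understates long-range dependence among severity variables, which makes
full 13-node structure recovery harder than under a true shared latent;
structure-recovery guarantees are therefore only claimed (and tested) for
small planted networks.
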