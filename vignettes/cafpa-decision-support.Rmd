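---
title: "Interpretable Bayes classification on CAFPAs: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable Bayes classification on CAFPAs: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cafpabayes)
```

## The problem and the model

Audiological diagnostics produce heterogeneous measurements — audiograms,
speech tests in noise, loudness scaling, cognitive screenings — that experts
integrate into findings ("high-frequency hearing loss", "recruitment") and
treatment recommendations ("hearing aid", "cochlear implant"). The Common
Audiological Functional Parameters (CAFPAs) compress this battery into ten
interpretable values in $[0,1]$ (0 = normal, 1 = maximally impaired): CA1–CA4
for audibility by increasing frequency band, CU1/CU2 for supra-threshold
deficits, CB, CN, CC for binaural, neural and cognitive function, and CE for
socio-economic status. Classifying on this layer rather than on raw
measurements keeps every decision inspectable: each step is a comparison of
two one-dimensional densities the user can plot.

**Comparison sets.** The elementary decision is binary: an ordered pair of
diagnostic categories $(c_1, c_2)$. For each CAFPA $i$ and category $c$ a
beta distribution $f_{c,i}$ is fitted to the CAFPA values of training
patients carrying that category's label (patients labeled with both
categories contribute to both). A patient with CAFPA vector $x$ receives the
score

$$s_c(x) \;=\; \sum_{i=1}^{10} w_i\, f_{c,i}(x_i),$$

a weighted sum of probability *density values* (deliberately not a
product-form naive Bayes — the sum keeps single uninformative CAFPAs from
vetoing a decision), and is classified to the category with the larger
score. With a single active CAFPA this reduces to the Bayes decision rule:
the classification threshold is the intersection of the two training
densities, and `decision_threshold()` exposes it directly.

**Weights.** Which CAFPAs should enter a given decision is an empirical
question. `search_weights()` evaluates all $2^{10}-1 = 1023$ binary
inclusion patterns, scoring each by the Youden index
$Y = \mathrm{Sens} + \mathrm{Spec} - 1$ computed over patients uniquely
labeled with one of the two categories (dual-labeled patients are
classified but never scored). The "Y90" rule (`select_y90()`) keeps all
combinations reaching at least 90 % of the maximum $Y$ — a robust band of
good combinations rather than a single winner. Normalizing the relative
frequency of each CAFPA among the Y90 combinations *common* to two CAFPA
sources (expert-estimated vs model-predicted) yields the *rel-model*
weights; pooling the expert source with all prediction models yields
*rel-all* (`derive_rel_weights()`). When no combination is common, the
single best combination of the model's own search is used and the result
flagged.

**Tree sets.** Two comparison sets chain into a three-category decision:
the root decides $A$ vs $B$; patients classified $B$ enter the leaf, which
decides $C$ vs $D$. The per-decision certainty is the classified score's
share, $\mathrm{Cert}_c = s_c / (s_1 + s_2)$, and it propagates
multiplicatively: $\mathrm{Cert}(A) = \mathrm{Cert}_\mathrm{root}(A)$,
$\mathrm{Cert}(C) = \mathrm{Cert}_\mathrm{root}(B)\,
\mathrm{Cert}_\mathrm{leaf}(C)$, likewise for $D$. The three terminal
certainties sum to 1 by construction, and with completely uninformative
training distributions they sit at their chance levels $(0.5, 0.25, 0.25)$
— the first terminal's path ends after one binary decision, the other two
after two.

**Prediction layer.** In deployment the CAFPAs themselves are predicted
from the measurement battery. `predict_cafpas_cv()` fits one model per
CAFPA (lasso, elastic net or random forest) and returns out-of-fold
cross-validated predictions: every patient is predicted by a model that
never saw them, so downstream classification performance is estimated as
for new patients. Predictions are clipped to $[0,1]$; no recalibration is
applied, because shifting thresholds toward the predicted distributions
would use knowledge unavailable when a genuinely new patient arrives.

## Tunable parameters

| Parameter | Default | Meaning / rationale |
|---|---|---|
| `eps` | $10^{-3}$ | Boundary clip before fitting and density evaluation. Beta densities diverge at 0/1 for shapes $<1$; expert CAFPAs are interior in practice, and the clip keeps all scores finite. |
| `grid_size` | 1001 | Threshold/expected-certainty grid on $(\varepsilon, 1-\varepsilon)$; crossings refined by bisection to $|\Delta x| < 10^{-6}$. Beta density pairs can cross more than once; all crossings are recorded. |
| Y90 fraction | 0.9 | Share of the maximum Youden index a combination must reach. |
| `nfolds` | 5 | Outer folds for out-of-fold CAFPA prediction; each fold must hold $\ge 10$ patients. |
| `dual_label_fraction` | 0.1 | Generator: probability that a patient of the designated pair carries both labels, mirroring multi-label expert annotations. |
| `n_per_category` | 80 | Generator default, i.e. a 240-patient three-category cohort — the scale of a realistic expert-labeled audiological data set. |

## The synthetic cohort generator

`simulate_cohort()` draws what the classifier assumes: per category, each
CAFPA independently from a beta distribution. The default conditions
(`default_cohort_spec()`) describe three categories of increasing
impairment (no device / hearing aid / cochlear implant) whose audibility
CAFPAs separate strongly, supra-threshold CAFPAs moderately, and central
CAFPAs weakly — the qualitative pattern of expert-estimated CAFPA profiles,
where impairment spreads from peripheral to central with severity.
Dual-labeled patients draw their CAFPAs from an equal mixture of the two
categories' distributions, with one mixture component per patient (a
patient plausibly *is* one case; the experts ticked both boxes). A Gaussian
copula hook can couple CAFPAs while preserving the beta marginals; it
defaults off because the marginal model is exactly what the per-CAFPA
training step assumes.

What the generator does **not** emulate: realistic audiogram shapes, the
empirical marginals of any clinical data set, inter-expert estimation
noise, or systematic dependence between labels and measurement artifacts.
Passing tests on synthetic cohorts therefore demonstrate the correctness
and internal consistency of the machinery — parameter recovery,
separability, calibration of certainties — not clinical performance on
real patients.

## Numerical and design choices

* **Beta fitting** is maximum likelihood (via `fitdistrplus`) with a
  method-of-moments start, falling back to the method-of-moments estimate
  when the optimizer fails; the fitting method is recorded per
  distribution. Fitting needs $\ge 3$ distinct values; fewer, or
  all-identical values after clipping, raise explicit errors.
* **Leave-one-out.** When a classified patient was part of the training
  cohort, `search_weights()` refits the training distributions with that
  patient excluded (the default, switchable), so in-sample Youden indices
  are not optimistically biased. A deployed system classifying new
  patients trains once.
* **Certainty combination.** Across CAFPAs the certainty is the ratio of
  the *weighted score sums* — identical to the quantities that decide the
  classification — rather than a weighted average of per-CAFPA
  certainties. This keeps "certainty of the classified category $\ge
  0.5$" an exact invariant. The per-CAFPA view is still available via
  single-CAFPA weights.
* **Ties** (exactly equal scores) resolve to the first listed category
  and are flagged; they have measure zero for continuous inputs.
* **Missing CAFPAs** with positive weight are dropped and the remaining
  weights renormalized, with a warning; a patient with no usable CAFPA is
  a hard error. Expert-labeled data are complete; this is a deployment
  convenience.
* **Y90 across sources** is applied per source (expert, each model) and
  the selections intersected; an externally imposed joint maximum is
  available through `select_y90(..., reference_max = )`.
* **Negative Youden indices** are retained and reported — a
  worse-than-chance combination is informative — though they can never
  pass the Y90 cut.
* **Tree topology** is configurable: any two fitted comparison sets with
  distinct terminals chain via `cafpa_tree()`; category labels pooling
  several cohort labels (e.g. "hearing device" = hearing aid ∪ cochlear
  implant) are declared through the `members` mapping. The shipped demo
  tree is the treatment-recommendation tree; finding-level trees are a
  configuration, not code.

## Problem sizes

The test suite simulates cohorts of 30–4000 patients per category
depending on what a check needs: parameter-recovery checks use
$n = 2000$ per category (where maximum-likelihood beta fits land within
10 % of the generating shapes), separability and end-to-end checks use
40–60 per category, and certainty-normalization properties run over 1000
random CAFPA vectors. The demo pipeline (240 patients, one prediction
model, full 1023-combination search with leave-one-out refits) completes
in about a minute and a half on a single core.

## Known limitations

* Classification uses densities, not calibrated posteriors: class priors
  are implicitly uniform within each comparison set, as in the underlying
  decision scheme.
* The certainty is a within-comparison-set quantity; it does not account
  for uncertainty in the fitted training distributions themselves
  (narrow training samples yield overconfident certainties).
* Multi-label ground truth is handled by exclusion (evaluation) and
  double-contribution (training); the classifier itself always returns a
  single category per tree.
* The prediction layer tunes hyperparameters over deliberately small
  grids; it is a faithful, reproducible stand-in for a full model-building
  exercise, not a replacement for one.
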