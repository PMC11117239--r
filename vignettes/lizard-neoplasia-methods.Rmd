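---
title: "Methods: boosting and survival analysis of lizard neoplasia cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boosting and survival analysis of lizard neoplasia cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sauronc)
```

## The problem and the data model

Retrospective oncology cohorts of lizards combine two very different
sources: published case reports (heterogeneous, publication-biased, with
most signalment fields unreported) and a standardized clinical registry.
`sauronc` harmonizes both into one case-record schema: eight categorical
predictors (species, sex, life stage, histologic diagnosis, malignancy,
metastasis status, tumor location, treatment category), a case outcome,
and a survival time in months from diagnosis. Age in months is carried
for description only — the modeled predictors are all categorical.

Three harmonization rules matter most in practice:

* **Unknown is a level, not a hole.** Empty cells, `NA` and spelling
  variants normalize to a single `unknown` level which enters every
  analysis as an ordinary category. In data like these, unknownness is
  informative — whether sex or metastasis status was ever recorded
  correlates with how a case was managed — so imputing or dropping it
  would discard signal.
* **Malignancy classification.** Hematopoietic neoplasms (lymphoma,
  leukemia and synonyms) are malignant by definition; a clearly reported
  behavior passes through; ambiguous reports become malignant only with
  observed metastasis or destructive local invasion, otherwise
  `undetermined`.
* **Treatment categories.** Modality sets map to a fixed vocabulary
  (surgery / chemotherapy / radiation alone or combined, supportive care,
  unknown, none), with cryotherapy counted as surgery,
  electrochemotherapy, steroids and NSAIDs as chemotherapy, and
  photoradiation as radiation. Diagnostic sampling alone (aspirates,
  biopsies) is deliberately *not* a treatment.

### Outcome coding

The outcome is binary: y = 1 for a non-neoplastic outcome (alive, or
death from a cause other than the identified neoplasm), y = 0 for death
or euthanasia due to the neoplasm. Published effect tables for this kind
of analysis print positive effects for levels associated with the
non-neoplastic outcome, and the package follows that sign convention so
its effect tables read the same way; `encodeOutcome(positive_class =
"neoplasia_death")` flips it. Deaths of unknown cause are grouped with the
non-neoplastic class by default — they are not deaths attributed to the
identified neoplasm, and the two-class scheme offers no third option —
with `unknown_death = "exclude"` available; either way the validation
report flags such records. Fully unknown outcomes are never modeled.

## Componentwise boosting with categorical base-learners

The fit is L2 boosting with one ridge-penalized base-learner per
predictor. For predictor *j* with indicator block $Z_j$ (each row one-hot
over its levels) the base-learner solves

$$\hat c_j = (Z_j^\top Z_j + \lambda_j I)^{-1} Z_j^\top r$$

against the current residual vector $r$. Because the levels of one
variable are mutually exclusive, $Z_j^\top Z_j$ is the diagonal matrix of
level sample sizes, so the solution is the per-level residual sums shrunk
by $n_l + \lambda_j$ — a closed form used throughout.

$\lambda_j$ is not free: it is set per block by bisection so that the
hat-matrix trace $\sum_l n_l/(n_l+\lambda_j)$ equals a common target
`df`. Equalizing effective degrees of freedom is what makes the
componentwise selection fair — otherwise predictors with many levels
(species, diagnosis) would absorb residual variance at every iteration
simply by being more flexible.

The loop: the intercept is $\bar y$; each of `mstop` iterations fits all
blocks to the residuals, selects the one with minimal residual sum of
squares (ties, which occur only when two predictors induce the same
partition, go to the lowest block index — deterministic), and adds
$\nu \hat c_j$ to that block's accumulated coefficients. Coefficients of
never-selected predictors are exactly zero, and the loss trace is
provably non-increasing for $\nu \le 1$.

**Defaults** (`boostHyperparams()`): `mstop = 100`, `nu = 0.1`,
`df = 4` — the conventional defaults of model-based boosting frameworks
for this learner type. They are exposed, not tuned: with squared-error
loss on a 0/1 outcome the effects are probability-scale deviations, and
their absolute size depends on `mstop × nu`; what the permutation test
consumes is the effect relative to its own null, which is insensitive to
that scale. Blocks with fewer than `df` levels (sex, malignancy,
metastasis, life stage all have 3 here) are fitted unpenalized
($\lambda = 0$), the natural limit of the trace equation. Indicator
columns are not centered; the ridge penalty absorbs the intercept
confounding, which is a documented divergence risk versus
implementations that center.

Squared-error loss rather than a logistic loss is a deliberate choice:
it keeps effects on the probability scale of the published tables this
format mirrors, admits the closed-form inner solver, and — because the
permutation calibration is loss-agnostic — costs nothing in validity. A
logistic-loss variant is out of scope.

## Permutation inference

Each level's significance comes from its own permutation null: the model
is refitted on B permutations of the outcome vector (design fixed,
unstratified by source), and the two-sided p-value is

$$p = \frac{1 + \#\{b : |\hat\beta^{(b)}| \ge |\hat\beta|\}}{B + 1},$$

the finite-sample-corrected tail position, valid exactly under
exchangeability. The alternative percentile rule — flag when the observed
effect leaves the null's central $1-\alpha$ interval — is available via
`tail_rule = "percentile"`; the absolute-value rule is the default
because its p-value is exact at finite B without interpolation
assumptions. Significance is only awarded to levels with at least
`min_n = 2` individuals (singleton levels are reported, suppressed), and
no multiple-testing correction is applied across levels — the analysis
this mirrors applies none, and the calibration study quantifies what the
per-level rate actually is. The analysis default is B = 2000; the
simulation studies below use B = 500 as a scaled-down setting.

A note on mechanics: all B refits run as columns of one residual matrix
(`rowsum` over the level index does B base-learner fits at once). Tests
verify column-by-column identity with the scalar path, and an
independent naive loop (dense `solve`, explicit iteration) serves as the
engine's oracle.

## Survival analysis

Survival curves are product-limit estimates (computed via the survival
package) with the standard tied-time convention that censorings at a
death time follow the deaths. Time-zero deaths are legal: survival is
measured from diagnosis and same-day euthanasia is common in these
cohorts, so median survival can genuinely be 0 months. The 95% bands are
Greenwood-based on the complementary log-log scale,
$\exp(-\exp(\log(-\log \hat S) \pm z\,\mathrm{se}))$ with
$\mathrm{se} = \sqrt{\hat V}/|\log \hat S|$, which keeps them inside
$[0,1]$ by construction (the plain Greenwood interval does not); they
degenerate where $\hat S \in \{0, 1\}$.

`groupSurvival()` panels by malignancy and splits each panel into
neoplasia-without-treatment, neoplasia-with-treatment, and
death-from-non-neoplastic-cause. Alive cases censor at their last known
time inside their treatment group; deaths of unknown cause are excluded
from the survival contrast (their event attribution is the very thing
that is unknown) and reported in the excluded count.

## The synthetic cohort generator

`syntheticConfig()` defaults encode the study conditions the package is
exercised under: 274 records split 219:55 between a literature arm and a
registry arm; per-arm categorical marginals taken from the published
frequency tables of such a cohort, including the dominant unknown mass
(138/219 literature cases of unknown sex, 156/219 of unknown metastasis
status); a logistic link from summed per-level effects to the
probability of a non-neoplastic outcome (a linear-probability link is
available); exponential event times with group means by malignancy ×
treatment status (malignant untreated 3 months, treated 12,
non-neoplastic deaths 6; benign 8/24/12; undetermined intermediate), so
untreated and malignant cases die faster; and a 0.4 probability that a
non-neoplastic-outcome case is still alive, censored at an exponential
time of mean 12 months. Event-time means are the package's own choice of
a minimal rate model consistent with mortality-rate contrasts between
these groups; covariates are drawn independently across variables, a
documented simplification (no species × diagnosis dependence). One root
seed drives deterministic per-stage substreams, so identical
configurations give byte-identical cohorts.

What the generator does **not** emulate: correlated covariates,
publication bias in the literature arm, informative censoring, and any
real species–neoplasm associations. Passing tests therefore demonstrate
that the machinery is correct and calibrated on data with this
structure, not that any specific biological association in real cohorts
is reproduced — the real per-animal records are restricted-access.

## Simulation studies and their problem sizes

Three study functions exercise the inference end to end, sized so the
whole suite runs in minutes on one core:

* `calibrationStudy()` — 100 global-null cohorts of 274, B = 500: the
  mean per-level false-positive rate at $\alpha = 0.05$ lands within
  Monte-Carlo error of 0.05 (the +1 correction makes it mildly
  conservative, about 0.047 in typical runs).
* `powerStudy()` — 50 cohorts of 300, one injected effect, B = 500. The
  injected effect of 0.3 is read on the probability scale
  (linear-probability link, 0.5 → 0.8 on the affected level): a 0.3
  log-odds shift would be a ~0.07 probability shift, undetectable at
  these sample sizes, so the probability-scale reading is the one under
  which a detection-rate target of 0.8+ is meaningful. Observed detection
  with correct direction is ≥ 0.95.
* `kmOrderingStudy()` — 50 default-generator cohorts: the untreated
  malignant curve lies below the treated one at the pooled median time in
  every replicate.

## Numerical choices

* Bisection for $\lambda(df)$ runs to a $10^{-11}$ trace tolerance;
  `df = rank` short-circuits to $\lambda = 0$, `df > rank` errors.
* RSS comparisons across blocks use the algebraically equivalent
  reduction form $\sum_l s_l^2 (n_l + 2\lambda)/(n_l+\lambda)^2$; ties are
  broken by block index.
* Table percents round half-up to one decimal (base `round()` is
  banker's); headline unknown-percentages round half-up to whole
  percents.
* Degenerate inputs: empty cohorts error in fitting but are valid for
  I/O and summaries; constant outcomes yield all-zero effects; B = 0 is
  a valid (empty) null set but an error at significance time.

## The packaged fixture

`inst/extdata/printed_cohort_synthetic.csv` is a synthetic 274-record
reconstruction of the published aggregate tables: its marginal counts
reproduce the printed species, sex, life-stage, diagnosis, malignancy,
metastasis, location, treatment, outcome, survival-time and age
summaries, but its rows are constructed, not real cases. Where the
published tables disagree internally (a table cell versus the running
text, category counts that overrun the stated arm size), the running
text wins and the case is recorded in
`inst/extdata/discrepancy_log.json`. The fixture supports the
descriptive-summary tests; nothing inferential is claimed from it.

## Known limitations

Age is never modeled; loss families other than squared error and
cross-validated `mstop` selection are out of scope; permutations are not
stratified by source; no log-rank or proportional-hazards testing
accompanies the survival curves (the descriptive contrast is the
analysis); and the per-level permutation p-values are marginal — levels
of the same predictor share a fit and are not independent tests.
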