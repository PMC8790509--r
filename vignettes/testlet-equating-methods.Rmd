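---
title: "Testlet response theory models for NEAT-design equating: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testlet response theory models for NEAT-design equating}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Large-scale tests are commonly built from *testlets* — bundles of items
that share a stimulus, such as a reading passage. Items within a testlet
remain correlated even after conditioning on the examinee's general
ability $\theta$: a student familiar with the passage topic does better
on every item of that passage. This *local item dependence* (LID)
violates the conditional-independence assumption of ordinary item
response theory (IRT) models.

The practical question this package addresses is what that violation
does to *equating*: placing two test forms, taken by non-equivalent
examinee groups, on one reporting scale. The design modelled here is
the non-equivalent groups with anchor test (NEAT) design with *internal
anchors*: each form has 40 unique items plus a 20-item anchor block
administered to both groups, and the link is established by *concurrent
calibration* — one multiple-group estimation run in which the anchor
items carry a single parameter set, so no post-hoc scale transformation
is needed.

`testleteq` provides the four response models, a synthetic-data
generator for the full factorial simulation design, a concurrent
calibration engine, and the equating error statistics, so that the
whole misspecification experiment (fit an IRT model to testlet data,
compare with the testlet model) is reproducible end to end.

## Models

For a dichotomous item $j$ with discrimination $a_j$ and difficulty
$b_j$, the two-parameter logistic model (2PLM) and its testlet
extension (2PTM) are

$$P(y_{ij}=1) = \mathrm{logistic}\{a_j(\theta_i - b_j)\}, \qquad
  P(y_{ij}=1) = \mathrm{logistic}\{a_j(\theta_i - b_j - \gamma_{i\,d(j)})\},$$

where $d(j)$ is the testlet containing item $j$ and
$\gamma_{id} \sim N(0, \sigma^2_{\gamma d})$ is a person-by-testlet
random effect. $\sigma^2_{\gamma d}$ *is* the testlet effect: zero
recovers the 2PLM exactly, and larger values mean stronger
within-testlet dependence. Note the slope on $\gamma$ is constrained to
the item's $a_j$ — the testlet effect acts as a person-specific
difficulty shift — and no $D = 1.7$ scaling constant is used anywhere.

For 5-category graded items (codes 0–4) the graded response model (GRM)
uses cumulative boundary probabilities
$P^*_x(\theta) = \mathrm{logistic}\{a(\theta - b_x)\}$ for ordered
boundaries $b_1 < \dots < b_4$, with category probabilities
$P_x = P^*_x - P^*_{x+1}$ (and $P^*_0 = 1$, $P^*_K = 0$). The graded
response testlet model (GRTM) subtracts $\gamma_{id(j)}$ inside the
logit, exactly as in the 2PTM. With two categories the GRM reduces
algebraically to the 2PLM, and the package's tests assert both
reductions to machine precision.

A transcription note: the packaged printed item pools contain a pair of
category boundaries tied at two decimals. The model functions therefore
reject *decreasing* boundary vectors but tolerate ties — a tied pair
simply yields a zero-probability category, which is well defined — while
the parameter generator always produces strictly increasing boundaries.

## The synthetic-data generator

`build_form_pair()` constructs one NEAT form pair: per form, 20 locally
independent items, 20 non-anchor testlet items (4 testlets of 5 or 2 of
10), and a shared anchor block of 10 testlet items (2 × 5 or 1 × 10)
plus 10 independent items. Parameters are drawn by rejection sampling
(never clipping, which would create mass points): $a = e^z$,
$z \sim N(0,1)$, kept in $(0, 2.5)$ for non-anchor and $(1, 2)$ for
anchor items; $b \sim N(0,1)$ kept in $(-3, 3)$. Graded boundaries are
sorted independent truncated-normal draws — the generating distribution
for boundaries is a package choice, as only their range and ordering
are pinned down externally. Testlet variances come from
$U(0.1, 0.5)$, $U(0.6, 1.0)$, or $U(1.1, 2.0)$ for low, moderate, and
high LID.

Abilities are $N(0,1)$ in the base group — matching the difficulty
scale — and $N(\mu, 1)$ in the new group. The new-group mean is
`new_form_mean_shift`, default $+0.5$; the design only calls for a
"slightly higher" new-group mean, so the value is configurable.
Responses are always *generated* under the testlet model (testlet
effects exist in every condition); which family is *fit* is a separate
choice. A dichotomous response is 1 when the model probability exceeds
a $U(0,1)$ draw; a graded response is the number of cumulative boundary
probabilities that still exceed the draw.

### Printed pools versus sampled pools

The package also ships the two complete printed item pools (120
dichotomous and 120 graded items) as plain-text fixtures, loadable
verbatim with `load_printed_forms()`. These printed pools have markedly
higher discriminations (mean 1.51 for the dichotomous reference form)
than the stated sampling distribution can produce (a truncated
lognormal with mean ≈ 0.94), so results generated from sampled pools
and from the printed pools are *not* interchangeable: the printed pools
carry roughly twice the test information. `printed_form_pair()`
reconstructs a coherent NEAT pair from the printed tables — both forms
share the new form's printed anchor block (the reference form's printed
anchor rows are a layout duplicate of other rows), and testlet
membership groups the printed rows in order into testlets of the
requested length. The scaled-down condition replications in the test
suite and the acceptance script generate from this printed pair,
because those are the pools the published condition tables were
computed from; the distributional sampler remains the generator for the
general factorial machinery.

### Reproducibility

Every replication's RNG stream is derived deterministically from
`(master seed, condition index, replication index)` by a documented
integer hash (`derive_seed()`), so any single replication can be re-run
in isolation and a full study is bit-reproducible from its manifest.

## The calibration engine

`fit_concurrent()` maximises the marginal likelihood by EM over item
parameters, testlet-effect variances, and the new group's ability mean
and variance. Identification: the base group is fixed at $N(0,1)$;
anchor items carry one shared parameter set across groups. Estimation
is pure maximum likelihood — no priors — with positivity of $a$ and
$\sigma_\gamma$ enforced by the update steps rather than by a prior.

**Dimension reduction.** Each item loads on $\theta$ plus at most one
$\gamma_d$, with the $\gamma$ slope tied to $a_j$, so conditionally on
$\theta$ the likelihood factors over testlets. Integration cost is
(number of $\theta$ nodes) × (number of $\gamma$ nodes) *per testlet*,
never exponential in the number of testlets — the standard bifactor
identity. $\theta$ uses a fixed rectangular grid (default 21 points on
$[-5, 5]$); each testlet effect uses standardized Gauss-Hermite nodes (default 11
points) with the effect SD entering the item predictor, so the variance
update is a one-dimensional search. The per-testlet
collapse and the posterior count accumulation are implemented in C++,
as is usual for EM engines of this kind.

**M-step.** All item updates use safeguarded Fisher scoring (3 steps
per cycle by default): the expected information matrix is assembled
from the per-category derivative structure, the step is damped, ordered
boundaries are enforced, and a step is accepted only if it increases
the item's expected complete-data log-likelihood (with up to four step
halvings). Testlet SDs use Brent search on $[0, 3]$, keeping the best
of the candidate, the current value, and 0 — an SD estimated at the
zero boundary is reported as 0, a legitimate boundary ML estimate under
weak LID. The new-group density update is the closed-form normal
M-step. Because every block update is ascent-guarded, the marginal
log-likelihood is non-decreasing across cycles up to quadrature
arithmetic; the test suite asserts this on every fit it runs.

**Acceleration.** Plain EM needs several hundred cycles here. The
engine extrapolates along the EM path (Ramsay-style) once per cycle
after a burn-in, falling back to the plain EM iterate whenever the
extrapolated point fails to increase the marginal likelihood, which
preserves the ascent property while cutting cycle counts roughly
five-fold. Convergence is declared when the largest absolute parameter
change in a cycle falls below `conv_tol` (default $10^{-4}$), within
`max_cycles` (default 500); non-convergence is reported with a warning,
never silently.

**Starting values.** Starts are group-aware: the new-group mean starts
at a moment estimate from the score difference on shared items, and
each item's boundary starts are offset by the mean ability (under that
estimate) of the examinees who took it. This matters: with naive
pooled-frequency starts the concurrent graded-model likelihood has a
competing local optimum in which a large part of the group-mean shift
is absorbed into the new form's item parameters, and EM stays there.
The group-aware start reaches the better optimum (verified by
comparing converged marginal log-likelihoods from truth starts).

**Identification edge cases.** An item whose observed responses are
constant is flagged and excluded with a warning. A testlet with a
single administered item cannot separate its effect from the item's
parameters; such testlets are treated as locally independent and their
variance reported as 0, which also makes the 2PTM collapse cleanly onto
the 2PLM when every testlet has size one.

**Scoring.** `eap_score()` returns the posterior mean of $\theta$ under
each person's group density, integrating out testlet effects for the
TRT families. Ability results in the study runner use EAP scores — the
scoring rule is a package choice (ML or MAP would be alternatives) and
is deliberately the same for all four models so that ability
comparisons reflect the calibration, not the scoring rule.

## Equating error statistics

Across $R$ replications with estimate $\hat\lambda_r$ of a true value
$\lambda$:

$$\mathrm{Bias} = \tfrac1R\sum_r(\hat\lambda_r - \lambda), \quad
  \mathrm{SEE} = \sqrt{\tfrac1R\sum_r(\hat\lambda_r - \bar{\hat\lambda})^2}, \quad
  \mathrm{RMSE} = \sqrt{\tfrac1R\sum_r(\hat\lambda_r - \lambda)^2},$$

with divisor $R$ throughout, so $\mathrm{RMSE}^2 =
\mathrm{Bias}^2 + \mathrm{SEE}^2$ *exactly*; the suite asserts the
identity to $10^{-12}$. Bias is signed — no absolute values.

Aggregation into one condition-table cell is a genuinely open choice
and is therefore explicit and configurable: each statistic is computed
per item across replications, then averaged (unweighted, signed mean
for bias) over the items in scope. The default scope is the new form's
non-anchor testlet items — the equated items of interest; anchor-testlet
and all-item scopes are available because the published tables do not
state which items contributed. For abilities, each replication draws
fresh examinees, so person-level statistics are pooled within a
replication and then averaged across replications; the per-replication
SEE is defined through the decomposition identity.

## Problem sizes and what the scaled-down replications show

The full published design is 500 replications per cell. The packaged
checks use desk-scale sizes chosen so the whole suite runs in tens of
minutes on one core: 100 replications for the dichotomous low-effect,
length-5, n = 1,000 cell (both families fit to the same data — pairing
removes Monte Carlo noise from the model contrast), 12 replications of
the high-effect companion used only for the qualitative effect-level
ordering, and 30 replications of the graded low-effect cell. Monte
Carlo standard errors at these sizes are a few hundredths on the
reported statistics, well inside the tolerances used.

Two caveats delimit what passing (or failing) these checks can show.
First, the generator emulates idealised conditions: normal abilities
and effects, no item drift, no missingness beyond the structural NEAT
pattern, parameters exactly on the printed values. Real testlet data
violate all of these. Second, the published cell values themselves
embed an unreported commercial-software pipeline. Several of its
reported patterns — a large *positive* discrimination bias even for the
correctly specified testlet model, uniformly negative difficulty and
ability biases of about −0.10 and −0.08 in every condition, and
discrimination-parameter cells whose printed Bias exceeds the printed
RMSE, which the divisor-$R$ identity makes impossible — cannot be
produced by a consistent maximum-likelihood calibration of the stated
models. Projection arguments give the opposite sign for the
discrimination distortion: integrating an ignored testlet effect out of
the response function *flattens* it, so a misspecified IRT fit
attenuates discriminations. The package reproduces the qualitative
findings (testlet-model RMSE below IRT-model RMSE, IRT-model error
growing with the testlet effect and robust testlet-model error) and
treats the cell-level magnitudes it cannot reproduce as external-
pipeline artifacts; the uniform negative biases are consistent with a
calibration that left the group-mean difference in the estimates
(e.g., a single-group run), which `estimate_new_group = FALSE`
emulates if a user wants to explore that reading.

## Known limitations

- Pure logistic metric only; no 3PL guessing, nominal, or
  partial-credit families; no mixed-format forms.
- One random effect per item (a testlet partition), with the effect
  slope tied to the item discrimination — general bifactor loadings are
  out of scope.
- Separate calibration with Stocking–Lord or Haebara linking is not
  implemented; the package is about concurrent calibration.
- Standard errors of item estimates are not produced; uncertainty is
  assessed across Monte Carlo replications instead.
- Rectangular quadrature with ML updates can leave a testlet SD at the
  search boundary (reported as 0 or `s_max`) in pathological data;
  the study runner records non-converged or failed replications and
  excludes them from summaries rather than aborting.
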