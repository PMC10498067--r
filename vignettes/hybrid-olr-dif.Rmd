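---
title: "Detecting differential item functioning with the iterative hybrid OLR/IRT procedure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting differential item functioning with the iterative hybrid OLR/IRT procedure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(difolr)
```

## The problem

A questionnaire item shows *differential item functioning* (DIF) when
respondents at the same level of the underlying trait — here, dental anxiety
measured by a 36-item, 5-category instrument — have systematically different
response probabilities depending on group membership (gender, education, age
group). Items with large DIF distort group comparisons: an observed group
difference may be an artefact of item wording rather than a true trait
difference. DIF analysis screens every item against a matching variable that
stands in for the trait, and `difolr` implements the iterative hybrid
ordinal-logistic/IRT version of that screen, in which the matching variable
is a latent trait score that is itself purified of flagged items.

## The model

For item $Y$ with ordered categories $k = 0, 1, \dots, m-1$, trait $\theta$
and binary group $g$, three nested proportional-odds models are fitted:

$$
\begin{aligned}
\text{M1}: \operatorname{logit} P(Y \le k \mid g, \theta) &= \beta_{0k} + \beta_1 \theta\\
\text{M2}: \qquad &= \beta_{0k} + \beta_1 \theta + \beta_2 g\\
\text{M3}: \qquad &= \beta_{0k} + \beta_1 \theta + \beta_2 g + \beta_3 \theta g
\end{aligned}
$$

*Uniform* DIF (one group's propensity shifted in the same direction at every
trait level) is tested by the 1-df likelihood-ratio $\chi^2$ between M1 and
M2; *nonuniform* DIF (the group effect changes with the trait; response
curves cross) by the 1-df test between M2 and M3. The 2-df M1-vs-M3 test is
also computed and reported, but flagging uses the two 1-df comparisons.
Because $\chi^2$ significance is cheap at large $n$, two effect sizes
accompany the tests:

* the pseudo-$R^2$ differences
  $\Delta R_1 = 1 - \ln L(\text{M2}) / \ln L(\text{M1})$ and
  $\Delta R_2 = 1 - \ln L(\text{M3}) / \ln L(\text{M2})$, with values above
  0.070 conventionally treated as large DIF;
* the Crane–van Belle–Larson beta-change criterion
  $\Delta\beta_1 = \lvert(\beta_1^{\text{M1}} - \beta_1^{\text{M2}}) /
  \beta_1^{\text{M1}}\rvert$, with values above 0.01 treated as large
  uniform DIF.

The ratio form of $\Delta R$ above is the default because it is the form
the 0.070 cutoff is attached to; the textbook McFadden difference
$R^2_{\text{full}} - R^2_{\text{sub}}$ with
$R^2 = 1 - \ln L(\text{model})/\ln L(\text{intercepts})$ is available as
`delta_r_formula = "mcfadden_difference"` since the two definitions
circulate under the same name. They are not numerically interchangeable —
the ratio form divides by the sub-model likelihood, the McFadden form by the
intercept-only likelihood — which is why the choice is surfaced in the
configuration rather than hidden.

## The matching variable and the hybrid loop

The matching trait is never observed. Summed scores are contaminated by the
very items under suspicion, so the hybrid procedure scores each person with
an *expected a posteriori* (EAP) estimate from a graded response model: the
cumulative probability of each item step is
$P(Y \ge k+1 \mid \theta) = \operatorname{logit}^{-1}(a(\theta - b_k))$
with discrimination $a > 0$ and ascending thresholds $b_1 < \dots <
b_{m-1}$. Parameters are estimated by marginal maximum likelihood with an
EM algorithm over a fixed quadrature grid; EAP scores are posterior means
over the same grid, linearly standardised to sample mean 0 and SD 1.

The literature attached to this procedure sometimes calls the matching
score a "Rasch trait score", but a Rasch model in the strict sense has no
per-item discrimination and dichotomous items; for 5-category items the
natural reading is the graded family. `difolr` defaults to the graded model
(`model_variant = "graded"`) and offers an `equal_discrimination` variant —
one common slope, the closest ordered-category analogue of the Rasch
constraint — as a configuration switch, so either reading can be run.

The purification loop is:

1. **Iteration 0** — estimate item parameters on *all* items, score
   everyone by EAP, run the three-model comparison per item, flag items
   whose uniform or nonuniform $\chi^2$ is significant at $\alpha$.
2. **Iteration $t$** — re-estimate item parameters on the current anchor
   (unflagged) items (or keep the iteration-0 parameters when
   `refit_anchors = FALSE`), re-score everyone using anchors only,
   re-analyse *every* item against the purified trait, re-flag.
3. **Stop** when the flagged set repeats any earlier flagged set (a fixed
   point, or a detected cycle — which occurred is recorded in
   `termination`), or at `max_purification_iters`. If every item is
   flagged the loop stops with the last non-empty anchor set and a
   prominent warning.

Flagging for anchor selection uses the $\chi^2$ tests alone: the effect
sizes are always reported, but with the conventional cutoffs they rarely
fire at questionnaire scale, and driving purification from them would leave
the anchor set equal to the full set in most runs. A configuration switch
(`purification_criterion`) lets the effect-size or combined rule drive
anchoring instead.

## What the synthetic generator emulates

Because the motivating study's raw responses are not deposited, the package
ships a generator (`synthetic_spec()`, `simulate_responses()`) that plays
the role of the study data with known truth:

* a normal latent trait per group with common SD; *impact* (a true group
  difference, distinct from DIF) is a focal-group mean shift in SD units;
* graded-model items; defaults cycle discriminations through 0.9–1.8 and
  spread threshold centres evenly over the trait scale — typical published
  ranges for attitude questionnaires;
* injected uniform DIF as a constant shift $\delta$ of all focal-group
  thresholds (the focal expected item score is then lower at every
  $\theta$, which is the behavioural definition of uniform DIF), and
  nonuniform DIF as a focal-group discrimination ratio $\rho$ (the group
  response curves then cross).

The shipped desk-scale scenario (`default_scenario()`) uses 20 items,
5 categories, 500 persons per group, no impact, two uniform items
($\delta = 0.5$) and two nonuniform items ($\rho = 2$). The magnitudes are
chosen for test power at this sample size, not to mimic any particular
population, and the generator is deliberately idealised: responses are
conditionally independent given a unidimensional normal trait, missingness
is only MCAR masking, and there are exactly two groups. Passing recovery
tests on these data shows the machinery is correct under its own
assumptions; it does not certify behaviour under multidimensionality,
non-normal traits, or informative missingness.

## Numerical choices

* **Quadrature**: 49 equally spaced points on $[-4, 4]$ with renormalised
  normal weights (configurable). EAP standardisation uses the sample SD
  with the $n-1$ denominator; higher raw responses map to higher scores
  through the threshold orientation.
* **EM**: full M-step maximisation per item (box-constrained quasi-Newton
  on $(\log a, b_1, \log\Delta b)$ with analytic gradients, which keeps
  thresholds strictly ascending and $a > 0$ by construction); convergence
  when the largest absolute parameter change drops below $10^{-4}$, cap
  500 cycles. The observed marginal log-likelihood is recorded each cycle
  and asserted non-decreasing in the tests. The equal-discrimination
  variant alternates threshold updates with a one-dimensional search for
  the common slope (coordinate ascent, still monotone).
* **Sparse categories**: an item category with zero observations is merged
  into the adjacent lower category and the recode map is kept; an item
  with a single observed category is excluded with a warning.
* **Proportional-odds fits**: Newton iterations with analytic gradient and
  Hessian, start values from empirical cumulative log-odds (slopes 0),
  step-halving up to 20 times per iteration, at most 100 iterations,
  convergence at gradient max-norm $10^{-8}$. Cutpoints are kept strictly
  ascending, so fitted category probabilities are proper for every person.
  Design columns with zero variance (e.g. a constant trait in degenerate
  examples) are held at coefficient 0 instead of producing a singular
  Hessian. Coefficients beyond $\lvert 30\rvert$ on the standardised trait
  are reported as divergence (complete separation) and the fit marked
  non-converged even when saturation makes the gradient numerically small.
* **Model form and signs**: the models are fitted exactly as written on
  $P(Y \le k)$, so a group that favours *higher* categories gets a
  *negative* $\beta_2$. $\Delta\beta_1$ takes an absolute value and is
  therefore invariant to the group coding; groups are coded reference 0 /
  focal 1 in alphabetical order unless the factor says otherwise.
* **$\chi^2$ statistics** are clipped at 0 against numerical noise;
  per-item tests are uncorrected for multiplicity (matching per-item
  $\alpha = .05$ practice), with a Bonferroni switch off by default.
* **Large-effect boundaries** are strict inequalities
  ($\Delta R > 0.070$, $\Delta\beta_1 > 0.01$), following the convention
  "higher than" used with these cutoffs.
* **CFA**: the one-factor model is fitted to Pearson covariances by
  minimising the normal-theory ML discrepancy with analytic gradients;
  uniquenesses are floored at $10^{-4}\,s_{jj}$ and fits at the floor are
  reported as Heywood cases. CFI and TLI are reported unclipped alongside
  clipped companions; SRMR includes the diagonal. Items are treated as
  continuous — a polychoric option is out of scope, so indices for
  strongly skewed categorical items inherit the usual continuous-treatment
  bias. $\omega$ (from the fitted loadings) and Guttman's $\lambda_6$ are
  both reported because published tables sometimes label one as the other.
* **Group comparisons**: the person score is the *mean* item response on
  the 1–5 scale (sums would change scale when DIF items are removed), and
  both the pooled t-test and the Mann–Whitney U-test are reported for
  every comparison rather than guessing which one a reader expects. The
  Mann–Whitney p-value is exact (tie-aware rank-sum enumeration by dynamic
  programming) whenever $n_x n_y \le 400$, otherwise a tie- and
  continuity-corrected normal approximation.

## Properties worth knowing

* EAP is *not* a function of the summed score under the graded model, even
  with equal discriminations — the sum score is sufficient only for
  adjacent-category (partial credit) models. What does hold, and what the
  tests assert, is coordinatewise monotonicity: raising any single response
  raises the EAP, and the all-lowest/all-highest patterns attain the sample
  extremes.
* With the matching trait fixed at its generating values, Model 1 is
  exactly the data-generating model for a graded item, so the two DIF
  tests are asymptotically calibrated; the test suite verifies their size
  empirically. With estimated EAP matching the nonuniform test loses
  power relative to true-trait matching (shrinkage plus inclusion of the
  studied item in the score), which is visible in the recovery rates of
  the nonuniform scenario items.
* Group-specific curves for flagged items (`export_dif_curves`,
  `plot.dif_olr`) re-estimate those items' parameters per group by
  fixed-trait maximum likelihood against the purified EAP scores, anchors
  held common — one defensible construction among several, chosen because
  it needs no multi-group marginal estimation.

## Problem sizes used by the checks

The package's own verification uses desk-scale runs: null calibration with
500 replicates of 10 no-DIF items at 500 persons per group; power with 100
replicates of a $\delta = 1$ uniform shift at 1000 per group; purification
recovery over 100 seeds of the shipped 20-item scenario (with iteration-0
parameters frozen, the documented fast path); graded-model recovery at
$n = 2000$; CFA calibration at $n = 5000$. These sizes give Monte-Carlo
standard errors small enough for the stated bounds while keeping a full
verification run in the minutes range.

## Limitations

Two groups per run; unidimensional matching trait; no polychoric CFA, no
partial proportional odds, no Monte-Carlo-calibrated flagging thresholds,
no plausible-value scoring. Listwise deletion is the default missing-data
policy (`pairwise_item` keeps persons in the items they answered and scores
the trait from observed items); neither policy models informative
missingness.

## A short run

```{r example, eval = FALSE}
sim <- simulate_responses(default_scenario(seed = 1))
fit <- dif_olr(sim$data, dif_config(refit_anchors = FALSE))
summary(fit)
compare_with_without_dif(fit)
```
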