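---
title: "Modelling continuous and binary learning in the Breathing Learning Task"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling continuous and binary learning in the Breathing Learning Task}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bltlearn)
library(dplyr)
```

## The task and its coding

The Breathing Learning Task (BLT) is a probabilistic cue–outcome
learning task in the interoceptive domain: on each of 80 trials one of
two visual cues is shown, the participant predicts whether an
inspiratory breathing resistance will follow, and the stimulus is then
delivered or not. One cue predicts resistance with probability 0.8 and
the other with probability 0.2; the pairing reverses after trial 30 and
then three more times at 12–13-trial intervals, so participants must
keep updating their beliefs. In the continuous version of the task the
prediction is a slider from "definitely no" (0) to "definitely yes"
(10), giving a bounded continuous response rather than a forced choice.

Because the two contingencies are coupled (when one cue means 80% the
other means 20%), both can be tracked on a single axis. `bltlearn`
codes every trial in *contingency space*: the outcome `o` is 1 when
cue 1 was paired with resistance or cue 2 with no resistance, and 0
otherwise; slider predictions under cue 2 are reflected
(`to_contingency_prediction()`). The coding is label-symmetric —
swapping cue labels complements both predictions and outcomes and
leaves every likelihood in the package unchanged (this is verified as a
test invariant). It does assume learning is the same for resistance and
no-resistance trials, which is exactly the assumption the dual-rate
model relaxes.

`blt_schedule()` generates this design. Two choices were genuinely
open:

* **Block lengths.** The partition `c(30, 13, 12, 13, 12)` is the only
  split of 80 trials into 30 + four blocks of 12–13 that matches the
  published design; it is the default and is configurable.
* **Outcome realization.** Whether the original task drew each trial
  independently (`"bernoulli"`) or fixed the per-block frequency of
  consistent outcomes is not documented. The default,
  `"exact_proportion"`, fixes the count at `round(0.8 * block length)`
  so that every simulated cohort experiences identical contingencies,
  which makes recovery experiments comparable across seeds. Cue order
  is balanced within block and uniformly shuffled.

## The learning model

Beliefs follow the Rescorla–Wagner update. With \(v_t\) the predicted
(contingency-space) outcome entering trial \(t\) and \(o_t\) the
outcome,

\[
v_{t+1} = v_t + \alpha\,\delta_t, \qquad \delta_t = o_t - v_t,
\]

with learning rate \(\alpha \in [0,1]\) and \(v_0 = 0.5\) (complete
uncertainty; fixed, never estimated). The dual-rate variant replaces
\(\alpha\) with \(\alpha_p\) on no-resistance (positive-valence,
\(s_t = 0\)) trials and \(\alpha_n\) on resistance (negative-valence,
\(s_t = 1\)) trials; with \(\alpha_p = \alpha_n\) it reproduces the
single-rate trajectory exactly. Trials with a missed response still
update the trajectory — the stimulus was experienced whether or not the
slider was moved — but contribute nothing to any likelihood.

## Observation models

**Binary.** Binarised predictions (slider \(> 0.5\) becomes 1,
\(< 0.5\) becomes 0, exactly 0.5 is treated as missed) are modelled by
a two-option softmax,

\[
p(y_t = 1 \mid v_t, \beta) =
\frac{e^{\beta v_t}}{e^{\beta v_t} + e^{\beta(1 - v_t)}}
= \mathrm{logistic}\!\big(\beta(2v_t - 1)\big),
\]

where the inverse temperature \(\beta > 0\) captures decision noise.
The logistic form is evaluated on the log-odds scale, so the likelihood
is exact and finite for \(\beta\) well beyond \(10^3\).

**Continuous.** Slider predictions in \([0,1]\) are modelled as beta
distributed with mean equal to the trajectory value and a shared
dispersion \(\phi\), via the mean–dispersion re-parameterisation
\(a = \mu\phi\), \(b = (1-\mu)\phi\). Larger \(\phi\) means responses
cluster more tightly around the model prediction — \(\phi\) is a direct
group-level index of response consistency and is deliberately a single
scalar across subjects and trials (per-subject dispersion is possible
in principle but not implemented). A response exactly at 0.5 is kept in
the continuous likelihood even though it is "missed" for the binary
model: the slider was used, and 0.5 is an informative statement of
indecision.

Because the beta density is degenerate at 0 and 1, both responses and
means are clipped to \([\varepsilon, 1-\varepsilon]\) with
\(\varepsilon = 10^{-4}\) before evaluation (`eps` is an argument
throughout). This follows standard beta-regression practice for
boundary observations. We examined the alternatives — treating boundary
responses as missing, reflecting them, or modelling them as censored
mass — and clipping retains by far the most information about
\(\alpha\) when responses saturate; the recovery correlations were
essentially flat for \(\varepsilon\) between \(10^{-4}\) and
\(10^{-2}\).

## MAP estimation

All fits maximise the response log-likelihood plus Gaussian log-priors
specified in native parameter space (`blt_priors()`): \(\alpha\) (and
both dual rates) \(\sim N(0.34,\, 0.88)\) truncated to \([0,1]\), and
\(\beta \sim N(4.21,\, 1.75)\), both derived from pilot data for this
task family. Truncation is implemented as the Gaussian log-density plus
hard box bounds — the normalisation constant does not depend on the
parameter, so it cannot move the MAP. The dispersion \(\phi\) carries
an improper flat prior on \((0, 500]\): no pilot information exists for
it, so its estimate is likelihood-driven.

Optimisation is single-start bounded L-BFGS-B from the prior means,
with analytic gradients throughout (the trajectory sensitivity
\(\partial v_t / \partial \alpha\) follows the recursion
\(g_{t+1} = (1-\alpha)g_t + \delta_t\); the \(\phi\) gradient uses
digamma terms). The binary model is fitted per subject (two or three
parameters). The continuous model is a genuinely joint problem — all
subject-level rates plus the one shared \(\phi\), i.e. \(S + 1\)
(or \(2S + 1\)) dimensions — and is solved in one L-BFGS-B call with
the gradient vectorised across subjects. \(\phi\) is optimised on the
log scale purely for conditioning; under its flat prior this cannot
move the optimum (it is the maximum-likelihood coordinate either way),
and \(\phi\) starts at 10, mid-range on the log scale. Convergence
tolerance is the optimiser's default objective tolerance
(`factr = 1e7`, roughly \(10^{-9}\) relative); non-convergence is
flagged in the `converged` column, never silent. Gradients are verified
against central finite differences, and MAP optima against dense
grid-search oracles, in the test suite.

### Null models and model comparison

The null model clamps \(\alpha = 0\), so \(v_t \equiv 0.5\): all
structure in the responses is attributed to noise. For the binary null
the likelihood is then exactly \(n \ln 0.5\) and does not depend on
\(\beta\) at all, so the null has **zero** free parameters; the
continuous null still genuinely estimates \(\phi\)
(\(\kappa = 1\)). This bookkeeping is the package's own resolution of
an ambiguity: counting a parameter the likelihood does not contain
would penalise the null for complexity it does not have (and the
published null-model BIC and AIC being identical is consistent with a
zero count). For the learning models, \(\kappa\) counts all free
parameters: \(2S\) for the binary model (\(\alpha, \beta\) per
subject), \(S + 1\) for the continuous group fit, \(3S\) and
\(2S + 1\) for the dual variants.

Criteria follow \(-2\ln\hat L + c\kappa\) with \(c = \ln n\) (BIC,
\(n\) = pooled non-missing responses) or \(c = 2\) (AIC), computed on
pooled data so each model gets one score
(`information_criteria()`, `glance()`). Score differences convert to
Bayes factors as \(\exp(\Delta/2)\) (`bayes_factor()`); BIC/AIC
comparisons are only meaningful between models fitted to the same
data, which `compare_fits()` checks. A second, complementary check is
`group_trajectory_validation()`: the per-trial mean of fitted
predictions (softmax probabilities for the binary model, \(v_t\) for
the continuous) correlated against the per-trial mean of observed
predictions; for a null model the modelled series is constant and the
correlation is reported as 0 by convention.

## Parameter recovery

`recovery_experiment()` implements the validation loop: per run, draw
500 learning rates from a normal with mean 0.34 and variance 0.88
truncated to \([0,1]\) (inverse-CDF sampling, `draw_alpha()`), simulate
responses on one shared schedule, re-fit with the matching model and
the standard priors, and compute the Pearson correlation between
simulated and recovered rates; 10 runs per noise level are pooled by
Fisher-z averaging. Binary simulations draw each response from the
softmax probability at the simulated \(\beta\) (which is then
re-estimated during fitting, not fixed); continuous simulations add
\(N(0, \sigma^2)\) noise to the trajectory and clip to \([0,1]\) —
of the readings of "bounding" we tested (clipping, reflection,
truncated resampling), only clipping preserves the information
structure that makes recovery work at high noise. Dual-rate recovery
draws \(\alpha_p\) and \(\alpha_n\) independently from the same
truncated normal. One master seed spawns an independent stream per run,
so any single run can be reproduced without re-running the rest.

Two qualitative signatures are worth knowing about (both asserted as
tests): at low decision noise the binary model shows a ceiling effect —
recovered rates flatten above \(\alpha \approx 0.6\), because once
learning is fast enough the binarised choices barely change — and at
high continuous noise (\(\sigma = 0.4\)) recovered rates are biased
downward.

One genuine sensitivity deserves emphasis: at high noise the recovery
correlation depends noticeably on the particular realization of the
outcome schedule (which trials carry the 20% inconsistent outcomes).
Across schedule seeds we observed Fisher-z mean correlations at
\(\sigma = 0.4\) ranging over roughly 0.78–0.89. The original task used
one fixed, unpublished outcome sequence; any comparison of recovery
values at high noise should therefore be read with this
schedule-realization variance in mind. The full-scale experiment
(4 + 4 + 1 noise levels, 10 runs of 500 subjects each) runs in a few
minutes on one CPU; the package's own test suite runs the same design
at full scale, and the smaller unit tests use 40–250 subjects, which is
enough for stable correlation checks.

## Synthetic studies

`generate_study()` produces complete artificial cohorts: ground-truth
rates from the truncated normal, responses through the simulators above
written back in the raw task dialect (cue-referenced 0–10 sliders),
uniform-at-random missed trials, report-phase answers echoing the true
stimulus with a configurable lapse rate, and questionnaire-like scores.
Questionnaires use Gaussian marginals (defaults set to published cohort
medians and IQR/1.349 — purely cosmetic) and can be tied to behaviour
through a Gaussian copula: to hit a target Spearman \(\rho_s\) with the
ground-truth rate or the certainty score, the latent correlation is set
to \(2\sin(\pi\rho_s/6)\).

What the generator does *not* emulate — and therefore what passing
tests cannot show about real data: sequential response dependencies
(perseveration, slider inertia), subject-specific response styles
(anchoring, granularity, per-subject dispersion), attention lapses that
correlate with the schedule, report-phase errors that depend on the
stimulus, and item-level questionnaire structure. Recovery results here
validate the *estimator*, not the model's adequacy for any empirical
cohort.

## Known limitations

* The continuous fit's shared \(\phi\) couples subjects: a few very
  noisy subjects lower \(\phi\) for everyone and thus increase
  prior shrinkage on everyone's \(\alpha\).
* Per-subject \(\alpha\) from one 80-trial session is only moderately
  identified; at \(\sigma = 0.4\) individual estimates carry
  substantial error even though cohort-level correlations stay high.
* Single-start optimisation is the documented design; the posterior
  surfaces here are well-behaved in practice (grid-search oracles agree
  in tests), but multimodality cannot be excluded for pathological
  response patterns.
* BIC/AIC use the pooled-observation \(n\) and the \(\kappa\)
  bookkeeping described above; other bookkeeping conventions shift both
  scores by a constant per model and can change Bayes-factor
  magnitudes, though rarely the ordering.

## A compact worked example

```{r example, eval = FALSE}
sched <- blt_schedule(seed = 1)
study <- generate_study(blt_study_spec(n_subjects = 30, noise = 0.2,
                                       seed = 8))
resp <- blt_preprocess(study$responses)

fit <- fit_continuous(resp, study$schedule)
null <- fit_null(resp, study$schedule, "continuous")
compare_fits(model = fit, null = null)

rec <- recovery_experiment("continuous", noise = c(0.05, 0.4),
                           n_runs = 2, n_subjects = 100, seed = 3)
glance(rec)
autoplot(rec)
```
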