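# bltlearn

Rescorla–Wagner modelling of continuous and binary prediction responses
in the Breathing Learning Task (BLT).

The BLT is a probabilistic reversal-learning task in the interoceptive
domain: across 80 trials, two visual cues predict an inspiratory
breathing resistance with coupled 80%/20% contingencies that reverse
four times, and participants predict the upcoming stimulus — either as
a forced choice or on a continuous "definitely no" to "definitely yes"
slider. `bltlearn` is for researchers in computational psychiatry and
interoception who want to fit trial-by-trial learning models to such
data, validate them by simulation, and relate the fitted parameters to
individual-difference measures.

## The models

Beliefs about the (contingency-space) outcome follow the
Rescorla–Wagner update with learning rate α and initial prediction
v₀ = 0.5:

    v[t+1] = v[t] + α (o[t] − v[t])

Two observation models link the trajectory to behaviour:

* **Binary**: binarised predictions are modelled by a softmax,
  p(y=1 | v, β) = logistic(β(2v − 1)), with inverse temperature β
  capturing decision noise; α and β are estimated per subject.
* **Continuous**: slider predictions are beta distributed with mean v
  and shared dispersion ϕ (shapes a = μϕ, b = (1−μ)ϕ); subject-level
  rates and the single group-level ϕ are estimated jointly.

A dual-rate variant splits α into αp (no-resistance trials) and αn
(resistance trials). Estimation is maximum a posteriori under Gaussian
priors in native space (α ~ N(0.34, 0.88) bounded to [0, 1],
β ~ N(4.21, 1.75)), by single-start bounded L-BFGS-B with analytic
gradients. No-learning null models (α = 0, so v ≡ 0.5), BIC/AIC,
Bayes factors, simulation-based parameter recovery with Fisher-z
averaged correlations, behavioural preprocessing (contingency-space
coding, binarisation, certainty scores, exclusion rules), and fully
synthetic study generation round out the pipeline. See the vignette
(`vignettes/modelling-the-blt.Rmd`) for the complete methods account.

## Worked example

Generate a synthetic 30-subject cohort with moderate slider noise
(σ = 0.2), preprocess it as raw task output, and fit the continuous
model:

```r
library(bltlearn)

study <- generate_study(blt_study_spec(n_subjects = 30, noise = 0.2, seed = 8))
resp  <- blt_preprocess(study$responses)
fit   <- fit_continuous(resp, study$schedule)
glance(fit)
#> # A tibble: 1 × 8
#>   model_id   n_subjects loglik kappa n_obs    bic    aic converged
#>   <chr>           <int>  <dbl> <int> <dbl>  <dbl>  <dbl> <lgl>
#> 1 continuous         30  1832.    31  2357 -3423. -3601. TRUE
```

The pooled log-likelihood covers all 2,357 non-missing responses;
κ = 31 counts the 30 subject learning rates plus the shared dispersion.
Comparing against the no-learning null model:

```r
compare_fits(model = fit, null = fit_null(resp, study$schedule, "continuous"))
#>   name  model_id        ... loglik kappa n_obs    bic    aic
#> 1 model continuous           1832.    31  2357 -3423. -3601.
#> 2 null  continuous_null       934.     1  2357 -1860. -1866.
```

The learning model wins by ~1,563 BIC points — overwhelming evidence
that responses track the contingencies. The fitted trajectories also
mirror cohort behaviour trial by trial:

```r
group_trajectory_validation(fit, resp, study$schedule)
#> <blt_validation> model: continuous  r = 0.956  p = 2.56e-43

cor(study$truth$alpha, fit$alpha)   # ground truth vs recovered rates
#> [1] 0.966
```

A scaled-down recovery experiment (the full design uses 10 runs of 500
subjects per noise level):

```r
rec <- recovery_experiment("continuous", noise = c(0.05, 0.4),
                           n_runs = 2, n_subjects = 100, seed = 3)
glance(rec)
#> # A tibble: 2 × 6
#>   noise parameter mean_r n_runs model_id   n_subjects
#> 1  0.05 alpha      0.998      2 continuous        100
#> 2  0.4  alpha      0.800      2 continuous        100
autoplot(rec)   # simulated-vs-recovered scatter per noise level
```

Learning rates recover almost perfectly under low response noise and
degrade (with a downward bias) as noise grows.

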