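# patsurv

Estimation of a failure-time distribution ("patience time") from survival
data observed through three channels at once:

* **served** subjects (category 1): the waiting time W is observed and the
  patience time T is *right-censored* at W;
* **announced abandonment** (category 2): T is *observed exactly* — the
  subject left and said so;
* **silent abandonment** (category 3): the subject left without saying so,
  which is discovered only when they are called to service, so T is
  *left-censored* at the (virtual) waiting time W.

This mix arises wherever self-reporting coexists with screening: patients
who leave an emergency department without being seen (some announce it,
some do not), self-detected vs screening-detected disease onset, customers
abandoning service queues or chats. Each subject contributes a triplet
(U, Y, Δ) with U = YT + (1−Y)W the recorded time, Δ = 1{T < W} the
abandonment indicator, and Y the announcement indicator (visible only when
Δ = 1). The announcement probability q(t) = P(Y = 1 | T = t) is an unknown
nuisance function that is never estimated.

## The estimators

**Semiparametric.** With parametric families g(·; γ) for W and f(·; θ) for
T, the likelihood factorizes so that γ̂ is an ordinary right-censored MLE
(W is observed except in category 2). θ is then estimated from the *partial
likelihood of the served subjects only*, whose contribution
g(U; γ̂)F̄(U; θ) / ∫ g(s; γ̂)F̄(s; θ) ds does not involve q. With both
families exponential the estimators are closed-form:

    γ̂ = (n − Σ Δᵢ Yᵢ) / Σ Uᵢ ,    θ̂ = Σ (1 − Δᵢ) / Σ (1 − Δᵢ) Uᵢ − γ̂ .

**Nonparametric.** From the identity

    F(t) = [p₃ r₃(t) + p₁ r₁(t) A(t)] / [p₃ r₃(t) + p₁ r₁(t)] ,

where p₁ = P(W ≤ T), p₃ = P(Y = 0, T < W), rᵢ is the conditional density of
U within category i, and A(t) = ∫₀ᵗ q(s)f(s) ds, the plug-in estimator uses
empirical proportions for p₁ and p₃, reflected Gaussian kernel estimates
for r₁ and r₃, and a Nelson–Aalen-type jump sum for A:
Â(t) = 1 − exp(−Σ 1/(n Ŷ(Uᵢ))) over announced events Uᵢ ≤ t, with Ŷ the
at-risk proportion. The result is made monotone by a running maximum.

A seeded simulator (with analytic category-probability oracles), a
density-weighted integrated-squared-error metric, and a Monte-Carlo harness
comparing both estimators across sample sizes complete the package.

## Worked example

```r
library(patsurv)
setting <- sim_setting(exp_family(mean = 16), exp_family(mean = 2),
                       q_exp_decay(), n = 2000, seed = 42)
obs <- simulate(setting)
format_category_counts(category_counts(obs))
#>        service      announced         silent
#> "1811 (90.5%)"    "71 (3.5%)"   "118 (5.9%)"

fit <- fit_semipar(obs, exp_family(rate = 1), exp_family(rate = 1),
                   bootstrap = 200, seed = 1)
fit
#> <semipar_fit: W ~ exponential, T ~ exponential, n = 2000>
#>   gamma_hat: rate = 0.502014
#>   theta_hat: rate = 0.0560757
#>   bootstrap SEs (B = 200): gamma 0.0118 | theta 0.00704

np <- fit_nonparam(obs)
np
#> <nonparam_fit: n = 2000 (served 1811, announced 71, silent 118)>
#>   tau = 6.154, grid = 512 points, bandwidths b1 = 0.2934, b3 = 0.831
#>   F_mono(tau) = 0.2730, A_hat(tau) = 0.0542
```

The simulated patience time is exponential with mean 16 h (rate 0.0625)
censored by waiting times of mean 2 h, so only ~9.5% of subjects abandon;
the waiting-time rate is recovered almost exactly (0.502 vs 0.5) and the
patience rate to within one bootstrap standard error (0.0561 ± 0.0070 vs
0.0625). The nonparametric fit estimates the abandonment cdf up to the 0.95
quantile of the observed times (τ ≈ 6.2 h); at 5 h it gives survival 0.736
against the true 0.732. The error metric weights squared survival error by
the true density:

```r
mse_survival(semipar_survfun(fit), setting$t_family)   #> 0.00087
mse_survival(nonparam_survfun(np), setting$t_family)   #> 0.128
```

(The nonparametric figure is dominated by the ~68% of patience-time mass
beyond τ, where the curve is extended as a constant; see the vignette.)

A thin command-line wrapper (`inst/cli/patsurv.R`) exposes `simulate`,
`fit` (per-stratum analysis of a CSV of triplets, with category accounting
and both survival curves), and `study` (the Monte-Carlo comparison) for
shell use; see `inst/extdata/example_config.yaml`.

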