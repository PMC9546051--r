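---
title: "Estimating patience-time distributions from served, announced, and silent observations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating patience-time distributions from served, announced, and silent observations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The observation model

Each subject carries a latent patience time $T$ (cdf $F$, density $f$) and
an independent waiting time $W$ (cdf $G$, density $g$); both are
nonnegative and continuous. The subject abandons if patience runs out
first, $\Delta = 1\{T < W\}$, and an abandoning subject announces it with
probability $q(t) = P(Y = 1 \mid T = t)$, a completely unknown function.
What the analyst records is the triplet $(U, Y, \Delta)$ with
$U = YT + (1-Y)W$, which partitions the sample into three categories:

| category | $(\Delta, Y)$ | recorded time | information on $T$ |
|---|---|---|---|
| 1 served | $(0, 0)$ | $U = W$ | right-censored at $U$ |
| 2 announced | $(1, 1)$ | $U = T$ | observed exactly |
| 3 silent | $(1, 0)$ | $U = W$ | left-censored at $U$ |

The configuration $(\Delta, Y) = (0, 1)$ cannot occur — an announcement is
only seen when the subject actually leaves — and the package rejects it at
data entry. The pair $(Y, T)$ is assumed independent of $W$; when that
fails (e.g. when urgency drives both waiting and patience), the intended
remedy is stratification, which the CSV interface and the `fit` command
support directly. Ties $T = W$ have probability zero for continuous
families; the indicator convention $\Delta = 1\{T < W\}$ classifies an
exact tie as "served".

The recorded time has sub-stochastic densities per category,
$h_1 = g\bar F$, $h_2 = qf\bar G$, $h_3(t) = g(t)\int_0^t(1-q)f$, with
category probabilities $p_i = \int h_i$ and conditional densities
$r_i = h_i / p_i$. `category_probabilities()`, `subdensities()`, and
`true_A()` evaluate these by adaptive quadrature (absolute tolerance
$10^{-8}$) and serve as analytic oracles throughout the test suite:
conservation $p_1 + p_2 + p_3 = 1$, normalization of each $r_i$, and
agreement of simulated frequencies with the analytic probabilities at
binomial-error resolution.

## Semiparametric estimation

With parametric families $g(\cdot;\gamma)$ and $f(\cdot;\theta)$, the full
likelihood factorizes into a $\gamma$-part — an ordinary right-censored
likelihood, since $W$ is observed in categories 1 and 3 and right-censored
at $T$ in category 2 — and a $\theta$-part contaminated by the unknown
$q$. The package therefore maximizes the $\gamma$-factor exactly, then
estimates $\theta$ from the partial likelihood of the served subjects
alone, each contributing
$g(U_i;\hat\gamma)\bar F(U_i;\theta) / \int_0^\infty
g(s;\hat\gamma)\bar F(s;\theta)\,ds$; the $g$-factors are constant in
$\theta$, so announced and silent observations influence $\hat\theta$ only
through $\hat\gamma$ (a property the suite verifies by a perturbation
test).

Numerical choices:

* **Exponential/exponential closed forms.**
  $\hat\gamma = (n - \sum\Delta_iY_i)/\sum U_i$ and
  $\hat\theta = \sum(1-\Delta_i)/\sum(1-\Delta_i)U_i - \hat\gamma$. The
  second is *not* truncated at zero: in small samples the difference can
  be negative, giving an improper survival curve $e^{-\hat\theta t} > 1$.
  Truncation would be a different estimator with different error
  behavior; the evaluation harness measures the estimator as defined, and
  a `clip` flag is available wherever curves are produced for practical
  use. `survival_curve()` flags improper values with a warning either way.
* **General families.** Quasi-Newton (BFGS) maximization on
  log-transformed parameters (positivity by construction), three starts
  scaled by ×½/×1/×2 around a moment-based start, objective tolerance
  $10^{-12}$; disagreeing near-optimal starts raise a multi-start warning
  (the model's uniqueness assumptions are not checked programmatically).
  For the exponential/exponential pair the partial objective is defined on
  the whole half-line $\theta > -\hat\gamma$ (the normalizing integral is
  $\hat\gamma/(\hat\gamma+\theta)$ in closed form), so the numerical path
  searches that full interval and agrees with the closed form to
  $10^{-6}$ on every tested dataset. For other pairs the normalizer is
  computed by quadrature at each step.
* **Standard errors.** The estimator's asymptotic covariances have no
  closed form here; `fit_semipar(bootstrap = B)` resamples triplets with
  replacement (seeded, default off) and reports bootstrap SDs.

## Nonparametric estimation

The identity
$F(t) = \{p_3 r_3(t) + p_1 r_1(t) A(t)\}/\{p_3 r_3(t) + p_1 r_1(t)\}$,
with $A(t) = \int_0^t q f$, expresses the target through quantities that
are estimable without knowing $q$:

* $\hat p_1 = n^{-1}\sum(1-\Delta_i)$,
  $\hat p_3 = n^{-1}\sum\Delta_i(1-Y_i)$;
* $\hat r_1, \hat r_3$: Gaussian kernel density estimates over each
  category's recorded times, reflected at zero (times are nonnegative, and
  reflection prevents the familiar halving of boundary mass), bandwidth by
  Silverman's rule per category unless supplied. The kernel and bandwidth
  are the package's choices — the underlying theory only prescribes a
  smoothness-dependent rate;
* $\hat A(t) = 1 - \exp(-\hat D(t))$ with
  $\hat D(t) = \sum_{i:\,Y_i\Delta_i = 1,\ U_i \le t} 1/(n\hat Y(U_i))$
  and $\hat Y(t) = n^{-1}\sum 1\{U_j \ge t\}$ — a Nelson–Aalen-type jump
  sum. The at-risk set is closed at $t$, so each jump's own observation is
  at risk and the ratio is always defined; tied announced times contribute
  separate jumps at the common at-risk count. Under universal
  announcement ($q \equiv 1$) this reduces *exactly* to one minus the
  exponentiated Nelson–Aalen cumulative hazard of $T$ right-censored by
  $W$, which the suite checks against `survival::survfit()`.

`fit_nonparam()` assembles these on 512 equally spaced points over
$[0, \tau]$. Where both density terms fall below $10^{-12}$ (far in the
observed-time tail) the ratio would be $0/0$; the last well-defined value
is carried forward instead. Kernel estimates make the raw ratio
non-monotone, so the estimate is replaced by its running maximum
(cumulative supremum) — idempotent, order-preserving, and the smallest
nondecreasing majorant on the grid. The construction keeps
$\hat F \in [0, 1]$ automatically. Fewer than ten silent observations
trigger an instability warning; fewer than two drop the $r_3$ term (with a
warning), which degrades gracefully to $\hat F \equiv 0$ when there is no
abandonment evidence at all.

**Choice of $\tau$.** Theory requires estimating on $[0, \tau]$ with both
$P(T > \tau)$ and $P(W > \tau)$ positive, but fixes no value. The
default is the 0.95 empirical quantile of the recorded times — a
conservative choice keeping kernel estimates inside the data-rich region,
appropriate for presenting a fitted curve. Beyond $\tau$ (and for
integration against a full-support density) the curve is extended as a
constant at $\hat F(\tau)$.

## The simulator

`sim_setting()` + `simulate()` generate triplets by drawing all $n$
patience times, then all $n$ waiting times, then all $n$ announcement
indicators $\mathrm{Bern}(q(T))$ — a documented order, so a seed pins the
whole dataset. The reference settings mirror an emergency-department-like
regime: patience exponential with mean 16 h (setting 1) or Weibull with
scale 16 and shape 1.5 (setting 2), waiting exponential with mean 2 h,
and $q(t) = e^{-t}$ — late abandoners rarely announce. Times are in
hours; since $q$ is not scale-free, the unit matters (in minutes the same
formula would extinguish announcements almost entirely), and both $q$ and
all family parameters are configurable.

What the simulator deliberately omits: dependence between $T$ and $W$
(excluded by the model; real queues induce it through congestion, which is
why the case-study workflow stratifies), covariates, arrival processes,
and discrete or rounded times. Passing tests therefore demonstrate
correctness under the model's assumptions, not robustness to their
violation.

## The Monte-Carlo study

`run_mse_study()` compares both estimators by
$\mathrm{MSE}(\hat{\bar F}, \bar F_0) = \int (\hat{\bar F} -
\bar F_0)^2 f_0\,dt$, the true-density-weighted integrated squared error.
Substituting $p = F_0(t)$ maps this to $\int_0^1 (\hat{\bar F}(F_0^{-1}(p))
- (1-p))^2\,dp$, evaluated two independent ways: 512-node Gauss–Legendre
quadrature (default) and stratified quasi-random sampling at $10^5$
midpoints; the suite requires the two to agree to $10^{-3}$ and checks
both against exact closed forms (a constant estimate gives $1/3$ for any
truth; a rate-shifted exponential gives
$1/3 - 2\theta/(3\theta+\delta) + \theta/(3\theta+2\delta)$). For a
negative fitted exponential rate with $|\hat\theta| \ge \theta_0/2$ the
integral is genuinely divergent; the fixed interior nodes then act as
truncation at roughly the $1 - 5\times10^{-6}$ quantile, producing very
large but finite and deterministic values. This affects only the smallest
sample sizes.

The harness runs each (setting, $n$, replicate) cell with a child seed
spawned deterministically from the master seed, fits the
exponential/exponential semiparametric estimator (deliberately
misspecified under the Weibull setting) and the nonparametric plug-in,
and summarizes replicate MSEs by mean, median, and sample SD ($n-1$
denominator; single replicates report `NA`). Replicate failures are
excluded and counted. Two study-specific choices:

* **Evaluation $\tau$.** Because the metric integrates over the *full*
  support of $f_0$ while waiting times (mean 2 h) end observation long
  before the patience scale (16 h), truncating the nonparametric fit at
  the 0.95 quantile of $U$ would leave an irreducible tail term of about
  $\bar F_0(\tau)^3/3$ in every cell — swamping the estimator's actual
  convergence. The harness therefore evaluates the nonparametric fit up to
  the largest recorded time (`tau_quantile = 1`, exposed as an argument).
  Even so, roughly a third of the patience-time mass lies beyond any
  observable time, so the nonparametric MSE retains a data-range floor
  that no estimator of this kind can cross; the semiparametric estimator,
  when its family is correct, extrapolates parametrically and does not pay
  it.
* **Problem sizes.** The default grid is the study's
  $n \in \{100, 200, 500, 1000, 2000\}$ with 100 replicates. The
  package's own test suite exercises the full default grid once; the
  consistency sweeps use 15–30 seeds at $n$ up to $1.6\times10^4$, sizes
  chosen to make Monte-Carlo orderings stable across reruns.

## Known limitations

* No estimation of $q(t)$, no confidence bands for the nonparametric
  curve (pointwise normality holds but usable variance formulas are not
  implemented), and no covariate models.
* Dependent $(T, W)$ is outside the model; stratification is the only
  provided mitigation.
* The partial likelihood discards categories 2 and 3 except through
  $\hat\gamma$; it trades efficiency for freedom from $q$. With very few
  served subjects it degrades accordingly, and with none it is undefined.
* Closed-form exponential fits can return negative rates in small
  samples; downstream consumers must either tolerate improper survival
  values (the evaluation default) or opt into clipping.
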