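#' Simulation settings for three-category patience data
#'
#' A simulation setting fixes the latent patience-time distribution T, the
#' waiting-time distribution W, the announcement-probability function q(t),
#' the sample size, and a seed. The reference settings of the Monte-Carlo
#' study are T ~ Exponential(mean 16 h) or Weibull(scale 16, shape 1.5),
#' W ~ Exponential(mean 2 h), and q(t) = exp(-t) with t in hours.
#'
#' @param t_family [parametric_family][exp_family] of the patience time T.
#' @param w_family [parametric_family][exp_family] of the waiting time W.
#' @param q An [announce_fn][q_exp_decay].
#' @param n Sample size (>= 1).
#' @param seed Optional integer seed; when set, [simulate.sim_setting()] is
#'   deterministic.
#' @return An object of class `sim_setting`.
#' @examples
#' s <- sim_setting(exp_family(mean = 16), exp_family(mean = 2),
#'                  q_exp_decay(), n = 500, seed = 1)
#' d <- simulate(s)
#' @export
sim_setting <- function(t_family, w_family, q, n, seed = NULL) {
  stopifnot(inherits(t_family, "parametric_family"),
            inherits(w_family, "parametric_family"),
            inherits(q, "announce_fn"),
            is.numeric(n), length(n) == 1L, n >= 1)
  structure(list(t_family = t_family, w_family = w_family, q = q,
                 n = as.integer(n), seed = seed),
            class = "sim_setting")
}

#' @export
print.sim_setting <- function(x, ...) {
  cat(sprintf("<sim_setting: T ~ %s, W ~ %s, q = %s, n = %d%s>\n",
              x$t_family$name, x$w_family$name, attr(x$q, "q_name"), x$n,
              if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  invisible(x)
}

#' Simulate observation triplets from a setting
#'
#' Draws, for each subject, a latent patience time T from `t_family` and an
#' independent waiting time W from `w_family`, then an announcement
#' indicator from Bernoulli(q(T)). The abandonment indicator is
#' Delta = 1(T < W); the announcement is visible only on abandonment
#' (observed Y = Y * Delta), and the recorded time is U = T for announced
#' abandonments and U = W otherwise.
#'
#' Randomness is consumed in a fixed documented order — all n patience
#' times, then all n waiting times, then all n announcement draws — so runs
#' are reproducible given the seed.
#'
#' @param object A [sim_setting()].
#' @param nsim,seed Unused / overrides the setting's seed.
#' @param ... Ignored.
#' @return A [patience_sample()] of `object$n` observations (hours).
#' @export
simulate.sim_setting <- function(object, nsim = 1, seed = NULL, ...) {
  seed <- seed %||% object$seed
  if (!is.null(seed)) set.seed(seed)
  n <- object$n
  t_lat <- object$t_family$rng(n)
  w_lat <- object$w_family$rng(n)
  ann <- stats::rbinom(n, 1L, object$q(t_lat))
  delta <- as.integer(t_lat < w_lat)
  y <- as.integer(ann * delta)
  u <- ifelse(y == 1L, t_lat, w_lat)
  patience_sample(u = u, y = y, delta = delta, time_unit = "hours")
}

#' Analytic category probabilities of a setting
#'
#' Computes, by adaptive quadrature, the probabilities of the three
#' observation categories:
#' \deqn{p_1 = \int_0^\infty g(w)\bar F(w)\,dw,\quad
#'       p_2 = \int_0^\infty q(w) f(w) \bar G(w)\,dw,\quad
#'       p_3 = \int_0^\infty g(w) \int_0^w (1-q(x)) f(x)\,dx\,dw,}
#' which sum to one. These serve as analytic oracles for the simulator and
#' for the plug-in estimator's components.
#'
#' @param setting A [sim_setting()] (the sample size and seed are ignored).
#' @return Named numeric vector `c(p1, p2, p3)`.
#' @examples
#' s <- sim_setting(exp_family(rate = 1), exp_family(rate = 1),
#'                  q_constant(0.5), n = 1)
#' category_probabilities(s)  # (0.5, 0.25, 0.25)
#' @export
category_probabilities <- function(setting) {
  stopifnot(inherits(setting, "sim_setting"))
  tf <- setting$t_family; wf <- setting$w_family; q <- setting$q
  p1 <- integrate_halfline(function(w) wf$pdf(w) * tf$surv(w))
  p2 <- integrate_halfline(function(w) q(w) * tf$pdf(w) * wf$surv(w))
  inner <- function(w)
    vapply(w, function(wi)
      if (wi <= 0) 0 else
        integrate_halfline(function(x) (1 - q(x)) * tf$pdf(x), 0, wi),
      numeric(1))
  p3 <- integrate_halfline(function(w) wf$pdf(w) * inner(w))
  c(p1 = p1, p2 = p2, p3 = p3)
}

#' Sub-stochastic densities of the observed time by category
#'
#' The observed time U has sub-stochastic density h_i(t) on the event
#' "category = i":
#' h1(t) = g(t) F̄(t) (served), h2(t) = q(t) f(t) Ḡ(t) (announced
#' abandonment), h3(t) = g(t) ∫_0^t (1-q(x)) f(x) dx (silent abandonment).
#' Each h_i integrates to the category probability p_i, and h_i / p_i is the
#' conditional density r_i of U given the category.
#'
#' @param setting A [sim_setting()].
#' @param t Nonnegative evaluation times.
#' @return A data frame with columns `t`, `h1`, `h2`, `h3`.
#' @export
subdensities <- function(setting, t) {
  stopifnot(inherits(setting, "sim_setting"), all(t >= 0))
  tf <- setting$t_family; wf <- setting$w_family; q <- setting$q
  h1 <- wf$pdf(t) * tf$surv(t)
  h2 <- q(t) * tf$pdf(t) * wf$surv(t)
  silent_mass <- vapply(t, function(ti)
    if (ti <= 0) 0 else
      integrate_halfline(function(x) (1 - q(x)) * tf$pdf(x), 0, ti),
    numeric(1))
  h3 <- wf$pdf(t) * silent_mass
  data.frame(t = t, h1 = h1, h2 = h2, h3 = h3)
}

#' Announced-abandonment sub-distribution A(t)
#'
#' A(t) = ∫_0^t q(s) f(s) ds, the probability of an announced abandonment by
#' time t ignoring censoring. Used as the analytic counterpart of the
#' jump-sum estimator [estimate_A()].
#'
#' @inheritParams subdensities
#' @return Numeric vector of A(t) values.
#' @export
true_A <- function(setting, t) {
  stopifnot(inherits(setting, "sim_setting"), all(t >= 0))
  tf <- setting$t_family; q <- setting$q
  vapply(t, function(ti)
    if (ti <= 0) 0 else
      integrate_halfline(function(s) q(s) * tf$pdf(s), 0, ti),
    numeric(1))
}
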