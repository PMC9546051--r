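#' Empirical category-probability estimators
#'
#' Estimates P(W <= T) (probability of being served) by `mean(1 - delta)`
#' and P(Y = 0, T < W) (probability of silent abandonment) by
#' `mean(delta * (1 - y))`. Both are root-n consistent by the CLT.
#'
#' @param data A [patience_sample()].
#' @return A list with `p_right` and `p_silent`.
#' @export
estimate_probs <- function(data) {
  stopifnot(inherits(data, "patience_sample"))
  if (nrow(data) == 0L) stop("empty sample")
  list(p_right = mean(1 - data$delta),
       p_silent = mean(data$delta * (1 - data$y)))
}

#' Jump-sum estimator of the announced-abandonment sub-distribution
#'
#' Estimates A(t) = ∫_0^t q(s) f(s) ds via a Nelson–Aalen-type construction:
#' with the counting process of announced abandonments
#' `N(t) = mean(y * delta * (u <= t))` and the at-risk process
#' `R(t) = mean(u >= t)`, the cumulative jump sum is
#' `D(t) = sum over announced event times u_i <= t of 1 / (n * R(u_i))`,
#' and `A_hat(t) = 1 - exp(-D(t))`. The at-risk set is closed at t (`>=`),
#' so the jumping observation is in its own risk set and the ratio is always
#' defined; tied announced times contribute separate jumps evaluated at the
#' common at-risk count.
#'
#' `A_hat` is a right-continuous nondecreasing step function with
#' `A_hat(0) = 0` and `A_hat < 1`.
#'
#' @param data A [patience_sample()].
#' @param grid Nonnegative evaluation times.
#' @return Numeric vector of `A_hat` on `grid`, with attributes
#'   `jump_times` (sorted announced event times) and `D_jumps` (cumulative
#'   jump sums just after each jump).
#' @examples
#' s <- patience_sample(u = 1:4, y = c(0, 1, 0, 0), delta = c(0, 1, 0, 1))
#' estimate_A(s, grid = c(1.5, 2, 4))  # 0, 1-exp(-1/3), 1-exp(-1/3)
#' @export
estimate_A <- function(data, grid) {
  stopifnot(inherits(data, "patience_sample"), all(grid >= 0))
  u <- data$u
  t2 <- sort(u[data$y == 1 & data$delta == 1])
  if (length(t2) == 0L) {
    return(structure(rep(0, length(grid)), jump_times = numeric(0),
                     D_jumps = numeric(0)))
  }
  sorted_u <- sort(u)
  n <- length(u)
  # at-risk count #\{u_j >= t\} with the closed-at-t convention
  at_risk <- n - findInterval(t2, sorted_u, left.open = TRUE)
  d_cum <- cumsum(1 / at_risk)
  d_on_grid <- c(0, d_cum)[findInterval(grid, t2) + 1L]
  structure(1 - exp(-d_on_grid), jump_times = t2, D_jumps = d_cum)
}

#' Kernel estimate of a category's observed-time density
#'
#' Gaussian kernel density estimate of r_i, the conditional density of the
#' observed time within category `category` (1 = served, 3 = silent
#' abandonment), with boundary reflection at zero (times are nonnegative, so
#' mass leaking below zero is folded back) and Silverman's rule-of-thumb
#' bandwidth ([stats::bw.nrd0()]) unless one is supplied.
#'
#' @param data A [patience_sample()].
#' @param category 1 or 3.
#' @param grid Nonnegative evaluation times.
#' @param bandwidth Optional positive bandwidth.
#' @return Density values on `grid`, with attribute `bandwidth`.
#' @export
estimate_r <- function(data, category, grid, bandwidth = NULL) {
  stopifnot(inherits(data, "patience_sample"), category %in% c(1L, 3L),
            all(grid >= 0))
  obs <- data$u[data$category == category]
  m <- length(obs)
  if (m < 2L)
    stop("too few observations (", m, ") in category ", category,
         " for kernel density estimation")
  b <- bandwidth %||% stats::bw.nrd0(obs)
  if (b <= 0) stop("bandwidth must be positive")
  # reflection at 0: K((t - u)/b) + K((t + u)/b)
  vals <- vapply(grid, function(t)
    sum(stats::dnorm((t - obs) / b) + stats::dnorm((t + obs) / b)),
    numeric(1)) / (m * b)
  structure(vals, bandwidth = b)
}

#' Plug-in combination of the estimated components
#'
#' Combines the category probabilities, the conditional densities of the
#' served and silent categories, and the announced-abandonment
#' sub-distribution into the plug-in estimator of the patience-time cdf:
#' \deqn{\hat F(t) = \frac{\hat p_{silent}\,\hat r_3(t) +
#'   \hat p_{right}\,\hat r_1(t)\,\hat A(t)}
#'   {\hat p_{silent}\,\hat r_3(t) + \hat p_{right}\,\hat r_1(t)}.}
#' With the exact (population) components this is an identity for F(t).
#'
#' Where the denominator is numerically zero (both density terms below
#' 1e-12, far in the tail) the last well-defined value is carried forward
#' (0 before any is available) rather than evaluating 0/0.
#'
#' @param p_right,p_silent Scalars, as from [estimate_probs()].
#' @param r1,r3 Density values on `grid`.
#' @param A Values of the announced-abandonment sub-distribution on `grid`.
#' @param grid Increasing evaluation times.
#' @return `F_raw` values on `grid` (not monotonized, not clipped).
#' @export
plugin_F <- function(p_right, p_silent, r1, r3, A, grid) {
  k <- length(grid)
  stopifnot(length(r1) == k, length(r3) == k, length(A) == k)
  num <- p_silent * r3 + p_right * r1 * A
  den <- p_silent * r3 + p_right * r1
  f <- num / den
  ok <- is.finite(f) & den >= 1e-12
  last <- 0
  for (i in seq_len(k)) {
    if (ok[i]) last <- f[i] else f[i] <- last
  }
  f
}

#' Running-maximum monotonization
#'
#' The plug-in estimator is built from density estimates and need not be
#' monotone; it is replaced by its cumulative supremum (running maximum,
#' left to right), which is the smallest nondecreasing majorant on the grid.
#' Idempotent and order-preserving.
#'
#' @param f_raw Values on an increasing grid.
#' @param grid Optional grid (checked for ordering if given).
#' @return Nondecreasing values, pointwise `>= f_raw`.
#' @examples
#' monotonize(c(0.1, 0.3, 0.2, 0.4))  # 0.1 0.3 0.3 0.4
#' @export
monotonize <- function(f_raw, grid = NULL) {
  if (!is.null(grid)) {
    stopifnot(length(grid) == length(f_raw))
    if (is.unsorted(grid)) stop("grid must be increasing")
  }
  cummax(f_raw)
}

#' Nonparametric plug-in fit of the patience-time distribution
#'
#' Orchestrates the four component estimators — empirical category
#' probabilities, kernel densities of the served and silent categories, and
#' the jump-sum estimator of the announced-abandonment sub-distribution —
#' on a common grid over \[0, tau\], combines them via [plugin_F()], and
#' monotonizes the result by running maximum.
#'
#' Estimation is restricted to \[0, tau\] with tau defaulting to the 0.95
#' empirical quantile of the observed times (both T and W must have positive
#' probability of exceeding tau). When the silent category has fewer than
#' two observations its density term is dropped (treated as identically
#' zero) with a warning; fewer than ten draws a stability warning.
#'
#' @param data A [patience_sample()].
#' @param tau Truncation point; default `quantile(u, 0.95)`.
#' @param grid_points Number of equally spaced grid points on \[0, tau\].
#' @param bandwidths Optional numeric vector `c(b1, b3)`; default Silverman
#'   per category.
#' @param min_n Minimum sample size (default 20).
#' @return An object of class `nonparam_fit` with the grid, tau, component
#'   estimates, `F_raw`, `F_mono`, bandwidths, and category counts.
#' @examples
#' s <- simulate(sim_setting(exp_family(mean = 16), exp_family(mean = 2),
#'                           q_exp_decay(), n = 2000, seed = 1))
#' f <- fit_nonparam(s)
#' @export
fit_nonparam <- function(data, tau = NULL, grid_points = 512L,
                         bandwidths = NULL, min_n = 20L) {
  stopifnot(inherits(data, "patience_sample"))
  n <- nrow(data)
  if (n < min_n) stop("need at least ", min_n, " observations")
  counts <- category_counts(data)$counts
  if (counts[1] < 2L)
    stop("too few served (category-1) observations for the plug-in estimator")
  tau <- tau %||% unname(stats::quantile(data$u, 0.95, type = 7))
  grid <- seq(0, tau, length.out = grid_points)
  probs <- estimate_probs(data)
  r1 <- estimate_r(data, 1L, grid, bandwidth = bandwidths[1])
  if (counts[3] >= 2L) {
    if (counts[3] < 10L)
      warning("fewer than 10 silent-abandonment observations; ",
              "r3 estimate is unstable")
    r3 <- estimate_r(data, 3L, grid, bandwidth = bandwidths[2])
  } else {
    warning("fewer than 2 silent-abandonment observations; ",
            "dropping the r3 term")
    r3 <- structure(rep(0, length(grid)), bandwidth = NA_real_)
  }
  A <- estimate_A(data, grid)
  f_raw <- plugin_F(probs$p_right, probs$p_silent, r1, r3, A, grid)
  structure(list(
    grid = grid, tau = tau,
    p_right = probs$p_right, p_silent = probs$p_silent,
    r1 = as.numeric(r1), r3 = as.numeric(r3), A = as.numeric(A),
    F_raw = f_raw, F_mono = monotonize(f_raw, grid),
    bandwidths = c(b1 = attr(r1, "bandwidth"), b3 = attr(r3, "bandwidth")),
    counts = counts, n = n), class = "nonparam_fit")
}

#' @export
print.nonparam_fit <- function(x, ...) {
  cat(sprintf("<nonparam_fit: n = %d (served %d, announced %d, silent %d)>\n",
              x$n, x$counts[1], x$counts[2], x$counts[3]))
  cat(sprintf("  tau = %.4g, grid = %d points, bandwidths b1 = %.4g, b3 = %.4g\n",
              x$tau, length(x$grid), x$bandwidths[1], x$bandwidths[2]))
  cat(sprintf("  F_mono(tau) = %.4f, A_hat(tau) = %.4f\n",
              x$F_mono[length(x$F_mono)], x$A[length(x$A)]))
  invisible(x)
}

#' Nonparametric survival function as a closure
#'
#' Linear interpolation of `1 - F_mono` within \[0, tau\], extended as a
#' constant beyond tau (and below the first grid point), so the estimate can
#' be integrated against a density supported on the whole half-line.
#'
#' @param fit A [fit_nonparam()] result.
#' @param clip Clip survival values into \[0, 1\]? (The plug-in construction
#'   already keeps them there; the flag mirrors [semipar_survfun()].)
#' @return A vectorized function t -> estimated survival.
#' @export
nonparam_survfun <- function(fit, clip = FALSE) {
  stopifnot(inherits(fit, "nonparam_fit"))
  fa <- stats::approxfun(fit$grid, fit$F_mono, rule = 2)
  if (clip) function(t) pmin(pmax(1 - fa(t), 0), 1)
  else function(t) 1 - fa(t)
}

#' Export a nonparametric fit as a grid table
#'
#' @param x A [fit_nonparam()] result.
#' @param ... Ignored.
#' @return A data frame with columns `t`, `A_hat`, `r1_hat`, `r3_hat`,
#'   `F_raw`, `F_mono`.
#' @export
as.data.frame.nonparam_fit <- function(x, ...) {
  data.frame(t = x$grid, A_hat = x$A, r1_hat = x$r1, r3_hat = x$r3,
             F_raw = x$F_raw, F_mono = x$F_mono)
}
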