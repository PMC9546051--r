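#' Full-likelihood estimation of the waiting-time parameter
#'
#' The waiting time W is observed exactly for served subjects and silent
#' abandoners (categories 1 and 3) and right-censored at the observed
#' patience time for announced abandoners (category 2). The factor of the
#' full likelihood that involves the waiting-time parameter gamma is
#' therefore the standard right-censored likelihood
#' \deqn{\prod_i g(U_i;\gamma)^{1-\Delta_i Y_i}\,\bar G(U_i;\gamma)^{\Delta_i Y_i},}
#' whose maximizer does not depend on the patience-time parameter or on the
#' announcement probability.
#'
#' For an exponential waiting-time family the maximizer has the closed form
#' `(n - sum(delta*y)) / sum(u)`; otherwise the log-likelihood is maximized
#' numerically on log-transformed parameters with multiple starts.
#'
#' @param data A [patience_sample()].
#' @param w_family [parametric_family][exp_family] of the waiting time.
#' @param method `"auto"` (closed form when available), `"closed_form"`, or
#'   `"numeric"`.
#' @param n_starts Number of optimizer starts for the numeric path.
#' @return A list with `gamma_hat` (named numeric), `loglik`, `converged`,
#'   `method`.
#' @examples
#' s <- patience_sample(u = 1:4, y = c(0, 0, 1, 0), delta = c(0, 0, 1, 1))
#' fit_gamma(s, exp_family(rate = 1))$gamma_hat  # 3/10
#' @export
fit_gamma <- function(data, w_family, method = c("auto", "closed_form", "numeric"),
                      n_starts = 3L) {
  stopifnot(inherits(data, "patience_sample"),
            inherits(w_family, "parametric_family"))
  method <- match.arg(method)
  dy <- data$delta * data$y
  if (sum(data$u) == 0) stop("degenerate data: all observed times are zero")
  if (method != "numeric" && w_family$name == "exponential") {
    gamma_hat <- c(rate = (nrow(data) - sum(dy)) / sum(data$u))
    ll <- gamma_loglik(gamma_hat, data$u, dy, w_family)
    return(list(gamma_hat = gamma_hat, loglik = ll, converged = TRUE,
                method = "closed_form"))
  }
  if (method == "closed_form")
    stop("no closed form for family: ", w_family$name)
  opt <- maximize_family(
    objective = function(par) gamma_loglik(par, data$u, dy, w_family),
    family = w_family, u = data$u, n_starts = n_starts,
    what = "waiting-time likelihood")
  list(gamma_hat = opt$par, loglik = opt$value, converged = opt$converged,
       method = "numeric")
}

gamma_loglik <- function(params, u, dy, w_family) {
  s <- w_family$surv(u, params)
  sum((1 - dy) * w_family$logpdf(u, params)) +
    sum(dy * log(pmax(s, .Machine$double.xmin)))
}

#' Partial-likelihood estimation of the patience-time parameter
#'
#' Maximizing the full likelihood over the patience-time parameter theta
#' would require the unknown announcement probability q(t). The partial
#' likelihood of the served subjects (category 1) avoids it: each served
#' subject contributes the conditional density of its observed time given
#' category 1,
#' \deqn{\frac{g(U_i;\hat\gamma)\,\bar F(U_i;\theta)}
#'            {\int_0^\infty g(s;\hat\gamma)\,\bar F(s;\theta)\,ds},}
#' and the g-factors are constant in theta. With both families exponential
#' the maximizer has the closed form
#' `sum(1-delta) / sum((1-delta)*u) - gamma_hat`, which is deliberately not
#' truncated at zero (see the package vignette); otherwise the objective is
#' maximized numerically, with the normalizing integral computed in closed
#' form for exponential waiting times and by quadrature otherwise.
#'
#' @inheritParams fit_gamma
#' @param t_family [parametric_family][exp_family] of the patience time.
#' @param gamma_hat Named numeric: fitted waiting-time parameters.
#' @return A list with `theta_hat`, `partial_loglik` (the category-1 partial
#'   log-likelihood at the maximizer, including the constant g-factors),
#'   `converged`, `method`.
#' @export
fit_theta_partial <- function(data, t_family, gamma_hat, w_family,
                              method = c("auto", "closed_form", "numeric"),
                              n_starts = 3L) {
  stopifnot(inherits(data, "patience_sample"),
            inherits(t_family, "parametric_family"),
            inherits(w_family, "parametric_family"))
  method <- match.arg(method)
  u1 <- data$u[data$delta == 0]
  n1 <- length(u1)
  if (n1 == 0L) stop("no category-1 (served) observations; ",
                     "the partial likelihood is undefined")
  both_exp <- t_family$name == "exponential" && w_family$name == "exponential"
  if (method != "numeric" && both_exp) {
    theta_hat <- c(rate = n1 / sum(u1) - unname(gamma_hat[1]))
    ll <- theta_partial_loglik(theta_hat, u1, t_family, w_family, gamma_hat)
    return(list(theta_hat = theta_hat, partial_loglik = ll, converged = TRUE,
                method = "closed_form"))
  }
  if (method == "closed_form")
    stop("closed form requires exponential patience and waiting families")
  if (both_exp) {
    # 1-D maximization over theta > -gamma_hat (the objective is defined on
    # that whole half-line; the maximizer may be negative)
    obj <- function(th)
      theta_partial_loglik(c(rate = th), u1, t_family, w_family, gamma_hat)
    g <- unname(gamma_hat[1])
    lo <- -g + 1e-9
    hi <- max(2 * n1 / sum(u1), 1)
    while (obj(hi) > obj(0.99 * hi) && hi < 1e8) hi <- hi * 4
    opt <- stats::optimize(obj, c(lo, hi), maximum = TRUE, tol = 1e-12)
    return(list(theta_hat = c(rate = opt$maximum),
                partial_loglik = opt$objective, converged = TRUE,
                method = "numeric"))
  }
  opt <- maximize_family(
    objective = function(par)
      theta_partial_loglik(par, u1, t_family, w_family, gamma_hat),
    family = t_family, u = u1, n_starts = n_starts,
    what = "category-1 partial likelihood")
  list(theta_hat = opt$par, partial_loglik = opt$value,
       converged = opt$converged, method = "numeric")
}

theta_partial_loglik <- function(theta, u1, t_family, w_family, gamma_hat) {
  n1 <- length(u1)
  norm_const <- partial_norm_const(theta, t_family, w_family, gamma_hat)
  if (!is.finite(norm_const) || norm_const <= 0) return(-Inf)
  sf <- pmax(t_family$surv(u1, theta), .Machine$double.xmin)
  sum(w_family$logpdf(u1, gamma_hat)) + sum(log(sf)) - n1 * log(norm_const)
}

# normalizing integral of the category-1 conditional density:
# integral of g(s; gamma) * Fbar(s; theta) ds over [0, Inf);
# exponential/exponential closed form gamma/(gamma+theta), valid for
# theta > -gamma
partial_norm_const <- function(theta, t_family, w_family, gamma_hat) {
  if (t_family$name == "exponential" && w_family$name == "exponential") {
    g <- unname(gamma_hat[1]); th <- unname(theta[1])
    if (g + th <= 0) return(NA_real_)
    return(g / (g + th))
  }
  integrate_halfline(function(s)
    w_family$pdf(s, gamma_hat) * t_family$surv(s, theta))
}

# multi-start quasi-Newton maximization over log-transformed parameters
maximize_family <- function(objective, family, u, n_starts, what) {
  start <- family$to_unc(family$start(u))
  offsets <- log(c(1, 0.5, 2, 0.25, 4))[seq_len(max(1L, n_starts))]
  fits <- lapply(offsets, function(off) {
    stats::optim(start + off,
                 fn = function(unc) {
                   # wild steps can overflow the parameter transform
                   v <- suppressWarnings(-objective(family$from_unc(unc)))
                   if (is.finite(v)) v else .Machine$double.xmax / 2
                 },
                 method = "BFGS",
                 control = list(reltol = 1e-12, maxit = 500L))
  })
  vals <- -vapply(fits, `[[`, numeric(1), "value")
  best <- which.max(vals)
  near <- which(vals > vals[best] - 1e-4)
  pars <- vapply(fits[near], function(f) f$par[1], numeric(1))
  if (length(near) > 1L && diff(range(pars)) > 1e-3 * (1 + abs(pars[1])))
    warning("multi-start disagreement maximizing the ", what,
            "; the objective may have multiple local maxima")
  list(par = family$from_unc(fits[[best]]$par), value = vals[best],
       converged = fits[[best]]$convergence == 0)
}

#' Semiparametric fit of the patience-time distribution
#'
#' Composes [fit_gamma()] (full likelihood, waiting time) and
#' [fit_theta_partial()] (category-1 partial likelihood, patience time), with
#' an optional nonparametric bootstrap — resampling observation triplets with
#' replacement — for standard errors. The bootstrap stands in for the
#' asymptotic covariance matrices, which have no closed form here.
#'
#' @inheritParams fit_theta_partial
#' @param bootstrap Number of bootstrap replicates (0 = no standard errors).
#' @param seed Optional seed for the bootstrap resampling.
#' @return An object of class `semipar_fit`: the two parameter estimates,
#'   objective values, convergence flags, the families, and (if requested)
#'   bootstrap standard errors.
#' @examples
#' s <- patience_sample(u = 1:4, y = c(0, 0, 1, 0), delta = c(0, 0, 1, 1))
#' f <- fit_semipar(s, exp_family(rate = 1), exp_family(rate = 1))
#' f$gamma_hat  # 0.3
#' f$theta_hat  # 2/3 - 0.3
#' @export
fit_semipar <- function(data, t_family, w_family, bootstrap = 0L,
                        method = c("auto", "closed_form", "numeric"),
                        seed = NULL) {
  method <- match.arg(method)
  gfit <- fit_gamma(data, w_family, method = method)
  tfit <- fit_theta_partial(data, t_family, gfit$gamma_hat, w_family,
                            method = method)
  out <- list(
    gamma_hat = gfit$gamma_hat, theta_hat = tfit$theta_hat,
    loglik_gamma = gfit$loglik, partial_loglik_theta = tfit$partial_loglik,
    converged = c(gamma = gfit$converged, theta = tfit$converged),
    method = c(gamma = gfit$method, theta = tfit$method),
    t_family = t_family, w_family = w_family,
    n = nrow(data), n_boot = bootstrap, se_gamma = NULL, se_theta = NULL)
  if (bootstrap > 0L) {
    if (!is.null(seed)) set.seed(seed)
    reps <- replicate(bootstrap, {
      idx <- sample.int(nrow(data), replace = TRUE)
      b <- patience_sample(data$u[idx], data$y[idx], data$delta[idx],
                           time_unit = attr(data, "time_unit"))
      bg <- fit_gamma(b, w_family, method = method)
      bt <- fit_theta_partial(b, t_family, bg$gamma_hat, w_family,
                              method = method)
      c(bg$gamma_hat, bt$theta_hat)
    })
    k <- length(gfit$gamma_hat)
    out$se_gamma <- apply(reps[seq_len(k), , drop = FALSE], 1, stats::sd)
    out$se_theta <- apply(reps[-seq_len(k), , drop = FALSE], 1, stats::sd)
  }
  class(out) <- "semipar_fit"
  out
}

#' @export
print.semipar_fit <- function(x, ...) {
  cat(sprintf("<semipar_fit: W ~ %s, T ~ %s, n = %d>\n",
              x$w_family$name, x$t_family$name, x$n))
  cat("  gamma_hat:", paste(sprintf("%s = %.6g", names(x$gamma_hat),
                                    x$gamma_hat), collapse = ", "), "\n")
  cat("  theta_hat:", paste(sprintf("%s = %.6g", names(x$theta_hat),
                                    x$theta_hat), collapse = ", "), "\n")
  if (!is.null(x$se_theta))
    cat(sprintf("  bootstrap SEs (B = %d): gamma %s | theta %s\n", x$n_boot,
                paste(signif(x$se_gamma, 3), collapse = ", "),
                paste(signif(x$se_theta, 3), collapse = ", ")))
  if (x$theta_hat[1] < 0 && x$t_family$name == "exponential")
    cat("  note: negative patience rate (small-sample artifact); fitted",
        "survival exceeds 1\n")
  invisible(x)
}

#' Fitted patience-time survival curve
#'
#' Evaluates the fitted survival function of the patience time on a grid.
#' For an exponential family with a negative fitted rate — possible under
#' the untruncated closed-form estimator in small samples — values exceed 1;
#' they are flagged with a warning but, by default, not clipped, matching
#' the behavior assumed by the Monte-Carlo evaluation. Set `clip = TRUE` for
#' a practical curve restricted to \[0, 1\].
#'
#' @param fit A [fit_semipar()] result.
#' @param grid Nonnegative times.
#' @param clip Clip values into \[0, 1\]?
#' @return Numeric vector of survival values; attribute `flagged` is `TRUE`
#'   when unclipped values fell outside \[0, 1\].
#' @export
survival_curve <- function(fit, grid, clip = FALSE) {
  stopifnot(inherits(fit, "semipar_fit"), all(grid >= 0))
  v <- fit$t_family$surv(grid, fit$theta_hat)
  flagged <- any(v > 1 | v < 0)
  if (flagged && !clip)
    warning("fitted survival outside [0, 1] (negative fitted rate); ",
            "values not clipped")
  if (clip) v <- pmin(pmax(v, 0), 1)
  structure(v, flagged = flagged)
}

#' Fitted survival function as a closure
#'
#' @inheritParams survival_curve
#' @return A vectorized function t -> fitted survival.
#' @export
semipar_survfun <- function(fit, clip = FALSE) {
  stopifnot(inherits(fit, "semipar_fit"))
  tf <- fit$t_family; th <- fit$theta_hat
  if (clip) function(t) pmin(pmax(tf$surv(t, th), 0), 1)
  else function(t) tf$surv(t, th)
}
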