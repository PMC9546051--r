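`%||%` <- function(x, y) if (is.null(x)) y else x

# Adaptive quadrature over [0, Inf) (or [lower, upper]); errors rather than
# returning a flagged non-result, since downstream probabilities must be
# trustworthy.
integrate_halfline <- function(f, lower = 0, upper = Inf, abs.tol = 1e-8) {
  res <- stats::integrate(f, lower, upper, abs.tol = abs.tol,
                          rel.tol = abs.tol, subdivisions = 500L,
                          stop.on.error = FALSE)
  if (!res$message %in% c("OK", "the integral is probably divergent"))
    stop("quadrature non-convergence: ", res$message)
  res$value
}
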