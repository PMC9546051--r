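# Shared fixtures, built in code.

# Example toy dataset: four observations, one announced abandonment at U = 3
# and one silent abandonment at U = 4; closed-form estimates are
# gamma_hat = 3/10 and theta_hat = 2/3 - 3/10.
toy_sample <- function() {
  patience_sample(u = c(1, 2, 3, 4), y = c(0, 0, 1, 0), delta = c(0, 0, 1, 1))
}

# Unit-rate exponential patience and waiting with constant announcement:
# category probabilities (0.5, 0.25, 0.25), r1(t) = 2 exp(-2t),
# r3(t) = 2 exp(-t)(1 - exp(-t)), A(t) = 0.5 (1 - exp(-t)).
unit_setting <- function(q = q_constant(0.5), n = 1L, seed = NULL) {
  sim_setting(exp_family(rate = 1), exp_family(rate = 1), q, n = n, seed = seed)
}

# The two reference simulation settings with overridden n/seed.
setting1 <- function(n, seed = NULL) {
  s <- reference_settings()$setting1
  s$n <- as.integer(n); s$seed <- seed
  s
}

setting2 <- function(n, seed = NULL) {
  s <- reference_settings()$setting2
  s$n <- as.integer(n); s$seed <- seed
  s
}

# draw a random valid setting (for conservation-style property sweeps)
random_setting <- function() {
  tf <- if (stats::runif(1) < 0.5) exp_family(mean = stats::runif(1, 2, 30)) else
    weibull_family(scale = stats::runif(1, 2, 30), shape = stats::runif(1, 0.7, 3))
  wf <- if (stats::runif(1) < 0.5) exp_family(mean = stats::runif(1, 0.5, 8)) else
    weibull_family(scale = stats::runif(1, 0.5, 8), shape = stats::runif(1, 0.7, 3))
  q <- switch(sample(3, 1),
              q_exp_decay(rate = stats::runif(1, 0.2, 2)),
              q_exp_rise(rate = stats::runif(1, 0.2, 2)),
              q_constant(stats::runif(1)))
  sim_setting(tf, wf, q, n = 100L)
}
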