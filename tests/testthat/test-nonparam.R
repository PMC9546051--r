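test_that("empirical category probabilities are direct counts", {
  s <- toy_sample()
  p <- estimate_probs(s)
  expect_equal(p$p_right, 0.5)
  expect_equal(p$p_silent, 0.25)
  all1 <- patience_sample(u = 1:3, y = rep(0, 3), delta = rep(0, 3))
  expect_equal(unlist(estimate_probs(all1)), c(p_right = 1, p_silent = 0))
})

test_that("the jump-sum estimator matches hand calculations", {
  # single announced event at the second-smallest of four times:
  # at-risk 3 of 4, jump 1/3, A = 1 - exp(-1/3) from there on
  s <- patience_sample(u = 1:4, y = c(0, 1, 0, 0), delta = c(0, 1, 0, 1))
  A <- estimate_A(s, grid = c(0, 1.5, 2, 3, 10))
  expect_equal(as.numeric(A), c(0, 0, rep(1 - exp(-1 / 3), 3)))
  expect_equal(attr(A, "D_jumps"), 1 / 3)
  # tied announced events share the at-risk count but jump separately
  s2 <- patience_sample(u = c(2, 2, 3), y = c(1, 1, 0), delta = c(1, 1, 0))
  A2 <- estimate_A(s2, grid = 2)
  expect_equal(as.numeric(A2), 1 - exp(-2 / 3))
  # no announced events: identically zero
  s3 <- patience_sample(u = 1:3, y = rep(0, 3), delta = c(0, 1, 1))
  expect_equal(as.numeric(estimate_A(s3, grid = 0:3)), rep(0, 4))
})

test_that("A_hat is a nondecreasing step function in [0, 1) jumping at announced times", {
  d <- suppressWarnings(simulate(setting1(500, seed = 10)))
  grid <- seq(0, max(d$u), length.out = 300)
  A <- estimate_A(d, grid)
  expect_equal(as.numeric(estimate_A(d, 0)), 0)
  expect_true(all(diff(A) >= 0))
  expect_true(all(A >= 0 & A < 1))
  expect_setequal(attr(A, "jump_times"), d$u[d$category == 2L])
})

test_that("with universal announcement A_hat is one minus exp of Nelson-Aalen", {
  skip_if_not_installed("survival")
  d <- simulate(unit_setting(q = q_constant(1), n = 500L, seed = 3))
  jt <- sort(unique(d$u[d$category == 2L]))
  A <- estimate_A(d, grid = jt)
  sf <- survival::survfit(survival::Surv(d$u, d$delta) ~ 1)
  na <- sf$cumhaz[match(jt, sf$time)]
  expect_equal(as.numeric(A), 1 - exp(-na), tolerance = 1e-12)
})

test_that("kernel estimates are normalized, reflected at zero, and match closed forms", {
  # half-normal: mode at 0; reflection must not halve the boundary value
  set.seed(21)
  s <- patience_sample(u = abs(stats::rnorm(2000)), y = rep(0, 2000),
                       delta = rep(0, 2000))
  grid <- seq(0, 4, length.out = 400)
  r <- estimate_r(s, 1L, grid)
  expect_equal(sum(r) * diff(grid)[1], 1, tolerance = 0.02)
  expect_equal(r[1], 2 * stats::dnorm(0), tolerance = 0.1)
  # closed form: category-1 times under unit exponentials are Exp(2)
  d <- simulate(unit_setting(q = q_constant(0.5), n = 1e5L, seed = 12))
  r1 <- estimate_r(d, 1L, grid = 1)
  expect_lt(abs(as.numeric(r1) - 2 * exp(-2)), 0.02)
  expect_error(estimate_r(patience_sample(1, 0, 0), 1L, grid), "too few")
})

test_that("plug-in combination is exact on oracle components and handles edge cases", {
  # population components for unit exponentials with q = 0.5:
  # the combination must return F(t) = 1 - exp(-t) identically
  grid <- seq(0, 5, length.out = 257)
  p1 <- 0.5; p3 <- 0.25
  r1 <- 2 * exp(-2 * grid)
  r3 <- 2 * exp(-grid) * (1 - exp(-grid))
  A <- 0.5 * (1 - exp(-grid))
  f <- plugin_F(p1, p3, r1, r3, A, grid)
  expect_equal(f, 1 - exp(-grid), tolerance = 1e-12)
  # no abandonment evidence
  expect_equal(plugin_F(1, 0, r1, rep(0, 257), rep(0, 257), grid),
               rep(0, 257))
  # saturated announced sub-distribution
  expect_equal(plugin_F(0.5, 0.25, r1, r3, rep(1, 257), grid), rep(1, 257))
  # degenerate denominator far in the tail carries the last value forward
  f2 <- plugin_F(0.5, 0.25, c(r1[1:3], 0, 0), c(r3[1:3], 0, 0),
                 c(A[1:3], 1, 1), grid[1:5])
  expect_equal(f2[4:5], rep(f2[3], 2))
})

test_that("monotonization is a running maximum: idempotent and dominating", {
  expect_equal(monotonize(c(0.1, 0.3, 0.2, 0.4)), c(0.1, 0.3, 0.3, 0.4))
  nondec <- c(0, 0.2, 0.2, 0.9)
  expect_equal(monotonize(nondec), nondec)
  set.seed(5)
  for (i in 1:20) {
    x <- stats::runif(50)
    m <- monotonize(x)
    expect_true(all(diff(m) >= 0) && all(m >= x))
    expect_equal(monotonize(m), m)
  }
  expect_error(monotonize(1:3, grid = c(1, 3, 2)), "increasing")
})

test_that("the assembled plug-in fit tracks the true distribution", {
  d <- simulate(setting1(2000, seed = 1))
  fit <- suppressWarnings(fit_nonparam(d))
  truth <- 1 - setting1(1)$t_family$surv(fit$grid)
  expect_lt(max(abs(fit$F_mono - truth)), 0.1)
  expect_true(all(diff(fit$F_mono) >= 0))
  expect_true(all(fit$F_mono >= fit$F_raw))
  expect_true(fit$p_right >= 0 && fit$p_right <= 1)
  expect_equal(fit$tau, unname(stats::quantile(d$u, 0.95)))
  expect_named(fit$bandwidths, c("b1", "b3"))
  # survival closure: interpolates inside, constant beyond tau
  sf <- nonparam_survfun(fit)
  expect_equal(sf(2 * fit$tau), 1 - fit$F_mono[length(fit$F_mono)])
  tab <- as.data.frame(fit)
  expect_named(tab, c("t", "A_hat", "r1_hat", "r3_hat", "F_raw", "F_mono"))
})

test_that("samples with no abandonment evidence give a null estimate", {
  s <- patience_sample(u = stats::rexp(50, 1) + 0.01, y = rep(0, 50),
                       delta = rep(0, 50))
  expect_warning(fit <- fit_nonparam(s), "silent-abandonment")
  expect_equal(fit$F_mono, rep(0, length(fit$grid)))
  expect_error(fit_nonparam(s, min_n = 100L), "at least 100")
})

test_that("sup-error over the estimation window shrinks with sample size", {
  med_err <- sapply(c(1000L, 4000L, 16000L), function(n) {
    errs <- sapply(1:30, function(i) {
      d <- suppressWarnings(simulate(setting1(n, seed = 7000 + 31 * i + n)))
      fit <- suppressWarnings(fit_nonparam(d))
      truth <- 1 - setting1(1)$t_family$surv(fit$grid)
      max(abs(fit$F_mono - truth))
    })
    stats::median(errs)
  })
  expect_true(all(diff(med_err) < 0))
})
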