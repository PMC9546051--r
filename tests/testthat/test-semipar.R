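test_that("exponential closed forms reproduce the worked example", {
  s <- toy_sample()
  gf <- fit_gamma(s, exp_family(rate = 1))
  expect_equal(gf$gamma_hat[["rate"]], 0.3)  # (4 - 1) / 10
  expect_identical(gf$method, "closed_form")
  tf <- fit_theta_partial(s, exp_family(rate = 1), gf$gamma_hat,
                          exp_family(rate = 1))
  expect_equal(tf$theta_hat[["rate"]], 2 / 3 - 0.3)  # 2 served, sum u = 3
  fit <- fit_semipar(s, exp_family(rate = 1), exp_family(rate = 1))
  expect_equal(unname(c(fit$gamma_hat, fit$theta_hat)), c(0.3, 2 / 3 - 0.3))
  # reported partial log-likelihood matches a by-hand evaluation
  g <- 0.3; th <- 2 / 3 - 0.3; u1 <- c(1, 2)
  manual <- sum(log(g) - g * u1) + sum(-th * u1) - 2 * log(g / (g + th))
  expect_equal(tf$partial_loglik, manual)
})

test_that("degenerate samples hit the documented closed-form limits", {
  # no announced abandonments: uncensored exponential MLE n / sum(u)
  s <- patience_sample(u = c(1, 2, 5), y = c(0, 0, 0), delta = c(0, 1, 1))
  expect_equal(fit_gamma(s, exp_family(rate = 1))$gamma_hat[["rate"]], 3 / 8)
  # everyone served: no abandonment evidence, theta_hat = 0
  s1 <- patience_sample(u = c(1, 2, 5), y = rep(0, 3), delta = rep(0, 3))
  f <- fit_semipar(s1, exp_family(rate = 1), exp_family(rate = 1))
  expect_equal(f$theta_hat[["rate"]], 0)
  # no served subjects: partial likelihood undefined
  s2 <- patience_sample(u = c(1, 2), y = c(1, 0), delta = c(1, 1))
  expect_error(fit_theta_partial(s2, exp_family(rate = 1), c(rate = 1),
                                 exp_family(rate = 1)), "category-1")
})

test_that("closed forms equal the package's numerical maximizers", {
  for (seed in 1:10) {
    d <- suppressWarnings(simulate(setting1(250, seed = seed)))
    cf <- fit_semipar(d, exp_family(rate = 1), exp_family(rate = 1))
    nm <- fit_semipar(d, exp_family(rate = 1), exp_family(rate = 1),
                      method = "numeric")
    expect_lt(abs(nm$gamma_hat - cf$gamma_hat), 1e-6)
    expect_lt(abs(nm$theta_hat - cf$theta_hat), 1e-6)
  }
})

test_that("partial likelihood ignores announced/silent observations given gamma", {
  d <- suppressWarnings(simulate(setting1(400, seed = 2)))
  gamma_hat <- c(rate = 0.45)
  base <- fit_theta_partial(d, exp_family(rate = 1), gamma_hat,
                            exp_family(rate = 1))
  # append extra category-2 and category-3 rows: their likelihood factors
  # do not enter the category-1 partial objective
  extra <- patience_sample(u = c(d$u, 0.3, 0.9, 2.2),
                           y = c(d$y, 1L, 0L, 1L),
                           delta = c(d$delta, 1L, 1L, 1L))
  pert <- fit_theta_partial(extra, exp_family(rate = 1), gamma_hat,
                            exp_family(rate = 1))
  expect_equal(pert$theta_hat, base$theta_hat)
})

test_that("numerical path recovers Weibull parameters against survreg", {
  skip_if_not_installed("survival")
  set.seed(31)
  w <- stats::rweibull(600, shape = 1.4, scale = 3)
  cens <- stats::rexp(600, rate = 1 / 8)
  s <- patience_sample(u = pmin(w, cens),
                       y = as.integer(cens < w),
                       delta = as.integer(cens < w))
  gf <- fit_gamma(s, weibull_family(scale = 1, shape = 1))
  sr <- survival::survreg(survival::Surv(s$u, 1 - s$delta * s$y) ~ 1,
                          dist = "weibull")
  expect_equal(gf$gamma_hat[["scale"]], exp(unname(sr$coefficients)),
               tolerance = 1e-4)
  expect_equal(gf$gamma_hat[["shape"]], 1 / sr$scale, tolerance = 1e-4)
})

test_that("patience estimates concentrate around the truth as n grows", {
  errs <- sapply(c(500L, 2000L, 8000L), function(n) {
    th <- sapply(1:15, function(i) {
      d <- suppressWarnings(simulate(setting1(n, seed = 100 * n + i)))
      fit_semipar(d, exp_family(rate = 1),
                  exp_family(rate = 1))$theta_hat[["rate"]]
    })
    stats::median(abs(th - 1 / 16))
  })
  expect_true(all(diff(errs) < 0))
})

test_that("survival curves evaluate, flag improper fits, and clip on request", {
  d <- suppressWarnings(simulate(setting1(300, seed = 4)))
  fit <- fit_semipar(d, exp_family(rate = 1), exp_family(rate = 1))
  grid <- seq(0, 30, length.out = 11)
  v <- survival_curve(fit, grid)
  expect_equal(as.numeric(v),
               exp(-fit$theta_hat[["rate"]] * grid))
  expect_equal(semipar_survfun(fit)(16), exp(-fit$theta_hat[["rate"]] * 16))
  # zero rate: flat survival at 1
  fit0 <- fit
  fit0$theta_hat <- c(rate = 0)
  expect_equal(as.numeric(survival_curve(fit0, grid)), rep(1, 11))
  # negative rate (possible in small samples): flagged, not silently clipped
  fitn <- fit
  fitn$theta_hat <- c(rate = -0.05)
  expect_warning(vn <- survival_curve(fitn, grid), "not clipped")
  expect_true(any(vn > 1) && isTRUE(attr(vn, "flagged")))
  vc <- survival_curve(fitn, grid, clip = TRUE)
  expect_true(all(vc <= 1 & vc >= 0))
})

test_that("bootstrap is optional, reproducible, and leaves point estimates alone", {
  d <- suppressWarnings(simulate(setting1(200, seed = 6)))
  f0 <- fit_semipar(d, exp_family(rate = 1), exp_family(rate = 1),
                    bootstrap = 0L)
  expect_null(f0$se_theta)
  f1 <- fit_semipar(d, exp_family(rate = 1), exp_family(rate = 1),
                    bootstrap = 25L, seed = 9)
  f2 <- fit_semipar(d, exp_family(rate = 1), exp_family(rate = 1),
                    bootstrap = 25L, seed = 9)
  expect_identical(f1$se_theta, f2$se_theta)
  expect_true(f1$se_theta > 0 && f1$se_gamma > 0)
  expect_identical(f1$theta_hat, f0$theta_hat)
})
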