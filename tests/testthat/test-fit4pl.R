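test_that("normalization divides by the control mean", {
  expect_equal(normalize_responses(0.6, 0.6), 1)
  expect_equal(normalize_responses(0, 0.6), 0)
  expect_equal(normalize_responses(0.3, 0.6), 0.5)
  expect_error(normalize_responses(1, 0), "degenerate")
  expect_error(normalize_responses(1, -2), "degenerate")
})

test_that("noiseless 4PL data is recovered essentially exactly", {
  d <- gen_series(10, 2)
  fit <- fit_4pl(d$conc, d$response)
  expect_true(fit$converged)
  expect_equal(fit$half_max, 10, tolerance = 1e-6)
  expect_equal(fit$hill, 2, tolerance = 1e-4)
  expect_equal(fit$top, 1, tolerance = 1e-6)
  expect_equal(fit$bottom, 0, tolerance = 1e-6)
  expect_equal(fit$direction, "inhibition")
  # the fitted curve passes through the midpoint at half_max
  expect_equal(predict(fit, fit$half_max), (fit$top + fit$bottom) / 2)
})

test_that("recovery holds across the truth grid with noiseless data", {
  for (ec50 in c(0.1, 1, 10, 100)) {
    for (hill in c(0.7, 2, 5)) {
      d <- gen_series(ec50, hill)
      fit <- fit_4pl(d$conc, d$response)
      expect_lt(abs(fit$half_max - ec50) / ec50, 1e-4)
    }
  }
})

test_that("the fit agrees with an independent nls() fit on noisy data", {
  set.seed(42)
  d <- gen_series(10, 2, noise = 0.05)
  fit <- fit_4pl(d$conc, d$response)
  ref <- nls(response ~ bottom + (top - bottom) / (1 + (conc / hm)^h),
             data = d,
             start = list(top = 1, bottom = 0, hm = 8, h = 1.5))
  expect_equal(fit$half_max, coef(ref)[["hm"]], tolerance = 1e-3)
  expect_equal(fit$hill, coef(ref)[["h"]], tolerance = 1e-2)
  expect_lte(fit$rss, sum(residuals(ref)^2) * (1 + 1e-6))
})

test_that("stimulation (protective) curves are fitted in mirror direction", {
  conc <- rep(100 / 2^(0:9), each = 2)
  resp <- 1 + 0.8 * (1 - 1 / (1 + (conc / 20)^2))  # rises with conc
  fit <- fit_4pl(conc, resp)
  expect_equal(fit$direction, "stimulation")
  expect_equal(fit$half_max, 20, tolerance = 1e-4)
  expect_gt(fit$top, fit$bottom)
})

test_that("half_max is scale equivariant; hill/top/bottom invariant", {
  set.seed(7)
  d <- gen_series(5, 1.5, noise = 0.03)
  f1 <- fit_4pl(d$conc, d$response)
  for (k in c(0.01, 7, 1000)) {
    f2 <- fit_4pl(d$conc * k, d$response)
    expect_equal(f2$half_max, f1$half_max * k, tolerance = 1e-5)
    expect_equal(f2$hill, f1$hill, tolerance = 1e-5)
    expect_equal(f2$top, f1$top, tolerance = 1e-6)
    expect_equal(f2$bottom, f1$bottom, tolerance = 1e-6)
  }
})

test_that("degenerate inputs give the sentinel or an informative error", {
  conc <- rep(c(1, 2, 4, 8, 16), each = 2)
  # all responses equal: no-inhibition sentinel, not an exception
  f <- fit_4pl(conc, rep(0.8, 10))
  expect_true(f$no_inhibition)
  expect_true(is.na(f$half_max))
  # dynamic range below 20% of control: sentinel
  f2 <- fit_4pl(conc, 0.9 + 0.1 / (1 + (conc / 4)^2))
  expect_true(f2$no_inhibition)
  expect_error(fit_4pl(c(1, 2, 4), c(1, 0.5, 0)), "insufficient")
  expect_error(fit_4pl(conc, rep(-1, 10)), ">= 0")
  # zero concentrations are excluded, so 3 nonzero levels is insufficient
  expect_error(fit_4pl(c(0, 0, 1, 2, 4), c(1, 1, 1, 0.5, 0)),
               "insufficient")
})

test_that("fitted half_max stays within a decade of the tested range", {
  set.seed(3)
  # truth far above the tested range: estimate must be clamped, not wild
  d <- gen_series(1e5, 2, top_conc = 512, noise = 0)
  # nearly flat within range -> should be a no-inhibition call
  f <- fit_4pl(d$conc, d$response)
  expect_true(f$no_inhibition)
  # moderately outside: fitted value bounded by max conc * 10
  d2 <- gen_series(2000, 2, top_conc = 512)
  f2 <- fit_4pl(d2$conc, d2$response)
  if (!f2$no_inhibition) {
    expect_lte(f2$half_max, max(d2$conc) * 10 + 1e-6)
    expect_gte(f2$half_max, min(d2$conc) / 10 - 1e-9)
  }
})

test_that("formula interface and methods are consistent", {
  set.seed(9)
  d <- gen_series(10, 2, noise = 0.02)
  f1 <- fit_4pl(response ~ conc, d)
  f2 <- fit_4pl(d$conc, d$response)
  expect_equal(coef(f1), coef(f2))
  expect_equal(unname(coef(f1)["half_max"]), f1$half_max)
  expect_equal(residuals(f1), d$response - fitted(f1))
  expect_equal(length(fitted(f1)), nrow(d))
  s <- summary(f1)
  expect_s3_class(s, "summary.fit4pl")
  expect_equal(s$n, nrow(d))
  sims <- simulate(f1, nsim = 3, seed = 5)
  expect_equal(dim(sims), c(nrow(d), 3L))
  expect_true(all(sims >= 0))
  expect_output(print(f1), "half_max")
})
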