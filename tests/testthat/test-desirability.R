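test_that("the peak evaluates to o + a at its mode and decays to o in both tails", {
  set.seed(42)
  for (k in 1:25) {
    o <- runif(1, 0, 5); a <- runif(1, 0.1, 100)
    b <- runif(1, -100, 500); cw <- runif(1, 0.1, 80)
    p <- desirability_params(o = o, a = a, b = b, c = cw)
    expect_identical(eval_f(b, p), o + a)
    expect_equal(eval_f(b + 500 * cw, p), o, tolerance = 1e-12)
    expect_equal(eval_f(b - 50 * cw, p), o, tolerance = 1e-12)
  }
})

test_that("hand-computed peak values are reproduced", {
  p <- desirability_params(o = 0, a = 1, b = 0, c = 1)
  expect_equal(eval_f(0, p), 1)
  # exp(-exp(-1) - 1 + 1) = exp(-1/e)
  expect_equal(eval_f(1, p), 0.6922006, tolerance = 1e-6)
  p2 <- desirability_params(o = 0.1, a = 2, b = 5, c = 2)
  expect_equal(eval_f(5, p2), 2.1)
})

test_that("evaluation is numerically stable for extreme standardized arguments", {
  p <- desirability_params(o = 0.5, a = 3, b = 0, c = 1)
  x <- c(-700, -100, 100, 700)
  f <- eval_f(x, p)
  expect_true(all(is.finite(f)))
  expect_equal(f, rep(0.5, 4), tolerance = 1e-12)
})

test_that("zero width is rejected", {
  expect_error(desirability_params(o = 0, a = 1, b = 0, c = 0), "non-zero")
})

test_that("scaling uses the analytic maximum and yields df(b) = 1", {
  p <- scale_desirability(desirability_params(o = 0.1, a = 2, b = 5, c = 2))
  expect_equal(p$max_value, 2.1)
  expect_equal(eval_df(5, p), 1)
  q <- scale_desirability(desirability_params(o = 0, a = 1, b = 0, c = 1))
  expect_equal(q$max_value, 1)
  xs <- seq(-5, 5, by = 0.25)
  expect_equal(eval_df(xs, q), eval_f(xs, q))
  # a negative offset can push the maximum below zero
  expect_error(scale_desirability(desirability_params(o = -2, a = 1, b = 0,
                                                      c = 1)),
               "non-positive maximum")
})

test_that("scaled desirability stays within [0, 1] and errors when unscaled", {
  expect_error(eval_df(0, desirability_params(o = 0, a = 1, b = 0, c = 1)),
               "unscaled")
  set.seed(7)
  for (k in 1:50) {
    p <- scale_desirability(desirability_params(
      o = runif(1, 0, 10), a = runif(1, 0.01, 50),
      b = runif(1, -200, 600), c = runif(1, 0.05, 100)))
    x <- runif(2000, p$b - 20 * p$c, p$b + 20 * p$c)
    d <- eval_df(x, p)
    expect_true(all(d >= 0 & d <= 1))
    expect_equal(eval_df(p$b, p), 1)
  }
})

test_that("desirability is unimodal: increasing toward b, decreasing after", {
  p <- scale_desirability(desirability_params(o = 0.3, a = 4, b = 10, c = 3))
  left <- eval_df(seq(10 - 30, 10, length.out = 200), p)
  right <- eval_df(seq(10, 10 + 60, length.out = 200), p)
  expect_true(all(diff(left) >= 0))
  expect_true(all(diff(right) <= 0))
})

test_that("a noiseless histogram is refit to the generating parameters", {
  h <- peak_histogram(o = 2, a = 40, b = 300, cw = 60)
  fit <- fit_desirability(h, n_starts = 4, seed = 1)
  cf <- coef(fit)
  truth <- c(o = 2, a = 40, b = 300, c = 60)
  expect_lt(max(abs(cf[names(truth)] - truth) / truth), 1e-4)
  expect_lt(fit$sse, 1e-6)
  expect_true(fit$converged)
})

test_that("Poisson-noise refits recover the mode within half a bin", {
  set.seed(11)
  for (k in 1:5) {
    b <- runif(1, 200, 400); cw <- runif(1, 30, 70)
    centers <- seq(b - 4 * cw, b + 8 * cw, length.out = 25)
    width <- centers[2] - centers[1]
    t <- (centers - b) / cw
    shape <- exp(-exp(-t) - t + 1)
    lam <- shape * 2000 / sum(shape)  # n_total ~ 2000
    h <- list(centers = centers, counts = rpois(length(lam), lam),
              descriptor = "MW")
    fit <- fit_desirability(h, n_starts = 8, seed = k)
    expect_lt(abs(coef(fit)[["b"]] - b), width / 2)
  }
})

test_that("under-determined histograms are rejected", {
  h <- list(centers = 1:4, counts = c(1, 5, 3, 1), descriptor = "RB")
  expect_error(fit_desirability(h), "at least 5 bins")
})

test_that("fit methods expose coefficients, predictions and residuals", {
  h <- peak_histogram(o = 1, a = 20, b = 50, cw = 10, n_bins = 20)
  fit <- fit_desirability(h, n_starts = 2, seed = 1)
  expect_named(coef(fit), c("o", "a", "b", "c", "max_value"))
  expect_equal(predict(fit, coef(fit)[["b"]]), 1)  # df at the mode
  expect_equal(length(residuals(fit)), 20)
  expect_output(print(fit), "Desirability peak fit")
})
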