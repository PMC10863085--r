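test_that("noise-free sigmoid parameters are recovered to 1e-4", {
  tt <- seq(0, 40, by = 0.25)
  for (model in c("logistic", "gompertz")) {
    series <- make_sigmoid_series(model, A = 2, mu_max = 0.8, lam = 10,
                                  n0 = 0.05, times = tt)
    fit <- fit_parametric(log_transform(series, tt), model)
    expect_true(fit$converged)
    expect_equal(fit$params$A, 2, tolerance = 1e-4)
    expect_equal(fit$params$mu_max, 0.8, tolerance = 1e-4)
    expect_equal(fit$params$lam, 10, tolerance = 1e-4)
    expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    expect_true(all(fit$se >= 0 | is.na(fit$se)))
  }
})

test_that("degenerate traces are rejected with data errors", {
  tt <- 0:10
  expect_error(
    fit_parametric(log_transform(exp(0.3 * 0:3), 0:3), "logistic"),
    "at least 5")
  flat <- log_transform(rep(0.4, 11), tt)
  expect_error(fit_parametric(flat, "logistic"), "not identifiable")
})

test_that("parametric fit attaches a sane exponential-phase window", {
  tt <- seq(0, 40, by = 0.25)
  series <- make_sigmoid_series("logistic", A = 2, mu_max = 0.8, lam = 10,
                                n0 = 0.05, times = tt)
  fit <- fit_parametric(log_transform(series, tt), "logistic")
  expect_false(is.null(fit$window))
  expect_lt(fit$window[1], fit$window[2])
  # window endpoints are the grid points nearest lam and lam + A/mu
  expect_equal(tt[fit$window[1]], 10, tolerance = 0.25)
  expect_equal(tt[fit$window[2]], 10 + 2 / 0.8, tolerance = 0.25)
})

test_that("the fitted optimum beats random probe parameter vectors", {
  tt <- seq(0, 50, by = 0.5)
  series <- make_sigmoid_series("gompertz", A = 2.5, mu_max = 0.5, lam = 8,
                                n0 = 0.03, times = tt)
  set.seed(9)
  noisy <- series + rnorm(length(series), 0, 0.01)
  lt <- log_transform(noisy, tt)
  fit <- fit_parametric(lt, "gompertz")
  ok <- lt$valid
  rss <- function(p) sum((lt$y[ok] - model_y(p, lt$times[ok]))^2)
  rss_hat <- rss(fit$params)
  for (i in 1:50) {
    probe <- model_params("gompertz", A = runif(1, 0.5, 4),
                          mu_max = runif(1, 0.05, 2),
                          lam = runif(1, 0, 40))
    expect_lte(rss_hat, rss(probe) + 1e-10)
  }
})

test_that("Easy Linear recovers a global line and breaks ties earliest", {
  tt <- seq(0, 20, by = 0.5)
  lt <- log_transform(0.1 * exp(0.5 * tt), tt)
  for (w in c(3, 10, 20)) {
    fit <- fit_easy_linear(lt, w)
    expect_equal(fit$mu_max, 0.5, tolerance = 1e-10)
    expect_equal(fit$window, c(1, w))  # all slopes equal -> earliest wins
  }
  # window = all valid points -> a single candidate spanning the trace
  fit <- fit_easy_linear(lt, length(tt))
  expect_equal(fit$window, c(1, length(tt)))
  expect_error(fit_easy_linear(lt, 1), ">= 2")
  expect_error(fit_easy_linear(lt, length(tt) + 1), "No contiguous run")
})

test_that("Easy Linear finds the exponential segment of a piecewise trace", {
  lt <- piecewise_trace()  # slope 1 on t in [5, 10], flat elsewhere
  fit <- fit_easy_linear(lt, 5)
  expect_equal(fit$mu_max, 1, tolerance = 1e-10)
  expect_true(lt$times[fit$window[1]] >= 5 - 1e-9)
  expect_true(lt$times[fit$window[2]] <= 10 + 1e-9)
  oracle <- brute_easy_linear(lt, 5)
  expect_equal(fit$mu_max, oracle$slope, tolerance = 1e-12)
  expect_equal(fit$window, oracle$window)
})

test_that("Easy Linear equals exhaustive enumeration on random noisy traces", {
  set.seed(21)
  for (i in 1:15) {
    n <- sample(30:120, 1)
    tt <- sort(runif(n, 0, 48))
    A <- runif(1, 0.5, 3)
    mu <- runif(1, 0.1, 1.5)
    lam <- runif(1, 0, 20)
    series <- make_sigmoid_series("logistic", A, mu, lam, 0.05, tt) +
      rnorm(n, 0, 0.01)
    lt <- tryCatch(log_transform(series, tt), error = function(e) NULL)
    if (is.null(lt)) next
    w <- sample(5:15, 1)
    fit <- tryCatch(fit_easy_linear(lt, w), error = function(e) NULL)
    oracle <- brute_easy_linear(lt, w)
    if (is.null(fit)) {
      expect_null(oracle)
      next
    }
    expect_equal(fit$mu_max, oracle$slope, tolerance = 1e-10)
    expect_equal(fit$window, oracle$window)
  }
})

test_that("masked points break Easy Linear window contiguity", {
  tt <- seq(0, 10, by = 1)
  series <- 0.1 * exp(0.4 * tt)
  series[6] <- -1  # masked after log transform
  lt <- log_transform(series, tt)
  fit <- fit_easy_linear(lt, 4)
  # no window may span index 6; candidates are 1..5 and 7..11
  expect_true(fit$window[2] <= 5 || fit$window[1] >= 7)
  expect_equal(fit$mu_max, 0.4, tolerance = 1e-10)
})

test_that("Easy Linear slope is non-increasing in window size on sigmoids", {
  tt <- seq(0, 30, by = 0.25)
  series <- make_sigmoid_series("gompertz", A = 2, mu_max = 0.9, lam = 6,
                                n0 = 0.05, times = tt)
  lt <- log_transform(series, tt)
  slopes <- vapply(c(3, 5, 10, 20, 40, 80),
                   function(w) fit_easy_linear(lt, w)$mu_max, numeric(1))
  expect_true(all(diff(slopes) <= 1e-10))
})

test_that("manual fit reproduces the generating rate and validates input", {
  tt <- seq(0, 20, by = 0.5)
  lt <- log_transform(0.07 * exp(0.35 * tt), tt)
  fit <- fit_manual(lt, 2, 15)
  expect_equal(fit$mu_max, 0.35, tolerance = 1e-10)
  expect_equal(fit$method, "manual")
  expect_error(fit_manual(lt, 15, 2), "less than")
  expect_error(fit_manual(lt, 4.9, 5.1), "at least 2")
})

test_that("manual fit over the Easy Linear window reproduces its slope", {
  lt <- piecewise_trace()
  el <- fit_easy_linear(lt, 5)
  man <- fit_manual(lt, lt$times[el$window[1]], lt$times[el$window[2]])
  expect_equal(man$mu_max, el$mu_max, tolerance = 1e-12)
  expect_equal(man$window, el$window)
})

test_that("tidy and glance expose broom-style summaries", {
  tt <- seq(0, 40, by = 0.5)
  series <- make_sigmoid_series("logistic", 2, 0.8, 10, 0.05, tt)
  fit <- fit_parametric(log_transform(series, tt), "logistic")
  td <- tidy(fit)
  expect_equal(td$term, c("A", "mu_max", "lam"))
  expect_equal(td$estimate[2], 0.8, tolerance = 1e-4)
  gl <- glance(fit)
  expect_true(gl$converged)
  expect_equal(gl$n, length(tt))
  el <- fit_easy_linear(log_transform(series, tt), 10)
  expect_equal(tidy(el)$term, "mu_max")
})
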