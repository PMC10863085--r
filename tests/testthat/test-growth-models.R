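# Closed-form "tight" landmarks, derived independently from the
# third-derivative zeros: for the logistic they sit at sigmoid levels
# y/A = (3 +/- sqrt(3))/6, for the Gompertz at inner-exponential values
# v = (3 +/- sqrt(5))/2.
logistic_tight_lag <- function(A, mu, lam) {
  lam + A / (4 * mu) * (2 - log(2 + sqrt(3)))
}
logistic_tight_end <- function(A, mu, lam) {
  lam + A / (4 * mu) * (2 + log(2 + sqrt(3)))
}
gompertz_tight_lag <- function(A, mu, lam) {
  lam + A * (1 - log((3 + sqrt(5)) / 2)) / (mu * exp(1))
}
gompertz_tight_end <- function(A, mu, lam) {
  lam + A * (1 - log((3 - sqrt(5)) / 2)) / (mu * exp(1))
}

test_that("model curves hit their exact spot values", {
  p <- model_params("logistic", A = 2, mu_max = 1, lam = 5)
  expect_equal(model_y(p, 5), 2 / (1 + exp(2)), tolerance = 1e-12)
  g <- model_params("gompertz", A = 3.3, mu_max = 0.7, lam = 12)
  expect_equal(model_y(g, 12), 3.3 * exp(-exp(1)), tolerance = 1e-12)
  e <- model_params("exponential", mu_max = 0.25)
  expect_equal(model_y(e, c(0, 4)), c(0, 1))
  # upper asymptote far past the transition
  expect_equal(model_y(p, 5 + 1e6 * 2 / 1), 2, tolerance = 1e-9)
  expect_equal(model_y(g, 12 + 1e6 * 3.3 / 0.7), 3.3, tolerance = 1e-9)
})

test_that("parameter validation rejects degenerate models", {
  expect_error(model_params("logistic", A = -1, mu_max = 1, lam = 0),
               "positive")
  expect_error(model_params("gompertz", A = 2, mu_max = 0, lam = 0),
               "positive")
  expect_error(lag_time(model_params("exponential", mu_max = 1)),
               "no lag")
  expect_error(inflection_time(model_params("exponential", mu_max = 1)),
               "no lag")
})

test_that("the slope at the inflection point is mu_max", {
  cases <- random_sigmoid_params(25, "logistic", seed = 1)
  for (model in c("logistic", "gompertz")) {
    for (i in seq_len(nrow(cases))) {
      p <- model_params(model, A = cases$A[i], mu_max = cases$mu_max[i],
                        lam = cases$lam[i])
      tm <- inflection_time(p)
      expect_equal(num_slope(function(t) model_y(p, t), tm), p$mu_max,
                   tolerance = 1e-6)
    }
  }
  # worked examples
  p <- model_params("logistic", A = 2, mu_max = 1, lam = 5)
  expect_equal(inflection_time(p), 6)
  expect_equal(model_y(p, 6), 1)  # A/2 at the logistic inflection
  g <- model_params("gompertz", A = exp(1), mu_max = 1, lam = 0)
  expect_equal(inflection_time(g), 1)
  expect_equal(model_y(g, 1), 1)  # A/e at the Gompertz inflection
})

test_that("standard landmarks are the tangent constructions", {
  for (model in c("logistic", "gompertz")) {
    p <- model_params(model, A = 2, mu_max = 1, lam = 5)
    expect_equal(lag_time(p, "standard"), 5)
    expect_equal(exp_phase_bounds(p, "standard"),
                 c(t_start = 5, t_end = 7))
  }
})

test_that("numeric third-derivative roots match the closed forms to 1e-8", {
  cases <- random_sigmoid_params(50, "logistic", seed = 2)
  for (i in seq_len(nrow(cases))) {
    A <- cases$A[i]; mu <- cases$mu_max[i]; lam <- cases$lam[i]
    p <- model_params("logistic", A = A, mu_max = mu, lam = lam)
    expect_equal(lag_time(p, "tight"), logistic_tight_lag(A, mu, lam),
                 tolerance = 1e-8)
    expect_equal(unname(exp_phase_bounds(p, "tight")["t_end"]),
                 logistic_tight_end(A, mu, lam), tolerance = 1e-8)
    g <- model_params("gompertz", A = A, mu_max = mu, lam = lam)
    expect_equal(lag_time(g, "tight"), gompertz_tight_lag(A, mu, lam),
                 tolerance = 1e-8)
    expect_equal(unname(exp_phase_bounds(g, "tight")["t_end"]),
                 gompertz_tight_end(A, mu, lam), tolerance = 1e-8)
  }
})

test_that("tight landmarks lie strictly inside the standard interval", {
  cases <- random_sigmoid_params(100, "logistic", seed = 3)
  for (model in c("logistic", "gompertz")) {
    for (i in seq_len(nrow(cases))) {
      p <- model_params(model, A = cases$A[i], mu_max = cases$mu_max[i],
                        lam = cases$lam[i])
      std <- exp_phase_bounds(p, "standard")
      tight <- exp_phase_bounds(p, "tight")
      expect_gt(tight[["t_start"]], std[["t_start"]])  # tight lag later
      expect_lt(tight[["t_end"]], std[["t_end"]])
      expect_lt(tight[["t_start"]], tight[["t_end"]])
    }
  }
})

test_that("sigmoids are increasing, bounded by A, with max slope mu_max", {
  cases <- random_sigmoid_params(10, "logistic", seed = 4)
  for (model in c("logistic", "gompertz")) {
    for (i in seq_len(nrow(cases))) {
      p <- model_params(model, A = cases$A[i], mu_max = cases$mu_max[i],
                        lam = cases$lam[i])
      grid <- seq(p$lam - p$A / p$mu_max, p$lam + 4 * p$A / p$mu_max,
                  length.out = 2000)
      y <- model_y(p, grid)
      expect_true(all(diff(y) > 0))
      expect_true(all(y > 0 & y < p$A))
      slopes <- diff(y) / diff(grid)
      expect_equal(max(slopes), p$mu_max, tolerance = 1e-4)
      expect_lt(max(slopes), p$mu_max * (1 + 1e-9))
    }
  }
})

test_that("y(lam) is the model-specific constant fraction of A", {
  cases <- random_sigmoid_params(20, "logistic", seed = 5)
  for (i in seq_len(nrow(cases))) {
    p <- model_params("logistic", A = cases$A[i], mu_max = cases$mu_max[i],
                      lam = cases$lam[i])
    expect_equal(model_y(p, p$lam) / p$A, 1 / (1 + exp(2)),
                 tolerance = 1e-12)
    g <- model_params("gompertz", A = cases$A[i], mu_max = cases$mu_max[i],
                      lam = cases$lam[i])
    expect_equal(model_y(g, g$lam) / g$A, exp(-exp(1)), tolerance = 1e-12)
  }
})

test_that("scaling A and mu_max together rescales y and fixes the times", {
  for (model in c("logistic", "gompertz")) {
    p1 <- model_params(model, A = 1.5, mu_max = 0.4, lam = 20)
    p2 <- model_params(model, A = 3 * 1.5, mu_max = 3 * 0.4, lam = 20)
    tt <- seq(0, 60, by = 0.5)
    expect_equal(model_y(p2, tt), 3 * model_y(p1, tt), tolerance = 1e-12)
    expect_equal(lag_time(p2, "tight"), lag_time(p1, "tight"),
                 tolerance = 1e-8)
    expect_equal(exp_phase_bounds(p2, "standard"),
                 exp_phase_bounds(p1, "standard"))
  }
})
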