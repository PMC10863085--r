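#' Growth model parameter set
#'
#' Bundle the parameters of a growth model in the Zwietering parameterization,
#' where the asymptote `A`, the maximum specific growth rate `mu_max` and the
#' lag time `lam` appear directly as parameters of the log-population curve
#' \eqn{y(t) = \ln(N(t)/N_0)}.
#'
#' @param model One of `"logistic"`, `"gompertz"` or `"exponential"`.
#' @param A Asymptotic log-population \eqn{A = \ln(N_\infty/N_0)}
#'   (dimensionless, > 0). Ignored by the exponential model.
#' @param mu_max Maximum specific growth rate \eqn{\mu_{max}} in 1/h (> 0).
#' @param lam Lag time \eqn{\lambda} in hours. Ignored by the exponential
#'   model.
#' @param n0 Reference population size \eqn{N_0} in population units
#'   (e.g. OD600); used only to map `y` back to population scale
#'   (\eqn{N_\infty = N_0 e^A}).
#'
#' @return An object of class `model_params`.
#' @export
#' @examples
#' model_params("logistic", A = 2, mu_max = 1, lam = 5)
model_params <- function(model = c("logistic", "gompertz", "exponential"),
                         A = NA_real_, mu_max, lam = NA_real_, n0 = NA_real_) {
  model <- match.arg(model)
  if (!is.numeric(mu_max) || length(mu_max) != 1L || !is.finite(mu_max) ||
      mu_max <= 0) {
    stop("`mu_max` must be a single positive finite number.", call. = FALSE)
  }
  if (model != "exponential") {
    if (!is.numeric(A) || length(A) != 1L || !is.finite(A) || A <= 0) {
      stop("`A` must be a single positive finite number for sigmoid models.",
           call. = FALSE)
    }
    if (!is.numeric(lam) || length(lam) != 1L || !is.finite(lam)) {
      stop("`lam` must be a single finite number for sigmoid models.",
           call. = FALSE)
    }
  }
  structure(
    list(model = model, A = as.numeric(A), mu_max = as.numeric(mu_max),
         lam = as.numeric(lam), n0 = as.numeric(n0)),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params> ", x$model, "\n", sep = "")
  cat(sprintf("  A = %s, mu_max = %s /h, lambda = %s h, N0 = %s\n",
              format(x$A), format(x$mu_max), format(x$lam), format(x$n0)))
  invisible(x)
}

check_sigmoid <- function(p) {
  if (!inherits(p, "model_params")) {
    stop("`p` must be a `model_params` object.", call. = FALSE)
  }
  if (p$model == "exponential") {
    stop("The exponential model has no lag or exponential-phase landmarks.",
         call. = FALSE)
  }
  invisible(p)
}

#' Evaluate a growth model on the log-population scale
#'
#' Closed-form evaluation of \eqn{y(t) = \ln(N(t)/N_0)} for the modified
#' Logistic, modified Gompertz and exponential growth models.
#'
#' The modified Logistic model is
#' \deqn{y = \frac{A}{1 + \exp[\frac{4\mu_{max}}{A}(\lambda - t) + 2]}}
#' and the modified Gompertz model is
#' \deqn{y = A \exp\{-\exp[\frac{\mu_{max} e}{A}(\lambda - t) + 1]\}.}
#' The exponential model is \eqn{N = N_0 e^{\mu_{max} t}}, i.e.
#' \eqn{y = \mu_{max} t}.
#'
#' @param p A [model_params] object.
#' @param t Time in hours (vectorized).
#'
#' @return Numeric vector of `y` values, same length as `t`.
#' @export
#' @examples
#' p <- model_params("logistic", A = 2, mu_max = 1, lam = 5)
#' model_y(p, c(0, 5, 10, 50))
model_y <- function(p, t) {
  if (!inherits(p, "model_params")) {
    stop("`p` must be a `model_params` object.", call. = FALSE)
  }
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t))) {
    stop("`t` must be finite numeric.", call. = FALSE)
  }
  switch(p$model,
    logistic = p$A / (1 + exp(4 * p$mu_max / p$A * (p$lam - t) + 2)),
    gompertz = p$A * exp(-exp(p$mu_max * exp(1) / p$A * (p$lam - t) + 1)),
    exponential = p$mu_max * t
  )
}

# Analytic third derivative of y(t) for the sigmoid models. For the logistic,
# with s = y/A, y''' = A c^3 s(1-s)(6s^2 - 6s + 1), c = 4 mu/A; for the
# Gompertz, with v = exp[(mu e/A)(lam - t) + 1], y''' = A k^3 v e^(-v)
# (v^2 - 3v + 1), k = mu e/A. Zeros of the polynomial factors are the
# curvature-change landmarks used by the "tight" phase definitions.
model_d3y <- function(p, t) {
  switch(p$model,
    logistic = {
      cc <- 4 * p$mu_max / p$A
      s <- 1 / (1 + exp(cc * (p$lam - t) + 2))
      p$A * cc^3 * s * (1 - s) * (6 * s^2 - 6 * s + 1)
    },
    gompertz = {
      k <- p$mu_max * exp(1) / p$A
      v <- exp(k * (p$lam - t) + 1)
      p$A * k^3 * v * exp(-v) * (v^2 - 3 * v + 1)
    },
    stop("Third derivative defined for sigmoid models only.", call. = FALSE)
  )
}

# All zeros of the third derivative, found numerically: sign-change
# bracketing on a grid spanning [lam - A/mu, lam + 3 A/mu], then bisection
# (uniroot) to 1e-10 h. Both sigmoids have exactly two such zeros.
third_derivative_zeros <- function(p, n_grid = 4000L) {
  check_sigmoid(p)
  span <- p$A / p$mu_max
  grid <- seq(p$lam - span, p$lam + 3 * span, length.out = n_grid)
  f <- model_d3y(p, grid)
  sgn <- sign(f)
  idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (length(idx) == 0L) {
    stop("Failed to bracket any zero of the third derivative.", call. = FALSE)
  }
  vapply(idx, function(i) {
    stats::uniroot(function(t) model_d3y(p, t),
                   lower = grid[i], upper = grid[i + 1L],
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Time of the inflection point of a sigmoid growth model
#'
#' The inflection point is where the curve's slope attains its maximum
#' \eqn{\mu_{max}}: \eqn{t_m = \lambda + A/(2\mu_{max})} for the Logistic
#' model and \eqn{t_m = \lambda + A/(e\,\mu_{max})} for the Gompertz model.
#'
#' @inheritParams model_y
#' @return Inflection time in hours.
#' @export
#' @examples
#' inflection_time(model_params("logistic", A = 2, mu_max = 1, lam = 5))
inflection_time <- function(p) {
  check_sigmoid(p)
  switch(p$model,
    logistic = p$lam + p$A / (2 * p$mu_max),
    gompertz = p$lam + p$A / (exp(1) * p$mu_max)
  )
}

#' Lag time of a sigmoid growth model
#'
#' Under the standard definition the lag time is where the tangent at the
#' inflection point crosses the x-axis; in the Zwietering parameterization
#' this is the model parameter \eqn{\lambda} itself. Under the "tight"
#' definition it is the smallest zero of the third derivative of \eqn{y(t)}
#' — the point where the slope increases fastest, which always lies later
#' than the standard lag and closer to the log-linear segment.
#'
#' @inheritParams model_y
#' @param definition `"standard"` (tangent x-intercept) or `"tight"`
#'   (smallest third-derivative zero).
#' @return Lag time in hours.
#' @export
#' @examples
#' p <- model_params("logistic", A = 2, mu_max = 1, lam = 5)
#' lag_time(p, "standard")
#' lag_time(p, "tight")
lag_time <- function(p, definition = c("standard", "tight")) {
  definition <- match.arg(definition)
  check_sigmoid(p)
  if (definition == "standard") {
    return(p$lam)
  }
  min(third_derivative_zeros(p))
}

#' Start and end of the exponential growth phase
#'
#' The phase starts at the lag time and ends, under the standard definition,
#' where the tangent at the inflection point reaches the plateau line
#' \eqn{y = A}, i.e. at \eqn{\lambda + A/\mu_{max}} for both sigmoid models.
#' Under the "tight" definition both boundaries are zeros of the third
#' derivative (smallest and largest), giving a strictly narrower interval.
#'
#' @inheritParams lag_time
#' @return Named numeric vector `c(t_start, t_end)` in hours.
#' @export
#' @examples
#' p <- model_params("logistic", A = 2, mu_max = 1, lam = 5)
#' exp_phase_bounds(p, "standard")  # c(5, 7)
exp_phase_bounds <- function(p, definition = c("standard", "tight")) {
  definition <- match.arg(definition)
  check_sigmoid(p)
  if (definition == "standard") {
    out <- c(t_start = p$lam, t_end = p$lam + p$A / p$mu_max)
  } else {
    z <- third_derivative_zeros(p)
    out <- c(t_start = min(z), t_end = max(z))
  }
  if (out[["t_start"]] >= out[["t_end"]]) {
    stop("Degenerate exponential phase: start is not before end.",
         call. = FALSE)
  }
  out
}
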