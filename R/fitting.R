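new_growth_fit <- function(method, trace, params = NULL, mu_max = NA_real_,
                           se = c(mu_max = NA_real_), r_squared = NA_real_,
                           window = NULL, converged = FALSE,
                           lag_definition = "standard") {
  structure(
    list(method = method, params = params, mu_max = mu_max, se = se,
         r_squared = r_squared, window = window, converged = converged,
         lag_definition = lag_definition, trace = trace),
    class = "growth_fit"
  )
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> method = %s, converged = %s\n",
              x$method, x$converged))
  if (x$converged) {
    cat(sprintf("  mu_max = %.6g /h (doubling time %.6g h), R^2 = %.6g\n",
                x$mu_max, log(2) / x$mu_max, x$r_squared))
    if (!is.null(x$window)) {
      cat(sprintf("  exponential window: data points %d..%d\n",
                  x$window[1], x$window[2]))
    }
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.growth_fit <- function(x, ...) {
  if (x$method %in% c("logistic", "gompertz") && !is.null(x$params)) {
    est <- c(A = x$params$A, mu_max = x$params$mu_max, lam = x$params$lam)
  } else {
    est <- c(mu_max = x$mu_max)
  }
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(x$se[names(est)])
  )
}

#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    converged = x$converged,
    r.squared = x$r_squared,
    n = sum(x$trace$valid)
  )
}

#' Fit a sigmoid growth model by nonlinear least squares
#'
#' Fits the modified Logistic or Gompertz model to an entire log-transformed
#' growth curve by bounded Levenberg-Marquardt least squares, minimizing
#' \eqn{\sum_i (y_i - y(t_i; A, \mu_{max}, \lambda))^2} over the valid
#' points. Starting values are derived from the data: `A` from the maximum
#' of `y`, `mu_max` from the steepest centered finite-difference slope, and
#' `lambda` from the tangent construction at that point. Optimizer failure
#' is reported via `converged = FALSE` rather than an error, so whole-plate
#' batch fits continue past pathological wells.
#'
#' @param trace A [log_trace] from [log_transform()].
#' @param model `"logistic"` or `"gompertz"`.
#' @param lag_definition `"standard"` or `"tight"`; controls the
#'   exponential-phase window attached to the result (see
#'   [exp_phase_bounds()]).
#'
#' @return A `growth_fit` object with fitted [model_params], standard
#'   errors, \eqn{R^2}, and the data-index window of the exponential phase.
#' @export
fit_parametric <- function(trace, model = c("logistic", "gompertz"),
                           lag_definition = c("standard", "tight")) {
  model <- match.arg(model)
  lag_definition <- match.arg(lag_definition)
  stopifnot(inherits(trace, "log_trace"))
  t_all <- trace$times
  ok <- trace$valid & is.finite(trace$y)
  tt <- t_all[ok]
  yy <- trace$y[ok]
  if (length(yy) < 5L) {
    stop("Parametric fitting needs at least 5 valid points.", call. = FALSE)
  }
  if (diff(range(yy)) < .Machine$double.eps^0.5) {
    stop("Flat trace: growth model parameters are not identifiable.",
         call. = FALSE)
  }

  span <- diff(range(tt))
  a0 <- max(yy)
  dy <- diff(yy) / diff(tt)
  slopes <- c(dy[1], (dy[-1] + dy[-length(dy)]) / 2, dy[length(dy)])
  imax <- which.max(slopes)
  mu0 <- max(slopes[is.finite(slopes)], 1e-6)
  lam0 <- tt[imax] - yy[imax] / mu0
  lower <- c(A = 1e-8, mu_max = 1e-8, lam = min(tt) - span)
  upper <- c(A = 2 * a0, mu_max = Inf, lam = max(tt))
  lam0 <- min(max(lam0, 0, lower[["lam"]]), upper[["lam"]])
  start <- list(A = a0, mu_max = mu0, lam = lam0)

  fn <- if (model == "logistic") {
    function(t, A, mu_max, lam) A / (1 + exp(4 * mu_max / A * (lam - t) + 2))
  } else {
    function(t, A, mu_max, lam) {
      A * exp(-exp(mu_max * exp(1) / A * (lam - t) + 1))
    }
  }

  fit <- tryCatch(
    minpack.lm::nlsLM(
      yy ~ fn(tt, A, mu_max, lam),
      start = start, lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(
        maxiter = 500, maxfev = 5000, ftol = 1e-10, ptol = 1e-10)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(new_growth_fit(model, trace, converged = FALSE,
                          se = c(A = NA_real_, mu_max = NA_real_,
                                 lam = NA_real_),
                          lag_definition = lag_definition))
  }

  est <- stats::coef(fit)
  params <- model_params(model, A = est[["A"]], mu_max = est[["mu_max"]],
                         lam = est[["lam"]], n0 = trace$n0)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) NULL)
  se <- if (is.null(se)) {
    c(A = NA_real_, mu_max = NA_real_, lam = NA_real_)
  } else {
    stats::setNames(as.numeric(se), names(est))
  }
  rss <- sum(stats::resid(fit)^2)
  tss <- sum((yy - mean(yy))^2)
  r2 <- 1 - rss / tss

  bounds <- tryCatch(exp_phase_bounds(params, lag_definition),
                     error = function(e) NULL)
  window <- NULL
  if (!is.null(bounds)) {
    i1 <- which.min(abs(t_all - bounds[["t_start"]]))
    i2 <- which.min(abs(t_all - bounds[["t_end"]]))
    if (i1 < i2) window <- c(i1, i2)
  }
  new_growth_fit(model, trace, params = params,
                 mu_max = est[["mu_max"]], se = se, r_squared = r2,
                 window = window, converged = TRUE,
                 lag_definition = lag_definition)
}

# Least-squares line through (x, y); returns slope, intercept, r2, slope se.
ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  rss <- sum((y - my - slope * (x - mx))^2)
  tss <- sum((y - my)^2)
  r2 <- if (tss > 0) 1 - rss / tss else NA_real_
  se <- if (n > 2L) sqrt(max(rss, 0) / (n - 2L) / sxx) else NA_real_
  list(slope = slope, intercept = my - slope * mx, r2 = r2, se = se)
}

# Maximal runs of TRUE in a logical vector, as a list of index vectors.
valid_runs <- function(valid) {
  r <- rle(valid)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  purrr::map2(starts[r$values], ends[r$values], seq.int)
}

#' Easy Linear estimation of the maximum growth rate
#'
#' The Easy Linear heuristic fits an ordinary least-squares line to every
#' contiguous subsegment of exactly `window` valid points of the
#' log-transformed curve and records the maximum slope as \eqn{\mu_{max}}.
#' The exponential phase is taken to run from the first to the last data
#' point of the winning subsegment. Ties — slopes equal to within a 1e-9
#' relative tolerance, as happens on exactly log-linear data — are broken
#' toward the earliest subsegment; masked points break contiguity, so a
#' window never spans a masked gap. Small windows tend to overestimate
#' \eqn{\mu_{max}} on noisy data.
#'
#' @param trace A [log_trace].
#' @param window Subsegment size in data points (>= 2). Default 10.
#'
#' @return A `growth_fit` with method `"easy_linear"`: slope, its standard
#'   error, the winning window's data indices and \eqn{R^2}.
#' @export
fit_easy_linear <- function(trace, window = 10L) {
  stopifnot(inherits(trace, "log_trace"))
  if (!is.numeric(window) || length(window) != 1L || is.na(window) ||
      window < 2) {
    stop("`window` must be an integer >= 2.", call. = FALSE)
  }
  window <- as.integer(window)
  runs <- valid_runs(trace$valid & is.finite(trace$y))
  runs <- runs[lengths(runs) >= window]
  if (length(runs) == 0L) {
    stop(sprintf(
      "No contiguous run of %d valid points for Easy Linear fitting.",
      window), call. = FALSE)
  }
  best <- NULL
  for (run in runs) {
    for (s in seq_len(length(run) - window + 1L)) {
      idx <- run[s:(s + window - 1L)]
      fit <- ols_line(trace$times[idx], trace$y[idx])
      # strict improvement beyond fp noise; near-ties keep the earliest
      if (is.null(best) ||
          fit$slope > best$fit$slope + 1e-9 * (1 + abs(best$fit$slope))) {
        best <- list(fit = fit, idx = idx)
      }
    }
  }
  new_growth_fit(
    "easy_linear", trace, mu_max = best$fit$slope,
    se = c(mu_max = best$fit$se), r_squared = best$fit$r2,
    window = c(best$idx[1], best$idx[window]), converged = TRUE
  )
}

#' Manual (exponential approximation) fit over a chosen time window
#'
#' Classic exponential approximation: the user identifies the log-linear
#' segment of the curve and a straight line is fitted to the valid points
#' with \eqn{t \in [t_{start}, t_{end}]}; the slope is \eqn{\mu_{max}} and
#' the window endpoints are the first and last selected data points.
#'
#' @param trace A [log_trace].
#' @param t_start,t_end Selection boundaries in hours, `t_start < t_end`.
#'
#' @return A `growth_fit` with method `"manual"`.
#' @export
fit_manual <- function(trace, t_start, t_end) {
  stopifnot(inherits(trace, "log_trace"))
  if (!is.numeric(t_start) || !is.numeric(t_end) || t_start >= t_end) {
    stop("`t_start` must be less than `t_end`.", call. = FALSE)
  }
  idx <- which(trace$valid & is.finite(trace$y) &
                 trace$times >= t_start & trace$times <= t_end)
  if (length(idx) < 2L) {
    stop("Manual selection must contain at least 2 valid points.",
         call. = FALSE)
  }
  fit <- ols_line(trace$times[idx], trace$y[idx])
  new_growth_fit(
    "manual", trace, mu_max = fit$slope, se = c(mu_max = fit$se),
    r_squared = fit$r2, window = c(idx[1], idx[length(idx)]),
    converged = TRUE
  )
}
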