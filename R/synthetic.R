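default_param_ranges <- function() {
  list(n0 = c(0, 0.5), A = c(0.5, 4), mu_max = c(0, 2), lam = c(0, 100))
}

#' Specification of a synthetic growth-curve study
#'
#' Describes a batch of simulated sigmoid growth curves: the generating
#' model, the uniform sampling ranges of the growth parameters, the
#' additive Gaussian measurement noise, and the sampling grid. The default
#' ranges are the biologically relevant ones used for fitter validation:
#' \eqn{N_0 \sim U(0, 0.5)}, \eqn{A \sim U(0.5, 4)},
#' \eqn{\mu_{max} \sim U(0, 2)} per hour, \eqn{\lambda \sim U(0, 100)}
#' hours. Noise is added on the population (measurement) scale, emulating
#' instrument noise on optical density; the default sd of 0.01 population
#' units is typical plate-reader noise. The default grid (0-200 h every
#' 0.5 h) spans the longest lag plus saturation for all but the slowest
#' growers.
#'
#' @param model Generating model, `"logistic"` or `"gompertz"`.
#' @param n_curves Number of curves (default 100).
#' @param noise_sd Standard deviation of additive Gaussian noise in
#'   population units; 0 for noiseless curves.
#' @param time_grid Strictly increasing sampling times in hours.
#' @param seed Integer seed; `NULL` leaves the RNG state untouched.
#' @param param_ranges Named list of `c(lower, upper)` uniform bounds for
#'   `n0`, `A`, `mu_max`, `lam`.
#'
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(model = c("logistic", "gompertz"),
                           n_curves = 100L, noise_sd = 0.01,
                           time_grid = seq(0, 200, by = 0.5),
                           seed = NULL,
                           param_ranges = default_param_ranges()) {
  model <- match.arg(model)
  stopifnot(n_curves >= 1, noise_sd >= 0)
  time_grid <- as.numeric(time_grid)
  if (any(diff(time_grid) <= 0)) {
    stop("`time_grid` must be strictly increasing.", call. = FALSE)
  }
  ranges <- utils::modifyList(default_param_ranges(), param_ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || r[1] >= r[2]) {
      stop(sprintf("Range for `%s` must be c(lower, upper).", nm),
           call. = FALSE)
    }
  }
  structure(
    list(model = model, n_curves = as.integer(n_curves),
         noise_sd = noise_sd, time_grid = time_grid,
         seed = if (is.null(seed)) NULL else as.integer(seed),
         param_ranges = ranges),
    class = "synthetic_spec"
  )
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf(
    "<synthetic_spec> %d %s curves, noise sd = %s, %d timepoints (%s-%s h)\n",
    x$n_curves, x$model, format(x$noise_sd), length(x$time_grid),
    format(min(x$time_grid)), format(max(x$time_grid))))
  invisible(x)
}

#' Draw random growth parameters for a synthetic study
#'
#' Independent uniform draws within the ranges of `spec`, one row per curve.
#' Draws of `n0` or `mu_max` below a floor of 1e-3 are redrawn so that no
#' generated curve is numerically degenerate (essentially flat or at zero
#' population).
#'
#' @param spec A [synthetic_spec]. Its `seed`, when set, seeds the RNG so
#'   the draw sequence is reproducible.
#'
#' @return A tibble with columns `curve`, `model`, `n0`, `A`, `mu_max`,
#'   `lam`.
#' @export
sample_parameters <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_curves
  r <- spec$param_ranges
  draw <- function(range, floor_at = -Inf) {
    x <- stats::runif(n, range[1], range[2])
    while (any(x < floor_at)) {
      i <- x < floor_at
      x[i] <- stats::runif(sum(i), range[1], range[2])
    }
    x
  }
  tibble::tibble(
    curve = seq_len(n),
    model = spec$model,
    n0 = draw(r$n0, floor_at = 1e-3),
    A = draw(r$A),
    mu_max = draw(r$mu_max, floor_at = 1e-3),
    lam = draw(r$lam)
  )
}

#' Generate one synthetic growth curve in population units
#'
#' Evaluates the model on the time grid of `spec` and adds Gaussian noise:
#' \eqn{N_i = N_0 e^{y(t_i)} + \epsilon_i},
#' \eqn{\epsilon_i \sim N(0, \sigma^2)}. With `noise_sd = 0` the exact
#' model values are returned. Uses the current RNG state (seed externally,
#' or via [run_validation()], for reproducibility).
#'
#' @param p A [model_params] with a finite `n0`.
#' @param spec A [synthetic_spec] supplying `time_grid` and `noise_sd`.
#'
#' @return Numeric vector of measurements, one per grid point.
#' @export
generate_curve <- function(p, spec) {
  stopifnot(inherits(p, "model_params"), inherits(spec, "synthetic_spec"))
  if (!is.finite(p$n0) || p$n0 <= 0) {
    stop("`p$n0` must be positive to generate population-scale curves.",
         call. = FALSE)
  }
  n_exact <- p$n0 * exp(model_y(p, spec$time_grid))
  if (spec$noise_sd == 0) {
    return(n_exact)
  }
  n_exact + stats::rnorm(length(n_exact), 0, spec$noise_sd)
}

#' Materialise a synthetic study as a growth dataset
#'
#' Draws parameters, generates every curve and packs them into a
#' [growth_dataset] (no blanks), e.g. to exercise the plate pipeline on
#' data with known truth.
#'
#' @param spec A [synthetic_spec].
#' @param ... Unused.
#' @return A [growth_dataset] whose samples are named `curve_1`,
#'   `curve_2`, ... with the true parameters attached as attribute
#'   `"truth"`.
#' @export
as_growth_dataset <- function(spec, ...) {
  stopifnot(inherits(spec, "synthetic_spec"))
  truth <- sample_parameters(spec)
  curves <- purrr::pmap(truth[c("n0", "A", "mu_max", "lam")],
    function(n0, A, mu_max, lam) {
      generate_curve(model_params(spec$model, A = A, mu_max = mu_max,
                                  lam = lam, n0 = n0), spec)
    })
  ds <- growth_dataset(spec$time_grid, curves,
                       paste0("curve_", truth$curve),
                       blank_ids = integer(0))
  attr(ds, "truth") <- truth
  ds
}

#' Run the synthetic fitter-validation study
#'
#' Generates `n_curves` random curves as described by `spec`, preprocesses each
#' (log transform; optional rolling-average smoothing), fits it with its
#' own generating model by nonlinear least squares, and reports the median
#' relative error \eqn{|\hat\theta - \theta|/|\theta|} per parameter over
#' the converged fits. Curves whose plateau is not reached within the time
#' grid are still fitted but flagged.
#'
#' Smoothing is off by default: an averaging window comparable to a
#' curve's rise time \eqn{A/\mu_{max}} flattens the transition and biases
#' \eqn{\mu_{max}} downward, so it should only be enabled deliberately for
#' data whose noise, not curvature, dominates at the window scale.
#'
#' @param spec A [synthetic_spec]; `spec$seed` makes the whole report
#'   reproducible bit for bit.
#' @param smooth_window Rolling-average window in data points applied
#'   before log transformation; 1 (the default) disables smoothing.
#'
#' @return A `validation_report`: a tibble with columns `model`,
#'   `parameter` (`A`, `mu_max`, `lam`) and `median_rel_error`, with the
#'   per-curve results in `attr(, "curves")` and the convergence count in
#'   `attr(, "n_converged")`. Errors if more than half the fits fail to
#'   converge.
#' @export
#' @examples
#' \donttest{
#' spec <- synthetic_spec("logistic", n_curves = 10, noise_sd = 0, seed = 42)
#' run_validation(spec)
#' }
run_validation <- function(spec, smooth_window = 1L) {
  stopifnot(inherits(spec, "synthetic_spec"), spec$n_curves >= 10)
  truth <- sample_parameters(spec)  # seeds the RNG when spec$seed is set

  fit_one <- function(n0, A, mu_max, lam, ...) {
    p <- model_params(spec$model, A = A, mu_max = mu_max, lam = lam,
                      n0 = n0)
    n <- generate_curve(p, spec)
    if (smooth_window > 1) n <- rolling_smooth(n, smooth_window)
    fit <- tryCatch(
      fit_parametric(log_transform(n, spec$time_grid), spec$model),
      error = function(e) NULL
    )
    plateau <- model_y(p, max(spec$time_grid)) >= 0.95 * A
    if (is.null(fit) || !fit$converged) {
      return(tibble::tibble(converged = FALSE, plateau_reached = plateau,
                            err_A = NA_real_, err_mu_max = NA_real_,
                            err_lam = NA_real_, r_squared = NA_real_))
    }
    tibble::tibble(
      converged = TRUE, plateau_reached = plateau,
      err_A = abs(fit$params$A - A) / abs(A),
      err_mu_max = abs(fit$params$mu_max - mu_max) / abs(mu_max),
      err_lam = abs(fit$params$lam - lam) / abs(lam),
      r_squared = fit$r_squared
    )
  }

  curves <- dplyr::bind_cols(
    truth,
    purrr::pmap(truth[c("n0", "A", "mu_max", "lam")], fit_one) |>
      dplyr::bind_rows()
  )
  n_conv <- sum(curves$converged)
  if (n_conv < spec$n_curves / 2) {
    stop(sprintf(
      "Validation failure: only %d of %d fits converged.",
      n_conv, spec$n_curves), call. = FALSE)
  }
  conv <- dplyr::filter(curves, .data$converged)
  report <- tibble::tibble(
    model = spec$model,
    parameter = c("A", "mu_max", "lam"),
    median_rel_error = c(stats::median(conv$err_A),
                         stats::median(conv$err_mu_max),
                         stats::median(conv$err_lam))
  )
  structure(report,
            curves = curves, n_converged = n_conv,
            noise_sd = spec$noise_sd,
            class = c("validation_report", class(report)))
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "<validation_report> %s model, noise sd = %s, %d/%d fits converged\n",
    x$model[1], format(attr(x, "noise_sd")), attr(x, "n_converged"),
    nrow(attr(x, "curves"))))
  print(tibble::as_tibble(x), ...)
  invisible(x)
}
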