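growth_stat_columns <- c(
  "doubling_time", "mu_max", "lag", "t_exp_start", "t_exp_end",
  "doublings_total", "doublings_exp", "yield_max"
)

#' Derive per-sample growth parameters from a fit
#'
#' Turns a `growth_fit` plus the underlying blank-corrected trace into the
#' summary statistics: doubling time \eqn{\ln 2/\mu_{max}}, lag time,
#' exponential-phase boundaries, number of doublings over the whole
#' experiment (\eqn{\log_2} of the ratio of the highest to the lowest
#' positive measured population size), doublings during exponential phase
#' (\eqn{\mu_{max}\,\Delta t_{exp}/\ln 2}) and yield (maximum measured
#' population size). For parametric fits the lag and phase bounds come from
#' the model landmarks; for window methods (Easy Linear, manual) the phase
#' bounds are the times of the window endpoints and the lag is undetermined.
#' An unconverged fit leaves every fit-derived field undetermined (`NA`)
#' while the data-derived fields (total doublings, yield) are still
#' computed.
#'
#' @param fit A `growth_fit` (possibly unconverged).
#' @param trace Numeric vector: the blank-corrected (optionally smoothed)
#'   measured series the fit belongs to, in population units.
#'
#' @return A one-row tibble with columns `method`, `converged`,
#'   `r_squared`, the eight growth statistics, `A_fit` and `yield_fitted`
#'   (the fitted plateau \eqn{N_0 e^A}, parametric fits only).
#' @export
derive_parameters <- function(fit, trace) {
  stopifnot(inherits(fit, "growth_fit"), is.numeric(trace))
  pos <- trace[!is.na(trace) & trace > 0]
  yield_max <- if (length(pos) > 0) max(pos) else NA_real_
  doublings_total <- if (length(pos) > 0) log2(max(pos) / min(pos)) else
    NA_real_

  out <- tibble::tibble(
    method = fit$method, converged = fit$converged,
    r_squared = fit$r_squared,
    doubling_time = NA_real_, mu_max = NA_real_, lag = NA_real_,
    t_exp_start = NA_real_, t_exp_end = NA_real_,
    doublings_total = doublings_total, doublings_exp = NA_real_,
    yield_max = yield_max, A_fit = NA_real_, yield_fitted = NA_real_
  )
  if (!isTRUE(fit$converged) || !is.finite(fit$mu_max)) {
    return(out)
  }

  out$mu_max <- fit$mu_max
  out$doubling_time <- log(2) / fit$mu_max
  if (fit$method %in% c("logistic", "gompertz") && !is.null(fit$params)) {
    out$lag <- lag_time(fit$params, fit$lag_definition)
    bounds <- exp_phase_bounds(fit$params, fit$lag_definition)
    out$t_exp_start <- bounds[["t_start"]]
    out$t_exp_end <- bounds[["t_end"]]
    out$A_fit <- fit$params$A
    out$yield_fitted <- fit$params$n0 * exp(fit$params$A)
  } else if (!is.null(fit$window)) {
    out$t_exp_start <- fit$trace$times[fit$window[1]]
    out$t_exp_end <- fit$trace$times[fit$window[2]]
  }
  if (is.finite(out$t_exp_start) && is.finite(out$t_exp_end)) {
    out$doublings_exp <- fit$mu_max * (out$t_exp_end - out$t_exp_start) /
      log(2)
  }
  out
}

#' Fit every sample of a dataset and extract growth parameters
#'
#' The whole-plate pipeline: each sample is blank-corrected against the
#' dataset's blanks (pointwise mean of the blank traces), optionally
#' smoothed with a centered rolling average, log-transformed, fitted with
#' the chosen method, and summarised with [derive_parameters()]. Samples
#' that cannot be processed (e.g. blank wells with no signal above blank,
#' flat traces) get an undetermined row rather than aborting the batch.
#'
#' @param dataset A [growth_dataset].
#' @param model Fitting method: `"logistic"`, `"gompertz"` or
#'   `"easy_linear"`.
#' @param window Easy Linear subsegment size in data points (default 10).
#' @param smooth Rolling-average window in data points, or `NULL` for no
#'   smoothing.
#' @param blanks Character vector of blank sample names overriding the
#'   dataset default (`character(0)` disables blanking), or `NULL` to use
#'   the dataset's blanks.
#' @param lag_definition `"standard"` or `"tight"` phase landmarks for
#'   parametric fits.
#'
#' @return A tibble with one row per sample: `sample`, `position`, `group`,
#'   `excluded`, the [derive_parameters()] columns, and a `fit` list-column
#'   holding each `growth_fit` (or `NULL` where fitting was impossible).
#' @export
#' @examples
#' \donttest{
#' spec <- synthetic_spec("logistic", n_curves = 3, noise_sd = 0, seed = 1)
#' ds <- as_growth_dataset(spec)
#' fit_plate(ds, model = "logistic", blanks = character(0))
#' }
fit_plate <- function(dataset,
                      model = c("logistic", "gompertz", "easy_linear"),
                      window = 10L, smooth = NULL, blanks = NULL,
                      lag_definition = c("standard", "tight")) {
  model <- match.arg(model)
  lag_definition <- match.arg(lag_definition)
  stopifnot(inherits(dataset, "growth_dataset"))
  if (!is.null(blanks)) dataset <- set_blanks(dataset, blanks)
  blank_traces <- dataset$samples$values[dataset$blank_ids]

  fit_one <- function(values) {
    corrected <- blank_correct(values, blank_traces)
    if (!is.null(smooth) && smooth > 1) {
      corrected <- rolling_smooth(corrected, smooth)
    }
    res <- tryCatch({
      lt <- log_transform(corrected, dataset$times)
      fit <- switch(model,
        logistic = ,
        gompertz = fit_parametric(lt, model, lag_definition),
        easy_linear = fit_easy_linear(lt, window)
      )
      list(fit = fit, row = derive_parameters(fit, corrected))
    }, error = function(e) {
      row <- tibble::tibble(
        method = model, converged = FALSE, r_squared = NA_real_,
        doubling_time = NA_real_, mu_max = NA_real_, lag = NA_real_,
        t_exp_start = NA_real_, t_exp_end = NA_real_,
        doublings_total = NA_real_, doublings_exp = NA_real_,
        yield_max = NA_real_, A_fit = NA_real_, yield_fitted = NA_real_
      )
      pos <- corrected[!is.na(corrected) & corrected > 0]
      if (length(pos) > 0) {
        row$yield_max <- max(pos)
        row$doublings_total <- log2(max(pos) / min(pos))
      }
      list(fit = NULL, row = row)
    })
    res
  }

  results <- purrr::map(dataset$samples$values, fit_one)
  dplyr::bind_cols(
    tibble::tibble(
      sample = dataset$samples$name,
      position = dataset$samples$well,
      group = dataset$samples$name,
      excluded = dataset$samples$excluded
    ),
    dplyr::bind_rows(purrr::map(results, "row"))
  ) |>
    dplyr::mutate(fit = purrr::map(results, "fit"))
}

#' Group replicate samples and summarise their growth parameters
#'
#' Samples sharing a name are replicates of one biological sample. For each
#' group (in order of first appearance) this computes the mean and sample
#' standard deviation (n - 1 divisor) of every growth statistic over the
#' determined, non-excluded members, and counts the excluded members. A
#' group whose members are all excluded reports `NA` means and its
#' exclusion count.
#'
#' @param results Per-sample results tibble from [fit_plate()] (needs
#'   `sample` and `excluded` columns plus the growth statistics).
#'
#' @return A tibble with one row per (group, statistic): `group`,
#'   `n_members`, `n_excluded`, `statistic`, `mean`, `sd`, `n_used`.
#' @export
group_replicates <- function(results) {
  results <- tibble::as_tibble(results)
  stopifnot(all(c("sample", "excluded") %in% names(results)))
  stats_present <- intersect(growth_stat_columns, names(results))
  if (nrow(results) == 0L) {
    return(tibble::tibble(
      group = character(), n_members = integer(), n_excluded = integer(),
      statistic = character(), mean = double(), sd = double(),
      n_used = integer()
    ))
  }
  results |>
    dplyr::mutate(group = factor(.data$sample,
                                 levels = unique(.data$sample))) |>
    tidyr::pivot_longer(dplyr::all_of(stats_present),
                        names_to = "statistic", values_to = "value") |>
    dplyr::mutate(statistic = factor(.data$statistic,
                                     levels = stats_present)) |>
    dplyr::group_by(.data$group, .data$statistic) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_excluded = sum(.data$excluded),
      mean = {
        v <- .data$value[!.data$excluded & !is.na(.data$value)]
        if (length(v) > 0) mean(v) else NA_real_
      },
      sd = {
        v <- .data$value[!.data$excluded & !is.na(.data$value)]
        if (length(v) > 1) stats::sd(v) else NA_real_
      },
      n_used = sum(!.data$excluded & !is.na(.data$value)),
      .groups = "drop"
    ) |>
    dplyr::mutate(group = as.character(.data$group),
                  statistic = as.character(.data$statistic)) |>
    dplyr::relocate("group", "n_members", "n_excluded", "statistic",
                    "mean", "sd", "n_used")
}
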