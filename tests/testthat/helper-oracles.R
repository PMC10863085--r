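# Shared fixtures and independent oracles used across the suite.

# Central finite-difference slope of f at t.
num_slope <- function(f, t, h = 1e-5) {
  (f(t + h) - f(t - h)) / (2 * h)
}

# Noise-free sigmoid trace in population units on a time grid.
make_sigmoid_series <- function(model, A, mu_max, lam, n0, times) {
  p <- model_params(model, A = A, mu_max = mu_max, lam = lam, n0 = n0)
  n0 * exp(model_y(p, times))
}

# Random valid sigmoid parameter draws (the validation-study ranges, away
# from degenerate floors).
random_sigmoid_params <- function(n, model, seed) {
  set.seed(seed)
  tibble::tibble(
    model = model,
    A = runif(n, 0.5, 4),
    mu_max = runif(n, 0.05, 2),
    lam = runif(n, 0, 100)
  )
}

# Exhaustive enumeration oracle for the Easy Linear search: every
# contiguous window of exactly `window` valid points, slope by lm().
brute_easy_linear <- function(trace, window) {
  ok <- trace$valid & is.finite(trace$y)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  best <- NULL
  for (k in which(r$values)) {
    run <- seq.int(starts[k], ends[k])
    if (length(run) < window) next
    for (s in seq_len(length(run) - window + 1L)) {
      idx <- run[s:(s + window - 1L)]
      co <- stats::coef(stats::lm(trace$y[idx] ~ trace$times[idx]))
      slope <- unname(co[2])
      if (is.null(best) ||
          slope > best$slope + 1e-9 * (1 + abs(best$slope))) {
        best <- list(slope = slope, window = c(idx[1], idx[window]))
      }
    }
  }
  best
}

# The piecewise log-linear trace used in the fitting examples: flat at 0
# until t = 5, slope 1 on [5, 10], flat after, sampled every 0.5 h.
piecewise_trace <- function() {
  times <- seq(0, 15, by = 0.5)
  y <- pmin(pmax(times - 5, 0), 5)
  structure(
    list(times = times, y = y, n0 = 1,
         valid = rep(TRUE, length(times))),
    class = "log_trace"
  )
}

# In-memory CSV text in the plate layout.
plate_csv <- function(times, values, names) {
  rows <- c(
    paste(c("time", times), collapse = ","),
    vapply(seq_along(values), function(i) {
      paste(c(names[i], values[[i]]), collapse = ",")
    }, character(1))
  )
  paste(rows, collapse = "\n")
}
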