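#' Construct a growth dataset
#'
#' A `growth_dataset` holds one shared time vector plus one raw measurement
#' series per well/sample, together with the blank assignment and per-sample
#' exclusion flags. Sample order is preserved from the input file; duplicate
#' names are allowed and treated as replicates.
#'
#' @param times Numeric vector of timestamps in hours, strictly increasing.
#' @param values List of numeric vectors, one per sample, each the same
#'   length as `times`, nonnegative measurements in population-size units.
#' @param names Character vector of sample names, one per series.
#' @param blank_ids Integer ordinals of the samples used as blanks. Defaults
#'   to the first three samples (or fewer if the file has fewer).
#' @param unit Population-size unit label; default `"OD600"`.
#' @param excluded Logical vector of exclusion flags, one per sample.
#'
#' @return An object of class `growth_dataset`.
#' @export
growth_dataset <- function(times, values, names,
                           blank_ids = seq_len(min(3L, length(values))),
                           unit = "OD600",
                           excluded = rep(FALSE, length(values))) {
  times <- as.numeric(times)
  if (anyNA(times) || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing with no missing values.",
         call. = FALSE)
  }
  if (length(values) != length(names) || length(values) != length(excluded)) {
    stop("`values`, `names` and `excluded` must have one entry per sample.",
         call. = FALSE)
  }
  lens <- vapply(values, length, integer(1))
  if (any(lens != length(times))) {
    stop(sprintf(
      "All series must have length %d (sample %d has %d values).",
      length(times), which(lens != length(times))[1],
      lens[lens != length(times)][1]), call. = FALSE)
  }
  blank_ids <- as.integer(blank_ids)
  if (any(blank_ids < 1L | blank_ids > length(values))) {
    stop("`blank_ids` out of range.", call. = FALSE)
  }
  samples <- tibble::tibble(
    id = seq_along(values),
    name = as.character(names),
    well = vapply(seq_along(values), well_label,
                  character(1), n_samples = length(values)),
    excluded = as.logical(excluded),
    values = values
  )
  structure(
    list(times = times, samples = samples, blank_ids = blank_ids,
         unit = unit),
    class = "growth_dataset"
  )
}

#' @export
print.growth_dataset <- function(x, ...) {
  cat(sprintf(
    "<growth_dataset> %d samples x %d timepoints (%s), t in [%s, %s] h\n",
    nrow(x$samples), length(x$times), x$unit,
    format(min(x$times)), format(max(x$times))))
  cat("  blanks:", paste(unique(x$samples$name[x$blank_ids]), collapse = ", "),
      sprintf("(samples %s)\n", paste(x$blank_ids, collapse = ", ")))
  if (any(x$samples$excluded)) {
    cat("  excluded:", sum(x$samples$excluded), "sample(s)\n")
  }
  invisible(x)
}

#' @export
as_tibble.growth_dataset <- function(x, ...) {
  tidyr::unnest(
    dplyr::mutate(x$samples, time = list(x$times)),
    c("time", "values")
  ) |>
    dplyr::select("id", "name", "well", "excluded", "time",
                  value = "values")
}

#' Names of the blank samples of a dataset
#' @param dataset A [growth_dataset].
#' @return Character vector of blank sample names.
#' @export
blank_names <- function(dataset) {
  unique(dataset$samples$name[dataset$blank_ids])
}

#' Set the blank samples of a dataset
#'
#' @param dataset A [growth_dataset].
#' @param blanks Character vector of sample names to use as blanks (every
#'   sample carrying one of these names becomes a blank), or `character(0)`
#'   for no blanking.
#' @return The modified [growth_dataset].
#' @export
set_blanks <- function(dataset, blanks) {
  stopifnot(inherits(dataset, "growth_dataset"))
  blanks <- as.character(blanks)
  missing <- setdiff(blanks, dataset$samples$name)
  if (length(missing) > 0L) {
    stop("Unknown blank sample name(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  dataset$blank_ids <- which(dataset$samples$name %in% blanks)
  dataset
}

#' Microtiter well label for a sample ordinal
#'
#' If the total number of samples matches a standard microtiter plate size
#' (6, 12, 24, 96 or 384 wells) the ordinal is mapped row-major onto the
#' plate geometry (96-well: 8 rows x 12 columns, etc.) and returned as a
#' row-letter/column label such as `"B2"`. Any other sample count returns
#' the ordinal as text.
#'
#' @param index 1-based sample ordinal.
#' @param n_samples Total number of samples in the file.
#'
#' @return A single character label.
#' @export
#' @examples
#' well_label(14, 96)  # "B2"
#' well_label(5, 100)  # "5"
well_label <- function(index, n_samples) {
  index <- as.integer(index)
  n_samples <- as.integer(n_samples)
  if (is.na(index) || index < 1L || index > n_samples) {
    stop(sprintf("`index` must be in [1, %d].", n_samples), call. = FALSE)
  }
  dims <- list(`6` = c(2L, 3L), `12` = c(3L, 4L), `24` = c(4L, 6L),
               `96` = c(8L, 12L), `384` = c(16L, 24L))
  d <- dims[[as.character(n_samples)]]
  if (is.null(d)) {
    return(as.character(index))
  }
  row <- (index - 1L) %/% d[2] + 1L
  col <- (index - 1L) %% d[2] + 1L
  paste0(LETTERS[row], col)
}

#' Read a wide-format growth table
#'
#' Parses the plate-reader layout: the first row holds a label (usually
#' `"time"`) followed by the shared time vector; every subsequent row holds
#' a sample name followed by one measurement per timepoint. The first three
#' samples in the file are taken as blanks by default (change with
#' [set_blanks()]).
#'
#' @param source File path (CSV, TSV or XLSX) or a literal text block of
#'   CSV/TSV content.
#' @param format One of `"csv"`, `"tsv"`, `"xlsx"`; inferred from the file
#'   extension when `NULL`.
#' @param unit Population-size unit label, default `"OD600"`.
#'
#' @return A [growth_dataset].
#' @export
read_growth_table <- function(source, format = NULL, unit = "OD600") {
  if (is.null(format)) {
    format <- if (is.character(source) && length(source) == 1L &&
                  !grepl("[\n,\t]", source)) {
      switch(tolower(tools::file_ext(source)),
             csv = "csv", tsv = "tsv", txt = "tsv",
             xlsx = "xlsx", xls = "xlsx",
             stop("Cannot infer format from extension; pass `format`.",
                  call. = FALSE))
    } else "csv"
  }
  format <- match.arg(format, c("csv", "tsv", "xlsx"))

  raw <- switch(format,
    csv = ,
    tsv = {
      src <- if (file.exists(source)) source else I(source)
      # ragged rows surface as NA cells and are reported below
      suppressWarnings(
        readr::read_delim(src, delim = if (format == "csv") "," else "\t",
                          col_names = FALSE,
                          col_types = readr::cols(.default = "c"),
                          trim_ws = TRUE, progress = FALSE,
                          show_col_types = FALSE)
      )
    },
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("Package `readxl` is required to read XLSX files.",
             call. = FALSE)
      }
      rx <- readxl::read_excel(source, col_names = FALSE,
                               col_types = "text", sheet = 1)
      tibble::as_tibble(rx, .name_repair = "minimal")
    }
  )
  if (nrow(raw) < 2L || ncol(raw) < 2L) {
    stop("Growth table needs a time row plus at least one sample row.",
         call. = FALSE)
  }

  cells <- as.matrix(raw)
  parse_row <- function(r, what) {
    x <- cells[r, -1]
    if (anyNA(x) || any(!nzchar(trimws(x)))) {
      bad <- which(is.na(x) | !nzchar(trimws(x)))[1] + 1L
      stop(sprintf(
        "Row %d (%s) is shorter than the time row: missing value in column %d.",
        r, what, bad), call. = FALSE)
    }
    v <- suppressWarnings(as.numeric(x))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf(
        "Non-numeric %s cell '%s' at row %d, column %d.",
        what, x[bad], r, bad + 1L), call. = FALSE)
    }
    v
  }

  times <- parse_row(1L, "time")
  if (any(diff(times) <= 0)) {
    stop("Timestamps must be strictly increasing.", call. = FALSE)
  }
  nm <- as.character(cells[-1, 1])
  vals <- lapply(seq(2L, nrow(cells)), parse_row, what = "measurement")
  growth_dataset(times, vals, nm, unit = unit)
}

summary_columns <- c(
  "sample", "position", "group", "excluded", "method", "converged",
  "doubling_time", "mu_max", "lag", "t_exp_start", "t_exp_end",
  "doublings_total", "doublings_exp", "yield_max"
)

#' Write the per-sample growth parameter summary
#'
#' Writes one CSV row per sample with the extracted growth parameters
#' (doubling time, maximum growth rate, lag time, exponential-phase
#' boundaries, doubling counts, yield). Undetermined values are written as
#' the literal `"nan"`. Numbers round-trip at full double precision.
#'
#' @param results A tibble of per-sample growth parameters as produced by
#'   [fit_plate()] (or assembled from [derive_parameters()] rows).
#' @param destination Output file path.
#' @return `destination`, invisibly.
#' @export
write_summary <- function(results, destination) {
  out <- tibble::as_tibble(results)
  for (col in summary_columns) {
    if (!col %in% names(out)) {
      out[[col]] <- if (col %in% c("sample", "position", "group", "method")) {
        NA_character_
      } else if (col %in% c("excluded", "converged")) NA else NA_real_
    }
  }
  out <- out[, summary_columns]
  readr::write_csv(out, destination, na = "nan", progress = FALSE)
  invisible(destination)
}

#' Read back a growth parameter summary written by [write_summary()]
#'
#' @param source Summary CSV path.
#' @return A tibble with the summary columns; `"nan"` cells become `NA`.
#' @export
read_summary <- function(source) {
  readr::read_csv(
    source, na = "nan", progress = FALSE, show_col_types = FALSE,
    col_types = readr::cols(
      sample = "c", position = "c", group = "c", method = "c",
      excluded = "l", converged = "l", .default = "d"
    )
  )
}
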