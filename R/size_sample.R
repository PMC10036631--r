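#' Construct a sample of non-negative sizes
#'
#' A `size_sample` is the raw input of every analysis in this package: a
#' vector of non-negative sizes (incomes, intensities, body masses, counts,
#' ...) in their original units, together with a free-text label. Zeros are
#' legal sizes -- they produce the horizontal segment of the empirical Lorenz
#' curve -- but the total must be positive.
#'
#' @param values numeric vector of sizes, all finite and `>= 0`, with at
#'   least one positive value.
#' @param label free-text provenance label.
#' @return An object of class `size_sample`: a list with elements `values`,
#'   `label` and `n`.
#' @examples
#' size_sample(c(1, 1, 99), label = "toy")
#' @export
size_sample <- function(values, label = "sample") {
  if (!is.numeric(values) || length(values) == 0L)
    stop("'values' must be a non-empty numeric vector", call. = FALSE)
  values <- as.numeric(values)
  if (any(!is.finite(values)))
    stop("all sizes must be finite", call. = FALSE)
  if (any(values < 0))
    stop(sprintf("sizes must be non-negative; first offending index: %d",
                 which(values < 0)[1L]), call. = FALSE)
  if (sum(values) <= 0)
    stop("at least one size must be positive (total size must be > 0)",
         call. = FALSE)
  structure(list(values = values, label = as.character(label)[1L],
                 n = length(values)),
            class = "size_sample")
}

#' @export
print.size_sample <- function(x, ...) {
  cat(sprintf("size_sample '%s': n = %d, total = %g, zeros = %d\n",
              x$label, x$n, sum(x$values), sum(x$values == 0)))
  invisible(x)
}

#' Read a column of sizes from a text file
#'
#' Accepts one size per record in CSV, TSV or whitespace-separated layout
#' (the latter matches the public power-law dataset files, which may carry
#' several values per line). A non-numeric first line is treated as a header
#' and skipped. Negative or non-numeric values are rejected with the
#' offending line number.
#'
#' @param path path to an existing text file.
#' @param dialect one of `"auto"`, `"csv"`, `"tsv"`, `"whitespace"`. With
#'   `"auto"` the dialect is inferred from the file extension (`.csv`,
#'   `.tsv`/`.tab`, anything else is whitespace-separated).
#' @param label provenance label; defaults to the file name.
#' @return A [size_sample()] holding the values in file order.
#' @export
read_sizes <- function(path, dialect = c("auto", "csv", "tsv", "whitespace"),
                       label = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop(sprintf("input file not found: '%s'", path), call. = FALSE)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext == "csv") "csv"
      else if (ext %in% c("tsv", "tab")) "tsv"
      else "whitespace"
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    stop(sprintf("empty input file: '%s'", path), call. = FALSE)

  split_one <- function(line) {
    tok <- switch(dialect,
                  csv = strsplit(line, ",", fixed = TRUE)[[1L]],
                  tsv = strsplit(line, "\t", fixed = TRUE)[[1L]],
                  whitespace = strsplit(trimws(line), "[[:space:]]+")[[1L]])
    trimws(tok[nzchar(trimws(tok))])
  }
  tokens <- lapply(lines, split_one)

  # header detection: skip the first line iff any of its tokens is non-numeric
  first <- suppressWarnings(as.numeric(tokens[[1L]]))
  start <- if (anyNA(first)) 2L else 1L
  if (start > length(tokens))
    stop(sprintf("no numeric records in '%s'", path), call. = FALSE)

  values <- numeric(0)
  for (i in seq(start, length(tokens))) {
    v <- suppressWarnings(as.numeric(tokens[[i]]))
    if (anyNA(v))
      stop(sprintf("non-numeric token on line %d of '%s': '%s'",
                   i, path, tokens[[i]][which(is.na(v))[1L]]), call. = FALSE)
    if (any(v < 0))
      stop(sprintf("negative size on line %d of '%s': %g",
                   i, path, v[v < 0][1L]), call. = FALSE)
    values <- c(values, v)
  }
  size_sample(values, label = label)
}

#' Empirical Lorenz points of a size sample
#'
#' Sorts the sizes ascending (stable sort) and forms the cumulative
#' normalized rank `x_i = i/n` against the cumulative normalized size
#' `y_i = (sum of the i smallest sizes) / total`. Observations of size zero
#' produce a horizontal run at `y = 0`; the implicit origin (0, 0) is not
#' stored but is flagged by `includes_origin`.
#'
#' @param sample a [size_sample()] or numeric vector of non-negative sizes.
#' @return An object of class `lorenz_points`: list with ascending `x` in
#'   (0, 1], non-decreasing `y` in [0, 1] ending at (1, 1), `n`, `total`,
#'   `includes_origin = TRUE` and the sample label.
#' @examples
#' lp <- empirical_lorenz(make_hypothetical())
#' lp$y[lp$x == 0.99]  # 0.5: the 99 small units hold half of the total
#' @export
empirical_lorenz <- function(sample) {
  sample <- as_size_sample(sample)
  s <- sort(sample$values, method = "radix")  # stable ascending
  total <- sum(s)
  n <- length(s)
  pts <- structure(list(x = seq_len(n) / n,
                        y = cumsum(s) / total,
                        n = n, total = total,
                        includes_origin = TRUE,
                        label = sample$label),
                   class = "lorenz_points")
  pts$y[n] <- 1  # guard against cumulative rounding at the top point
  pts
}

as_size_sample <- function(x) {
  if (inherits(x, "size_sample")) x else size_sample(x)
}

#' @export
print.lorenz_points <- function(x, ...) {
  cat(sprintf("lorenz_points '%s': n = %d, total = %g\n",
              x$label, x$n, x$total))
  invisible(x)
}

#' @export
as.data.frame.lorenz_points <- function(x, ...) {
  data.frame(x = x$x, y = x$y)
}

as_lorenz_points <- function(x) {
  if (inherits(x, "lorenz_points")) return(x)
  if (inherits(x, "size_sample") || is.numeric(x))
    return(empirical_lorenz(x))
  stop("cannot interpret input as Lorenz points", call. = FALSE)
}

#' Descriptive statistics of a size sample
#'
#' Minimum, maximum, mean, sample standard deviation (n-1 denominator) and
#' the number of observations, matching the layout of the descriptive tables
#' usually reported alongside Lorenz analyses.
#'
#' @param sample a [size_sample()] or numeric vector.
#' @return A one-row data.frame with columns `minimum`, `maximum`, `mean`,
#'   `standard_deviation`, `n`.
#' @export
descriptive_stats <- function(sample) {
  sample <- as_size_sample(sample)
  if (sample$n < 2L)
    stop("need at least two observations for the sample standard deviation",
         call. = FALSE)
  v <- sample$values
  data.frame(minimum = min(v), maximum = max(v), mean = mean(v),
             standard_deviation = stats::sd(v), n = sample$n)
}

#' Discrete ("actual") Gini index of empirical Lorenz points
#'
#' The population variant is one minus twice the trapezoid area under the
#' empirical Lorenz polygon (with the origin prepended); the sample variant
#' multiplies by `n/(n-1)`, the small-sample correction that reproduces the
#' conventional "actual" Gini reported for per-observation data. The default
#' is the sample variant.
#'
#' @param points [empirical_lorenz()] output, a [size_sample()] or a numeric
#'   vector of sizes.
#' @param correction `"sample"` (default) or `"population"`.
#' @return The Gini index, a scalar in [0, 1].
#' @examples
#' gini_discrete(make_hypothetical())                         # 0.49494...
#' gini_discrete(make_hypothetical(), correction = "population")  # 0.4900...
#' @export
gini_discrete <- function(points, correction = c("sample", "population")) {
  correction <- match.arg(correction)
  points <- as_lorenz_points(points)
  x <- c(0, points$x)
  y <- c(0, points$y)
  area <- sum(diff(x) * (y[-1] + y[-length(y)])) / 2
  g <- 1 - 2 * area
  if (correction == "sample") {
    n <- points$n
    if (n < 2L)
      stop("sample correction needs n >= 2", call. = FALSE)
    g <- g * n / (n - 1)
  }
  g
}
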