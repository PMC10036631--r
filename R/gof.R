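#' Goodness-of-fit battery for fitted Lorenz curves
#'
#' Compares empirical cumulative shares `y` with fitted shares `yhat` using
#' five statistics: the coefficient of determination R^2 (1 - SSE/SST about
#' the mean of `y`), mean squared error, mean absolute error, maximum
#' absolute error, and Theil's information inaccuracy measure
#' \deqn{IIM = \sum_i y_i \log_{10}(y_i / \hat y_i).}
#' Terms with `y_i = 0` contribute 0 (continuity limit); a term with
#' `y_i > 0` and `yhat_i = 0` makes the IIM infinite and is flagged rather
#' than raised as an error, since models with a horizontal segment
#' legitimately predict 0 where the data are 0. Individual IIM terms can be
#' negative; a smaller absolute value indicates a better fit.
#'
#' @param y empirical cumulative shares in [0, 1].
#' @param yhat fitted cumulative shares in [0, 1].
#' @return An object of class `gof_report`: list with `r2`, `mse`, `mae`,
#'   `mas`, `iim`, `n`, and `notes` (character vector flagging an undefined
#'   R^2 when `y` is constant, or an infinite IIM).
#' @examples
#' lorenz_gof(c(0.2, 1), c(0.1, 1))
#' @export
lorenz_gof <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("'y' and 'yhat' must have equal length", call. = FALSE)
  if (length(y) == 0L) stop("empty input", call. = FALSE)
  if (any(!is.finite(y)) || any(!is.finite(yhat)))
    stop("shares must be finite", call. = FALSE)
  if (any(y < 0 | y > 1) || any(yhat < -1e-12 | yhat > 1 + 1e-12))
    stop("shares must lie in [0, 1]", call. = FALSE)

  notes <- character(0)
  e <- y - yhat
  mse <- mean(e^2)
  mae <- mean(abs(e))
  mas <- max(abs(e))

  sst <- sum((y - mean(y))^2)
  if (sst == 0) {
    r2 <- NA_real_
    notes <- c(notes, "R^2 undefined: empirical shares are constant")
  } else {
    r2 <- 1 - sum(e^2) / sst
  }

  pos <- y > 0
  if (any(pos & yhat == 0)) {
    iim <- Inf
    notes <- c(notes, "IIM infinite: fitted share is 0 where data are > 0")
  } else {
    iim <- sum(y[pos] * log10(y[pos] / yhat[pos]))
  }

  structure(list(r2 = r2, mse = mse, mae = mae, mas = mas, iim = iim,
                 n = length(y), notes = notes),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, digits = 4, ...) {
  cat(sprintf("Goodness of fit (n = %d): R2 = %s, MSE = %s, MAE = %s, MAS = %s, IIM = %s\n",
              x$n, fmt(x$r2, digits), fmt(x$mse, digits), fmt(x$mae, digits),
              fmt(x$mas, digits), fmt(x$iim, digits)))
  for (note in x$notes) cat(" note:", note, "\n")
  invisible(x)
}

fmt <- function(v, digits) {
  if (is.na(v)) "NA" else if (!is.finite(v)) as.character(v)
  else formatC(v, format = "f", digits = digits)
}

#' @export
as.data.frame.gof_report <- function(x, ...) {
  data.frame(r2 = x$r2, mse = x$mse, mae = x$mae, mas = x$mas, iim = x$iim,
             n = x$n)
}
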