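#' The one-large/many-equal extreme-inequality sample
#'
#' Generates `n_small` observations of size `small` plus a single
#' observation of size `large`. The defaults reproduce the canonical
#' extreme-inequality benchmark: a society of 100 in which 99 members hold
#' one unit each and one member holds 99 units, whose Lorenz plot consists
#' of two positive-slope linear segments and whose sample Gini index is
#' 0.495.
#'
#' @param n_small number of small observations, >= 1.
#' @param small size of each small observation, > 0.
#' @param large size of the single large observation, > 0.
#' @return A [size_sample()].
#' @examples
#' descriptive_stats(make_hypothetical())  # mean 1.98, sd 9.80, n 100
#' @export
make_hypothetical <- function(n_small = 99L, small = 1, large = 99) {
  if (n_small < 1L) stop("need n_small >= 1", call. = FALSE)
  if (small <= 0 || large <= 0)
    stop("sizes must be positive", call. = FALSE)
  smp <- size_sample(c(rep(small, n_small), large), label = "hypothetical")
  attr(smp, "scenario") <- list(scenario = "hypothetical",
                                n_small = n_small, small = small,
                                large = large)
  smp
}

#' Zero-inflated size sample
#'
#' `floor(n * zero_fraction)` exact zeros plus positives drawn from a
#' Pareto or lognormal law. Zeros are a structural feature of many size
#' datasets (earthquake magnitudes below the detection floor, metabolites
#' with no connections, battles with no deaths); they produce the
#' horizontal segment of the Lorenz curve that the universal model captures
#' through its `delta` parameter. Deterministic given `seed`.
#'
#' @param n total number of observations, >= 2.
#' @param zero_fraction fraction of zeros, in [0, 1).
#' @param positive_law `"pareto"` or `"lognormal"`.
#' @param law_params for `"pareto"`: `xmin > 0` (scale) and `shape > 0`;
#'   for `"lognormal"`: `meanlog` and `sdlog >= 0`.
#' @param seed RNG seed, recorded in the scenario attribute.
#' @return A [size_sample()] with the zeros first and the positives in draw
#'   order.
#' @export
make_zero_inflated <- function(n, zero_fraction,
                               positive_law = c("pareto", "lognormal"),
                               law_params = list(xmin = 1, shape = 1.5),
                               seed = 20230323L) {
  positive_law <- match.arg(positive_law)
  if (n < 2L) stop("need n >= 2", call. = FALSE)
  if (zero_fraction < 0 || zero_fraction >= 1)
    stop("need 0 <= zero_fraction < 1", call. = FALSE)
  n_zero <- floor(n * zero_fraction)
  n_pos <- n - n_zero
  pos <- with_local_seed(seed, {
    if (positive_law == "pareto") {
      xmin <- law_params$xmin %||% 1
      shape <- law_params$shape %||% 1.5
      if (xmin <= 0 || shape <= 0)
        stop("pareto law needs xmin > 0 and shape > 0", call. = FALSE)
      xmin * stats::runif(n_pos)^(-1 / shape)  # inverse-CDF draw
    } else {
      meanlog <- law_params$meanlog %||% 0
      sdlog <- law_params$sdlog %||% 1
      if (sdlog < 0) stop("lognormal law needs sdlog >= 0", call. = FALSE)
      stats::rlnorm(n_pos, meanlog, sdlog)
    }
  })
  smp <- size_sample(c(rep(0, n_zero), pos),
                     label = sprintf("zero_inflated(%s)", positive_law))
  attr(smp, "scenario") <- list(scenario = "zero_inflated", n = n,
                                zero_fraction = zero_fraction,
                                positive_law = positive_law,
                                law_params = law_params, seed = seed)
  smp
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Sample whose empirical Lorenz curve follows the universal model exactly
#'
#' Sizes are the first differences of the model curve on the uniform rank
#' grid: `s_i = y(i/n) - y((i-1)/n)`. Convexity of the curve makes the
#' sizes non-decreasing, so the empirical Lorenz points of the output lie
#' exactly on the model curve at `x_i = i/n`. The jump at `x = 1` (present
#' whenever `rho < 1` and `P > 1`) becomes the single largest observation
#' -- the one-large/many-equal regime -- which makes these samples exactly
#' solvable fitting fixtures.
#'
#' @param params a [proposed_params()] object.
#' @param n number of observations, >= 10.
#' @return A [size_sample()] with total size 1.
#' @examples
#' smp <- make_model_conformant(proposed_params(0.2, 0.9, 0.5, 3), n = 50)
#' head(smp$values)  # leading zeros from the horizontal segment
#' @export
make_model_conformant <- function(params, n = 100L) {
  stopifnot(inherits(params, "proposed_params"))
  if (n < 10L) stop("need n >= 10", call. = FALSE)
  y <- lorenz_proposed(seq_len(n) / n, params)
  sizes <- diff(c(0, y))
  sizes[sizes < 0] <- 0  # guard against roundoff at the delta kink
  smp <- size_sample(sizes, label = "model_conformant")
  attr(smp, "scenario") <- c(list(scenario = "model_conformant", n = n),
                             unclass(params))
  smp
}
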