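#' Parameters of the universal (proposed) Lorenz model
#'
#' The model combines a linear segment with a convex mix of a power
#' ("exponential") component and a Pareto-implied component:
#' \deqn{y(x) = (1-\rho)\,\frac{2}{P+1}\,u + \rho\left[(1-\omega)\,u^P +
#'   \omega\,(1 - (1-u)^{1/P})\right], \quad u = \frac{x-\delta}{1-\delta},}
#' with `y = 0` where `x < delta` and `y(1) = 1` enforced by the piecewise
#' definition of the linear component. `delta` is the length of the
#' horizontal segment produced by zero sizes; `rho` weights the convex mix
#' against the linear segment; `omega` moves curvature between the power and
#' Pareto components without changing the Gini index; `P >= 1` is the
#' inequality parameter.
#'
#' @param delta horizontal-segment length, `0 <= delta < 1`.
#' @param rho weight on the convex component, in [0, 1].
#' @param omega weight on the Pareto-implied component within the convex
#'   mix, in [0, 1].
#' @param P inequality parameter, `P >= 1`.
#' @return An object of class `proposed_params`.
#' @export
proposed_params <- function(delta = 0, rho = 1, omega = 0.5, P = 1) {
  chk_num(delta, "delta"); chk_num(rho, "rho")
  chk_num(omega, "omega"); chk_num(P, "P")
  if (delta < 0 || delta >= 1) stop("need 0 <= delta < 1", call. = FALSE)
  if (rho < 0 || rho > 1) stop("need 0 <= rho <= 1", call. = FALSE)
  if (omega < 0 || omega > 1) stop("need 0 <= omega <= 1", call. = FALSE)
  if (P < 1) stop("need P >= 1", call. = FALSE)
  structure(list(delta = delta, rho = rho, omega = omega, P = P),
            class = c("proposed_params", "lorenz_params"))
}

#' Parameters of the SCS comparator model
#'
#' Three-parameter Lorenz form \eqn{y(x) = x^\gamma (1-(1-x)^\alpha)^\beta}.
#' Its Gini index has no closed form and is obtained by quadrature.
#'
#' @param gamma exponent on `x`, `gamma >= 0`.
#' @param alpha exponent inside the bracket, `0 < alpha <= 1`.
#' @param beta exponent on the bracket, `beta >= 1`.
#' @return An object of class `scs_params`.
#' @export
scs_params <- function(gamma = 0, alpha = 1, beta = 1) {
  chk_num(gamma, "gamma"); chk_num(alpha, "alpha"); chk_num(beta, "beta")
  if (gamma < 0) stop("need gamma >= 0", call. = FALSE)
  if (alpha <= 0 || alpha > 1) stop("need 0 < alpha <= 1", call. = FALSE)
  if (beta < 1) stop("need beta >= 1", call. = FALSE)
  structure(list(gamma = gamma, alpha = alpha, beta = beta),
            class = c("scs_params", "lorenz_params"))
}

#' Parameters of the S comparator model
#'
#' Four-parameter convex combination of the egalitarian line, a power Lorenz
#' curve and the classical Pareto Lorenz curve:
#' \eqn{y(x) = (1-\lambda+\eta)x + \lambda x^{a_1+1} - \eta[1-(1-x)^{a_2+1}]}.
#'
#' @param lambda weight on the power term, `lambda >= 0`.
#' @param eta weight on the Pareto term, `eta >= 0` (all published fits use
#'   non-negative values).
#' @param a1 power-term exponent offset, `a1 >= 0`.
#' @param a2 Pareto-term exponent offset, `a2 + 1 > 0` and `eta * a2 >= 0`.
#'   Jointly, `eta * a2 + lambda <= 1`.
#' @return An object of class `s_params`.
#' @export
s_params <- function(lambda = 0, eta = 0, a1 = 0, a2 = 0) {
  chk_num(lambda, "lambda"); chk_num(eta, "eta")
  chk_num(a1, "a1"); chk_num(a2, "a2")
  if (lambda < 0) stop("need lambda >= 0", call. = FALSE)
  if (eta < 0) stop("need eta >= 0", call. = FALSE)
  if (a1 < 0) stop("need a1 >= 0", call. = FALSE)
  if (a2 + 1 <= 0) stop("need a2 + 1 > 0", call. = FALSE)
  if (eta * a2 < 0) stop("need eta * a2 >= 0", call. = FALSE)
  if (eta * a2 + lambda > 1 + 1e-12)
    stop("need eta * a2 + lambda <= 1", call. = FALSE)
  structure(list(lambda = lambda, eta = eta, a1 = a1, a2 = a2),
            class = c("s_params", "lorenz_params"))
}

chk_num <- function(v, name) {
  if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
}

#' @export
print.lorenz_params <- function(x, ...) {
  cat(sprintf("%s: %s\n", class(x)[1L],
              paste(sprintf("%s = %g", names(x), unlist(x)),
                    collapse = ", ")))
  invisible(x)
}

chk_x <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0) || any(x > 1))
    stop("'x' must lie in [0, 1]", call. = FALSE)
  as.numeric(x)
}

#' Evaluate the universal Lorenz model
#'
#' Vectorized in `x`. Below `delta` the curve is 0; at `x = 1` it equals 1
#' by the piecewise definition of the linear component, which creates a jump
#' discontinuity at the top rank whenever `rho < 1` and `P > 1` -- exactly
#' the shape of a distribution with one observation much larger than the
#' rest (a mass atom at the top).
#'
#' @param x cumulative normalized rank(s) in [0, 1].
#' @param params a [proposed_params()] object.
#' @return `y(x)`, same length as `x`, in [0, 1].
#' @export
lorenz_proposed <- function(x, params) {
  stopifnot(inherits(params, "proposed_params"))
  x <- chk_x(x)
  d <- params$delta; r <- params$rho; w <- params$omega; P <- params$P
  u <- (x - d) / (1 - d)
  lin <- (2 / (P + 1)) * u
  expo <- u^P
  pareto <- 1 - (1 - u)^(1 / P)
  y <- (1 - r) * lin + r * ((1 - w) * expo + w * pareto)
  y[x < d] <- 0
  y[x == 1] <- 1  # piecewise rule of the linear component
  y
}

#' Area under the universal Lorenz model
#'
#' Closed form: each of the three components integrates to
#' `(1 - delta) / (P + 1)` on [0, 1], so the weighted combination does too
#' (the weights are convex). Independent of `rho` and `omega`.
#'
#' @inheritParams lorenz_proposed
#' @return The area, in (0, 0.5].
#' @export
area_proposed <- function(params) {
  stopifnot(inherits(params, "proposed_params"))
  (1 - params$delta) / (params$P + 1)
}

#' Closed-form Gini index of the universal Lorenz model
#'
#' `1 - 2 * (1 - delta) / (P + 1)`; 0 iff `delta = 0` and `P = 1` (the
#' egalitarian line), approaching 1 as `delta -> 1` or `P -> Inf`.
#'
#' @inheritParams lorenz_proposed
#' @return Gini index in [0, 1].
#' @examples
#' gini_proposed(proposed_params(delta = 0, rho = 0, omega = 0, P = 2.96))
#' @export
gini_proposed <- function(params) {
  1 - 2 * area_proposed(params)
}

#' Evaluate the SCS Lorenz model
#'
#' `y(x) = x^gamma * (1 - (1 - x)^alpha)^beta`, with `0^0 = 1` by continuity
#' so that `y(1) = 1` for every `gamma >= 0`.
#'
#' @param x cumulative normalized rank(s) in [0, 1].
#' @param params an [scs_params()] object.
#' @return `y(x)` in [0, 1].
#' @export
lorenz_scs <- function(x, params) {
  stopifnot(inherits(params, "scs_params"))
  x <- chk_x(x)
  x^params$gamma * (1 - (1 - x)^params$alpha)^params$beta
}

#' Gini index of the SCS model by adaptive quadrature
#'
#' The SCS form has no explicit Gini solution; the index is computed as
#' `1 - 2 * integral(y)` with adaptive quadrature.
#'
#' @param params an [scs_params()] object.
#' @param tol absolute quadrature tolerance.
#' @return Gini index in [0, 1].
#' @examples
#' gini_scs(scs_params(gamma = 0, alpha = 0.31, beta = 1))  # ~0.527
#' @export
gini_scs <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "scs_params"))
  q <- stats::integrate(function(x) lorenz_scs(x, params), 0, 1,
                        abs.tol = tol, rel.tol = tol,
                        subdivisions = 1000L, stop.on.error = FALSE)
  if (!q$message %in% c("OK", "roundoff error was detected"))
    stop(sprintf("quadrature failed for the SCS Gini index: %s", q$message),
         call. = FALSE)
  1 - 2 * q$value
}

#' Evaluate the S Lorenz model
#'
#' `y(x) = (1 - lambda + eta) x + lambda x^(a1+1) - eta (1 - (1-x)^(a2+1))`.
#' The boundary conditions `y(0) = 0` and `y(1) = 1` hold algebraically.
#'
#' @param x cumulative normalized rank(s) in [0, 1].
#' @param params an [s_params()] object.
#' @return `y(x)`.
#' @export
lorenz_s <- function(x, params) {
  stopifnot(inherits(params, "s_params"))
  x <- chk_x(x)
  l <- params$lambda; e <- params$eta
  (1 - l + e) * x + l * x^(params$a1 + 1) - e * (1 - (1 - x)^(params$a2 + 1))
}

#' Closed-form Gini index of the S model
#'
#' `lambda * (1 - 2/(2 + a1)) + eta * (1 - 2/(2 + a2))`.
#'
#' @param params an [s_params()] object.
#' @return Gini index.
#' @export
gini_s <- function(params) {
  stopifnot(inherits(params, "s_params"))
  params$lambda * (1 - 2 / (2 + params$a1)) +
    params$eta * (1 - 2 / (2 + params$a2))
}

model_curve <- function(model, params) {
  switch(model,
         proposed = function(x) lorenz_proposed(x, params),
         scs = function(x) lorenz_scs(x, params),
         s = function(x) lorenz_s(x, params),
         stop(sprintf("unknown model '%s'", model), call. = FALSE))
}

#' Numerical area under any of the three models
#'
#' Adaptive quadrature of the model curve on [0, 1], splitting the interval
#' at `delta` for the universal model (the curve is identically zero below
#' `delta` and the Pareto component has an infinite derivative at the top
#' endpoint, which adaptive quadrature absorbs after the split).
#'
#' @param model `"proposed"`, `"scs"` or `"s"`.
#' @param params the matching parameter object.
#' @param tol absolute quadrature tolerance.
#' @return The area under the curve on [0, 1].
#' @export
area_quadrature <- function(model = c("proposed", "scs", "s"), params,
                            tol = 1e-9) {
  model <- match.arg(model)
  f <- model_curve(model, params)
  lo <- if (model == "proposed") params$delta else 0
  if (lo >= 1) return(0)
  q <- stats::integrate(f, lo, 1, abs.tol = tol, rel.tol = tol,
                        subdivisions = 1000L, stop.on.error = FALSE)
  if (!q$message %in% c("OK", "roundoff error was detected"))
    stop(sprintf("quadrature failed: %s", q$message), call. = FALSE)
  q$value
}

#' Check the theoretical Lorenz-curve conditions of a fitted form
#'
#' Verifies on a uniform grid that `y(0) = 0`, `y(1) = 1`, first differences
#' are non-negative (monotonicity) and second differences are non-negative
#' on the convex part (strictly inside `(delta, 1)` for the universal
#' model). The jump discontinuity of the universal model at `x = 1` when
#' `rho < 1` (a mass atom at the top rank) is reported, not treated as a
#' failure.
#'
#' @param model `"proposed"`, `"scs"` or `"s"`.
#' @param params the matching parameter object.
#' @param grid_size number of grid points, at least 10.
#' @return A list of class `lorenz_conditions` with logical fields
#'   `y0_ok`, `y1_ok`, `monotone`, `convex`, `jump_at_top`, `all_ok`,
#'   and the tolerances used.
#' @export
check_lorenz_conditions <- function(model = c("proposed", "scs", "s"),
                                    params, grid_size = 1000L) {
  model <- match.arg(model)
  if (grid_size < 10L) stop("need grid_size >= 10", call. = FALSE)
  f <- model_curve(model, params)
  tol1 <- 1e-12; tol2 <- 1e-10

  y0_ok <- abs(f(0)) <= tol1
  y1_ok <- abs(f(1) - 1) <= 1e-9

  grid <- seq(0, 1, length.out = grid_size)
  y <- f(grid)
  jump_at_top <- FALSE
  if (model == "proposed" && params$rho < 1) {
    # left limit at 1: evaluate just inside
    ylim <- f(1 - 1e-9)
    jump_at_top <- (1 - ylim) > 1e-6
  }
  dy <- diff(y)
  monotone <- all(dy >= -tol1)

  # convexity on the open convex part only: skip the kink at delta and the
  # top atom for the universal model
  lo <- if (model == "proposed") params$delta else 0
  inner <- seq(lo + (1 - lo) / grid_size, 1 - (1 - lo) / grid_size,
               length.out = grid_size)
  if (model == "proposed") inner <- inner[inner < 1 - 1e-9]
  d2 <- diff(f(inner), differences = 2L)
  convex <- all(d2 >= -tol2)

  structure(list(model = model, y0_ok = y0_ok, y1_ok = y1_ok,
                 monotone = monotone, convex = convex,
                 jump_at_top = jump_at_top,
                 all_ok = y0_ok && y1_ok && monotone && convex,
                 grid_size = grid_size,
                 tol_monotone = tol1, tol_convex = tol2),
            class = "lorenz_conditions")
}

#' @export
print.lorenz_conditions <- function(x, ...) {
  cat(sprintf(
    "Lorenz conditions (%s model): y(0)=0 %s; y(1)=1 %s; monotone %s; convex %s%s\n",
    x$model, ok(x$y0_ok), ok(x$y1_ok), ok(x$monotone), ok(x$convex),
    if (x$jump_at_top) "; jump at x = 1 (top mass atom)" else ""))
  invisible(x)
}

ok <- function(b) if (b) "OK" else "FAIL"

#' Serialize a parameter object to JSON
#'
#' Field names are explicit (`delta`, `rho`, `omega`, `P` / `gamma`,
#' `alpha`, `beta` / `lambda`, `eta`, `a1`, `a2`) plus a `model` tag, so the
#' file round-trips through [params_from_json()].
#'
#' @param params a parameter object.
#' @param path optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
params_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "lorenz_params"))
  model <- switch(class(params)[1L],
                  proposed_params = "proposed",
                  scs_params = "scs",
                  s_params = "s")
  txt <- jsonlite::toJSON(c(list(model = model), unclass(params)),
                          auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Deserialize a parameter object from JSON
#'
#' @param x a JSON string or a path to a JSON file written by
#'   [params_to_json()].
#' @return The parameter object, validated against its constraints.
#' @export
params_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  if (is.null(obj$model)) stop("JSON lacks a 'model' field", call. = FALSE)
  switch(obj$model,
         proposed = proposed_params(obj$delta, obj$rho, obj$omega, obj$P),
         scs = scs_params(obj$gamma, obj$alpha, obj$beta),
         s = s_params(obj$lambda, obj$eta, obj$a1, obj$a2),
         stop(sprintf("unknown model '%s'", obj$model), call. = FALSE))
}
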