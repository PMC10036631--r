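#' Configuration for constrained Lorenz-curve fitting
#'
#' Fitting minimizes the sum of squared errors between empirical and model
#' cumulative shares over the model's constraint box, using multistart
#' bounded L-BFGS-B. The multistart design is deterministic given the seed:
#' the box center, the box corners, and the leading rows of a fixed
#' 256-point Latin hypercube; wide parameter ranges (such as the
#' inequality exponent) are sampled on a log-like scale. The best start is
#' re-polished at tight tolerance.
#'
#' @param model `"proposed"`, `"scs"` or `"s"`.
#' @param n_starts number of optimizer starts (>= 1); default 32.
#' @param seed RNG seed fixing the Latin-hypercube design; default 20230323.
#' @param lower,upper optional numeric bounds overriding the defaults; must
#'   lie within the model's theoretical constraints (`delta < 1` and
#'   `alpha > 0` are enforced as closed bounds `delta <= 1 - 1e-6`,
#'   `alpha >= 1e-6`).
#' @param maxit maximum L-BFGS-B iterations per start.
#' @param canonicalize logical: resolve non-identifiable directions of the
#'   universal model after fitting (see [canonicalize_proposed()]).
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(model = c("proposed", "scs", "s"),
                       n_starts = 32L, seed = 20230323L,
                       lower = NULL, upper = NULL,
                       maxit = 500L, canonicalize = TRUE) {
  model <- match.arg(model)
  if (n_starts < 1L) stop("need n_starts >= 1", call. = FALSE)
  box <- default_bounds(model)
  if (!is.null(lower)) {
    if (length(lower) != length(box$lower) || any(lower < box$lower - 1e-12))
      stop("'lower' must respect the model constraints", call. = FALSE)
    box$lower <- as.numeric(lower)
  }
  if (!is.null(upper)) {
    if (length(upper) != length(box$upper))
      stop("'upper' has the wrong length", call. = FALSE)
    box$upper <- pmin(as.numeric(upper), default_bounds(model)$upper)
  }
  if (any(box$lower >= box$upper))
    stop("bounds define an empty box", call. = FALSE)
  structure(list(model = model, n_starts = as.integer(n_starts),
                 seed = as.integer(seed), lower = box$lower,
                 upper = box$upper, par_names = box$names,
                 maxit = as.integer(maxit),
                 canonicalize = isTRUE(canonicalize)),
            class = "fit_config")
}

default_bounds <- function(model) {
  switch(model,
    proposed = list(names = c("delta", "rho", "omega", "P"),
                    lower = c(0, 0, 0, 1),
                    upper = c(1 - 1e-6, 1, 1, 500)),
    scs = list(names = c("gamma", "alpha", "beta"),
               lower = c(0, 1e-6, 1),
               upper = c(50, 1, 500)),
    s = list(names = c("lambda", "eta", "a1", "a2"),
             lower = c(0, 0, 0, 0),
             upper = c(1, 100, 500, 500)))
}

make_params <- function(model, theta) {
  switch(model,
         proposed = proposed_params(theta[1L], theta[2L], theta[3L], theta[4L]),
         scs = scs_params(theta[1L], theta[2L], theta[3L]),
         s = s_params(theta[1L], theta[2L], theta[3L], theta[4L]))
}

# multistart design: center + corners + leading rows of a fixed 256-point
# Latin hypercube; columns with a wide range are mapped log-like so small
# parameter values are well represented
start_matrix <- function(config) {
  lo <- config$lower; hi <- config$upper; k <- length(lo)
  center <- (lo + hi) / 2
  corners <- as.matrix(expand.grid(rep(list(c(0, 1)), k)))
  corners <- sweep(sweep(corners, 2L, hi - lo, "*"), 2L, lo, "+")
  det_starts <- rbind(center, corners)

  if (config$n_starts <= nrow(det_starts))
    return(unname(det_starts[seq_len(config$n_starts), , drop = FALSE]))

  n_lhs <- min(config$n_starts - nrow(det_starts), 256L)
  u <- with_local_seed(config$seed,
                       lhs::randomLHS(256L, k))[seq_len(n_lhs), ,
                                                drop = FALSE]
  wide <- (hi - lo) > 10
  m <- u
  for (j in seq_len(k)) {
    m[, j] <- if (wide[j])
      lo[j] + expm1(u[, j] * log1p(hi[j] - lo[j]))
    else
      lo[j] + u[, j] * (hi[j] - lo[j])
  }
  unname(rbind(det_starts, m))
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

sse_objective <- function(model, x, y) {
  if (model == "s") {
    function(theta) {
      p <- theta
      viol <- max(0, p[2L] * p[4L] + p[1L] - 1)
      yhat <- (1 - p[1L] + p[2L]) * x + p[1L] * x^(p[3L] + 1) -
        p[2L] * (1 - (1 - x)^(p[4L] + 1))
      sum((y - yhat)^2) + 1e6 * viol^2
    }
  } else if (model == "scs") {
    function(theta) {
      yhat <- x^theta[1L] * (1 - (1 - x)^theta[2L])^theta[3L]
      sum((y - yhat)^2)
    }
  } else {
    function(theta) {
      d <- theta[1L]; r <- theta[2L]; w <- theta[3L]; P <- theta[4L]
      u <- pmax((x - d) / (1 - d), 0)
      yhat <- (1 - r) * (2 / (P + 1)) * u +
        r * ((1 - w) * u^P + w * (1 - (1 - u)^(1 / P)))
      yhat[x == 1] <- 1
      sum((y - yhat)^2)
    }
  }
}

#' Fit a Lorenz model to empirical Lorenz points
#'
#' Estimates the model parameters by constrained least squares on the
#' empirical points: minimize `sum((y_i - yhat(x_i))^2)` over the
#' parameter box, all `n` points included (the top point (1, 1) is matched
#' exactly by construction for the universal and S models). The run is
#' deterministic given `(points, config)`.
#'
#' @param points [empirical_lorenz()] output, a [size_sample()] or a numeric
#'   vector of sizes.
#' @param model `"proposed"` (the universal model), `"scs"` or `"s"`;
#'   ignored when `config` is supplied.
#' @param config a [fit_config()]; defaults to `fit_config(model)`.
#' @return An object of class `lorenz_fit`: list with `model`, `params`
#'   (the fitted parameter object), `sse`, `gof` (a [lorenz_gof()] report),
#'   `gini` (closed form for the universal and S models, quadrature for
#'   SCS), `conditions` (a [check_lorenz_conditions()] report),
#'   `convergence` (start diagnostics) and `notes` (canonicalization etc.).
#' @examples
#' fit <- fit_lorenz(make_hypothetical(), "proposed")
#' round(fit$gini, 3)  # 0.495
#' @export
fit_lorenz <- function(points, model = c("proposed", "scs", "s"),
                       config = NULL) {
  if (is.null(config)) config <- fit_config(match.arg(model))
  stopifnot(inherits(config, "fit_config"))
  model <- config$model
  points <- as_lorenz_points(points)
  k <- length(config$lower)
  if (points$n < k)
    stop(sprintf("need at least %d points to fit %d parameters",
                 k, k), call. = FALSE)

  obj <- sse_objective(model, points$x, points$y)
  starts <- start_matrix(config)
  ctrl <- list(maxit = config$maxit, factr = 1e4)

  runs <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    runs[[i]] <- tryCatch(
      stats::optim(starts[i, ], obj, method = "L-BFGS-B",
                   lower = config$lower, upper = config$upper,
                   control = ctrl),
      error = function(e) NULL)
  }
  runs <- Filter(Negate(is.null), runs)
  if (model == "s")  # drop starts that ended outside the joint constraint
    runs <- Filter(function(r)
      r$par[2L] * r$par[4L] + r$par[1L] - 1 <= 1e-8, runs)
  if (length(runs) == 0L)
    stop("optimizer failed on all starts", call. = FALSE)

  best <- pick_best(runs, model)
  # tight polish from the best start; never accepted if it does not improve
  pol <- tryCatch(
    stats::optim(best$par, obj, method = "L-BFGS-B",
                 lower = config$lower, upper = config$upper,
                 control = list(maxit = 2L * config$maxit, factr = 1,
                                pgtol = 0)),
    error = function(e) NULL)
  if (!is.null(pol) && pol$value <= best$value &&
      (model != "s" || pol$par[2L] * pol$par[4L] + pol$par[1L] - 1 <= 1e-8))
    best <- pol

  theta <- pmin(pmax(best$par, config$lower), config$upper)
  names(theta) <- config$par_names
  sse <- obj(theta)
  notes <- character(0)

  params <- make_params(model, unname(theta))
  if (model == "proposed" && config$canonicalize) {
    can <- canonicalize_proposed(params, sse_context = obj)
    params <- can$params
    notes <- c(notes, can$notes)
    sse <- can$sse
  }

  yhat <- model_curve(model, params)(points$x)
  gof <- lorenz_gof(points$y, yhat)
  gini <- switch(model,
                 proposed = gini_proposed(params),
                 scs = gini_scs(params),
                 s = gini_s(params))
  structure(list(model = model, params = params, sse = sse, gof = gof,
                 gini = gini,
                 conditions = check_lorenz_conditions(model, params),
                 convergence = list(n_starts = nrow(starts),
                                    n_converged = sum(vapply(runs, function(r)
                                      r$convergence == 0L, logical(1L))),
                                    best_value = best$value,
                                    best_convergence = best$convergence),
                 notes = notes, n = points$n, label = points$label,
                 config = config),
            class = "lorenz_fit")
}

pick_best <- function(runs, model) {
  vals <- vapply(runs, `[[`, numeric(1L), "value")
  cand <- which(vals <= min(vals) + 1e-12)
  if (length(cand) > 1L) {
    # equal-SSE tie-break: smallest rho, then omega, then delta (universal
    # model); lexicographic smallest parameters otherwise
    pars <- t(vapply(runs[cand], `[[`, numeric(length(runs[[1L]]$par)), "par"))
    key <- if (model == "proposed") pars[, c(2L, 3L, 1L, 4L), drop = FALSE]
           else pars
    ord <- do.call(order, as.data.frame(key))
    cand <- cand[ord[1L]]
  } else {
    cand <- cand[which.min(vals[cand])]
  }
  runs[[cand]]
}

#' Resolve non-identifiable directions of a fitted universal model
#'
#' Two directions of the universal model are flat in the least-squares
#' objective: when `rho` is (numerically) 0 the curve does not depend on
#' `omega`, and on the egalitarian line (`delta = 0`, `P = 1`) all three
#' components coincide so neither `rho` nor `omega` matters. Canonical
#' values (0) are substituted in those cases; the substitution is accepted
#' only if it leaves the SSE unchanged (within 1e-8) when an SSE context is
#' supplied.
#'
#' @param params a [proposed_params()] object, typically fitted.
#' @param sse_context optional function mapping a parameter vector
#'   `c(delta, rho, omega, P)` to an SSE, used to assert invariance.
#' @param eps numerical threshold for "at the boundary"; default 1e-6.
#' @return A list with the (possibly updated) `params`, the achieved `sse`
#'   (`NA` without a context), `changed` flag and `notes`.
#' @export
canonicalize_proposed <- function(params, sse_context = NULL, eps = 1e-6) {
  stopifnot(inherits(params, "proposed_params"))
  out <- params
  notes <- character(0)
  if (out$rho <= eps && (out$rho != 0 || out$omega != 0)) {
    out$rho <- 0; out$omega <- 0
    notes <- c(notes, "canonicalized: rho ~ 0, omega has no effect; both set to 0")
  }
  if (abs(out$P - 1) <= eps && out$delta <= eps &&
      (out$rho != 0 || out$omega != 0)) {
    out$rho <- 0; out$omega <- 0
    notes <- c(notes,
               "canonicalized: delta = 0, P = 1 is the egalitarian line; rho and omega set to 0")
  }
  changed <- length(notes) > 0L
  sse <- NA_real_
  if (!is.null(sse_context)) {
    sse_old <- sse_context(unlist(params[c("delta", "rho", "omega", "P")]))
    sse <- sse_context(unlist(out[c("delta", "rho", "omega", "P")]))
    if (changed && abs(sse - sse_old) > 1e-8) {
      # flat direction assumption violated; keep the fitted values
      out <- params
      sse <- sse_old
      notes <- "canonicalization skipped: SSE would change"
      changed <- FALSE
    }
  }
  list(params = out, sse = sse, changed = changed, notes = notes)
}

#' Profile the SSE along the curvature parameter omega
#'
#' With `delta` and `P` fixed (and `rho = 1`), the Gini index of the
#' universal model is constant in `omega`: the parameter only redistributes
#' curvature between the power and Pareto components. This helper evaluates
#' the SSE against a set of empirical points along an `omega` grid,
#' exhibiting which member of the iso-Gini family fits best.
#'
#' @param points empirical Lorenz points (or sizes).
#' @param delta,P fixed values of the universal model.
#' @param omega grid of omega values in [0, 1].
#' @return A data.frame with columns `omega`, `sse` and the (constant)
#'   `gini`.
#' @export
profile_omega <- function(points, delta, P,
                          omega = seq(0, 1, length.out = 101L)) {
  points <- as_lorenz_points(points)
  if (any(omega < 0 | omega > 1)) stop("omega grid must lie in [0, 1]",
                                       call. = FALSE)
  obj <- sse_objective("proposed", points$x, points$y)
  sse <- vapply(omega, function(w) obj(c(delta, 1, w, P)), numeric(1L))
  data.frame(omega = omega, sse = sse,
             gini = gini_proposed(proposed_params(delta, 1, 0.5, P)))
}

#' @export
print.lorenz_fit <- function(x, ...) {
  cat(sprintf("Lorenz fit (%s model) to '%s' (n = %d)\n",
              x$model, x$label, x$n))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$params), unlist(x$params)),
            collapse = ", "), "\n")
  cat(sprintf("  SSE = %.6g, Gini = %.3f\n", x$sse, x$gini))
  print(x$gof)
  for (note in x$notes) cat("  note:", note, "\n")
  invisible(x)
}

#' One-row summary table of a fit
#'
#' Parameters, the five goodness-of-fit statistics and the Gini index in a
#' single data.frame row, convenient for report tables.
#'
#' @param x a `lorenz_fit`.
#' @param ... unused.
#' @return A one-row data.frame.
#' @export
as.data.frame.lorenz_fit <- function(x, ...) {
  cbind(data.frame(label = x$label, model = x$model, n = x$n),
        as.data.frame(unclass(x$params)),
        data.frame(sse = x$sse), as.data.frame(x$gof)[, 1:5],
        data.frame(gini = x$gini))
}
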