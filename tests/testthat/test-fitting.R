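test_that("the extreme-inequality sample is fitted exactly by the universal model", {
  fit <- fit_lorenz(make_hypothetical(), "proposed")
  expect_equal(round(fit$params$delta, 2), 0)
  expect_equal(round(fit$params$rho, 2), 0)
  expect_equal(round(fit$params$P, 2), 2.96)
  expect_lt(fit$sse, 1e-10)
  expect_equal(round(fit$gof$r2, 4), 1)
  expect_equal(round(fit$gof$mse, 4), 0)
  expect_equal(round(fit$gini, 3), 0.495)
  # the fit is the two-linear-segment shape: jump at the top rank
  expect_true(fit$conditions$jump_at_top)
})

test_that("noise-free model-conformant data are recovered by all three models", {
  # universal model via its synthetic generator
  truth <- proposed_params(0.2, 0.9, 0.5, 3)
  fit <- fit_lorenz(make_model_conformant(truth, 200L), "proposed")
  expect_lt(fit$sse, 1e-10)
  for (nm in c("delta", "rho", "omega", "P"))
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-3)

  # comparator models from exact curve points
  scs_truth <- scs_params(0.5, 0.7, 2)
  fs <- fit_lorenz(curve_points("scs", scs_truth), "scs")
  expect_lt(fs$sse, 1e-8)
  for (nm in c("gamma", "alpha", "beta"))
    expect_equal(fs$params[[nm]], scs_truth[[nm]], tolerance = 1e-2)

  s_truth <- s_params(0.5, 0.3, 2, 1)
  fss <- fit_lorenz(curve_points("s", s_truth), "s")
  expect_lt(fss$sse, 1e-8)
  for (nm in c("lambda", "eta", "a1", "a2"))
    expect_equal(fss$params[[nm]], s_truth[[nm]], tolerance = 1e-2)
})

test_that("perfect equality is fitted by the diagonal with Gini 0", {
  fit <- fit_lorenz(size_sample(rep(5, 20)), "proposed")
  expect_equal(fit$sse, 0, tolerance = 1e-20)
  expect_equal(fit$gini, 0, tolerance = 1e-9)
  expect_equal(fit$params$rho, 0)   # canonical diagonal
  expect_equal(fit$params$omega, 0)
})

test_that("fits are deterministic and improve weakly with more starts", {
  smp <- make_zero_inflated(120L, 0.3, "lognormal",
                            list(meanlog = 0, sdlog = 1.2), seed = 99L)
  f1 <- fit_lorenz(smp, config = quick_config("proposed"))
  f2 <- fit_lorenz(smp, config = quick_config("proposed"))
  expect_identical(unclass(f1$params), unclass(f2$params))
  expect_identical(f1$sse, f2$sse)

  sse_by_starts <- vapply(c(4L, 16L, 32L), function(k)
    fit_lorenz(smp, config = quick_config("proposed", n_starts = k))$sse,
    numeric(1))
  expect_true(all(diff(sse_by_starts) <= 1e-12))
})

test_that("fitted universal curves satisfy the Lorenz conditions", {
  for (smp in list(make_hypothetical(),
                   make_zero_inflated(100L, 0.4, seed = 7L),
                   make_model_conformant(proposed_params(0.1, 1, 0.8, 5)))) {
    fit <- fit_lorenz(smp, "proposed")
    expect_true(fit$conditions$y0_ok)
    expect_true(fit$conditions$y1_ok)
    expect_true(fit$conditions$monotone)
    expect_true(fit$conditions$convex)
  }
})

test_that("canonicalization resolves the flat directions and keeps the SSE", {
  # rho ~ 0: omega has no effect
  can <- canonicalize_proposed(proposed_params(0, 1e-9, 0.73, 2.96))
  expect_equal(can$params$rho, 0)
  expect_equal(can$params$omega, 0)
  expect_equal(can$params$P, 2.96)
  # diagonal: rho and omega are both meaningless
  can <- canonicalize_proposed(proposed_params(0, 0.5, 0.5, 1))
  expect_equal(can$params$rho, 0)
  expect_equal(can$params$omega, 0)
  expect_true(can$changed)
  # identifiable interior point is untouched
  can <- canonicalize_proposed(proposed_params(0.1, 0.8, 0.4, 2))
  expect_false(can$changed)
  expect_equal(can$params, proposed_params(0.1, 0.8, 0.4, 2))
  # with an SSE context the substitution must not change the objective
  pts <- empirical_lorenz(make_hypothetical())
  obj <- function(theta) sum((pts$y - lorenz_proposed(pts$x,
    proposed_params(theta[1], theta[2], theta[3], theta[4])))^2)
  can <- canonicalize_proposed(proposed_params(0, 1e-9, 0.73, 2.96),
                               sse_context = obj)
  expect_equal(can$sse, obj(c(0, 0, 0, 2.96)))
})

test_that("profiling omega shows an SSE minimum at constant Gini", {
  truth <- proposed_params(0, 1, 0.8, 3)
  pts <- curve_points("proposed", truth, 150L)
  prof <- profile_omega(pts, delta = 0, P = 3)
  expect_equal(prof$omega[which.min(prof$sse)], 0.8, tolerance = 0.02)
  expect_equal(unique(prof$gini), gini_proposed(truth))

  # on the diagonal every omega fits equally (and perfectly)
  diag_pts <- empirical_lorenz(rep(1, 20))
  prof0 <- profile_omega(diag_pts, delta = 0, P = 1)
  expect_true(all(prof0$sse < 1e-20))
})

test_that("fit preconditions are enforced", {
  expect_error(fit_lorenz(size_sample(c(1, 2)), "proposed"), "at least 4")
  expect_error(fit_config("proposed", n_starts = 0), "n_starts")
  expect_error(fit_config("proposed", lower = c(-1, 0, 0, 1)), "constraints")
})
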