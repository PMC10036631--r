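test_that("parameter constructors enforce the model constraints", {
  expect_error(proposed_params(delta = 1), "delta")
  expect_error(proposed_params(rho = 1.1), "rho")
  expect_error(proposed_params(P = 0.5), "P >= 1")
  expect_error(scs_params(alpha = 0), "alpha")
  expect_error(scs_params(beta = 0.9), "beta")
  expect_error(s_params(lambda = 0.8, eta = 0.5, a2 = 1), "eta \\* a2")
  expect_error(s_params(a2 = -1), "a2")
  expect_silent(s_params(0.5, 0.3, 2, 1))
})

test_that("the universal model honours its boundary and piecewise rules", {
  grid_params <- list(proposed_params(0, 1, 0.5, 2),
                      proposed_params(0.3, 0.7, 0.2, 5),
                      proposed_params(0.9, 0, 1, 13.42))
  for (p in grid_params) {
    expect_equal(lorenz_proposed(0, p), 0)
    expect_equal(lorenz_proposed(1, p), 1)
  }
  # pure linear component: slope 2/(P+1) through (x - delta)
  p <- proposed_params(0, 0, 0, 2.96)
  expect_equal(lorenz_proposed(0.99, p), 0.5)
  # below delta the curve is identically zero
  p <- proposed_params(0.5, 1, 0.5, 2)
  expect_equal(lorenz_proposed(0.3, p), 0)
  expect_error(lorenz_proposed(1.5, p), "\\[0, 1\\]")
})

test_that("closed-form area and Gini match their formulas", {
  expect_equal(area_proposed(proposed_params(0, 1, 0, 1)), 0.5)
  expect_equal(area_proposed(proposed_params(0, 1, 0, 2.96)), 1 / 3.96)
  expect_equal(area_proposed(proposed_params(0.9, 1, 0, 13.42)), 0.1 / 14.42)
  expect_equal(gini_proposed(proposed_params(0, 1, 0, 1)), 0)
  # published parameter sets reproduce the published Gini values
  expect_equal(round(gini_proposed(proposed_params(0.00, 1, 0.91, 15.34)), 3),
               0.878)  # solar flares
  expect_equal(round(gini_proposed(proposed_params(0.90, 0.88, 0, 13.42)), 3),
               0.986)  # metabolic degrees
  expect_equal(round(gini_proposed(proposed_params(0.58, 1, 0.39, 11.62)), 3),
               0.933)  # inter-state wars
})

test_that("SCS model evaluates per its formula with 0^0 = 1", {
  expect_equal(lorenz_scs(c(0, 0.3, 1), scs_params(0, 1, 1)), c(0, 0.3, 1))
  expect_equal(lorenz_scs(0.5, scs_params(0, 0.31, 1)), 1 - 0.5^0.31)
  expect_equal(lorenz_scs(1, scs_params(2, 0.5, 3)), 1)
  expect_equal(lorenz_scs(0, scs_params(0, 0.5, 3)), 0)
})

test_that("SCS Gini by quadrature matches known values", {
  expect_equal(gini_scs(scs_params(0, 1, 1)), 0, tolerance = 1e-9)
  expect_equal(round(gini_scs(scs_params(0, 0.31, 1)), 3), 0.527)
  expect_equal(gini_scs(scs_params(1, 1, 1)), 1 / 3, tolerance = 1e-8)
  # beta = 1, gamma = 0 closed form: 1 - 2*alpha/(alpha+1)... via area 1 - 1/(a+1)
  for (a in c(0.2, 0.5, 0.9)) {
    expect_equal(gini_scs(scs_params(0, a, 1)),
                 1 - 2 * (1 - 1 / (a + 1)), tolerance = 1e-8)
  }
})

test_that("S model evaluates per its formula and its closed-form Gini", {
  x <- seq(0, 1, by = 0.25)
  expect_equal(lorenz_s(x, s_params(0, 0, 0, 0)), x)
  expect_equal(lorenz_s(0.5, s_params(1, 0, 1, 0)), 0.25)
  expect_equal(lorenz_s(0.5, s_params(0.5, 0, 1, 0)), 0.375)
  expect_equal(gini_s(s_params(0, 0, 0, 0)), 0)
  expect_equal(gini_s(s_params(1, 0, 2, 0)), 0.5)
})

test_that("quadrature of the universal model reproduces the closed-form area", {
  set.seed(7)
  for (i in 1:25) {
    p <- proposed_params(runif(1, 0, 0.95), runif(1), runif(1),
                         1 + rexp(1, 1 / 10))
    expect_equal(area_quadrature("proposed", p), area_proposed(p),
                 tolerance = 1e-7)
  }
})

test_that("S-model closed-form Gini agrees with quadrature", {
  set.seed(11)
  for (i in 1:25) {
    l <- runif(1); a2 <- runif(1, 0, 3)
    e <- if (a2 > 0) runif(1, 0, (1 - l) / a2) else runif(1)
    p <- s_params(l, e, runif(1, 0, 5), a2)
    expect_equal(gini_s(p), 1 - 2 * area_quadrature("s", p, tol = 1e-10),
                 tolerance = 1e-8)
  }
})

test_that("Gini of the universal model is invariant to rho and omega", {
  for (r in c(0, 0.3, 1)) for (w in c(0, 0.5, 1)) {
    expect_equal(gini_proposed(proposed_params(0.2, r, w, 4)),
                 gini_proposed(proposed_params(0.2, 0, 0, 4)))
  }
})

test_that("all three model curves are monotone with convex convex-parts", {
  cases <- list(
    list("proposed", proposed_params(0, 1, 0.5, 2)),
    list("proposed", proposed_params(0.4, 0.6, 0.9, 8)),
    list("proposed", proposed_params(0, 0, 0, 2.96)),
    list("scs", scs_params(0.5, 0.7, 2)),
    list("scs", scs_params(0, 0.31, 1)),
    list("s", s_params(0.5, 0.3, 2, 1)))
  for (case in cases) {
    f <- switch(case[[1]],
                proposed = function(x) lorenz_proposed(x, case[[2]]),
                scs = function(x) lorenz_scs(x, case[[2]]),
                s = function(x) lorenz_s(x, case[[2]]))
    y <- f(seq(0, 1, length.out = 1000))
    expect_true(all(diff(y) >= -1e-12))
    rep <- check_lorenz_conditions(case[[1]], case[[2]])
    expect_true(rep$monotone)
    expect_true(rep$convex)
  }
})

test_that("condition checker reports the top jump instead of failing", {
  # smooth convex case: everything passes
  rep <- check_lorenz_conditions("proposed", proposed_params(0, 1, 0.5, 2))
  expect_true(rep$all_ok)
  expect_false(rep$jump_at_top)
  # linear component with P > 1: slope 2/(P+1) < 1, jump to 1 at the top
  rep <- check_lorenz_conditions("proposed", proposed_params(0, 0, 0, 2.96))
  expect_true(rep$monotone)
  expect_true(rep$jump_at_top)
  # egalitarian parameters: the curve is the diagonal
  rep <- check_lorenz_conditions("proposed", proposed_params(0, 1, 0, 1))
  expect_true(rep$all_ok)
  y <- lorenz_proposed(seq(0, 1, 0.1), proposed_params(0, 1, 0, 1))
  expect_equal(y, seq(0, 1, 0.1))
})

test_that("parameter objects round-trip through JSON", {
  for (p in list(proposed_params(0.1, 0.8, 0.4, 2),
                 scs_params(0.5, 0.7, 2),
                 s_params(0.5, 0.3, 2, 1))) {
    q <- params_from_json(params_to_json(p))
    expect_equal(q, p)
  }
  path <- withr::local_tempfile(fileext = ".json")
  params_to_json(proposed_params(0, 0, 0, 2.96), path)
  expect_equal(params_from_json(path)$P, 2.96)
})
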