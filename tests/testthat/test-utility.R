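test_that("linear utility honours goals, caps and the alpha down-weight", {
  p <- utility_params("linear", goal_low = 1, goal_mid = 1, alpha = 1)
  expect_equal(utility_linear(1, 1, p), 1)
  expect_equal(utility_linear(0, 0, p), 0)
  expect_equal(utility_linear(0.5, 0.7, p), 0.6)
  # no extra credit beyond a goal
  p2 <- utility_params("linear", goal_low = 0.5, goal_mid = 0.5, alpha = 0.6)
  expect_equal(utility_linear(0.9, 0.5, p2), utility_linear(0.5, 0.5, p2))
  # alpha < 1 weights the mid-acuity cohort more
  pa <- utility_params("linear", alpha = 0.6, goal_low = 1, goal_mid = 1)
  expect_gt(utility_linear(0.2, 0.8, pa), utility_linear(0.8, 0.2, pa))
})

test_that("elliptical utility is a normalized elliptical deficit score", {
  p <- utility_params("elliptical", goal_low = 1, goal_mid = 0.9,
                      lambda = 1.5, delta = 0.3)
  expect_equal(utility_elliptical(1, 0.9, p), 1)
  expect_equal(utility_elliptical(0, 0, p), 0)
  # lambda > 1: moving a shortfall from the low to the mid cohort lowers utility
  pl <- utility_params("elliptical", goal_low = 0.8, goal_mid = 0.8, lambda = 1.5)
  grid <- seq(0, 0.5, by = 0.05)
  for (s in grid) {
    expect_gte(utility_elliptical(0.8 - s, 0.8, pl),
               utility_elliptical(0.8, 0.8 - s, pl))
  }
  # lambda = 1 with equal goals: symmetric in the two cohorts
  ps <- utility_params("elliptical", goal_low = 0.9, goal_mid = 0.9, lambda = 1)
  for (i in 1:20) {
    v <- runif(2)
    expect_equal(utility_elliptical(v[1], v[2], ps),
                 utility_elliptical(v[2], v[1], ps))
  }
  # overshoot credit never pushes utility above 1
  expect_equal(utility_elliptical(1, 1, p), 1)
})

test_that("both families stay in [0,1] and reach 1 exactly at the goals", {
  params <- list(
    utility_params("elliptical", goal_low = 0.7, goal_mid = 0.9, lambda = 1.5, delta = 0.3),
    utility_params("linear", goal_low = 0.7, goal_mid = 0.9, alpha = 0.6)
  )
  g <- seq(0, 1, by = 0.1)
  for (p in params) {
    for (vl in g) for (vm in g) {
      u <- utility_value(vl, vm, p)
      expect_gte(u, 0); expect_lte(u, 1)
      expect_equal(u == 1, vl >= p$goal_low - 1e-12 && vm >= p$goal_mid - 1e-12,
                   info = sprintf("%s v=(%.1f, %.1f)", p$family, vl, vm))
    }
    # non-decreasing in each attainment below its goal
    for (vm in g) {
      u <- utility_value(g, vm, p)
      expect_true(all(diff(u) >= -1e-12))
    }
  }
})

test_that("utility parameters are validated", {
  expect_error(utility_params("linear", goal_low = 0), "goals")
  expect_error(utility_params("elliptical", lambda = -1), "lambda")
  expect_error(utility_params("elliptical", delta = 2), "delta")
  expect_error(utility_params("linear", alpha = 0), "alpha")
  p <- utility_params("linear")
  expect_error(utility_elliptical(0.5, 0.5, p), "family")
  expect_error(utility_linear(1.5, 0.5, utility_params("linear")), "v_low")
})

test_that("utility curves track the threshold grid and preserve monotonicity below goals", {
  g <- seq(0, 720, 5)
  p <- utility_params("elliptical", goal_low = 1, goal_mid = 1)
  goal_curve <- new_attainment_curve(g, rep(1, length(g)))
  uc <- utility_curve(goal_curve, goal_curve, p)
  expect_equal(uc$u, rep(1, length(g)))
  set.seed(5)
  for (i in 1:10) {
    a <- cummax(runif(length(g))); a <- a / max(a) * runif(1, 0.8, 1)
    b <- cummax(runif(length(g))); b <- b / max(b) * runif(1, 0.8, 1)
    uu <- utility_curve(new_attainment_curve(g, a), new_attainment_curve(g, b), p)
    expect_true(all(diff(uu$u) >= -1e-12))
  }
  short <- new_attainment_curve(seq(0, 300, 5), rep(1, 61))
  expect_error(utility_curve(goal_curve, short, p), "grid")
})

scatter_fixture <- function() {
  g <- seq(0, 720, 5)
  list(
    A = list(low = new_attainment_curve(g, pmin(g / 400, 1), strategy = "A"),
             mid = new_attainment_curve(g, pmin(g / 600, 1), strategy = "A")),
    B = list(low = new_attainment_curve(g, pmin(g / 500, 1), strategy = "B"),
             mid = new_attainment_curve(g, pmin(g / 450, 1), strategy = "B"))
  )
}

test_that("utility scatter reports raw attainments with utility only as a colouring", {
  curves <- scatter_fixture()
  p <- utility_params("elliptical", goal_low = 1, goal_mid = 0.9)
  sc <- utility_scatter(curves, 300, p)
  expect_equal(nrow(sc), 2)
  # axes are the raw curve values at t*, untouched by the utility map
  expect_equal(sc$v_low[sc$strategy == "A"], curves$A$low$value[curves$A$low$t == 300])
  expect_equal(sc$v_mid[sc$strategy == "B"], curves$B$mid$value[curves$B$mid$t == 300])
  expect_equal(sc$u, utility_value(sc$v_low, sc$v_mid, p))
  # identical strategies give identical points
  twin <- list(A = curves$A, A2 = curves$A)
  sc2 <- utility_scatter(twin, 300, p)
  expect_equal(sc2$u[1], sc2$u[2])
  expect_error(utility_scatter(curves, 301, p), "grid")
  # a strategy exactly at the goals lands on utility 1
  g <- seq(0, 720, 5)
  ideal <- list(X = list(low = new_attainment_curve(g, rep(1, length(g))),
                         mid = new_attainment_curve(g, rep(0.9, length(g)))))
  expect_equal(utility_scatter(ideal, 300, p)$u, 1)
})

test_that("cross-utility agreement detects identity, reversal and degeneracy", {
  curves <- scatter_fixture()
  p1 <- utility_params("elliptical", goal_low = 0.5, goal_mid = 0.5)
  same <- cross_utility(curves, 180, p1, p1)
  expect_equal(same$slope, 1, tolerance = 1e-10)
  expect_equal(same$r_squared, 1, tolerance = 1e-10)
  expect_equal(same$n_discordant, 0)
  # anti-monotone synthetic utilities flag a negative slope
  g <- seq(0, 720, 5)
  anti <- list(
    A = list(low = new_attainment_curve(g, rep(0.9, length(g))),
             mid = new_attainment_curve(g, rep(0.1, length(g)))),
    B = list(low = new_attainment_curve(g, rep(0.1, length(g))),
             mid = new_attainment_curve(g, rep(0.9, length(g))))
  )
  lopsided1 <- utility_params("linear", goal_low = 1, goal_mid = 1, alpha = 1e-6)
  lopsided2 <- utility_params("linear", goal_low = 1, goal_mid = 1e-6, alpha = 1)
  xr <- cross_utility(anti, 300, lopsided2, lopsided1)
  expect_lt(xr$slope, 0)
  expect_equal(xr$n_discordant, 1)
  flat <- list(A = anti$A, B = anti$A)
  expect_error(cross_utility(flat, 300, p1, p1), class = "edflow_degenerate_fit")
})
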