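ap <- activation_params()

test_that("activation rate follows the branch-switched first-order law", {
  expect_equal(activation_rate(0.3, 0.3, ap), 0)
  expect_equal(activation_rate(0, 1, ap), 1 / 0.015)
  expect_equal(activation_rate(1, 0, ap), -1 / 0.050)
  expect_error(activation_rate(1.2, 0.5, ap), "\\[0, 1\\]")
})

test_that("discrete activation update matches its closed form", {
  expect_equal(activation_step(0.3, 0.3, 0.01, ap), 0.3)
  expect_equal(activation_step(0, 1, 0.015, ap), 1 - exp(-1),
               tolerance = 1e-12)
  expect_equal(activation_step(0.9, 0.2, 100, ap), 0.2, tolerance = 1e-12)
  expect_error(activation_step(0.5, 0.5, 0, ap), "dt")
})

test_that("activation update is monotone, bounded and a semigroup", {
  set.seed(11)
  for (rep in 1:50) {
    a0 <- runif(1); u <- runif(1); dt <- runif(1, 1e-3, 0.1)
    one <- activation_step(a0, u, dt, ap)
    expect_true(one >= 0 && one <= 1)
    two <- activation_step(activation_step(a0, u, dt / 2, ap), u, dt / 2, ap)
    expect_equal(two, one, tolerance = 1e-12)
    # monotone in a0 and u
    expect_gte(activation_step(min(a0 + 0.05, 1), u, dt, ap) - one, -1e-12)
    expect_gte(activation_step(a0, min(u + 0.05, 1), dt, ap) - one, -1e-12)
  }
})

test_that("discrete update agrees with numerical integration of the rate ODE", {
  set.seed(12)
  for (rep in 1:10) {
    a0 <- runif(1); u <- runif(1); dt <- runif(1, 0.005, 0.05)
    num <- deSolve::ode(y = c(a = a0), times = c(0, dt),
                        func = function(t, y, p)
                          list(activation_rate(min(max(y, 0), 1), u, ap)),
                        rtol = 1e-10, atol = 1e-12)[2, "a"]
    expect_equal(activation_step(a0, u, dt, ap), unname(num),
                 tolerance = 1e-8)
  }
})

test_that("activation bounds bracket the previous activation and relax with dt", {
  b <- activation_bounds(0.5, 0.01, ap)
  expect_equal(b$aMin, 0.5 * exp(-0.2), tolerance = 1e-12)
  expect_equal(b$aMax, 1 - 0.5 * exp(-2 / 3), tolerance = 1e-12)
  expect_true(b$aMin <= 0.5 && 0.5 <= b$aMax)
  wide <- activation_bounds(0.5, 1e3, ap)
  expect_equal(wide$aMin, 0, tolerance = 1e-9)
  expect_equal(wide$aMax, 1, tolerance = 1e-9)
  expect_equal(activation_bounds(1, 0.01, ap)$aMax, 1)
  # widen monotonically with dt
  b2 <- activation_bounds(0.5, 0.02, ap)
  expect_lt(b2$aMin, b$aMin)
  expect_gt(b2$aMax, b$aMax)
})

test_that("PHY2 bounds compose activation bounds with the rigid-tendon force", {
  mp <- fix_muscles(1000)[1, ]
  cv <- hill_curves()
  at_opt <- mp$lTs + mp$l0M
  bb <- force_bounds_phy2(list(a = 0.5), at_opt, 0, 0.01, mp, cv)
  expect_equal(bb$FMin, 0.5 * exp(-0.2) * 1000, tolerance = 1e-9)
  expect_equal(bb$FMax, (1 - 0.5 * exp(-2 / 3)) * 1000, tolerance = 1e-9)
  # dt -> infinity collapses to the PHY3 bounds
  wide <- force_bounds_phy2(list(a = 0.5), at_opt, 0, 1e3, mp, cv)
  p3 <- force_bounds_phy3(at_opt, 0, mp, cv)
  expect_equal(wide$FMin, p3$FMin, tolerance = 1e-6)
  expect_equal(wide$FMax, p3$FMax, tolerance = 1e-6)
})

test_that("PHY3 bounds are the passive floor and the maximal-activation force", {
  mp <- fix_muscles(1000)[1, ]
  cv <- hill_curves()
  p3 <- force_bounds_phy3(mp$lTs + mp$l0M, 0, mp, cv)
  expect_equal(unname(p3$FMin), 0)
  expect_equal(unname(p3$FMax), 1000)
  long <- mp$lTs + 1.15 * mp$l0M
  p3l <- force_bounds_phy3(long, 0, mp, cv)
  expect_gt(p3l$FMin, 0)   # passive floor on the descending limb
})

test_that("bound nesting holds across random states: previous force within PHY2 within PHY3", {
  set.seed(13)
  mp <- fix_muscles(1200)[1, ]
  cv <- hill_curves()
  for (rep in 1:25) {
    lbar <- runif(1, 0.8, 1.1)
    lMT <- mp$lTs + lbar * mp$l0M
    vMT <- runif(1, -0.2, 0.2)
    a_prev <- runif(1)
    dt <- 0.01
    F_prev <- rigid_tendon_force(a_prev, lMT, vMT, mp, cv)
    p2 <- force_bounds_phy2(list(a = a_prev), lMT, vMT, dt, mp, cv)
    p3 <- force_bounds_phy3(lMT, vMT, mp, cv)
    expect_gte(p2$FMin - p3$FMin, -1e-9)
    expect_lte(p2$FMax - p3$FMax, 1e-9)
    expect_gte(F_prev - p2$FMin, -1e-9)
    expect_lte(F_prev - p2$FMax, 1e-9)
  }
})

test_that("PHY1 bounds come from the two excitation-extreme integrations", {
  mp <- muscle_params("m", 900, l0M = 0.10, lTs = 0.20, alpha0 = 0.05,
                      PCSA = 15)
  cv <- hill_curves()
  lMT <- mp$lTs * 1.01 + mp$l0M * cos(mp$alpha0)
  F0 <- static_elastic_force(0.4, lMT, mp, cv)
  st <- muscle_state(0.4, F0)
  kin <- list(t = c(0, 0.01), lMT = c(lMT, lMT), vMT = c(0, 0))
  bb <- force_bounds_phy1(st, kin, mp, cv)
  expect_true(bb$FMin <= F0 + 1e-6 && F0 <= bb$FMax + 1e-6)
  expect_true(bb$aMin < 0.4 && bb$aMax > 0.4)
  # zero-length step leaves the state untouched
  bb0 <- force_bounds_phy1(st, list(t = c(0, 0), lMT = c(lMT, lMT),
                                    vMT = c(0, 0)), mp, cv)
  expect_equal(bb0$FMin, F0)
  expect_equal(bb0$FMax, F0)
})

test_that("trapezoid contraction integrator agrees with a stiff reference integration", {
  mp <- muscle_params("m", 900, l0M = 0.10, lTs = 0.20, alpha0 = 0.05,
                      PCSA = 15)
  cv <- hill_curves()
  lMT0 <- mp$lTs * 1.01 + mp$l0M * cos(mp$alpha0)
  F0 <- static_elastic_force(0.3, lMT0, mp, cv)
  kin <- list(t = c(0, 0.01), lMT = c(lMT0, lMT0 * 1.002),
              vMT = c(0.2, 0.2))
  for (u in c(0, 1)) {
    mine <- contract_integrate(u, 0.3, F0, kin, mp, cv, n_sub = 20)
    ref <- deSolve::ode(
      y = c(a = 0.3, FMT = F0), times = kin$t,
      func = function(t, y, p) {
        s <- t / 0.01
        list(c(activation_rate(min(max(y[1], 0), 1), u),
               contraction_ode(min(max(y[1], 0), 1), max(y[2], 0),
                               (1 - s) * kin$lMT[1] + s * kin$lMT[2],
                               0.2, mp, cv, quiet = TRUE)))
      }, method = "lsoda", rtol = 1e-8, atol = 1e-10)
    expect_equal(mine$FMT, unname(ref[2, "FMT"]), tolerance = 2e-3)
    expect_equal(mine$a, unname(ref[2, "a"]), tolerance = 1e-6)
  }
})
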