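test_that("muscle table validation enforces physiological invariants", {
  mp <- fix_muscles()
  expect_s3_class(mp, "muscle_params")
  expect_equal(mp$w_apo, mp$l0M * sin(mp$alpha0))
  expect_error(muscle_params("x", F0M = -1, l0M = 0.1, lTs = 0.2), "F0M")
  expect_error(muscle_params("x", F0M = 100, l0M = 0.1, lTs = 0.2,
                             alpha0 = pi / 2), "alpha0")
  bad <- mp; bad$w_apo[1] <- bad$w_apo[1] + 1e-3
  expect_error(validate_muscle_params(bad), "w_apo")
})

test_that("length-parameter scaling is proportional and keeps pennation", {
  mp <- muscle_params("m", 1000, l0M = 0.10, lTs = 0.20, alpha0 = 0.15,
                      PCSA = 16)
  same <- scale_length_params(mp, 0.30, 0.30)
  expect_equal(same$l0M, mp$l0M)
  expect_equal(same$lTs, mp$lTs)
  sc <- scale_length_params(mp, 0.33, 0.30)
  expect_equal(sc$l0M, 0.11)
  expect_equal(sc$lTs, 0.22)
  expect_equal(sc$alpha0, mp$alpha0)
  expect_equal(sc$w_apo, 0.11 * sin(0.15))
  expect_error(scale_length_params(mp, 0.33, 0), "positive")
})

test_that("rigid fiber geometry matches the pennation construction", {
  mp0 <- muscle_params("m", 1000, l0M = 0.10, lTs = 0.30, alpha0 = 0,
                       PCSA = 16)
  g <- rigid_fiber_geometry(0.5, mp0)
  expect_equal(g$alpha, 0)
  expect_equal(g$lM, 0.2)
  # lMT - lTs = w gives alpha = pi/4
  mp1 <- fix_muscles(1000)
  mp1$l0M <- 0.2 / sin(0.5); mp1$alpha0 <- NULL
  mp1 <- muscle_params("m", 1000, l0M = 0.4, lTs = 0.3,
                       alpha0 = asin(0.2 / 0.4), PCSA = 16)
  g2 <- rigid_fiber_geometry(0.3 + mp1$w_apo, mp1)
  expect_equal(g2$alpha, pi / 4)
  expect_equal(g2$lM, mp1$w_apo * sqrt(2))
  expect_error(rigid_fiber_geometry(0.3, mp0), "degenerate")
})

test_that("geometry round-trips lMT to machine precision", {
  set.seed(42)
  for (rep in 1:20) {
    mp <- muscle_params("m", 1000, l0M = runif(1, 0.05, 0.15),
                        lTs = runif(1, 0.05, 0.4),
                        alpha0 = runif(1, 0, 0.4), PCSA = 16)
    lMT <- mp$lTs + runif(1, 0.5, 1.5) * mp$l0M * cos(mp$alpha0)
    g <- rigid_fiber_geometry(lMT, mp)
    expect_equal(mp$lTs + g$lM * cos(g$alpha), lMT, tolerance = 1e-12)
  }
})

test_that("optimal-length clamp pins the peak normalized fiber length at 1", {
  mp <- muscle_params(c("a", "b"), F0M = 1000, l0M = c(0.08, 0.12),
                      lTs = 0.2, alpha0 = c(0, 0.25), PCSA = 16)
  tj <- seq(0, 1, by = 0.01)
  lMT <- cbind(0.2 + 0.09 + 0.01 * sin(2 * pi * tj),
               0.2 + 0.11 + 0.02 * cos(2 * pi * tj))
  cl <- clamp_optimal_length(mp, lMT)
  lbar <- rigid_fiber_geometry(lMT, cl)$lbar
  expect_equal(unname(apply(lbar, 2, max)), c(1, 1), tolerance = 1e-12)
  expect_true(all(lbar > 0.5 & lbar <= 1.2))
  expect_equal(cl$w_apo, cl$l0M * sin(cl$alpha0))
  # constant trajectory: l0M equals the constant fiber length
  cl2 <- clamp_optimal_length(mp[1, ], rep(0.2 + 0.1, 5))
  expect_equal(cl2$l0M, 0.1)
  expect_error(clamp_optimal_length(mp[1, ], numeric(0)))
})

test_that("rigid-tendon force matches the Hill decomposition", {
  mp <- muscle_params("m", 1000, l0M = 0.10, lTs = 0.30, alpha0 = 0,
                      PCSA = 16)
  cv <- hill_curves()
  at_opt <- mp$lTs + mp$l0M
  expect_equal(rigid_tendon_force(0, at_opt, 0, mp, cv), 0)   # passive-free
  expect_equal(rigid_tendon_force(1, at_opt, 0, mp, cv), 1000)
  expect_equal(rigid_tendon_force(0.5, at_opt, 0, mp, cv), 500)
  # affine and monotone in activation at fixed kinematics
  set.seed(1)
  for (rep in 1:10) {
    lMT <- mp$lTs + runif(1, 0.7, 1.3) * mp$l0M
    vMT <- runif(1, -0.3, 0.3)
    a <- sort(runif(3))
    fr <- vapply(a, function(ai) rigid_tendon_force(ai, lMT, vMT, mp, cv),
                 numeric(1))
    expect_true(all(diff(fr) >= -1e-12))
    slope1 <- (fr[2] - fr[1]) / (a[2] - a[1])
    slope2 <- (fr[3] - fr[2]) / (a[3] - a[2])
    expect_equal(slope1, slope2, tolerance = 1e-8)
  }
  expect_error(rigid_tendon_force(1.5, at_opt, 0, mp, cv), "activation")
})

test_that("passive element can be dropped for the strict activation-scaled form", {
  mp <- muscle_params("m", 1000, l0M = 0.10, lTs = 0.30, alpha0 = 0,
                      PCSA = 16)
  cv_np <- hill_curves(include_passive = FALSE)
  long <- mp$lTs + 1.15 * mp$l0M     # passive region
  expect_equal(rigid_tendon_force(0, long, 0, mp, cv_np), 0)
  expect_gt(rigid_tendon_force(0, long, 0, mp, hill_curves()), 0)
})

test_that("hill curves satisfy their shape constraints", {
  cv <- hill_curves()
  expect_equal(cv$active_fl(1), 1)
  expect_true(all(cv$active_fl(seq(0.3, 1.8, by = 0.01)) >= 0))
  expect_equal(cv$passive_fl(1), 0)
  expect_equal(cv$passive_fl(0.8), 0)
  pf <- cv$passive_fl(seq(1, 1.6, by = 0.01))
  expect_true(all(diff(pf) >= 0))
  expect_equal(cv$fv(0), 1)
  expect_equal(cv$fv(-1), 0)
  fvv <- cv$fv(seq(-1, 1, by = 0.01))
  expect_true(all(diff(fvv) >= 0))
  expect_true(all(fvv <= cv$fv_max))
  expect_equal(cv$tendon_fl(0), 0)
  expect_equal(cv$tendon_fl(-0.01), 0)
  tf <- cv$tendon_fl(seq(0, 0.1, by = 0.001))
  expect_true(all(diff(tf) >= 0))
  # analytic inverses round-trip
  eps <- seq(1e-4, 0.09, by = 0.003)
  expect_equal(cv$tendon_fl_inv(cv$tendon_fl(eps)), eps, tolerance = 1e-10)
  v <- seq(-0.95, 0.9, by = 0.05)
  expect_equal(cv$fv_inv(cv$fv(v)), v, tolerance = 1e-9)
})

test_that("contraction dynamics vanish at equilibrium and at full slack", {
  mp <- muscle_params("m", 1000, l0M = 0.10, lTs = 0.30, alpha0 = 0.1,
                      PCSA = 16)
  cv <- hill_curves()
  # construct an exact isometric elastic equilibrium
  a <- 0.6
  lMT <- mp$lTs * 1.02 + mp$l0M
  FMT <- static_elastic_force(a, lMT, mp, cv)
  expect_equal(contraction_ode(a, FMT, lMT, 0, mp, cv), 0,
               tolerance = 1e-6 * mp$F0M)
  # fully slack: zero force, zero activation, short fiber, still no drive
  expect_equal(contraction_ode(0, 0, mp$lTs + 0.5 * mp$l0M, 0, mp, cv,
                               quiet = TRUE), 0, tolerance = 1e-9)
  # stepping activation up from equilibrium pulls the force up
  expect_gt(contraction_ode(0.9, FMT, lMT, 0, mp, cv), 0)
})

test_that("forward elastic integration approaches the rigid-tendon force as the tendon stiffens", {
  mp <- muscle_params("m", 800, l0M = 0.10, lTs = 0.20, alpha0 = 0,
                      PCSA = 13)
  lMT <- mp$lTs + mp$l0M
  a <- 0.5
  kin <- list(t = c(0, 0.5), lMT = c(lMT, lMT), vMT = c(0, 0))
  rigid <- rigid_tendon_force(a, lMT, 0, mp, hill_curves())
  errs <- vapply(c(0.04, 0.01, 0.002), function(e0) {
    cv <- hill_curves(t_e0 = e0)
    st <- contract_integrate(a, a, rigid_tendon_force(a, lMT, 0, mp, cv) * 0.5,
                             kin, mp, cv, n_sub = 400)
    abs(st$FMT - rigid)
  }, numeric(1))
  # equilibria converge to the rigid value as strain-at-F0M shrinks
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 0.01 * rigid)
})

test_that("muscle table round-trips through CSV and the packaged table loads", {
  mp <- default_muscle_table()
  expect_equal(nrow(mp), 43)
  expect_true(all(mp$F0M > 0))
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(mp[, c("name", "F0M", "l0M", "lTs", "alpha0", "PCSA")],
                   tmp, row.names = FALSE)
  mp2 <- read_muscle_table(tmp)
  expect_equal(mp2$F0M, mp$F0M)
  expect_equal(mp2$w_apo, mp$w_apo)
})
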