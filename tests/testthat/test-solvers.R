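test_that("frame solver reproduces closed-form solutions of the four criteria", {
  mp <- fix_muscles(c(1000, 1000))[, ]
  # criterion I least-norm: F_i = r_i Q / sum(r^2)
  s1 <- solve_frame(5, matrix(c(1, 2), 1), c(0, 0), c(10, 10),
                    so_criterion("I"), mp)
  expect_equal(s1$forces, c(1, 2), tolerance = 1e-8)
  # criterion IV symmetric split
  s4 <- solve_frame(1, matrix(c(1, 1), 1), c(0, 0), c(10, 10),
                    so_criterion("IV"), mp)
  expect_equal(s4$forces, c(0.5, 0.5), tolerance = 1e-8)
  # criterion II stationarity with unequal F0M
  mp2 <- fix_muscles(c(2, 1))
  s2 <- solve_frame(1, matrix(c(1, 1), 1), c(0, 0), c(10, 10),
                    so_criterion("II"), mp2)
  expect_equal(s2$forces, c(0.8, 0.2), tolerance = 1e-8)
})

test_that("frame solver matches the active-set enumeration oracle on random instances", {
  set.seed(101)
  for (rep in 1:60) {
    inst <- random_instance()
    mp <- muscle_params(c("a", "b", "c"), F0M = inst$F0M, l0M = 0.1,
                        lTs = 0.2, alpha0 = 0, PCSA = inst$PCSA)
    for (which in c("I", "II", "III")) {
      crit <- so_criterion(which)
      k <- switch(which, I = rep(1, 3), II = inst$F0M, III = inst$PCSA)
      sol <- solve_frame(inst$b, matrix(inst$a, 1), inst$lo, inst$up,
                         crit, mp)
      ora <- oracle_poly_qp(inst$a, inst$b, inst$lo, inst$up, k)
      expect_true(sol$feasible)
      expect_equal(sol$objective, ora$objective,
                   tolerance = 1e-6 * max(1, ora$objective))
    }
  }
})

test_that("min/max solutions beat every feasible sample and match the bisection oracle", {
  set.seed(102)
  for (rep in 1:40) {
    inst <- random_instance()
    mp <- muscle_params(c("a", "b", "c"), F0M = inst$F0M, l0M = 0.1,
                        lTs = 0.2, alpha0 = 0, PCSA = inst$PCSA)
    sol <- solve_frame(inst$b, matrix(inst$a, 1), inst$lo, inst$up,
                       so_criterion("IV"), mp)
    t_star <- oracle_minmax(inst$a, inst$b, inst$lo, inst$up, inst$F0M)
    expect_equal(sol$objective, t_star, tolerance = 1e-6 * max(1, t_star))
    # no dense random feasible point does better
    for (dr in 1:30) {
      x23 <- runif(2, inst$lo[2:3], inst$up[2:3])
      x1 <- (inst$b - sum(inst$a[2:3] * x23)) / inst$a[1]
      if (x1 < inst$lo[1] || x1 > inst$up[1]) next
      expect_gte(max(c(x1, x23) / inst$F0M) - sol$objective, -1e-7)
    }
  }
})

test_that("bound handling: solutions respect bounds exactly and flag infeasibility", {
  mp <- fix_muscles(c(1000, 1000))
  s <- solve_frame(5, matrix(c(1, 1), 1), c(0, 0), c(2, 4),
                   so_criterion("I"), mp)
  expect_true(all(s$forces >= 0 - 1e-12 & s$forces <= c(2, 4) + 1e-12))
  expect_equal(sum(s$forces), 5, tolerance = 1e-8)
  infs <- solve_frame(100, matrix(c(1, 1), 1), c(0, 0), c(2, 4),
                      so_criterion("I"), mp)
  expect_false(infs$feasible)
  expect_gt(attr(infs, "min_violation"), 90)
  expect_error(solve_frame(1, matrix(c(1, 1), 1), c(3, 0), c(2, 4),
                           so_criterion("I"), mp), "FMin")
})

test_that("criterion equivalences: II = I under equal F0M; III = II under constant specific tension", {
  set.seed(103)
  for (rep in 1:20) {
    a <- runif(3, 0.02, 0.08); b <- sum(a * runif(3, 50, 600))
    F0M <- rep(1400, 3)
    mp_eq <- muscle_params(c("a", "b", "c"), F0M = F0M, l0M = 0.1,
                           lTs = 0.2, alpha0 = 0, PCSA = F0M / 61)
    s1 <- solve_frame(b, matrix(a, 1), rep(0, 3), F0M, so_criterion("I"),
                      mp_eq)
    s2 <- solve_frame(b, matrix(a, 1), rep(0, 3), F0M, so_criterion("II"),
                      mp_eq)
    expect_equal(s1$forces, s2$forces, tolerance = 1e-6)
    # unequal F0M but PCSA proportional to it
    F0v <- runif(3, 400, 2000)
    mp_pr <- muscle_params(c("a", "b", "c"), F0M = F0v, l0M = 0.1,
                           lTs = 0.2, alpha0 = 0, PCSA = F0v / 61)
    s2b <- solve_frame(b, matrix(a, 1), rep(0, 3), F0v, so_criterion("II"),
                       mp_pr)
    s3 <- solve_frame(b, matrix(a, 1), rep(0, 3), F0v, so_criterion("III"),
                      mp_pr)
    expect_equal(s2b$forces, s3$forces, tolerance = 1e-6 * max(s3$forces))
  }
})

test_that("method bounds dispatch: SO uses [0, F0M], PHY variants use the dynamics", {
  mp <- fix_muscles(c(1000, 1500))
  tr <- fix_trial_const(mp, QID_row = 50)
  so <- bounds_for_method("SO", 3, NULL, tr, mp, hill_curves())
  expect_equal(so$FMin, c(0, 0))
  expect_equal(so$FMax, mp$F0M)
  p3 <- bounds_for_method("PHY3", 3, NULL, tr, mp, hill_curves())
  expect_equal(unname(p3$FMax), mp$F0M, tolerance = 1e-9)  # optimal isometric
  # frame-0 physiological bounds: a = 0 / a = 1 at zero fiber velocity
  p2 <- bounds_for_method("PHY2", 1, NULL, tr, mp, hill_curves())
  expect_equal(unname(p2$FMin), c(0, 0), tolerance = 1e-9)
  expect_equal(unname(p2$FMax), mp$F0M, tolerance = 1e-9)
})

test_that("trial solve recovers construction-optimal forces and is deterministic", {
  cfg <- synth_config(n_subjects = 1, n_muscles = 8, n_dofs = 3, seed = 21)
  sub <- gen_subject(cfg)
  res <- solve_trial(sub$trial, sub$muscles, "SO", so_criterion("I"),
                     seed = 5)
  rel <- max(abs(res$forces - sub$truth$forces)) / max(sub$truth$forces)
  expect_lt(rel, 1e-6)
  expect_true(all(res$residual <=
                    1e-6 * pmax(1, apply(abs(sub$trial$QID), 1, max))))
  res_b <- solve_trial(sub$trial, sub$muscles, "SO", so_criterion("I"),
                       seed = 5)
  expect_identical(res$forces, res_b$forces)
  # constant-kinematics trial: identical solution at every frame
  mp <- fix_muscles()
  tr <- fix_trial_const(mp, QID_row = 30, f = 4)
  rc <- solve_trial(tr, mp, "SO", so_criterion("I"), seed = 2)
  for (j in 2:4) expect_equal(rc$forces[j, ], rc$forces[1, ],
                              tolerance = 1e-9)
})

test_that("activation extraction inverts the force maps", {
  mp <- fix_muscles(c(1000, 1500))
  tr <- fix_trial_const(mp, QID_row = 40, f = 3)
  cv <- hill_curves()
  F <- matrix(c(0, 500, 1000, 0, 750, 1500), 3, 2)
  a_so <- activations_from_forces(F, "SO", tr, mp, cv)
  expect_equal(a_so, F / matrix(mp$F0M, 3, 2, byrow = TRUE))
  # PHY3 at optimal isometric with no passive force: affine inversion
  a_p3 <- activations_from_forces(F, "PHY3", tr, mp, cv)
  expect_equal(a_p3[2, ], c(0.5, 0.5), tolerance = 1e-9)
  expect_equal(a_p3[3, ], c(1, 1), tolerance = 1e-9)
})

test_that("PHY2 and PHY3 collapse together when the step dwarfs the time constants", {
  cfg <- synth_config(n_subjects = 1, n_muscles = 8, n_dofs = 3, seed = 23)
  sub <- gen_subject(cfg)
  fast <- activation_params(tau_act = 1e-5, tau_deact = 1e-5)
  r2 <- solve_trial(sub$trial, sub$muscles, "PHY2", act_params = fast,
                    seed = 4)
  r3 <- solve_trial(sub$trial, sub$muscles, "PHY3", seed = 4)
  expect_lt(max(abs(r2$forces - r3$forces)) / max(r3$forces), 1e-6)
})

test_that("SO-I and PHY3 coincide where no physiological bound is active", {
  cfg <- synth_config(n_subjects = 1, n_muscles = 8, n_dofs = 3, seed = 24)
  sub <- gen_subject(cfg)
  rs <- solve_trial(sub$trial, sub$muscles, "SO", so_criterion("I"),
                    seed = 4)
  r3 <- solve_trial(sub$trial, sub$muscles, "PHY3", seed = 4)
  cv <- hill_curves()
  inact <- vapply(seq_len(sub$trial$n_frames), function(j) {
    bb <- bounds_for_method("PHY3", j, NULL, sub$trial, sub$muscles, cv)
    all(r3$forces[j, ] < bb$FMax - 1e-6) && all(r3$forces[j, ] >
                                                  bb$FMin + 1e-6 |
                                                  r3$forces[j, ] < 1e-9)
  }, logical(1))
  expect_gt(sum(inact), 0)
  scale <- max(rs$forces)
  expect_lt(max(abs(rs$forces[inact, ] - r3$forces[inact, ])) / scale, 1e-6)
})
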