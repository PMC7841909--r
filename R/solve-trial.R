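#' Force bounds for a solving method at one frame
#'
#' Dispatches to the bound rule of the requested method. Static optimization
#' uses the constant bounds \code{[0, F0M]}. The physiological variants use
#' the current frame's musculotendon kinematics: PHY3 evaluates the
#' rigid-tendon force at a = 0 and a = 1; PHY2 first propagates the previous
#' activation through one step of activation dynamics; PHY1 integrates the
#' coupled activation + elastic-tendon contraction dynamics over the step
#' with the excitation held at 0 and 1. At frame 1 the physiological methods
#' use the static initial condition: bounds from a = 0 and a = 1 with zero
#' fiber velocity (elastic-tendon equilibrium for PHY1).
#'
#' @param method \code{"SO"}, \code{"PHY1"}, \code{"PHY2"} or \code{"PHY3"}.
#' @param j frame index (1-based).
#' @param prev list with vectors \code{a} and \code{FMT} at frame j-1
#'   (ignored for SO/PHY3 and at j = 1).
#' @param trial a \code{\link{gait_trial}}.
#' @param params \code{muscle_params}.
#' @param curves a \code{\link{hill_curves}} object.
#' @param act_params an \code{\link{activation_params}} object.
#' @return a list with vectors \code{FMin} and \code{FMax} (N).
#' @export
bounds_for_method <- function(method, j, prev, trial, params, curves,
                              act_params = activation_params()) {
  m <- trial$n_muscles
  if (method == "SO")
    return(list(FMin = rep(0, m), FMax = params$F0M))
  lMT <- trial$lMT[j, ]; vMT <- trial$vMT[j, ]
  if (method == "PHY3")
    return(force_bounds_phy3(lMT, vMT, params, curves))
  if (j == 1) {
    # static initial condition: a = 0 / a = 1 with zero fiber velocity
    if (method == "PHY2")
      return(force_bounds_phy3(lMT, rep(0, m), params, curves))
    FMin <- FMax <- numeric(m)
    for (i in seq_len(m)) {
      FMin[i] <- static_elastic_force(0, lMT[i], params[i, ], curves)
      FMax[i] <- static_elastic_force(1, lMT[i], params[i, ], curves)
    }
    return(list(FMin = FMin, FMax = pmax(FMax, FMin)))
  }
  if (method == "PHY2") {
    bb <- force_bounds_phy2(list(a = prev$a), lMT, vMT, trial$dt,
                            params, curves, act_params)
    return(list(FMin = bb$FMin, FMax = bb$FMax))
  }
  # PHY1: per-muscle stiff integration over the step
  FMin <- FMax <- numeric(m)
  for (i in seq_len(m)) {
    kin <- list(t = trial$t[(j - 1):j],
                lMT = trial$lMT[(j - 1):j, i],
                vMT = trial$vMT[(j - 1):j, i])
    bb <- force_bounds_phy1(muscle_state(prev$a[i], max(prev$FMT[i], 0)),
                            kin, params[i, ], curves, act_params)
    FMin[i] <- bb$FMin; FMax[i] <- bb$FMax
  }
  list(FMin = FMin, FMax = FMax)
}

# Small seeded real-coded evolutionary search over the box, minimizing the
# recruitment cost plus a quadratic penalty on the moment residual. Mirrors
# the reference protocol (several population-based global runs feeding the
# gradient solver at the first frame); the per-frame problems are convex, so
# the seeding fixes the protocol path rather than the optimum.
.evolve_seed <- function(obj, lo, up, runs = 5, pop = 50, gens = 20) {
  m <- length(lo)
  best_x <- NULL; best_f <- Inf
  for (r in seq_len(runs)) {
    P <- matrix(stats::runif(pop * m, lo, up), pop, m, byrow = TRUE)
    fit <- apply(P, 1, obj)
    for (g in seq_len(gens)) {
      ord <- order(fit)
      elite <- P[ord[seq_len(max(2, pop %/% 5))], , drop = FALSE]
      pa <- elite[sample(nrow(elite), pop, TRUE), , drop = FALSE]
      pb <- elite[sample(nrow(elite), pop, TRUE), , drop = FALSE]
      w <- matrix(stats::runif(pop * m), pop, m)
      child <- w * pa + (1 - w) * pb +
        matrix(stats::rnorm(pop * m, 0, 0.05), pop, m) *
        matrix(up - lo, pop, m, byrow = TRUE) * (0.5^(g / gens))
      child <- pmin(pmax(child, matrix(lo, pop, m, byrow = TRUE)),
                    matrix(up, pop, m, byrow = TRUE))
      cf <- apply(child, 1, obj)
      keep <- cf < fit
      P[keep, ] <- child[keep, ]; fit[keep] <- cf[keep]
    }
    if (min(fit) < best_f) { best_f <- min(fit); best_x <- P[which.min(fit), ] }
  }
  best_x
}

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  force(expr)
}

#' Solve a full gait trial
#'
#' Sequentially solves the per-frame muscle force-sharing problem over one
#' gait cycle. The first frame's initial guess is the best of several seeded
#' population-based global searches refined by the gradient-based frame
#' solver; subsequent frames are warm-started from the previous optimum. For
#' the physiological methods the per-muscle state (activation, force) is
#' propagated frame to frame and drives the next frame's bounds; for PHY1
#' the activation consistent with the solved force is recovered by
#' root-finding the constant excitation whose one-step integration reaches
#' that force.
#'
#' @param trial a \code{\link{gait_trial}}.
#' @param params \code{muscle_params} matching the trial's muscles.
#' @param method \code{"SO"}, \code{"PHY1"}, \code{"PHY2"} or \code{"PHY3"}.
#' @param crit a \code{\link{criterion_spec}} (the squared-force criterion I
#'   by default, as used for all physiological variants).
#' @param curves a \code{\link{hill_curves}} object.
#' @param act_params an \code{\link{activation_params}} object.
#' @param seed integer seed for the global-search populations.
#' @param protocol list: \code{ga_runs}, \code{ga_pop}, \code{ga_gens}
#'   (global-search shape) and \code{soft} (on an infeasible frame, keep the
#'   minimal-violation point and continue instead of aborting).
#' @param tol relative equality-constraint tolerance.
#' @return a \code{solver_result}: matrices \code{forces}, \code{activations}
#'   (f x m), \code{QMT} (f x d reconstructed moments), per-frame
#'   \code{objective}, \code{residual}, \code{converged}, plus method
#'   metadata and wall time.
#' @export
solve_trial <- function(trial, params, method = c("SO", "PHY1", "PHY2", "PHY3"),
                        crit = so_criterion("I"), curves = hill_curves(),
                        act_params = activation_params(), seed = 1,
                        protocol = list(), tol = 1e-6) {
  method <- match.arg(method)
  pr <- utils::modifyList(list(ga_runs = 5, ga_pop = 50, ga_gens = 20,
                               soft = FALSE), protocol)
  t0 <- proc.time()["elapsed"]
  f <- trial$n_frames; m <- trial$n_muscles; d <- trial$n_dofs
  forces <- acts <- matrix(0, f, m,
                           dimnames = list(NULL, trial$muscle_names))
  QMT <- matrix(0, f, d)
  objective <- residual <- numeric(f)
  converged <- logical(f)
  prev <- NULL; lambda <- NULL; x_prev <- NULL

  for (j in seq_len(f)) {
    bb <- bounds_for_method(method, j, prev, trial, params, curves,
                            act_params)
    A_j <- trial$moment_arms[, , j, drop = FALSE]
    dim(A_j) <- c(d, m)
    b_j <- trial$QID[j, ]
    if (j == 1) {
      pen <- function(x) .frame_cost(x, crit, params) +
        1e4 * sum((drop(A_j %*% x) - b_j)^2) / max(1, max(abs(b_j)))^2
      x0 <- .with_seed(seed, .evolve_seed(pen, bb$FMin, bb$FMax,
                                          runs = pr$ga_runs, pop = pr$ga_pop,
                                          gens = pr$ga_gens))
    } else {
      x0 <- pmin(pmax(x_prev, bb$FMin), bb$FMax)
    }
    sol <- solve_frame(b_j, A_j, bb$FMin, bb$FMax, crit, params,
                       x0 = x0, lambda0 = lambda, tol = tol)
    if (!sol$feasible && !pr$soft)
      stop(sprintf("frame %d infeasible for method %s (min violation %.3g)",
                   j, method, attr(sol, "min_violation")))
    forces[j, ] <- sol$forces
    objective[j] <- sol$objective
    residual[j] <- sol$residual
    converged[j] <- isTRUE(sol$converged) && sol$feasible
    QMT[j, ] <- drop(A_j %*% sol$forces)
    lambda <- sol$lambda; x_prev <- sol$forces
    prev <- .update_state(method, j, prev, sol$forces, bb, trial, params,
                          curves, act_params)
    acts[j, ] <- prev$a
  }
  structure(list(forces = forces, activations = acts, QMT = QMT,
                 objective = objective, residual = residual,
                 converged = converged, method = method,
                 criterion = crit, seed = seed,
                 wall_time = unname(proc.time()["elapsed"] - t0)),
            class = "solver_result")
}

.frame_cost <- function(x, crit, params) {
  if (crit$kind == "minmax") max(x / params$F0M)
  else sum((x / .criterion_weights(crit, params))^crit$power)
}

# per-frame state update: activation consistent with the solved force
.update_state <- function(method, j, prev, F_j, bb, trial, params, curves,
                          act_params) {
  m <- trial$n_muscles
  if (method %in% c("SO", "PHY3")) {
    a <- .invert_activation(method, F_j, trial$lMT[j, ], trial$vMT[j, ],
                            params, curves)
    return(list(a = a, FMT = F_j))
  }
  if (method == "PHY2") {
    a <- .invert_activation("PHY2", F_j, trial$lMT[j, ], trial$vMT[j, ],
                            params, curves)
    if (j > 1) {
      ab <- activation_bounds(prev$a, trial$dt, act_params)
      a <- pmin(pmax(a, ab$aMin), ab$aMax)
    }
    return(list(a = a, FMT = F_j))
  }
  # PHY1: find the constant excitation reaching F_j over the step
  a <- numeric(m)
  for (i in seq_len(m)) {
    if (j == 1) {
      rng <- bb$FMax[i] - bb$FMin[i]
      a[i] <- if (rng > 1e-9) (F_j[i] - bb$FMin[i]) / rng else 0
      next
    }
    kin <- list(t = trial$t[(j - 1):j],
                lMT = trial$lMT[(j - 1):j, i],
                vMT = trial$vMT[(j - 1):j, i])
    a[i] <- .phy1_terminal_activation(F_j[i], muscle_state(prev$a[i],
                                                          max(prev$FMT[i], 0)),
                                      kin, params[i, ], curves, act_params,
                                      Flo = bb$FMin[i], Fhi = bb$FMax[i])
  }
  list(a = pmin(pmax(a, 0), 1), FMT = F_j)
}

.phy1_terminal_activation <- function(F_target, state, kin, params, curves,
                                      act_params, Flo = NULL, Fhi = NULL) {
  dt <- kin$t[2] - kin$t[1]
  # terminal forces at the excitation extremes are the already-computed
  # bounds; regula falsi on u needs only a few extra integrations
  if (is.null(Flo))
    Flo <- contract_integrate(0, state$a, state$FMT, kin, params, curves,
                              act_params)$FMT
  if (is.null(Fhi))
    Fhi <- contract_integrate(1, state$a, state$FMT, kin, params, curves,
                              act_params)$FMT
  glo <- Flo - F_target; ghi <- Fhi - F_target
  if (glo >= 0) return(activation_step(state$a, 0, dt, act_params))
  if (ghi <= 0) return(activation_step(state$a, 1, dt, act_params))
  ulo <- 0; uhi <- 1
  a_out <- state$a
  ftol <- 1e-4 * max(params$F0M, 1)
  for (it in 1:6) {
    u <- ulo - glo * (uhi - ulo) / (ghi - glo)
    u <- min(max(u, ulo + 1e-6), uhi - 1e-6)
    st <- contract_integrate(u, state$a, state$FMT, kin, params, curves,
                             act_params)
    g <- st$FMT - F_target
    a_out <- st$a
    if (abs(g) < ftol) break
    if (g < 0) { ulo <- u; glo <- g } else { uhi <- u; ghi <- g }
  }
  a_out
}

.invert_activation <- function(method, F_j, lMT, vMT, params, curves,
                               warn_tol = 0.05) {
  if (method == "SO") return(pmin(pmax(F_j / params$F0M, 0), 1))
  m <- nrow(params)
  geo <- rigid_fiber_geometry(matrix(lMT, 1, m), params)
  alpha <- as.numeric(geo$alpha); lbar <- as.numeric(geo$lbar)
  vbar <- .rigid_vbar(vMT, alpha, params$l0M, curves$vmax)
  pas <- if (curves$include_passive) curves$passive_fl(lbar) else 0
  denom <- curves$active_fl(lbar) * curves$fv(vbar)
  a <- (F_j / (params$F0M * cos(alpha)) - pas) / pmax(denom, 1e-9)
  if (any(a > 1 + warn_tol) || any(a < -warn_tol))
    warning("activation inversion outside [0, 1] beyond tolerance; clipped")
  pmin(pmax(a, 0), 1)
}

#' Muscle activations from solved forces
#'
#' Maps a matrix of solved muscle forces to activations: for static
#' optimization the conventional normalization \code{a = F/F0M}; for the
#' physiological (rigid tendon) variants the inversion of the active part of
#' the rigid-tendon force at the frame's kinematics, clipped to \[0, 1\]
#' (with a warning when the inversion overshoots beyond tolerance).
#'
#' @param forces f x m force matrix (N).
#' @param method \code{"SO"}, \code{"PHY1"}, \code{"PHY2"} or \code{"PHY3"}.
#' @param trial a \code{\link{gait_trial}}.
#' @param params \code{muscle_params}.
#' @param curves a \code{\link{hill_curves}} object.
#' @return f x m activation matrix in \[0, 1\].
#' @export
activations_from_forces <- function(forces, method, trial, params, curves) {
  f <- nrow(forces)
  out <- matrix(0, f, ncol(forces), dimnames = dimnames(forces))
  meth <- if (method == "SO") "SO" else "PHY3"
  for (j in seq_len(f))
    out[j, ] <- suppressWarnings(
      .invert_activation(meth, forces[j, ], trial$lMT[j, ], trial$vMT[j, ],
                         params, curves))
  out
}

#' @export
print.solver_result <- function(x, ...) {
  cat(sprintf("solver_result: %s", x$method))
  if (!is.null(x$criterion))
    cat(sprintf(" (criterion %s/%s)", x$criterion$kind, x$criterion$weight_rule))
  cat(sprintf(", %d frames x %d muscles\n", nrow(x$forces), ncol(x$forces)))
  cat(sprintf("  max equality residual: %.3g N m; converged frames: %d/%d\n",
              max(x$residual), sum(x$converged), length(x$converged)))
  cat(sprintf("  wall time: %.2f s\n", x$wall_time))
  invisible(x)
}
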