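#' Activation dynamics parameters
#'
#' First-order activation dynamics time constants. Defaults: 15 ms to
#' activate, 50 ms to deactivate.
#'
#' @param tau_act activation time constant (s).
#' @param tau_deact deactivation time constant (s).
#' @return a list of class \code{activation_params}.
#' @export
activation_params <- function(tau_act = 0.015, tau_deact = 0.050) {
  stopifnot(tau_act > 0, tau_deact > 0)
  structure(list(tau_act = tau_act, tau_deact = tau_deact),
            class = "activation_params")
}

#' Muscle state at one frame
#'
#' Activation, musculotendon force and the force bounds that constrained it.
#'
#' @param a activation in \[0, 1\].
#' @param FMT musculotendon force (N).
#' @param FMin,FMax lower/upper force bounds (N).
#' @return a list of class \code{muscle_state}.
#' @export
muscle_state <- function(a, FMT, FMin = 0, FMax = Inf) {
  stopifnot(a >= 0, a <= 1, FMin >= 0, FMin <= FMax)
  structure(list(a = a, FMT = FMT, FMin = FMin, FMax = FMax),
            class = "muscle_state")
}

.check_unit <- function(x, what) {
  if (any(x < 0) || any(x > 1))
    stop(what, " must lie in [0, 1]")
}

#' Activation rate
#'
#' First-order activation dynamics \code{da/dt = (u - a)/tau}, with
#' \code{tau = tau_act} when \code{a <= u} (activation builds up) and
#' \code{tau = tau_deact} otherwise. Vectorized.
#'
#' @param a activation in \[0, 1\].
#' @param u neural excitation in \[0, 1\].
#' @param params an \code{\link{activation_params}} object.
#' @return da/dt in 1/s.
#' @export
activation_rate <- function(a, u, params = activation_params()) {
  .check_unit(a, "activation"); .check_unit(u, "excitation")
  tau <- ifelse(a <= u, params$tau_act, params$tau_deact)
  (u - a) / tau
}

#' Exact discrete activation update
#'
#' Closed-form solution of the first-order activation dynamics over one step
#' with constant excitation:
#' \code{a(t_k) = u + (a(t_{k-1}) - u) * exp(-dt/tau)}, with the time
#' constant switched on \code{a(t_{k-1}) <= u}. When \code{a_prev = u} the
#' update is a fixed point and the branch choice is immaterial.
#'
#' @param a_prev previous activation in \[0, 1\].
#' @param u constant excitation over the step, in \[0, 1\].
#' @param dt step length (s), > 0.
#' @param params an \code{\link{activation_params}} object.
#' @return activation at the end of the step, in \[0, 1\]. Vectorized.
#' @export
activation_step <- function(a_prev, u, dt, params = activation_params()) {
  .check_unit(a_prev, "activation"); .check_unit(u, "excitation")
  if (any(dt <= 0)) stop("dt must be positive")
  tau <- ifelse(a_prev <= u, params$tau_act, params$tau_deact)
  pmin(pmax(u + (a_prev - u) * exp(-dt / tau), 0), 1)
}

#' Activation bounds over one step
#'
#' The activations reachable from \code{a_prev} in one step: holding the
#' excitation at 0 (full deactivation) gives the lower bound, holding it at 1
#' (full excitation) the upper bound.
#'
#' @inheritParams activation_step
#' @return a list with \code{aMin} and \code{aMax};
#'   \code{aMin <= a_prev <= aMax}.
#' @export
activation_bounds <- function(a_prev, dt, params = activation_params()) {
  list(aMin = activation_step(a_prev, 0, dt, params),
       aMax = activation_step(a_prev, 1, dt, params))
}

#' Static elastic-tendon force
#'
#' Isometric musculotendon force of the elastic-tendon model at a given
#' activation: the force at which the series-elastic equilibrium holds with
#' zero fiber velocity. Found by scalar root bracketing. Used for the static
#' initial condition of the physiological approach (frame 0 bounds from
#' a = 0 and a = 1 with zero fiber velocity).
#'
#' @param a activation in \[0, 1\].
#' @param lMT musculotendon length (m).
#' @param params single-row \code{muscle_params}.
#' @param curves a \code{\link{hill_curves}} object.
#' @return equilibrium force (N).
#' @export
static_elastic_force <- function(a, lMT, params, curves) {
  F0M <- params$F0M
  g <- function(FMT) {
    eps <- curves$tendon_fl_inv(FMT / F0M)
    seg <- lMT - params$lTs * (1 + eps)
    if (seg <= 0) return(-FMT - 1)  # force too high for the geometry
    lM <- sqrt(seg^2 + params$w_apo^2)
    lbar <- lM / params$l0M
    pas <- if (curves$include_passive) curves$passive_fl(lbar) else 0
    (a * curves$active_fl(lbar) + pas) * (seg / lM) * F0M - FMT
  }
  if (g(0) <= 0) return(0)
  upper <- 2 * F0M * curves$fv_max
  stats::uniroot(g, c(0, upper), tol = 1e-12 * F0M)$root
}

#' Force bounds by elastic-tendon extrapolation (PHY1)
#'
#' Extrapolates the previous frame's muscle state through feasible
#' musculotendon dynamics: the coupled activation + contraction ODE system is
#' integrated over one step twice, with the excitation held at 0 (lower
#' bound) and at 1 (upper bound), using the A-stable implicit trapezoidal
#' integrator of \code{\link{contract_integrate}} (the series-elastic tendon
#' makes the system stiff). Musculotendon kinematics are interpolated
#' linearly within the step.
#'
#' @param state a \code{\link{muscle_state}} at the previous frame.
#' @param kin a list with \code{t} (length-2 vector: step endpoints, s),
#'   \code{lMT} and \code{vMT} (length-2 vectors at the endpoints).
#' @param params single-row \code{muscle_params}.
#' @param curves a \code{\link{hill_curves}} object.
#' @param act_params an \code{\link{activation_params}} object.
#' @return a list with \code{FMin}, \code{FMax} (N, clipped so
#'   \code{0 <= FMin <= FMax}) and the terminal activations \code{aMin},
#'   \code{aMax}.
#' @export
force_bounds_phy1 <- function(state, kin, params, curves,
                              act_params = activation_params(),
                              n_sub = 10) {
  dt <- kin$t[2] - kin$t[1]
  if (dt < 0) stop("non-increasing step endpoints")
  if (dt == 0)
    return(list(FMin = state$FMT, FMax = state$FMT,
                aMin = state$a, aMax = state$a))
  lo <- contract_integrate(0, state$a, state$FMT, kin, params, curves,
                           act_params, n_sub)
  hi <- contract_integrate(1, state$a, state$FMT, kin, params, curves,
                           act_params, n_sub)
  FMin <- max(min(lo$FMT, hi$FMT), 0)
  FMax <- max(lo$FMT, hi$FMT, FMin)
  list(FMin = FMin, FMax = FMax,
       aMin = min(max(lo$a, 0), 1), aMax = min(max(hi$a, 0), 1))
}

#' Integrate the coupled musculotendon dynamics over one step
#'
#' Advances the coupled activation + elastic-tendon contraction dynamics of
#' one muscle across a single frame step at constant excitation. The
#' activation sub-state has the exact exponential solution, so only the
#' force state is integrated numerically, with an A-stable implicit
#' trapezoidal scheme (Newton iterations on the scalar stage equation) on
#' \code{n_sub} substeps; musculotendon kinematics are interpolated
#' linearly within the step. This is the workhorse behind the PHY1 force
#' bounds.
#'
#' @param u constant excitation over the step, in \[0, 1\].
#' @param a0,F0 state at the step start (activation; force, N).
#' @param kin list with length-2 vectors \code{t}, \code{lMT}, \code{vMT}
#'   at the step endpoints.
#' @param params single-row \code{muscle_params}.
#' @param curves a \code{\link{hill_curves}} object.
#' @param act_params an \code{\link{activation_params}} object.
#' @param n_sub number of substeps.
#' @return a list with terminal \code{a} and \code{FMT}.
#' @export
contract_integrate <- function(u, a0, F0, kin, params, curves,
                               act_params = activation_params(),
                               n_sub = 10) {
  params <- as.list(params[1, , drop = FALSE])  # fast field access in the hot loop
  dt <- kin$t[2] - kin$t[1]
  h <- dt / n_sub
  s_grid <- seq(0, 1, length.out = n_sub + 1)
  lMT_g <- (1 - s_grid) * kin$lMT[1] + s_grid * kin$lMT[2]
  vMT_g <- (1 - s_grid) * kin$vMT[1] + s_grid * kin$vMT[2]
  # exact activation trajectory (constant u keeps one branch of tau)
  a_g <- numeric(n_sub + 1); a_g[1] <- a0
  for (k in seq_len(n_sub))
    a_g[k + 1] <- activation_step(a_g[k], u, h, act_params)
  rhs <- function(FMT, k)
    contraction_ode(a_g[k], max(FMT, 0), lMT_g[k], vMT_g[k], params, curves,
                    quiet = TRUE)
  FMT <- F0
  Fscale <- max(params$F0M, 1)
  for (k in seq_len(n_sub)) {
    f0 <- rhs(FMT, k)
    # implicit-friendly predictor: start the corrector from the current
    # state (an explicit Euler guess overshoots badly on stiff tendons)
    F1 <- FMT
    gfun <- function(Fc) Fc - FMT - h / 2 * (f0 + rhs(Fc, k + 1))
    g <- gfun(F1)
    for (it in 1:30) {
      if (abs(g) < 1e-10 * Fscale) break
      dF <- 1e-7 * Fscale
      gp <- (gfun(F1 + dF) - g) / dF
      if (!is.finite(gp) || abs(gp) < 1e-12) gp <- 1
      step <- -g / gp
      # damped update: keep |g| decreasing
      for (ls in 1:30) {
        F_new <- max(F1 + step, 0)
        g_new <- gfun(F_new)
        if (abs(g_new) < abs(g)) break
        step <- step / 2
      }
      if (abs(g_new) >= abs(g)) break
      F1 <- F_new; g <- g_new
    }
    FMT <- max(F1, 0)
  }
  list(a = a_g[n_sub + 1], FMT = FMT)
}

#' Force bounds with rigid tendon and activation time response (PHY2)
#'
#' One-step activation bounds mapped through the rigid-tendon force at the
#' current frame's kinematics: the muscle cannot leave the force corridor
#' reachable by its activation dynamics within one time step.
#'
#' @param state a \code{\link{muscle_state}} at the previous frame (only its
#'   activation is used).
#' @param lMT,vMT current-frame musculotendon length (m) and velocity (m/s);
#'   vectors when \code{params} has multiple rows.
#' @param dt step length (s).
#' @param params \code{muscle_params} (1 or m rows).
#' @param curves a \code{\link{hill_curves}} object.
#' @param act_params an \code{\link{activation_params}} object.
#' @return a list with vectors \code{FMin}, \code{FMax}, \code{aMin},
#'   \code{aMax}.
#' @export
force_bounds_phy2 <- function(state, lMT, vMT, dt, params, curves,
                              act_params = activation_params()) {
  ab <- activation_bounds(state$a, dt, act_params)
  m <- nrow(params)
  FMin <- rigid_tendon_force(matrix(ab$aMin, 1, m), matrix(lMT, 1, m),
                             matrix(vMT, 1, m), params, curves)
  FMax <- rigid_tendon_force(matrix(ab$aMax, 1, m), matrix(lMT, 1, m),
                             matrix(vMT, 1, m), params, curves)
  list(FMin = pmin(FMin, FMax), FMax = pmax(FMin, FMax),
       aMin = ab$aMin, aMax = ab$aMax)
}

#' Force bounds with rigid tendon, activation time response ignored (PHY3)
#'
#' With \code{a(t) = u(t)} the whole activation range is reachable at every
#' frame, so the bounds are the rigid-tendon forces at a = 0 (passive floor)
#' and a = 1.
#'
#' @inheritParams force_bounds_phy2
#' @return a list with vectors \code{FMin} and \code{FMax}.
#' @export
force_bounds_phy3 <- function(lMT, vMT, params, curves) {
  m <- nrow(params)
  list(FMin = rigid_tendon_force(matrix(0, 1, m), matrix(lMT, 1, m),
                                 matrix(vMT, 1, m), params, curves),
       FMax = rigid_tendon_force(matrix(1, 1, m), matrix(lMT, 1, m),
                                 matrix(vMT, 1, m), params, curves))
}
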