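# Shared fixtures and independent oracles, all built in code.

# two- and three-muscle tables with simple geometry (zero pennation unless
# stated), convenient for closed-form checks
fix_muscles <- function(F0M = c(1000, 1500, 500), alpha0 = 0,
                        PCSA = F0M / 61) {
  m <- length(F0M)
  muscle_params(sprintf("mu%d", seq_len(m)), F0M = F0M,
                l0M = rep(0.10, m), lTs = rep(0.20, m),
                alpha0 = alpha0, PCSA = PCSA)
}

# a tiny constant-kinematics trial at the optimal fiber length
fix_trial_const <- function(params, QID_row, f = 5, dt = 0.01,
                            arms_row = NULL) {
  m <- nrow(params); d <- length(QID_row)
  if (is.null(arms_row)) arms_row <- matrix(0.05, d, m)
  lMT <- matrix(params$lTs + params$l0M * cos(params$alpha0),
                f, m, byrow = TRUE)
  gait_trial(t = seq(0, by = dt, length.out = f),
             QID = matrix(QID_row, f, d, byrow = TRUE),
             lMT = lMT, vMT = matrix(0, f, m),
             moment_arms = array(arms_row, c(d, m, f)),
             muscle_names = params$name)
}

# Exact oracle for min sum((x_i/k_i)^2) s.t. a'x = b, lo <= x <= up on
# small m: enumerate every active-set pattern (each variable free / at lo /
# at up), solve the free-coordinate stationarity in closed form, keep the
# best primal-feasible candidate. Independent of the package's dual solver.
oracle_poly_qp <- function(a, b, lo, up, k) {
  m <- length(a)
  states <- expand.grid(rep(list(0:2), m))  # 0 free, 1 at lo, 2 at up
  best <- NULL; best_obj <- Inf
  for (r in seq_len(nrow(states))) {
    st <- as.integer(states[r, ])
    x <- ifelse(st == 1, lo, ifelse(st == 2, up, NA))
    free <- which(st == 0)
    if (length(free) == 0) {
      if (abs(sum(a * x) - b) > 1e-9 * max(1, abs(b))) next
    } else {
      denom <- sum(a[free]^2 * k[free]^2)
      if (denom == 0) next
      # stationarity on the free set: x_i = c * k_i^2 * a_i, c from equality
      cc <- (b - sum((a * x)[st != 0])) / denom
      x[free] <- k[free]^2 * a[free] * cc
    }
    if (any(x < lo - 1e-9) || any(x > up + 1e-9)) next
    if (abs(sum(a * x) - b) > 1e-8 * max(1, abs(b))) next
    obj <- sum((x / k)^2)
    if (obj < best_obj) { best_obj <- obj; best <- x }
  }
  list(forces = best, objective = best_obj)
}

# Exact oracle for the min/max criterion with one equality constraint:
# bisection on the level t, with the box-hyperplane feasibility test done
# in closed form (interval of reachable a'x over the box).
oracle_minmax <- function(a, b, lo, up, F0M) {
  feasible <- function(t) {
    hi <- pmin(up, t * F0M)
    if (any(hi < lo - 1e-15)) return(FALSE)
    span_lo <- sum(pmin(a * lo, a * hi))
    span_hi <- sum(pmax(a * lo, a * hi))
    b >= span_lo - 1e-12 && b <= span_hi + 1e-12
  }
  t_hi <- max(up / F0M)
  if (!feasible(t_hi)) return(NULL)
  t_lo <- 0
  for (i in 1:200) {
    mid <- (t_lo + t_hi) / 2
    if (feasible(mid)) t_hi <- mid else t_lo <- mid
  }
  t_hi
}

# random feasible 1-DOF instances (bounded away from degeneracy)
random_instance <- function(m = 3) {
  a <- stats::runif(m, 0.02, 0.08) * sample(c(-1, 1), m, TRUE)
  F0M <- stats::runif(m, 300, 2500)
  lo <- rep(0, m); up <- F0M
  # pick b reachable strictly inside the span
  x_mid <- stats::runif(m, 0.1, 0.9) * F0M
  b <- sum(a * x_mid)
  list(a = a, b = b, lo = lo, up = up, F0M = F0M,
       PCSA = F0M / stats::runif(m, 40, 80))
}
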