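#' Number of B-spline nodes per synergy activation
#'
#' \code{p = (f - 1)/5 + 1}, rounded to the nearest integer (half away from
#' zero), where f is the number of frames.
#'
#' @param f frame count, >= 2.
#' @return integer node count p.
#' @examples
#' num_nodes(101)  # 21
#' @export
num_nodes <- function(f) {
  if (f < 2) stop("a synergy activation needs at least 2 frames")
  x <- (f - 1) / 5 + 1
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

#' Clamped B-spline basis matrix
#'
#' Evaluates a clamped, uniform-knot B-spline basis with \code{p} basis
#' functions at \code{f} uniformly spaced parameter values over \[0, 1\].
#' Rows sum to one (partition of unity), all entries are non-negative, and
#' the first/last rows are unit vectors at the first/last node, so constant
#' nodal values reproduce a constant trajectory and the endpoints
#' interpolate. Cubic by default; the degree is reduced when \code{p} is too
#' small to support it.
#'
#' @param f number of evaluation frames.
#' @param p number of basis functions (nodes), \code{2 <= p <= f}.
#' @param degree spline degree (default 3, cubic).
#' @return an f x p basis matrix.
#' @export
bspline_design <- function(f, p, degree = 3) {
  if (p < 2) stop("need at least 2 nodes")
  if (p > f) stop("more nodes than frames")
  deg <- min(degree, p - 1)
  ord <- deg + 1
  n_int <- p - ord
  knots <- c(rep(0, ord), seq_len(n_int) / (n_int + 1), rep(1, ord))
  x <- seq(0, 1, length.out = f)
  B <- splines::splineDesign(knots, pmin(x, 1 - 1e-12), ord = ord)
  B[1, ] <- c(1, rep(0, p - 1))
  B[f, ] <- c(rep(0, p - 1), 1)
  B
}

#' Synergy set
#'
#' The design variables of synergy optimization: a p x nS matrix of B-spline
#' nodal values (the time-varying synergy activations) and an nS x m matrix
#' of synergy vectors (time-invariant, non-negative weights, each row
#' summing to 1).
#'
#' @param nodes p x nS non-negative matrix of nodal values.
#' @param vectors nS x m non-negative matrix; rows must sum to 1.
#' @return a list of class \code{synergy_set} with \code{nodes},
#'   \code{vectors}, \code{nS}, \code{p}.
#' @export
synergy_set <- function(nodes, vectors) {
  nodes <- as.matrix(nodes); vectors <- as.matrix(vectors)
  if (ncol(nodes) != nrow(vectors))
    stop("nodes columns must match vectors rows (synergy count)")
  if (any(nodes < 0) || any(vectors < 0))
    stop("synergy nodal values and weights must be non-negative")
  if (any(abs(rowSums(vectors) - 1) > 1e-8))
    stop("each synergy vector must sum to 1")
  structure(list(nodes = nodes, vectors = vectors,
                 nS = ncol(nodes), p = nrow(nodes)),
            class = "synergy_set")
}

#' Synergy-constructed muscle activations
#'
#' Reconstructs the f x m activation matrix from a synergy set:
#' \code{a* = B \%*\% nodes \%*\% vectors}, with B the clamped B-spline
#' basis. Entries are non-negative by construction (and may exceed 1; the
#' optimization penalizes that).
#'
#' @param s a \code{\link{synergy_set}}.
#' @param f number of frames.
#' @param degree spline degree.
#' @return f x m activation matrix.
#' @export
synergy_activations <- function(s, f, degree = 3) {
  bspline_design(f, s$p, degree) %*% s$nodes %*% s$vectors
}

#' Synergy optimization configuration
#'
#' @param beta moment-tracking scale factor (default 100, the compromise
#'   between tracking and activation minimization).
#' @param lambda_pen penalty factor on activations outside \[0, 1\]
#'   (default 1e5).
#' @param nS synergy count (default 3).
#' @param degree B-spline degree.
#' @param restarts number of seeded random restarts.
#' @param maxit optimizer iteration cap per restart.
#' @return a list of class \code{syno_config}.
#' @export
syno_config <- function(beta = 100, lambda_pen = 1e5, nS = 3, degree = 3,
                        restarts = 5, maxit = 1500) {
  stopifnot(beta > 0, lambda_pen >= 0, nS >= 1)
  structure(list(beta = beta, lambda_pen = lambda_pen, nS = nS,
                 degree = degree, restarts = restarts, maxit = maxit),
            class = "syno_config")
}

# precompute the affine force map F = a* Gact + Gpas, the moment-arm array
# and the per-DOF normalizers
.syno_setup <- function(trial, params, curves, cfg) {
  f <- trial$n_frames; m <- trial$n_muscles
  geo <- rigid_fiber_geometry(trial$lMT, params)
  alpha <- as.matrix(geo$alpha); lbar <- as.matrix(geo$lbar)
  l0M <- matrix(params$l0M, f, m, byrow = TRUE)
  F0M <- matrix(params$F0M, f, m, byrow = TRUE)
  vbar <- .rigid_vbar(trial$vMT, alpha, l0M, curves$vmax)
  Gact <- curves$active_fl(lbar) * curves$fv(vbar) * F0M * cos(alpha)
  Gpas <- if (curves$include_passive)
    curves$passive_fl(lbar) * F0M * cos(alpha) else matrix(0, f, m)
  normQ <- apply(abs(trial$QID), 2, max)
  if (any(normQ == 0)) {
    warning("DOF with all-zero inverse-dynamics moment; normalizer set to 1")
    normQ[normQ == 0] <- 1
  }
  d <- trial$n_dofs
  # flattened moment-arm layout for vectorized moment mapping:
  # rows indexed by (dof, frame) with dof fastest
  Amat <- matrix(aperm(trial$moment_arms, c(1, 3, 2)), d * f, m)
  list(B = bspline_design(f, num_nodes(f), cfg$degree),
       Gact = Gact, Gpas = Gpas, normQ = normQ, f = f, m = m, d = d,
       Amat = Amat, jidx = rep(seq_len(f), each = d),
       p = num_nodes(f))
}

.syno_cost_core <- function(astar, setup, trial, cfg, grad = FALSE) {
  FMT <- astar * setup$Gact + setup$Gpas
  f <- setup$f; d <- setup$d
  QMT <- t(matrix(rowSums(setup$Amat * FMT[setup$jidx, , drop = FALSE]),
                  d, f))
  R <- sweep(QMT - trial$QID, 2, setup$normQ, "/")
  lam <- cfg$lambda_pen * (astar < 0 | astar > 1)
  cost <- cfg$beta * sum(R^2) + sum(astar^2 + lam * (astar - 1)^2)
  if (!grad) return(list(cost = cost, QMT = QMT))
  W <- sweep(R, 2, setup$normQ, "/") * (2 * cfg$beta)
  E <- rowsum(setup$Amat * as.vector(t(W)), setup$jidx)
  E <- E * setup$Gact + 2 * astar + 2 * lam * (astar - 1)
  list(cost = cost, QMT = QMT, E = E)
}

#' Synergy optimization cost
#'
#' The all-frame cost of synergy optimization: a scaled sum of squared
#' normalized moment-tracking errors (per DOF, normalized by the peak
#' absolute inverse-dynamics moment over the cycle) plus the activation
#' effort \code{a*^2} and a large penalty on activations outside \[0, 1\].
#' Forces are mapped from activations by the rigid-tendon model without
#' activation dynamics (as in PHY3).
#'
#' @param s a \code{\link{synergy_set}}.
#' @param trial a \code{\link{gait_trial}}.
#' @param cfg a \code{\link{syno_config}}.
#' @param params \code{muscle_params}.
#' @param curves a \code{\link{hill_curves}} object.
#' @return the scalar cost.
#' @export
syno_cost <- function(s, trial, cfg = syno_config(), params,
                      curves = hill_curves()) {
  setup <- .syno_setup(trial, params, curves, cfg)
  if (s$p != setup$p)
    setup$B <- bspline_design(trial$n_frames, s$p, cfg$degree)
  astar <- setup$B %*% s$nodes %*% s$vectors
  .syno_cost_core(astar, setup, trial, cfg)$cost
}

#' Solve the synergy optimization problem
#'
#' Minimizes the synergy-optimization cost over the B-spline nodal values
#' and synergy vectors, subject to non-negativity of all design variables
#' and each synergy vector summing to 1. The sum-to-one simplex constraint
#' is enforced by a softmax reparameterization of the vectors (exact at the
#' returned point); nodes are box-bounded at 0 inside L-BFGS-B; gradients
#' are analytic. Several seeded random restarts are run and the best kept.
#'
#' @param trial a \code{\link{gait_trial}}.
#' @param params \code{muscle_params}.
#' @param cfg a \code{\link{syno_config}}.
#' @param curves a \code{\link{hill_curves}} object.
#' @param seed integer seed driving the restarts.
#' @return a list with \code{synergy} (a \code{\link{synergy_set}}),
#'   \code{result} (a \code{solver_result} with activations, PHY3-mapped
#'   forces, reconstructed moments \code{QMT}, the final cost as
#'   \code{objective}) and \code{matching} (the mean moment-matching
#'   percentage, see \code{\link{moment_matching}}).
#' @export
solve_syno <- function(trial, params, cfg = syno_config(),
                       curves = hill_curves(), seed = 1) {
  t0 <- proc.time()["elapsed"]
  setup <- .syno_setup(trial, params, curves, cfg)
  p <- setup$p; nS <- cfg$nS; m <- setup$m
  n_nodes <- p * nS
  unpack <- function(par) {
    N <- matrix(par[seq_len(n_nodes)], p, nS)
    Z <- matrix(par[-seq_len(n_nodes)], nS, m)
    V <- exp(Z - apply(Z, 1, max))
    V <- V / rowSums(V)
    list(N = N, V = V)
  }
  fn <- function(par) {
    u <- unpack(par)
    astar <- setup$B %*% u$N %*% u$V
    .syno_cost_core(astar, setup, trial, cfg)$cost
  }
  gr <- function(par) {
    u <- unpack(par)
    astar <- setup$B %*% u$N %*% u$V
    E <- .syno_cost_core(astar, setup, trial, cfg, grad = TRUE)$E
    gN <- crossprod(setup$B, E %*% t(u$V))
    gV <- crossprod(setup$B %*% u$N, E)
    gZ <- u$V * (gV - matrix(rowSums(gV * u$V), nS, m))
    c(as.vector(gN), as.vector(gZ))
  }
  lower <- c(rep(0, n_nodes), rep(-Inf, nS * m))
  best <- NULL
  .with_seed(seed, {
    for (r in seq_len(cfg$restarts)) {
      par0 <- c(stats::runif(n_nodes, 0, 0.5), stats::rnorm(nS * m))
      f0 <- fn(par0)
      opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B", lower = lower,
                          control = list(maxit = cfg$maxit, factr = 1e4))
      if (opt$value > f0 + 1e-12) opt <- list(par = par0, value = f0,
                                              convergence = 1)
      if (is.null(best) || opt$value < best$value) best <- opt
    }
  })
  u <- unpack(best$par)
  syn <- synergy_set(u$N, u$V)
  astar <- setup$B %*% u$N %*% u$V
  core <- .syno_cost_core(astar, setup, trial, cfg)
  FMT <- astar * setup$Gact + setup$Gpas
  res <- structure(list(forces = FMT, activations = astar, QMT = core$QMT,
                        objective = best$value,
                        residual = apply(abs(core$QMT - trial$QID), 1, max),
                        converged = rep(best$convergence == 0, setup$f),
                        method = "SynO", criterion = NULL, seed = seed,
                        wall_time = unname(proc.time()["elapsed"] - t0)),
                   class = "solver_result")
  list(synergy = syn, result = res,
       matching = moment_matching(core$QMT, trial$QID))
}

#' Moment-matching percentage
#'
#' Agreement between reconstructed and inverse-dynamics joint moments,
#' reported as \code{100 * (1 - RMS(QMT_k - QID_k)/RMS(QID_k))} per DOF
#' (RMS over frames) and averaged over DOFs.
#'
#' @param QMT,QID f x d moment matrices (N m).
#' @param by_dof return the per-DOF percentages instead of their mean.
#' @return matching percentage (scalar, or length-d vector).
#' @export
moment_matching <- function(QMT, QID, by_dof = FALSE) {
  rms <- function(x) sqrt(mean(x^2))
  per <- vapply(seq_len(ncol(QID)), function(k)
    100 * (1 - rms(QMT[, k] - QID[, k]) / rms(QID[, k])), numeric(1))
  if (by_dof) per else mean(per)
}
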