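#' Muscle recruitment criterion
#'
#' Specification of the per-frame recruitment cost. Polynomial criteria
#' minimize \code{sum((F_i/k_i)^power)} with the weight \code{k_i} given by
#' the weight rule: \code{unit} (raw forces, criterion I), \code{F0M}
#' (relative forces, criterion II), or \code{PCSA} (stresses, criterion III).
#' The min/max criterion (criterion IV) minimizes the largest relative force
#' \code{max(F_i/F0M_i)}.
#'
#' @param kind \code{"poly"} or \code{"minmax"}.
#' @param weight_rule \code{"unit"}, \code{"F0M"} or \code{"PCSA"}; min/max
#'   always uses \code{F0M}.
#' @param power polynomial exponent, >= 1 (default 2, the squared form).
#' @return a list of class \code{criterion_spec}.
#' @export
criterion_spec <- function(kind = c("poly", "minmax"),
                           weight_rule = c("unit", "F0M", "PCSA"),
                           power = 2) {
  kind <- match.arg(kind); weight_rule <- match.arg(weight_rule)
  if (power < 1) stop("power must be >= 1")
  if (kind == "minmax") weight_rule <- "F0M"
  structure(list(kind = kind, weight_rule = weight_rule, power = power),
            class = "criterion_spec")
}

#' Standard recruitment criteria I-IV
#'
#' @param which \code{"I"} (squared forces), \code{"II"} (squared relative
#'   forces), \code{"III"} (squared stresses) or \code{"IV"} (min/max
#'   relative force).
#' @return a \code{\link{criterion_spec}}.
#' @export
so_criterion <- function(which = c("I", "II", "III", "IV")) {
  switch(match.arg(which),
         I = criterion_spec("poly", "unit"),
         II = criterion_spec("poly", "F0M"),
         III = criterion_spec("poly", "PCSA"),
         IV = criterion_spec("minmax"))
}

.criterion_weights <- function(crit, params) {
  switch(crit$weight_rule,
         unit = rep(1, nrow(params)),
         F0M = params$F0M,
         PCSA = params$PCSA)
}

# Primal point of the separable convex dual: x_i = clamp(h(nu_i), lo, up)
# where h inverts the stationarity w x^(w-1) / k^w = nu.
.primal_from_nu <- function(nu, k, w, lo, up) {
  x <- ifelse(nu > 0, k * (pmax(nu, 0) * k / w)^(1 / (w - 1)), 0)
  pmin(pmax(x, lo), up)
}

# Dual semismooth Newton for: min sum (x_i/k_i)^w  s.t.  A x = b, lo<=x<=up.
# g(lambda) = A x(A'lambda) - b is monotone; finite convergence for w = 2.
.solve_poly_qp <- function(A, b, lo, up, k, w = 2, lambda0 = NULL,
                           tol = 1e-10, maxit = 200) {
  d <- nrow(A)
  K2 <- k^2 / 2                      # interior dual scale (w = 2 form)
  if (is.null(lambda0)) {
    # unconstrained-interior solution as the starting dual point
    lambda0 <- tryCatch(
      drop(solve(A %*% (t(A) * K2) + diag(d) * 1e-12, b)),
      error = function(e) rep(0, d))
  }
  lambda <- lambda0
  dprime <- function(nu, x) {
    # d x / d nu of x = k (nu k / w)^(1/(w-1)) on the unclamped set
    free <- x > lo + 1e-14 * pmax(1, up) & x < up - 1e-14 * pmax(1, up) &
      nu > 0
    ifelse(free, (k^(w / (w - 1)) / ((w - 1) * w^(1 / (w - 1)))) *
             pmax(nu, 1e-300)^((2 - w) / (w - 1)), 0)
  }
  scale_b <- max(1, max(abs(b)))
  gval <- function(lambda) {
    nu <- drop(crossprod(A, lambda))
    x <- .primal_from_nu(nu, k, w, lo, up)
    list(g = drop(A %*% x) - b, x = x, nu = nu)
  }
  st <- gval(lambda)
  for (it in seq_len(maxit)) {
    if (max(abs(st$g)) <= tol * scale_b) break
    Dp <- dprime(st$nu, st$x)
    J <- A %*% (t(A) * Dp)
    # regularize on the interior dual scale so a fully-clamped active set
    # still produces a sane step length
    scaleJ <- max(abs(A %*% (t(A) * K2)))
    J <- J + diag(d) * (1e-10 * scaleJ + 1e-8 * max(abs(J)))
    step <- tryCatch(solve(J, -st$g), error = function(e) -st$g)
    # damped line search on ||g||^2
    base <- sum(st$g^2); alpha <- 1; ok <- FALSE
    for (ls in 1:60) {
      cand <- gval(lambda + alpha * step)
      if (sum(cand$g^2) < base) { ok <- TRUE; break }
      alpha <- alpha / 2
    }
    if (!ok) break
    lambda <- lambda + alpha * step
    st <- cand
  }
  obj <- sum((st$x / k)^w)
  list(forces = st$x, lambda = lambda, objective = obj,
       residual = max(abs(st$g)),
       converged = max(abs(st$g)) <= 1e-6 * scale_b)
}

# Minimal L1 constraint violation over the box (feasibility phase-1 LP).
.feasibility_lp <- function(A, b, lo, up) {
  d <- nrow(A); m <- ncol(A)
  ub <- up - lo
  b3 <- b - drop(A %*% lo)
  sgn <- ifelse(b3 < 0, -1, 1)
  A3 <- cbind(A * sgn, diag(sgn, d), -diag(sgn, d))
  obj <- c(rep(0, m), rep(1, 2 * d))
  res <- boot::simplex(a = obj,
                       A1 = cbind(diag(1, m), matrix(0, m, 2 * d)), b1 = ub,
                       A3 = A3, b3 = b3 * sgn, maxi = FALSE)
  list(violation = res$value, x = lo + res$soln[seq_len(m)],
       solved = res$solved == 1)
}

# Criterion IV: min t s.t. F_i <= t*F0M_i, A F = b, box; then lexicographic
# tie-break minimizing sum (F_i/F0M_i)^2 at the optimal level.
.solve_minmax <- function(A, b, lo, up, F0M, tol = 1e-10) {
  d <- nrow(A); m <- ncol(A)
  ub <- up - lo
  b3 <- b - drop(A %*% lo)
  sgn <- ifelse(b3 < 0, -1, 1)
  # variables: y (shifted forces), t
  A3 <- cbind(A * sgn, 0)
  A1 <- cbind(diag(1, m), 0)                    # y <= ub
  A2 <- cbind(-diag(1, m), F0M)                 # t*F0M - y >= lo
  res <- boot::simplex(a = c(rep(0, m), 1), A1 = A1, b1 = ub,
                       A2 = A2, b2 = lo, A3 = A3, b3 = b3 * sgn,
                       maxi = FALSE)
  x_lp <- lo + res$soln[seq_len(m)]
  lp_resid <- max(abs(drop(A %*% x_lp) - b))
  if (res$solved != 1 && lp_resid > tol * max(1, max(abs(b))))
    return(list(forces = x_lp, objective = NA_real_,
                residual = lp_resid, converged = FALSE, level = NA_real_))
  level <- max(res$soln[m + 1], max(x_lp / F0M))
  # tie-break: quadratic relative-force polish under the optimal level
  cap <- pmin(up, level * F0M * (1 + 1e-9) + 1e-12)
  qp <- .solve_poly_qp(A, b, lo, pmax(cap, lo), F0M, w = 2)
  x <- if (qp$converged) qp$forces else x_lp
  list(forces = x, lambda = qp$lambda, objective = max(x / F0M),
       residual = max(abs(drop(A %*% x) - b)),
       converged = TRUE, level = level)
}

#' Solve the muscle force-sharing problem at one frame
#'
#' Minimizes the recruitment cost subject to the moment equality constraints
#' \code{A \%*\% F = QID} and the per-muscle force bounds. Polynomial
#' criteria are solved by a dual semismooth-Newton active-set method (exact
#' for the convex separable cost); the min/max criterion is solved by its
#' linear-programming reformulation with an auxiliary level variable,
#' followed by a quadratic relative-force tie-break that makes the
#' (generally non-unique) min/max solution deterministic.
#'
#' @param QID_j joint moment vector at the frame (N m), length d.
#' @param A_j d x m moment-arm matrix at the frame (m).
#' @param FMin,FMax force bounds (N), length m, \code{0 <= FMin <= FMax}.
#' @param crit a \code{\link{criterion_spec}}.
#' @param params \code{muscle_params} (supplies the criterion weights).
#' @param x0 optional warm-start force vector (used to initialize the dual).
#' @param lambda0 optional warm-start dual vector.
#' @param tol equality-constraint tolerance, relative to
#'   \code{max(1, max(abs(QID_j)))}.
#' @return a list of class \code{frame_solution}: \code{forces},
#'   \code{objective}, \code{residual}, \code{converged}, \code{feasible},
#'   \code{lambda} and, for min/max, the optimal \code{level}.
#' @examples
#' mp <- muscle_params(c("a", "b"), F0M = c(1000, 1000), l0M = 0.1,
#'                     lTs = 0.2, alpha0 = 0, PCSA = 16)
#' solve_frame(5, matrix(c(1, 2), 1), c(0, 0), c(10, 10),
#'             so_criterion("I"), mp)$forces   # c(1, 2): least-norm
#' @export
solve_frame <- function(QID_j, A_j, FMin, FMax, crit, params,
                        x0 = NULL, lambda0 = NULL, tol = 1e-6) {
  A_j <- as.matrix(A_j); b <- as.numeric(QID_j)
  m <- ncol(A_j)
  if (length(FMin) != m || length(FMax) != m)
    stop("bounds must have one entry per muscle")
  if (any(FMin > FMax + 1e-12)) stop("FMin must not exceed FMax")
  FMin <- pmax(FMin, 0); FMax <- pmax(FMax, FMin)
  scale_b <- max(1, max(abs(b)))

  if (crit$kind == "minmax") {
    sol <- .solve_minmax(A_j, b, FMin, FMax, params$F0M)
  } else if (crit$power == 1) {
    # linear cost: plain LP on shifted variables
    k <- .criterion_weights(crit, params)
    ub <- FMax - FMin
    b3 <- b - drop(A_j %*% FMin)
    sgn <- ifelse(b3 < 0, -1, 1)
    res <- boot::simplex(a = 1 / k, A1 = diag(1, m), b1 = ub,
                         A3 = A_j * sgn, b3 = b3 * sgn, maxi = FALSE)
    x <- FMin + res$soln[seq_len(m)]
    sol <- list(forces = x, lambda = NULL, objective = sum(x / k),
                residual = max(abs(drop(A_j %*% x) - b)),
                converged = res$solved == 1)
  } else {
    k <- .criterion_weights(crit, params)
    # near-degenerate bound widths (e.g. silent muscles under physiological
    # corridors) pin the variable; solve the reduced problem over the rest
    wid <- FMax - FMin
    pin <- wid <= 1e-9 * pmax(1, FMax)
    if (is.null(lambda0) && !is.null(x0)) {
      # dual guess from interior stationarity at the warm-start point
      nu0 <- crit$power * pmax(x0, 0)^(crit$power - 1) / k^crit$power
      lambda0 <- tryCatch(
        solve(A_j %*% t(A_j) + diag(nrow(A_j)) * 1e-10, A_j %*% nu0),
        error = function(e) NULL)
      if (!is.null(lambda0)) lambda0 <- drop(lambda0)
    }
    if (any(pin) && !all(pin)) {
      mid <- (FMin + FMax) / 2
      b_red <- b - drop(A_j[, pin, drop = FALSE] %*% mid[pin])
      red <- .solve_poly_qp(A_j[, !pin, drop = FALSE], b_red,
                            FMin[!pin], FMax[!pin], k[!pin],
                            w = crit$power, lambda0 = lambda0)
      x_full <- numeric(m); x_full[pin] <- mid[pin]
      x_full[!pin] <- red$forces
      sol <- red
      sol$forces <- x_full
      sol$objective <- sum((x_full / k)^crit$power)
      sol$residual <- max(abs(drop(A_j %*% x_full) - b))
    } else {
      sol <- .solve_poly_qp(A_j, b, FMin, FMax, k, w = crit$power,
                            lambda0 = lambda0)
    }
  }

  feasible <- sol$residual <= tol * scale_b
  if (!feasible) {
    fe <- .feasibility_lp(A_j, b, FMin, FMax)
    if (fe$violation > tol * scale_b) {
      sol$forces <- fe$x
      sol$converged <- FALSE
      attr(sol, "min_violation") <- fe$violation
    } else if (crit$kind != "minmax") {
      # feasible but Newton stalled: restart from the LP point
      nu0 <- crit$power * pmax(fe$x, 0)^(crit$power - 1) /
        .criterion_weights(crit, params)^crit$power
      l0 <- drop(solve(A_j %*% t(A_j) + diag(nrow(A_j)) * 1e-10,
                       A_j %*% nu0))
      sol2 <- .solve_poly_qp(A_j, b, FMin, FMax,
                             .criterion_weights(crit, params),
                             w = crit$power, lambda0 = l0, maxit = 500)
      if (sol2$residual <= tol * scale_b) {
        sol <- sol2
        feasible <- TRUE
      } else {
        # frame is feasible (the LP proved it) but the dual iteration
        # cannot resolve it: keep the LP's feasible point, unconverged
        sol$forces <- fe$x
        sol$objective <- .frame_cost(fe$x, crit, params)
        sol$converged <- FALSE
        feasible <- TRUE
      }
    } else {
      # minmax with a sloppy LP point but a feasible frame: keep the
      # phase-1 feasible point, unconverged
      sol$forces <- fe$x
      sol$objective <- .frame_cost(fe$x, crit, params)
      sol$converged <- FALSE
      feasible <- TRUE
    }
  }
  sol$feasible <- feasible
  sol$residual <- max(abs(drop(A_j %*% sol$forces) - b))
  class(sol) <- "frame_solution"
  sol
}
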