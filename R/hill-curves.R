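#' Hill-type musculotendon characteristic curves
#'
#' Builds the set of dimensionless characteristic curves of a Hill-type
#' musculotendon actuator: active force-length, passive force-length,
#' force-velocity, and tendon force-strain, together with the analytic
#' inverses needed by the elastic-tendon contraction dynamics.
#'
#' The functional forms are the widely used smooth ones: a Gaussian active
#' force-length curve, an exponential passive force-length curve, a hyperbolic
#' (Hill) concentric force-velocity branch joined C1-continuously to a
#' saturating eccentric branch, and an exponential-toe-then-linear tendon.
#' All coefficients are exposed so alternative parameterisations can be
#' swapped in.
#'
#' Velocity convention: the normalized fiber velocity \code{vbar} is the fiber
#' velocity divided by \code{vmax * l0M}, negative when the fiber shortens, so
#' the concentric branch lives on \code{vbar} in \[-1, 0\] with
#' \code{fv(-1) = 0} and \code{fv(0) = 1}.
#'
#' @param fl_gamma shape factor of the Gaussian active force-length curve.
#' @param pe_k exponential shape factor of the passive force-length curve.
#' @param pe_e0 passive strain at which the passive force reaches one
#'   maximal isometric force.
#' @param fv_af Hill constant of the concentric force-velocity branch.
#' @param fv_max eccentric force-velocity plateau (multiple of isometric
#'   force).
#' @param t_ftoe normalized tendon force at the end of the exponential toe
#'   region.
#' @param t_ktoe exponential shape factor of the tendon toe region.
#' @param t_e0 tendon strain at one maximal isometric force.
#' @param vmax maximal fiber contraction velocity in optimal fiber lengths
#'   per second (used to normalize fiber velocities).
#' @param include_passive logical; include the parallel passive element in
#'   the rigid-tendon force (the strict activation-scaled form drops it).
#'
#' @return An object of class \code{hill_curves}: a list with the curve
#'   functions \code{active_fl}, \code{passive_fl}, \code{fv}, \code{fv_inv},
#'   \code{tendon_fl}, \code{tendon_fl_inv}, \code{tendon_stiffness} (all
#'   vectorized) and the coefficients.
#' @examples
#' cv <- hill_curves()
#' cv$active_fl(1)        # 1 at optimal length
#' cv$fv(0)               # 1 at zero velocity
#' cv$tendon_fl(0)        # slack tendon transmits no force
#' @export
hill_curves <- function(fl_gamma = 0.45,
                        pe_k = 4,
                        pe_e0 = 0.6,
                        fv_af = 0.25,
                        fv_max = 1.4,
                        t_ftoe = 0.33,
                        t_ktoe = 3,
                        t_e0 = 0.04,
                        vmax = 10,
                        include_passive = TRUE) {
  stopifnot(fl_gamma > 0, pe_k > 0, pe_e0 > 0, fv_af > 0, fv_max > 1,
            t_ftoe > 0, t_ktoe > 0, t_e0 > 0, vmax > 0)

  t_etoe <- 0.609 * t_e0
  t_klin <- 1.712 / t_e0
  # eccentric constant chosen for slope continuity at vbar = 0:
  # concentric slope 1 + 1/af must equal (fv_max - 1)/fv_c
  fv_c <- (fv_max - 1) / (1 + 1 / fv_af)

  active_fl <- function(lbar) exp(-(lbar - 1)^2 / fl_gamma)

  passive_fl <- function(lbar) {
    out <- (exp(pe_k * (lbar - 1) / pe_e0) - 1) / (exp(pe_k) - 1)
    out[lbar <= 1] <- 0
    out
  }

  fv <- function(vbar) {
    vbar <- pmax(vbar, -1)
    conc <- (1 + vbar) / (1 - vbar / fv_af)
    ecc <- (fv_max * vbar + fv_c) / (vbar + fv_c)
    ifelse(vbar <= 0, conc, ecc)
  }

  # inverse of fv; values outside (0, fv_max) are clamped to the curve domain
  fv_inv <- function(y) {
    eps <- 1e-9
    y <- pmin(pmax(y, 0), fv_max - eps)
    conc <- fv_af * (y - 1) / (fv_af + y)
    ecc <- fv_c * (y - 1) / (fv_max - y)
    ifelse(y <= 1, conc, ecc)
  }

  tendon_fl <- function(strain) {
    toe <- t_ftoe / (exp(t_ktoe) - 1) * (exp(t_ktoe * strain / t_etoe) - 1)
    lin <- t_klin * (strain - t_etoe) + t_ftoe
    out <- ifelse(strain <= t_etoe, toe, lin)
    out[strain <= 0] <- 0
    out
  }

  tendon_fl_inv <- function(fbar) {
    fbar <- pmax(fbar, 0)
    toe <- t_etoe / t_ktoe * log1p(fbar * (exp(t_ktoe) - 1) / t_ftoe)
    lin <- t_etoe + (fbar - t_ftoe) / t_klin
    out <- ifelse(fbar <= t_ftoe, toe, lin)
    out[fbar <= 0] <- 0
    out
  }

  # d(tendon_fl)/d(strain), zero below slack
  tendon_stiffness <- function(strain) {
    toe <- t_ftoe / (exp(t_ktoe) - 1) * (t_ktoe / t_etoe) *
      exp(t_ktoe * strain / t_etoe)
    out <- ifelse(strain <= t_etoe, toe, t_klin)
    out[strain <= 0] <- 0
    out
  }

  structure(
    list(active_fl = active_fl, passive_fl = passive_fl,
         fv = fv, fv_inv = fv_inv,
         tendon_fl = tendon_fl, tendon_fl_inv = tendon_fl_inv,
         tendon_stiffness = tendon_stiffness,
         fl_gamma = fl_gamma, pe_k = pe_k, pe_e0 = pe_e0,
         fv_af = fv_af, fv_max = fv_max, fv_c = fv_c,
         t_ftoe = t_ftoe, t_ktoe = t_ktoe, t_e0 = t_e0,
         t_etoe = t_etoe, t_klin = t_klin,
         vmax = vmax, include_passive = include_passive),
    class = "hill_curves")
}

#' @export
print.hill_curves <- function(x, ...) {
  cat("Hill-type characteristic curves\n")
  cat(sprintf("  active fl: Gaussian (gamma = %.3g)\n", x$fl_gamma))
  cat(sprintf("  passive fl: exponential (k = %.3g, e0 = %.3g)\n",
              x$pe_k, x$pe_e0))
  cat(sprintf("  fv: Hill hyperbolic (af = %.3g), eccentric plateau %.3g\n",
              x$fv_af, x$fv_max))
  cat(sprintf("  tendon: toe + linear (e0 = %.3g)\n", x$t_e0))
  cat(sprintf("  vmax = %.3g l0M/s; passive element %s\n",
              x$vmax, if (x$include_passive) "included" else "dropped"))
  invisible(x)
}
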