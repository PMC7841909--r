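#' Muscle parameter table
#'
#' Constructs and validates the per-muscle Hill parameter table used across
#' the package: maximal isometric force \code{F0M} (N), optimal fiber length
#' \code{l0M} (m), tendon slack length \code{lTs} (m), pennation angle at
#' optimal fiber length \code{alpha0} (rad) and physiological cross-sectional
#' area \code{PCSA} (cm^2). The constant inter-aponeurosis width
#' \code{w_apo = l0M * sin(alpha0)} (m) is derived and kept consistent by all
#' operations that rescale \code{l0M}.
#'
#' @param name character vector of muscle labels.
#' @param F0M,l0M,lTs,alpha0,PCSA numeric vectors (recycled to a common
#'   length) with the units above.
#' @return A data frame of class \code{muscle_params}, one row per muscle.
#' @examples
#' mp <- muscle_params("vasmed", F0M = 1294, l0M = 0.089, lTs = 0.126,
#'                     alpha0 = 0.087, PCSA = 21)
#' mp$w_apo  # l0M * sin(alpha0)
#' @export
muscle_params <- function(name, F0M, l0M, lTs, alpha0 = 0, PCSA = F0M / 61) {
  df <- data.frame(name = as.character(name), F0M = F0M, l0M = l0M,
                   lTs = lTs, alpha0 = alpha0, PCSA = PCSA,
                   stringsAsFactors = FALSE)
  df$w_apo <- df$l0M * sin(df$alpha0)
  class(df) <- c("muscle_params", "data.frame")
  validate_muscle_params(df)
}

#' Validate a muscle parameter table
#'
#' Checks positivity of forces, lengths and areas, the pennation range
#' \code{[0, pi/2)}, and that \code{w_apo} equals \code{l0M * sin(alpha0)} to
#' machine precision. Called by all constructors; exported so externally read
#' tables can be checked.
#'
#' @param params a \code{muscle_params} data frame.
#' @return \code{params}, invisibly validated (errors on violation).
#' @export
validate_muscle_params <- function(params) {
  req <- c("name", "F0M", "l0M", "lTs", "alpha0", "PCSA", "w_apo")
  miss <- setdiff(req, names(params))
  if (length(miss))
    stop("muscle table is missing columns: ", paste(miss, collapse = ", "))
  with(params, {
    if (any(!is.finite(F0M)) || any(F0M <= 0)) stop("F0M must be positive")
    if (any(!is.finite(l0M)) || any(l0M <= 0)) stop("l0M must be positive")
    if (any(!is.finite(lTs)) || any(lTs < 0)) stop("lTs must be non-negative")
    if (any(!is.finite(PCSA)) || any(PCSA <= 0)) stop("PCSA must be positive")
    if (any(alpha0 < 0) || any(alpha0 >= pi / 2))
      stop("alpha0 must lie in [0, pi/2)")
    if (any(abs(w_apo - l0M * sin(alpha0)) >
              4 * .Machine$double.eps * pmax(1, l0M)))
      stop("w_apo inconsistent with l0M * sin(alpha0)")
  })
  if (!inherits(params, "muscle_params"))
    class(params) <- c("muscle_params", class(params))
  params
}

#' Read a muscle parameter table from CSV
#'
#' Expects a header \code{name,F0M,l0M,lTs,alpha0,PCSA} with units N, m, m,
#' rad, cm^2; \code{w_apo} is derived.
#'
#' @param path path to the CSV file.
#' @return a validated \code{muscle_params} data frame.
#' @export
read_muscle_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  muscle_params(df$name, df$F0M, df$l0M, df$lTs, df$alpha0, df$PCSA)
}

#' Packaged default muscle table
#'
#' A synthetic 43-muscle right-leg table with parameters in physiological
#' ranges, styled on the standard lower-limb OpenSim muscle set. The values
#' are a constructed stand-in, not the original model's data.
#'
#' @return a validated \code{muscle_params} data frame with 43 rows.
#' @export
default_muscle_table <- function() {
  read_muscle_table(system.file("extdata", "gait_muscles_synthetic.csv",
                                package = "gaitmuscle", mustWork = TRUE))
}

#' Subject-specific scaling of musculotendon length parameters
#'
#' Scales tendon slack length and optimal fiber length by the ratio of the
#' subject's musculotendon length in the standing position to that of the
#' generic model; the pennation angle of the reference is kept and the
#' inter-aponeurosis width is recomputed from the scaled \code{l0M}.
#'
#' @param generic a \code{muscle_params} table (any number of rows).
#' @param lMT_subject_standing,lMT_generic_standing standing musculotendon
#'   lengths (m), scalars or per-muscle vectors; both must be positive.
#' @return the scaled \code{muscle_params} table.
#' @examples
#' mp <- muscle_params("m", 1000, 0.10, 0.20, 0.1, 16)
#' scale_length_params(mp, 0.33, 0.30)  # l0M -> 0.11, lTs -> 0.22
#' @export
scale_length_params <- function(generic, lMT_subject_standing,
                                lMT_generic_standing) {
  if (any(lMT_subject_standing <= 0) || any(lMT_generic_standing <= 0))
    stop("standing musculotendon lengths must be positive")
  ratio <- lMT_subject_standing / lMT_generic_standing
  out <- generic
  out$l0M <- generic$l0M * ratio
  out$lTs <- generic$lTs * ratio
  out$w_apo <- out$l0M * sin(out$alpha0)
  validate_muscle_params(out)
}

#' Rigid-tendon fiber geometry
#'
#' Under the rigid-tendon assumption the tendon stays at its slack length, so
#' fiber length and pennation follow from the musculotendon length alone:
#' \code{alpha = arctan(w_apo / (lMT - lTs))} and
#' \code{lM = (lMT - lTs) / cos(alpha)}.
#'
#' @param lMT musculotendon length(s) (m): a vector (one muscle over frames)
#'   or an f x m matrix (frames x muscles).
#' @param params \code{muscle_params} with 1 row (vector input) or m rows
#'   (matrix input).
#' @return a list of class \code{fiber_geometry} with elements \code{lM},
#'   \code{alpha}, \code{lbar} (\code{= lM/l0M}), each shaped like
#'   \code{lMT}.
#' @examples
#' mp <- muscle_params("m", 1000, 0.10, 0.30, 0, 16)
#' rigid_fiber_geometry(0.5, mp)$lM  # 0.2
#' @export
rigid_fiber_geometry <- function(lMT, params) {
  lMT <- as.matrix(lMT)
  if (nrow(params) == 1 && ncol(lMT) == 1) {
    # single muscle, column of frames
  } else if (ncol(lMT) != nrow(params)) {
    stop("lMT columns must match the number of muscles")
  }
  lTs <- rep(params$lTs, each = nrow(lMT))
  w <- rep(params$w_apo, each = nrow(lMT))
  l0M <- rep(params$l0M, each = nrow(lMT))
  seg <- lMT - lTs
  if (any(seg <= 0)) {
    bad <- which(seg <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "degenerate geometry: lMT <= lTs for muscle '%s' at frame %d",
      params$name[min(bad[2], nrow(params))], bad[1]))
  }
  alpha <- atan2(w, seg)
  lM <- sqrt(seg^2 + w^2)          # = seg / cos(alpha)
  out <- list(lM = drop(array(lM, dim(lMT))),
              alpha = drop(array(alpha, dim(lMT))),
              lbar = drop(array(lM / l0M, dim(lMT))))
  class(out) <- "fiber_geometry"
  out
}

#' Clamp the optimal fiber length to the motion
#'
#' Final step of the subject-specific scaling: the scaled optimal fiber
#' length is set to the maximum approximated (rigid-tendon) fiber length over
#' the motion, so the normalized fiber length peaks at exactly 1 and stays
#' inside the physiological window (0.5, 1.2]. Because the inter-aponeurosis
#' width itself depends on \code{l0M}, the update is iterated to its fixed
#' point (a contraction; converges in a handful of steps), after which both
#' \code{w_apo = l0M*sin(alpha0)} and \code{max lbar = 1} hold to machine
#' precision.
#'
#' A warning (not an error) is raised if the clamped trajectory dips below
#' the 0.5 lower bound of the physiological window.
#'
#' @param params \code{muscle_params} (1 or m rows).
#' @param lMT_trajectory numeric vector (one muscle) or f x m matrix of
#'   musculotendon lengths over the motion (m).
#' @return the updated \code{muscle_params} table.
#' @export
clamp_optimal_length <- function(params, lMT_trajectory) {
  lMT <- as.matrix(lMT_trajectory)
  if (nrow(lMT) < 1 || !all(is.finite(lMT))) stop("trajectory must be a non-empty finite series")
  out <- params
  for (it in 1:100) {
    geo <- rigid_fiber_geometry(lMT, out)
    lM <- as.matrix(geo$lM)
    l0_new <- apply(lM, 2, max)
    if (max(abs(l0_new - out$l0M) / out$l0M) < 1e-15) break
    out$l0M <- l0_new
    out$w_apo <- out$l0M * sin(out$alpha0)
  }
  out$l0M <- apply(as.matrix(rigid_fiber_geometry(lMT, out)$lM), 2, max)
  out$w_apo <- out$l0M * sin(out$alpha0)
  lbar <- as.matrix(rigid_fiber_geometry(lMT, out)$lbar)
  if (any(lbar < 0.5))
    warning("normalized fiber length below 0.5 for: ",
            paste(out$name[apply(lbar < 0.5, 2, any)], collapse = ", "))
  validate_muscle_params(out)
}

# normalized fiber velocity under the rigid tendon: differentiating
# lM*cos(alpha) = lMT - lTs with constant w_apo gives vM = vMT*cos(alpha)
.rigid_vbar <- function(vMT, alpha, l0M, vmax) {
  (vMT * cos(alpha)) / (vmax * l0M)
}

#' Rigid-tendon musculotendon force
#'
#' Force transmitted to the skeleton by a Hill-type actuator with a rigid
#' tendon: \code{(a * fl(lbar) * fv(vbar) + fp(lbar)) * F0M * cos(alpha)},
#' with fiber kinematics from \code{\link{rigid_fiber_geometry}} and the
#' normalized fiber velocity \code{vbar = vMT*cos(alpha)/(vmax*l0M)}. The
#' parallel passive term is included by default and dropped when the curve
#' set was built with \code{include_passive = FALSE}, which reduces the
#' expression to the strict activation-scaled form \code{a * g(lMT, vMT)}.
#'
#' @param a activation(s) in \[0, 1\], shaped like \code{lMT}.
#' @param lMT,vMT musculotendon length (m) and velocity (m/s), vectors or
#'   f x m matrices.
#' @param params \code{muscle_params} (1 or m rows).
#' @param curves a \code{\link{hill_curves}} object.
#' @return musculotendon force(s) in N, non-negative, shaped like \code{lMT}.
#' @examples
#' mp <- muscle_params("m", 1000, 0.10, 0.30, 0, 16)
#' cv <- hill_curves()
#' rigid_tendon_force(1, lMT = 0.40, vMT = 0, mp, cv)  # F0M at optimum
#' @export
rigid_tendon_force <- function(a, lMT, vMT, params, curves) {
  if (any(a < -1e-12) || any(a > 1 + 1e-12))
    stop("activation must lie in [0, 1]")
  a <- pmin(pmax(a, 0), 1)
  geo <- rigid_fiber_geometry(lMT, params)
  dims <- dim(as.matrix(lMT))
  l0M <- rep(params$l0M, each = dims[1])
  F0M <- rep(params$F0M, each = dims[1])
  alpha <- array(geo$alpha, dims)
  lbar <- array(geo$lbar, dims)
  vbar <- .rigid_vbar(array(vMT, dims), alpha, l0M, curves$vmax)
  act <- a * curves$active_fl(lbar) * curves$fv(vbar)
  pas <- if (curves$include_passive) curves$passive_fl(lbar) else 0
  drop(array(pmax((act + pas) * F0M * cos(alpha), 0), dims))
}

#' Elastic-tendon contraction dynamics
#'
#' Rate of change of the musculotendon force for the elastic-tendon Hill
#' model, obtained from the series equilibrium: the tendon strain is found by
#' inverting the tendon force-strain curve at \code{FMT/F0M}; the fiber
#' length and pennation follow from the musculotendon length minus the tendon
#' length (constant inter-aponeurosis width); the fiber velocity is found by
#' inverting the force-velocity curve at the fiber force balance; and
#' \code{dF/dt} is the tendon stiffness times the tendon lengthening rate.
#'
#' When the force balance asks for a force-velocity value outside the curve's
#' range (e.g. near-zero active capacity), the query is clamped to the curve
#' domain and the fiber velocity to \[-vmax, +vmax\]; a warning is emitted
#' unless \code{quiet = TRUE} (the bound-extrapolation integrator runs
#' quiet).
#'
#' @param a activation in \[0, 1\].
#' @param FMT current musculotendon force (N), non-negative.
#' @param lMT,vMT musculotendon length (m) and velocity (m/s).
#' @param params single-row \code{muscle_params}.
#' @param curves a \code{\link{hill_curves}} object.
#' @param quiet suppress clamping warnings.
#' @return dF/dt in N/s.
#' @export
contraction_ode <- function(a, FMT, lMT, vMT, params, curves, quiet = FALSE) {
  if (FMT < 0) {
    if (!quiet) warning("negative musculotendon force clamped to 0")
    FMT <- 0
  }
  F0M <- params$F0M; lTs <- params$lTs; l0M <- params$l0M; w <- params$w_apo
  eps <- curves$tendon_fl_inv(FMT / F0M)
  lT <- lTs * (1 + eps)
  seg <- lMT - lT
  if (seg <= 0)
    stop(sprintf("degenerate geometry in contraction dynamics for '%s'",
                 params$name))
  lM <- sqrt(seg^2 + w^2)
  cosa <- seg / lM
  lbar <- lM / l0M
  fm <- (FMT / cosa) / F0M                    # normalized fiber force
  pas <- if (curves$include_passive) curves$passive_fl(lbar) else 0
  fl <- curves$active_fl(lbar)
  denom <- a * fl
  clamped <- FALSE
  if (denom > 1e-8) {
    target <- (fm - pas) / denom
    clamped <- target < 0 || target > curves$fv_max - 1e-9
    vbar <- curves$fv_inv(target)
    if (abs(vbar) > 1) { vbar <- sign(vbar); clamped <- TRUE }
  } else if (fm - pas > 1e-10) {
    vbar <- 1; clamped <- TRUE      # force demanded with no active capacity
  } else {
    vbar <- 0                       # no drive, no load: fiber follows
  }
  if (clamped && !quiet)
    warning("force-velocity query clamped to the curve domain")
  vM <- vbar * curves$vmax * l0M
  vT <- vMT - vM / cosa
  # below slack the toe-region right-limit stiffness is kept so F = 0 is not
  # an absorbing fixed point (the force state may dip marginally below zero
  # and is clamped at use); keeps the ODE right-hand side continuous
  kT <- curves$tendon_stiffness(max(eps, 1e-9))
  F0M * kT * vT / lTs
}
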