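#' Synthetic cohort configuration
#'
#' Conditions for the synthetic gait generator: one gait cycle per trial,
#' moments and musculotendon kinematics at 100 Hz, EMG-like signals at
#' 1 kHz, 43 muscles actuating 6 degrees of freedom, ten subjects. The
#' cycle duration of 1 s gives the canonical 101-frame cycle.
#'
#' @param n_subjects cohort size.
#' @param n_muscles muscles per leg model (>= 2 * n_dofs so every DOF has
#'   agonists and antagonists).
#' @param n_dofs actuated degrees of freedom.
#' @param duration cycle duration (s).
#' @param frame_rate trial sampling rate (Hz).
#' @param emg_rate EMG sampling rate (Hz).
#' @param emg_noise measurement-noise level of the EMG emulation, as a
#'   fraction of the carrier amplitude (0 = noise free).
#' @param n_emg number of EMG channels (first \code{n_emg} muscles).
#' @param mode ground-truth construction: \code{"least_norm"} (forces are
#'   the squared-force-optimal solution of smooth feasible moments, so the
#'   SO criterion-I solve recovers them) or \code{"synergy"} (activations
#'   are an exact low-rank synergy product mapped through the rigid-tendon
#'   model).
#' @param nS synergy count for synergy mode.
#' @param const_specific_tension if TRUE, PCSA is proportional to F0M.
#' @param seed integer seed; a fixed seed makes the cohort byte-identical.
#' @return a list of class \code{synth_config}.
#' @export
synth_config <- function(n_subjects = 10, n_muscles = 43, n_dofs = 6,
                         duration = 1.0, frame_rate = 100, emg_rate = 1000,
                         emg_noise = 0.05, n_emg = 9,
                         mode = c("least_norm", "synergy"), nS = 3,
                         const_specific_tension = FALSE, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(frame_rate > 0, emg_rate > 0, duration > 0,
            n_muscles >= n_dofs, n_subjects >= 1)
  structure(list(n_subjects = n_subjects, n_muscles = n_muscles,
                 n_dofs = n_dofs, duration = duration,
                 frame_rate = frame_rate, emg_rate = emg_rate,
                 emg_noise = emg_noise, n_emg = min(n_emg, n_muscles),
                 mode = mode, nS = nS,
                 const_specific_tension = const_specific_tension,
                 seed = seed),
            class = "synth_config")
}

#' Generate a synthetic muscle table
#'
#' Draws \code{n_muscles} parameter rows in physiological lower-limb
#' ranges: F0M in \[100, 3000\] N, l0M in \[0.05, 0.15\] m, lTs in
#' \[0.05, 0.45\] m, alpha0 in \[0, 0.35\] rad. PCSA is F0M divided by a
#' specific tension, constant across muscles when
#' \code{const_specific_tension} is set.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @return a validated \code{muscle_params} table.
#' @export
gen_muscles <- function(cfg) {
  .with_seed(cfg$seed * 1000L + 1L, {
    m <- cfg$n_muscles
    F0M <- stats::runif(m, 100, 3000)
    sigma <- if (cfg$const_specific_tension) rep(61, m) else
      stats::runif(m, 40, 80)
    muscle_params(name = sprintf("m%02d", seq_len(m)),
                  F0M = F0M,
                  l0M = stats::runif(m, 0.05, 0.15),
                  lTs = stats::runif(m, 0.05, 0.45),
                  alpha0 = stats::runif(m, 0, 0.35),
                  PCSA = F0M / sigma)
  })
}

#' Generate smooth gait-cycle musculotendon kinematics and moment arms
#'
#' Musculotendon lengths are sums of 1-3 cycle-frequency harmonics around
#' the neutral length \code{lTs + l0M*cos(alpha0)}, with total amplitude
#' bounded at 15% of the fiber projection so \code{lMT > lTs} always holds;
#' velocities are the analytic derivative. Moment arms are smooth, bounded
#' by 0.08 m, sign-constant per entry, and each DOF is actuated by at least
#' two muscles of opposite sign at every frame.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param muscles a \code{muscle_params} table.
#' @param subject subject index (offsets the seed).
#' @return a list with \code{t}, \code{lMT}, \code{vMT} (f x m) and
#'   \code{moment_arms} (d x m x f).
#' @export
gen_kinematics <- function(cfg, muscles, subject = 1) {
  .with_seed(cfg$seed * 1000L + 10L + subject, {
    m <- cfg$n_muscles; d <- cfg$n_dofs; T <- cfg$duration
    t <- seq(0, T, by = 1 / cfg$frame_rate)
    f <- length(t)
    lMT <- vMT <- matrix(0, f, m, dimnames = list(NULL, muscles$name))
    for (i in seq_len(m)) {
      seg0 <- muscles$l0M[i] * cos(muscles$alpha0[i])
      nh <- sample(1:3, 1)
      amp <- stats::runif(nh); amp <- amp / sum(amp) *
        stats::runif(1, 0.05, 0.15) * seg0
      phi <- stats::runif(nh, 0, 2 * pi)
      L <- muscles$lTs[i] + seg0
      li <- rep(L, f); vi <- rep(0, f)
      for (h in seq_len(nh)) {
        wh <- 2 * pi * h / T
        li <- li + amp[h] * sin(wh * t + phi[h])
        vi <- vi + amp[h] * wh * cos(wh * t + phi[h])
      }
      lMT[, i] <- li; vMT[, i] <- vi
    }
    if (any(lMT <= matrix(muscles$lTs, f, m, byrow = TRUE)))
      stop("kinematics amplitude violates lMT > lTs")
    # each muscle gets a primary DOF; sign alternates so every DOF has
    # agonists and antagonists
    arms <- array(0, c(d, m, f))
    for (i in seq_len(m)) {
      dof <- ((i - 1) %% d) + 1
      sgn <- if ((((i - 1) %/% d) %% 2) == 0) 1 else -1
      c0 <- stats::runif(1, 0.03, 0.055)
      e0 <- stats::runif(1, 0, 0.4) * c0
      phi <- stats::runif(1, 0, 2 * pi)
      arms[dof, i, ] <- sgn * (c0 + e0 * sin(2 * pi * t / T + phi))
      # weak secondary action on a neighboring DOF
      dof2 <- (dof %% d) + 1
      c2 <- stats::runif(1, 0.005, 0.02)
      arms[dof2, i, ] <- sgn * c2 * (1 + 0.3 * sin(2 * pi * t / T +
                                                     stats::runif(1, 0, 2 * pi)))
    }
    list(t = t, lMT = lMT, vMT = vMT, moment_arms = arms)
  })
}

#' Generate ground-truth activations, forces and feasible joint moments
#'
#' Moments are derived from forces (never the reverse) so the moment
#' equality constraints are feasible by construction. In
#' \code{least_norm} mode smooth feasible moments are drawn by pushing a
#' smooth activation pattern through the moment arms, and the emitted
#' ground-truth forces are the squared-force (criterion I) optimum of those
#' moments, so the SO-I solve recovers them. In \code{synergy} mode a
#' rank-nS non-negative activation matrix is built from smooth synergy
#' activations and weight vectors, mapped through the rigid-tendon model
#' (as PHY3 does) to forces.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param muscles a \code{muscle_params} table (after length clamping).
#' @param kin output of \code{\link{gen_kinematics}}.
#' @param curves a \code{\link{hill_curves}} object.
#' @param subject subject index (offsets the seed).
#' @return a list with \code{activations}, \code{forces} (f x m) and
#'   \code{QID} (f x d).
#' @export
gen_ground_truth <- function(cfg, muscles, kin, curves = hill_curves(),
                             subject = 1) {
  f <- nrow(kin$lMT); m <- cfg$n_muscles; d <- cfg$n_dofs
  .with_seed(cfg$seed * 1000L + 100L + subject, {
    if (cfg$mode == "synergy") {
      t <- kin$t; T <- cfg$duration
      C <- matrix(0, f, cfg$nS)
      for (s in seq_len(cfg$nS)) {
        ctr <- stats::runif(1, 0.1, 0.9) * T
        wid <- stats::runif(1, 0.08, 0.2) * T
        dist <- pmin(abs(t - ctr), T - abs(t - ctr))  # periodic bump
        C[, s] <- stats::runif(1, 0.3, 0.8) * exp(-dist^2 / (2 * wid^2)) +
          stats::runif(1, 0.02, 0.08)
      }
      V <- matrix(stats::rexp(cfg$nS * m), cfg$nS, m)
      V <- V / rowSums(V)
      astar <- C %*% V
      astar <- astar * (0.8 / max(astar))
      FMT <- rigid_tendon_force(astar, kin$lMT, kin$vMT, muscles, curves)
      QID <- .map_moments(kin$moment_arms, FMT)
      return(list(activations = astar, forces = FMT, QID = QID))
    }
    # least_norm mode: smooth feasible seed forces -> moments -> SO-I optimum
    for (try in 1:20) {
      a_seed <- matrix(0, f, m)
      t <- kin$t; T <- cfg$duration
      for (i in seq_len(m)) {
        # moderate walking-effort activations (well under maximal)
        lev <- stats::runif(1, 0.05, 0.25)
        a_seed[, i] <- lev + lev * 0.8 *
          sin(2 * pi * sample(1:2, 1) * t / T + stats::runif(1, 0, 2 * pi))
      }
      F_seed <- a_seed * matrix(muscles$F0M, f, m, byrow = TRUE)
      QID <- .map_moments(kin$moment_arms, F_seed)
      crit <- so_criterion("I")
      FMT <- matrix(0, f, m)
      ok <- TRUE
      lam <- NULL
      for (j in seq_len(f)) {
        A_j <- matrix(kin$moment_arms[, , j], d, m)
        sol <- solve_frame(QID[j, ], A_j, rep(0, m), muscles$F0M, crit,
                           muscles, lambda0 = lam)
        if (!sol$feasible) { ok <- FALSE; break }
        FMT[j, ] <- sol$forces; lam <- sol$lambda
      }
      if (ok) break
    }
    if (!ok) stop("could not draw a feasible least-norm ground truth")
    list(activations = FMT / matrix(muscles$F0M, f, m, byrow = TRUE),
         forces = FMT, QID = QID)
  })
}

.map_moments <- function(arms, FMT) {
  f <- nrow(FMT); d <- dim(arms)[1]
  Q <- matrix(0, f, d)
  for (j in seq_len(f)) Q[j, ] <- matrix(arms[, , j], d, ncol(FMT)) %*% FMT[j, ]
  Q
}

#' Generate EMG-like signals from activations
#'
#' Emulates surface EMG at the EMG rate: each selected muscle's activation
#' is upsampled by spline interpolation and used as the amplitude envelope
#' of band-limited (20-450 Hz) zero-mean Gaussian carrier noise, plus white
#' measurement noise at the configured level. Rectifying and low-pass
#' filtering the output recovers an envelope that correlates with the input
#' activation.
#'
#' @param activations f x m activation matrix at the trial rate.
#' @param cfg a \code{\link{synth_config}}.
#' @param subject subject index (offsets the seed).
#' @param channels muscle column indices to emulate (default the first
#'   \code{n_emg}).
#' @param muscle_names optional labels.
#' @return a list of \code{\link{emg_record}} objects, one per channel.
#' @export
gen_emg <- function(activations, cfg, subject = 1,
                    channels = seq_len(cfg$n_emg), muscle_names = NULL) {
  if (any(activations < -1e-9) || any(activations > 1 + 1e-9))
    stop("activations must lie in [0, 1]")
  .with_seed(cfg$seed * 1000L + 200L + subject, {
    n_out <- round(cfg$duration * cfg$emg_rate) + 1
    bf <- signal::butter(4, c(20, 450) / (cfg$emg_rate / 2), type = "pass")
    lapply(channels, function(i) {
      env <- resample_series(activations[, i], cfg$frame_rate,
                             cfg$emg_rate, n_out = n_out)
      env <- pmax(env, 0)
      carrier <- signal::filtfilt(bf, stats::rnorm(n_out))
      carrier <- carrier / max(stats::sd(carrier), 1e-12)
      raw <- env * carrier + cfg$emg_noise * stats::rnorm(n_out)
      emg_record(raw, fs = cfg$emg_rate,
                 muscle = if (is.null(muscle_names)) sprintf("m%02d", i)
                 else muscle_names[i])
    })
  })
}

#' Generate one synthetic subject
#'
#' Draws kinematics for the shared muscle set, applies the motion-based
#' optimal-fiber-length clamp (so normalized fiber lengths peak at 1),
#' builds the ground truth and the trial, and emulates the EMG channels.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param muscles a \code{muscle_params} table (defaults to a fresh
#'   \code{\link{gen_muscles}} draw).
#' @param subject subject index.
#' @param curves a \code{\link{hill_curves}} object.
#' @return a list with \code{trial} (\code{\link{gait_trial}}),
#'   \code{muscles} (clamped table), \code{truth} (activations, forces,
#'   QID) and \code{emg} (list of records).
#' @export
gen_subject <- function(cfg, muscles = gen_muscles(cfg), subject = 1,
                        curves = hill_curves()) {
  kin <- gen_kinematics(cfg, muscles, subject)
  muscles_c <- suppressWarnings(clamp_optimal_length(muscles, kin$lMT))
  truth <- gen_ground_truth(cfg, muscles_c, kin, curves, subject)
  trial <- gait_trial(kin$t, truth$QID, kin$lMT, kin$vMT, kin$moment_arms,
                      muscle_names = muscles_c$name)
  # electrodes go on the most active muscles, as in a real protocol
  chan <- order(colMeans(truth$activations), decreasing = TRUE)[
    seq_len(cfg$n_emg)]
  chan <- sort(chan)
  emg <- gen_emg(truth$activations, cfg, subject, channels = chan,
                 muscle_names = muscles_c$name)
  list(trial = trial, muscles = muscles_c, truth = truth, emg = emg,
       emg_channels = chan)
}

#' Generate a synthetic cohort
#'
#' One shared muscle draw; per-subject kinematics, ground truth and EMG.
#' Byte-reproducible under a fixed config seed.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param curves a \code{\link{hill_curves}} object.
#' @return a list of subjects (see \code{\link{gen_subject}}).
#' @export
gen_cohort <- function(cfg, curves = hill_curves()) {
  muscles <- gen_muscles(cfg)
  lapply(seq_len(cfg$n_subjects), function(s)
    gen_subject(cfg, muscles, subject = s, curves = curves))
}
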