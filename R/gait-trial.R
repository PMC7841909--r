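#' Gait trial container
#'
#' One gait cycle of solver inputs: a uniform time grid, inverse-dynamics
#' joint moments for the actuated degrees of freedom, per-muscle
#' musculotendon lengths and velocities, and per-frame moment-arm matrices
#' mapping muscle forces to joint moments.
#'
#' @param t uniform time grid (s), length f.
#' @param QID f x d matrix of inverse-dynamics joint moments (N m).
#' @param lMT,vMT f x m matrices of musculotendon lengths (m) and velocities
#'   (m/s).
#' @param moment_arms d x m x f array of moment arms (m); frame j's matrix
#'   \code{moment_arms[, , j]} maps the force vector to the d joint moments.
#' @param muscle_names optional character vector of length m.
#' @return an object of class \code{gait_trial}.
#' @export
gait_trial <- function(t, QID, lMT, vMT, moment_arms, muscle_names = NULL) {
  t <- as.numeric(t); QID <- as.matrix(QID)
  lMT <- as.matrix(lMT); vMT <- as.matrix(vMT)
  f <- length(t)
  if (f < 2) stop("a trial needs at least 2 frames")
  dt <- diff(t)
  if (any(abs(dt - dt[1]) > 1e-9 * dt[1])) stop("time grid must be uniform")
  if (nrow(QID) != f || nrow(lMT) != f || nrow(vMT) != f)
    stop("QID, lMT and vMT must have one row per frame")
  if (!all(dim(lMT) == dim(vMT))) stop("lMT and vMT dimensions differ")
  d <- ncol(QID); m <- ncol(lMT)
  if (!is.array(moment_arms) || length(dim(moment_arms)) != 3 ||
      !all(dim(moment_arms) == c(d, m, f)))
    stop("moment_arms must be a d x m x f array matching QID/lMT")
  if (!all(is.finite(t)) || !all(is.finite(QID)) || !all(is.finite(lMT)) ||
      !all(is.finite(vMT)) || !all(is.finite(moment_arms)))
    stop("trial contains non-finite values")
  if (is.null(muscle_names)) muscle_names <- colnames(lMT)
  if (is.null(muscle_names)) muscle_names <- sprintf("m%02d", seq_len(m))
  structure(list(t = t, QID = QID, lMT = lMT, vMT = vMT,
                 moment_arms = moment_arms, muscle_names = muscle_names,
                 dt = dt[1], n_frames = f, n_dofs = d, n_muscles = m),
            class = "gait_trial")
}

#' @export
print.gait_trial <- function(x, ...) {
  cat(sprintf("gait_trial: %d frames @ %.0f Hz, %d DOFs, %d muscles\n",
              x$n_frames, 1 / x$dt, x$n_dofs, x$n_muscles))
  invisible(x)
}

#' Write / read a gait trial as plain-text CSV
#'
#' The trial is stored as two CSVs: a wide per-frame table
#' (\code{<stem>.csv}: time, moments \code{Q1..Qd}, then \code{lMT_*} and
#' \code{vMT_*} columns per muscle) and a long moment-arm table
#' (\code{<stem>_arms.csv}: frame, dof, muscle, arm).
#'
#' @param trial a \code{\link{gait_trial}}.
#' @param stem path stem (no extension).
#' @return \code{write_trial} returns the stem invisibly; \code{read_trial}
#'   returns a \code{gait_trial}.
#' @export
write_trial <- function(trial, stem) {
  wide <- data.frame(time = trial$t)
  for (k in seq_len(trial$n_dofs)) wide[[paste0("Q", k)]] <- trial$QID[, k]
  for (i in seq_len(trial$n_muscles)) {
    wide[[paste0("lMT_", trial$muscle_names[i])]] <- trial$lMT[, i]
    wide[[paste0("vMT_", trial$muscle_names[i])]] <- trial$vMT[, i]
  }
  utils::write.csv(wide, paste0(stem, ".csv"), row.names = FALSE)
  idx <- expand.grid(dof = seq_len(trial$n_dofs),
                     muscle = seq_len(trial$n_muscles),
                     frame = seq_len(trial$n_frames))
  arms <- data.frame(frame = idx$frame, dof = idx$dof,
                     muscle = trial$muscle_names[idx$muscle],
                     arm = as.vector(trial$moment_arms))
  utils::write.csv(arms, paste0(stem, "_arms.csv"), row.names = FALSE)
  invisible(stem)
}

#' @rdname write_trial
#' @export
read_trial <- function(stem) {
  wide <- utils::read.csv(paste0(stem, ".csv"))
  arms <- utils::read.csv(paste0(stem, "_arms.csv"))
  qcols <- grep("^Q[0-9]+$", names(wide), value = TRUE)
  lcols <- grep("^lMT_", names(wide), value = TRUE)
  vcols <- grep("^vMT_", names(wide), value = TRUE)
  names_m <- sub("^lMT_", "", lcols)
  f <- nrow(wide); d <- length(qcols); m <- length(lcols)
  A <- array(0, c(d, m, f))
  mi <- match(arms$muscle, names_m)
  A[cbind(arms$dof, mi, arms$frame)] <- arms$arm
  gait_trial(wide$time, as.matrix(wide[qcols]), as.matrix(wide[lcols]),
             as.matrix(wide[vcols]), A, muscle_names = names_m)
}

#' Minimal OpenSim storage-format text I/O
#'
#' Reads and writes the simple column-oriented \code{.sto}/\code{.mot} text
#' dialect (header with \code{nRows}/\code{nColumns}, \code{endheader},
#' tab-separated columns, first column time). Only the plain uncompressed
#' text form is supported; used to exchange moments or musculotendon
#' kinematics with OpenSim-based toolchains.
#'
#' @param path file path.
#' @return \code{read_sto} returns a data frame whose first column is time.
#' @export
read_sto <- function(path) {
  lines <- readLines(path)
  hdr_end <- which(trimws(lines) == "endheader")
  if (length(hdr_end) != 1) stop("not a storage file: no endheader line")
  utils::read.table(text = lines[-seq_len(hdr_end)], header = TRUE,
                    sep = "\t", check.names = FALSE)
}

#' @rdname read_sto
#' @param df data frame, first column time.
#' @param name dataset name written into the header.
#' @export
write_sto <- function(df, path, name = "gaitmuscle") {
  hdr <- c(name, "version=1",
           sprintf("nRows=%d", nrow(df)), sprintf("nColumns=%d", ncol(df)),
           "inDegrees=no", "endheader",
           paste(names(df), collapse = "\t"))
  body <- apply(df, 1, function(r)
    paste(formatC(r, format = "g", digits = 12), collapse = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}
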