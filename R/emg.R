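#' EMG record
#'
#' A raw surface EMG signal with its sampling rate and muscle label.
#'
#' @param raw numeric signal (arbitrary units).
#' @param fs sampling rate (Hz).
#' @param muscle muscle label.
#' @return a list of class \code{emg_record}.
#' @export
emg_record <- function(raw, fs = 1000, muscle = "") {
  stopifnot(fs > 0, is.numeric(raw))
  structure(list(raw = as.numeric(raw), fs = fs, muscle = muscle),
            class = "emg_record")
}

#' EMG linear envelope
#'
#' Full-wave rectification followed by smoothing and normalization to unit
#' peak. Two smoothing modes: the zero-phase low-pass Butterworth filter
#' (order 5, 6 Hz cut-off, applied forward and reverse) and singular
#' spectrum analysis (window length 250 samples), which reconstructs the
#' slow trend from the leading eigencomponents; the two are practically
#' equivalent on gait EMG. The Butterworth path is the canonical one since
#' it is fully determined by its order and cut-off; the SSA grouping rule
#' keeps the components whose eigenvalue share exceeds a threshold.
#'
#' @param raw numeric signal or an \code{\link{emg_record}}.
#' @param fs sampling rate (Hz); taken from the record if one is given.
#' @param mode \code{"butterworth"} or \code{"ssa"}.
#' @param cutoff low-pass cut-off (Hz).
#' @param order Butterworth order.
#' @param ssa_window SSA embedding window (samples).
#' @param ssa_share minimum eigenvalue share for an SSA component to enter
#'   the reconstruction.
#' @return envelope signal in \[0, 1\] with max exactly 1.
#' @export
envelope <- function(raw, fs = 1000, mode = c("butterworth", "ssa"),
                     cutoff = 6, order = 5, ssa_window = 250,
                     ssa_share = 0.01) {
  if (inherits(raw, "emg_record")) { fs <- raw$fs; raw <- raw$raw }
  mode <- match.arg(mode)
  if (!all(is.finite(raw))) stop("signal contains non-finite values")
  rect <- abs(raw)
  if (max(rect) == 0) stop("cannot normalize an all-zero signal")
  if (mode == "butterworth") {
    if (length(rect) < 3 * (order + 1))
      stop("signal shorter than the filter warm-up")
    bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
    # reflective padding suppresses the zero-phase filter's edge transients
    n <- length(rect)
    pad <- min(n - 1, 9 * ceiling(fs / cutoff))
    xp <- c(2 * rect[1] - rect[(pad + 1):2],
            rect,
            2 * rect[n] - rect[(n - 1):(n - pad)])
    env <- signal::filtfilt(bf, xp)[(pad + 1):(pad + n)]
  } else {
    env <- .ssa_trend(rect, L = min(ssa_window, floor(length(rect) / 2)),
                      share = ssa_share)
  }
  env <- pmax(env, 0)
  if (max(env) == 0) stop("envelope vanished after filtering")
  env / max(env)
}

# SSA trend extraction: embed, SVD, keep components by eigenvalue share,
# reconstruct by diagonal (anti-diagonal) averaging.
.ssa_trend <- function(x, L, share) {
  n <- length(x); K <- n - L + 1
  X <- matrix(0, L, K)
  for (i in seq_len(L)) X[i, ] <- x[i:(i + K - 1)]
  sv <- svd(X)
  lam <- sv$d^2
  keep <- which(lam / sum(lam) >= share)
  if (!length(keep)) keep <- 1
  Y <- sv$u[, keep, drop = FALSE] %*%
    (t(sv$v[, keep, drop = FALSE]) * sv$d[keep])
  out <- numeric(n); cnt <- numeric(n)
  for (i in seq_len(L)) {
    idx <- i:(i + K - 1)
    out[idx] <- out[idx] + Y[i, ]
    cnt[idx] <- cnt[idx] + 1
  }
  out / cnt
}

#' Resample a series to a new rate by spline interpolation
#'
#' @param x numeric series sampled uniformly at \code{fs_from}.
#' @param fs_from,fs_to source and target rates (Hz).
#' @param n_out optional exact output length (overrides the rate-derived
#'   length).
#' @return the resampled series.
#' @export
resample_series <- function(x, fs_from, fs_to, n_out = NULL) {
  t_in <- (seq_along(x) - 1) / fs_from
  if (is.null(n_out)) n_out <- floor(t_in[length(t_in)] * fs_to) + 1
  t_out <- seq(0, t_in[length(t_in)], length.out = n_out)
  stats::spline(t_in, x, xout = t_out)$y
}

#' Maximum-lag Pearson cross-correlation
#'
#' Pearson correlation between two series evaluated at every integer-sample
#' delay within \code{[-max_delay, +max_delay]} over the overlapping
#' support; returns the maximum correlation and the delay at which it
#' occurs (ties broken toward the smallest absolute delay). Both series must
#' share the sampling rate; use \code{\link{resample_series}} first if they
#' do not.
#'
#' @param a_est estimated activation series.
#' @param emg_env EMG envelope series.
#' @param fs common sampling rate (Hz).
#' @param max_delay maximum delay magnitude (s), default 0.150.
#' @return a list with \code{r} and \code{lag} (s).
#' @export
xcorr_pearson <- function(a_est, emg_env, fs, max_delay = 0.150) {
  if (max_delay < 0) stop("max_delay must be non-negative")
  n <- min(length(a_est), length(emg_env))
  a_est <- a_est[seq_len(n)]; emg_env <- emg_env[seq_len(n)]
  if (stats::sd(a_est) == 0 || stats::sd(emg_env) == 0)
    stop("correlation undefined for a zero-variance series")
  L <- floor(max_delay * fs)
  lags <- -L:L
  lags <- lags[order(abs(lags))]          # smallest |lag| first, ties -> 0
  best_r <- -Inf; best_lag <- 0
  for (l in lags) {
    if (l >= 0) { x <- a_est[1:(n - l)]; y <- emg_env[(1 + l):n] }
    else { x <- a_est[(1 - l):n]; y <- emg_env[1:(n + l)] }
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) next
    r <- stats::cor(x, y)
    if (r > best_r + 1e-12) { best_r <- r; best_lag <- l }
  }
  list(r = best_r, lag = best_lag / fs)
}

#' Paired t-test on per-subject mean correlations
#'
#' Two-sided paired t-test comparing two methods' per-subject mean Pearson
#' correlations. Identical samples (all differences exactly zero) are the
#' degenerate no-difference case and return t = 0, p = 1; non-zero constant
#' differences have no variance estimate and raise an error.
#'
#' @param rA,rB numeric vectors of per-subject means, equal length >= 2.
#' @return a list with \code{t}, \code{p} and \code{df}.
#' @export
paired_ttest <- function(rA, rB) {
  if (length(rA) != length(rB)) stop("samples must have equal length")
  if (length(rA) < 2) stop("need at least 2 pairs")
  d <- rA - rB
  if (all(d == 0)) return(list(t = 0, p = 1, df = length(d) - 1))
  if (stats::sd(d) == 0)
    stop("zero-variance non-zero differences: t statistic undefined")
  tt <- stats::t.test(rA, rB, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter))
}

#' Validation table
#'
#' Container for the method x subject x muscle array of Pearson
#' correlations (and optionally the chosen delays).
#'
#' @param r 3-d array \code{[method, subject, muscle]} with dimnames.
#' @param lags optional array of the same shape with the chosen delays (s).
#' @param max_delay the delay bound used (s).
#' @return a list of class \code{validation_table}.
#' @export
validation_table <- function(r, lags = NULL, max_delay = 0.150) {
  if (length(dim(r)) != 3) stop("r must be a method x subject x muscle array")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must not exceed 1")
  if (!is.null(lags) && any(abs(lags) > max_delay + 1e-12, na.rm = TRUE))
    stop("lags exceed the delay bound")
  structure(list(r = r, lags = lags, max_delay = max_delay),
            class = "validation_table")
}

#' Summary tables of the method comparison
#'
#' Per-muscle means across subjects, per-subject means across muscles,
#' grand means per method, and the full matrix of pairwise paired t-test
#' p-values on the per-subject means. Cells with \code{r < 0.40} (weak) and
#' \code{r > 0.60} (good) are flagged. Missing cells are excluded from the
#' means, with the contributing count recorded.
#'
#' @param v a \code{\link{validation_table}}.
#' @return a list with \code{per_muscle}, \code{per_subject} (matrices with
#'   methods in rows), \code{grand} (named vector), \code{pvals} (symmetric
#'   matrix, NA diagonal), \code{flags_weak}, \code{flags_good} (logical
#'   matrices over \code{per_muscle}), and \code{n_missing}.
#' @export
summary_tables <- function(v) {
  r <- v$r
  per_muscle <- apply(r, c(1, 3), mean, na.rm = TRUE)
  per_subject <- apply(r, c(1, 2), mean, na.rm = TRUE)
  grand <- rowMeans(per_muscle, na.rm = TRUE)
  methods <- dimnames(r)[[1]]
  nm <- length(methods)
  pvals <- matrix(NA_real_, nm, nm, dimnames = list(methods, methods))
  if (nm >= 2 && dim(r)[2] >= 2) {
    for (i in seq_len(nm - 1)) for (j in (i + 1):nm) {
      p <- tryCatch(paired_ttest(per_subject[i, ], per_subject[j, ])$p,
                    error = function(e) NA_real_)
      pvals[i, j] <- pvals[j, i] <- p
    }
  }
  list(per_muscle = per_muscle, per_subject = per_subject, grand = grand,
       pvals = pvals,
       flags_weak = per_muscle < 0.40, flags_good = per_muscle > 0.60,
       n_missing = sum(is.na(r)))
}
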