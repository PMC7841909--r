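#' Method labels
#'
#' The eight approaches of the comparison: static optimization under
#' criteria I-IV (\code{so1}-\code{so4}), the physiological approaches
#' (\code{phy1} elastic tendon, \code{phy2} rigid tendon with activation
#' time response, \code{phy3} rigid tendon without), all using criterion I,
#' and the 3-synergy optimization (\code{syno3}).
#'
#' @return character vector of the known labels.
#' @export
method_labels <- function() {
  c("so1", "so2", "so3", "so4", "phy1", "phy2", "phy3", "syno3")
}

#' Solve one trial with a labelled method
#'
#' Thin dispatcher from a comparison label to \code{\link{solve_trial}} or
#' \code{\link{solve_syno}}.
#'
#' @param label one of \code{\link{method_labels}}.
#' @param trial a \code{\link{gait_trial}}.
#' @param params \code{muscle_params}.
#' @param curves a \code{\link{hill_curves}} object.
#' @param seed integer seed.
#' @param ... passed on to the underlying solver.
#' @return a \code{solver_result}.
#' @export
solve_method <- function(label, trial, params, curves = hill_curves(),
                         seed = 1, ...) {
  label <- match.arg(label, method_labels())
  if (label == "syno3")
    return(solve_syno(trial, params, syno_config(nS = 3), curves,
                      seed = seed, ...)$result)
  map <- list(so1 = list("SO", "I"), so2 = list("SO", "II"),
              so3 = list("SO", "III"), so4 = list("SO", "IV"),
              phy1 = list("PHY1", "I"), phy2 = list("PHY2", "I"),
              phy3 = list("PHY3", "I"))[[label]]
  solve_trial(trial, params, method = map[[1]],
              crit = so_criterion(map[[2]]), curves = curves,
              seed = seed, ...)
}

#' Run the full method comparison on a synthetic cohort
#'
#' Generates (or takes) a cohort, solves every requested method for every
#' subject, extracts EMG envelopes, cross-correlates estimated activations
#' with the envelopes (activations upsampled to the EMG rate; delays up to
#' \code{max_delay}), and assembles the validation tables and pairwise
#' paired t-tests.
#'
#' @param cfg a \code{\link{synth_config}}.
#' @param methods subset of \code{\link{method_labels}}.
#' @param cohort optional pre-generated cohort (from
#'   \code{\link{gen_cohort}}); generated from \code{cfg} when missing.
#' @param curves a \code{\link{hill_curves}} object.
#' @param max_delay cross-correlation delay bound (s).
#' @param ... passed to the per-trial solvers.
#' @return a list of class \code{comparison_report}: \code{results}
#'   (method x subject list of \code{solver_result}), \code{validation}
#'   (a \code{\link{validation_table}}), \code{tables} (from
#'   \code{\link{summary_tables}}), \code{wall_times} (method x subject
#'   matrix, s), \code{matching} (per-method mean moment matching, %),
#'   \code{cfg} and \code{seed}.
#' @export
run_comparison <- function(cfg = synth_config(), methods = method_labels(),
                           cohort = NULL, curves = hill_curves(),
                           max_delay = 0.150, ...) {
  methods <- match.arg(methods, method_labels(), several.ok = TRUE)
  if (is.null(cohort)) cohort <- gen_cohort(cfg, curves)
  ns <- length(cohort)
  n_chan <- length(cohort[[1]]$emg)
  r_arr <- lag_arr <- array(
    NA_real_, c(length(methods), ns, n_chan),
    dimnames = list(methods, paste0("S", seq_len(ns)),
                    paste0("ch", seq_len(n_chan))))
  wall <- matrix(NA_real_, length(methods), ns,
                 dimnames = list(methods, paste0("S", seq_len(ns))))
  matching <- matrix(NA_real_, length(methods), ns,
                     dimnames = dimnames(wall))
  results <- list()
  for (s in seq_len(ns)) {
    sub <- cohort[[s]]
    chan <- if (!is.null(sub$emg_channels)) sub$emg_channels
            else seq_along(sub$emg)
    envs <- lapply(sub$emg, envelope)
    for (mi in seq_along(methods)) {
      lab <- methods[mi]
      res <- solve_method(lab, sub$trial, sub$muscles, curves,
                          seed = cfg$seed + s, ...)
      results[[paste(lab, s, sep = ".")]] <- res
      wall[mi, s] <- res$wall_time
      matching[mi, s] <- moment_matching(res$QMT, sub$trial$QID)
      for (ci in seq_along(chan)) {
        a_up <- resample_series(res$activations[, chan[ci]],
                                cfg$frame_rate, cfg$emg_rate,
                                n_out = length(envs[[ci]]))
        xc <- tryCatch(xcorr_pearson(a_up, envs[[ci]], cfg$emg_rate,
                                     max_delay),
                       error = function(e) list(r = NA_real_, lag = NA_real_))
        r_arr[mi, s, ci] <- xc$r
        lag_arr[mi, s, ci] <- xc$lag
      }
    }
  }
  v <- validation_table(r_arr, lag_arr, max_delay)
  structure(list(results = results, validation = v,
                 tables = summary_tables(v), wall_times = wall,
                 matching = matching, cfg = cfg, seed = cfg$seed,
                 methods = methods),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("comparison_report: %d methods x %d subjects x %d EMG channels\n",
              dim(x$validation$r)[1], dim(x$validation$r)[2],
              dim(x$validation$r)[3]))
  cat("grand mean r per method:\n")
  print(round(x$tables$grand, 3))
  invisible(x)
}

#' Emit the comparison tables
#'
#' Formats the four-table analogue of the method comparison: per-muscle
#' mean correlations across subjects (with mean computational time),
#' pairwise p-values on across-subject means, per-subject mean correlations
#' across muscles, and pairwise p-values again. Weak (\code{r < 0.40}) and
#' good (\code{r > 0.60}) cells and significant pairs (\code{p < 0.05}) are
#' flagged in the Markdown rendering.
#'
#' @param report a \code{comparison_report}.
#' @param dir optional directory; when given, the tables are written as
#'   CSV (\code{table1.csv} ... \code{table4.csv}) and Markdown
#'   (\code{tables.md}).
#' @return (invisibly) a list of the four data frames plus the Markdown
#'   lines.
#' @export
report_tables <- function(report, dir = NULL) {
  tb <- report$tables
  t1 <- as.data.frame(t(tb$per_muscle))
  t1 <- rbind(t1, Mean = tb$grand,
              MeanTime = rowMeans(report$wall_times, na.rm = TRUE))
  t2 <- as.data.frame(tb$pvals)
  t3 <- as.data.frame(t(tb$per_subject))
  t3 <- rbind(t3, Mean = rowMeans(tb$per_subject, na.rm = TRUE))
  t4 <- t2
  md <- c("## Mean r per muscle (across subjects)",
          .md_table(t1, flag = TRUE),
          "", "## Pairwise paired t-test p-values (per-muscle means)",
          .md_table(t2, pflag = TRUE),
          "", "## Mean r per subject (across muscles)",
          .md_table(t3, flag = TRUE),
          "", "## Pairwise paired t-test p-values (per-subject means)",
          .md_table(t4, pflag = TRUE))
  out <- list(per_muscle = t1, pvals_muscle = t2, per_subject = t3,
              pvals_subject = t4, markdown = md)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (i in 1:4) utils::write.csv(out[[i]],
                                    file.path(dir, sprintf("table%d.csv", i)))
    writeLines(md, file.path(dir, "tables.md"))
  }
  invisible(out)
}

.md_table <- function(df, flag = FALSE, pflag = FALSE) {
  fmt <- function(x, rn) {
    if (!is.numeric(x)) return(as.character(x))
    s <- sprintf("%.3f", x)
    if (flag && !rn %in% c("MeanTime")) {
      s[!is.na(x) & x > 0.60] <- paste0("*", s[!is.na(x) & x > 0.60], "*")
      s[!is.na(x) & x < 0.40] <- paste0("_", s[!is.na(x) & x < 0.40], "_")
    }
    if (pflag) s[!is.na(x) & x < 0.05] <- paste0("_", s[!is.na(x) & x < 0.05], "_")
    s[is.na(x)] <- "NA"
    s
  }
  rows <- vapply(seq_len(nrow(df)), function(i)
    paste0("| ", rownames(df)[i], " | ",
           paste(fmt(unlist(df[i, ]), rownames(df)[i]), collapse = " | "),
           " |"), character(1))
  c(paste0("| | ", paste(colnames(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df) + 1), collapse = "|"), "|"),
    rows)
}
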