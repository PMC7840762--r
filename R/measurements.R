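## Reduction of measured cell-tip trajectories: loading, plateau detection,
## on/off cycle summaries and lumped-parameter estimation.

.traj_columns <- c("cell_id", "type", "t_s", "elong_um", "V_pp", "freq_hz",
                   "w_um", "d_um", "R_um", "phase")

#' Single cell-tip trajectory
#'
#' Time-stamped tip elongation of one cell under one experimental condition,
#' with optional voltage on/off phase annotations.
#'
#' @param time Time stamps in seconds, strictly increasing.
#' @param elong Tip elongation in micrometres, finite.
#' @param cell_id Cell identifier.
#' @param type Cell type label (optional).
#' @param V,freq,w,d,R Condition metadata: drive voltage (Vpp), frequency
#'   (Hz), electrode width/gap (um) and cell radius estimate (um).
#' @param phase Optional character vector (`"on"`/`"off"`) per sample.
#' @return An object of class `dep_trajectory`.
#' @export
dep_trajectory <- function(time, elong, cell_id, type = NA_character_,
                           V = NA_real_, freq = NA_real_, w = NA_real_,
                           d = NA_real_, R = NA_real_, phase = NULL) {
  stopifnot(length(time) == length(elong), length(time) >= 2L)
  if (any(!is.finite(time)) || any(diff(time) <= 0))
    stop("schema error: time stamps must be finite and strictly increasing")
  if (any(!is.finite(elong)))
    stop("schema error: elongation samples must be finite")
  if (!is.null(phase)) {
    phase <- as.character(phase)
    stopifnot(length(phase) == length(time))
    if (!all(phase %in% c("on", "off")))
      stop("schema error: phase must be 'on' or 'off'")
  }
  structure(list(time = as.numeric(time), elong = as.numeric(elong),
                 cell_id = as.character(cell_id), type = as.character(type),
                 V = V, freq = freq, w = w, d = d, R = R, phase = phase),
            class = "dep_trajectory")
}

#' @export
print.dep_trajectory <- function(x, ...) {
  cat(sprintf("<dep_trajectory> cell %s (%s), %d samples over %.3g s\n",
              x$cell_id, x$type, length(x$time), diff(range(x$time))))
  cat(sprintf("  V = %g Vpp, f = %g Hz, w = %g, d = %g, R = %g um\n",
              x$V, x$freq, x$w, x$d, x$R))
  invisible(x)
}

#' Plot a trajectory
#'
#' @param x A `dep_trajectory`.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.dep_trajectory <- function(x, ...) {
  graphics::plot(x$time, x$elong, type = "l", xlab = "time [s]",
                 ylab = "tip elongation [um]", ...)
  if (!is.null(x$phase))
    graphics::rug(x$time[x$phase == "off"], col = "grey60")
  invisible(x)
}

#' Load trajectories from a delimited text file
#'
#' Expects tab- or comma-separated text with columns
#' `cell_id, type, t_s, elong_um, V_pp, freq_hz, w_um, d_um, R_um, phase`
#' (`type` and `phase` optional). Rows are grouped by `cell_id`; each group
#' becomes one [dep_trajectory()]. Malformed groups are rejected with an
#' error identifying the offending cell and line numbers.
#'
#' @param path File path.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @return Named list of `dep_trajectory` objects.
#' @export
load_trajectories <- function(path, sep = NULL) {
  if (is.null(sep)) {
    l1 <- readLines(path, n = 1L)
    sep <- if (grepl("\t", l1)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, comment.char = "#")
  mandatory <- c("cell_id", "t_s", "elong_um", "V_pp", "w_um", "d_um", "R_um")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("schema error: missing mandatory columns: ",
         paste(missing, collapse = ", "))
  df$.line <- seq_len(nrow(df)) + 1L
  out <- lapply(split(df, df$cell_id), function(g) {
    g <- g[order(g$t_s), ]
    tryCatch(
      dep_trajectory(g$t_s, g$elong_um, g$cell_id[1L],
                     type = if ("type" %in% names(g)) g$type[1L]
                            else NA_character_,
                     V = g$V_pp[1L],
                     freq = if ("freq_hz" %in% names(g)) g$freq_hz[1L]
                            else NA_real_,
                     w = g$w_um[1L], d = g$d_um[1L], R = g$R_um[1L],
                     phase = if ("phase" %in% names(g)) g$phase else NULL),
      error = function(e)
        stop(sprintf("cell %s (lines %d-%d): %s", g$cell_id[1L],
                     min(g$.line), max(g$.line), conditionMessage(e)),
             call. = FALSE))
  })
  out
}

#' Write trajectories to a delimited text file
#'
#' Long-format TSV with the canonical column schema of
#' [load_trajectories()].
#'
#' @param trajectories List of [dep_trajectory()] objects or a data frame in
#'   the canonical schema.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajectories, path) {
  df <- if (is.data.frame(trajectories)) trajectories
  else do.call(rbind, lapply(trajectories, function(tr)
    data.frame(cell_id = tr$cell_id, type = tr$type, t_s = tr$time,
               elong_um = tr$elong, V_pp = tr$V, freq_hz = tr$freq,
               w_um = tr$w, d_um = tr$d, R_um = tr$R,
               phase = if (is.null(tr$phase)) "on" else tr$phase)))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Steady-state elongation of a trajectory
#'
#' Declares a plateau when the straight-line slope over the trailing
#' `window` seconds is smaller than `tol * plateau / window` (i.e. the
#' trailing drift over one window is below a fraction `tol` of the level,
#' with a two-standard-error allowance so that tracking noise on weak
#' signals is not mistaken for drift) and reports the mean over that
#' window. Trajectories that have not saturated are flagged, not rejected.
#'
#' @param traj A [dep_trajectory()]. When phases are annotated only the
#'   first `"on"` interval is used.
#' @param window Trailing window in seconds (default 10).
#' @param tol Relative drift tolerance (default 0.02).
#' @return List with `L_plateau` (um), `L_star` (plateau / R), `converged`
#'   flag and the trailing `slope` (um/s).
#' @export
steady_state_elongation <- function(traj, window = 10, tol = 0.02) {
  stopifnot(inherits(traj, "dep_trajectory"), window > 0, tol > 0)
  tt <- traj$time
  ee <- traj$elong
  if (!is.null(traj$phase)) {
    r <- rle(traj$phase)
    stops <- cumsum(r$lengths)
    first_on <- which(r$values == "on")[1L]
    if (!is.na(first_on)) {
      ix <- (c(0L, stops)[first_on] + 1L):stops[first_on]
      tt <- tt[ix]; ee <- ee[ix]
    }
  }
  if (diff(range(tt)) < window)
    stop("contract error: trajectory shorter than the plateau window")
  sel <- tt >= max(tt) - window
  plateau <- mean(ee[sel])
  slope <- 0
  se_slope <- 0
  if (sum(sel) >= 3L) {
    x <- tt[sel] - mean(tt[sel])
    y <- ee[sel]
    Sxx <- sum(x^2)
    slope <- sum(x * y) / Sxx
    res <- y - mean(y) - slope * x
    se_slope <- sqrt(max(sum(res^2), 0) / ((length(y) - 2L) * Sxx))
  }
  ## a trajectory is flagged only when the trailing drift is both
  ## practically relevant (more than tol of the plateau per window) and
  ## statistically resolved above the tracking noise (2 SE guard)
  converged <- is.finite(slope) &&
    abs(slope) < tol * max(abs(plateau), 1e-12) / window + 2 * se_slope
  list(L_plateau = plateau,
       L_star = plateau / traj$R,
       converged = converged,
       slope = slope)
}

#' Summarize voltage on/off cycles of a trajectory
#'
#' For each annotated on-interval the peak elongation is recorded; for the
#' following off-interval the residual elongation at its end gives the
#' recovery fraction \eqn{1 - \mathrm{residual}/\mathrm{peak}} (clipped to
#' `[0, 1]`). The relative drop from the first to the last peak summarizes
#' degradation across cycles. Recovery fractions are invariant to uniform
#' rescaling of the elongation axis.
#'
#' @param traj A [dep_trajectory()] with phase annotations covering at least
#'   one on interval.
#' @return An object of class `cycles_summary` with `peaks`, `recovery`
#'   (one per completed off interval) and `peak_drop`.
#' @export
cycle_summary <- function(traj) {
  stopifnot(inherits(traj, "dep_trajectory"))
  if (is.null(traj$phase))
    stop("contract error: trajectory has no on/off annotations")
  r <- rle(traj$phase)
  stops <- cumsum(r$lengths)
  starts <- c(1L, utils::head(stops, -1L) + 1L)
  on_ix <- which(r$values == "on")
  if (!length(on_ix))
    stop("contract error: no 'on' interval annotated")
  peaks <- vapply(on_ix, function(i)
    max(traj$elong[starts[i]:stops[i]]), numeric(1L))
  recovery <- numeric(0)
  for (k in seq_along(on_ix)) {
    i <- on_ix[k]
    if (i < length(r$values) && r$values[i + 1L] == "off") {
      residual <- traj$elong[stops[i + 1L]]
      recovery <- c(recovery,
                    min(max(1 - residual / peaks[k], 0), 1))
    }
  }
  peak_drop <- if (length(peaks) >= 2L)
    (peaks[1L] - peaks[length(peaks)]) / peaks[1L] else NA_real_
  structure(list(peaks = peaks, recovery = recovery, peak_drop = peak_drop,
                 n_cycles = length(peaks)),
            class = "cycles_summary")
}

#' @export
print.cycles_summary <- function(x, ...) {
  cat(sprintf("<cycles_summary> %d cycle(s)\n", x$n_cycles))
  cat("  peaks [um]:", paste(signif(x$peaks, 4), collapse = ", "), "\n")
  if (length(x$recovery))
    cat("  recovery  :", paste(signif(x$recovery, 3), collapse = ", "), "\n")
  if (!is.na(x$peak_drop))
    cat(sprintf("  first-to-last peak drop: %.3g%%\n", 100 * x$peak_drop))
  invisible(x)
}

#' Reduce trajectories to a measurement table
#'
#' Applies [steady_state_elongation()] to each trajectory and assembles the
#' flat table consumed by [fit_S()]. Non-converged trajectories are dropped
#' with a message (their ids are recorded in the `"dropped"` attribute).
#'
#' @param trajectories List of [dep_trajectory()] objects.
#' @inheritParams steady_state_elongation
#' @return Data frame with columns `cell_id, type, Lstar, V, R, d, w`.
#' @export
reduce_trajectories <- function(trajectories, window = 10, tol = 0.02) {
  rows <- lapply(trajectories, function(tr) {
    ss <- steady_state_elongation(tr, window, tol)
    data.frame(cell_id = tr$cell_id, type = tr$type, Lstar = ss$L_star,
               V = tr$V, R = tr$R, d = tr$d, w = tr$w,
               converged = ss$converged)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  dropped <- df$cell_id[!df$converged]
  if (length(dropped))
    message(length(dropped), " non-converged trajectories dropped: ",
            paste(utils::head(dropped, 5L), collapse = ", "),
            if (length(dropped) > 5L) ", ..." else "")
  out <- df[df$converged, setdiff(names(df), "converged")]
  attr(out, "dropped") <- dropped
  out
}

#' Estimate the lumped parameter S from measured trajectories
#'
#' Reduces each trajectory to its steady-state normalized elongation and
#' fits \eqn{L^* = S V^2 \gamma(R, d, w)} (see [fit_S()]): a pooled fit per
#' cell type plus per-cell fits whose mean and standard error summarize the
#' type. Single-cell groups are flagged by an undefined standard error.
#'
#' @param trajectories List of [dep_trajectory()] objects.
#' @param table A [gamma_table()] covering the measured geometries.
#' @inheritParams steady_state_elongation
#' @param ... Passed to [fit_S()].
#' @return A `lumped_fit` (see [fit_S()]); the reduced measurement table is
#'   attached as attribute `"measurements"`.
#' @export
estimate_S <- function(trajectories, table, window = 10, tol = 0.02, ...) {
  meas <- reduce_trajectories(trajectories, window, tol)
  if (!nrow(meas)) stop("contract error: no converged trajectories")
  fit <- fit_S(meas, table, ...)
  attr(fit, "measurements") <- meas
  fit
}
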