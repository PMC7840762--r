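#' Generate synthetic cell-tip trajectories
#'
#' Seeded stand-in for tracked video data, built on the lumped elongation
#' law: each cell's plateau is \eqn{L^*_\infty = S_{type} V^2 \gamma(R,d,w)}
#' with multiplicative lognormal cell-to-cell variation (coefficient of
#' variation `noise_cv`, unit mean), approached as a single-exponential rise
#' with type-specific time constant `tau`, plus additive Gaussian tracking
#' noise on the recorded tip position. With `cycles > 1` the drive is
#' switched off between cycles and the tip relaxes towards a residual set by
#' `recovery` (1 = fully elastic), with the per-cycle peak additionally
#' scaled down by `peak_decay` per cycle to emulate degradation.
#'
#' The default design mirrors a three-cell-type study: 16 cells per
#' condition, nine electrode conditions (three widths times three gaps) at a
#' fixed drive.
#'
#' @param S_true Named numeric of per-type lumped parameters (1/V^2).
#' @param table A [gamma_table()] covering the conditions.
#' @param conditions Data frame with columns `V`, `w`, `d` (and optionally
#'   `freq`); default nine conditions `w in {10,30,50}` x `d in {20,45,70}`
#'   at `V = 8`, 3 MHz.
#' @param R_types Named numeric of mean cell radii per type (um); a mild
#'   uniform jitter of +-10% is applied per cell, clipped to the table hull.
#' @param tau Named numeric of rise time constants per type (s).
#' @param duration Record length per type (s); default `pmax(60, 8 * tau)`
#'   so that the recorded plateau is within a tenth of a percent of the
#'   asymptote.
#' @param dt Sampling interval (s), default 1.
#' @param n_cells Cells per type and condition (default 16).
#' @param noise_cv Cell-to-cell coefficient of variation (default 0.05).
#' @param noise_track_um Tracking noise standard deviation (um,
#'   default 0.05).
#' @param cycles Number of on/off cycles (default 1: a single on interval).
#' @param recovery Off-interval recovery fraction in `[0, 1]` (default 1).
#' @param peak_decay Per-cycle multiplicative peak decay (default 0).
#' @param seed Integer seed; every random draw is governed by it.
#' @param path Optional output file; when given the table is written with
#'   [write_trajectories()].
#' @return List of [dep_trajectory()] objects (invisibly the file path is
#'   attached as attribute `"path"` when written).
#' @export
synth_trajectories <- function(S_true = c(erythrocyte = 4e-3, pbmc = 2e-3,
                                          t47d = 8e-4),
                               table,
                               conditions = NULL,
                               R_types = c(erythrocyte = 4.5, pbmc = 6,
                                           t47d = 7.5),
                               tau = c(erythrocyte = 5, pbmc = 10, t47d = 30),
                               duration = NULL, dt = 1,
                               n_cells = 16L,
                               noise_cv = 0.05, noise_track_um = 0.05,
                               cycles = 1L, recovery = 1, peak_decay = 0,
                               seed = 1L, path = NULL) {
  stopifnot(n_cells >= 1L, noise_cv >= 0, noise_track_um >= 0,
            cycles >= 1L, recovery >= 0, recovery <= 1,
            inherits(table, "gamma_table"),
            all(names(S_true) %in% names(R_types)),
            all(names(S_true) %in% names(tau)))
  if (is.null(conditions))
    conditions <- expand.grid(V = 8, w = c(10, 30, 50), d = c(20, 45, 70))
  if (is.null(conditions$freq)) conditions$freq <- 3e6
  tau <- tau[names(S_true)]
  R_types <- R_types[names(S_true)]
  if (is.null(duration)) duration <- pmax(60, 8 * tau)
  duration <- rep_len(duration, length(S_true))
  names(duration) <- names(S_true)
  set.seed(seed)
  sdlog <- sqrt(log(1 + noise_cv^2))
  Rlim <- range(table$R)
  out <- list()
  for (ty in names(S_true)) {
    t_on <- duration[[ty]]
    for (ci in seq_len(nrow(conditions))) {
      cond <- conditions[ci, ]
      for (k in seq_len(n_cells)) {
        Rk <- R_types[[ty]] * stats::runif(1, 0.9, 1.1)
        Rk <- min(max(Rk, Rlim[1L]), Rlim[2L])
        gam <- interpolate_gamma(table, Rk, cond$d, cond$w)
        cell_factor <- if (noise_cv > 0)
          stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog) else 1
        Lstar_inf <- S_true[[ty]] * cond$V^2 * gam * cell_factor
        u_inf <- Lstar_inf * Rk
        tt <- numeric(0); uu <- numeric(0); ph <- character(0)
        t0 <- 0
        level <- 0
        for (cyc in seq_len(cycles)) {
          peak <- u_inf * (1 - peak_decay)^(cyc - 1L)
          ton <- seq(0, t_on, by = dt)
          u_on <- peak + (level - peak) * exp(-ton / tau[[ty]])
          tt <- c(tt, t0 + ton); uu <- c(uu, u_on)
          ph <- c(ph, rep("on", length(ton)))
          level_end <- u_on[length(u_on)]
          t0 <- t0 + t_on + dt
          if (cyc < cycles || cycles > 1L) {
            toff <- seq(0, t_on / 2, by = dt)
            resid <- level_end * (1 - recovery)
            u_off <- resid + (level_end - resid) * exp(-toff / tau[[ty]])
            tt <- c(tt, t0 + toff); uu <- c(uu, u_off)
            ph <- c(ph, rep("off", length(toff)))
            level <- u_off[length(u_off)]
            t0 <- t0 + t_on / 2 + dt
          }
        }
        if (noise_track_um > 0)
          uu <- uu + stats::rnorm(length(uu), 0, noise_track_um)
        id <- sprintf("%s_c%02d_%03d", ty, ci, k)
        out[[id]] <- dep_trajectory(tt, uu, id, type = ty,
                                    V = cond$V, freq = cond$freq,
                                    w = cond$w, d = cond$d, R = Rk,
                                    phase = ph)
      }
    }
  }
  if (!is.null(path)) {
    write_trajectories(out, path)
    attr(out, "path") <- path
  }
  out
}
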