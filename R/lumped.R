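#' Estimate the permittivity-contrast exponent
#'
#' The elongation of a given cell in a given chip is, to a good
#' approximation, a power law in the permittivity contrast
#' \eqn{\Delta\varepsilon = |\varepsilon_m - \varepsilon_c|}:
#' \eqn{L^* \propto \Delta\varepsilon^{\alpha}} with a single exponent
#' shared by all electrode geometries and cell sizes. The exponent is
#' estimated by minimizing, over a grid of candidate \eqn{\alpha}, the
#' worst-case (over geometries) relative spread
#' \eqn{(\max - \min)/\mathrm{mean}} of \eqn{L^*/\Delta\varepsilon^\alpha}
#' across the contrast levels, followed by a golden-section refinement
#' around the best grid value.
#'
#' @param data Data frame with columns `Lstar` (normalized elongation),
#'   `d_eps` (permittivity contrast, > 0) and `geometry` (configuration
#'   identifier); at least 3 distinct contrasts per geometry.
#' @param alpha_grid Candidate exponents (default `seq(0.5, 1.2, 0.01)`).
#' @param refine Golden-section refinement around the best grid point
#'   (default `TRUE`).
#' @return An object of class `alpha_fit` with the fitted `alpha`, the
#'   worst-case relative deviation at the fit, and per-geometry deviations.
#' @export
fit_alpha <- function(data, alpha_grid = seq(0.5, 1.2, by = 0.01),
                      refine = TRUE) {
  need <- c("Lstar", "d_eps", "geometry")
  if (!is.data.frame(data) || !all(need %in% names(data)))
    stop("contract error: data must have columns ",
         paste(need, collapse = ", "))
  if (any(data$d_eps <= 0)) stop("contract error: d_eps must be positive")
  groups <- split(data, data$geometry)
  n_lev <- vapply(groups, function(g) length(unique(g$d_eps)), integer(1L))
  if (any(n_lev < 3L))
    stop("contract error: need >= 3 distinct contrast levels per geometry")
  spread_at <- function(alpha) {
    vapply(groups, function(g) {
      v <- g$Lstar / g$d_eps^alpha
      (max(v) - min(v)) / mean(v)
    }, numeric(1L))
  }
  worst <- vapply(alpha_grid, function(a) max(spread_at(a)), numeric(1L))
  best <- which.min(worst)
  alpha <- alpha_grid[best]
  if (refine && length(alpha_grid) > 1L) {
    step <- if (best == 1L) alpha_grid[2L] - alpha_grid[1L]
            else alpha_grid[best] - alpha_grid[best - 1L]
    lo <- alpha - step
    hi <- alpha + step
    opt <- stats::optimize(function(a) max(spread_at(a)), c(lo, hi),
                           tol = 1e-5)
    if (opt$objective <= worst[best]) alpha <- opt$minimum
  }
  per_geo <- spread_at(alpha)
  structure(list(alpha = alpha,
                 max_relative_deviation = max(per_geo),
                 per_geometry = per_geo,
                 alpha_grid = alpha_grid,
                 worst_spread = worst,
                 n = nrow(data)),
            class = "alpha_fit")
}

#' @export
print.alpha_fit <- function(x, ...) {
  cat(sprintf("<alpha_fit> alpha = %.4g\n", x$alpha))
  cat(sprintf("  worst-case relative deviation = %.3g%% over %d geometries (n = %d)\n",
              100 * x$max_relative_deviation, length(x$per_geometry), x$n))
  invisible(x)
}

#' Fit the lumped cell parameter S
#'
#' Least squares through the origin of \eqn{L^* = S \, V^2 \gamma(R, d, w)}:
#' with \eqn{x = V^2\gamma} and \eqn{y = L^*},
#' \eqn{\hat S = \sum xy / \sum x^2}. S lumps the cell's mechanical
#' compliance and permittivity contrast into a single number (units
#' 1/V^2) characteristic of the cell type. When `cell_id` (and optionally
#' `type`) columns are present, per-cell fits and per-type summaries are
#' also returned; the pooled fit is the default estimate.
#'
#' @param measurements Data frame with columns `Lstar`, `V`, `R`, `d`, `w`
#'   and optionally `cell_id`, `type`.
#' @param table A [gamma_table()] covering all `(R, d, w)` rows.
#' @param d_eps,alpha Optional contrast and exponent; when both are given
#'   the mechanical factor \eqn{D = S/\Delta\varepsilon^\alpha} is also
#'   reported.
#' @return An object of class `lumped_fit`.
#' @export
fit_S <- function(measurements, table, d_eps = NULL, alpha = NULL) {
  need <- c("Lstar", "V", "R", "d", "w")
  if (!is.data.frame(measurements) || !all(need %in% names(measurements)) ||
      nrow(measurements) < 1L)
    stop("contract error: measurements must have >= 1 row and columns ",
         paste(need, collapse = ", "))
  gam <- interpolate_gamma(table, measurements$R, measurements$d,
                           measurements$w)
  x <- measurements$V^2 * gam
  y <- measurements$Lstar
  if (all(x == 0)) stop("degenerate-design error: all V^2*gamma are zero")
  ls_origin <- function(x, y) {
    S <- sum(x * y) / sum(x^2)
    r <- y - S * x
    se <- if (length(x) > 1L) sqrt(sum(r^2) / (length(x) - 1L) / sum(x^2))
          else NA_real_
    list(S = S, se = se, residuals = r)
  }
  pooled <- ls_origin(x, y)
  per_cell <- NULL
  if ("cell_id" %in% names(measurements)) {
    per_cell <- do.call(rbind, lapply(split(seq_len(nrow(measurements)),
                                            measurements$cell_id),
      function(ix) {
        f <- ls_origin(x[ix], y[ix])
        data.frame(cell_id = measurements$cell_id[ix[1L]],
                   type = if ("type" %in% names(measurements))
                     measurements$type[ix[1L]] else NA_character_,
                   S = f$S, se = f$se, n = length(ix))
      }))
    rownames(per_cell) <- NULL
  }
  per_type <- NULL
  if ("type" %in% names(measurements)) {
    per_type <- do.call(rbind, lapply(split(seq_len(nrow(measurements)),
                                            measurements$type),
      function(ix) {
        f <- ls_origin(x[ix], y[ix])
        cs <- if (!is.null(per_cell))
          per_cell$S[per_cell$type == measurements$type[ix[1L]]] else NULL
        data.frame(type = measurements$type[ix[1L]],
                   S_pooled = f$S, se_pooled = f$se,
                   S_cell_mean = if (length(cs)) mean(cs) else NA_real_,
                   S_cell_se = if (length(cs) > 1L)
                     stats::sd(cs) / sqrt(length(cs)) else NA_real_,
                   n_obs = length(ix),
                   n_cells = if (length(cs)) length(cs) else NA_integer_)
      }))
    rownames(per_type) <- NULL
  }
  D <- if (!is.null(d_eps) && !is.null(alpha)) pooled$S / d_eps^alpha
       else NA_real_
  structure(list(S = pooled$S, se = pooled$se,
                 n = nrow(measurements),
                 n_cells = if (!is.null(per_cell)) nrow(per_cell) else 1L,
                 per_cell = per_cell, per_type = per_type,
                 D = D, d_eps = d_eps, alpha = alpha,
                 residual_rms = sqrt(mean(pooled$residuals^2)),
                 units = list(S = "1/V^2",
                              D = "1/(V^2 * d_eps^alpha)")),
            class = "lumped_fit")
}

#' @export
print.lumped_fit <- function(x, ...) {
  cat(sprintf("<lumped_fit> S = %.5g 1/V^2 (se %.2g, n = %d, %d cells)\n",
              x$S, x$se, x$n, x$n_cells))
  if (!is.na(x$D))
    cat(sprintf("  D = S/d_eps^alpha = %.5g (d_eps = %g, alpha = %g)\n",
                x$D, x$d_eps, x$alpha))
  if (!is.null(x$per_type)) {
    cat("  per type:\n")
    print(x$per_type, row.names = FALSE)
  }
  invisible(x)
}

#' Predict the normalized elongation from the lumped law
#'
#' \eqn{\hat L^* = S V^2 \gamma(R, d, w)}.
#'
#' @param S Lumped parameter (1/V^2).
#' @param V Peak-to-peak voltage(s).
#' @param R,d,w Geometry (um).
#' @param table A [gamma_table()].
#' @param ... Passed to [interpolate_gamma()].
#' @return Numeric vector of predicted L*.
#' @export
predict_elongation <- function(S, V, R, d, w, table, ...) {
  stopifnot(is.numeric(S), is.numeric(V), all(V >= 0))
  S * V^2 * interpolate_gamma(table, R, d, w, ...)
}
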