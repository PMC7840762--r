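#' Maxwell stress tensor at a point
#'
#' In the absence of magnetic fields the electrical stress carried by a
#' dielectric is \eqn{\sigma_{ij} = \varepsilon (E_i E_j - \tfrac12
#' \delta_{ij} |E|^2)}. For an in-plane field the 2-D tensor is symmetric and
#' trace-free, with eigenvalues \eqn{\pm\varepsilon|E|^2/2}: tension along
#' the field, equal compression across it.
#'
#' @param E Length-2 numeric field vector in V/m.
#' @param eps Absolute permittivity in F/m.
#' @return A 2x2 symmetric matrix of class `mst_tensor`, units N/m^2.
#' @examples
#' mst_tensor(c(1e5, 0), 80 * EPS0)
#' @export
mst_tensor <- function(E, eps) {
  stopifnot(is.numeric(E), length(E) == 2L, all(is.finite(E)),
            is.numeric(eps), length(eps) == 1L, is.finite(eps))
  E2 <- sum(E^2)
  m <- eps * (outer(E, E) - diag(2L) * E2 / 2)
  structure(m, class = c("mst_tensor", class(m)))
}

#' Surface traction on the cell boundary
#'
#' The jump of the Maxwell stress tensor across the cell interface gives the
#' electrical traction on the cell surface:
#' \deqn{f = \varepsilon_m[(E_{out}\cdot\hat n)E_{out} -
#'   \tfrac12|E_{out}|^2\hat n] - \varepsilon_c[(E_{in}\cdot\hat n)E_{in} -
#'   \tfrac12|E_{in}|^2\hat n].}
#' Real permittivities at the drive frequency are used (the single-shell
#' model supplies the frequency dependence of `eps_c`). With
#' `mode = "peak"` (default) the amplitude fields give the peak-of-cycle
#' traction; `mode = "rms"` applies the AC time-average factor 1/2.
#'
#' @param solution A [solve_potential()] result with interface samples.
#' @param eps_m,eps_c Relative permittivities of medium and cell (real parts
#'   at the drive frequency); converted internally with [EPS0].
#' @param mode `"peak"` or `"rms"` AC convention.
#' @return An object of class `surface_traction`: data frame of stations with
#'   Cartesian (`fx`, `fy`) and polar (`fr`, `ft`) traction components in
#'   N/m^2, plus the cell radius and convention.
#' @export
surface_traction <- function(solution, eps_m, eps_c,
                             mode = c("peak", "rms")) {
  mode <- match.arg(mode)
  if (!inherits(solution, "field_solution") || is.null(solution$interface))
    stop("contract error: field solution with interface samples required")
  itf <- solution$interface
  em <- eps_m * EPS0
  ec <- eps_c * EPS0
  En_out <- itf$Ex_out * itf$nx + itf$Ey_out * itf$ny
  E2_out <- itf$Ex_out^2 + itf$Ey_out^2
  En_in <- itf$Ex_in * itf$nx + itf$Ey_in * itf$ny
  E2_in <- itf$Ex_in^2 + itf$Ey_in^2
  fx <- em * (En_out * itf$Ex_out - E2_out * itf$nx / 2) -
        ec * (En_in * itf$Ex_in - E2_in * itf$nx / 2)
  fy <- em * (En_out * itf$Ey_out - E2_out * itf$ny / 2) -
        ec * (En_in * itf$Ey_in - E2_in * itf$ny / 2)
  if (mode == "rms") { fx <- fx / 2; fy <- fy / 2 }
  tr <- data.frame(theta = itf$theta, nx = itf$nx, ny = itf$ny,
                   fx = fx, fy = fy,
                   fr = fx * itf$nx + fy * itf$ny,
                   ft = -fx * itf$ny + fy * itf$nx)
  structure(list(stations = tr, R = solution$geom$cell_radius, mode = mode,
                 eps_m = eps_m, eps_c = eps_c),
            class = "surface_traction")
}

#' Construct a surface traction from explicit station values
#'
#' Lower-level constructor used by tests and by analytic harnesses: supply
#' traction components directly at equally spaced boundary angles.
#'
#' @param theta Station angles in radians, equally spaced over `[0, 2*pi)`.
#' @param fx,fy Cartesian traction components, N/m^2.
#' @param R Cell radius in micrometres.
#' @return A `surface_traction`.
#' @export
traction_from_samples <- function(theta, fx, fy, R) {
  stopifnot(length(theta) == length(fx), length(fx) == length(fy),
            all(is.finite(fx)), all(is.finite(fy)), R > 0)
  nxv <- cos(theta); nyv <- sin(theta)
  tr <- data.frame(theta = theta, nx = nxv, ny = nyv, fx = fx, fy = fy,
                   fr = fx * nxv + fy * nyv, ft = -fx * nyv + fy * nxv)
  structure(list(stations = tr, R = R, mode = "peak",
                 eps_m = NA_real_, eps_c = NA_real_),
            class = "surface_traction")
}

#' @export
print.surface_traction <- function(x, ...) {
  f <- net_force(x)
  cat(sprintf("<surface_traction> %d stations, R = %g um, mode = %s\n",
              nrow(x$stations), x$R, x$mode))
  cat(sprintf("  max |f| = %.4g Pa, net force = (%.3g, %.3g) N/m\n",
              max(sqrt(x$stations$fx^2 + x$stations$fy^2)), f[1L], f[2L]))
  invisible(x)
}

#' @export
as.data.frame.surface_traction <- function(x, ...) {
  x$stations[, c("theta", "fr", "ft", "fx", "fy")]
}

#' Export a traction table as delimited text
#'
#' @param traction A [surface_traction()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_traction <- function(traction, path) {
  stopifnot(inherits(traction, "surface_traction"))
  utils::write.table(as.data.frame(traction), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Net force of a surface traction
#'
#' Trapezoidal integral of the traction over the cell circle, per unit
#' out-of-plane depth.
#'
#' @param traction A [surface_traction()].
#' @return Length-2 numeric, N/m of depth.
#' @export
net_force <- function(traction) {
  stopifnot(inherits(traction, "surface_traction"))
  s <- traction$stations
  dth <- 2 * pi / nrow(s)
  Rm <- traction$R * 1e-6
  c(sum(s$fx), sum(s$fy)) * dth * Rm
}

## net torque about the cell centre, N m / m of depth (internal)
.net_torque <- function(traction) {
  s <- traction$stations
  dth <- 2 * pi / nrow(s)
  Rm <- traction$R * 1e-6
  sum(s$ft) * dth * Rm^2
}

#' Point-dipole DEP force (3-D spherical particle)
#'
#' The classical time-averaged dipole-approximation force
#' \eqn{\langle F\rangle = 2\pi r^3 \varepsilon_0 \varepsilon_m
#' \mathrm{Re}[K(\omega)] \nabla|E|^2} for a sphere of radius `r`. It
#' predicts zero force in a uniform field and ignores both the field
#' disturbance by the particle and the traction distribution over its
#' surface, which is why the Maxwell-stress route is used for stretching;
#' this function exists for cross-checking only.
#'
#' @param r_um Particle radius in micrometres.
#' @param eps_m Relative medium permittivity.
#' @param K_real Real part of the Clausius-Mossotti factor.
#' @param grad_E2 Length-2 gradient of \eqn{|E|^2} in V^2/m^3.
#' @return Length-2 force vector in newtons.
#' @export
dipole_force <- function(r_um, eps_m, K_real, grad_E2) {
  stopifnot(r_um > 0, length(grad_E2) == 2L)
  2 * pi * (r_um * 1e-6)^3 * EPS0 * eps_m * K_real * grad_E2
}

#' Line-dipole DEP force (2-D cylinder, per unit depth)
#'
#' Planar analogue of [dipole_force()] for an infinite dielectric cylinder:
#' \eqn{F/L = \pi r^2 \varepsilon_0 \varepsilon_m K_{2D} \nabla|E|^2} with
#' the two-dimensional contrast factor \eqn{K_{2D} = (\varepsilon_p -
#' \varepsilon_m)/(\varepsilon_p + \varepsilon_m)}. This is the expression
#' dimensionally commensurate with the 2-D Maxwell-stress [net_force()]
#' (both are per unit out-of-plane depth) and is the one used for the
#' small-particle cross-validation of the simulator.
#'
#' @inheritParams dipole_force
#' @param K2d Two-dimensional contrast factor.
#' @return Length-2 force vector in N/m of depth.
#' @export
dipole_force_2d <- function(r_um, eps_m, K2d, grad_E2) {
  stopifnot(r_um > 0, length(grad_E2) == 2L)
  pi * (r_um * 1e-6)^2 * EPS0 * eps_m * K2d * grad_E2
}
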