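#' Elastic properties of the cell disk
#'
#' Linear isotropic elasticity in one of the two planar regimes. The cell is
#' nearly incompressible, so the default Poisson ratio is 0.49; in
#' `plane_stress` (default, a thin free-standing disk) the Kolosov constant
#' is \eqn{\kappa = (3-\nu)/(1+\nu)}, in `plane_strain` it is
#' \eqn{\kappa = 3-4\nu}.
#'
#' @param youngs_modulus Young's modulus in Pa (> 0); soft cells are of order
#'   100 Pa.
#' @param poisson Poisson ratio, in (-1, 0.5).
#' @param regime `"plane_stress"` or `"plane_strain"`.
#' @return An object of class `elastic_properties` with derived shear modulus
#'   `mu` and Kolosov constant `kappa`.
#' @export
elastic_properties <- function(youngs_modulus, poisson = 0.49,
                               regime = c("plane_stress", "plane_strain")) {
  regime <- match.arg(regime)
  stopifnot(is.numeric(youngs_modulus), length(youngs_modulus) == 1L,
            is.numeric(poisson), length(poisson) == 1L)
  if (!is.finite(youngs_modulus) || youngs_modulus <= 0)
    stop("Young's modulus must be positive")
  if (!is.finite(poisson) || poisson <= -1 || poisson >= 0.5)
    stop("Poisson ratio must lie in (-1, 0.5)")
  mu <- youngs_modulus / (2 * (1 + poisson))
  kappa <- if (regime == "plane_stress") (3 - poisson) / (1 + poisson)
           else 3 - 4 * poisson
  structure(list(youngs_modulus = youngs_modulus, poisson = poisson,
                 regime = regime, mu = mu, kappa = kappa),
            class = "elastic_properties")
}

#' @export
print.elastic_properties <- function(x, ...) {
  cat(sprintf("<elastic_properties> E = %g Pa, nu = %g, %s (mu = %g, kappa = %g)\n",
              x$youngs_modulus, x$poisson, x$regime, x$mu, x$kappa))
  invisible(x)
}

## Fourier analysis of the polar traction components over equally spaced
## stations. Returns coefficient vectors indexed by harmonic n = 0..n_max:
##   fr(theta) = a[1] + sum_n a[n+1] cos(n th) + b[n+1] sin(n th)
##   ft(theta) = c[1] + sum_n c[n+1] cos(n th) + d[n+1] sin(n th)
.traction_fourier <- function(traction, n_max) {
  s <- traction$stations
  K <- nrow(s)
  n_max <- min(n_max, K %/% 2L - 1L)
  coef1 <- function(f) {
    Fc <- stats::fft(f) / K
    a <- 2 * Re(Fc[seq_len(n_max + 1L)])
    b <- -2 * Im(Fc[seq_len(n_max + 1L)])
    a[1L] <- a[1L] / 2
    b[1L] <- 0
    list(a = a, b = b)
  }
  fr <- coef1(s$fr); ft <- coef1(s$ft)
  list(a = fr$a, b = fr$b, cc = ft$a, d = ft$b, n_max = n_max)
}

#' Remove rigid-body resultants from a surface traction
#'
#' A static disk can only equilibrate a self-equilibrated boundary traction.
#' This projects out the net-force part of the n = 1 Fourier harmonics and
#' the net-torque (uniform tangential) component, leaving the
#' deformation-producing part unchanged. The self-equilibrated n = 1
#' deformation modes (those with zero force resultant) are retained.
#'
#' @param traction A [surface_traction()].
#' @return A `surface_traction` with zero net force and torque (to roundoff).
#' @export
equilibrate_traction <- function(traction) {
  stopifnot(inherits(traction, "surface_traction"))
  s <- traction$stations
  K <- nrow(s)
  Fc_r <- stats::fft(s$fr) / K
  Fc_t <- stats::fft(s$ft) / K
  a1 <- 2 * Re(Fc_r[2L]); b1 <- -2 * Im(Fc_r[2L])
  c1 <- 2 * Re(Fc_t[2L]); d1 <- -2 * Im(Fc_t[2L])
  c0 <- Re(Fc_t[1L])
  ## equilibrated n=1 parts: cos-parity needs a1 = d1, sin-parity b1 = -c1
  da1 <- (a1 - d1) / 2; dd1 <- -da1
  db1 <- (b1 + c1) / 2; dc1 <- db1
  th <- s$theta
  fr <- s$fr - da1 * cos(th) - db1 * sin(th)
  ft <- s$ft - c0 - dc1 * cos(th) - dd1 * sin(th)
  nxv <- s$nx; nyv <- s$ny
  out <- traction
  out$stations$fr <- fr
  out$stations$ft <- ft
  out$stations$fx <- fr * nxv - ft * nyv
  out$stations$fy <- fr * nyv + ft * nxv
  out
}

#' Deform the elastic cell disk under a boundary traction
#'
#' Solves the linear elastostatic boundary-value problem on the circular cell
#' under a prescribed self-equilibrated surface traction, by expanding the
#' traction in Fourier harmonics and summing the corresponding Michell
#' (Airy stress function) solutions that are regular at the disk centre.
#' Each harmonic \eqn{n \ge 2} combines the \eqn{r^n} and \eqn{r^{n+2}}
#' stress functions; \eqn{n = 0} is the Lame uniform-pressure solution and
#' the self-equilibrated \eqn{n = 1} mode uses the \eqn{r^3} term.
#'
#' @param traction A self-equilibrated [surface_traction()]
#'   (see [equilibrate_traction()]).
#' @param props An [elastic_properties()].
#' @param n_max Highest Fourier harmonic retained (default 90, capped by the
#'   station count).
#' @param force_tol Relative tolerance on the residual force/torque beyond
#'   which the input is rejected as unequilibrated (default 1e-8).
#' @return An object of class `disk_deformation` carrying the modal
#'   coefficients, the boundary displacement at the traction stations
#'   (micrometres), and an evaluator for interior displacements
#'   (see [disk_displacement()]).
#' @export
deform_disk <- function(traction, props, n_max = 90L, force_tol = 1e-8) {
  stopifnot(inherits(traction, "surface_traction"),
            inherits(props, "elastic_properties"))
  s <- traction$stations
  fscale <- max(sqrt(s$fx^2 + s$fy^2), 1e-300)
  Rm <- traction$R * 1e-6
  F <- net_force(traction)
  Tq <- .net_torque(traction)
  if (max(abs(F)) > force_tol * fscale * 2 * pi * Rm ||
      abs(Tq) > force_tol * fscale * 2 * pi * Rm^2)
    stop("contract error: traction is not self-equilibrated; ",
         "call equilibrate_traction() first")
  fo <- .traction_fourier(traction, n_max)
  nm <- fo$n_max
  kap <- props$kappa
  ## modal coefficients (A, B) for cos-parity and (C, D) for sin-parity,
  ## scaled so that stresses at r = R are linear with unit coefficients
  At <- Bt <- Ct <- Dt <- numeric(nm + 1L)
  if (nm >= 1L) {
    ## n = 1: only the r^3 stress function is regular and stress-producing
    Bt[2L] <- (fo$a[2L] + fo$d[2L]) / 4   # a1' = d1' = 2*Bt
    Dt[2L] <- (fo$b[2L] - fo$cc[2L]) / 4  # b1' = 2*Dt, c1' = -2*Dt
  }
  if (nm >= 2L) {
    for (n in 2:nm) {
      M <- matrix(c(-n * (n - 1), 2 + n - n^2,
                    n * (n - 1), n * (n + 1)), 2L, 2L, byrow = TRUE)
      ab <- solve(M, c(fo$a[n + 1L], fo$d[n + 1L]))
      At[n + 1L] <- ab[1L]; Bt[n + 1L] <- ab[2L]
      Ms <- matrix(c(-n * (n - 1), 2 + n - n^2,
                     -n * (n - 1), -n * (n + 1)), 2L, 2L, byrow = TRUE)
      cd <- solve(Ms, c(fo$b[n + 1L], fo$cc[n + 1L]))
      Ct[n + 1L] <- cd[1L]; Dt[n + 1L] <- cd[2L]
    }
  }
  def <- structure(list(a0 = fo$a[1L], At = At, Bt = Bt, Ct = Ct, Dt = Dt,
                        n_max = nm, props = props, R = traction$R,
                        theta = s$theta),
                   class = "disk_deformation")
  ub <- disk_displacement(def, r = traction$R, theta = s$theta)
  def$u_r <- ub$ur
  def$u_t <- ub$ut
  def$max_u <- max(sqrt(ub$ur^2 + ub$ut^2))
  if (def$max_u / traction$R > 0.2)
    warning(sprintf("large deformation: max |u|/R = %.2f exceeds the small-strain regime",
                    def$max_u / traction$R))
  def
}

#' Evaluate the displacement field of a deformed disk
#'
#' Displacements (micrometres) of the Michell-series solution at polar points
#' inside or on the disk.
#'
#' @param def A [deform_disk()] result.
#' @param r Radius (micrometres), scalar or vector, `0 <= r <= R`.
#' @param theta Angle(s) in radians; recycled against `r`.
#' @return List with components `ur`, `ut` (polar) and `ux`, `uy`
#'   (Cartesian), micrometres.
#' @export
disk_displacement <- function(def, r, theta) {
  stopifnot(inherits(def, "disk_deformation"))
  n <- max(length(r), length(theta))
  r <- rep_len(r, n); theta <- rep_len(theta, n)
  if (any(r < 0 | r > def$R * (1 + 1e-9)))
    stop("radius outside the disk")
  rho <- pmin(r / def$R, 1)
  p <- def$props
  kap <- p$kappa
  Rm <- def$R * 1e-6
  pref <- Rm / (2 * p$mu)
  ## n = 0: u_r = a0 r (kappa-1)/(4 mu); the common R/(2 mu) sits in `pref`
  ur <- def$a0 * rho * (kap - 1) / 2
  ut <- numeric(n)
  if (def$n_max >= 1L) {
    ## n = 1 (r^3 terms)
    B1 <- def$Bt[2L]; D1 <- def$Dt[2L]
    ur <- ur + (kap - 2) * rho^2 * (B1 * cos(theta) + D1 * sin(theta))
    ut <- ut + (kap + 2) * rho^2 * (B1 * sin(theta) - D1 * cos(theta))
  }
  if (def$n_max >= 2L) {
    for (nn in 2:def$n_max) {
      A <- def$At[nn + 1L]; B <- def$Bt[nn + 1L]
      C <- def$Ct[nn + 1L]; D <- def$Dt[nn + 1L]
      if (A == 0 && B == 0 && C == 0 && D == 0) next
      cs <- cos(nn * theta); sn <- sin(nn * theta)
      rn1 <- rho^(nn - 1L); rp1 <- rho^(nn + 1L)
      ur <- ur + (-nn * A * rn1 + (kap - nn - 1) * B * rp1) * cs +
                 (-nn * C * rn1 + (kap - nn - 1) * D * rp1) * sn
      ut <- ut + (nn * A * rn1 + (kap + nn + 1) * B * rp1) * sn -
                 (nn * C * rn1 + (kap + nn + 1) * D * rp1) * cs
    }
  }
  ur <- ur * pref * 1e6  # metres -> micrometres
  ut <- ut * pref * 1e6
  list(ur = ur, ut = ut,
       ux = ur * cos(theta) - ut * sin(theta),
       uy = ur * sin(theta) + ut * cos(theta))
}

#' @export
print.disk_deformation <- function(x, ...) {
  cat(sprintf("<disk_deformation> R = %g um, %d harmonics, %s\n",
              x$R, x$n_max, x$props$regime))
  cat(sprintf("  max |u| on boundary = %.4g um (|u|/R = %.3g)\n",
              x$max_u, x$max_u / x$R))
  invisible(x)
}

#' @export
as.data.frame.disk_deformation <- function(x, n_r = 12L, ...) {
  rr <- seq(0, x$R, length.out = n_r)
  grid <- expand.grid(r = rr, theta = x$theta)
  u <- disk_displacement(x, grid$r, grid$theta)
  data.frame(x = grid$r * cos(grid$theta), y = grid$r * sin(grid$theta),
             ux = u$ux, uy = u$uy)
}

#' Normalized elongation of the deformed cell
#'
#' Tip displacement along the stretching axis, averaged over the two opposite
#' tips: \eqn{u_{tip} = [u_a(\theta_0) - u_a(\theta_0+\pi)]/2} where
#' \eqn{u_a} is the displacement projected on the axis. The deformed
#' semi-axis is \eqn{L = R + u_{tip}} and the normalized elongation
#' \eqn{L^* = (L - R)/R = u_{tip}/R}.
#'
#' @param def A [deform_disk()] result.
#' @param axis Unit 2-vector of the elongation axis (default the x axis,
#'   i.e. the line between the electrodes).
#' @return An object of class `elongation_result` with fields `u_tip_um`,
#'   `L_um`, `L_star`, `R_um` and a strain summary.
#' @export
elongation <- function(def, axis = c(1, 0)) {
  stopifnot(inherits(def, "disk_deformation"), length(axis) == 2L)
  axis <- axis / sqrt(sum(axis^2))
  th0 <- atan2(axis[2L], axis[1L])
  u1 <- disk_displacement(def, def$R, th0)
  u2 <- disk_displacement(def, def$R, th0 + pi)
  proj <- function(u) u$ux * axis[1L] + u$uy * axis[2L]
  u_tip <- (proj(u1) - proj(u2)) / 2
  structure(list(u_tip_um = u_tip,
                 L_um = def$R + u_tip,
                 L_star = u_tip / def$R,
                 R_um = def$R,
                 axis = axis,
                 max_u_over_R = def$max_u / def$R),
            class = "elongation_result")
}

#' @export
print.elongation_result <- function(x, ...) {
  cat(sprintf("<elongation_result> R = %g um\n", x$R_um))
  cat(sprintf("  u_tip = %.5g um, L = %.5g um, L* = %.5g\n",
              x$u_tip_um, x$L_um, x$L_star))
  invisible(x)
}

#' @export
as.list.elongation_result <- function(x, ...) {
  list(u_tip_um = x$u_tip_um, L_um = x$L_um, L_star = x$L_star,
       R_um = x$R_um, max_u_over_R = x$max_u_over_R)
}
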