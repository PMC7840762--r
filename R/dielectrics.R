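#' Dielectric material
#'
#' A linear isotropic dielectric described by its relative permittivity and
#' ohmic conductivity. Used for the suspending medium, the cell membrane and
#' the cytoplasm.
#'
#' @param eps_r Relative permittivity (dimensionless, > 0).
#' @param sigma Conductivity in S/m (>= 0). Default 0 (lossless).
#' @return An object of class `dep_material`.
#' @examples
#' medium <- dep_material(80, sigma = 1e-4)
#' complex_permittivity(medium, omega = 2 * pi * 3e6, relative = TRUE)
#' @seealso [complex_permittivity()], [shell_cell()]
#' @export
dep_material <- function(eps_r, sigma = 0) {
  stopifnot(is.numeric(eps_r), length(eps_r) == 1L,
            is.numeric(sigma), length(sigma) == 1L)
  if (!is.finite(eps_r) || eps_r <= 0)
    stop("relative permittivity must be positive and finite")
  if (!is.finite(sigma) || sigma < 0)
    stop("conductivity must be non-negative and finite")
  structure(list(eps_r = eps_r, sigma = sigma), class = "dep_material")
}

#' @export
print.dep_material <- function(x, ...) {
  cat(sprintf("<dep_material> eps_r = %g, sigma = %g S/m\n", x$eps_r, x$sigma))
  invisible(x)
}

#' Complex permittivity of a lossy dielectric
#'
#' Evaluates \eqn{\varepsilon^* = \varepsilon_r \varepsilon_0 - j\sigma/\omega}
#' (absolute form) or \eqn{\varepsilon_r - j\sigma/(\omega\varepsilon_0)}
#' (relative form) at angular frequency \eqn{\omega}.
#'
#' @param material A [dep_material()].
#' @param omega Angular frequency in rad/s (> 0); may be a vector.
#' @param relative If `TRUE` return the relative (dimensionless) form;
#'   default `FALSE` returns farads per metre.
#' @return Complex vector, one element per `omega`.
#' @export
complex_permittivity <- function(material, omega, relative = FALSE) {
  stopifnot(inherits(material, "dep_material"))
  if (!is.numeric(omega) || length(omega) < 1L ||
      any(!is.finite(omega)) || any(omega <= 0))
    stop("invalid frequency: omega must be positive and finite")
  if (relative)
    complex(real = material$eps_r, imaginary = -material$sigma / (omega * EPS0))
  else
    complex(real = material$eps_r * EPS0, imaginary = -material$sigma / omega)
}

#' Clausius-Mossotti factor
#'
#' The complex contrast factor
#' \eqn{K = (\varepsilon_p^* - \varepsilon_m^*)/(\varepsilon_p^* + 2\varepsilon_m^*)}
#' of a spherical particle with complex permittivity `eps_p` in a medium with
#' complex permittivity `eps_m`. Its real part sets the sign and magnitude of
#' the dipole DEP force: positive for particles more polarizable than the
#' medium (pDEP, attraction towards high field), negative otherwise.
#' Both arguments may be given in absolute or relative units as long as they
#' are consistent (K is invariant under joint rescaling).
#'
#' @param eps_p Complex (or real) particle permittivity.
#' @param eps_m Complex (or real) medium permittivity.
#' @return Complex vector.
#' @examples
#' clausius_mossotti(120, 80)   # 40/280
#' @export
clausius_mossotti <- function(eps_p, eps_m) {
  eps_p <- as.complex(eps_p); eps_m <- as.complex(eps_m)
  den <- eps_p + 2 * eps_m
  scale <- pmax(Mod(eps_p), Mod(eps_m))
  if (any(Mod(den) <= 1e-12 * scale))
    stop("singular contrast: eps_p + 2*eps_m is zero")
  (eps_p - eps_m) / den
}

#' Single-shell cell model
#'
#' A membrane-bounded cell represented as two concentric dielectrics: a thin
#' membrane shell of thickness `thickness` over a cytoplasmic core. The
#' effective homogeneous-sphere permittivity depends on the ratio of membrane
#' thickness to cell radius and on both materials.
#'
#' @param radius Cell radius in micrometres (> 0).
#' @param thickness Membrane thickness in micrometres (0 < thickness < radius).
#'   Typical lipid bilayers are 5-10 nm, i.e. 0.005-0.01 um.
#' @param membrane,cytoplasm [dep_material()] objects.
#' @return An object of class `shell_cell`.
#' @seealso [shell_effective_permittivity()]
#' @export
shell_cell <- function(radius, thickness, membrane, cytoplasm) {
  stopifnot(is.numeric(radius), length(radius) == 1L,
            is.numeric(thickness), length(thickness) == 1L,
            inherits(membrane, "dep_material"),
            inherits(cytoplasm, "dep_material"))
  if (!is.finite(radius) || radius <= 0)
    stop("cell radius must be positive")
  if (!is.finite(thickness) || thickness <= 0 || thickness >= radius)
    stop("membrane thickness must satisfy 0 < thickness < radius")
  structure(list(radius = radius, thickness = thickness,
                 membrane = membrane, cytoplasm = cytoplasm),
            class = "shell_cell")
}

#' @export
print.shell_cell <- function(x, ...) {
  cat(sprintf("<shell_cell> R = %g um, t = %g um (t/R = %.3g)\n",
              x$radius, x$thickness, x$thickness / x$radius))
  cat("  membrane : "); print(x$membrane)
  cat("  cytoplasm: "); print(x$cytoplasm)
  invisible(x)
}

#' Effective complex permittivity of a single-shell cell
#'
#' Concentric-shell mixing rule: with \eqn{a = R/(R-t)} and
#' \eqn{X = (\varepsilon_{cyt}^* - \varepsilon_{mem}^*)/(\varepsilon_{cyt}^* +
#' 2\varepsilon_{mem}^*)}, the equivalent homogeneous sphere has
#' \deqn{\varepsilon_c^* = \varepsilon_{mem}^* \frac{a^3 + 2X}{a^3 - X}.}
#' As \eqn{t \to 0} this tends to the cytoplasm permittivity; for
#' \eqn{\varepsilon_{mem}^* = \varepsilon_{cyt}^*} it reduces to the
#' homogeneous value exactly.
#'
#' @param cell A [shell_cell()].
#' @param omega Angular frequency in rad/s (> 0).
#' @inheritParams complex_permittivity
#' @return Complex scalar (or vector over `omega`).
#' @export
shell_effective_permittivity <- function(cell, omega, relative = FALSE) {
  stopifnot(inherits(cell, "shell_cell"))
  e_mem <- complex_permittivity(cell$membrane, omega, relative = TRUE)
  e_cyt <- complex_permittivity(cell$cytoplasm, omega, relative = TRUE)
  a <- cell$radius / (cell$radius - cell$thickness)
  X <- (e_cyt - e_mem) / (e_cyt + 2 * e_mem)
  den <- a^3 - X
  if (any(Mod(den) <= 1e-12 * a^3))
    stop("singular shell: a^3 - X vanishes")
  out <- e_mem * (a^3 + 2 * X) / den
  if (relative) out else out * EPS0
}
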