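#' Simulation configuration for a single stretch
#'
#' Bundles the cell, materials, drive, electrode geometry, elastic properties
#' and numerical settings of one stretching simulation. Defaults follow the
#' optimization study conditions: an 8 um diameter cell with relative
#' permittivity 120 and Young's modulus 0.1 kPa in a medium of permittivity
#' 80, driven at 10 V peak-to-peak.
#'
#' @param R Cell radius in micrometres (default 4).
#' @param eps_m,eps_c Relative permittivities of medium and cell (real parts
#'   used in the quasi-static solve). `eps_c` is ignored when `cell` is
#'   given.
#' @param cell Optional [shell_cell()]; its effective permittivity at the
#'   drive frequency replaces `eps_c` (real part).
#' @param V Peak-to-peak voltage (default 10).
#' @param freq Drive frequency in Hz (default 3e6); only used with `cell`.
#' @param w,d Electrode width and gap in micrometres (defaults 30 and 45).
#' @param shapes Length-2 character, facing-face shapes (default both
#'   rectangular); see [electrode_shapes()].
#' @param apex_half_angle,ellipse_ratio Shape parameters, see
#'   [electrode_pair()].
#' @param cell_center Cell centre (um), default the gap midpoint.
#' @param youngs_modulus Young's modulus in Pa (default 100, i.e. 0.1 kPa).
#' @param poisson Poisson ratio (default 0.49, nearly incompressible).
#' @param regime Planar elasticity regime (default `"plane_stress"`).
#' @param n_R Field-solver resolution, grid cells per cell radius
#'   (default 20).
#' @param stations Interface sampling stations (default 360).
#' @param domain_factor Domain extent in units of `w + d` (default 4).
#' @param traction_mode `"peak"` or `"rms"`, see [surface_traction()].
#' @return An object of class `stretch_config`.
#' @export
stretch_config <- function(R = 4, eps_m = 80, eps_c = 120, cell = NULL,
                           V = 10, freq = 3e6,
                           w = 30, d = 45,
                           shapes = c("rectangular", "rectangular"),
                           apex_half_angle = 30, ellipse_ratio = 0.5,
                           cell_center = c(0, 0),
                           youngs_modulus = 100, poisson = 0.49,
                           regime = "plane_stress",
                           n_R = 20, stations = 360L,
                           domain_factor = 4,
                           traction_mode = "peak") {
  shapes <- rep_len(as.character(shapes), 2L)
  cfg <- list(R = R, eps_m = eps_m, eps_c = eps_c, cell = cell,
              V = V, freq = freq, w = w, d = d, shapes = shapes,
              apex_half_angle = apex_half_angle,
              ellipse_ratio = ellipse_ratio,
              cell_center = cell_center,
              youngs_modulus = youngs_modulus, poisson = poisson,
              regime = regime, n_R = n_R, stations = as.integer(stations),
              domain_factor = domain_factor,
              traction_mode = traction_mode)
  class(cfg) <- "stretch_config"
  cfg
}

#' Modify a stretch configuration
#'
#' Returns a copy of `config` with the named fields replaced.
#'
#' @param config A [stretch_config()].
#' @param ... Named fields to replace.
#' @return A `stretch_config`.
#' @export
update_config <- function(config, ...) {
  stopifnot(inherits(config, "stretch_config"))
  mods <- list(...)
  bad <- setdiff(names(mods), names(config))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  config[names(mods)] <- mods
  config
}

#' @export
print.stretch_config <- function(x, ...) {
  cat(sprintf("<stretch_config> R = %g um, %s|%s w = %g d = %g um\n",
              x$R, x$shapes[1L], x$shapes[2L], x$w, x$d))
  cat(sprintf("  eps_m = %g, eps_c = %s, V = %g Vpp, E = %g Pa (nu = %g, %s)\n",
              x$eps_m,
              if (is.null(x$cell)) format(x$eps_c) else "from shell model",
              x$V, x$youngs_modulus, x$poisson, x$regime))
  cat(sprintf("  numerics: n_R = %d, %d stations, domain x%g, %s traction\n",
              as.integer(x$n_R), x$stations, x$domain_factor, x$traction_mode))
  invisible(x)
}

#' Read a stretch configuration from a YAML or JSON file
#'
#' The file holds a flat mapping of [stretch_config()] arguments (units as
#' documented there: micrometres, volts, hertz, pascals). An optional `cell`
#' block with fields `radius`, `thickness`, `membrane` and `cytoplasm`
#' (each material a mapping of `eps_r` and `sigma`) defines a single-shell
#' cell.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return A `stretch_config`.
#' @export
read_stretch_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("unsupported config format: .", ext)
  if (!is.null(raw$cell)) {
    cb <- raw$cell
    raw$cell <- shell_cell(cb$radius, cb$thickness,
                           dep_material(cb$membrane$eps_r, cb$membrane$sigma %||% 0),
                           dep_material(cb$cytoplasm$eps_r, cb$cytoplasm$sigma %||% 0))
    if (!is.null(cb$radius)) raw$R <- cb$radius
  }
  raw <- raw[names(raw) %in% names(formals(stretch_config))]
  do.call(stretch_config, raw)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## effective relative cell permittivity used by the quasi-static solve
.config_eps_c <- function(config) {
  if (is.null(config$cell)) config$eps_c
  else Re(shell_effective_permittivity(config$cell, 2 * pi * config$freq,
                                       relative = TRUE))
}

#' Simulate one dielectrophoretic stretch end-to-end
#'
#' Runs the full one-way-coupled pipeline: build the chip geometry, solve the
#' electrostatics, evaluate the Maxwell-stress surface traction on the cell
#' boundary, remove rigid-body resultants, solve the elastic disk problem and
#' report the elongation. The coupling is a single pass (forces from the
#' undeformed geometry), so the result is exactly quadratic in `V` and
#' exactly inversely proportional to the Young's modulus.
#'
#' @param config A [stretch_config()].
#' @param keep If `TRUE`, attach the field solution, traction and
#'   deformation objects to the result (default `FALSE` to keep results
#'   light).
#' @return An `elongation_result` with the configuration and stage
#'   diagnostics attached (`$config`, `$diagnostics`).
#' @export
simulate_stretch <- function(config, keep = FALSE) {
  stopifnot(inherits(config, "stretch_config"))
  stage <- "geometry"
  out <- tryCatch({
    pair <- electrode_pair(config$w, config$d,
                           left = config$shapes[1L], right = config$shapes[2L],
                           apex_half_angle = config$apex_half_angle,
                           ellipse_ratio = config$ellipse_ratio)
    geom <- build_geometry(pair, config$R, cell_center = config$cell_center,
                           domain_factor = config$domain_factor)
    stage <- "field"
    eps_c <- .config_eps_c(config)
    sol <- solve_potential(geom, config$eps_m, eps_c, config$V,
                           n_R = config$n_R, stations = config$stations)
    stage <- "traction"
    tr <- surface_traction(sol, config$eps_m, eps_c,
                           mode = config$traction_mode)
    F_raw <- net_force(tr)
    stage <- "equilibrate"
    tre <- equilibrate_traction(tr)
    stage <- "elastic"
    props <- elastic_properties(config$youngs_modulus, config$poisson,
                                config$regime)
    def <- deform_disk(tre, props)
    stage <- "elongation"
    res <- elongation(def)
    res$config <- config
    res$diagnostics <- list(
      max_E = max(sqrt(sol$Ex^2 + sol$Ey^2)),
      max_traction = max(sqrt(tr$stations$fx^2 + tr$stations$fy^2)),
      net_force_raw = F_raw,
      solver_residual = sol$residual,
      n_unknowns = sol$n_unknowns,
      eps_c_effective = eps_c)
    if (keep) {
      res$field <- sol
      res$traction <- tre
      res$deformation <- def
    }
    res
  }, error = function(e) {
    stop(sprintf("simulate_stretch failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  out
}

#' Mesh-independence study
#'
#' Runs the full pipeline over a ladder of solver resolutions and returns the
#' coarsest resolution at which one further refinement changes the elongation
#' by less than `tol` (relative).
#'
#' @param config A [stretch_config()]; its `n_R` field is ignored.
#' @param tol Relative tolerance on L* (default 0.01). `tol = Inf` returns
#'   the coarsest ladder entry.
#' @param ladder Increasing integer resolutions to try
#'   (default `c(6, 8, 11, 16, 23, 32)`).
#' @return The selected `n_R`, with the per-resolution elongations attached
#'   as attribute `"history"`.
#' @export
mesh_independence <- function(config, tol = 0.01,
                              ladder = c(6L, 8L, 11L, 16L, 23L, 32L)) {
  stopifnot(inherits(config, "stretch_config"), tol > 0, length(ladder) >= 2L)
  ladder <- sort(as.integer(ladder))
  if (is.infinite(tol)) {
    out <- ladder[1L]
    attr(out, "history") <- NULL
    return(out)
  }
  ls <- numeric(length(ladder))
  for (i in seq_along(ladder)) {
    ls[i] <- simulate_stretch(update_config(config, n_R = ladder[i]))$L_star
    if (i >= 2L) {
      change <- abs(ls[i] - ls[i - 1L]) / max(abs(ls[i]), 1e-300)
      if (change < tol) {
        out <- ladder[i - 1L]
        attr(out, "history") <- data.frame(n_R = ladder[seq_len(i)],
                                           L_star = ls[seq_len(i)])
        return(out)
      }
    }
  }
  stop("refinement error: elongation did not converge within the ladder")
}
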