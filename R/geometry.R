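#' Electrode shape names
#'
#' The facing-face shapes supported for a coplanar electrode pair. `"plate"`
#' is a full-height electrode spanning the whole domain edge; it is the
#' uniform-field validation harness (a dielectric cylinder between two
#' parallel plates) rather than a chip design.
#'
#' @return Character vector of shape names.
#' @export
electrode_shapes <- function() c("rectangular", "triangular", "elliptical", "plate")

#' The six electrode-pair scenarios
#'
#' All pairings of rectangular, triangular and elliptical facing faces that
#' are compared when ranking chip designs.
#'
#' @return Character vector of scenario codes, e.g. `"rect-rect"`.
#' @export
dep_scenarios <- function() {
  c("rect-rect", "rect-tri", "rect-ell", "tri-tri", "tri-ell", "ell-ell")
}

.shape_code <- c(rect = "rectangular", tri = "triangular", ell = "elliptical",
                 plate = "plate")

.match_shape <- function(shape) {
  shape <- as.character(shape)
  hit <- match.arg(shape, c(electrode_shapes(), names(.shape_code)))
  if (hit %in% names(.shape_code)) .shape_code[[hit]] else hit
}

#' Coplanar electrode pair
#'
#' Two facing coplanar electrodes (top view). The gap `gap` separates the two
#' facing apices along the x axis; `width` is the lateral extent of each
#' electrode along y. The facing face of each electrode can be flat
#' (`rectangular`), a protruding triangular tip, or a protruding semi-ellipse.
#' For protruding shapes the apex still sits at the nominal gap edge so that
#' the minimum electrode separation is always `gap`.
#'
#' @param width Electrode width w in micrometres (> 0; 5-50 typical).
#' @param gap Electrode gap d in micrometres (> 0; 20-70 typical).
#' @param left,right Face shapes, see [electrode_shapes()]. Short codes
#'   `"rect"`, `"tri"`, `"ell"` are accepted.
#' @param apex_half_angle Half-angle of the triangular tip in degrees
#'   (default 30).
#' @param ellipse_ratio Protrusion semi-axis of the elliptical face as a
#'   fraction of `width/2` (default 0.5).
#' @return An object of class `electrode_pair`.
#' @export
electrode_pair <- function(width, gap, left = "rectangular", right = left,
                           apex_half_angle = 30, ellipse_ratio = 0.5) {
  stopifnot(is.numeric(width), length(width) == 1L,
            is.numeric(gap), length(gap) == 1L)
  if (!is.finite(width) || width <= 0) stop("electrode width must be positive")
  if (!is.finite(gap) || gap <= 0) stop("electrode gap must be positive")
  if (!is.finite(apex_half_angle) || apex_half_angle <= 0 || apex_half_angle >= 90)
    stop("apex_half_angle must lie in (0, 90) degrees")
  if (!is.finite(ellipse_ratio) || ellipse_ratio <= 0)
    stop("ellipse_ratio must be positive")
  structure(list(width = width, gap = gap,
                 left = .match_shape(left), right = .match_shape(right),
                 apex_half_angle = apex_half_angle,
                 ellipse_ratio = ellipse_ratio),
            class = "electrode_pair")
}

#' Build an electrode pair from a scenario code
#'
#' @param scenario One of [dep_scenarios()], e.g. `"rect-tri"`.
#' @inheritParams electrode_pair
#' @param ... Passed to [electrode_pair()].
#' @return An `electrode_pair`.
#' @export
scenario_pair <- function(scenario, width, gap, ...) {
  scenario <- match.arg(scenario, dep_scenarios())
  parts <- strsplit(scenario, "-", fixed = TRUE)[[1L]]
  electrode_pair(width, gap, left = parts[1L], right = parts[2L], ...)
}

#' @export
print.electrode_pair <- function(x, ...) {
  cat(sprintf("<electrode_pair> %s | %s, w = %g um, d = %g um\n",
              x$left, x$right, x$width, x$gap))
  invisible(x)
}

## Vectorized membership test: is node (x, y) inside the electrode on `side`
## (-1 = left, +1 = right)? Shapes are defined for the left electrode and
## mirrored. Coordinates in micrometres.
in_electrode <- function(x, y, pair, side) {
  xs <- if (side < 0) -x else x
  shape <- if (side < 0) pair$left else pair$right
  d2 <- pair$gap / 2
  w2 <- pair$width / 2
  tolg <- 1e-9 * max(1, d2)
  switch(shape,
    plate = xs >= d2 - tolg,
    rectangular = xs >= d2 - tolg & abs(y) <= w2 + tolg,
    triangular = {
      ta <- tan(pair$apex_half_angle * pi / 180)
      xs >= d2 - tolg & abs(y) <= pmin(w2, ta * (xs - d2)) + tolg
    },
    elliptical = {
      ax <- pair$ellipse_ratio * w2
      body <- xs >= d2 + ax - tolg & abs(y) <= w2 + tolg
      cap <- xs >= d2 - tolg & xs < d2 + ax &
        ((xs - (d2 + ax))^2 / ax^2 + y^2 / w2^2) <= 1 + 1e-9
      body | cap
    },
    stop("unknown electrode shape: ", shape))
}

## Distance from a point to the facing boundary of the electrode on `side`.
## Used only for the cell/electrode clearance check; for protruding shapes the
## apex point dominates near the gap centre, for rectangular the face segment.
.electrode_clearance <- function(pt, pair, side) {
  d2 <- pair$gap / 2
  w2 <- pair$width / 2
  xs <- if (side < 0) -pt[1L] else pt[1L]
  y <- pt[2L]
  shape <- pair[[if (side < 0) "left" else "right"]]
  if (shape %in% c("rectangular", "plate")) {
    ## signed distance to the half-strip {x >= d2, |y| <= w2}
    dx <- d2 - xs
    dy <- if (shape == "plate") -Inf else abs(y) - w2
    if (dx <= 0 && dy <= 0) max(dx, dy)          # inside (negative)
    else sqrt(max(dx, 0)^2 + max(dy, 0)^2)
  } else {
    ## protruding shapes: the facing point nearest the gap is the apex (d2, 0)
    sqrt((d2 - xs)^2 + y^2) * (if (xs >= d2 && abs(y) < 1e-12) -1 else 1)
  }
}

#' Chip geometry: electrode pair plus embedded cell disk
#'
#' Places a circular cell of radius `cell_radius` (default centred midway
#' between the two electrode faces) in a rectangular simulation domain whose
#' total extent is `domain_factor * (width + gap)` in each direction.
#'
#' The cell disk must not touch either electrode: the 2-D plane model
#' represents the channel mid-height, and a disk overlapping the electrode
#' footprint leaves the model's domain of validity (the Maxwell traction on
#' the covered arc is not representable in-plane). Touching or overlapping
#' disks therefore raise a geometry error.
#'
#' @param pair An [electrode_pair()].
#' @param cell_radius Cell radius R in micrometres (> 0).
#' @param cell_center Cell centre (x, y) in micrometres; default the gap
#'   midpoint `c(0, 0)`.
#' @param domain_factor Domain extent in units of `width + gap` (default 4).
#' @return An object of class `chip_geometry`; element `clearance` is the
#'   smallest distance (um) from the cell boundary to an electrode.
#' @examples
#' geom <- build_geometry(electrode_pair(50, 20), cell_radius = 4)
#' @export
build_geometry <- function(pair, cell_radius, cell_center = c(0, 0),
                           domain_factor = 4) {
  stopifnot(inherits(pair, "electrode_pair"),
            is.numeric(cell_radius), length(cell_radius) == 1L,
            is.numeric(cell_center), length(cell_center) == 2L)
  if (!is.finite(cell_radius) || cell_radius <= 0)
    stop("cell radius must be positive")
  plate <- pair$left == "plate" || pair$right == "plate"
  if (plate) {
    half_x <- pair$gap / 2
    half_y <- pair$gap / 2
  } else {
    half_x <- domain_factor * (pair$width + pair$gap) / 2
    half_y <- half_x
  }
  if (abs(cell_center[1L]) + cell_radius >= half_x ||
      abs(cell_center[2L]) + cell_radius >= half_y)
    stop("geometry error: cell disk does not fit inside the domain")
  clearance <- Inf
  for (side in c(-1, 1)) {
    clr <- .electrode_clearance(cell_center, pair, side) - cell_radius
    if (clr <= 0)
      stop(sprintf(
        "geometry error: cell disk touches the %s electrode (by %.2f um)",
        if (side < 0) "left" else "right", -clr))
    clearance <- min(clearance, clr)
  }
  structure(list(pair = pair, cell_radius = cell_radius,
                 cell_center = cell_center,
                 half_x = half_x, half_y = half_y,
                 domain_factor = domain_factor,
                 clearance = clearance),
            class = "chip_geometry")
}

#' @export
print.chip_geometry <- function(x, ...) {
  cat(sprintf("<chip_geometry> %s|%s  w = %g, d = %g, R = %g um\n",
              x$pair$left, x$pair$right, x$pair$width, x$pair$gap,
              x$cell_radius))
  cat(sprintf("  domain: [%g, %g] x [%g, %g] um, cell at (%g, %g)\n",
              -x$half_x, x$half_x, -x$half_y, x$half_y,
              x$cell_center[1L], x$cell_center[2L]))
  invisible(x)
}
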