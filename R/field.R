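## 2-D electrostatics of the chip: finite-volume discretization of
## div(eps grad Phi) = 0 on a graded tensor-product grid, Dirichlet +-V/2 on
## the electrodes, homogeneous Neumann on the outer boundary. The dielectric
## cell disk enters through face permittivities; faces cut by the cell
## boundary use a 1-D harmonic sub-grid average so the normal flux sees the
## interface at its true position rather than at the staircase.

## Graded 1-D grid: uniform spacing h inside [core[1], core[2]], geometric
## growth (ratio `stretch`) out to the domain boundaries, which are hit
## exactly.
.grid_1d <- function(core, h, dom, stretch = 1.25) {
  core[1L] <- max(core[1L], dom[1L])
  core[2L] <- min(core[2L], dom[2L])
  n_core <- max(2L, ceiling((core[2L] - core[1L]) / h))
  g <- seq(core[1L], core[2L], length.out = n_core + 1L)
  step <- h
  right <- numeric(0)
  x <- core[2L]
  while (x < dom[2L] - 1e-9) {
    step <- step * stretch
    x <- x + step
    if (x >= dom[2L] - 0.35 * step) x <- dom[2L]
    right <- c(right, x)
  }
  step <- h
  left <- numeric(0)
  x <- core[1L]
  while (x > dom[1L] + 1e-9) {
    step <- step * stretch
    x <- x - step
    if (x <= dom[1L] + 0.35 * step) x <- dom[1L]
    left <- c(x, left)
  }
  c(left, g, right)
}

## Bilinear interpolation of a matrix field M[i, j] given grid vectors gx, gy
## at query points (xi, yi). Vectorized; queries must lie inside the grid.
.interp2 <- function(gx, gy, M, xi, yi) {
  i <- findInterval(xi, gx, rightmost.closed = TRUE)
  j <- findInterval(yi, gy, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(gx) - 1L)
  j <- pmin(pmax(j, 1L), length(gy) - 1L)
  tx <- (xi - gx[i]) / (gx[i + 1L] - gx[i])
  ty <- (yi - gy[j]) / (gy[j + 1L] - gy[j])
  n <- nrow(M)
  p00 <- M[i + (j - 1L) * n]
  p10 <- M[i + 1L + (j - 1L) * n]
  p01 <- M[i + j * n]
  p11 <- M[i + 1L + j * n]
  (1 - tx) * (1 - ty) * p00 + tx * (1 - ty) * p10 +
    (1 - tx) * ty * p01 + tx * ty * p11
}

## Face permittivity between two nodes with radii (from the cell centre)
## ra, rb: harmonic average weighted by the fraction of the segment lying
## inside the disk when the face is cut by the interface.
.face_eps <- function(ra, rb, ea, eb, R, eps_in, eps_out) {
  cross <- (ra - R) * (rb - R) < 0
  out <- 2 * ea * eb / (ea + eb)
  if (any(cross)) {
    lo <- pmin(ra, rb)
    hi <- pmax(ra, rb)
    f_in <- pmin(1, pmax(0, (R - lo) / (hi - lo)))
    out[cross] <- 1 / (f_in[cross] / eps_in + (1 - f_in[cross]) / eps_out)
  }
  out
}

#' Solve the chip electrostatics
#'
#' Solves \eqn{\nabla\cdot(\varepsilon\nabla\Phi) = 0} on the 2-D chip plane
#' with piecewise permittivity (`eps_c` inside the cell disk, `eps_m`
#' outside), Dirichlet \eqn{\Phi = \pm V/2} on the two electrodes and
#' homogeneous Neumann conditions on the outer boundary. A finite-volume
#' scheme on a graded tensor grid is used; faces cut by the cell boundary
#' carry a sub-grid harmonic permittivity. The electric field
#' \eqn{E = -\nabla\Phi} is returned on the grid together with one-sided
#' field samples on both sides of the cell interface at `stations` angular
#' stations (each obtained by linear extrapolation from two sampling rings so
#' that the discontinuity is never straddled).
#'
#' @param geom A [build_geometry()] result.
#' @param eps_m,eps_c Relative permittivities of medium and cell (real).
#' @param V Peak-to-peak drive voltage; electrode potentials are
#'   \eqn{\pm V/2}.
#' @param n_R Resolution: number of grid cells across the cell radius in the
#'   fine region (default 20).
#' @param stations Number of interface sampling angles (default 360).
#' @param stretch Geometric grid-growth ratio outside the fine core
#'   (default 1.25).
#' @return An object of class `field_solution` with elements `x`, `y` (grid
#'   vectors, um), `phi` (V), `Ex`, `Ey` (V/m), `interface` (data frame of
#'   interface samples), and solver metadata.
#' @export
solve_potential <- function(geom, eps_m, eps_c, V, n_R = 20, stations = 360L,
                            stretch = 1.25) {
  stopifnot(inherits(geom, "chip_geometry"),
            is.numeric(eps_m), eps_m > 0, is.numeric(eps_c), eps_c > 0,
            is.numeric(V), V > 0, n_R >= 4)
  pair <- geom$pair
  R <- geom$cell_radius
  cc <- geom$cell_center
  h <- R / n_R
  pad <- 2 * h
  plate <- pair$left == "plate" || pair$right == "plate"
  if (plate) {
    x_core <- c(cc[1L] - R - 6 * h, cc[1L] + R + 6 * h)
    y_core <- x_core - cc[1L] + cc[2L]
  } else {
    x_core <- c(min(-pair$gap / 2 - pad, cc[1L] - R - 6 * h),
                max(pair$gap / 2 + pad, cc[1L] + R + 6 * h))
    y_core <- c(min(-pair$width / 2 - pad, cc[2L] - R - 6 * h),
                max(pair$width / 2 + pad, cc[2L] + R + 6 * h))
  }
  gx <- .grid_1d(x_core, h, c(-geom$half_x, geom$half_x), stretch)
  gy <- .grid_1d(y_core, h, c(-geom$half_y, geom$half_y), stretch)
  nx <- length(gx); ny <- length(gy)

  X <- matrix(gx, nx, ny)
  Y <- matrix(gy, nx, ny, byrow = TRUE)
  inL <- in_electrode(X, Y, pair, -1L)
  inR <- in_electrode(X, Y, pair, +1L)
  if (any(inL & inR)) stop("electrodes intersect; check width/gap")
  diri <- inL | inR
  phi_d <- matrix(0, nx, ny)
  phi_d[inL] <- -V / 2
  phi_d[inR] <- +V / 2

  r_node <- sqrt((X - cc[1L])^2 + (Y - cc[2L])^2)
  eps_node <- matrix(eps_m, nx, ny)
  eps_node[r_node <= R] <- eps_c

  ## control-volume widths
  dxc <- diff(gx); dyc <- diff(gy)
  wx <- c(dxc[1L] / 2, (dxc[-1L] + dxc[-(nx - 1L)]) / 2, dxc[nx - 1L] / 2)
  wy <- c(dyc[1L] / 2, (dyc[-1L] + dyc[-(ny - 1L)]) / 2, dyc[ny - 1L] / 2)

  ## face conductances
  efx <- .face_eps(r_node[-nx, ], r_node[-1L, ], eps_node[-nx, ],
                   eps_node[-1L, ], R, eps_c, eps_m)
  Gx <- efx * matrix(wy, nx - 1L, ny, byrow = TRUE) /
    matrix(dxc, nx - 1L, ny)
  efy <- .face_eps(r_node[, -ny], r_node[, -1L], eps_node[, -ny],
                   eps_node[, -1L], R, eps_c, eps_m)
  Gy <- efy * matrix(wx, nx, ny - 1L) /
    matrix(dyc, nx, ny - 1L, byrow = TRUE)

  free <- !diri
  n_free <- sum(free)
  idx <- matrix(NA_integer_, nx, ny)
  idx[free] <- seq_len(n_free)

  trip_i <- vector("list", 6L); trip_j <- trip_i; trip_x <- trip_i
  rhs <- numeric(n_free)
  k <- 0L
  add_faces <- function(ia, ib, g, pda, pdb) {
    ## ia, ib: unknown indices (NA if Dirichlet); g conductance
    ff <- !is.na(ia) & !is.na(ib)
    fd <- !is.na(ia) & is.na(ib)
    df <- is.na(ia) & !is.na(ib)
    k <<- k + 1L
    trip_i[[k]] <<- c(ia[ff], ib[ff], ia[ff], ib[ff], ia[fd], ib[df])
    trip_j[[k]] <<- c(ia[ff], ib[ff], ib[ff], ia[ff], ia[fd], ib[df])
    trip_x[[k]] <<- c(g[ff], g[ff], -g[ff], -g[ff], g[fd], g[df])
    if (any(fd)) rhs[ia[fd]] <<- rhs[ia[fd]] + g[fd] * pdb[fd]
    if (any(df)) rhs[ib[df]] <<- rhs[ib[df]] + g[df] * pda[df]
    invisible(NULL)
  }
  add_faces(as.vector(idx[-nx, ]), as.vector(idx[-1L, ]), as.vector(Gx),
            as.vector(phi_d[-nx, ]), as.vector(phi_d[-1L, ]))
  add_faces(as.vector(idx[, -ny]), as.vector(idx[, -1L]), as.vector(Gy),
            as.vector(phi_d[, -ny]), as.vector(phi_d[, -1L]))

  A <- Matrix::sparseMatrix(i = unlist(trip_i[seq_len(k)]),
                            j = unlist(trip_j[seq_len(k)]),
                            x = unlist(trip_x[seq_len(k)]),
                            dims = c(n_free, n_free))
  sol <- tryCatch(
    as.numeric(Matrix::solve(Matrix::forceSymmetric(A, uplo = "L"), rhs)),
    error = function(e) stop("solver error: linear solve failed (",
                             conditionMessage(e), ")"))
  resid <- max(abs(A %*% sol - rhs)) / max(abs(rhs), 1e-30)
  if (!all(is.finite(sol)) || resid > 1e-6)
    stop(sprintf("solver error: non-convergent solve, relative residual %.3g",
                 resid))

  phi <- phi_d
  phi[free] <- sol

  ## E = -grad(phi); coordinates are um, so multiply by 1e6 to get V/m
  Ex <- matrix(0, nx, ny)
  Ex[2:(nx - 1L), ] <- -(phi[3:nx, ] - phi[1:(nx - 2L), ]) /
    (gx[3:nx] - gx[1:(nx - 2L)])
  Ex[1L, ] <- -(phi[2L, ] - phi[1L, ]) / dxc[1L]
  Ex[nx, ] <- -(phi[nx, ] - phi[nx - 1L, ]) / dxc[nx - 1L]
  Ey <- matrix(0, nx, ny)
  Ey[, 2:(ny - 1L)] <- -sweep(phi[, 3:ny] - phi[, 1:(ny - 2L)], 2L,
                              gy[3:ny] - gy[1:(ny - 2L)], "/")
  Ey[, 1L] <- -(phi[, 2L] - phi[, 1L]) / dyc[1L]
  Ey[, ny] <- -(phi[, ny] - phi[, ny - 1L]) / dyc[ny - 1L]
  Ex <- Ex * 1e6
  Ey <- Ey * 1e6

  ## interface samples: two rings on each side, linear extrapolation to R
  th <- 2 * pi * (seq_len(stations) - 1L) / stations
  nxv <- cos(th); nyv <- sin(th)
  ## sampling offsets: 1.5 and 3 fine cells; the outer rings are capped so
  ## they never come closer than a third of the clearance to an electrode
  ## (near-gap-filling cells), the inner rings are unconstrained
  d1o <- min(1.5 * h, geom$clearance / 3)
  d2o <- 2 * d1o
  d1i <- 1.5 * h
  d2i <- 3 * h
  samp <- function(r) {
    xs <- cc[1L] + r * nxv; ys <- cc[2L] + r * nyv
    list(Ex = .interp2(gx, gy, Ex, xs, ys), Ey = .interp2(gx, gy, Ey, xs, ys))
  }
  so1 <- samp(R + d1o); so2 <- samp(R + d2o)
  si1 <- samp(max(R - d1i, 0.05 * R)); si2 <- samp(max(R - d2i, 0.05 * R))
  raw <- data.frame(
    theta = th, nx = nxv, ny = nyv,
    Ex_out = 2 * so1$Ex - so2$Ex, Ey_out = 2 * so1$Ey - so2$Ey,
    Ex_in = 2 * si1$Ex - si2$Ex, Ey_in = 2 * si1$Ey - si2$Ey)
  ## Reconcile the one-sided samples with the exact interface conditions:
  ## the tangential field and the normal displacement eps*E.n are continuous
  ## across a charge-free dielectric interface, so the best estimate of each
  ## is the average of the two sides. The reconciled samples satisfy both
  ## conditions identically, which removes the cancellation error that the
  ## stress jump would otherwise amplify; the raw samples are kept for
  ## discretization-error diagnostics.
  En_out <- raw$Ex_out * nxv + raw$Ey_out * nyv
  En_in <- raw$Ex_in * nxv + raw$Ey_in * nyv
  Et_out <- -raw$Ex_out * nyv + raw$Ey_out * nxv
  Et_in <- -raw$Ex_in * nyv + raw$Ey_in * nxv
  Dn <- (eps_m * En_out + eps_c * En_in) / 2
  Et <- (Et_out + Et_in) / 2
  interface <- data.frame(
    theta = th, nx = nxv, ny = nyv,
    Ex_out = (Dn / eps_m) * nxv - Et * nyv,
    Ey_out = (Dn / eps_m) * nyv + Et * nxv,
    Ex_in = (Dn / eps_c) * nxv - Et * nyv,
    Ey_in = (Dn / eps_c) * nyv + Et * nxv)

  structure(list(x = gx, y = gy, phi = phi, Ex = Ex, Ey = Ey,
                 interface = interface, interface_raw = raw,
                 geom = geom, V = V,
                 eps_m = eps_m, eps_c = eps_c, n_R = n_R, h = h,
                 residual = resid, n_unknowns = n_free),
            class = "field_solution")
}

#' @export
print.field_solution <- function(x, ...) {
  cat(sprintf("<field_solution> %d x %d grid (%d unknowns), h = %.3g um\n",
              length(x$x), length(x$y), x$n_unknowns, x$h))
  cat(sprintf("  V = %g V, eps_m = %g, eps_c = %g, residual = %.2g\n",
              x$V, x$eps_m, x$eps_c, x$residual))
  cat(sprintf("  phi in [%.4g, %.4g] V, max |E| = %.4g V/m\n",
              min(x$phi), max(x$phi), max(sqrt(x$Ex^2 + x$Ey^2))))
  invisible(x)
}

#' @export
as.data.frame.field_solution <- function(x, ...) {
  nx <- length(x$x); ny <- length(x$y)
  data.frame(x = rep(x$x, ny), y = rep(x$y, each = nx),
             phi = as.vector(x$phi),
             Ex = as.vector(x$Ex), Ey = as.vector(x$Ey))
}

#' Export a field solution as a delimited node table
#'
#' Writes columns `x, y, phi, Ex, Ey` (um, V, V/m) as tab-separated text.
#'
#' @param solution A [solve_potential()] result.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_field <- function(solution, path) {
  stopifnot(inherits(solution, "field_solution"))
  utils::write.table(as.data.frame(solution), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Gradient of the squared field magnitude at a point
#'
#' Central-difference estimate of \eqn{\nabla|E|^2} from the gridded solution,
#' in V^2/m^3. Used for dipole-approximation cross-checks; evaluate it on a
#' solution computed without the cell (`eps_c = eps_m`) to obtain the
#' unperturbed field gradient at the cell position.
#'
#' @param solution A [solve_potential()] result.
#' @param x,y Evaluation point in micrometres.
#' @param delta Half-step of the central difference in micrometres
#'   (default two fine-grid cells).
#' @return Numeric length-2 vector `c(dE2/dx, dE2/dy)`.
#' @export
field_grad_E2 <- function(solution, x, y, delta = 2 * solution$h) {
  E2 <- solution$Ex^2 + solution$Ey^2
  gx <- solution$x; gy <- solution$y
  dm <- delta * 1e-6  # metres
  c((.interp2(gx, gy, E2, x + delta, y) -
       .interp2(gx, gy, E2, x - delta, y)) / (2 * dm),
    (.interp2(gx, gy, E2, x, y + delta) -
       .interp2(gx, gy, E2, x, y - delta)) / (2 * dm))
}

#' Plot a field solution
#'
#' Filled image of the potential with the cell outline and electrode masks.
#'
#' @param x A `field_solution`.
#' @param what `"phi"` (default) or `"E"` for the field magnitude.
#' @param ... Passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.field_solution <- function(x, what = c("phi", "E"), ...) {
  what <- match.arg(what)
  z <- if (what == "phi") x$phi else sqrt(x$Ex^2 + x$Ey^2)
  graphics::image(x$x, x$y, z, xlab = "x [um]", ylab = "y [um]",
                  col = grDevices::hcl.colors(64), ...)
  th <- seq(0, 2 * pi, length.out = 181L)
  cc <- x$geom$cell_center
  graphics::lines(cc[1L] + x$geom$cell_radius * cos(th),
                  cc[2L] + x$geom$cell_radius * sin(th))
  invisible(x)
}
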