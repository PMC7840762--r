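test_that("geometry construction places and protects the cell", {
  geom <- build_geometry(electrode_pair(50, 20), 4)
  expect_s3_class(geom, "chip_geometry")
  expect_identical(geom$cell_center, c(0, 0))
  expect_gte(geom$half_x, 2 * (50 + 20))
  ## disk reaching into the gap edge is rejected
  expect_error(build_geometry(electrode_pair(50, 6), 4), "geometry error")
  expect_error(build_geometry(electrode_pair(50, 20), 10), "geometry error")
  ## all shape pairings construct over the design bounds while the disk
  ## stays clear of the gap
  for (sc in dep_scenarios())
    for (w in c(5, 50)) for (d in c(20, 70))
      expect_s3_class(build_geometry(scenario_pair(sc, w, d),
                                     min(8, 0.45 * d)),
                      "chip_geometry")
})

test_that("parallel-plate limit: mid-gap field approaches V/d", {
  ## facing edges much longer than the gap, no dielectric contrast
  geom <- build_geometry(electrode_pair(120, 20), 4)
  sol <- solve_potential(geom, 80, 80, 10, n_R = 10)
  pts_y <- seq(-20, 20, by = 5)
  Exm <- depstretch:::.interp2(sol$x, sol$y, sol$Ex, rep(0, length(pts_y)),
                               pts_y)
  Eym <- depstretch:::.interp2(sol$x, sol$y, sol$Ey, rep(0, length(pts_y)),
                               pts_y)
  expect_equal(sqrt(Exm^2 + Eym^2), rep(10 / 20e-6, length(pts_y)),
               tolerance = 0.02)
})

test_that("discrete maximum principle, voltage linearity and mirror symmetry", {
  sol <- rectrect_solution()
  expect_gte(min(sol$phi), -sol$V / 2 - 1e-12)
  expect_lte(max(sol$phi), sol$V / 2 + 1e-12)

  geom <- sol$geom
  sol2 <- solve_potential(geom, 80, 120, 20, n_R = 8)
  expect_equal(sol2$phi, 2 * sol$phi, tolerance = 1e-10)

  ## antisymmetry about the gap mid-plane for the centred rect-rect chip
  flip <- sol$phi[rev(seq_along(sol$x)), ]
  expect_lt(max(abs(sol$phi + flip)), 1e-8 * sol$V)
})

test_that("dielectric cylinder in a uniform field matches the analytic solution", {
  cyl <- cylinder_fixture()
  ## interior field is uniform with magnitude 2 eps_m/(eps_m+eps_p) E0
  th <- stations_theta(40L)
  xs <- 0.5 * cyl$R * cos(th); ys <- 0.5 * cyl$R * sin(th)
  Exs <- depstretch:::.interp2(cyl$sol$x, cyl$sol$y, cyl$sol$Ex, xs, ys)
  Eys <- depstretch:::.interp2(cyl$sol$x, cyl$sol$y, cyl$sol$Ey, xs, ys)
  Emag <- sqrt(Exs^2 + Eys^2)
  E_in_exact <- 2 * 80 / (80 + 120) * cyl$E0
  expect_equal(Emag, rep(E_in_exact, length(th)), tolerance = 0.02)
  ## interface samples match the transmission solution
  itf <- cyl$sol$interface
  A <- -cyl$E0  # the plate at x = -gap/2 is at -V/2, so E points along -x
  Er_out <- itf$Ex_out * itf$nx + itf$Ey_out * itf$ny
  expect_equal(Er_out, A * (1 + cyl$beta) * cos(itf$theta), tolerance = 0.02)
  Er_in <- itf$Ex_in * itf$nx + itf$Ey_in * itf$ny
  expect_equal(Er_in, A * (1 - cyl$beta) * cos(itf$theta), tolerance = 0.02)
})

test_that("normal displacement-field continuity holds within discretization error", {
  sol <- rectrect_solution()
  raw <- sol$interface_raw
  Dn_out <- sol$eps_m * (raw$Ex_out * raw$nx + raw$Ey_out * raw$ny)
  Dn_in <- sol$eps_c * (raw$Ex_in * raw$nx + raw$Ey_in * raw$ny)
  scale <- stats::median(abs(Dn_out) + abs(Dn_in)) / 2
  expect_lt(stats::median(abs(Dn_out - Dn_in)) / scale, 0.1)
  ## tangential continuity on the raw samples as well
  Et_out <- -raw$Ex_out * raw$ny + raw$Ey_out * raw$nx
  Et_in <- -raw$Ex_in * raw$ny + raw$Ey_in * raw$nx
  expect_lt(stats::median(abs(Et_out - Et_in)) /
              max(stats::median(abs(Et_out)), 1), 0.15)
})

test_that("field gradient concentrates near electrode edges", {
  sol <- rectrect_solution()
  near <- sqrt(sum(field_grad_E2(sol, -45 / 2, 0)^2))
  far <- sqrt(sum(field_grad_E2(sol, 0, 40)^2))
  expect_gt(near, 10 * far)
})

test_that("outer-boundary truncation error is below a percent", {
  cfg <- coarse_config()
  L4 <- suppressWarnings(simulate_stretch(cfg))$L_star
  L8 <- suppressWarnings(simulate_stretch(update_config(cfg,
                                                        domain_factor = 8)))$L_star
  expect_equal(L4, L8, tolerance = 0.01)
})

test_that("field tables export with the documented columns", {
  sol <- rectrect_solution()
  df <- as.data.frame(sol)
  expect_named(df, c("x", "y", "phi", "Ex", "Ey"))
  expect_equal(nrow(df), length(sol$x) * length(sol$y))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_field(sol, path)
  back <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(dim(back), dim(df))
})

test_that("mesh independence selects a converged resolution", {
  cfg <- coarse_config()
  expect_identical(mesh_independence(cfg, tol = Inf,
                                     ladder = c(6L, 8L, 11L)), 6L)
  nr <- mesh_independence(cfg, tol = 0.02, ladder = c(6L, 8L, 11L, 16L, 23L))
  hist <- attr(nr, "history")
  expect_true(as.integer(nr) %in% c(6L, 8L, 11L, 16L))
  ## the selected resolution is the one before the sub-tolerance step
  i <- match(as.integer(nr), hist$n_R)
  expect_lt(abs(hist$L_star[i + 1L] - hist$L_star[i]) /
              abs(hist$L_star[i + 1L]), 0.02)
  ## the field concentrates at sharp triangular tips: the peak field of the
  ## tri-tri chip exceeds the rect-rect one at the same drive and design
  geom_tri <- build_geometry(scenario_pair("tri-tri", 30, 45), 4)
  sol_tri <- solve_potential(geom_tri, 80, 120, 10, n_R = 8)
  sol_rect <- rectrect_solution()
  expect_gt(max(sol_tri$Ex^2 + sol_tri$Ey^2),
            1.5 * max(sol_rect$Ex^2 + sol_rect$Ey^2))
})
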