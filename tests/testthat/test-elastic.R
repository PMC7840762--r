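test_that("elastic properties validate and derive plane constants", {
  p <- elastic_properties(100, 0.49)
  expect_equal(p$mu, 100 / (2 * 1.49))
  expect_equal(p$kappa, (3 - 0.49) / 1.49)
  ps <- elastic_properties(100, 0.49, "plane_strain")
  expect_equal(ps$kappa, 3 - 4 * 0.49)
  expect_error(elastic_properties(-1), "positive")
  expect_error(elastic_properties(100, 0.5), "Poisson")
})

test_that("rigid-body removal leaves a self-equilibrated traction", {
  th <- stations_theta()
  ## translation-like traction (pure n = 1 force mode) is removed entirely
  tr <- traction_from_samples(th, rep(10, 360), rep(0, 360), 4)
  tre <- equilibrate_traction(tr)
  expect_lt(max(abs(tre$stations$fx), abs(tre$stations$fy)), 1e-10)

  ## already self-equilibrated input passes through unchanged
  tr2 <- traction_from_samples(th, 5 * cos(2 * th), 3 * sin(3 * th), 4)
  tre2 <- equilibrate_traction(tr2)
  expect_equal(tre2$stations$fr, tr2$stations$fr, tolerance = 1e-12)
  expect_equal(tre2$stations$ft, tr2$stations$ft, tolerance = 1e-12)

  ## random traction: residual force and torque below 1e-10 of the scale
  set.seed(11)
  trr <- traction_from_samples(th, rnorm(360), rnorm(360), 4)
  trre <- equilibrate_traction(trr)
  scale <- max(sqrt(trre$stations$fx^2 + trre$stations$fy^2)) *
    2 * pi * 4e-6
  expect_lt(sqrt(sum(net_force(trre)^2)) / scale, 1e-10)
  expect_lt(abs(depstretch:::.net_torque(trre)) / (scale * 4e-6), 1e-10)

  ## deform_disk rejects unequilibrated input
  props <- elastic_properties(100, 0.49)
  expect_error(deform_disk(trr, props), "self-equilibrated")
})

test_that("uniform radial pressure reproduces the Lame closed form", {
  th <- stations_theta()
  p0 <- 50
  R <- 4
  tr <- traction_from_samples(th, p0 * cos(th), p0 * sin(th), R)
  for (regime in c("plane_stress", "plane_strain")) {
    props <- elastic_properties(200, 0.3, regime)
    def <- suppressWarnings(deform_disk(tr, props))
    u <- disk_displacement(def, R, 0)
    u_exact <- if (regime == "plane_stress")
      p0 * (R * 1e-6) * (1 - 0.3) / 200 * 1e6
    else
      p0 * (R * 1e-6) * (1 + 0.3) * (1 - 2 * 0.3) / 200 * 1e6
    expect_equal(u$ur, u_exact, tolerance = 0.005)
    ## radial symmetry: no tangential motion, elongation is isotropic
    expect_lt(max(abs(disk_displacement(def, R, th)$ut)), 1e-12 * u_exact)
  }
})

test_that("displacement field is Hooke-consistent with the imposed traction", {
  ## independent check: differentiate the displacement numerically, apply
  ## Hooke's law, and compare the boundary stresses with the input traction
  tr <- random_traction(seed = 3)
  props <- elastic_properties(100, 0.49)
  def <- suppressWarnings(deform_disk(tr, props))
  r0 <- tr$R * (1 - 1e-3)
  hh <- 1e-4 * tr$R
  sig <- function(t) {
    u0 <- disk_displacement(def, r0, t)
    dur_dr <- (disk_displacement(def, r0 + hh, t)$ur -
                 disk_displacement(def, r0 - hh, t)$ur) / (2 * hh)
    dut_dr <- (disk_displacement(def, r0 + hh, t)$ut -
                 disk_displacement(def, r0 - hh, t)$ut) / (2 * hh)
    dur_dt <- (disk_displacement(def, r0, t + 1e-6)$ur -
                 disk_displacement(def, r0, t - 1e-6)$ur) / 2e-6
    dut_dt <- (disk_displacement(def, r0, t + 1e-6)$ut -
                 disk_displacement(def, r0, t - 1e-6)$ut) / 2e-6
    err <- dur_dr
    ett <- (dut_dt + u0$ur) / r0
    ert <- 0.5 * (dur_dt / r0 + dut_dr - u0$ut / r0)
    E <- props$youngs_modulus; nu <- props$poisson
    c(E / (1 - nu^2) * (err + nu * ett), E / (1 + nu) * ert)
  }
  ts <- stations_theta(24L)
  S <- vapply(ts, sig, numeric(2))
  fr_in <- approx(tr$stations$theta, tr$stations$fr, xout = ts)$y
  ft_in <- approx(tr$stations$theta, tr$stations$ft, xout = ts)$y
  expect_equal(S[1, ], fr_in, tolerance = 0.01)
  expect_equal(S[2, ], ft_in, tolerance = 0.01)
})

test_that("Betti reciprocity holds between independent load cases", {
  props <- elastic_properties(100, 0.49)
  tr1 <- random_traction(seed = 5)
  tr2 <- random_traction(seed = 8)
  def1 <- suppressWarnings(deform_disk(tr1, props))
  def2 <- suppressWarnings(deform_disk(tr2, props))
  w12 <- boundary_work(tr1, def2)
  w21 <- boundary_work(tr2, def1)
  expect_equal(w12, w21, tolerance = 1e-8)
})

test_that("elongation is the axis-projected mean tip displacement", {
  th <- stations_theta()
  R <- 4
  props <- elastic_properties(100, 0.49)
  ## zero traction: zero elongation
  z <- deform_disk(traction_from_samples(th, rep(0, 360), rep(0, 360), R),
                   props)
  expect_identical(elongation(z)$L_star, 0)
  ## uniform pressure tuned to produce u_tip = 0.8 um at R = 4 um
  p0 <- 0.8e-6 * 100 / ((1 - 0.49) * R * 1e-6)
  def <- suppressWarnings(deform_disk(
    traction_from_samples(th, p0 * cos(th), p0 * sin(th), R), props))
  el <- elongation(def)
  expect_equal(el$u_tip_um, 0.8, tolerance = 1e-9)
  expect_equal(el$L_star, 0.2, tolerance = 1e-9)
  expect_equal(el$L_um, 4.8, tolerance = 1e-9)
  ## the elongation axis can be rotated
  expect_equal(elongation(def, axis = c(0, 1))$L_star, 0.2,
               tolerance = 1e-9)
})

test_that("full pipeline on the uniform-field cylinder matches the closed form", {
  cyl <- cylinder_fixture()
  tr <- equilibrate_traction(surface_traction(cyl$sol, cyl$eps_m, cyl$eps_c))
  props <- elastic_properties(100, 0.49)
  def <- deform_disk(tr, props)
  el <- elongation(def)
  ## analytic elongation: Lame response to the n = 0 pressure plus the
  ## Michell n = 2 response, for traction eps_m beta E0^2 (1 + beta cos 2th)
  p0 <- cyl$eps_m * EPS0 * cyl$beta * cyl$E0^2
  p2 <- cyl$eps_m * EPS0 * cyl$beta^2 * cyl$E0^2
  nu <- 0.49; E <- 100
  mu <- E / (2 * (1 + nu)); kap <- (3 - nu) / (1 + nu)
  Rm <- cyl$R * 1e-6
  u_exact <- (p0 * Rm * (1 - nu) / E + p2 * Rm * (kap + 3) / (12 * mu)) * 1e6
  expect_equal(el$u_tip_um, u_exact, tolerance = 0.02)
  expect_gt(el$L_star, 0)  # stretching along the field
})
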