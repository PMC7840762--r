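## Shared, lazily built fixtures. Everything is generated in code; the
## heavier objects (field solutions, gamma tables) are cached for the test
## run so several test files can reuse them.

.fx_env <- new.env(parent = emptyenv())

fx <- function(name, build) {
  if (is.null(.fx_env[[name]])) .fx_env[[name]] <- build()
  .fx_env[[name]]
}

## coarse default-configuration simulation settings used across tests
coarse_config <- function(...) stretch_config(n_R = 8, ...)

## uniform-field harness: dielectric cylinder between parallel plates;
## plate separation 16 R keeps image corrections well below a percent
cylinder_fixture <- function(eps_c = 120, n_R = 20, R = 4, V = 10) {
  key <- sprintf("cyl_%g_%d_%g_%g", eps_c, n_R, R, V)
  fx(key, function() {
    pair <- electrode_pair(width = 1, gap = 16 * R, left = "plate")
    geom <- build_geometry(pair, R)
    sol <- solve_potential(geom, 80, eps_c, V, n_R = n_R)
    list(sol = sol, R = R, V = V, eps_m = 80, eps_c = eps_c,
         E0 = V / (16 * R * 1e-6),
         beta = (eps_c - 80) / (eps_c + 80))
  })
}

## coarse rect-rect field solution reused by field/maxwell tests
rectrect_solution <- function() {
  fx("rectrect_sol", function() {
    geom <- build_geometry(electrode_pair(30, 45), 4)
    solve_potential(geom, 80, 120, 10, n_R = 8)
  })
}

## equally spaced boundary stations
stations_theta <- function(K = 360L) 2 * pi * (seq_len(K) - 1L) / K

## a reproducible random self-equilibrated traction
random_traction <- function(seed = 1L, R = 4, K = 360L) {
  set.seed(seed)
  th <- stations_theta(K)
  fr <- ft <- rep(0, K)
  for (n in 2:6) {
    fr <- fr + stats::rnorm(1, sd = 20) * cos(n * th) +
      stats::rnorm(1, sd = 20) * sin(n * th)
    ft <- ft + stats::rnorm(1, sd = 20) * cos(n * th) +
      stats::rnorm(1, sd = 20) * sin(n * th)
  }
  equilibrate_traction(traction_from_samples(
    th, fr * cos(th) - ft * sin(th), fr * sin(th) + ft * cos(th), R))
}

## line integral of f . u around the disk boundary (work pairing)
boundary_work <- function(traction, def) {
  s <- traction$stations
  u <- disk_displacement(def, def$R, s$theta)
  dth <- 2 * pi / nrow(s)
  sum(s$fx * u$ux + s$fy * u$uy) * dth * def$R  # um-scaled, fine for ratios
}

## the shipped gamma table (read once)
shipped_gamma <- function() fx("shipped_gamma", default_gamma_table)

## small simulated gamma table at very coarse resolution
tiny_gamma <- function(V = 10) {
  key <- sprintf("tiny_gamma_%g", V)
  fx(key, function()
    build_gamma_table(R_grid = c(4, 6), d_grid = c(30, 60),
                      w_grid = c(20, 40),
                      base_config = stretch_config(n_R = 6, V = V),
                      reference = c(R = 4, d = 30, w = 20)))
}

## purely synthetic, exactly trilinear gamma table
linear_gamma <- function() {
  R <- c(4, 8); d <- c(20, 40); w <- c(10, 30)
  g <- array(0, c(2, 2, 2))
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    g[i, j, k] <- 0.2 + 0.05 * R[i] + 0.01 * (60 - d[j]) + 0.02 * w[k]
  gamma_table(R, d, w, g, reference = c(R = 4, d = 20, w = 10))
}
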