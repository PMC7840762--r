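test_that("trajectory files load with schema validation", {
  tab <- shipped_gamma()
  trajs <- synth_trajectories(
    S_true = c(pbmc = 2e-3), table = tab,
    conditions = data.frame(V = 8, w = 30, d = 45),
    n_cells = 16L, seed = 2L)
  expect_length(trajs, 16L)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_trajectories(trajs, path)
  back <- load_trajectories(path)
  expect_length(back, 16L)
  tr <- back[[1L]]
  expect_s3_class(tr, "dep_trajectory")
  expect_true(all(diff(tr$time) > 0))
  expect_true(all(is.finite(tr$elong)))
  expect_equal(tr$V, 8)

  ## missing mandatory columns are a schema error
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell_id\tt_s\telong_um", "a\t0\t0.1", "a\t1\t0.2"), bad)
  expect_error(load_trajectories(bad), "schema error")

  ## non-monotone time stamps are rejected with the offending cell named
  bad2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("cell_id,t_s,elong_um,V_pp,w_um,d_um,R_um",
               "c7,0,0.1,8,30,45,5", "c7,0,0.2,8,30,45,5"), bad2)
  expect_error(load_trajectories(bad2), "c7")
})

test_that("plateau detection matches the saturating-rise closed form", {
  ## constant trajectory: the plateau is the constant
  tr_const <- dep_trajectory(0:60, rep(1.5, 61), "k", R = 5)
  ss <- steady_state_elongation(tr_const)
  expect_equal(ss$L_plateau, 1.5)
  expect_equal(ss$L_star, 0.3)
  expect_true(ss$converged)

  ## L(t) = Linf (1 - exp(-t/tau)), tau = 10 s, 60 s record
  tt <- seq(0, 60, by = 0.5)
  tr_sat <- dep_trajectory(tt, 2 * (1 - exp(-tt / 10)), "s", R = 5)
  ss2 <- steady_state_elongation(tr_sat)
  expect_true(ss2$converged)
  expect_equal(ss2$L_plateau, 2, tolerance = 0.01)

  ## a pure ramp never saturates: flagged, not an error
  tr_ramp <- dep_trajectory(tt, 0.05 * tt, "r", R = 5)
  expect_false(steady_state_elongation(tr_ramp)$converged)

  ## records shorter than the window cannot be reduced
  expect_error(steady_state_elongation(
    dep_trajectory(0:5, rep(1, 6), "x", R = 5)), "window")
})

test_that("cycle summaries report planted recovery and degradation", {
  tt <- seq(0, 99, by = 1)
  phase <- rep(rep(c("on", "off"), each = 25), 2)
  ## perfectly elastic: rises to 2, falls back to 0 each cycle
  shape <- c(2 * (1 - exp(-(0:24) / 4)), 2 * exp(-(0:24) / 4))
  tr <- dep_trajectory(tt, rep(shape, 2), "e", R = 5, phase = phase)
  cs <- cycle_summary(tr)
  expect_equal(cs$n_cycles, 2L)
  expect_equal(cs$recovery, rep(1, 2), tolerance = 0.01)
  expect_equal(cs$peak_drop, 0, tolerance = 1e-9)

  ## plastic residual of 50 percent
  shape2 <- c(2 * (1 - exp(-(0:24) / 4)), 1 + 1 * exp(-(0:24) / 2))
  tr2 <- dep_trajectory(tt, rep(shape2, 2), "p", R = 5, phase = phase)
  cs2 <- cycle_summary(tr2)
  expect_equal(cs2$recovery, rep(0.5, 2), tolerance = 0.01)

  ## declining peaks across four cycles are detected as a positive drop
  tt4 <- seq(0, 199, by = 1)
  phase4 <- rep(rep(c("on", "off"), each = 25), 4)
  decl <- unlist(lapply(1:4, function(k) 0.8^(k - 1) * shape))
  tr4 <- dep_trajectory(tt4, decl, "d", R = 5, phase = phase4)
  cs4 <- cycle_summary(tr4)
  expect_equal(cs4$n_cycles, 4L)
  expect_gt(cs4$peak_drop, 0.4)

  ## recovery is invariant under rescaling of the elongation axis
  tr_scaled <- dep_trajectory(tt, 7.3 * rep(shape2, 2), "p2", R = 5,
                              phase = phase)
  expect_equal(cycle_summary(tr_scaled)$recovery, cs2$recovery)

  ## missing annotations are a contract error
  expect_error(cycle_summary(dep_trajectory(0:10, rep(1, 11), "n", R = 5)),
               "contract error")
})

test_that("noiseless fixtures return the planted S exactly through the full chain", {
  tab <- shipped_gamma()
  trajs <- synth_trajectories(
    S_true = c(erythrocyte = 4e-3, t47d = 8e-4), table = tab,
    conditions = expand.grid(V = 8, w = c(10, 50), d = c(20, 70)),
    n_cells = 3L, noise_cv = 0, noise_track_um = 0, seed = 5L)
  fit <- estimate_S(trajs, tab)
  pt <- fit$per_type
  expect_equal(pt$S_pooled[pt$type == "erythrocyte"], 4e-3,
               tolerance = 1e-3)
  expect_equal(pt$S_pooled[pt$type == "t47d"], 8e-4, tolerance = 1e-3)
})

test_that("synthetic fixtures are seeded and distributionally stable", {
  tab <- shipped_gamma()
  mk <- function(seed) synth_trajectories(
    S_true = c(pbmc = 2e-3), table = tab,
    conditions = data.frame(V = 8, w = 30, d = 45),
    n_cells = 12L, seed = seed)
  a1 <- mk(1L); a1b <- mk(1L); a2 <- mk(2L)
  expect_identical(a1[[1L]]$elong, a1b[[1L]]$elong)
  expect_false(identical(a1[[1L]]$elong, a2[[1L]]$elong))
  m1 <- mean(vapply(a1, function(t) max(t$elong), numeric(1)))
  m2 <- mean(vapply(a2, function(t) max(t$elong), numeric(1)))
  expect_equal(m1, m2, tolerance = 0.1)
})

test_that("single-cell groups are flagged by an undefined standard error", {
  tab <- shipped_gamma()
  trajs <- synth_trajectories(
    S_true = c(pbmc = 2e-3), table = tab,
    conditions = data.frame(V = 8, w = 30, d = 45),
    n_cells = 1L, noise_cv = 0, noise_track_um = 0, seed = 3L)
  fit <- estimate_S(trajs, tab)
  expect_true(is.na(fit$per_type$S_cell_se))
})
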